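#' Repeated-measures ANOVA
#'
#' Univariate repeated-measures ANOVA via `stats::aov` with an
#' `Error(subject/within)` stratum: one within-subject factor (e.g. day),
#' optionally one between-subject factor (e.g. phenotype), and their
#' interaction. Subjects missing any within-factor level are excluded with
#' a warning (the decomposition assumes complete data). No sphericity
#' correction is applied by default; Greenhouse-Geisser is available.
#'
#' @param data data frame.
#' @param response,subject,within,between column names (between may be
#'   NULL).
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the
#'   within-stratum tests.
#' @return data frame of class `rm_anova`: one row per effect with `effect`,
#'   `df1`, `df2`, `F`, `p`. The fitted `aov` object is attached as
#'   attribute `fit` for post hoc tests.
#' @export
rm_anova <- function(data, response, subject, within, between = NULL,
                     gg_correction = FALSE) {
  d <- data.frame(y = data[[response]],
                  subj = factor(data[[subject]]),
                  w = factor(data[[within]]))
  if (!is.null(between)) d$b <- factor(data[[between]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  # drop subjects missing any within level
  tab <- table(d$subj, d$w)
  bad <- rownames(tab)[apply(tab == 0, 1, any)]
  if (length(bad) > 0) {
    warning("rm_anova: excluded subject(s) missing within levels: ",
            paste(bad, collapse = ", "))
    d <- d[!(d$subj %in% bad), , drop = FALSE]
    d$subj <- droplevels(d$subj)
  }
  if (nlevels(d$w) < 2)
    stop("rm_anova: need at least 2 within-factor levels", call. = FALSE)
  # sum-to-zero contrasts: F tables are unchanged on balanced designs and
  # the fit can be reused directly for marginal-means post hoc tests
  old_c <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_c))
  if (!is.null(between)) {
    per_group <- table(unique(d[c("subj", "b")])$b)
    if (any(per_group < 2))
      stop("rm_anova: every group needs at least 2 subjects", call. = FALSE)
    fit <- stats::aov(y ~ b * w + Error(subj / w), data = d)
  } else {
    fit <- stats::aov(y ~ w + Error(subj / w), data = d)
  }
  sm <- summary(fit)
  rows <- list()
  grab <- function(stratum, label_map) {
    tb <- sm[[stratum]][[1]]
    for (nm in rownames(tb)) {
      key <- trimws(nm)
      if (key %in% names(label_map)) {
        Fv <- tb[nm, "F value"]
        pv <- tb[nm, "Pr(>F)"]
        if (tb[nm, "Sum Sq"] < 1e-12 * max(1, sum(tb[, "Sum Sq"]))) {
          # effect variance that is zero up to rounding (possibly with a
          # zero residual as well): define F = 0, p = 1
          Fv <- 0
          pv <- 1
        }
        rows[[length(rows) + 1]] <<- data.frame(
          effect = label_map[[key]],
          df1 = tb[nm, "Df"],
          df2 = tb["Residuals", "Df"],
          F = Fv,
          p = pv)
      }
    }
  }
  if (!is.null(between)) {
    grab("Error: subj", list(b = "between"))
    grab("Error: subj:w", list(w = "within", `b:w` = "interaction"))
  } else {
    grab("Error: subj:w", list(w = "within"))
  }
  out <- do.call(rbind, rows)
  if (gg_correction) {
    eps <- gg_epsilon(d)
    wi <- out$effect %in% c("within", "interaction")
    out$p[wi] <- stats::pf(out$F[wi], out$df1[wi] * eps, out$df2[wi] * eps,
                           lower.tail = FALSE)
    out$gg_epsilon <- ifelse(wi, eps, NA_real_)
  }
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "data") <- d
  class(out) <- c("rm_anova", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the subject x within-level response matrix
gg_epsilon <- function(d) {
  m <- tapply(d$y, list(d$subj, d$w), mean)
  S <- stats::cov(m, use = "complete.obs")
  k <- ncol(S)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * mean(rowMeans(S)^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Tukey post hoc comparisons after a repeated-measures ANOVA
#'
#' Pairwise comparisons over the levels of one effect of an [rm_anova()]
#' fit, adjusted with Tukey's honest-significant-difference method
#' (via estimated marginal means).
#'
#' @param anova an `rm_anova` object.
#' @param effect `"within"`, `"between"`, or `"interaction_by_within"` (the
#'   between-group contrast at each within level, i.e. the per-day
#'   group comparison).
#' @return data frame with `contrast`, (`level`,) `estimate`, `p_adj`.
#' @export
posthoc_tukey <- function(anova, effect = c("within", "between",
                                            "interaction_by_within")) {
  effect <- match.arg(effect)
  fit <- attr(anova, "fit")
  if (is.null(fit)) stop("posthoc_tukey: run rm_anova first", call. = FALSE)
  spec <- switch(effect,
                 within = ~w,
                 between = ~b,
                 interaction_by_within = ~b | w)
  nl <- function(v) nlevels(attr(anova, "data")[[v]])
  if (effect == "within" && nl("w") < 2 ||
      effect != "within" && is.null(attr(anova, "data")$b))
    stop("posthoc_tukey: effect has fewer than 2 levels", call. = FALSE)
  suppressMessages({
    emm <- emmeans::emmeans(fit, spec, data = attr(anova, "data"))
    prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                     adjust = "tukey"))
  })
  out <- data.frame(contrast = as.character(prs$contrast),
                    estimate = prs$estimate,
                    p_adj = prs$p.value)
  if (!is.null(prs$w)) out$level <- as.character(prs$w)
  rownames(out) <- NULL
  out
}

#' Two-sample t test
#'
#' Thin wrapper around `stats::t.test` (pooled variance by default, Welch
#' optional) with the degenerate-case convention that two zero-variance
#' samples with equal means give t = 0, p = 1.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param welch use the Welch unequal-variance form.
#' @return data frame: `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
group_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("group_ttest: each sample needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(data.frame(t = 0, df = length(a) + length(b) - 2, p = 1,
                        mean_a = mean(a), mean_b = mean(b),
                        sd_a = 0, sd_b = 0))
    stop("group_ttest: zero variance with unequal means", call. = FALSE)
  }
  h <- stats::t.test(a, b, var.equal = !welch)
  data.frame(t = unname(h$statistic), df = unname(h$parameter),
             p = h$p.value, mean_a = mean(a), mean_b = mean(b),
             sd_a = stats::sd(a), sd_b = stats::sd(b))
}

#' Tau-burden quantification from ROI grey levels
#'
#' For each region of interest a normal distribution is fitted to the grey
#' levels (maximum likelihood, i.e. sample mean and sd); ROI means are
#' averaged per animal and region, z-scored across animals within each
#' region (denominator n - 1) and sign-inverted, so that darker staining
#' (lower grey level, more tau) maps to a larger positive burden.
#'
#' @param rois data frame with columns `animal_id`, `region`, `roi`,
#'   `grey` (one row per pixel/grey-level sample), or a named list of
#'   numeric vectors (one region, one ROI per element, names = animal ids).
#' @param min_rois minimum ROIs required per animal and region.
#' @return list of class `tau_burden`: `roi` (per-ROI fitted mean/sd, with
#'   zero-sd ROIs flagged), `animal` (per animal x region mean grey and
#'   z-scored, sign-inverted `burden`).
#' @export
tau_burden <- function(rois, min_rois = 3) {
  if (is.list(rois) && !is.data.frame(rois)) {
    rois <- do.call(rbind, lapply(seq_along(rois), function(i)
      data.frame(animal_id = names(rois)[i], region = "region1", roi = i,
                 grey = rois[[i]])))
  }
  if (any(!is.finite(rois$grey)))
    stop("tau_burden: non-finite grey levels", call. = FALSE)
  key <- interaction(rois$animal_id, rois$region, rois$roi, drop = TRUE)
  roi_fit <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- rois[key == k, , drop = FALSE]
    s <- if (nrow(sub) > 1) stats::sd(sub$grey) else 0
    data.frame(animal_id = sub$animal_id[1], region = sub$region[1],
               roi = sub$roi[1], mean_grey = mean(sub$grey), sd_grey = s,
               flagged_constant = s == 0)
  }))
  if (any(roi_fit$flagged_constant))
    warning("tau_burden: ", sum(roi_fit$flagged_constant),
            " ROI(s) with zero grey-level variance (mean still used)")
  cnt <- stats::aggregate(roi ~ animal_id + region, data = roi_fit,
                          FUN = length)
  if (any(cnt$roi < min_rois))
    warning("tau_burden: fewer than ", min_rois,
            " ROIs for some animal/region")
  animal <- stats::aggregate(mean_grey ~ animal_id + region, data = roi_fit,
                             FUN = mean)
  animal$burden <- NA_real_
  for (r in unique(animal$region)) {
    i <- animal$region == r
    v <- animal$mean_grey[i]
    animal$burden[i] <- -(v - mean(v)) / stats::sd(v)
  }
  structure(list(roi = roi_fit, animal = animal), class = "tau_burden")
}

#' @export
print.tau_burden <- function(x, ...) {
  cat("Tau burden (z-scored, sign-inverted ROI grey levels)\n")
  print(x$animal, digits = 3)
  invisible(x)
}
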
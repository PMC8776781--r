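#' Build the per-reversal regression design for one animal
#'
#' Rows are stimulus reversals (pooled over days); regressors are `day`,
#' `block` (block number within the day), `speed` (epoch mean running
#' speed) and `pupil` (epoch mean normalised pupil area); the target is the
#' single-epoch VEP amplitude. Regressors and target are min-max normalised
#' to span exactly [0, 1]; constant columns cannot be normalised and raise
#' an error (target) or are flagged (regressors). Rows with any missing
#' value are dropped and counted.
#'
#' @param data data frame with columns `day`, `block_index`, `mean_speed`,
#'   `mean_pupil`, `amplitude` (one row per reversal).
#' @return object of class `design_matrix`: `X` (T x 4 matrix, columns
#'   day/block/speed/pupil), `y` (length-T target), `ranges` (original
#'   min/max per column, for un-normalising), `constant` (names of constant
#'   regressors, normalised to 0), `n_dropped`.
#' @export
build_design <- function(data) {
  need <- c("day", "block_index", "mean_speed", "mean_pupil", "amplitude")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("build_design: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw <- cbind(day = data$day, block = data$block_index,
               speed = data$mean_speed, pupil = data$mean_pupil,
               amplitude = data$amplitude)
  ok <- stats::complete.cases(raw)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("build_design: dropped %d row(s) with missing values",
                    n_drop))
  raw <- raw[ok, , drop = FALSE]
  if (nrow(raw) < 2)
    stop("build_design: fewer than 2 complete rows", call. = FALSE)
  rng <- apply(raw, 2, range)
  if (rng[1, "amplitude"] == rng[2, "amplitude"])
    stop("build_design: constant target; min-max normalisation undefined",
         call. = FALSE)
  constant <- character(0)
  norm <- sapply(colnames(raw), function(cn) {
    lo <- rng[1, cn]; hi <- rng[2, cn]
    if (hi == lo) {
      constant <<- c(constant, cn)
      rep(0, nrow(raw))
    } else (raw[, cn] - lo) / (hi - lo)
  })
  structure(list(X = norm[, c("day", "block", "speed", "pupil"),
                          drop = FALSE],
                 y = norm[, "amplitude"],
                 ranges = rng, constant = constant, n_dropped = n_drop),
            class = "design_matrix")
}

#' Fit the elastic-net regularisation path
#'
#' Solves, for every penalty `lambda_l` on a log-spaced grid,
#' \deqn{\min_{w, c} \frac{1}{2T}\|y - c - Xw\|^2 +
#'   \lambda_l\left(\alpha\|w\|_1 + \frac{1-\alpha}{2}\|w\|_2^2\right)}
#' The grid runs from the smallest lambda that zeroes every weight
#' (`lambda_max`, computed in closed form from the KKT conditions) down to
#' `lambda_min_ratio * lambda_max`. The default mixing `alpha = 2/3` fixes
#' the L1:L2 mixing ratio `alpha/(1-alpha)` at 2.
#'
#' Fitting is delegated to \pkg{glmnet}. glmnet standardises the response
#' internally, which silently rescales the effective L2 penalty by
#' `1/sd(y)`; the `(lambda, alpha)` passed down are adjusted so that the
#' objective above holds exactly in the units of `X` and `y` (verified in
#' the test suite against closed-form ridge and OLS limits).
#'
#' @param X design matrix (rows = reversals, columns = regressors).
#' @param y target vector.
#' @param L number of penalty values (grid length, >= 2; up to 10,000).
#' @param alpha elastic-net mixing in [0, 1]; `alpha = 0` is pure ridge,
#'   `alpha = 1` pure lasso.
#' @param lambda_min_ratio ratio of the smallest to the largest penalty.
#' @param lambda optional explicit penalty grid (overrides `L` and
#'   `lambda_min_ratio`).
#' @return object of class `enet_path`: `lambda` (decreasing), `beta`
#'   (p x L weight matrix), `a0` (intercepts), `alpha`, `lambda_max`, and
#'   the training data sums needed by [regressor_impact()].
#' @export
fit_enet_path <- function(X, y, L = 10000, alpha = 2 / 3,
                          lambda_min_ratio = 1e-4, lambda = NULL) {
  if (inherits(X, "design_matrix")) {
    y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n)
    stop("fit_enet_path: X and y sizes differ", call. = FALSE)
  if (is.null(lambda) && L < 2)
    stop("fit_enet_path: need at least 2 penalty values", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lambda_max <- max(abs(crossprod(Xc, yc))) / (n * max(alpha, 1e-3))
  # a hair above the KKT boundary, so the first path point is all-zero
  # in floating-point arithmetic too
  lambda_max <- lambda_max * (1 + 1e-9)
  if (is.null(lambda))
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = L))
  lambda <- sort(lambda, decreasing = TRUE)
  # undo glmnet's internal response standardisation: it scales the L2 (but
  # not the L1) penalty coefficient by 1/sd(y), sd taken with denominator n
  sy <- sqrt(mean(yc^2))
  lam_g <- lambda * (alpha + (1 - alpha) * sy)
  alpha_g <- lambda * alpha / lam_g
  if (max(alpha_g) - min(alpha_g) > 1e-12)
    stop("internal error: lambda-dependent alpha adjustment", call. = FALSE)
  # glmnet requires >= 2 columns; pad a null regressor when given one
  pad <- ncol(X) == 1
  Xfit <- if (pad) cbind(X, `.null.` = 0) else X
  fit <- glmnet::glmnet(Xfit, y, family = "gaussian", alpha = alpha_g[1],
                        lambda = lam_g, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12, maxit = 1e7)
  if (length(fit$lambda) != length(lambda))
    stop(sprintf("fit_enet_path: path did not converge (%d of %d penalties returned)",
                 length(fit$lambda), length(lambda)), call. = FALSE)
  beta <- as.matrix(fit$beta)
  if (pad) beta <- beta[1, , drop = FALSE]
  structure(list(lambda = lambda, beta = beta,
                 a0 = as.numeric(fit$a0), alpha = alpha,
                 lambda_max = lambda_max,
                 n = n, col_sums = colSums(X), y_mean = mean(y)),
            class = "enet_path")
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf("Elastic-net path: %d penalties (lambda %.3g .. %.3g), alpha = %.3f\n",
              length(x$lambda), x$lambda[1], x$lambda[length(x$lambda)],
              x$alpha))
  nz <- colSums(x$beta != 0)
  cat(sprintf("  active regressors: %d at lambda_max .. %d at lambda_min\n",
              nz[1], nz[length(nz)]))
  invisible(x)
}

#' @export
coef.enet_path <- function(object, ...) {
  rbind(`(intercept)` = object$a0, object$beta)
}

#' @export
predict.enet_path <- function(object, newx, ...) {
  sweep(as.matrix(newx) %*% object$beta, 2, object$a0, "+")
}

#' Per-regressor impact over the whole regularisation path
#'
#' The impact of regressor i is its summed contribution to the model
#' predictions across every reversal and every penalty on the path,
#' expressed as a percentage of the summed predictions:
#' \deqn{M(r_i) = \frac{\sum_{l=1}^{L}\sum_{t=1}^{T} w_{i,l}\, r_{i,t}}
#'   {\sum_{l=1}^{L}\sum_{t=1}^{T} \hat y_{l,t}} \times 100}
#' Because the double sums factorise
#' (\eqn{\sum_l\sum_t w_{i,l} r_{i,t} = (\sum_l w_{i,l})(\sum_t r_{i,t})}),
#' the metric is evaluated from the path coefficients and the column sums
#' of the design without materialising the L x T prediction matrix; a naive
#' double-loop oracle verifies the identity in the test suite.
#'
#' The denominator includes the intercept contribution by default; the
#' regressor-terms-only denominator is also reported (`impact_pct_reg_only`)
#' since either convention is defensible.
#'
#' @param path an `enet_path`.
#' @param X optionally, the design matrix the path was fit on (defaults to
#'   the column sums stored in the path object).
#' @return data frame of class `impact_table`: `regressor`, `impact_pct`,
#'   `impact_pct_reg_only`, `weight_sum` (sum of the regressor's path
#'   weights).
#' @export
regressor_impact <- function(path, X = NULL) {
  col_sums <- if (is.null(X)) path$col_sums else colSums(as.matrix(X))
  w_sums <- rowSums(path$beta)             # sum over l per regressor
  numer <- w_sums * col_sums               # sum_l sum_t w_il r_it
  Lp <- length(path$lambda)
  denom_int <- sum(path$a0) * path$n + sum(numer)
  denom_reg <- sum(numer)
  if (denom_int <= 0)
    stop("regressor_impact: degenerate denominator (sum of predictions <= 0)",
         call. = FALSE)
  out <- data.frame(regressor = rownames(path$beta),
                    impact_pct = 100 * numer / denom_int,
                    impact_pct_reg_only = if (abs(denom_reg) > 0)
                      100 * numer / denom_reg else NA_real_,
                    weight_sum = w_sums)
  rownames(out) <- NULL
  structure(out, intercept_share_pct = 100 * sum(path$a0) * path$n / denom_int,
            class = c("impact_table", "data.frame"))
}

#' Correlations between behaviour, time and potentiation
#'
#' Pearson correlations (with p values) for the three checks run on a
#' cohort's behaviour table: (i) behaviour (speed, pupil) against day,
#' (ii) percent time running on day d against the SRP increment on day
#' d + 1, (iii) an animal's mean activity against its total day-9 SRP.
#'
#' @param behaviour data frame with one row per animal-day: `animal_id`,
#'   `day`, `percent_running`, `mean_pupil`, and `delta_from_day1` (familiar
#'   stimulus).
#' @return data frame: `comparison`, `r`, `p`, `n`.
#' @export
behavior_day_correlations <- function(behaviour) {
  ct <- function(a, b, label) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3)
      stop("behavior_day_correlations: fewer than 3 pairs for ", label,
           call. = FALSE)
    h <- stats::cor.test(a[ok], b[ok])
    data.frame(comparison = label, r = unname(h$estimate), p = h$p.value,
               n = sum(ok))
  }
  rows <- list(
    ct(behaviour$mean_speed %||% behaviour$percent_running, behaviour$day,
       "speed vs day"),
    ct(behaviour$mean_pupil, behaviour$day, "pupil vs day"))
  # day-d running vs day-(d+1) SRP increment, within animal
  b <- behaviour[order(behaviour$animal_id, behaviour$day), , drop = FALSE]
  run_d <- srp_next <- numeric(0)
  for (a in unique(b$animal_id)) {
    sub <- b[b$animal_id == a, , drop = FALSE]
    if (nrow(sub) < 2) next
    i <- seq_len(nrow(sub) - 1)
    run_d <- c(run_d, sub$percent_running[i])
    srp_next <- c(srp_next, diff(sub$delta_from_day1))
  }
  rows <- c(rows, list(ct(run_d, srp_next, "running(day d) vs SRP gain(day d+1)")))
  last_day <- max(b$day)
  act <- stats::aggregate(percent_running ~ animal_id, data = b, FUN = mean)
  d9 <- b[b$day == last_day, c("animal_id", "delta_from_day1")]
  mrg <- merge(act, d9, by = "animal_id")
  rows <- c(rows, list(ct(mrg$percent_running, mrg$delta_from_day1,
                          "mean activity vs final-day SRP")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
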
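#' Daily averaged VEP amplitudes (SRP table)
#'
#' For each session and stimulus familiarity, averages the selected epochs
#' (average-then-metric: epochs are averaged into one waveform first, then
#' the trough/peak amplitude of that waveform is taken) and returns one row
#' per (animal, day, familiarity, state filter).
#'
#' @param sessions list of `recording_session` objects, or of prepared
#'   session summaries from [analyze_session()].
#' @param state_filter `"all"`, `"stationary"` or `"running"`.
#' @return data frame with `animal_id`, `group`, `phenotype`, `age`, `day`,
#'   `familiarity`, `state`, `amplitude` (uV), `n_epochs`. Sessions with no
#'   epoch surviving the filter yield an `NA` amplitude with a warning.
#' @export
daily_amplitudes <- function(sessions, state_filter = c("all", "stationary",
                                                        "running")) {
  state_filter <- match.arg(state_filter)
  rows <- lapply(sessions, function(s) {
    sm <- if (inherits(s, "session_summary")) s else analyze_session(s)
    sub <- sm$srp_rows[sm$srp_rows$state == state_filter, , drop = FALSE]
    sub
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(is.na(out$amplitude)))
    warning("daily_amplitudes: some sessions had no epochs after filtering; ",
            "amplitude set to NA")
  out
}

#' Change in VEP amplitude from day 1
#'
#' The change is computed within animal (and familiarity and state) before
#' any group averaging: `delta_from_day1 = amplitude(day) - amplitude(day 1)`.
#' Animals without a day-1 row for a given familiarity/state are excluded
#' with a warning.
#'
#' @param table an SRP table from [daily_amplitudes()].
#' @return object of class `srp_change`: list with `table` (per-animal rows
#'   plus `delta_from_day1`) and `group` (per group x day x familiarity x
#'   state mean, sem, n).
#' @export
srp_change <- function(table) {
  key <- interaction(table$animal_id, table$familiarity, table$state,
                     drop = TRUE)
  out <- NULL
  dropped <- character(0)
  for (k in levels(key)) {
    sub <- table[key == k, , drop = FALSE]
    d1 <- sub$amplitude[sub$day == 1]
    if (length(d1) != 1 || is.na(d1)) {
      dropped <- c(dropped, as.character(sub$animal_id[1]))
      next
    }
    sub$delta_from_day1 <- sub$amplitude - d1
    out <- rbind(out, sub)
  }
  if (length(dropped) > 0)
    warning("srp_change: no day-1 amplitude for ",
            paste(unique(dropped), collapse = ", "), "; excluded")
  if (is.null(out))
    stop("srp_change: no animal has a day-1 row", call. = FALSE)
  grp <- stats::aggregate(delta_from_day1 ~ group + day + familiarity + state,
                          data = out,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) /
                                                sqrt(length(v)),
                                              n = length(v)))
  grp <- cbind(grp[, c("group", "day", "familiarity", "state")],
               as.data.frame(grp$delta_from_day1))
  rownames(out) <- rownames(grp) <- NULL
  structure(list(table = out, group = grp), class = "srp_change")
}

#' @export
print.srp_change <- function(x, ...) {
  cat("Change in VEP amplitude from day 1 (group mean +- sem, uV)\n")
  print(x$group, digits = 3)
  invisible(x)
}

#' Within-block VEP amplitude timecourse
#'
#' Splits each block into consecutive non-overlapping bins of `step`
#' reversals, averages the epochs of each bin into one waveform and takes
#' that waveform's trough-to-peak amplitude (average-then-metric, matching
#' the averaged-VEP definition).
#'
#' @param epochs an `epoch_matrix` (labels must carry `block_index` and
#'   `reversal_index_in_block`).
#' @param step bin width in reversals (default 20).
#' @param familiarity optional familiarity filter.
#' @param state optional behavioural-state filter (`"stationary"` /
#'   `"running"`); requires a `state` label column. Bins left without any
#'   epoch are omitted.
#' @return data frame: `block_index`, `bin` (1-based), `bin_centre`
#'   (reversals, at `(bin - 0.5) * step`), `amplitude` (uV), `n_epochs`;
#'   attribute `step`.
#' @export
block_timecourse <- function(epochs, step = 20, familiarity = NULL,
                             state = NULL) {
  lab <- epochs$labels
  keep <- rep(TRUE, nrow(lab))
  if (!is.null(familiarity)) keep <- keep & lab$familiarity %in% familiarity
  if (!is.null(state)) {
    if (is.null(lab$state))
      stop("block_timecourse: no 'state' labels on these epochs",
           call. = FALSE)
    keep <- keep & lab$state %in% state
  }
  lab <- lab[keep, , drop = FALSE]
  ep <- epochs$epochs[keep, , drop = FALSE]
  if (nrow(lab) == 0)
    stop("block_timecourse: no epochs after filtering", call. = FALSE)
  if (max(lab$reversal_index_in_block) < step)
    stop("block_timecourse: blocks shorter than one bin", call. = FALSE)
  bin <- (lab$reversal_index_in_block - 1) %/% step + 1
  key <- interaction(lab$block_index, bin, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    w <- colMeans(ep[sel, , drop = FALSE])
    m <- compute_metrics(w, epochs$fs)
    data.frame(block_index = lab$block_index[sel][1],
               bin = bin[sel][1],
               bin_centre = (bin[sel][1] - 0.5) * step,
               amplitude = m$amplitude,
               n_epochs = sum(sel))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$block_index, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "step") <- step
  out
}

parse_block_set <- function(block_set) {
  switch(block_set,
         "2-10" = 2:10, "2-5" = 2:5, "6-10" = 6:10,
         stop("unknown block set: ", block_set, call. = FALSE))
}

#' Steady-state-subtracted within-block adaptation curve
#'
#' From a binned block timecourse (possibly pooled over several sessions:
#' extra grouping columns such as `animal_id`/`day` are respected), the mean
#' amplitude over each block's final `last_n` reversals is subtracted from
#' that block, the requested block set is selected, and the normalised
#' curves are averaged bin-wise.
#'
#' @param timecourse output of [block_timecourse()], optionally row-bound
#'   over sessions with `animal_id`/`day` columns added.
#' @param last_n steady-state window in reversals, counted from the block
#'   end (default 100).
#' @param block_set `"2-10"`, `"2-5"` or `"6-10"` (block 1 with its rising
#'   profile is always excluded), or an integer vector of block indices.
#' @return object of class `adaptation_curve`: data frame `bin`,
#'   `bin_centre`, `amplitude` (uV, steady state removed), `n_blocks`;
#'   attributes `step`, `last_n`, `block_set`.
#' @export
steady_state_subtract <- function(timecourse, last_n = 100,
                                  block_set = "2-10") {
  step <- attr(timecourse, "step") %||% 20
  blocks <- if (is.character(block_set)) parse_block_set(block_set) else
    block_set
  tc <- timecourse[timecourse$block_index %in% blocks, , drop = FALSE]
  if (nrow(tc) == 0)
    stop("steady_state_subtract: block set is empty", call. = FALSE)
  gcols <- intersect(c("animal_id", "day"), names(tc))
  key <- if (length(gcols))
    do.call(interaction, c(unname(tc[gcols]), list(tc$block_index),
                           drop = TRUE)) else
      factor(tc$block_index)
  n_rev <- max(tc$bin) * step
  if (last_n > n_rev)
    stop("steady_state_subtract: last_n exceeds the block length",
         call. = FALSE)
  tail_bins <- tc$bin_centre > n_rev - last_n
  tc$norm <- NA_real_
  for (k in levels(key)) {
    sel <- key == k
    tc$norm[sel] <- tc$amplitude[sel] - mean(tc$amplitude[sel & tail_bins])
  }
  agg <- stats::aggregate(norm ~ bin + bin_centre, data = tc,
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(bin = agg$bin, bin_centre = agg$bin_centre,
                    amplitude = agg$norm[, 1], n_blocks = agg$norm[, 2])
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, step = step, last_n = last_n,
            block_set = paste(range(blocks), collapse = "-"),
            class = c("adaptation_curve", "data.frame"))
}

# exact mean of exp(-(n-1)/tau) over the reversals of each bin; the curve
# is built from bin means, so this (not exp at the bin centre) is the
# matching regression basis
adapt_basis <- function(bin_centre, tau, step) {
  n0 <- bin_centre - step / 2 + 1  # first 1-based reversal of the bin
  exp(-(n0 - 1) / tau) * (1 - exp(-step / tau)) /
    (step * (1 - exp(-1 / tau)))
}

#' Fixed-tau exponential amplitude of an adaptation curve
#'
#' Least-squares amplitude of `A * exp(-(n - 1) / tau)` for fixed `tau`,
#' fitted to a 20-reversal-binned adaptation curve. Because the data are
#' bin means, the regression basis is the exact per-bin mean of the
#' exponential; the solution is the closed-form projection
#' `A = sum(y * b) / sum(b^2)`.
#'
#' @param curve an `adaptation_curve` (or data frame with `bin_centre` and
#'   `amplitude`; bin width from the `step` attribute, default 20).
#' @param tau_fixed time constant in reversals.
#' @return object of class `adaptation_fit`: `amplitude` (uV), `tau`,
#'   `rss` (uV^2), `n`.
#' @export
fit_adaptation_amplitude <- function(curve, tau_fixed) {
  if (tau_fixed <= 0)
    stop("fit_adaptation_amplitude: tau must be positive", call. = FALSE)
  step <- attr(curve, "step") %||% 20
  b <- adapt_basis(curve$bin_centre, tau_fixed, step)
  if (sum(b^2) < 1e-12)
    stop("fit_adaptation_amplitude: degenerate basis (all bins in the tail)",
         call. = FALSE)
  A <- sum(curve$amplitude * b) / sum(b^2)
  structure(list(amplitude = A, tau = tau_fixed,
                 rss = sum((curve$amplitude - A * b)^2),
                 n = nrow(curve)),
            class = "adaptation_fit")
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf("Adaptation fit: A = %.2f uV (tau fixed at %.2f reversals), rss = %.2f, n = %d bins\n",
              x$amplitude, x$tau, x$rss, x$n))
  invisible(x)
}

#' @export
coef.adaptation_fit <- function(object, ...) {
  c(amplitude = object$amplitude, tau = object$tau)
}

#' Pooled adaptation time constant
#'
#' Joint least-squares fit of `A * exp(-(n - 1) / tau)` over `(A, tau)` to a
#' grand-mean adaptation curve (all animals, days 2 to n-1, blocks 2-10):
#' for each candidate `tau` the amplitude has the closed form of
#' [fit_adaptation_amplitude()], and the profile is minimised over `tau` by
#' golden-section search. The returned `tau` is intended for reuse as the
#' fixed constant of the per-session fits.
#'
#' @param curve an `adaptation_curve` with at least 3 bins.
#' @param interval search interval for `tau` (reversals).
#' @return object of class `adaptation_fit` with fitted `amplitude`, `tau`,
#'   `rss`, `n`, plus `rss_null` (amplitude-zero residual) for judging
#'   whether the exponential explains anything.
#' @export
fit_pooled_tau <- function(curve, interval = c(0.5, 200)) {
  if (nrow(curve) < 3)
    stop("fit_pooled_tau: need at least 3 bins", call. = FALSE)
  step <- attr(curve, "step") %||% 20
  prof <- function(tau) {
    b <- adapt_basis(curve$bin_centre, tau, step)
    A <- sum(curve$amplitude * b) / sum(b^2)
    sum((curve$amplitude - A * b)^2)
  }
  opt <- stats::optimize(prof, interval, tol = 1e-8)
  if (!is.finite(opt$objective))
    stop("fit_pooled_tau: fit did not converge (non-finite residual); ",
         "inspect the curve for NA bins", call. = FALSE)
  if (min(abs(opt$minimum - interval)) < 1e-3 * diff(interval))
    warning(sprintf("fit_pooled_tau: tau estimate (%.2f) sits at the search boundary; the curve does not constrain an exponential decay",
                    opt$minimum))
  fit <- fit_adaptation_amplitude(
    structure(curve, step = step), opt$minimum)
  fit$rss_null <- sum(curve$amplitude^2)
  fit$tau <- opt$minimum
  fit
}

#' Saturating growth fit of an SRP day course
#'
#' Least-squares fit of `delta(d) = delta_max * (1 - exp(-(d - 1) / tau_d))`
#' to per-day change-from-day-1 values, profiling the amplitude in closed
#' form and searching `tau_d` by golden section. Summarises a potentiation
#' curve by its plateau change and growth time constant.
#'
#' @param day day indices.
#' @param delta change from day 1 (uV).
#' @param interval search interval for `tau_d` (days).
#' @return list: `delta_max` (uV), `tau_days`, `rss`.
#' @export
fit_srp_growth <- function(day, delta, interval = c(0.2, 30)) {
  ok <- is.finite(delta)
  day <- day[ok]; delta <- delta[ok]
  if (length(day) < 3)
    stop("fit_srp_growth: need at least 3 days", call. = FALSE)
  prof <- function(tau) {
    b <- 1 - exp(-(day - 1) / tau)
    A <- sum(delta * b) / sum(b^2)
    sum((delta - A * b)^2)
  }
  opt <- stats::optimize(prof, interval, tol = 1e-8)
  b <- 1 - exp(-(day - 1) / opt$minimum)
  A <- sum(delta * b) / sum(b^2)
  list(delta_max = A, tau_days = opt$minimum, rss = opt$objective)
}
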
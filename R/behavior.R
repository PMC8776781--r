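#' Convert cumulative wheel-encoder counts to running speed
#'
#' Instantaneous speed is `|delta count| / delta t * circumference /
#' resolution`, smoothed with a Gaussian kernel (default 50 ms window,
#' kernel sd = window / 4, truncated at +-2 sd). The rotation direction is
#' kept separately; `speed` is the non-negative magnitude.
#'
#' @param counts cumulative encoder counts.
#' @param timestamps seconds, strictly increasing, same length as `counts`.
#' @param circumference_cm wheel circumference.
#' @param resolution_counts_per_rev encoder resolution.
#' @param smooth_ms Gaussian smoothing window (0 disables smoothing).
#' @return data frame of class `speed_trace`: `time_s`, `speed` (cm/s, >= 0),
#'   `direction` (-1/0/+1 before smoothing).
#' @export
wheel_to_speed <- function(counts, timestamps, circumference_cm = 50,
                           resolution_counts_per_rev = 1024,
                           smooth_ms = 50) {
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("wheel_to_speed: timestamps must be strictly increasing",
         call. = FALSE)
  if (resolution_counts_per_rev <= 0)
    stop("wheel_to_speed: encoder resolution must be positive",
         call. = FALSE)
  dt <- diff(timestamps)
  dc <- diff(counts)
  inst <- c(0, abs(dc) / dt) * circumference_cm / resolution_counts_per_rev
  direction <- c(0, sign(dc))
  speed <- if (smooth_ms > 0) {
    dt_med <- stats::median(dt)
    sd_samp <- (smooth_ms / 1000 / 4) / dt_med
    half <- max(1L, ceiling(2 * sd_samp - 1e-9))
    k <- stats::dnorm(seq(-half, half), sd = sd_samp)
    k <- k / sum(k)
    sm <- as.numeric(stats::filter(c(rep(inst[1], half), inst,
                                     rep(inst[length(inst)], half)),
                                   k, sides = 2))
    sm[(half + 1):(half + length(inst))]
  } else inst
  structure(data.frame(time_s = timestamps, speed = pmax(speed, 0),
                       direction = direction),
            class = c("speed_trace", "data.frame"))
}

#' Remove blinks from a raw pupil trace
#'
#' A sample is flagged as a blink when its eye position deviates from the
#' (robust) centre by more than `criterion` standard deviations on either
#' coordinate: `|x - median(x)| > criterion * sd(x)`, likewise for y.
#' Flagged samples are replaced -- position and area alike -- by the values
#' of the nearest unflagged sample. A trace that has already been cleaned
#' passes through unchanged, so the operation is idempotent.
#'
#' @param pupil data frame with `time_s`, `x_px`, `y_px`, `area_px2`.
#' @param criterion deviation criterion in sd units (default 2).
#' @return data frame of class `pupil_trace` with cleaned columns and a
#'   logical `blink_mask` column marking the replaced samples.
#' @export
remove_blinks <- function(pupil, criterion = 2) {
  if (inherits(pupil, "pupil_trace")) return(pupil)
  if (nrow(pupil) < 10)
    stop("remove_blinks: need at least 10 samples", call. = FALSE)
  dev <- function(v) abs(v - stats::median(v)) > criterion * stats::sd(v)
  mask <- dev(pupil$x_px) | dev(pupil$y_px)
  if (all(mask))
    stop("remove_blinks: every sample flagged; criterion too strict",
         call. = FALSE)
  out <- pupil
  if (any(mask)) {
    good <- which(!mask)
    bad <- which(mask)
    # nearest unmasked neighbour
    nn <- good[pmax(1, findInterval(bad, good))]
    right <- pmin(length(good), findInterval(bad, good) + 1)
    use_right <- abs(good[right] - bad) < abs(nn - bad)
    nn[use_right] <- good[right][use_right]
    for (col in c("x_px", "y_px", "area_px2"))
      out[[col]][bad] <- out[[col]][nn]
  }
  out$blink_mask <- mask
  class(out) <- c("pupil_trace", "data.frame")
  out
}

#' Normalise pupil area to a pre-stimulus baseline
#'
#' Two baseline conventions are implemented because both occur in this kind
#' of protocol: `"pre2min"` divides by the mean area in the 2 minutes of
#' grey screen before the first stimulus onset; `"stationary12s"` divides by
#' the mean area over stationary samples in the 12 s before onset (used for
#' event-triggered pupil responses, where running-driven dilation must not
#' contaminate the baseline).
#'
#' @param area pupil area values (any consistent unit; normalisation is
#'   scale-invariant).
#' @param time_s sample times.
#' @param stimulus_onset_s onset of the first stimulus block.
#' @param baseline `"pre2min"` or `"stationary12s"`.
#' @param state optional per-sample `"stationary"`/`"running"` labels
#'   (required for `"stationary12s"`).
#' @param baseline_s length of the pre-onset window for each convention.
#' @return normalised area (baseline mean = 1), with attribute
#'   `baseline_mean`.
#' @export
normalise_pupil <- function(area, time_s, stimulus_onset_s,
                            baseline = c("pre2min", "stationary12s"),
                            state = NULL,
                            baseline_s = NULL) {
  baseline <- match.arg(baseline)
  win <- baseline_s %||% if (baseline == "pre2min") 120 else 12
  sel <- time_s >= stimulus_onset_s - win & time_s < stimulus_onset_s
  if (!any(sel))
    stop("normalise_pupil: no samples in the baseline window", call. = FALSE)
  if (baseline == "stationary12s") {
    if (is.null(state))
      stop("normalise_pupil: 'stationary12s' baseline needs state labels",
           call. = FALSE)
    sel <- sel & state == "stationary"
    if (!any(sel))
      stop("normalise_pupil: no stationary samples in the baseline window",
           call. = FALSE)
  }
  m <- mean(area[sel])
  if (!is.finite(m) || m <= 0)
    stop("normalise_pupil: baseline mean must be positive", call. = FALSE)
  structure(area / m, baseline_mean = m)
}

#' Classify the behavioural state of each reversal epoch
#'
#' Epoch mean speed over `[t_rev, t_rev + period)`; an epoch is `"running"`
#' when its mean speed exceeds the threshold and `"stationary"` otherwise
#' (a mean speed exactly at the threshold counts as stationary). Epochs not
#' fully covered by the speed trace are labelled `NA` and reported.
#'
#' @param speed a `speed_trace` (or data frame with `time_s`, `speed`).
#' @param events reversal events (`time_s` column).
#' @param period epoch length, seconds.
#' @param threshold_cm_s running threshold (default 1 cm/s).
#' @return data frame: events joined with `mean_speed` and `state`.
#' @export
classify_state <- function(speed, events, period, threshold_cm_s = 1) {
  t <- speed$time_s
  v <- speed$speed
  dt <- stats::median(diff(t))
  eps <- 1e-9
  i_lo <- findInterval(events$time_s - eps, t) + 1  # first sample >= t0
  i_hi <- findInterval(events$time_s + period - eps, t)  # last sample < t0+period
  cs <- c(0, cumsum(v))
  covered <- i_lo <= i_hi & events$time_s >= t[1] - eps &
    events$time_s + period <= t[length(t)] + dt + eps
  mean_speed <- ifelse(covered,
                       (cs[pmin(i_hi, length(v)) + 1] - cs[pmax(i_lo, 1)]) /
                         pmax(i_hi - i_lo + 1, 1),
                       NA_real_)
  n_miss <- sum(is.na(mean_speed))
  if (n_miss > 0)
    message(sprintf("classify_state: %d epoch(s) outside speed coverage labelled missing",
                    n_miss))
  out <- events
  out$mean_speed <- mean_speed
  out$state <- ifelse(is.na(mean_speed), NA_character_,
                      ifelse(mean_speed > threshold_cm_s, "running",
                             "stationary"))
  out
}

#' Event-triggered behavioural responses
#'
#' Aligns a trace (normalised pupil area, speed, ...) to a set of onsets,
#' subtracts the per-onset pre-event baseline mean and returns the aligned
#' traces with their mean and standard error.
#'
#' @param trace sample values.
#' @param time_s sample times.
#' @param onsets event times (seconds).
#' @param window_s c(pre, post) window around each onset, e.g. `c(-12, 30)`.
#' @param baseline_s length of the pre-onset baseline subtracted from each
#'   aligned trace (0 disables baseline referencing).
#' @return list: `time` (relative to onset), `responses` (onsets x samples),
#'   `mean`, `sem`, `n`.
#' @export
event_triggered_response <- function(trace, time_s, onsets,
                                     window_s = c(-12, 30),
                                     baseline_s = 12) {
  dt <- stats::median(diff(time_s))
  rel <- seq(window_s[1], window_s[2], by = dt)
  # index-based baseline selection avoids floating-point leakage of the
  # onset sample into the pre-onset window
  i0 <- which.min(abs(rel))
  bl_idx <- which(rel >= -baseline_s - dt / 2 & seq_along(rel) < i0)
  rows <- lapply(onsets, function(t0) {
    tt <- t0 + rel
    if (tt[1] < time_s[1] - dt / 2 ||
        tt[length(tt)] > time_s[length(time_s)] + dt / 2)
      return(NULL)
    y <- stats::approx(time_s, trace, xout = tt, rule = 1)$y
    if (baseline_s > 0 && length(bl_idx) > 0)
      y <- y - mean(y[bl_idx])
    y
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    stop("event_triggered_response: no onset with full window coverage",
         call. = FALSE)
  m <- do.call(rbind, rows)
  list(time = rel, responses = m, mean = colMeans(m),
       sem = apply(m, 2, stats::sd) / sqrt(nrow(m)), n = nrow(m))
}

#' Percentage of stimulus-presentation time spent running
#'
#' Fraction of speed samples that fall inside a stimulus block and exceed
#' the running threshold, as a percentage.
#'
#' @param speed a `speed_trace`.
#' @param events reversal events (used to delimit the blocks).
#' @param period reversal period (the last reversal of a block extends the
#'   block by one period).
#' @param threshold_cm_s running threshold.
#' @return percentage in `[0, 100]`.
#' @export
percent_time_running <- function(speed, events, period,
                                 threshold_cm_s = 1) {
  in_block <- rep(FALSE, length(speed$time_s))
  for (b in unique(events$block_index)) {
    tb <- events$time_s[events$block_index == b]
    in_block <- in_block |
      (speed$time_s >= tb[1] & speed$time_s < tb[length(tb)] + period)
  }
  if (!any(in_block)) return(0)
  100 * mean(speed$speed[in_block] > threshold_cm_s)
}
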
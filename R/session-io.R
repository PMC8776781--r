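#' Write a recording session to a directory
#'
#' Layout: `meta.json` (ids, labels, schedule, rates), `lfp.bin`
#' (little-endian 32-bit float, uV) with `lfp.json` sidecar (sampling rate,
#' sample count, units), `events.csv`, `wheel.csv`, `pupil.csv`, and --
#' only when ground truth is supplied -- `truth.csv`. Ground truth is kept
#' in a separate file so analysis code can load a session without ever
#' seeing it.
#'
#' @param session a `recording_session`.
#' @param dir output directory (created if missing).
#' @param truth optional ground-truth data frame (from [simulate_session()]).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # serialise doubles with 17 significant digits so CSV columns re-read
  # to the identical IEEE-754 value
  write.csv <- function(d, file, ...) {
    for (cn in names(d))
      if (is.double(d[[cn]]))
        d[[cn]] <- sub("^\\s+", "", formatC(d[[cn]], digits = 17,
                                            format = "g"))
    utils::write.csv(d, file, ...)
  }
  jsonlite::write_json(session$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "lfp.bin"), "wb")
  writeBin(as.numeric(session$lfp), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(sampling_rate = session$fs,
                            n_samples = length(session$lfp),
                            units = "uV", dtype = "float32le"),
                       file.path(dir, "lfp.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(session$events, file.path(dir, "events.csv"),
            row.names = FALSE)
  write.csv(session$wheel, file.path(dir, "wheel.csv"),
            row.names = FALSE)
  write.csv(session$pupil, file.path(dir, "pupil.csv"),
            row.names = FALSE)
  if (!is.null(truth))
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a recording session from a directory
#'
#' Inverse of [write_session()] (the LFP is stored as 32-bit floats, so a
#' float32 session round-trips bit-exactly). Ground truth, if present, is
#' deliberately not loaded; use [read_truth()].
#'
#' Validates on load: event times must be strictly increasing and fall
#' inside the recording, and the LFP must be free of non-finite values.
#'
#' @param dir session directory.
#' @return a `recording_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  side <- jsonlite::read_json(file.path(dir, "lfp.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "lfp.bin"), "rb")
  lfp <- readBin(con, "numeric", n = side$n_samples, size = 4,
                 endian = "little")
  close(con)
  if (any(!is.finite(lfp)))
    stop("read_session: LFP contains non-finite values", call. = FALSE)
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  if (is.unsorted(events$time_s, strictly = TRUE))
    stop("read_session: event times must be strictly increasing",
         call. = FALSE)
  if (any(events$time_s < 0) ||
      any(events$time_s >= length(lfp) / side$sampling_rate))
    stop("read_session: event times outside the recording", call. = FALSE)
  structure(list(
    lfp = lfp, fs = side$sampling_rate, events = events,
    wheel = utils::read.csv(file.path(dir, "wheel.csv")),
    pupil = utils::read.csv(file.path(dir, "pupil.csv")),
    meta = meta), class = "recording_session")
}

#' Read the ground truth of a simulated session directory
#' @param dir session directory.
#' @return data frame, or NULL when no truth file exists.
#' @export
read_truth <- function(dir) {
  f <- file.path(dir, "truth.csv")
  if (!file.exists(f)) return(NULL)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

# design the anti-alias lowpass for one decimation stage: 8th-order
# Chebyshev type I, 0.01 dB passband ripple, corner at 0.4 x output Nyquist.
# 0.01 dB keeps the squared (forward-backward) passband ripple below 0.5%.
decim_filter <- function(factor) {
  signal::cheby1(8, 0.01, 0.4 / factor)
}

#' Lowpass-filter and downsample an LFP trace
#'
#' Anti-alias filtering uses an 8th-order Chebyshev type I lowpass applied
#' forward-backward (zero phase, so trough/peak latencies are not shifted),
#' followed by sample picking. Decimation factors above 10 are split into
#' stages of at most 10 to keep the filter numerically well conditioned.
#'
#' @param x uV series.
#' @param fs_in,fs_out input/output sampling rates; `fs_in / fs_out` must be
#'   an integer.
#' @return uV series at `fs_out`, length `floor(length(x) * fs_out / fs_in)`.
#' @export
decimate_lfp <- function(x, fs_in, fs_out) {
  if (fs_in < fs_out)
    stop("decimate_lfp: fs_out must not exceed fs_in", call. = FALSE)
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("decimate_lfp: fs_in/fs_out must be an integer; ",
         "resample to an integer multiple of the target rate first",
         call. = FALSE)
  ratio <- round(ratio)
  if (ratio == 1) return(x)
  factors <- integer(0)
  r <- ratio
  while (r > 10) {
    f <- max(Filter(function(k) r %% k == 0, 2:10))
    factors <- c(factors, f)
    r <- r / f
  }
  factors <- c(factors, r)
  for (f in factors) {
    flt <- decim_filter(f)
    x <- filtfilt_zp(flt, x)[seq(1, length(x), by = f)]
  }
  x
}

#' Band-pass filter an LFP trace for VEP analysis
#'
#' Second-order Butterworth band-pass (0.3--50 Hz by default) applied
#' forward-backward (zero phase). Removes the DC level and slow drift while
#' preserving VEP deflection latencies.
#'
#' @param x uV series.
#' @param fs sampling rate, Hz (> 100).
#' @param low,high band edges, Hz.
#' @return filtered uV series.
#' @export
bandpass_vep <- function(x, fs, low = 0.3, high = 50) {
  if (fs <= 100)
    stop("bandpass_vep: sampling rate must exceed 100 Hz", call. = FALSE)
  flt <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  if (length(x) <= 3 * (length(flt$a) - 1) * 2)
    stop("bandpass_vep: signal shorter than the filter warm-up", call. = FALSE)
  filtfilt_zp(flt, x)
}

#' Detect stimulus reversals from a photodiode/sync channel
#'
#' One event per rising threshold crossing, with hysteresis: after a rising
#' crossing of the upper threshold the signal must fall below the lower
#' threshold before another event can be registered. Block boundaries are
#' inferred from inter-event gaps longer than `gap_factor` reversal periods.
#'
#' @param sync sync-channel samples.
#' @param fs sampling rate, Hz.
#' @param threshold upper threshold (default midway between the observed
#'   extremes); the lower threshold sits 10% of the signal range below it.
#' @param period expected reversal period, seconds (for block splitting).
#' @param gap_factor gaps longer than `gap_factor * period` start a new
#'   block.
#' @param expected_n optional expected event count; a mismatch raises a
#'   warning with both counts.
#' @return data frame with `time_s`, `block_index`, `reversal_index_in_block`.
#' @export
detect_reversals <- function(sync, fs, threshold = NULL,
                             period = 1 / 1.95, gap_factor = 5,
                             expected_n = NULL) {
  rng <- range(sync)
  if (is.null(threshold)) threshold <- mean(rng)
  lo <- threshold - 0.1 * diff(rng)
  above <- sync >= threshold
  below_lo <- sync < lo
  cand <- which(above & !c(TRUE, above[-length(above)]))  # rising transitions
  # hysteresis: keep a crossing only if the signal dipped below the lower
  # threshold since the previously kept crossing
  n_below <- cumsum(below_lo)
  idx <- integer(length(cand))
  k <- 0L
  last <- NA_integer_
  for (i in cand) {
    if (is.na(last) || n_below[i] > n_below[last]) {
      k <- k + 1L
      idx[k] <- i
      last <- i
    }
  }
  idx <- idx[seq_len(k)]
  if (length(idx) == 0)
    stop("detect_reversals: no threshold crossings found", call. = FALSE)
  t <- (idx - 1) / fs
  newblock <- c(TRUE, diff(t) > gap_factor * period)
  blk <- cumsum(newblock)
  rev_in <- stats::ave(blk, blk, FUN = seq_along)
  if (!is.null(expected_n) && expected_n != length(t))
    warning(sprintf("detect_reversals: %d events detected, %d expected",
                    length(t), expected_n))
  data.frame(time_s = t, block_index = blk,
             reversal_index_in_block = rev_in)
}

#' Slice an LFP trace into reversal-aligned epochs
#'
#' Epoch i holds the samples in the half-open window
#' `[time_i, time_i + period)`, time 0 at the reversal event. Epochs that
#' would run past the end of the recording are dropped (counted in the
#' `n_dropped` attribute, with a message).
#'
#' @param x uV series (typically band-passed).
#' @param fs sampling rate, Hz.
#' @param events reversal events (data frame with `time_s` and, if
#'   available, block/reversal/familiarity labels, carried through).
#' @param period epoch length in seconds.
#' @return an `epoch_matrix`: list with `epochs` (n_reversals x n_samples
#'   matrix), `time_s` (epoch time axis, starts at 0), `labels` (per-epoch
#'   event rows), `fs`.
#' @export
epoch_lfp <- function(x, fs, events, period) {
  nsamp <- floor(period * fs)
  # the 1e-6-sample guard keeps events lying exactly on the sample grid
  # from flooring one sample early through floating-point error
  start <- floor(events$time_s * fs + 1e-6) + 1
  keep <- start + nsamp - 1 <= length(x) & start >= 1
  n_drop <- sum(!keep)
  if (!any(keep))
    stop("epoch_lfp: no epoch fits inside the recording", call. = FALSE)
  if (n_drop > 0)
    message(sprintf("epoch_lfp: dropped %d epoch(s) overlapping the recording end",
                    n_drop))
  start <- start[keep]
  idx <- outer(start, 0:(nsamp - 1), "+")
  ep <- matrix(x[idx], nrow = length(start), ncol = nsamp)
  structure(list(epochs = ep,
                 time_s = (0:(nsamp - 1)) / fs,
                 labels = events[keep, , drop = FALSE],
                 fs = fs,
                 n_dropped = n_drop),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("Epoch matrix: %d epochs x %d samples (%.0f ms @ %g Hz)\n",
              nrow(x$epochs), ncol(x$epochs),
              1000 * ncol(x$epochs) / x$fs, x$fs))
  if (x$n_dropped > 0) cat(sprintf("  %d epoch(s) dropped\n", x$n_dropped))
  invisible(x)
}
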
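#' Average epochs into one VEP waveform
#'
#' Pointwise mean over a selection of epochs. Selection can combine
#' familiarity, block indices and behavioural-state labels (a `state`
#' column must have been joined onto the epoch labels, e.g. by
#' [classify_state()]), or be given directly as a logical/integer vector.
#'
#' @param epochs an `epoch_matrix`.
#' @param familiarity optional `"familiar"`/`"unfamiliar"`.
#' @param blocks optional block indices to keep.
#' @param state optional `"stationary"`/`"running"`.
#' @param which optional logical or integer row selector (applied after the
#'   label filters).
#' @return numeric waveform (uV) with attributes `fs`, `time_s` and
#'   `n_epochs` (number averaged).
#' @export
average_vep <- function(epochs, familiarity = NULL, blocks = NULL,
                        state = NULL, which = NULL) {
  keep <- rep(TRUE, nrow(epochs$epochs))
  lab <- epochs$labels
  if (!is.null(familiarity)) keep <- keep & lab$familiarity %in% familiarity
  if (!is.null(blocks)) keep <- keep & lab$block_index %in% blocks
  if (!is.null(state)) {
    if (is.null(lab$state))
      stop("average_vep: no 'state' labels on these epochs", call. = FALSE)
    keep <- keep & lab$state %in% state
  }
  if (!is.null(which)) {
    w <- rep(FALSE, length(keep))
    w[which] <- TRUE
    keep <- keep & w
  }
  if (!any(keep))
    stop(sprintf("average_vep: empty selection (familiarity=%s, blocks=%s, state=%s)",
                 paste(familiarity %||% "any", collapse = "/"),
                 paste(blocks %||% "any", collapse = ","),
                 paste(state %||% "any", collapse = "/")), call. = FALSE)
  w <- colMeans(epochs$epochs[keep, , drop = FALSE])
  structure(w, fs = epochs$fs, time_s = epochs$time_s,
            n_epochs = sum(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-max crossing by linear interpolation, scanning outward from an
# extremum; returns NA when the deflection never returns to half inside
# the waveform
half_cross <- function(w, t, i_ext, half, direction) {
  sgn <- sign(w[i_ext])
  idx <- if (direction < 0) rev(seq_len(i_ext - 1)) else
    seq(i_ext + 1, length(w))
  if (i_ext == 1 && direction < 0) return(NA_real_)
  if (i_ext == length(w) && direction > 0) return(NA_real_)
  for (i in idx) {
    if (sgn * w[i] <= sgn * half) {
      j <- i - direction  # neighbour still above half
      frac <- (half - w[j]) / (w[i] - w[j])
      return(t[j] + frac * (t[i] - t[j]))
    }
  }
  NA_real_
}

#' VEP waveform metrics
#'
#' Trough = minimum in the first 150 ms after the reversal; peak = maximum
#' in the first 250 ms; amplitude = peak minus trough. Ties are broken by
#' the earliest sample. Full width at half maximum is computed per
#' deflection at half of that deflection's extremum relative to 0 uV (the
#' signal is assumed band-passed and zero-mean), with linear interpolation
#' at the crossings; if a deflection never returns to half inside the
#' waveform its FWHM is `NA`. The decay slope is the least-squares slope of
#' the waveform from the peak to the first return to half the peak value
#' (capped at the waveform end).
#'
#' @param waveform uV vector covering at least 250 ms.
#' @param sampling_rate Hz (taken from the waveform's `fs` attribute when
#'   omitted).
#' @param trough_window_ms,peak_window_ms search windows (defaults 150/250).
#' @return object of class `vep_metrics`: `trough_amp`, `peak_amp`,
#'   `amplitude`, `t_trough`, `t_peak` (ms), `fwhm_trough`, `fwhm_peak`
#'   (ms), `decay_slope` (uV/ms), `n_epochs_averaged`.
#' @export
compute_metrics <- function(waveform, sampling_rate = NULL,
                            trough_window_ms = 150, peak_window_ms = 250) {
  fs <- sampling_rate %||% attr(waveform, "fs")
  if (is.null(fs)) stop("compute_metrics: sampling rate unknown",
                        call. = FALSE)
  if (any(!is.finite(waveform)))
    stop("compute_metrics: waveform contains non-finite values",
         call. = FALSE)
  n <- length(waveform)
  if (n < ceiling(peak_window_ms / 1000 * fs))
    stop(sprintf("compute_metrics: waveform must cover at least %g ms",
                 peak_window_ms), call. = FALSE)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  w_tr <- which(t_ms <= trough_window_ms)
  w_pk <- which(t_ms <= peak_window_ms)
  i_tr <- w_tr[which.min(waveform[w_tr])]   # which.min: earliest tie wins
  i_pk <- w_pk[which.max(waveform[w_pk])]
  trough <- waveform[i_tr]
  peak <- waveform[i_pk]
  w <- as.numeric(waveform)
  fwhm <- function(i_ext) {
    half <- w[i_ext] / 2
    a <- half_cross(w, t_ms, i_ext, half, -1L)
    b <- half_cross(w, t_ms, i_ext, half, +1L)
    if (is.na(a) || is.na(b)) NA_real_ else b - a
  }
  # decay slope: peak to first return to half-peak (or waveform end)
  ret <- half_cross(w, t_ms, i_pk, peak / 2, +1L)
  i_end <- if (is.na(ret)) n else max(i_pk + 1, which(t_ms <= ret)[sum(t_ms <= ret)])
  slope <- if (i_end > i_pk) {
    seg_t <- t_ms[i_pk:i_end]
    seg_w <- w[i_pk:i_end]
    sum((seg_t - mean(seg_t)) * (seg_w - mean(seg_w))) /
      sum((seg_t - mean(seg_t))^2)
  } else NA_real_
  structure(list(
    trough_amp = trough, peak_amp = peak, amplitude = peak - trough,
    t_trough = t_ms[i_tr], t_peak = t_ms[i_pk],
    fwhm_trough = if (trough < 0) fwhm(i_tr) else NA_real_,
    fwhm_peak = if (peak > 0) fwhm(i_pk) else NA_real_,
    decay_slope = slope,
    n_epochs_averaged = attr(waveform, "n_epochs") %||% 1L),
    class = "vep_metrics")
}

#' @export
print.vep_metrics <- function(x, ...) {
  cat(sprintf("VEP metrics (n = %d epochs averaged)\n", x$n_epochs_averaged))
  cat(sprintf("  trough %.1f uV @ %.0f ms; peak %.1f uV @ %.0f ms; amplitude %.1f uV\n",
              x$trough_amp, x$t_trough, x$peak_amp, x$t_peak, x$amplitude))
  cat(sprintf("  FWHM trough %.1f ms, peak %.1f ms; decay slope %.3f uV/ms\n",
              x$fwhm_trough, x$fwhm_peak, x$decay_slope))
  invisible(x)
}

#' Per-reversal (single-epoch) VEP amplitudes
#'
#' Applies the trough/peak definition of [compute_metrics()] to every epoch
#' row: trough = row minimum within the first 150 ms, peak = row maximum
#' within the first 250 ms, amplitude = peak - trough. Vectorised over rows;
#' the windows are identical to those used for averaged waveforms.
#'
#' @param epochs an `epoch_matrix`.
#' @param trough_window_ms,peak_window_ms search windows.
#' @return data frame: per-epoch labels joined with `amplitude`,
#'   `trough_amp`, `peak_amp` (uV).
#' @export
single_epoch_amplitudes <- function(epochs, trough_window_ms = 150,
                                    peak_window_ms = 250) {
  t_ms <- epochs$time_s * 1000
  if (max(t_ms) + 1000 / epochs$fs < peak_window_ms)
    stop(sprintf("single_epoch_amplitudes: epochs must cover at least %g ms",
                 peak_window_ms), call. = FALSE)
  if (any(!is.finite(epochs$epochs)))
    stop("single_epoch_amplitudes: epochs contain non-finite values",
         call. = FALSE)
  tr_cols <- which(t_ms <= trough_window_ms)
  pk_cols <- which(t_ms <= peak_window_ms)
  trough <- do.call(pmin, as.data.frame(epochs$epochs[, tr_cols,
                                                      drop = FALSE]))
  peak <- do.call(pmax, as.data.frame(epochs$epochs[, pk_cols,
                                                    drop = FALSE]))
  out <- epochs$labels
  out$trough_amp <- trough
  out$peak_amp <- peak
  out$amplitude <- peak - trough
  rownames(out) <- NULL
  out
}
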
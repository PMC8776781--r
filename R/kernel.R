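#' Evaluate the analytic VEP template at arbitrary times
#'
#' The template is a piecewise smoothstep curve through the anchor points
#' (onset, 0) -> (trough latency, trough amplitude) -> (peak latency, peak
#' amplitude) -> (offset, 0), with zero slope at every anchor. The extrema
#' therefore fall exactly on the anchors: the unique minimum equals the
#' trough amplitude at the trough latency and the unique maximum equals the
#' peak amplitude at the peak latency, and the curve returns to zero after
#' the positive deflection. Being a function of continuous time, samplings
#' at different rates agree exactly at shared time points.
#'
#' Onset is `trough_latency - trough_width` (floored at 0) and offset is
#' `peak_latency + 2 * peak_width`, so the width parameters set how fast the
#' deflections grow and decay.
#'
#' @param t times in seconds (vector).
#' @param kernel_params list with `trough_latency_ms`, `peak_latency_ms`,
#'   `trough_amp_uv`, `peak_amp_uv`, `trough_width_ms`, `peak_width_ms`.
#' @return template values in uV at `t`.
#' @export
vep_kernel_value <- function(t, kernel_params) {
  kp <- kernel_params
  mu_t <- kp$trough_latency_ms / 1000
  mu_p <- kp$peak_latency_ms / 1000
  a_t <- kp$trough_amp_uv
  a_p <- kp$peak_amp_uv
  t_on <- max(0, mu_t - kp$trough_width_ms / 1000)
  t_off <- mu_p + 2 * kp$peak_width_ms / 1000
  s <- function(x) x * x * (3 - 2 * x)  # smoothstep, zero slope at 0 and 1
  y <- numeric(length(t))
  seg <- function(lo, hi, from, to) {
    i <- which(t >= lo & t < hi)
    if (length(i) && hi > lo)
      y[i] <<- from + (to - from) * s((t[i] - lo) / (hi - lo))
  }
  seg(t_on, mu_t, 0, a_t)
  seg(mu_t, mu_p, a_t, a_p)
  seg(mu_p, t_off, a_p, 0)
  y[t == mu_t] <- a_t
  y[t == mu_p] <- a_p
  y
}

#' Sample the VEP template over one reversal period
#'
#' @param kernel_params see [vep_kernel_value()].
#' @param sampling_rate Hz.
#' @param period reversal period in seconds; the template must return to
#'   zero before the period ends, i.e. both latencies must lie inside it.
#' @return numeric vector of `floor(period * sampling_rate)` uV samples,
#'   time 0 at the reversal.
#' @export
make_kernel <- function(kernel_params, sampling_rate, period = 1 / 1.95) {
  kp <- kernel_params
  if (kp$trough_latency_ms / 1000 >= period ||
      kp$peak_latency_ms / 1000 >= period)
    stop("make_kernel: kernel latencies must lie inside one reversal period",
         call. = FALSE)
  if (kp$trough_latency_ms < 0)
    stop("make_kernel: latencies must be non-negative", call. = FALSE)
  n <- floor(period * sampling_rate)
  vep_kernel_value((seq_len(n) - 1) / sampling_rate, kp)
}

#' Noise-free amplitude (peak minus trough) of a kernel parameter set
#' @noRd
kernel_amplitude <- function(kernel_params) {
  kernel_params$peak_amp_uv - kernel_params$trough_amp_uv
}
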
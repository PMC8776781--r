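# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) * 100003 + a * 1009 + b * 7) %% 2147483629 + 1)
}

# mean-one log-normal multiplier for between-animal variability
latent_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# per-animal latent parameters, reproducible from the master seed alone
animal_latents <- function(config, animal_index) {
  old <- .Random.seed_guard(derive_seed(config$seed, 900000L + animal_index))
  on.exit(old())
  list(
    baseline_mult = latent_mult(1, config$animal_cv$baseline),
    srp_mult = latent_mult(1, config$animal_cv$srp_gain),
    adapt_mult = latent_mult(1, config$animal_cv$adaptation),
    familiar_orientation = sample(c(-45, 45), 1))
}

# save/restore RNG state around seeded sections
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

# 1/f^beta Gaussian noise via spectral shaping, unit sd
pink_noise <- function(n, beta) {
  if (n < 2) return(stats::rnorm(n))
  m <- stats::nextn(n, c(2, 3, 5))  # highly composite length keeps the FFT fast
  m <- m + m %% 2
  f <- c(1, seq_len(m / 2), rev(seq_len(m / 2 - 1)))  # avoid f = 0 blow-up
  amp <- f^(-beta / 2)
  spec <- complex(real = amp * stats::rnorm(m),
                  imaginary = amp * stats::rnorm(m))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# saturating across-day growth of the familiar-stimulus VEP change
srp_level_delta <- function(day, delta_max, tau_days) {
  delta_max * (1 - exp(-(day - 1) / tau_days))
}

#' Simulate one animal-day recording session
#'
#' Generates a raw session (LFP, reversal events, wheel counts, pupil trace)
#' together with its ground truth. The LFP is the sum of per-reversal scaled
#' VEP templates, 1/f^beta pink noise and white noise. The per-reversal
#' template scale follows the injected day-level potentiation, the
#' within-block adaptation decay (blocks 2+; block 1 instead rises with a
#' saturating profile), and is multiplied by the running gain whenever the
#' behavioural state at the reversal is "running". On the first and last day
#' familiar and unfamiliar (orthogonal) orientations alternate block-wise;
#' all other days present the familiar stimulus only. Blocks are separated
#' by grey-screen gaps that contain no reversal events.
#'
#' @param config a [sim_config()].
#' @param animal_id animal identifier from [cohort_animals()] (or its integer
#'   row index).
#' @param day day index in `1..n_days`.
#' @return list with elements `session` (a `recording_session`: `lfp`, `fs`,
#'   `events`, `wheel`, `pupil`, `meta`) and `truth` (data frame with one row
#'   per simulated reversal: injected amplitude, behavioural state, speed).
#' @export
simulate_session <- function(config, animal_id, day) {
  validate_sim_config(config)
  roster <- cohort_animals(config)
  if (is.numeric(animal_id)) animal_id <- roster$animal_id[animal_id]
  ai <- match(animal_id, roster$animal_id)
  if (is.na(ai)) stop("simulate_session: unknown animal_id", call. = FALSE)
  if (day < 1 || day > config$n_days)
    stop("simulate_session: day out of range", call. = FALSE)
  gi <- roster$group_index[ai]
  lat <- animal_latents(config, ai)

  fs <- config$sampling_rate
  period <- config$reversal_period
  B <- config$blocks_per_day
  R <- config$reversals_per_block
  block_dur <- R * period
  t0 <- config$baseline_grey_s
  dur <- t0 + B * block_dur + (B - 1) * config$gap_s + 2
  n <- ceiling(dur * fs)

  restore <- .Random.seed_guard(derive_seed(config$seed, ai, day))
  on.exit(restore())

  ## ---- schedule ------------------------------------------------------
  interleave <- day == 1 || day == config$n_days
  if (interleave) {
    first_fam <- sample(c(TRUE, FALSE), 1)
    fam_block <- rep(c(first_fam, !first_fam), length.out = B)
  } else {
    fam_block <- rep(TRUE, B)
  }
  block_start <- t0 + (seq_len(B) - 1) * (block_dur + config$gap_s)
  ev_time <- rep(block_start, each = R) + (seq_len(R) - 1) * period
  ev_time <- round(ev_time * fs) / fs  # sync recorded on the LFP clock
  ev_block <- rep(seq_len(B), each = R)
  ev_rev <- rep(seq_len(R), times = B)
  ev_fam <- fam_block[ev_block]
  unfam_orientation <- -lat$familiar_orientation
  events <- data.frame(
    time_s = ev_time,
    block_index = ev_block,
    reversal_index_in_block = ev_rev,
    orientation_deg = ifelse(ev_fam, lat$familiar_orientation,
                             unfam_orientation),
    familiarity = ifelse(ev_fam, "familiar", "unfamiliar"),
    stringsAsFactors = FALSE)

  ## ---- behavioural state (1-s Markov chain) --------------------------
  sp <- config$state_params
  n_sec <- ceiling(dur)
  occ <- sp$running_occupancy[gi]
  p10 <- 1 / sp$mean_bout_s
  p01 <- if (occ > 0) occ * p10 / (1 - occ) else 0
  st <- integer(n_sec)
  st[1] <- stats::rbinom(1, 1, occ)
  u <- stats::runif(n_sec)
  for (s in 2:n_sec)
    st[s] <- if (st[s - 1] == 1) as.integer(u[s] >= p10) else
      as.integer(u[s] < p01)
  sec_speed <- ifelse(st == 1,
                      stats::rlnorm(n_sec, sp$speed_meanlog, sp$speed_sdlog),
                      0)

  ## ---- per-reversal injected amplitude -------------------------------
  kamp <- kernel_amplitude(config$kernel_params)
  day_jit <- stats::rnorm(1, 0, config$animal_cv$day_jitter_uv)
  base <- kamp * lat$baseline_mult
  lvl_fam <- base + lat$srp_mult *
    srp_level_delta(day, config$srp_params$delta_max_uv[gi],
                    config$srp_params$tau_days[gi]) + day_jit
  lvl_unfam <- base + lat$srp_mult *
    config$srp_params$unfamiliar_delta_uv[gi] *
    as.numeric(day == config$n_days) + day_jit
  lvl <- ifelse(ev_fam, lvl_fam, lvl_unfam)
  A_ad <- config$adaptation_params$amplitude_uv[gi] * lat$adapt_mult
  tau_ad <- config$adaptation_params$tau_reversals[gi]
  b1 <- config$block1_params
  amp <- ifelse(
    ev_block == 1,
    lvl * (1 - b1$rise_frac * exp(-(ev_rev - 1) / b1$tau_reversals)),
    lvl + A_ad * exp(-(ev_rev - 1) / tau_ad))
  ev_state_idx <- pmin(floor(ev_time) + 1, n_sec)
  ev_running <- st[ev_state_idx] == 1
  amp <- amp * ifelse(ev_running, sp$running_gain, 1)

  ## ---- LFP -----------------------------------------------------------
  np <- config$noise_params
  lfp <- numeric(n)
  if (np$white_sd_uv > 0) lfp <- lfp + stats::rnorm(n, 0, np$white_sd_uv)
  if (np$pink_sd_uv > 0)
    lfp <- lfp + np$pink_sd_uv * pink_noise(n, np$pink_exponent)
  kp <- config$kernel_params
  t_off <- kp$peak_latency_ms / 1000 + 2 * kp$peak_width_ms / 1000
  klen <- min(ceiling(t_off * fs) + 1, floor(period * fs))
  kern <- vep_kernel_value((seq_len(klen) - 1) / fs, kp)
  i0 <- round(ev_time * fs) + 1
  for (j in seq_along(i0)) {
    idx <- i0[j]:(i0[j] + klen - 1)
    lfp[idx] <- lfp[idx] + (amp[j] / kamp) * kern
  }

  ## ---- wheel ---------------------------------------------------------
  wp <- config$wheel_params
  wt <- seq(0, dur, by = 1 / wp$fs)
  w_speed <- sec_speed[pmin(floor(wt) + 1, n_sec)]
  dist <- cumsum(w_speed) / wp$fs
  wheel <- data.frame(time_s = wt,
                      cumulative_count = floor(dist * wp$resolution /
                                                 wp$circumference_cm))

  ## ---- pupil ---------------------------------------------------------
  pp <- config$pupil_params
  pt <- seq(0, dur, by = 1 / pp$fs)
  run_ind <- st[pmin(floor(pt) + 1, n_sec)]
  # ~2 s moving-average smoothing of the arousal signal
  kweights <- rep(1 / (2 * pp$fs + 1), 2 * pp$fs + 1)
  run_sm <- as.numeric(stats::filter(run_ind, kweights, sides = 2))
  run_sm[is.na(run_sm)] <- 0
  ndf <- pp$naive_dilation_frac
  ndf <- if (length(ndf) >= gi) ndf[gi] else ndf[1]
  onset <- rep(0, length(pt))
  if (day == 1 && ndf != 0) {
    rel <- pt - block_start[1]
    resp <- ifelse(rel > 0, (1 - exp(-rel / 1.5)) * exp(-rel / 8), 0)
    onset <- ndf * resp / max(resp)
  }
  ar <- as.numeric(stats::filter(stats::rnorm(length(pt)), 0.97,
                                 method = "recursive"))
  ar <- ar / stats::sd(ar)
  area <- pp$baseline_area_px2 *
    (1 + pp$running_dilation_frac * run_sm + onset + pp$noise_frac * ar)
  x <- stats::rnorm(length(pt), 0, pp$pos_sd_px) + 320
  y <- stats::rnorm(length(pt), 0, pp$pos_sd_px) + 240
  n_blink <- stats::rpois(1, pp$blink_rate_per_min * dur / 60)
  blink_truth <- rep(FALSE, length(pt))
  if (n_blink > 0) {
    bt <- sort(stats::runif(n_blink, 1, dur - 1))
    for (tb in bt) {
      ib <- which(pt >= tb & pt < tb + 0.15)
      blink_truth[ib] <- TRUE
      area[ib] <- area[ib] * 0.25
      x[ib] <- x[ib] + 12 * pp$pos_sd_px
      y[ib] <- y[ib] - 10 * pp$pos_sd_px
    }
  }
  pupil <- data.frame(time_s = pt, x_px = x, y_px = y, area_px2 = area)

  session <- structure(list(
    lfp = lfp, fs = fs, events = events, wheel = wheel, pupil = pupil,
    meta = list(animal_id = animal_id,
                group = roster$group[ai],
                phenotype = roster$phenotype[ai],
                age = roster$age[ai],
                day = day,
                n_days = config$n_days,
                familiar_orientation_deg = lat$familiar_orientation,
                reversal_period = period,
                stimulus_onset_s = block_start[1],
                gap_s = config$gap_s)),
    class = "recording_session")

  truth <- data.frame(
    animal_id = animal_id, group = roster$group[ai],
    phenotype = roster$phenotype[ai], age = roster$age[ai], day = day,
    block_index = ev_block, reversal_index_in_block = ev_rev,
    time_s = ev_time, familiarity = events$familiarity,
    true_amp_uv = amp, state = ifelse(ev_running, "running", "stationary"),
    speed_cms = sec_speed[ev_state_idx],
    stringsAsFactors = FALSE)
  attr(truth, "animal_params") <- c(lat[c("baseline_mult", "srp_mult",
                                          "adapt_mult")],
                                    list(day_jitter_uv = day_jit))
  attr(truth, "pupil_blink_mask") <- blink_truth

  list(session = session, truth = truth)
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("Recording session: %s day %d [%s, %s]\n", x$meta$animal_id,
              x$meta$day, x$meta$phenotype, x$meta$age))
  cat(sprintf("  LFP: %d samples @ %g Hz (%.1f s)\n", length(x$lfp), x$fs,
              length(x$lfp) / x$fs))
  cat(sprintf("  %d reversals in %d block(s); familiar orientation %+d deg\n",
              nrow(x$events), max(x$events$block_index),
              x$meta$familiar_orientation_deg))
  invisible(x)
}

#' Simulate a whole cohort
#'
#' One session per animal per day, with per-session seeds derived
#' deterministically from the master seed (identical configuration and seed
#' give bit-identical output regardless of call order). For large cohorts
#' the raw LFP of all sessions does not fit comfortably in memory; passing a
#' `process` function analyses each session as it is generated and stores
#' only the result.
#'
#' @param config a [sim_config()].
#' @param days days to simulate (default all).
#' @param process optional `function(session, truth)` applied to each
#'   session; its return value is stored in place of the raw session.
#' @return list with `sessions` (list, one element per animal-day, raw or
#'   processed), `truth` (pooled ground-truth data frame) and `animals`
#'   (the roster).
#' @export
simulate_cohort <- function(config, days = NULL, process = NULL) {
  roster <- cohort_animals(config)
  if (is.null(days)) days <- seq_len(config$n_days)
  out <- vector("list", nrow(roster) * length(days))
  truths <- vector("list", length(out))
  k <- 0
  for (ai in seq_len(nrow(roster))) {
    for (d in days) {
      k <- k + 1
      sim <- simulate_session(config, roster$animal_id[ai], d)
      truths[[k]] <- sim$truth
      out[[k]] <- if (is.null(process)) sim$session else
        process(sim$session, sim$truth)
      names(out)[k] <- sprintf("%s_day%d", roster$animal_id[ai], d)
    }
  }
  list(sessions = out, truth = do.call(rbind, truths), animals = roster)
}
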
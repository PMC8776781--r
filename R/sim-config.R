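#' Configuration for the synthetic session generator
#'
#' Builds a validated configuration object describing a simulated chronic
#' VEP recording study: the stimulus protocol (days, blocks, reversals),
#' the shape of the evoked potential, per-group long-term potentiation and
#' within-block adaptation parameters, behavioural-state dynamics, recording
#' noise, and the pupil/wheel channels.
#'
#' Defaults describe a two-group study (mutant-tau-expressing "Tau+" mice and
#' doxycycline-suppressed "Tau-" littermates at 5 months): 9 daily sessions of
#' 10 blocks x 200 contrast reversals at 1.95 Hz, familiar/unfamiliar
#' orientations interleaved on the first and last day, saturating growth of
#' the familiar-stimulus VEP across days, exponential within-block adaptation
#' (tau = 8.4 reversals) in blocks 2 and later, a rising profile in block 1,
#' and amplitude suppression during running bouts.
#'
#' @param n_animals_per_group animals simulated per group.
#' @param groups named list of groups; each element is a list with entries
#'   `phenotype` and `age` (labels only).
#' @param n_days number of daily sessions.
#' @param blocks_per_day blocks per session.
#' @param reversals_per_block contrast reversals per block.
#' @param reversal_period seconds between reversals (default 1/1.95).
#' @param sampling_rate LFP sampling rate in Hz.
#' @param gap_s grey-screen gap between blocks, seconds.
#' @param baseline_grey_s grey-screen period before the first block, seconds
#'   (must cover the 2-minute pupil normalisation baseline).
#' @param kernel_params list: `trough_latency_ms`, `peak_latency_ms`,
#'   `trough_amp_uv` (<= 0), `peak_amp_uv` (>= 0), `trough_width_ms`,
#'   `peak_width_ms`. The noise-free VEP amplitude is
#'   `peak_amp_uv - trough_amp_uv`.
#' @param srp_params per-group long-term potentiation of the familiar
#'   response: `delta_max_uv` (plateau change from day 1), `tau_days`
#'   (time constant of the saturating growth; plateau is reached around
#'   3 * tau_days), `unfamiliar_delta_uv` (last-day change for the
#'   unfamiliar stimulus). Each entry is a vector with one value per group.
#' @param adaptation_params per-group within-block adaptation:
#'   `amplitude_uv` (initial excess over the steady state) and
#'   `tau_reversals`. Vectors with one value per group.
#' @param block1_params rising profile of the first block of each session:
#'   `rise_frac` (initial fractional suppression) and `tau_reversals`.
#' @param state_params behavioural state model (1-s two-state Markov chain):
#'   `running_occupancy` (per group, long-run fraction of time running),
#'   `mean_bout_s` (mean running bout length), `speed_meanlog`/`speed_sdlog`
#'   (log-normal running speed, cm/s), `running_gain` (multiplicative VEP
#'   amplitude factor during running, in (0, 1]).
#' @param noise_params recording noise: `white_sd_uv`, `pink_sd_uv`,
#'   `pink_exponent` (spectral slope beta of the 1/f^beta component).
#' @param pupil_params `baseline_area_px2`, `naive_dilation_frac` (fractional
#'   dilation at first-ever stimulus onset), `running_dilation_frac`,
#'   `blink_rate_per_min`, `camera_res_mm_px`, `pos_sd_px` (eye-position
#'   jitter), `noise_frac`, `fs` (camera rate, Hz).
#' @param wheel_params `circumference_cm`, `resolution` (encoder counts per
#'   revolution), `fs` (sampling rate of the count channel, Hz).
#' @param animal_cv between-animal coefficients of variation:
#'   `baseline`, `srp_gain`, `adaptation`; plus `day_jitter_uv`, a day-level
#'   additive amplitude jitter (sd, uV).
#' @param seed master integer seed; all per-animal and per-session seeds are
#'   derived deterministically from it.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_animals_per_group = 12,
                       groups = list(
                         tau_minus = list(phenotype = "Tau-", age = "5m"),
                         tau_plus  = list(phenotype = "Tau+", age = "5m")),
                       n_days = 9,
                       blocks_per_day = 10,
                       reversals_per_block = 200,
                       reversal_period = 1 / 1.95,
                       sampling_rate = 1000,
                       gap_s = 30,
                       baseline_grey_s = 150,
                       kernel_params = list(
                         trough_latency_ms = 70, peak_latency_ms = 140,
                         trough_amp_uv = -60, peak_amp_uv = 90,
                         trough_width_ms = 40, peak_width_ms = 50),
                       srp_params = list(
                         delta_max_uv = c(90, 60),
                         tau_days = c(1.3, 3.0),
                         unfamiliar_delta_uv = c(53, 29)),
                       adaptation_params = list(
                         amplitude_uv = c(42, 28),
                         tau_reversals = c(8.4, 8.4)),
                       block1_params = list(rise_frac = 0.35,
                                            tau_reversals = 25),
                       state_params = list(
                         running_occupancy = c(0.17, 0.10),
                         mean_bout_s = 10,
                         speed_meanlog = log(8), speed_sdlog = 0.5,
                         running_gain = 0.8),
                       noise_params = list(white_sd_uv = 25,
                                           pink_sd_uv = 30,
                                           pink_exponent = 1),
                       pupil_params = list(
                         baseline_area_px2 = 8000,
                         naive_dilation_frac = 0.3,
                         running_dilation_frac = 0.15,
                         blink_rate_per_min = 4,
                         camera_res_mm_px = 0.01,
                         pos_sd_px = 3,
                         noise_frac = 0.02,
                         fs = 30),
                       wheel_params = list(circumference_cm = 50,
                                           resolution = 1024,
                                           fs = 100),
                       animal_cv = list(baseline = 0.2, srp_gain = 0.2,
                                        adaptation = 0.2, day_jitter_uv = 5),
                       seed = 1L) {
  cfg <- list(
    n_animals_per_group = as.integer(n_animals_per_group),
    groups = groups,
    n_days = as.integer(n_days),
    blocks_per_day = as.integer(blocks_per_day),
    reversals_per_block = as.integer(reversals_per_block),
    reversal_period = reversal_period,
    sampling_rate = sampling_rate,
    gap_s = gap_s,
    baseline_grey_s = baseline_grey_s,
    kernel_params = kernel_params,
    srp_params = srp_params,
    adaptation_params = adaptation_params,
    block1_params = block1_params,
    state_params = state_params,
    noise_params = noise_params,
    pupil_params = pupil_params,
    wheel_params = wheel_params,
    animal_cv = animal_cv,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  ng <- length(x$groups)
  cat("Synthetic VEP study configuration\n")
  cat(sprintf("  %d group(s) x %d animals x %d days\n",
              ng, x$n_animals_per_group, x$n_days))
  cat(sprintf("  %d blocks/day x %d reversals @ %.4f s (fs = %g Hz)\n",
              x$blocks_per_day, x$reversals_per_block,
              x$reversal_period, x$sampling_rate))
  for (i in seq_len(ng)) {
    g <- x$groups[[i]]
    cat(sprintf("  group %-12s [%s, %s]: SRP %g uV (tau %g d), adaptation %g uV (tau %g rev)\n",
                names(x$groups)[i], g$phenotype, g$age,
                x$srp_params$delta_max_uv[i], x$srp_params$tau_days[i],
                x$adaptation_params$amplitude_uv[i],
                x$adaptation_params$tau_reversals[i]))
  }
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg$groups), length(cfg$groups) >= 1)
  ng <- length(cfg$groups)
  pos <- function(v, what) {
    if (any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("sim_config: '%s' must be strictly positive", what),
           call. = FALSE)
  }
  pos(cfg$n_animals_per_group, "n_animals_per_group")
  pos(cfg$n_days, "n_days")
  pos(cfg$blocks_per_day, "blocks_per_day")
  pos(cfg$reversals_per_block, "reversals_per_block")
  pos(cfg$reversal_period, "reversal_period")
  pos(cfg$sampling_rate, "sampling_rate")
  pos(cfg$gap_s, "gap_s")
  pos(cfg$baseline_grey_s, "baseline_grey_s")
  pos(cfg$state_params$mean_bout_s, "state_params$mean_bout_s")
  pos(cfg$adaptation_params$tau_reversals, "adaptation_params$tau_reversals")
  pos(cfg$wheel_params$circumference_cm, "wheel_params$circumference_cm")
  pos(cfg$wheel_params$resolution, "wheel_params$resolution")
  pos(cfg$wheel_params$fs, "wheel_params$fs")
  pos(cfg$pupil_params$fs, "pupil_params$fs")
  g <- cfg$state_params$running_gain
  if (!is.finite(g) || g <= 0 || g > 1)
    stop("sim_config: running_gain must lie in (0, 1]", call. = FALSE)
  occ <- cfg$state_params$running_occupancy
  if (any(occ < 0) || any(occ >= 1))
    stop("sim_config: running_occupancy must lie in [0, 1)", call. = FALSE)
  kp <- cfg$kernel_params
  if (kp$trough_latency_ms >= 150)
    stop("sim_config: kernel trough latency must be < 150 ms", call. = FALSE)
  if (kp$peak_latency_ms >= 250)
    stop("sim_config: kernel peak latency must be < 250 ms", call. = FALSE)
  if (kp$trough_latency_ms <= 0 || kp$peak_latency_ms <= kp$trough_latency_ms)
    stop("sim_config: need 0 < trough latency < peak latency", call. = FALSE)
  for (fld in c("delta_max_uv", "tau_days", "unfamiliar_delta_uv"))
    if (length(cfg$srp_params[[fld]]) != ng)
      stop(sprintf("sim_config: srp_params$%s needs one value per group", fld),
           call. = FALSE)
  for (fld in c("amplitude_uv", "tau_reversals"))
    if (length(cfg$adaptation_params[[fld]]) != ng)
      stop(sprintf("sim_config: adaptation_params$%s needs one value per group",
                   fld), call. = FALSE)
  if (length(occ) != ng)
    stop("sim_config: state_params$running_occupancy needs one value per group",
         call. = FALSE)
  invisible(cfg)
}

#' Read a study configuration from a JSON file
#'
#' The file may override any subset of [sim_config()]'s arguments; nested
#' parameter lists (`kernel_params`, `srp_params`, ...) are merged
#' field-wise into the defaults, so a file only needs to name what it
#' changes.
#'
#' @param path JSON file.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(sim_config)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("read_sim_config: unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && !is.null(names(over[[nm]]))) {
      base <- eval(defaults[[nm]])
      base[names(over[[nm]])] <- over[[nm]]
      args[[nm]] <- base
    } else {
      args[[nm]] <- over[[nm]]
    }
  }
  do.call(sim_config, args)
}

#' Animal roster implied by a configuration
#'
#' @param config a [sim_config()] object.
#' @return data frame with one row per simulated animal: `animal_id`,
#'   `group` (name), `group_index`, `phenotype`, `age`.
#' @export
cohort_animals <- function(config) {
  ng <- length(config$groups)
  na <- config$n_animals_per_group
  gname <- names(config$groups)
  if (is.null(gname)) gname <- paste0("group", seq_len(ng))
  out <- do.call(rbind, lapply(seq_len(ng), function(gi) {
    data.frame(
      animal_id = sprintf("%s_a%02d", gname[gi], seq_len(na)),
      group = gname[gi],
      group_index = gi,
      phenotype = config$groups[[gi]]$phenotype,
      age = config$groups[[gi]]$age,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
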
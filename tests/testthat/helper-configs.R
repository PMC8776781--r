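# Small study configurations for unit tests. The protocol knobs
# (days/blocks/reversals) are scaled down so single sessions simulate in
# tens of milliseconds; signal parameters keep their defaults unless a
# test needs them silenced.

tiny_config <- function(..., seed = 1) {
  sim_config(n_animals_per_group = 2, n_days = 3, blocks_per_day = 3,
             reversals_per_block = 60, baseline_grey_s = 130,
             seed = seed, ...)
}

# deterministic, noise-free, running-free, homogeneous-animal variant
quiet_config <- function(..., adaptation_uv = c(0, 0), rise_frac = 0,
                         occupancy = c(0, 0), seed = 1) {
  tiny_config(
    noise_params = list(white_sd_uv = 0, pink_sd_uv = 0, pink_exponent = 1),
    adaptation_params = list(amplitude_uv = adaptation_uv,
                             tau_reversals = c(8.4, 8.4)),
    block1_params = list(rise_frac = rise_frac, tau_reversals = 25),
    state_params = list(running_occupancy = occupancy, mean_bout_s = 10,
                        speed_meanlog = log(8), speed_sdlog = 0.5,
                        running_gain = 0.8),
    animal_cv = list(baseline = 0, srp_gain = 0, adaptation = 0,
                     day_jitter_uv = 0),
    seed = seed, ...)
}

default_kernel <- function() {
  list(trough_latency_ms = 70, peak_latency_ms = 140,
       trough_amp_uv = -60, peak_amp_uv = 90,
       trough_width_ms = 40, peak_width_ms = 50)
}

# raw (unfiltered) epochs of a session, for filter-free identities
raw_epochs <- function(sim, config) {
  epoch_lfp(sim$session$lfp, sim$session$fs, sim$session$events,
            config$reversal_period)
}
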
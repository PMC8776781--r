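test_that("noise-free daily amplitudes reproduce the injected day levels", {
  cfg <- quiet_config(seed = 13)
  sims <- lapply(1:3, function(d) simulate_session(cfg, 1, d))
  # filter-free analysis: measured = injected exactly
  sms <- lapply(sims, function(s) analyze_session(s$session,
                                                  bandpass = FALSE))
  tab <- daily_amplitudes(sms, "all")
  fam <- tab[tab$familiarity == "familiar", ]
  truth_levels <- vapply(sims, function(s)
    s$truth$true_amp_uv[s$truth$familiarity == "familiar"][1], numeric(1))
  expect_equal(fam$amplitude[order(fam$day)], truth_levels,
               tolerance = 1e-9)
  # with the band-pass the measured level shifts by at most ~1%
  sm_f <- analyze_session(sims[[2]]$session)
  a_f <- sm_f$srp_rows$amplitude[sm_f$srp_rows$state == "all"]
  expect_equal(a_f, truth_levels[2], tolerance = 0.015)
})

test_that("familiar and unfamiliar day-1 amplitudes agree when injected equal", {
  cfg <- quiet_config(seed = 19)
  sim <- simulate_session(cfg, 1, 1)
  sm <- analyze_session(sim$session, bandpass = FALSE)
  rows <- sm$srp_rows[sm$srp_rows$state == "all", ]
  expect_equal(rows$amplitude[rows$familiarity == "familiar"],
               rows$amplitude[rows$familiarity == "unfamiliar"],
               tolerance = 1e-9)
})

test_that("stationary-only amplitudes exceed all-epoch amplitudes under running suppression", {
  cfg <- quiet_config(occupancy = c(0.4, 0.4), seed = 37)
  sim <- simulate_session(cfg, 1, 2)
  sm <- analyze_session(sim$session, bandpass = FALSE)
  rows <- sm$srp_rows[sm$srp_rows$familiarity == "familiar", ]
  a_all <- rows$amplitude[rows$state == "all"]
  a_st <- rows$amplitude[rows$state == "stationary"]
  expect_gt(a_st, a_all)
})

test_that("srp_change subtracts day 1 within animal before group averaging", {
  tab <- data.frame(
    animal_id = rep(c("a1", "a2"), each = 3),
    group = "g", day = rep(1:3, 2),
    familiarity = "familiar", state = "all",
    amplitude = c(100, 110, 110, 100, 130, 130))
  sc <- srp_change(tab)
  expect_equal(sc$table$delta_from_day1[sc$table$day == 1], c(0, 0))
  d3 <- sc$group[sc$group$day == 3, ]
  expect_equal(d3$mean, 20)
  expect_equal(d3$sem, 10)
  expect_equal(d3$n, 2)
  # identical amplitudes across days -> all deltas zero
  tab0 <- tab
  tab0$amplitude <- 100
  expect_true(all(srp_change(tab0)$table$delta_from_day1 == 0))
  # missing day 1 -> animal excluded with warning
  expect_warning(sc2 <- srp_change(tab[tab$day > 1 |
                                         tab$animal_id == "a1", ]),
                 "a2")
  expect_equal(unique(sc2$table$animal_id), "a1")
})

test_that("block timecourses bin correctly and are flat for constant epochs", {
  k <- make_kernel(default_kernel(), 1000)
  n_rev <- 200
  ep <- structure(list(
    epochs = matrix(rep(k, each = n_rev), n_rev, length(k)),
    time_s = (seq_along(k) - 1) / 1000,
    labels = data.frame(time_s = seq_len(n_rev),
                        block_index = 1,
                        reversal_index_in_block = seq_len(n_rev)),
    fs = 1000, n_dropped = 0L), class = "epoch_matrix")
  tc <- block_timecourse(ep, step = 20)
  expect_equal(nrow(tc), 10)
  expect_equal(tc$bin_centre, (1:10 - 0.5) * 20)
  expect_equal(tc$amplitude, rep(150, 10))
  expect_equal(tc$n_epochs, rep(20L, 10))
  expect_error(block_timecourse(ep, step = 500), "shorter")
})

test_that("a noise-free session's binned curve matches the bin-averaged exponential", {
  cfg <- quiet_config(adaptation_uv = c(40, 40), seed = 43)
  cfg$blocks_per_day <- 3
  cfg$reversals_per_block <- 200
  sim <- simulate_session(cfg, 1, 2)
  ep <- raw_epochs(sim, cfg)
  tc <- block_timecourse(ep, step = 20)
  cur <- steady_state_subtract(tc, last_n = 100, block_set = 2:3)
  # analytic oracle: bin-averaged exponential minus its last-100 mean
  b_oracle <- vapply(1:10, function(k) {
    n <- ((k - 1) * 20 + 1):(k * 20)
    mean(40 * exp(-(n - 1) / 8.4))
  }, numeric(1))
  b_oracle <- b_oracle - mean(b_oracle[6:10])
  expect_equal(cur$amplitude, b_oracle, tolerance = 1e-6)
})

test_that("steady-state subtraction removes offsets and self-normalises", {
  b <- srpvep:::adapt_basis((1:10 - 0.5) * 20, 8.4, 20)
  tc <- data.frame(block_index = 2, bin = 1:10,
                   bin_centre = (1:10 - 0.5) * 20,
                   amplitude = 40 * b + 7, n_epochs = 20)
  attr(tc, "step") <- 20
  cur <- steady_state_subtract(tc, last_n = 100, block_set = 2:10)
  # offset removed: tail ~ 0, bin 1 ~ 40 * b1
  expect_equal(mean(cur$amplitude[6:10]), 0, tolerance = 1e-9)
  expect_equal(cur$amplitude[1], 40 * (b[1] - mean(b[6:10])),
               tolerance = 1e-9)
  # constant curve -> all zeros
  tc0 <- tc
  tc0$amplitude <- 5
  expect_equal(steady_state_subtract(tc0, 100, 2:10)$amplitude, rep(0, 10))
  # last_n = block length -> mean exactly zero by construction
  cur_all <- steady_state_subtract(tc, last_n = 200, block_set = 2:10)
  expect_equal(mean(cur_all$amplitude), 0, tolerance = 1e-12)
  expect_error(steady_state_subtract(tc, 100, 5:6), "empty")
  expect_error(steady_state_subtract(tc, 999, 2:10), "block length")
})

test_that("the pooled tau fit recovers a noiseless time constant to 3 decimals", {
  b <- srpvep:::adapt_basis((1:10 - 0.5) * 20, 8.4, 20)
  cur <- structure(data.frame(bin = 1:10, bin_centre = (1:10 - 0.5) * 20,
                              amplitude = 40 * b, n_blocks = 9),
                   step = 20, class = c("adaptation_curve", "data.frame"))
  fit <- fit_pooled_tau(cur)
  expect_equal(fit$tau, 8.4, tolerance = 1e-4)
  expect_equal(fit$amplitude, 40, tolerance = 1e-6)
  # pure-noise curve: the exponential explains little of the variance
  set.seed(51)
  curn <- cur
  curn$amplitude <- rnorm(10)
  fn <- suppressWarnings(fit_pooled_tau(curn))  # may warn: boundary tau
  expect_gt(fn$rss, 0.3 * fn$rss_null)
  expect_error(fit_pooled_tau(cur[1:2, ]), "3 bins")
})

test_that("the fixed-tau amplitude is the closed-form projection", {
  step <- 20
  centres <- (1:10 - 0.5) * step
  b84 <- srpvep:::adapt_basis(centres, 8.4, step)
  cur <- structure(data.frame(bin = 1:10, bin_centre = centres,
                              amplitude = 40 * b84),
                   step = step, class = c("adaptation_curve", "data.frame"))
  expect_equal(fit_adaptation_amplitude(cur, 8.4)$amplitude, 40,
               tolerance = 1e-12)
  # zero curve -> zero amplitude
  cur0 <- cur
  cur0$amplitude <- 0
  expect_equal(fit_adaptation_amplitude(cur0, 8.4)$amplitude, 0)
  # mis-specified tau: equals the projection oracle computed by hand
  b12 <- srpvep:::adapt_basis(centres, 12, step)
  cur12 <- cur
  cur12$amplitude <- 40 * b12
  oracle <- sum(40 * b12 * b84) / sum(b84^2)
  expect_equal(fit_adaptation_amplitude(cur12, 8.4)$amplitude, oracle,
               tolerance = 1e-12)
  # linearity in the curve
  cur3 <- cur
  cur3$amplitude <- 3 * cur$amplitude
  expect_equal(fit_adaptation_amplitude(cur3, 8.4)$amplitude,
               3 * fit_adaptation_amplitude(cur, 8.4)$amplitude)
  expect_error(fit_adaptation_amplitude(cur, -1), "positive")
  far <- structure(data.frame(bin = 1:3, bin_centre = c(5000, 6000, 7000),
                              amplitude = c(1, 2, 3)),
                   step = 20, class = c("adaptation_curve", "data.frame"))
  expect_error(fit_adaptation_amplitude(far, 8.4), "degenerate")
})

test_that("average-then-metric and metric-then-average differ on noisy epochs", {
  set.seed(61)
  k <- make_kernel(default_kernel(), 1000)
  m <- matrix(rep(k, each = 40), 40, length(k)) +
    matrix(rnorm(40 * length(k), 0, 30), 40)
  ep <- structure(list(epochs = m, time_s = (seq_along(k) - 1) / 1000,
                       labels = data.frame(time_s = 1:40, block_index = 1,
                                           reversal_index_in_block = 1:40),
                       fs = 1000, n_dropped = 0L), class = "epoch_matrix")
  avg_then <- compute_metrics(colMeans(m), 1000)$amplitude
  then_avg <- mean(single_epoch_amplitudes(ep)$amplitude)
  # single-epoch extreme-value bias inflates metric-then-average
  expect_gt(then_avg, avg_then + 10)
})

test_that("the saturating growth fit summarises an SRP day course", {
  day <- 1:9
  delta <- 90 * (1 - exp(-(day - 1) / 1.3))
  fit <- fit_srp_growth(day, delta)
  expect_equal(fit$delta_max, 90, tolerance = 1e-4)
  expect_equal(fit$tau_days, 1.3, tolerance = 1e-3)
  expect_error(fit_srp_growth(1:2, c(0, 1)), "3 days")
})
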
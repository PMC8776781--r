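test_that("wheel counts convert to speed with the expected units", {
  ts <- seq(0, 2, by = 0.01)
  # constant 1024 counts/s, resolution 1024, circumference 50 -> 50 cm/s
  sp <- wheel_to_speed(round(1024 * ts), ts, 50, 1024, smooth_ms = 0)
  expect_equal(sp$speed[50:150], rep(50, 101), tolerance = 0.26)
  # zero count change -> zero speed
  sp0 <- wheel_to_speed(rep(3, length(ts)), ts, 50, 1024)
  expect_equal(sp0$speed, rep(0, length(ts)))
  expect_error(wheel_to_speed(1:5, c(1, 2, 2, 3, 4), 50, 1024),
               "increasing")
})

test_that("speed smoothing equals a direct Gaussian convolution oracle", {
  ts <- seq(0, 5, by = 0.005)
  counts <- cumsum(c(0, rep(c(10, 0), each = length(ts) / 2 - 0.5)))[
    seq_along(ts)]
  sm <- wheel_to_speed(counts, ts, 50, 1024, smooth_ms = 50)
  raw <- wheel_to_speed(counts, ts, 50, 1024, smooth_ms = 0)
  # oracle: same kernel definition (sd = window/4, truncated +-2 sd),
  # edge-replicated convolution
  sd_samp <- (0.05 / 4) / median(diff(ts))
  half <- max(1, ceiling(2 * sd_samp - 1e-9))
  k <- dnorm(seq(-half, half), sd = sd_samp)
  k <- k / sum(k)
  padded <- c(rep(raw$speed[1], half), raw$speed,
              rep(raw$speed[length(raw$speed)], half))
  oracle <- vapply(seq_along(raw$speed), function(i)
    sum(padded[i:(i + 2 * half)] * rev(k)), numeric(1))
  expect_equal(sm$speed, pmax(oracle, 0), tolerance = 1e-10)
})

test_that("blink removal masks position outliers and is idempotent", {
  set.seed(2)
  n <- 500
  # uniform position jitter: bounded support, so the 2-sd criterion has no
  # false positives and the test isolates the outlier handling
  p <- data.frame(time_s = (1:n) / 30,
                  x_px = runif(n, 318, 322), y_px = runif(n, 238, 242),
                  area_px2 = rnorm(n, 5000, 50))
  # constant trace: nothing flagged
  pc <- p
  pc$x_px <- 320
  pc$y_px <- 240
  expect_false(any(remove_blinks(pc)$blink_mask))
  # a single 10-sd excursion is flagged and replaced by its neighbour
  p2 <- p
  p2$x_px[100] <- 320 + 10 * sd(p$x_px)
  p2$area_px2[100] <- 100
  cl <- remove_blinks(p2)
  expect_true(cl$blink_mask[100])
  expect_equal(sum(cl$blink_mask), 1)
  expect_true(cl$area_px2[100] %in% p2$area_px2[c(99, 101)])
  # idempotence: a second pass changes nothing
  cl2 <- remove_blinks(cl)
  expect_identical(cl, cl2)
  expect_error(remove_blinks(p[1:5, ]), "10 samples")
})

test_that("blink recall is near-perfect on 1% contaminated traces", {
  set.seed(3)
  n <- 3000
  p <- data.frame(time_s = (1:n) / 30,
                  x_px = rnorm(n, 320, 2), y_px = rnorm(n, 240, 2),
                  area_px2 = rnorm(n, 5000, 50))
  bad <- sample(n, n / 100)
  # blink-sized excursions: ~20 native sd of eye position
  p$x_px[bad] <- p$x_px[bad] + 20 * 2 * sample(c(-1, 1), length(bad), TRUE)
  cl <- remove_blinks(p)
  recall <- mean(cl$blink_mask[bad])
  expect_gte(recall, 0.99)
})

test_that("pupil normalisation is exact and scale-invariant", {
  t <- seq(0, 300, by = 1 / 30)
  a <- ifelse(t < 150, 2, 3)
  z <- normalise_pupil(a, t, 150)
  expect_equal(as.numeric(z[t < 150]), rep(1, sum(t < 150)))
  expect_equal(as.numeric(z[t >= 160][1]), 1.5)
  # constant area -> constant 1 whatever the baseline
  expect_equal(as.numeric(normalise_pupil(rep(4, length(t)), t, 150)),
               rep(1, length(t)))
  # scale invariance
  expect_equal(as.numeric(normalise_pupil(5 * a, t, 150)), as.numeric(z))
  expect_error(normalise_pupil(a - 2, t, 150), "positive")
  expect_error(normalise_pupil(a, t, 0), "baseline window")
})

test_that("the stationary 12-s baseline uses only stationary samples", {
  t <- seq(0, 40, by = 1 / 30)
  a <- rep(2, length(t))
  state <- rep("stationary", length(t))
  running <- t >= 25 & t < 30
  state[running] <- "running"
  a[running] <- 4  # dilation while running would contaminate the baseline
  z <- normalise_pupil(a, t, 32, baseline = "stationary12s", state = state)
  # hand-filtered oracle
  sel <- t >= 20 & t < 32 & state == "stationary"
  expect_equal(attr(z, "baseline_mean"), mean(a[sel]))
  expect_equal(attr(z, "baseline_mean"), 2)
  expect_error(normalise_pupil(a, t, 32, baseline = "stationary12s"),
               "state")
})

test_that("epoch state classification applies the speed threshold", {
  t <- seq(0, 60, by = 0.01)
  ev <- data.frame(time_s = seq(1, 55, by = 0.5))
  mk <- function(v) data.frame(time_s = t, speed = v)
  all0 <- classify_state(mk(rep(0, length(t))), ev, 0.5)
  expect_true(all(all0$state == "stationary"))
  all5 <- classify_state(mk(rep(5, length(t))), ev, 0.5)
  expect_true(all(all5$state == "running"))
  # exactly at threshold -> stationary (strict inequality)
  at1 <- classify_state(mk(rep(1, length(t))), ev, 0.5, threshold_cm_s = 1)
  expect_true(all(at1$state == "stationary"))
  # epochs outside the trace are labelled missing
  ev2 <- rbind(ev, data.frame(time_s = 100))
  expect_message(out <- classify_state(mk(rep(0, length(t))), ev2, 0.5),
                 "missing")
  expect_true(is.na(out$state[nrow(out)]))
})

test_that("state labels recovered from the wheel match the generator truth", {
  cfg <- tiny_config(seed = 17)
  sim <- simulate_session(cfg, 1, 2)
  sm <- analyze_session(sim$session)
  acc <- mean(sm$epoch_table$state == sim$truth$state, na.rm = TRUE)
  expect_gte(acc, 0.95)
})

test_that("event-triggered responses recover steps and transient peaks", {
  t <- seq(0, 100, by = 1 / 30)
  # constant trace -> zero-change response
  r0 <- event_triggered_response(rep(2, length(t)), t, 50,
                                 window_s = c(-5, 10), baseline_s = 5)
  expect_equal(r0$mean, rep(0, length(r0$time)), tolerance = 1e-12)
  # step of +0.5 at onset
  r1 <- event_triggered_response(ifelse(t >= 50, 2.5, 2), t, 50,
                                 window_s = c(-5, 10), baseline_s = 5)
  expect_equal(mean(r1$mean[r1$time > 0.1]), 0.5, tolerance = 1e-6)
  expect_error(event_triggered_response(rep(1, 10), (1:10) / 30, 99,
                                        window_s = c(-5, 10)),
               "coverage")
})

test_that("the simulated naive pupil dilation peaks at the injected latency", {
  cfg <- quiet_config(seed = 23)
  cfg$pupil_params$noise_frac <- 0
  cfg$pupil_params$blink_rate_per_min <- 0
  sim <- simulate_session(cfg, 1, 1)  # day 1 = naive
  s <- sim$session
  r <- event_triggered_response(s$pupil$area_px2, s$pupil$time_s,
                                s$meta$stimulus_onset_s,
                                window_s = c(-12, 30), baseline_s = 12)
  # analytic oracle: argmax of (1 - exp(-t/1.5)) * exp(-t/8) on this grid
  tpost <- r$time[r$time > 0]
  shape <- (1 - exp(-tpost / 1.5)) * exp(-tpost / 8)
  t_inj <- tpost[which.max(shape)]
  t_obs <- r$time[which.max(r$mean)]
  expect_lt(abs(t_obs - t_inj), 1 / 30 + 1e-9)
})

test_that("percent time running counts in-block samples only", {
  t <- seq(0, 100, by = 0.01)
  ev <- data.frame(time_s = c(seq(10, 29.5, by = 0.5),
                              seq(70, 89.5, by = 0.5)),
                   block_index = rep(1:2, each = 40))
  sp <- data.frame(time_s = t, speed = rep(0, length(t)))
  expect_equal(percent_time_running(sp, ev, 0.5), 0)
  # running exactly during the first block -> 50% of stimulus time
  sp2 <- sp
  sp2$speed[t >= 10 & t < 30] <- 5
  expect_equal(percent_time_running(sp2, ev, 0.5), 50, tolerance = 0.5)
  # running only in the inter-block interval -> still 0
  sp3 <- sp
  sp3$speed[t >= 40 & t < 60] <- 5
  expect_equal(percent_time_running(sp3, ev, 0.5), 0)
})

test_that("percent running tracks the Markov occupancy of the generator", {
  cfg <- tiny_config(seed = 29)
  sim <- simulate_session(cfg, 1, 2)  # group 1: occupancy 0.17
  sm <- analyze_session(sim$session)
  truth_frac <- 100 * mean(sim$truth$state == "running")
  expect_lt(abs(sm$percent_running - truth_frac), 7)
})
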
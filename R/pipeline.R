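# mean of v over [t0, t0 + period) windows on an (approximately) regular
# time base, via cumulative sums
window_means <- function(t, v, t0, period) {
  eps <- 1e-9
  i_lo <- findInterval(t0 - eps, t) + 1
  i_hi <- findInterval(t0 + period - eps, t)
  cs <- c(0, cumsum(v))
  ok <- i_lo <= i_hi & i_lo >= 1 & i_hi <= length(v)
  ifelse(ok, (cs[pmin(i_hi, length(v)) + 1] - cs[pmax(i_lo, 1)]) /
           pmax(i_hi - i_lo + 1, 1), NA_real_)
}

#' Analyse one recording session
#'
#' Runs the single-session stages: band-pass filtering (0.3-50 Hz,
#' zero-phase), reversal epoching, behavioural-state classification from
#' the wheel channel, pupil cleaning and normalisation, averaged VEP
#' metrics per familiarity and state, per-reversal amplitudes, the binned
#' within-block amplitude timecourse, and the stimulus-onset pupil
#' response. Returns compact summaries (the raw LFP and epoch matrices are
#' not retained), so whole cohorts can be analysed session by session.
#'
#' @param session a `recording_session`.
#' @param step timecourse bin width in reversals.
#' @param threshold_cm_s running-speed threshold.
#' @param keep_epochs retain the epoch matrix (memory-hungry; default off).
#' @param bandpass apply the 0.3-50 Hz zero-phase band-pass before epoching
#'   (the standard pipeline; disable only for filter-free checks).
#' @return object of class `session_summary`: `meta`, `srp_rows` (averaged
#'   amplitude per familiarity x state), `epoch_table` (per-reversal
#'   amplitude + behaviour), `timecourse` (familiar blocks), `percent_running`,
#'   `pupil_onset` (baseline-referenced normalised pupil around the first
#'   block onset), and optionally `epochs`.
#' @export
analyze_session <- function(session, step = 20, threshold_cm_s = 1,
                            keep_epochs = FALSE, bandpass = TRUE) {
  meta <- session$meta
  period <- meta$reversal_period %||% stats::median(diff(session$events$time_s))
  filt <- if (bandpass) bandpass_vep(session$lfp, session$fs) else
    session$lfp
  ep <- epoch_lfp(filt, session$fs, session$events, period)

  speed <- wheel_to_speed(session$wheel$cumulative_count,
                          session$wheel$time_s)
  ep$labels <- classify_state(speed, ep$labels, period, threshold_cm_s)

  pupil <- remove_blinks(session$pupil)
  onset_t <- meta$stimulus_onset_s %||% session$events$time_s[1]
  pnorm <- normalise_pupil(pupil$area_px2, pupil$time_s, onset_t,
                           baseline = "pre2min")
  ep$labels$mean_pupil <- window_means(pupil$time_s, as.numeric(pnorm),
                                       ep$labels$time_s, period)

  amp <- single_epoch_amplitudes(ep)
  day <- meta$day %||% NA_integer_
  ids <- data.frame(animal_id = meta$animal_id %||% NA_character_,
                    group = meta$group %||% NA_character_,
                    phenotype = meta$phenotype %||% NA_character_,
                    age = meta$age %||% NA_character_,
                    day = day)
  epoch_table <- cbind(ids[rep(1, nrow(amp)), , drop = FALSE], amp)
  rownames(epoch_table) <- NULL

  srp_rows <- NULL
  for (fam in unique(ep$labels$familiarity)) {
    for (st in c("all", "stationary", "running")) {
      sel_state <- if (st == "all") NULL else st
      m <- tryCatch({
        w <- average_vep(ep, familiarity = fam, state = sel_state)
        compute_metrics(w, ep$fs)
      }, error = function(e) NULL)
      srp_rows <- rbind(srp_rows, cbind(ids, data.frame(
        familiarity = fam, state = st,
        amplitude = if (is.null(m)) NA_real_ else m$amplitude,
        peak_amp = if (is.null(m)) NA_real_ else m$peak_amp,
        trough_amp = if (is.null(m)) NA_real_ else m$trough_amp,
        t_trough = if (is.null(m)) NA_real_ else m$t_trough,
        t_peak = if (is.null(m)) NA_real_ else m$t_peak,
        n_epochs = if (is.null(m)) 0L else m$n_epochs_averaged)))
    }
  }
  rownames(srp_rows) <- NULL

  tc <- block_timecourse(ep, step = step, familiarity = "familiar")
  tc$animal_id <- ids$animal_id
  tc$day <- day
  # stationary-only variant: running multiplies the amplitude, and bout
  # durations are commensurate with the bin length, so the all-epoch
  # curve carries bin-correlated state noise that the stationary subset
  # avoids
  tc_st <- tryCatch(block_timecourse(ep, step = step,
                                     familiarity = "familiar",
                                     state = "stationary"),
                    error = function(e) NULL)
  if (!is.null(tc_st)) {
    tc_st$animal_id <- ids$animal_id
    tc_st$day <- day
  }

  pr <- percent_time_running(speed, session$events, period, threshold_cm_s)

  # stimulus-onset pupil response (12-s stationary pre-onset baseline)
  p_state <- ifelse(stats::approx(speed$time_s, speed$speed,
                                  xout = pupil$time_s, rule = 2)$y >
                      threshold_cm_s, "running", "stationary")
  onset_resp <- tryCatch({
    pn12 <- normalise_pupil(pupil$area_px2, pupil$time_s, onset_t,
                            baseline = "stationary12s", state = p_state)
    event_triggered_response(as.numeric(pn12), pupil$time_s, onset_t,
                             window_s = c(-12, 30), baseline_s = 12)
  }, error = function(e) NULL)

  out <- list(meta = meta, srp_rows = srp_rows, epoch_table = epoch_table,
              timecourse = tc, timecourse_stationary = tc_st,
              percent_running = pr,
              mean_pupil = mean(epoch_table$mean_pupil, na.rm = TRUE),
              pupil_onset = if (is.null(onset_resp)) NULL else
                list(time = onset_resp$time, mean = onset_resp$mean))
  if (keep_epochs) out$epochs <- ep
  class(out) <- "session_summary"
  out
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("Session summary: %s day %s, %d reversals, %.1f%% time running\n",
              x$meta$animal_id, x$meta$day, nrow(x$epoch_table),
              x$percent_running))
  invisible(x)
}

#' Within-block adaptation analysis of a set of session summaries
#'
#' Pools the binned familiar-stimulus timecourses of the adaptation days
#' (all but the first and last day, where only the familiar stimulus is
#' shown), estimates the shared time constant from the grand-mean curve
#' (blocks 2-10), then fits the fixed-tau amplitude per session and block
#' set.
#'
#' @param summaries list of `session_summary` objects.
#' @param last_n steady-state window (reversals from the block end).
#' @param tau_fixed optional externally fixed tau (reversals); default:
#'   the pooled estimate from the data.
#' @param block_sets block sets to fit per session.
#' @param state `"stationary"` (default) restricts the curves to
#'   stationary epochs: locomotion multiplies the VEP amplitude and
#'   running bouts last about as long as one 20-reversal bin, so all-epoch
#'   curves carry bin-correlated state noise that dominates the error of
#'   the time-constant fit. `"all"` uses every epoch.
#' @return list of class `adaptation_analysis`: `tau` (reversals),
#'   `pooled_fit`, `pooled_curve`, `fits` (data frame: one row per session
#'   x block set with the fitted amplitude).
#' @export
adaptation_analysis <- function(summaries, last_n = 100, tau_fixed = NULL,
                                block_sets = c("2-10", "2-5", "6-10"),
                                state = c("stationary", "all")) {
  state <- match.arg(state)
  n_days <- summaries[[1]]$meta$n_days %||% max(vapply(summaries, function(s)
    s$meta$day %||% 1L, numeric(1)))
  mid <- Filter(function(s) {
    d <- s$meta$day %||% NA_integer_
    !is.na(d) && d > 1 && d < n_days
  }, summaries)
  if (length(mid) == 0)
    stop("adaptation_analysis: no adaptation days (2..n_days-1) present",
         call. = FALSE)
  tc_of <- function(s) {
    if (state == "stationary" && !is.null(s$timecourse_stationary))
      s$timecourse_stationary else s$timecourse
  }
  step <- attr(mid[[1]]$timecourse, "step") %||% 20
  pool <- do.call(rbind, lapply(mid, tc_of))
  attr(pool, "step") <- step
  # drop block sets entirely outside the protocol (e.g. 6-10 when fewer
  # blocks were run)
  max_block <- max(pool$block_index)
  block_sets <- Filter(function(bs) any(parse_block_set(bs) <= max_block),
                       block_sets)
  pooled_curve <- steady_state_subtract(pool, last_n = last_n,
                                        block_set = "2-10")
  pooled_fit <- fit_pooled_tau(pooled_curve)
  tau <- tau_fixed %||% pooled_fit$tau
  fits <- do.call(rbind, lapply(mid, function(s) {
    do.call(rbind, lapply(block_sets, function(bs) {
      cur <- steady_state_subtract(tc_of(s), last_n = last_n,
                                   block_set = bs)
      f <- fit_adaptation_amplitude(cur, tau)
      data.frame(animal_id = s$meta$animal_id, group = s$meta$group,
                 phenotype = s$meta$phenotype, age = s$meta$age,
                 day = s$meta$day, block_set = bs,
                 amplitude = f$amplitude, rss = f$rss)
    }))
  }))
  rownames(fits) <- NULL
  structure(list(tau = tau, pooled_fit = pooled_fit,
                 pooled_curve = pooled_curve, fits = fits,
                 last_n = last_n, state = state),
            class = "adaptation_analysis")
}

#' @export
print.adaptation_analysis <- function(x, ...) {
  cat(sprintf("Adaptation analysis: pooled tau = %.2f reversals (steady state = last %d reversals)\n",
              x$tau, x$last_n))
  agg <- stats::aggregate(amplitude ~ group + block_set, data = x$fits,
                          FUN = mean)
  print(agg, digits = 3)
  invisible(x)
}

#' Run the full analysis pipeline on a simulated cohort or session set
#'
#' Simulates (or loads) every session, analyses each one, and assembles the
#' study-level results: SRP tables and change-from-day-1 for all/stationary/
#' running epochs, the pooled and per-session adaptation fits, per-animal
#' elastic-net path regressor impacts, behaviour/plasticity correlations,
#' the day x phenotype repeated-measures ANOVA with per-day post hoc
#' comparisons, and group comparisons of adaptation amplitude and time
#' spent running. Optionally writes all tables, a JSON summary and a run
#' log to `out_dir`.
#'
#' @param config a [sim_config()] (ignored when `session_dirs` is given).
#' @param session_dirs optional character vector of session directories to
#'   load instead of simulating.
#' @param out_dir optional output directory for the report bundle.
#' @param seed optional override of `config$seed`.
#' @param enet_L penalties on the elastic-net path.
#' @param last_n steady-state window (reversals) for adaptation.
#' @param tau_fixed optional fixed adaptation time constant (reversals).
#' @param adaptation_state epochs used for the adaptation curves
#'   (see [adaptation_analysis()]).
#' @param verbose print progress.
#' @return list of class `srp_report` with elements `srp` (per state:
#'   `srp_change` objects), `adaptation`, `impact` (per-animal + group
#'   aggregate), `correlations`, `anova`, `posthoc`, `behaviour` (per
#'   session), `percent_running_test`, `summaries`, `truth` (when
#'   simulated).
#' @export
run_pipeline <- function(config = sim_config(), session_dirs = NULL,
                         out_dir = NULL, seed = NULL, enet_L = 10000,
                         last_n = 100, tau_fixed = NULL,
                         adaptation_state = c("stationary", "all"),
                         verbose = FALSE) {
  adaptation_state <- match.arg(adaptation_state)
  t_start <- Sys.time()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(session_dirs)) {
    co <- simulate_cohort(config, process = function(s, tr) {
      if (verbose) message("analysing ", s$meta$animal_id, " day ",
                           s$meta$day)
      analyze_session(s)
    })
    summaries <- co$sessions
    truth <- co$truth
  } else {
    summaries <- lapply(session_dirs, function(d)
      analyze_session(read_session(d)))
    truth <- NULL
  }

  ## SRP across days, per behavioural state
  srp <- lapply(c(all = "all", stationary = "stationary",
                  running = "running"), function(st) {
    tab <- suppressWarnings(daily_amplitudes(summaries, st))
    suppressWarnings(srp_change(tab))
  })

  ## within-block adaptation
  adaptation <- adaptation_analysis(summaries, last_n = last_n,
                                    tau_fixed = tau_fixed,
                                    state = adaptation_state)
  adapt_tests <- NULL
  groups <- unique(adaptation$fits$group)
  if (length(groups) == 2) {
    adapt_tests <- do.call(rbind, lapply(unique(adaptation$fits$block_set),
                                         function(bs) {
      f <- adaptation$fits[adaptation$fits$block_set == bs, ]
      tt <- group_ttest(f$amplitude[f$group == groups[1]],
                        f$amplitude[f$group == groups[2]])
      cbind(data.frame(block_set = bs, group_a = groups[1],
                       group_b = groups[2]), tt)
    }))
  }

  ## per-animal regularisation-path impact (familiar epochs)
  animals <- unique(vapply(summaries, function(s) s$meta$animal_id, ""))
  impact <- do.call(rbind, lapply(animals, function(a) {
    tab <- do.call(rbind, lapply(summaries, function(s)
      if (identical(s$meta$animal_id, a))
        s$epoch_table[s$epoch_table$familiarity == "familiar", ] else NULL))
    des <- suppressMessages(build_design(tab))
    path <- fit_enet_path(des, L = enet_L)
    im <- regressor_impact(path)
    cbind(data.frame(animal_id = a, group = tab$group[1],
                     phenotype = tab$phenotype[1], age = tab$age[1]), im)
  }))
  impact_group <- stats::aggregate(impact_pct ~ group + regressor,
                                   data = impact,
                                   FUN = function(v) c(mean = mean(v),
                                                       sem = stats::sd(v) /
                                                         sqrt(length(v))))
  impact_group <- cbind(impact_group[c("group", "regressor")],
                        as.data.frame(impact_group$impact_pct))

  ## behaviour table + correlations
  behaviour <- do.call(rbind, lapply(summaries, function(s)
    data.frame(animal_id = s$meta$animal_id, group = s$meta$group,
               day = s$meta$day, percent_running = s$percent_running,
               mean_pupil = s$mean_pupil)))
  fam_all <- srp$all$table[srp$all$table$familiarity == "familiar" &
                             srp$all$table$state == "all", ]
  behaviour <- merge(behaviour,
                     fam_all[c("animal_id", "day", "delta_from_day1")],
                     by = c("animal_id", "day"), all.x = TRUE)
  correlations <- tryCatch(behavior_day_correlations(behaviour),
                           error = function(e) NULL)

  ## group statistics on the familiar-stimulus change from day 1
  anova <- posthoc <- NULL
  if (length(unique(fam_all$group)) >= 2 &&
      length(unique(fam_all$day)) >= 2) {
    anova <- rm_anova(fam_all, response = "amplitude",
                      subject = "animal_id", within = "day",
                      between = "group")
    delta_d2 <- fam_all[fam_all$day > 1, ]
    an_delta <- rm_anova(delta_d2, response = "delta_from_day1",
                         subject = "animal_id", within = "day",
                         between = "group")
    posthoc <- posthoc_tukey(an_delta, "interaction_by_within")
  }
  pr_test <- if (length(groups) == 2) {
    group_ttest(behaviour$percent_running[behaviour$group == groups[1]],
                behaviour$percent_running[behaviour$group == groups[2]])
  } else NULL

  report <- structure(list(
    srp = srp, adaptation = adaptation, adaptation_tests = adapt_tests,
    impact = impact, impact_group = impact_group,
    behaviour = behaviour, correlations = correlations,
    anova = anova, posthoc = posthoc,
    percent_running_test = pr_test,
    summaries = summaries, truth = truth,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "srp_report")

  if (!is.null(out_dir)) write_report(report, out_dir, config)
  report
}

#' @export
print.srp_report <- function(x, ...) {
  cat("SRP/adaptation pipeline report\n")
  cat(sprintf("  %d sessions analysed in %.1f s\n", length(x$summaries),
              x$elapsed_s))
  cat(sprintf("  pooled adaptation tau: %.2f reversals\n", x$adaptation$tau))
  g <- x$srp$all$group
  g9 <- g[g$day == max(g$day) & g$familiarity == "familiar", ]
  for (i in seq_len(nrow(g9)))
    cat(sprintf("  final-day familiar SRP, %s: %.1f +- %.1f uV\n",
                g9$group[i], g9$mean[i], g9$sem[i]))
  invisible(x)
}

# write the report bundle: CSV tables, summary.json, run.log
write_report <- function(report, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) if (!is.null(d))
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wcsv(report$srp$all$table, "srp_table.csv")
  wcsv(report$srp$stationary$table, "srp_table_stationary.csv")
  wcsv(report$srp$running$table, "srp_table_running.csv")
  wcsv(as.data.frame(report$adaptation$pooled_curve),
       "adaptation_curve_pooled.csv")
  wcsv(report$adaptation$fits, "adaptation_fits.csv")
  wcsv(report$impact, "impact.csv")
  wcsv(report$behaviour, "behavior.csv")
  wcsv(do.call(rbind, lapply(report$summaries, function(s) s$srp_rows)),
       "vep_metrics.csv")
  wcsv(do.call(rbind, lapply(report$summaries, function(s) {
    if (is.null(s$pupil_onset)) return(NULL)
    data.frame(animal_id = s$meta$animal_id, day = s$meta$day,
               time_s = s$pupil_onset$time,
               pupil_response = s$pupil_onset$mean)
  })), "responses.csv")
  summary <- list(
    n_sessions = length(report$summaries),
    pooled_tau_reversals = report$adaptation$tau,
    srp_group_change = report$srp$all$group,
    adaptation_group = stats::aggregate(
      amplitude ~ group + block_set, data = report$adaptation$fits,
      FUN = mean),
    impact_group = report$impact_group,
    anova = if (!is.null(report$anova)) as.data.frame(report$anova),
    elapsed_s = report$elapsed_s)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log <- c(sprintf("srpvep %s", as.character(utils::packageVersion("srpvep"))),
           sprintf("R %s", getRversion()),
           sprintf("run at %s", format(Sys.time())),
           if (!is.null(config)) sprintf("seed %d", config$seed),
           sprintf("%d sessions, %.1f s elapsed", length(report$summaries),
                   report$elapsed_s))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
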
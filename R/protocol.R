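#' Configuration of the emulated 15-week training study
#'
#' Describes the protocol of the cycling study the synthetic generator
#' emulates: a baseline week of trials only (week 0), 8 weeks with 3
#' combined trial + 4-repetition session days per week (weeks 1-8), a rest
#' week with trials only (week 9), 4 weeks of 5 consecutive training days
#' with trials on days 1/3/5 and 5-repetition sessions on days 2/4
#' (weeks 10-13), and 2 final rest weeks with trials only (weeks 14-15).
#' Each performance trial is worth 100 tu and yields a measurement; session
#' intensity is prescribed at 85% of the last measured performance, so a
#' session's dose is `trial_load * reps * (P_mean / P_lim5)` with
#' `P_mean = intensity_fraction * P_lim5`.
#'
#' @param weeks_phase1 weeks in the first training period (default 8).
#' @param sessions_per_week_phase1 training days per week in phase 1
#'   (default 3).
#' @param rest_week index of the rest week between the phases (default 9).
#' @param weeks_phase2 weeks in the intensified period (default 4).
#' @param sessions_per_week_phase2 consecutive training days per week in
#'   phase 2 (default 5).
#' @param taper_weeks final weeks without training (default 2).
#' @param reps_phase1 5-min repetitions per session in phase 1 (default 4).
#' @param reps_phase2_extra_days repetitions on the session-only days of
#'   phase 2 (default 5).
#' @param intensity_fraction prescribed intensity relative to the last
#'   measured performance (default 0.85).
#' @param trial_load dose of one maximal 5-min trial (default 100 tu).
#' @param noise_sd standard deviation of the Gaussian measurement noise
#'   (watts; default 3).
#' @param seed integer seed for the noise draw.
#' @param baseline_perf true baseline performance (watts; default 250).
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(weeks_phase1 = 8L,
                            sessions_per_week_phase1 = 3L,
                            rest_week = 9L,
                            weeks_phase2 = 4L,
                            sessions_per_week_phase2 = 5L,
                            taper_weeks = 2L,
                            reps_phase1 = 4L,
                            reps_phase2_extra_days = 5L,
                            intensity_fraction = 0.85,
                            trial_load = 100,
                            noise_sd = 3,
                            seed = 1L,
                            baseline_perf = 250) {
  cfg <- list(weeks_phase1 = as.integer(weeks_phase1),
              sessions_per_week_phase1 = as.integer(sessions_per_week_phase1),
              rest_week = as.integer(rest_week),
              weeks_phase2 = as.integer(weeks_phase2),
              sessions_per_week_phase2 = as.integer(sessions_per_week_phase2),
              taper_weeks = as.integer(taper_weeks),
              reps_phase1 = as.integer(reps_phase1),
              reps_phase2_extra_days = as.integer(reps_phase2_extra_days),
              intensity_fraction = intensity_fraction,
              trial_load = trial_load,
              noise_sd = noise_sd,
              seed = as.integer(seed),
              baseline_perf = baseline_perf)
  counts <- c("weeks_phase1", "sessions_per_week_phase1", "weeks_phase2",
              "sessions_per_week_phase2", "taper_weeks", "reps_phase1",
              "reps_phase2_extra_days")
  bad <- counts[vapply(cfg[counts], function(v) v < 1L, logical(1))]
  if (length(bad)) {
    stop("count(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$sessions_per_week_phase1 > 7L || cfg$sessions_per_week_phase2 > 7L) {
    stop("at most 7 sessions per week", call. = FALSE)
  }
  if (cfg$rest_week != cfg$weeks_phase1 + 1L) {
    stop("phases overlap: rest_week must directly follow phase 1",
         call. = FALSE)
  }
  if (cfg$intensity_fraction <= 0 || cfg$intensity_fraction > 1) {
    stop("intensity_fraction must be in (0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$baseline_perf <= 0) {
    stop("baseline_perf must be > 0", call. = FALSE)
  }
  class(cfg) <- "protocol_config"
  cfg
}

# weekdays (0 = Monday) carrying n training days: Mon/Wed/Fri spacing when
# they fit, otherwise consecutive from Monday
training_weekdays <- function(n) {
  if (n <= 4L) seq(0L, by = 2L, length.out = n) else 0L:(n - 1L)
}

#' Build the day-by-day schedule of the protocol
#'
#' Expands a [protocol_config()] into one row per day with the session
#' repetitions (0 on non-session days) and a trial flag. Week 0 carries
#' three trials (Mon/Wed/Fri) and no sessions; rest and taper weeks carry
#' two trials each (Tue/Fri); in phase 2 trials sit on training days 1, 3
#' and 5 of the block. The default configuration yields 45 trials, within
#' the study's 40-46.
#'
#' @param config a [protocol_config()].
#' @return `data.frame` with columns `day`, `week`, `weekday`,
#'   `session_reps`, `trial`.
#' @export
build_protocol <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  n_weeks <- 1L + config$weeks_phase1 + 1L + config$weeks_phase2 +
    config$taper_weeks
  days <- seq.int(0L, n_weeks * 7L - 1L)
  week <- days %/% 7L
  weekday <- days %% 7L
  reps <- integer(length(days))
  trial <- logical(length(days))

  rest_weeks <- c(config$rest_week,
                  (config$rest_week + config$weeks_phase2 + 1L):(n_weeks - 1L))
  phase1 <- seq_len(config$weeks_phase1)
  phase2 <- config$rest_week + seq_len(config$weeks_phase2)

  wd1 <- training_weekdays(config$sessions_per_week_phase1)
  wd2 <- training_weekdays(config$sessions_per_week_phase2)
  # within the phase-2 block: odd positions (1st, 3rd, 5th day) are
  # trial + phase-1-style session, even positions are extra-rep sessions
  wd2_trial <- wd2[seq_along(wd2) %% 2L == 1L]
  wd2_extra <- setdiff(wd2, wd2_trial)

  for (i in seq_along(days)) {
    w <- week[i]; d <- weekday[i]
    if (w == 0L) {
      trial[i] <- d %in% c(0L, 2L, 4L)
    } else if (w %in% phase1) {
      if (d %in% wd1) {
        trial[i] <- TRUE
        reps[i] <- config$reps_phase1
      }
    } else if (w %in% phase2) {
      if (d %in% wd2_trial) {
        trial[i] <- TRUE
        reps[i] <- config$reps_phase1
      } else if (d %in% wd2_extra) {
        reps[i] <- config$reps_phase2_extra_days
      }
    } else if (w %in% rest_weeks) {
      trial[i] <- d %in% c(1L, 4L)
    }
  }
  data.frame(day = days, week = week, weekday = weekday,
             session_reps = reps, trial = trial)
}

#' Generate a synthetic subject under the study protocol
#'
#' Walks the protocol day by day in closed loop: each session's dose is
#' computed from the current last-measured performance as
#' `trial_load * reps * (P_mean / P_lim5)` with
#' `P_mean = intensity_fraction * P_lim5` (so the per-session dose is
#' constant at `trial_load * reps * intensity_fraction` when intensity
#' tracks performance, e.g. 340 tu for a 4-repetition session at 85%);
#' each trial adds `trial_load` tu and yields a measurement equal to the
#' model observable plus Gaussian noise. The day-0 trial's load is recorded
#' as 0, since the recursion initialises the day-0 dose to zero.
#'
#' @inheritParams simulate_trajectory
#' @param config a [protocol_config()]; its `seed` makes generation
#'   reproducible (the schedule and loads are deterministic, only the
#'   measurement noise varies between seeds).
#' @return a [training_series()] with attributes `"true_params"`,
#'   `"true_kind"` and `"config"`.
#' @examples
#' p <- model_params("TI", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
#'                   k_i = 0.0021)
#' s <- generate_subject("TI", p, protocol_config(noise_sd = 3, seed = 42))
#' n_measurements(s)
#' @export
generate_subject <- function(kind, params, config = protocol_config(),
                             perf_decay = c("euler", "exp")) {
  kind <- match_kind(kind)
  perf_decay <- match.arg(perf_decay)
  validate_params(kind, params)
  stopifnot(inherits(config, "protocol_config"))
  sched <- build_protocol(config)
  n <- nrow(sched)

  k_off <- params[["k_off"]]
  keep <- if (perf_decay == "euler") 1 - k_off else exp(-k_off)
  k0 <- (1 - keep) * config$baseline_perf
  decay_s <- exp(-params[["k_s1"]])
  k_s2 <- params[["k_s2"]]
  k_i <- param_or_zero(params, "k_i")
  k_f1 <- param_or_zero(params, "k_f1")
  decay_f <- exp(-if ("k_f2" %in% names(params)) params[["k_f2"]] else 1)

  loads <- numeric(n)
  meas <- rep(NA_real_, n)
  with_seed(config$seed, {
    sig <- fat <- 0
    perf <- config$baseline_perf
    prod <- k0
    for (i in seq_len(n)) {
      w <- 0
      if (i > 1L) {                       # W_0 is initialised to 0
        if (sched$trial[i]) w <- w + config$trial_load
        if (sched$session_reps[i] > 0L) {
          # tu rule: trial_load * reps * (P_mean / P_lim5'); the intensity
          # prescription P_mean = intensity_fraction * last measured
          # P_lim5' makes the ratio exactly intensity_fraction, so the
          # per-session dose is constant even as performance drifts
          w <- w + config$trial_load * sched$session_reps[i] *
            config$intensity_fraction
        }
        # state update (day i), using yesterday's production
        perf_new <- keep * perf + prod
        sig <- sig * decay_s + w
        prod <- k0 + k_s2 * (1 - k_i * w) * sig
        fat <- fat * decay_f + k_f1 * w
        perf <- perf_new
      }
      loads[i] <- w
      if (sched$trial[i]) {
        obs_state <- if (kind %in% c("TF", "TIF")) perf - fat else perf
        if (!is.finite(obs_state)) {
          stop("model diverged on day ", i - 1L,
               ": non-finite performance", call. = FALSE)
        }
        meas[i] <- obs_state + stats::rnorm(1L, 0, config$noise_sd)
      }
    }
  })
  out <- training_series(load = loads, performance = meas)
  attr(out, "true_params") <- params
  attr(out, "true_kind") <- kind
  attr(out, "config") <- config
  out
}

#' Parameter-recovery simulation study
#'
#' Generates replicate synthetic subjects from known parameters, fits each
#' one, and summarises the estimation error per parameter. The r-th
#' replicate uses noise seed `config$seed + r` and fit seed
#' `config$seed + 1000 + r`, so the whole study is reproducible.
#'
#' @inheritParams generate_subject
#' @param true_params generating parameter vector for `kind`.
#' @param n_replicates number of replicate subjects (>= 10).
#' @param fit_options list of arguments passed on to [fit_model()]
#'   (e.g. `n_starts`).
#' @return a `recovery_study` list: `estimates` (replicate x parameter
#'   matrix, `NA` rows for failed fits), `summary` (per-parameter true
#'   value, median estimate, bias, median absolute relative error),
#'   `n_failed`, `kind`, `config`.
#' @export
recovery_study <- function(kind, true_params, config = protocol_config(),
                           n_replicates = 10L, fit_options = list()) {
  kind <- match_kind(kind)
  if (n_replicates < 10L) {
    stop("need at least 10 replicates for a meaningful summary",
         call. = FALSE)
  }
  pnames <- model_param_names(kind)
  est <- matrix(NA_real_, n_replicates, length(pnames),
                dimnames = list(NULL, pnames))
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    subj <- generate_subject(kind, true_params, cfg_r)
    fit <- tryCatch(
      do.call(fit_model,
              c(list(kind = kind, series = subj,
                     seed = config$seed + 1000L + r), fit_options)),
      error = function(e) NULL)
    if (is.null(fit)) failed <- failed + 1L else est[r, ] <- fit$params
  }
  truth <- vapply(pnames, function(nm) true_params[[nm]], numeric(1))
  rel_err <- sweep(est, 2L, truth, "/") - 1
  summ <- data.frame(
    param = pnames,
    true = truth,
    median_est = apply(est, 2L, stats::median, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - truth,
    median_abs_rel_err = apply(abs(rel_err), 2L, stats::median,
                               na.rm = TRUE),
    row.names = NULL)
  structure(list(estimates = est, summary = summ, n_failed = failed,
                 kind = kind, config = config),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery, Model %s: %d replicates (%d failed)\n",
              x$kind, nrow(x$estimates), x$n_failed))
  print(x$summary, digits = 4)
  invisible(x)
}
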
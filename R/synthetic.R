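#' Configuration for a synthetic validation study
#'
#' Encodes the study conditions emulated by the generator: ~30 athletes each
#' performing 1-3 maximal 30 m sprints, measured simultaneously by a
#' high-rate smoothed criterion instrument (laser gun, resampled at 1000 Hz)
#' and a low-rate noisy positional-tracking device (LPS, 20 Hz) that also
#' reports an acceleration channel.
#'
#' @param n_athletes Number of athletes (default 30).
#' @param trials_min,trials_max Per-athlete sprint count range (default 1-3).
#' @param sprint_distance Sprint length, m (default 30).
#' @param criterion_rate Criterion sampling rate, Hz (default 1000).
#' @param device_rate Device sampling rate, Hz (default 20).
#' @param criterion_noise_sd Additive Gaussian velocity noise on the
#'   criterion, m/s (default 0.03).
#' @param device_noise_sd Additive Gaussian velocity noise on the device,
#'   m/s (default 0.10).
#' @param smoothing_cutoff Zero-phase low-pass cut-off applied to the noisy
#'   criterion trace, Hz (default 10); stands in for the criterion
#'   manufacturer's undisclosed smoother.
#' @param mss_range,tau_range,tc_range Uniform sampling ranges for the true
#'   athlete parameters: MSS m/s (default 7-10), TAU s (default 0.9-1.5),
#'   TC s (default 0.05-0.30).
#' @param seed Integer seed governing all randomness.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_athletes = 30L, trials_min = 1L, trials_max = 3L,
                         sprint_distance = 30, criterion_rate = 1000,
                         device_rate = 20, criterion_noise_sd = 0.03,
                         device_noise_sd = 0.10, smoothing_cutoff = 10,
                         mss_range = c(7.0, 10.0), tau_range = c(0.9, 1.5),
                         tc_range = c(0.05, 0.30), seed = 1L) {
  cfg <- list(
    n_athletes = as.integer(n_athletes), trials_min = as.integer(trials_min),
    trials_max = as.integer(trials_max), sprint_distance = sprint_distance,
    criterion_rate = criterion_rate, device_rate = device_rate,
    criterion_noise_sd = criterion_noise_sd, device_noise_sd = device_noise_sd,
    smoothing_cutoff = smoothing_cutoff, mss_range = mss_range,
    tau_range = tau_range, tc_range = tc_range, seed = as.integer(seed)
  )
  if (cfg$n_athletes < 2L) stop("config error: n_athletes must be >= 2", call. = FALSE)
  if (cfg$trials_min < 1L || cfg$trials_max < cfg$trials_min) {
    stop("config error: invalid trials range", call. = FALSE)
  }
  if (cfg$criterion_rate <= 0 || cfg$device_rate <= 0) {
    stop("config error: rates must be positive", call. = FALSE)
  }
  for (r in list(cfg$mss_range, cfg$tau_range, cfg$tc_range)) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop("config error: parameter ranges must be ordered pairs", call. = FALSE)
    }
  }
  if (cfg$criterion_noise_sd < 0 || cfg$device_noise_sd < 0) {
    stop("config error: noise sds must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "study_config")
}

#' Sample a synthetic athlete population
#'
#' Draws each athlete's true parameters uniformly from the configured ranges
#' (MSS, TAU, TC independent) and derives MAC and PMAX. Deterministic per
#' `config$seed`.
#'
#' @param config A [study_config()].
#' @return A data frame with columns `athlete_id`, `mss`, `tau`, `tc`, `mac`,
#'   `pmax`; one row per athlete.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n <- config$n_athletes
  mss <- stats::runif(n, config$mss_range[1], config$mss_range[2])
  tau <- stats::runif(n, config$tau_range[1], config$tau_range[2])
  tc <- stats::runif(n, config$tc_range[1], config$tc_range[2])
  data.frame(
    athlete_id = sprintf("ath%02d", seq_len(n)),
    mss = mss, tau = tau, tc = tc, mac = mss / tau, pmax = mss * (mss / tau) / 4
  )
}

population_profile <- function(pop, i) {
  av_profile(mss = pop$mss[i], tau = pop$tau[i], tc = pop$tc[i])
}

#' Simulate a criterion (laser-gun style) velocity trace
#'
#' Samples the mono-exponential velocity curve at `criterion_rate` over the
#' time needed to cover `sprint_distance` (found by inverting the analytic
#' distance curve), adds independent Gaussian velocity noise, and applies a
#' zero-phase 2nd-order Butterworth low-pass at `smoothing_cutoff`. With
#' `criterion_noise_sd = 0` no noise is added and no smoothing is applied, so
#' the trace equals the model exactly at the sample times.
#'
#' Uses the current RNG state (seed upstream for reproducibility).
#'
#' @param profile The athlete's true [av_profile()].
#' @param config A [study_config()].
#' @param athlete_id,trial_id Identifiers attached to the trace.
#' @return A `velocity_trace` with `source = "criterion"`.
#' @export
simulate_criterion_trace <- function(profile, config,
                                     athlete_id = NA_character_,
                                     trial_id = NA_character_) {
  stopifnot(inherits(config, "study_config"))
  t_end <- time_to_distance(profile, config$sprint_distance)
  t <- seq(0, t_end, by = 1 / config$criterion_rate)
  v <- velocity_at_time(profile, t)
  sd <- config$criterion_noise_sd
  if (sd > 0) {
    v <- v + stats::rnorm(length(v), sd = sd)
    v <- lowpass_zerophase(v, config$smoothing_cutoff, config$criterion_rate)
  }
  velocity_trace(t, pmax(v, 0), source = "criterion",
                 athlete_id = athlete_id, trial_id = trial_id)
}

# Zero-phase 2nd-order Butterworth low-pass with odd-reflection edge padding
# (forward-backward filtering alone leaves transients at both ends).
lowpass_zerophase <- function(x, cutoff_hz, rate_hz) {
  bf <- signal::butter(2, cutoff_hz / (rate_hz / 2))
  npad <- min(length(x) - 1L, 3L * ceiling(rate_hz / cutoff_hz))
  head_pad <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  n <- length(x)
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(npad + 1L):(npad + n)]
}

# Device-reported acceleration channel: central differences of a 5-sample
# moving-average velocity (one-sided at the ends).
device_acceleration <- function(v, dt) {
  n <- length(v)
  vs <- stats::filter(v, rep(1 / 5, 5), sides = 2)
  vs <- as.numeric(vs)
  # fill the two edge samples the moving average leaves NA
  vs[is.na(vs)] <- v[is.na(vs)]
  a <- numeric(n)
  a[2:(n - 1)] <- (vs[3:n] - vs[1:(n - 2)]) / (2 * dt)
  a[1] <- (vs[2] - vs[1]) / dt
  a[n] <- (vs[n] - vs[n - 1]) / dt
  a
}

#' Simulate a continuous device (LPS-style) stream for one athlete
#'
#' Builds one continuous 20 Hz stream interleaving low-velocity filler with
#' the athlete's sprints: for each trial, a walking segment (velocity random
#' walk within 0.5-2.0 m/s for 30-90 s, exercising trial detection), a
#' stationary "set" phase (~4 s near 0 m/s), the sprint itself (model
#' velocity until `sprint_distance` is covered), and a deceleration ramp
#' (-3 m/s^2) back to a stop. Gaussian velocity noise of sd
#' `device_noise_sd` is added throughout; the acceleration channel is the
#' central difference of a 5-sample moving-average velocity, mirroring a
#' device-computed signal. Uses the current RNG state.
#'
#' @param profile The athlete's true [av_profile()].
#' @param n_trials Number of sprints to embed (1-3 in the study design).
#' @param config A [study_config()].
#' @param athlete_id Identifier attached to the stream.
#' @return A `velocity_trace` with `source = "device"`, an `acceleration`
#'   column, and attribute `truth`: a data frame of ground-truth windows
#'   (`trial`, `onset_s` motion onset, `peak_s` time of peak true velocity,
#'   `end_s` end of deceleration).
#' @export
simulate_device_stream <- function(profile, n_trials, config,
                                   athlete_id = NA_character_) {
  stopifnot(inherits(config, "study_config"), n_trials >= 1L)
  dt <- 1 / config$device_rate
  sd <- config$device_noise_sd
  segs <- list()
  truth <- data.frame(trial = integer(0), onset_s = numeric(0),
                      peak_s = numeric(0), end_s = numeric(0))
  t_cursor <- 0
  push <- function(v) segs[[length(segs) + 1L]] <<- v

  # opening stand
  n_stand <- round(5 / dt)
  push(rep(0.02, n_stand)); t_cursor <- t_cursor + n_stand * dt

  for (k in seq_len(n_trials)) {
    # walking filler, random walk clamped to [0.5, 2.0] m/s
    n_walk <- round(stats::runif(1, 30, 90) / dt)
    w <- numeric(n_walk)
    w[1] <- stats::runif(1, 0.8, 1.5)
    steps <- stats::rnorm(n_walk - 1, sd = 0.05)
    for (i in 2:n_walk) w[i] <- min(max(w[i - 1] + steps[i - 1], 0.5), 2.0)
    push(w); t_cursor <- t_cursor + n_walk * dt

    # stationary set position
    n_set <- round(4 / dt)
    push(rep(0.02, n_set)); t_cursor <- t_cursor + n_set * dt

    # the sprint itself
    t_sprint_end <- time_to_distance(profile, config$sprint_distance)
    ts <- seq(0, t_sprint_end, by = dt)
    vs <- velocity_at_time(profile, ts)
    onset <- t_cursor
    push(vs); t_cursor <- t_cursor + length(ts) * dt
    peak_s <- onset + ts[length(ts)]

    # deceleration ramp back to a stop at -3 m/s^2
    v_end <- vs[length(vs)]
    vd <- seq(v_end - 3 * dt, 0.02, by = -3 * dt)
    vd <- pmax(vd, 0.02)
    push(vd); t_cursor <- t_cursor + length(vd) * dt
    truth <- rbind(truth, data.frame(trial = k, onset_s = onset,
                                     peak_s = peak_s, end_s = t_cursor))
  }
  # closing stand
  push(rep(0.02, round(10 / dt)))

  v <- unlist(segs, use.names = FALSE)
  if (sd > 0) v <- v + stats::rnorm(length(v), sd = sd)
  v <- pmax(v, 0)
  t <- seq(0, by = dt, length.out = length(v))
  a <- device_acceleration(v, dt)
  tr <- velocity_trace(t, v, acceleration = a, source = "device",
                       athlete_id = athlete_id)
  attr(tr, "truth") <- truth
  tr
}

#' Run the full synthetic validation study end to end
#'
#' Generates a population and its paired measurements, then mirrors the study
#' analysis: criterion traces are filtered and fitted with the time-velocity
#' method (per trial, best-aggregated per athlete); device streams are
#' segmented into trials, each fitted with the time-velocity method, and the
#' whole stream's velocity-acceleration samples are pooled into one in-situ
#' fit per athlete. Paired estimates are assembled with trials as the
#' observation unit for the time-velocity comparison and athletes for the
#' velocity-acceleration comparison, and summarised with
#' [agreement_report()]. Athletes with no detected sprint are dropped with a
#' warning.
#'
#' @param config A [study_config()].
#' @param n_resamples Bootstrap resamples per interval (default 5000); `0`
#'   gives point estimates only.
#' @param conf,threshold Passed to [agreement_report()].
#' @return A list of class `validation_study`: `report` (an
#'   `agreement_report`), `pairs` (the paired-estimates data frame), `truth`
#'   (list: `population`, `trial_counts`, per-athlete ground-truth windows)
#'   and `config`.
#' @export
run_validation_study <- function(config, n_resamples = 5000L, conf = 0.95,
                                 threshold = 5) {
  stopifnot(inherits(config, "study_config"))
  pop <- sample_population(config)  # seeds the RNG stream
  trial_choices <- seq(config$trials_min, config$trials_max)
  n_trials <- if (length(trial_choices) == 1L) {
    rep(trial_choices, config$n_athletes)
  } else {
    sample(trial_choices, config$n_athletes, replace = TRUE)
  }

  params <- c("MSS", "TAU", "MAC", "PMAX")
  pull_par <- function(profile) {
    c(MSS = profile$mss, TAU = profile$tau, MAC = profile$mac,
      PMAX = profile$pmax)
  }
  pair_rows <- list()
  windows_truth <- list()
  dropped <- character(0)

  for (i in seq_len(config$n_athletes)) {
    aid <- pop$athlete_id[i]
    truth_profile <- population_profile(pop, i)

    # criterion: per-trial traces and fits
    crit_profiles <- vector("list", n_trials[i])
    for (k in seq_len(n_trials[i])) {
      tr <- simulate_criterion_trace(truth_profile, config, athlete_id = aid,
                                     trial_id = sprintf("T%02d", k))
      crit_profiles[[k]] <- fit_time_velocity(filter_trace(tr))$profile
    }
    crit_best <- aggregate_best(crit_profiles)

    # device: continuous stream, segmentation, per-trial fits
    stream <- simulate_device_stream(truth_profile, n_trials[i], config,
                                     athlete_id = aid)
    windows_truth[[aid]] <- attr(stream, "truth")
    wins <- detect_sprints(stream)
    if (nrow(wins) == 0L) {
      warning("athlete ", aid, " had no detectable sprint; dropped")
      dropped <- c(dropped, aid)
      next
    }
    n_pairable <- min(nrow(wins), n_trials[i])
    dev_tv <- vector("list", n_pairable)
    for (k in seq_len(n_pairable)) {
      wtr <- extract_window(stream, wins$start_s[k], wins$end_s[k],
                            trial_id = sprintf("T%02d", k))
      dev_tv[[k]] <- fit_time_velocity(filter_trace(wtr))$profile
    }

    # time-velocity pairs: one observation per trial
    for (k in seq_len(n_pairable)) {
      cp <- pull_par(crit_profiles[[k]])
      dp <- pull_par(dev_tv[[k]])
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        parameter = params, method = "time_velocity",
        unit_id = sprintf("%s_T%02d", aid, k),
        criterion = unname(cp[params]), device = unname(dp[params])
      )
    }

    # velocity-acceleration: pooled in-situ fit on the whole stream,
    # paired against the criterion best-aggregate (one observation/athlete)
    sam <- av_samples(stream$velocity, stream$acceleration,
                      trial_id = aid, time = stream$time)
    va_fit <- tryCatch(profile_insitu(sam), error = function(e) NULL)
    if (!is.null(va_fit)) {
      cp <- pull_par(crit_best)
      dp <- pull_par(va_fit$profile)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        parameter = params, method = "velocity_acceleration",
        unit_id = aid,
        criterion = unname(cp[params]), device = unname(dp[params])
      )
    }
  }
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  report <- agreement_report(pairs, n_resamples = n_resamples, conf = conf,
                             threshold = threshold, seed = config$seed)
  structure(
    list(report = report, pairs = pairs,
         truth = list(population = pop, trial_counts = n_trials,
                      windows = windows_truth, dropped = dropped),
         config = config),
    class = "validation_study"
  )
}

#' @export
print.validation_study <- function(x, ...) {
  cat(sprintf(
    "<validation_study: %d athletes, %d trials, seed %d>\n",
    x$config$n_athletes, sum(x$truth$trial_counts), x$config$seed
  ))
  print(as.data.frame(x$report), digits = 4)
  invisible(x)
}
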
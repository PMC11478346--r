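#' Build a velocity-acceleration sample table
#'
#' Instantaneous (velocity, acceleration) observations harvested from a
#' tracking-system stream, pooled over one or more sprint trials, feeding the
#' in-situ (velocity-acceleration) profiling method.
#'
#' @param velocity Velocities, m/s.
#' @param acceleration Accelerations, m/s^2.
#' @param trial_id Optional trial identifiers (recycled).
#' @param time Optional sample times, s (provenance only).
#' @return A data frame of class `av_samples`.
#' @export
av_samples <- function(velocity, acceleration, trial_id = NA_character_, time = NULL) {
  if (length(velocity) != length(acceleration)) {
    stop("`velocity` and `acceleration` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(velocity)) || any(!is.finite(acceleration))) {
    stop("samples must be finite", call. = FALSE)
  }
  df <- data.frame(
    velocity = as.numeric(velocity),
    acceleration = as.numeric(acceleration),
    trial_id = rep_len(as.character(trial_id), length(velocity))
  )
  if (!is.null(time)) df$time <- as.numeric(time)
  structure(df, class = c("av_samples", "data.frame"))
}

#' Filter velocity-acceleration samples to the sprint-relevant region
#'
#' Keeps samples with strictly positive acceleration above `a_min` and
#' velocity strictly above `v_min` (default 3 m/s): only accelerating,
#' already-fast observations inform the upper part of the
#' acceleration-velocity line. Both inequalities are strict.
#'
#' @param samples An [av_samples()] table.
#' @param v_min Velocity threshold, m/s (exclusive).
#' @param a_min Acceleration threshold, m/s^2 (exclusive).
#' @return The filtered `av_samples` (possibly empty).
#' @export
filter_av_samples <- function(samples, v_min = 3.0, a_min = 0.0) {
  stopifnot(inherits(samples, "av_samples"))
  keep <- samples$velocity > v_min & samples$acceleration > a_min
  structure(samples[keep, , drop = FALSE], class = class(samples))
}

#' Select the top accelerations within velocity bins
#'
#' Pools samples across trials, partitions velocity into half-open bins
#' `[anchor + i*w, anchor + (i+1)*w)` of width `w` (default 0.2 m/s) anchored
#' at the filtering threshold (default 3 m/s), and keeps the `top_k` (default
#' 2) largest-acceleration samples in each non-empty bin (all of them when a
#' bin holds fewer). Ties in acceleration keep the earlier sample (stable
#' order).
#'
#' @param samples Filtered [av_samples()].
#' @param bin_width Bin width, m/s.
#' @param top_k Samples retained per bin.
#' @param anchor Left edge of the first bin, m/s.
#' @return An `av_samples` table of the selected points, with a `bin` column
#'   (integer bin index).
#' @export
select_bin_maxima <- function(samples, bin_width = 0.2, top_k = 2L, anchor = 3.0) {
  stopifnot(inherits(samples, "av_samples"), bin_width > 0, top_k >= 1L)
  if (nrow(samples) == 0L) {
    stop("insufficient data: no samples to bin", call. = FALSE)
  }
  bin <- as.integer(floor((samples$velocity - anchor) / bin_width))
  picked <- unlist(lapply(split(seq_len(nrow(samples)), bin), function(idx) {
    # order() is stable: ties keep the earlier sample
    idx[order(-samples$acceleration[idx])][seq_len(min(top_k, length(idx)))]
  }), use.names = FALSE)
  picked <- sort(picked)
  if (length(unique(bin[picked])) < 2L) {
    stop("insufficient data: need samples in at least 2 velocity bins",
         call. = FALSE)
  }
  out <- samples[picked, , drop = FALSE]
  out$bin <- bin[picked]
  structure(out, class = class(samples))
}

#' Fit the acceleration-velocity line (in-situ method)
#'
#' Fits `a = b0 + b1 * v` by (optionally velocity-weighted) least squares to
#' the selected per-bin maxima and reads the profile off the line: the maximal
#' acceleration MAC is the intercept `b0`, the maximal sprinting speed MSS is
#' the x-intercept `-b0/b1`, then `TAU = MSS/MAC` and `PMAX = MSS*MAC/4`. No
#' time correction is involved. With `weighting = "velocity"` the weights are
#' `v` rescaled to mean 1 (higher-velocity observations count more).
#'
#' A physically meaningful profile needs a decreasing line with positive
#' intercept; `b1 >= 0` or `b0 <= 0` raises a non-physical-profile error.
#'
#' @param points Selected [av_samples()] (at least 3 points spanning at least
#'   2 distinct velocities).
#' @param weighting `"velocity"` (default) or `"none"`.
#' @return A `sprint_fit` with `method = "velocity_acceleration"`; `rse` is the
#'   unweighted residual standard error of the line, m/s^2, df = n - 2.
#' @export
fit_velocity_acceleration <- function(points, weighting = c("velocity", "none")) {
  stopifnot(inherits(points, "av_samples"))
  weighting <- match.arg(weighting)
  n <- nrow(points)
  if (n < 3L || length(unique(points$velocity)) < 2L) {
    stop("insufficient data: need >= 3 points spanning >= 2 velocity bins",
         call. = FALSE)
  }
  v <- points$velocity
  a <- points$acceleration
  w <- if (weighting == "velocity") v / mean(v) else rep(1, n)
  fit <- stats::lm(a ~ v, weights = w)
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  if (!is.finite(b1) || b1 >= 0) {
    stop("non-physical profile: acceleration does not decrease with velocity",
         call. = FALSE)
  }
  if (b0 <= 0) {
    stop("non-physical profile: non-positive intercept (MAC)", call. = FALSE)
  }
  mss <- -b0 / b1
  profile <- av_profile(mss = mss, tau = mss / b0)
  res <- a - (b0 + b1 * v)
  new_sprint_fit(
    profile = profile,
    rse = sqrt(sum(res^2) / (n - 2)),
    n_used = n,
    converged = TRUE,
    method = "velocity_acceleration"
  )
}

#' In-situ profile from raw velocity-acceleration samples
#'
#' Convenience pipeline: [filter_av_samples()] then [select_bin_maxima()] then
#' [fit_velocity_acceleration()].
#'
#' @param samples Raw [av_samples()].
#' @param v_min,a_min Filtering thresholds.
#' @param bin_width,top_k Binning parameters.
#' @param weighting Passed to [fit_velocity_acceleration()].
#' @return A `sprint_fit`.
#' @export
profile_insitu <- function(samples, v_min = 3.0, a_min = 0.0,
                           bin_width = 0.2, top_k = 2L,
                           weighting = c("velocity", "none")) {
  filtered <- filter_av_samples(samples, v_min = v_min, a_min = a_min)
  if (nrow(filtered) == 0L) {
    stop("insufficient data: no samples pass the velocity/acceleration filter",
         call. = FALSE)
  }
  pts <- select_bin_maxima(filtered, bin_width = bin_width, top_k = top_k,
                           anchor = v_min)
  fit_velocity_acceleration(pts, weighting = match.arg(weighting))
}

#' Best-value aggregation of profiles across trials
#'
#' Combines per-trial profile estimates into a single per-athlete profile by
#' taking the maximum of MSS, MAC and PMAX and the minimum of TAU (the best
#' value of each parameter). Because the components can come from different
#' trials, the result is marked as an aggregate and the within-trial identity
#' `MAC = MSS/TAU` is suspended; TC is dropped.
#'
#' @param profiles A non-empty list of [av_profile()] objects.
#' @return An aggregate `av_profile` (see [is_aggregate()]).
#' @export
aggregate_best <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L ||
      !all(vapply(profiles, inherits, logical(1), "av_profile"))) {
    stop("`profiles` must be a non-empty list of av_profile objects",
         call. = FALSE)
  }
  pull <- function(f) vapply(profiles, `[[`, numeric(1), f)
  new_av_profile(
    mss = max(pull("mss")), tau = min(pull("tau")),
    mac = max(pull("mac")), pmax = max(pull("pmax")),
    tc = NA_real_, aggregate = TRUE
  )
}
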
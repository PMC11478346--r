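#' Construct an acceleration-velocity profile
#'
#' An acceleration-velocity profile (AVP) summarises short-sprint capability
#' through the parameters of the mono-exponential sprint model:
#' \deqn{v(t) = MSS (1 - e^{-(t + TC)/TAU})}
#' where `MSS` is the maximal sprinting speed (m/s), `TAU` the relative
#' acceleration time constant (s) and `TC` an optional time correction (s)
#' absorbing start-trigger offset. The derived parameters are the maximal
#' acceleration `MAC = MSS / TAU` (m/s^2, the y-intercept of the linear
#' acceleration-velocity relation) and the relative maximal propulsive power
#' `PMAX = MSS * MAC / 4` (W/kg).
#'
#' @param mss Maximal sprinting speed, m/s. Must be positive.
#' @param tau Relative acceleration time constant, s. Must be positive.
#' @param tc Time correction, s, or `NULL` when the estimation method does not
#'   model one (the velocity-acceleration method). May be negative.
#'
#' @return An object of class `av_profile`: a list with elements `mss`, `tau`,
#'   `mac`, `pmax` and `tc` (`NA` when absent).
#' @examples
#' p <- av_profile(mss = 9, tau = 1.2)
#' p$mac   # 7.5
#' p$pmax  # 16.875
#' @export
av_profile <- function(mss, tau, tc = NULL) {
  if (!is.numeric(mss) || length(mss) != 1L || !is.finite(mss) || mss <= 0) {
    stop("`mss` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive finite number", call. = FALSE)
  }
  if (!is.null(tc) && (!is.numeric(tc) || length(tc) != 1L || !is.finite(tc))) {
    stop("`tc` must be a single finite number or NULL", call. = FALSE)
  }
  mac <- mss / tau
  new_av_profile(
    mss = mss, tau = tau, mac = mac, pmax = mss * mac / 4,
    tc = if (is.null(tc)) NA_real_ else as.numeric(tc)
  )
}

# Low-level constructor; `aggregate = TRUE` marks profiles assembled from the
# best components of several trials, for which MAC = MSS/TAU need not hold.
new_av_profile <- function(mss, tau, mac, pmax, tc = NA_real_, aggregate = FALSE) {
  structure(
    list(mss = mss, tau = tau, mac = mac, pmax = pmax, tc = tc),
    aggregate = aggregate,
    class = "av_profile"
  )
}

#' Test whether a profile is a cross-trial aggregate
#'
#' Aggregate profiles combine the best parameter values across trials
#' ([aggregate_best()]); their components may come from different sprints, so
#' the within-trial identities `MAC = MSS/TAU` and `PMAX = MSS*MAC/4` are
#' suspended for them.
#'
#' @param profile An `av_profile`.
#' @return `TRUE` for aggregates, `FALSE` otherwise.
#' @export
is_aggregate <- function(profile) {
  isTRUE(attr(profile, "aggregate"))
}

#' Validate an acceleration-velocity profile
#'
#' Checks positivity of `MSS`, `TAU`, `MAC` and, for non-aggregate profiles,
#' the identities `MAC = MSS/TAU` and `PMAX = MSS*MAC/4` to relative tolerance
#' `1e-9`.
#'
#' @param profile An `av_profile`.
#' @return The profile, invisibly; errors when invalid.
#' @export
validate_av_profile <- function(profile) {
  stopifnot(inherits(profile, "av_profile"))
  with(profile, {
    if (!is.finite(mss) || mss <= 0) stop("invalid profile: mss <= 0", call. = FALSE)
    if (!is.finite(tau) || tau <= 0) stop("invalid profile: tau <= 0", call. = FALSE)
    if (!is.finite(mac) || mac <= 0) stop("invalid profile: mac <= 0", call. = FALSE)
  })
  if (!is_aggregate(profile)) {
    rel <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.eps)
    if (rel(profile$mac, profile$mss / profile$tau) > 1e-9) {
      stop("invalid profile: mac != mss/tau", call. = FALSE)
    }
    if (rel(profile$pmax, profile$mss * profile$mac / 4) > 1e-9) {
      stop("invalid profile: pmax != mss*mac/4", call. = FALSE)
    }
  }
  invisible(profile)
}

#' Model velocity at a given time
#'
#' Evaluates the mono-exponential sprint model
#' `v(t) = MSS * (1 - exp(-(t + TC)/TAU))`. The time correction `TC` is taken
#' as 0 when the profile carries none. The curve is strictly increasing in `t`
#' and bounded above by `MSS`.
#'
#' @param profile An `av_profile`.
#' @param t Time since sprint onset, s (vectorised). Must be finite and >= 0.
#' @return Velocity in m/s, same length as `t`.
#' @export
velocity_at_time <- function(profile, t) {
  validate_av_profile(profile)
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  tc <- if (is.na(profile$tc)) 0 else profile$tc
  profile$mss * (1 - exp(-(t + tc) / profile$tau))
}

#' Model acceleration at a given velocity
#'
#' The mono-exponential model implies a straight line in
#' acceleration-velocity space: `a(v) = MAC * (1 - v/MSS)`, with intercept
#' `MAC` at `v = 0` and x-intercept `MSS`.
#'
#' @param profile An `av_profile`.
#' @param v Velocity, m/s (vectorised). Must satisfy `0 <= v <= MSS`;
#'   velocities above `MSS` (negative acceleration) are not modelled.
#' @return Acceleration in m/s^2, same length as `v`.
#' @export
acceleration_at_velocity <- function(profile, v) {
  validate_av_profile(profile)
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop("`v` must be finite numeric", call. = FALSE)
  }
  if (any(v < 0) || any(v > profile$mss)) {
    stop("`v` must lie in [0, MSS]", call. = FALSE)
  }
  profile$mac * (1 - v / profile$mss)
}

#' Analytic sprint distance at a given time
#'
#' Distance covered since sprint onset, obtained by integrating the
#' mono-exponential velocity curve from 0 to `t`:
#' `d(t) = MSS*t + MSS*TAU*(exp(-(t + TC)/TAU) - exp(-TC/TAU))`,
#' so that `d(0) = 0` exactly.
#'
#' @inheritParams velocity_at_time
#' @return Distance in m, same length as `t`.
#' @export
distance_at_time <- function(profile, t) {
  validate_av_profile(profile)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite numeric >= 0", call. = FALSE)
  }
  tc <- if (is.na(profile$tc)) 0 else profile$tc
  with(profile, mss * t + mss * tau * (exp(-(t + tc) / tau) - exp(-tc / tau)))
}

#' Time needed to cover a given distance
#'
#' Inverts [distance_at_time()] numerically (the distance curve is strictly
#' increasing once the athlete moves).
#'
#' @param profile An `av_profile`.
#' @param distance Target distance, m (> 0).
#' @param upper Upper search bound in s.
#' @return Time in s.
#' @export
time_to_distance <- function(profile, distance, upper = 120) {
  stopifnot(is.numeric(distance), length(distance) == 1L, distance > 0)
  stats::uniroot(
    function(t) distance_at_time(profile, t) - distance,
    lower = 0, upper = upper, tol = 1e-10
  )$root
}

#' @export
format.av_profile <- function(x, ...) {
  tag <- if (is_aggregate(x)) "aggregate acceleration-velocity profile"
         else "acceleration-velocity profile"
  tc <- if (is.na(x$tc)) "-" else sprintf("%.3f s", x$tc)
  paste0(
    "<", tag, ">\n",
    sprintf("  MSS  %.3f m/s\n", x$mss),
    sprintf("  TAU  %.3f s\n", x$tau),
    sprintf("  MAC  %.3f m/s^2\n", x$mac),
    sprintf("  PMAX %.3f W/kg\n", x$pmax),
    sprintf("  TC   %s", tc)
  )
}

#' @export
print.av_profile <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' @export
as.data.frame.av_profile <- function(x, ...) {
  data.frame(mss = x$mss, tau = x$tau, mac = x$mac, pmax = x$pmax, tc = x$tc)
}

#' Serialise a profile to a flat JSON record
#'
#' @param profile An `av_profile`.
#' @param method Optional method tag (`"tv"` time-velocity, `"va"`
#'   velocity-acceleration) recorded in the JSON.
#' @return A JSON string with fields `mss`, `tau`, `mac`, `pmax`, `tc`
#'   (null when absent), plus `method` and `aggregate` when relevant.
#' @export
profile_to_json <- function(profile, method = NULL) {
  validate_av_profile(profile)
  rec <- list(
    mss = profile$mss, tau = profile$tau, mac = profile$mac,
    pmax = profile$pmax, tc = if (is.na(profile$tc)) NULL else profile$tc
  )
  if (!is.null(method)) rec$method <- match.arg(method, c("tv", "va"))
  rec$aggregate <- is_aggregate(profile)
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
}
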
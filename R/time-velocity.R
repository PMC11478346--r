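#' Fit the time-corrected mono-exponential model to a velocity-time trace
#'
#' The time-velocity method estimates (MSS, TAU, TC) by nonlinear least
#' squares on `v(t) = MSS * (1 - exp(-(t + TC)/TAU))`. Sample times are
#' re-zeroed to the first retained sample before fitting, so the estimates are
#' invariant to uniform time shifts of the input (absorbed by TC). With
#' `weighting = "time"` each observation is weighted by its (re-zeroed) time,
#' rescaled to mean 1, so late, high-velocity samples count more; the choice
#' of a weight linear in time is the simplest monotone realisation of
#' "higher time, more weight" and is configurable.
#'
#' The trace is expected to be already filtered ([filter_trace()]). At least 4
#' samples are required (3 parameters + 1 residual degree of freedom).
#' Optimisation uses Levenberg-Marquardt with bounds MSS in (0, 15], TAU in
#' (0, 5], TC in \[-1, 1\]; starting values are MSS0 = max observed velocity,
#' TAU0 = 1 s, TC0 = 0, with up to 4 restarts at TAU0 in {0.5, 0.8, 1.2, 1.5}
#' on failure.
#'
#' @param trace A filtered [velocity_trace()].
#' @param weighting `"time"` (default) or `"none"`.
#' @return A `sprint_fit` object: list with `profile` (an [av_profile()] with
#'   TC), `rse` (unweighted residual standard error, m/s, df = n - 3),
#'   `n_used`, `converged`, `method = "time_velocity"` and `flags` (character;
#'   contains `"mss_below_peak"` when the MSS estimate fell below 99% of the
#'   observed maximum velocity — suspicious but not fatal).
#' @export
fit_time_velocity <- function(trace, weighting = c("time", "none")) {
  stopifnot(inherits(trace, "velocity_trace"))
  weighting <- match.arg(weighting)
  n <- nrow(trace)
  if (n < 4L) {
    stop("insufficient data: need at least 4 samples to fit 3 parameters",
         call. = FALSE)
  }
  t <- trace$time - trace$time[1]
  v <- trace$velocity
  w <- if (weighting == "time") t / mean(t) else rep(1, n)

  dat <- data.frame(t = t, v = v)
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = 500, ftol = 1e-15, ptol = 1e-15
  )
  starts <- lapply(c(1, 0.5, 0.8, 1.2, 1.5), function(tau0) {
    list(mss = max(v), tau = tau0, tc = 0)
  })
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ mss * (1 - exp(-(t + tc) / tau)),
        data = dat, start = st, weights = w,
        lower = c(mss = 1e-6, tau = 1e-6, tc = -1),
        upper = c(mss = 15, tau = 5, tc = 1),
        control = ctrl
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && isTRUE(fit$convInfo$isConv)) break
  }
  if (is.null(fit)) {
    stop("time-velocity fit failed to converge after restarts", call. = FALSE)
  }
  cf <- stats::coef(fit)
  profile <- av_profile(mss = cf[["mss"]], tau = cf[["tau"]], tc = cf[["tc"]])
  res <- v - velocity_at_time(profile, t)
  flags <- character(0)
  if (profile$mss < 0.99 * max(v)) flags <- c(flags, "mss_below_peak")
  new_sprint_fit(
    profile = profile,
    rse = sqrt(sum(res^2) / (n - 3)),
    n_used = n,
    converged = isTRUE(fit$convInfo$isConv),
    method = "time_velocity",
    flags = flags
  )
}

new_sprint_fit <- function(profile, rse, n_used, converged, method, flags = character(0)) {
  structure(
    list(profile = profile, rse = rse, n_used = n_used,
         converged = converged, method = method, flags = flags),
    class = "sprint_fit"
  )
}

#' @export
print.sprint_fit <- function(x, ...) {
  cat(sprintf("<sprint_fit: %s>\n", x$method))
  print(x$profile)
  cat(sprintf("  RSE %.4f m/s over %d samples (converged: %s)\n",
              x$rse, x$n_used, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
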
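#' Build a velocity-time trace
#'
#' A trace is one sampled `v(t)` signal from a single sprint (criterion laser
#' trace, typically 1000 Hz) or a continuous device stream (LPS, typically
#' 20 Hz). Stored as a data frame with columns `time` (s) and `velocity`
#' (m/s), optionally `acceleration` (m/s^2) for device streams.
#'
#' @param time Sample times, s; strictly increasing.
#' @param velocity Velocities, m/s; finite and >= 0.
#' @param acceleration Optional accelerations, m/s^2.
#' @param source `"criterion"` or `"device"`.
#' @param athlete_id,trial_id Optional identifiers kept as attributes.
#' @return A data frame of class `velocity_trace`.
#' @export
velocity_trace <- function(time, velocity, acceleration = NULL,
                           source = c("criterion", "device"),
                           athlete_id = NA_character_, trial_id = NA_character_) {
  source <- match.arg(source)
  if (length(time) != length(velocity)) {
    stop("`time` and `velocity` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(velocity))) {
    stop("trace samples must be finite", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(velocity < 0)) {
    stop("`velocity` must be >= 0", call. = FALSE)
  }
  df <- data.frame(time = as.numeric(time), velocity = as.numeric(velocity))
  if (!is.null(acceleration)) {
    if (length(acceleration) != length(time)) {
      stop("`acceleration` must match `time` in length", call. = FALSE)
    }
    df$acceleration <- as.numeric(acceleration)
  }
  structure(df,
    source = source, athlete_id = athlete_id, trial_id = trial_id,
    class = c("velocity_trace", "data.frame")
  )
}

# Keep trace attributes through a row subset.
subset_trace <- function(trace, keep) {
  velocity_trace(
    time = trace$time[keep], velocity = trace$velocity[keep],
    acceleration = if ("acceleration" %in% names(trace)) trace$acceleration[keep],
    source = attr(trace, "source") %||% "criterion",
    athlete_id = attr(trace, "athlete_id") %||% NA_character_,
    trial_id = attr(trace, "trial_id") %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict a trace to the modelled acceleration phase
#'
#' Applies the pre-fit filtering rule of the time-velocity method: keep
#' samples with velocity at or above `v_min` (default 0.75 m/s, discarding the
#' slow start where the model is unreliable) and at or before the first
#' occurrence of the trace's maximum velocity (the peak of the already-smoothed
#' signal; deceleration after the peak is not modelled).
#'
#' @param trace A [velocity_trace()].
#' @param v_min Lower velocity cut-off, m/s.
#' @return The filtered `velocity_trace`, order preserved.
#' @export
filter_trace <- function(trace, v_min = 0.75) {
  stopifnot(inherits(trace, "velocity_trace"))
  i_peak <- which.max(trace$velocity)
  keep <- trace$velocity >= v_min & seq_len(nrow(trace)) <= i_peak
  if (!any(keep)) {
    stop("insufficient data: no samples remain after filtering", call. = FALSE)
  }
  subset_trace(trace, keep)
}

#' Read velocity traces from CSV
#'
#' Expects a header `time_s,velocity_ms`, optionally `acceleration_ms2`,
#' `athlete_id` and `trial_id`. A file holding several sprints in long format
#' (id columns present) is split into one trace per `athlete_id` x `trial_id`
#' combination.
#'
#' @param path CSV file path.
#' @param source `"criterion"` or `"device"`.
#' @return A single `velocity_trace`, or a list of them for long-format files.
#' @export
read_trace_csv <- function(path, source = c("criterion", "device")) {
  source <- match.arg(source)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "velocity_ms") %in% names(df))) {
    stop("CSV must have columns `time_s` and `velocity_ms`", call. = FALSE)
  }
  make <- function(d, aid, tid) {
    velocity_trace(
      time = d$time_s, velocity = d$velocity_ms,
      acceleration = if ("acceleration_ms2" %in% names(d)) d$acceleration_ms2,
      source = source, athlete_id = aid, trial_id = tid
    )
  }
  if (all(c("athlete_id", "trial_id") %in% names(df))) {
    key <- interaction(df$athlete_id, df$trial_id, drop = TRUE)
    if (nlevels(key) > 1L) {
      return(lapply(split(df, key), function(d) {
        make(d, as.character(d$athlete_id[1]), as.character(d$trial_id[1]))
      }))
    }
    return(make(df, as.character(df$athlete_id[1]), as.character(df$trial_id[1])))
  }
  make(df, NA_character_, NA_character_)
}

#' Write a velocity trace to CSV
#'
#' Inverse of [read_trace_csv()]; writes `time_s,velocity_ms`
#' (+ `acceleration_ms2` when present, + id columns when known).
#'
#' @param trace A `velocity_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  out <- data.frame(time_s = trace$time, velocity_ms = trace$velocity)
  if ("acceleration" %in% names(trace)) out$acceleration_ms2 <- trace$acceleration
  aid <- attr(trace, "athlete_id")
  tid <- attr(trace, "trial_id")
  if (!is.na(aid)) out$athlete_id <- aid
  if (!is.na(tid)) out$trial_id <- tid
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
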
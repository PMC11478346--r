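#' Detect sprint trials in a continuous device stream
#'
#' Recognises discrete maximal-sprint windows inside a continuous
#' low-rate (~20 Hz) tracking stream, so that individual trials can be fitted
#' with the time-velocity method. The detector:
#'
#' 1. opens a candidate where velocity crosses `v_trigger` upward and the
#'    ensuing local maximum (before velocity falls back under `v_trigger`)
#'    reaches at least `v_peak_min`;
#' 2. extends the window start backward to the last sample with velocity
#'    below `v_start` (the athlete's stationary set position), but no further
#'    than `max_duration` before the crossing;
#' 3. closes the window at the first sample after the peak where velocity
#'    drops below `v_trigger`, or at `start + max_duration`, whichever is
#'    first;
#' 4. merges windows separated by less than `min_gap`;
#' 5. flags windows truncated by the stream edges.
#'
#' Default thresholds are set so that a maximal 30 m sprint (peak 7-10 m/s) is
#' always captured while jogging or shuffling segments (peaks under 5 m/s)
#' are rejected.
#'
#' @param stream A [velocity_trace()] (continuous device stream).
#' @param v_trigger Upward-crossing threshold, m/s.
#' @param v_peak_min Minimum peak velocity for a window to count as a sprint,
#'   m/s.
#' @param v_start Stationary threshold for backward start extension, m/s.
#' @param max_duration Maximum window length, s.
#' @param min_gap Minimum separation between windows, s; closer windows merge.
#' @return A data frame of class `sprint_windows` with columns `athlete_id`,
#'   `trial_index`, `start_s`, `end_s`, `peak_v`, `truncated`.
#' @export
detect_sprints <- function(stream, v_trigger = 3.0, v_peak_min = 5.0,
                           v_start = 0.5, max_duration = 8.0, min_gap = 2.0) {
  stopifnot(inherits(stream, "velocity_trace"))
  n <- nrow(stream)
  if (n == 0L) stop("empty stream", call. = FALSE)
  t <- stream$time
  v <- stream$velocity
  aid <- attr(stream, "athlete_id") %||% NA_character_

  empty <- data.frame(
    athlete_id = character(0), trial_index = integer(0),
    start_s = numeric(0), end_s = numeric(0),
    peak_v = numeric(0), truncated = logical(0)
  )
  up <- which(v[-1] >= v_trigger & v[-n] < v_trigger) + 1L
  if (v[1] >= v_trigger) up <- c(1L, up)
  if (length(up) == 0L) {
    return(structure(empty, class = c("sprint_windows", "data.frame")))
  }

  wins <- list()
  last_end_idx <- 0L
  for (i_cross in up) {
    if (i_cross <= last_end_idx) next  # inside a previous window's span
    # segment above trigger: i_cross .. first drop below v_trigger
    j <- i_cross
    while (j < n && v[j + 1L] >= v_trigger) j <- j + 1L
    seg <- i_cross:j
    i_peak <- seg[which.max(v[seg])]
    if (v[i_peak] < v_peak_min) { last_end_idx <- j; next }
    # backward start extension to last stationary sample
    before <- which(t < t[i_cross] & v < v_start)
    i_start <- if (length(before)) max(before) else NA_integer_
    t_start <- if (!is.na(i_start) && t[i_cross] - t[i_start] <= max_duration) {
      t[i_start]
    } else {
      max(t[1], t[i_cross] - max_duration)
    }
    # forward end: first sample after the peak under v_trigger, capped
    after <- which(t > t[i_peak] & v < v_trigger)
    t_cap <- t_start + max_duration
    truncated <- FALSE
    if (length(after)) {
      t_end <- min(t[min(after)], t_cap)
    } else {
      t_end <- min(t[n], t_cap)
      truncated <- t[n] <= t_cap  # deceleration clipped by stream edge
    }
    if (t_start <= t[1] && v[1] >= v_start) truncated <- TRUE
    wins[[length(wins) + 1L]] <- list(
      start = t_start, end = t_end, peak_v = v[i_peak], truncated = truncated
    )
    last_end_idx <- max(j, findInterval(t_end, t))
  }
  if (length(wins) == 0L) {
    return(structure(empty, class = c("sprint_windows", "data.frame")))
  }
  # merge windows separated by less than min_gap
  merged <- list(wins[[1]])
  for (wcur in wins[-1]) {
    prev <- merged[[length(merged)]]
    if (wcur$start - prev$end < min_gap) {
      prev$end <- max(prev$end, wcur$end)
      prev$peak_v <- max(prev$peak_v, wcur$peak_v)
      prev$truncated <- prev$truncated || wcur$truncated
      merged[[length(merged)]] <- prev
    } else {
      merged[[length(merged) + 1L]] <- wcur
    }
  }
  out <- data.frame(
    athlete_id = rep(aid, length(merged)),
    trial_index = seq_along(merged),
    start_s = vapply(merged, `[[`, numeric(1), "start"),
    end_s = vapply(merged, `[[`, numeric(1), "end"),
    peak_v = vapply(merged, `[[`, numeric(1), "peak_v"),
    truncated = vapply(merged, `[[`, logical(1), "truncated")
  )
  structure(out, class = c("sprint_windows", "data.frame"))
}

#' Extract one detected window as a stand-alone trace
#'
#' @param stream The continuous [velocity_trace()].
#' @param start_s,end_s Window bounds, s (inclusive).
#' @param trial_id Identifier attached to the extracted trace.
#' @return A `velocity_trace` covering `[start_s, end_s]`, with the device
#'   `source` and original athlete id.
#' @export
extract_window <- function(stream, start_s, end_s, trial_id = NA_character_) {
  stopifnot(inherits(stream, "velocity_trace"), start_s < end_s)
  keep <- stream$time >= start_s & stream$time <= end_s
  if (!any(keep)) stop("window contains no samples", call. = FALSE)
  tr <- subset_trace(stream, keep)
  attr(tr, "trial_id") <- trial_id
  tr
}

#' Write detected sprint windows to CSV
#'
#' Columns: `athlete_id,trial_index,start_s,end_s,peak_v,truncated`.
#'
#' @param windows A `sprint_windows` data frame from [detect_sprints()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  stopifnot(inherits(windows, "sprint_windows"))
  utils::write.csv(as.data.frame(windows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
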
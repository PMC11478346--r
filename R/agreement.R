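#' Percent difference between device and criterion values
#'
#' `%Diff = 100 * (device - criterion) / criterion`, the per-observation
#' relative disagreement of a device measurement with the criterion
#' (reference) measurement.
#'
#' @param device Device values (vectorised).
#' @param criterion Criterion values, strictly positive (they sit in the
#'   denominator).
#' @return Percent differences, same length as the inputs.
#' @export
percent_diff <- function(device, criterion) {
  if (length(device) != length(criterion)) {
    stop("`device` and `criterion` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(criterion)) || any(criterion <= 0)) {
    stop("`criterion` values must be positive", call. = FALSE)
  }
  100 * (device - criterion) / criterion
}

#' Percent bias (mean percent difference)
#'
#' @param diffs Percent differences, non-empty.
#' @return Their arithmetic mean.
#' @export
percent_bias <- function(diffs) {
  if (length(diffs) == 0L) stop("`diffs` must be non-empty", call. = FALSE)
  mean(diffs)
}

#' Percent mean absolute difference
#'
#' Default (`mode = "centered"`): mean absolute deviation of the percent
#' differences about their own mean, `mean(|%Diff_i - mean(%Diff)|)` — the
#' spread of the disagreement net of bias. `mode = "raw"` gives
#' `mean(|%Diff_i|)` instead, for sensitivity analysis.
#'
#' @param diffs Percent differences, non-empty.
#' @param mode `"centered"` (default) or `"raw"`.
#' @return A non-negative percent value.
#' @export
percent_mad <- function(diffs, mode = c("centered", "raw")) {
  mode <- match.arg(mode)
  if (length(diffs) == 0L) stop("`diffs` must be non-empty", call. = FALSE)
  if (mode == "centered") mean(abs(diffs - mean(diffs))) else mean(abs(diffs))
}

#' Percent residual standard error of the device-on-criterion regression
#'
#' Fits ordinary least squares `device = b0 + b1 * criterion` and returns
#' \deqn{\%RSE = \sqrt{ \sum_i (100 (y_i - \hat y_i) / \hat y_i)^2 / (N - 2) }}
#' with residuals percentised against the fitted values. Treating the
#' criterion as error-free, %RSE is the device's percent standard error of
#' measurement (%SEM).
#'
#' @param criterion Criterion values (predictor), length >= 3.
#' @param device Device values (outcome), same length.
#' @return %RSE, a non-negative percent.
#' @export
percent_rse <- function(criterion, device) {
  n <- length(criterion)
  if (length(device) != n) {
    stop("`criterion` and `device` must have equal length", call. = FALSE)
  }
  if (n < 3L) {
    stop("insufficient data: %RSE needs at least 3 pairs (df = N - 2 >= 1)",
         call. = FALSE)
  }
  # closed-form simple OLS (identical to lm(device ~ criterion))
  sxx <- sum((criterion - mean(criterion))^2)
  if (sxx == 0) stop("criterion values are constant; slope undefined", call. = FALSE)
  b1 <- sum((criterion - mean(criterion)) * (device - mean(device))) / sxx
  b0 <- mean(device) - b1 * mean(criterion)
  yhat <- b0 + b1 * criterion
  if (any(yhat <= 0)) {
    stop("numerical domain error: non-positive fitted values", call. = FALSE)
  }
  sqrt(sum((100 * (device - yhat) / yhat)^2) / (n - 2))
}

#' Minimal detectable change at 95% confidence
#'
#' `%MDC95 = %RSE * sqrt(2) * 1.96`: the smallest observed percent change
#' that can be interpreted as a real change with 95% confidence, given the
#' device's percent SEM.
#'
#' @param rse_pct %RSE (or %SEM), non-negative.
#' @return %MDC95.
#' @export
mdc95 <- function(rse_pct) {
  if (any(!is.finite(rse_pct)) || any(rse_pct < 0)) {
    stop("`rse_pct` must be non-negative", call. = FALSE)
  }
  rse_pct * sqrt(2) * 1.96
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric BCa interval for `statistic(data)`. Resampling draws units
#' (elements of a vector or list, or rows of a data frame) with replacement;
#' when observations are grouped (e.g. trials within athletes), pass a list of
#' per-unit chunks and let `statistic` reassemble them, so that the unit of
#' resampling matches the study design. The bias-correction constant `z0`
#' comes from the fraction of bootstrap replicates below the point estimate;
#' the acceleration constant `a` from the skewness of the leave-one-out
#' jackknife values. Deterministic given `seed`: the resample index matrix is
#' `matrix(sample.int(n, n * B, replace = TRUE), nrow = B)` drawn immediately
#' after `set.seed(seed)`.
#'
#' @param data A vector, list or data frame of resampling units (>= 2).
#' @param statistic Function of a resampled `data` returning one number.
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric `c(lower, upper)` with attributes `t0` (point estimate),
#'   `z0`, `accel` and `conf`. Degenerate bootstrap distributions (all
#'   replicates equal) give a zero-width interval at the point estimate with
#'   a warning.
#' @export
bootstrap_bca <- function(data, statistic, n_resamples = 5000L, conf = 0.95,
                          seed = NULL) {
  n <- NROW(data)
  if (n < 2L) stop("need at least 2 resampling units", call. = FALSE)
  stopifnot(is.function(statistic), n_resamples >= 1L, conf > 0, conf < 1)
  take <- if (is.data.frame(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  t0 <- statistic(data)
  if (!is.null(seed)) {
    # seeded runs must not disturb the caller's RNG stream
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                nrow = n_resamples)
  tb <- vapply(seq_len(n_resamples), function(b) {
    tryCatch(statistic(take(idx[b, ])), error = function(e) NA_real_)
  }, numeric(1))
  tb <- tb[is.finite(tb)]
  if (length(tb) == 0L || max(tb) - min(tb) == 0) {
    warning("degenerate bootstrap distribution; zero-width interval returned")
    return(structure(c(t0, t0), t0 = t0, z0 = 0, accel = 0, conf = conf))
  }
  prop <- mean(tb < t0)
  # guard against a point estimate outside the bootstrap support
  prop <- min(max(prop, 1 / (length(tb) + 1)), length(tb) / (length(tb) + 1))
  z0 <- stats::qnorm(prop)
  # jackknife acceleration
  tj <- vapply(seq_len(n), function(i) {
    tryCatch(statistic(take(-i)), error = function(e) NA_real_)
  }, numeric(1))
  tj <- tj[is.finite(tj)]
  d <- mean(tj) - tj
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  alpha <- (1 - conf) / 2
  adj <- function(z) {
    zt <- z0 + z
    stats::pnorm(z0 + zt / (1 - a * zt))
  }
  probs <- c(adj(stats::qnorm(alpha)), adj(stats::qnorm(1 - alpha)))
  ci <- unname(stats::quantile(tb, probs = probs, names = FALSE, type = 7))
  structure(ci, t0 = t0, z0 = z0, accel = a, conf = conf)
}

#' Classify a confidence interval against a practical-significance band
#'
#' Compares a 95% interval with the practically significant magnitude band:
#' `[-threshold, +threshold]` for signed metrics (bias), `[0, threshold]` for
#' non-negative metrics (MAD, MDC95). The interval is `"within"` when fully
#' inside the band, `"outside"` when disjoint from it, `"overlapping"`
#' otherwise.
#'
#' @param lo,hi Interval endpoints, `lo <= hi`.
#' @param threshold Practical threshold, percent (default 5).
#' @param band `"symmetric"` or `"nonnegative"`.
#' @return One of `"within"`, `"overlapping"`, `"outside"`.
#' @export
classify_practical <- function(lo, hi, threshold = 5,
                               band = c("symmetric", "nonnegative")) {
  band <- match.arg(band)
  if (lo > hi) stop("`lo` must be <= `hi`", call. = FALSE)
  bl <- if (band == "symmetric") -threshold else 0
  bu <- threshold
  if (lo >= bl && hi <= bu) return("within")
  if (hi < bl || lo > bu) return("outside")
  "overlapping"
}

#' Agreement and sensitivity report for paired estimates
#'
#' Computes, for each parameter x method group of paired
#' (criterion, device) estimates: %Bias, %MAD and %MDC95 (via %RSE of the
#' device-on-criterion regression), each with a BCa bootstrap confidence
#' interval (resampling unit = `unit_id`: trials for the time-velocity
#' analysis, athletes for the velocity-acceleration analysis) and a
#' practical-significance classification against `threshold`.
#'
#' @param pairs Data frame with columns `parameter`, `method`, `unit_id`,
#'   `criterion`, `device`.
#' @param n_resamples Bootstrap resamples per interval (default 5000); `0`
#'   skips the bootstrap (point estimates only, `NA` intervals and flags).
#' @param conf Confidence level.
#' @param threshold Practical-significance threshold, percent.
#' @param mad_mode Passed to [percent_mad()].
#' @param seed Optional base seed; each parameter x method x metric interval
#'   uses a distinct deterministic offset of it.
#' @return A data frame of class `agreement_report`: one row per
#'   parameter x method x metric with `estimate`, `ci_lo`, `ci_hi`, `n`
#'   (number of pairs) and `practical`.
#' @export
agreement_report <- function(pairs, n_resamples = 5000L, conf = 0.95,
                             threshold = 5, mad_mode = c("centered", "raw"),
                             seed = NULL) {
  mad_mode <- match.arg(mad_mode)
  need <- c("parameter", "method", "unit_id", "criterion", "device")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(pairs, list(pairs$parameter, pairs$method), drop = TRUE)
  metrics <- c("bias_pct", "mad_pct", "mdc95_pct")
  stat_fns <- list(
    bias_pct  = function(d) percent_bias(percent_diff(d$device, d$criterion)),
    mad_pct   = function(d) percent_mad(percent_diff(d$device, d$criterion),
                                        mode = mad_mode),
    mdc95_pct = function(d) mdc95(percent_rse(d$criterion, d$device))
  )
  bands <- c(bias_pct = "symmetric", mad_pct = "nonnegative",
             mdc95_pct = "nonnegative")
  rows <- list()
  g_i <- 0L
  for (g in groups) {
    g_i <- g_i + 1L
    units <- split(g, g$unit_id)  # list of per-unit chunks
    rebind <- function(chunks) do.call(rbind, chunks)
    for (m_i in seq_along(metrics)) {
      m <- metrics[m_i]
      fn <- stat_fns[[m]]
      est <- fn(g)
      if (n_resamples > 0L) {
        s <- if (is.null(seed)) NULL else seed + 1000L * g_i + m_i
        ci <- bootstrap_bca(units, function(ch) fn(rebind(ch)),
                            n_resamples = n_resamples, conf = conf, seed = s)
        flag <- classify_practical(ci[1], ci[2], threshold = threshold,
                                   band = bands[[m]])
        lo <- ci[1]; hi <- ci[2]
      } else {
        lo <- hi <- NA_real_; flag <- NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = g$parameter[1], method = g$method[1], metric = m,
        estimate = est, ci_lo = lo, ci_hi = hi, n = nrow(g), practical = flag
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, threshold = threshold, conf = conf,
            class = c("agreement_report", "data.frame"))
}

#' Read a paired-estimates CSV
#'
#' Header `parameter,method,unit_id,criterion,device`, one row per paired
#' observation.
#'
#' @param path CSV file path.
#' @return A data frame suitable for [agreement_report()].
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "method", "unit_id", "criterion", "device")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an agreement report to CSV or JSON
#'
#' @param report An `agreement_report`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
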
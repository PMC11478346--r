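# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the bin oracle is an exhaustive sort-and-take,
# the RSE oracle goes through lm(), and the BCa oracle re-derives the
# bias-correction/acceleration/quantile machinery from the textbook formulas.

# Exhaustive per-bin top-k selection: for each half-open bin [anchor + i*w,
# anchor + (i+1)*w), sort that bin's rows by decreasing acceleration (stable)
# and take the first k row indices.
oracle_bin_topk <- function(v, a, width = 0.2, k = 2L, anchor = 3.0) {
  bin <- floor((v - anchor) / width)
  picked <- integer(0)
  for (b in sort(unique(bin))) {
    rows <- which(bin == b)
    rows <- rows[order(-a[rows])]  # stable: earlier row wins ties
    picked <- c(picked, rows[seq_len(min(k, length(rows)))])
  }
  sort(picked)
}

# Spreadsheet-style %RSE: OLS via lm, residuals percentised against fitted
# values, df = N - 2.
oracle_rse <- function(criterion, device) {
  fit <- lm(device ~ criterion)
  yhat <- fitted(fit)
  sqrt(sum((100 * (device - yhat) / yhat)^2) / (length(device) - 2))
}

# Independent BCa interval given the same documented resample-index scheme
# as bootstrap_bca (set.seed(seed); matrix(sample.int(n, n*B, TRUE), nrow=B)).
oracle_bca <- function(x, statistic, B, conf, seed) {
  n <- length(x)
  t0 <- statistic(x)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  tb <- apply(idx, 1, function(i) statistic(x[i]))
  z0 <- qnorm(sum(tb < t0) / B)
  tj <- sapply(seq_len(n), function(i) statistic(x[-i]))
  d <- mean(tj) - tj
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- (1 - conf) / 2
  q <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  quantile(tb, probs = c(q(qnorm(alpha)), q(qnorm(1 - alpha))),
           names = FALSE, type = 7)
}

# A raw profile structure with decoupled components, standing in for an
# aggregate input whose MAC/PMAX need not satisfy the within-trial identities.
new_profile_for_test <- function(mss = 9, tau = 1.2, mac = mss / tau,
                                 pmax = mss * mac / 4) {
  structure(list(mss = mss, tau = tau, mac = mac, pmax = pmax, tc = NA_real_),
            aggregate = TRUE, class = "av_profile")
}

# Shortcut: noiseless model trace at a given rate/duration.
model_trace <- function(mss, tau, tc, rate, duration) {
  p <- av_profile(mss, tau, tc)
  t <- seq(0, duration, by = 1 / rate)
  velocity_trace(t, velocity_at_time(p, t))
}
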
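# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary data.

# A tiny uniformly sampled hemo stream with known per-channel content.
make_hemo <- function(n = 100, n_opt = 2, fs = 2,
                      fill = function(i, o) 0) {
  time <- (seq_len(n) - 1) / fs
  hbo <- outer(seq_len(n), seq_len(n_opt), Vectorize(fill))
  hemo_stream(time, hbo, -hbo / 3, sampling_rate = fs)
}

# Constant-intensity optical stream (n x n_opt x 2).
make_optical <- function(n = 40, n_opt = 4, fs = 2, level = 1000) {
  time <- (seq_len(n) - 1) / fs
  optical_stream(time, array(level, dim = c(n, n_opt, 2L)))
}

# Reference EMA computed by the literal recurrence, independent of the
# package's filtering path.
ema_reference <- function(x, n_window, y0) {
  a <- 2 / (n_window + 1)
  y <- numeric(length(x))
  prev <- y0
  for (i in seq_along(x)) {
    y[i] <- a * x[i] + (1 - a) * prev
    prev <- y[i]
  }
  y
}

# Steady-state amplitude of a filtered sinusoid, measured by regressing
# the tail of the output on sin/cos at the driving frequency.
measured_gain <- function(config, f, duration_s = 600, settle_s = 200) {
  fs <- config$sampling_rate
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * f * t)
  stream <- hemo_stream(t, matrix(x), matrix(x), sampling_rate = fs)
  y <- filter_stream(stream, config)$hbo[, 1]
  keep <- t >= settle_s
  fit <- lm(y[keep] ~ sin(2 * pi * f * t[keep]) + cos(2 * pi * f * t[keep]))
  sqrt(sum(coef(fit)[2:3]^2))
}

# Balanced two-cluster features: class means +/- delta on every feature.
make_clusters <- function(n_per_class = 5, p = 20, delta = 5, sd = 0.1,
                          seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * p, -delta, sd), n_per_class, p),
    matrix(rnorm(n_per_class * p, +delta, sd), n_per_class, p))
  list(x = x, y = rep(c("low", "high"), each = n_per_class))
}
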
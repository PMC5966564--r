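test_that("EMA recurrence matches the direct formula", {
  # N = 3, y0 = 0: weight 1/2 gives 0.5, 0.75, 0.875 on a unit step
  st <- ema_state(3, init = "zero")
  out <- numeric(3)
  for (i in 1:3) {
    r <- ema_update(st, 1)
    st <- r$state; out[i] <- r$y
  }
  expect_equal(out, c(0.5, 0.75, 0.875))

  # constant input starting at its own value is a fixed point
  st <- ema_state(13, init = "first")
  for (i in 1:10) {
    r <- ema_update(st, 4.2)
    st <- r$state
    expect_identical(r$y, 4.2)
  }

  # N = 1 reproduces the input exactly
  st <- ema_state(1, init = "zero")
  for (x in c(3, -1, 7)) {
    r <- ema_update(st, x)
    st <- r$state
    expect_identical(r$y, x)
  }

  expect_error(ema_state(0), ">= 1")
})

test_that("batch EMA equals the sample-by-sample recurrence", {
  set.seed(2)
  x <- rnorm(200)
  for (N in c(3, 12, 26)) {
    expect_equal(fnirsbci:::ema_filter_vec(x, N, "first"),
                 ema_reference(x, N, y0 = x[1]), tolerance = 1e-12)
    expect_equal(fnirsbci:::ema_filter_vec(x, N, "zero"),
                 ema_reference(x, N, y0 = 0), tolerance = 1e-12)
  }
})

test_that("MACD rejects DC and matches closed-form impulse response", {
  # constant stream -> exactly zero at every step
  short <- ema_state(12); long <- ema_state(26)
  for (i in 1:50) {
    r <- macd_update(short, long, 2.5)
    short <- r$short; long <- r$long
    expect_identical(r$y, 0)
  }

  # impulse: closed-form geometric difference of the two EMA responses
  a_s <- 2 / 13; a_l <- 2 / 27
  short <- ema_state(12, init = "zero"); long <- ema_state(26, init = "zero")
  x <- c(1, rep(0, 29))
  got <- numeric(30)
  for (i in 1:30) {
    r <- macd_update(short, long, x[i])
    short <- r$short; long <- r$long
    got[i] <- r$y
  }
  n <- 1:30
  expected <- a_s * (1 - a_s)^(n - 1) - a_l * (1 - a_l)^(n - 1)
  expect_equal(got, expected, tolerance = 1e-12)

  expect_error(macd_update(ema_state(26), ema_state(12), 1), "shorter")
})

test_that("filter_stream equals per-channel streaming MACD and is causal", {
  set.seed(7)
  stream <- make_hemo(n = 120, n_opt = 3, fs = 2,
                      fill = function(i, o) rnorm(1))
  cfg <- macd_config(sampling_rate = 2)
  out <- filter_stream(stream, cfg)

  # batch == streaming per channel
  for (o in 1:3) {
    short <- ema_state(cfg$n_short); long <- ema_state(cfg$n_long)
    y <- numeric(120)
    for (i in 1:120) {
      r <- macd_update(short, long, stream$hbo[i, o])
      short <- r$short; long <- r$long; y[i] <- r$y
    }
    expect_equal(out$hbo[, o], y, tolerance = 1e-12)
  }

  # causality: truncation leaves earlier outputs bit-identical
  half <- 60
  trunc <- hemo_stream(stream$time[1:half], stream$hbo[1:half, ],
                       stream$hhb[1:half, ], 2)
  out_tr <- filter_stream(trunc, cfg)
  expect_identical(out$hbo[1:half, ], out_tr$hbo)

  # all-zero stream maps to all zero
  z <- make_hemo(n = 50, n_opt = 2, fs = 2)
  expect_equal(filter_stream(z, cfg)$hbo, matrix(0, 50, 2),
               ignore_attr = TRUE)

  # non-uniform sampling is rejected
  bad_t <- stream$time; bad_t[50] <- bad_t[50] + 0.2
  bad <- hemo_stream(bad_t, stream$hbo, stream$hhb, 2)
  expect_error(filter_stream(bad, cfg), "uniform")
})

test_that("the filter is linear and time-invariant", {
  set.seed(8)
  cfg <- macd_config(sampling_rate = 2, init = "zero")
  n <- 150
  t <- (seq_len(n) - 1) / 2
  x1 <- rnorm(n); x2 <- rnorm(n)
  run <- function(x) filter_stream(
    hemo_stream(t, matrix(x), matrix(x), 2), cfg)$hbo[, 1]
  expect_equal(run(2 * x1 + 3 * x2), 2 * run(x1) + 3 * run(x2),
               tolerance = 1e-10)
  # time invariance: a delayed input gives a delayed output (zero init)
  lag <- 10
  xd <- c(rep(0, lag), x1[1:(n - lag)])
  expect_equal(run(xd)[(lag + 1):n], run(x1)[1:(n - lag)],
               tolerance = 1e-10)
})

test_that("closed-form frequency response is a band-pass matching simulation", {
  cfg <- macd_config(sampling_rate = 2)

  # DC gain exactly zero; rises to an interior max, decays toward Nyquist
  expect_identical(frequency_response(cfg, 0), 0)
  f <- seq(0, 1, by = 0.005)
  H <- frequency_response(cfg, f)
  ipk <- which.max(H)
  expect_gt(ipk, 1)
  expect_lt(ipk, length(f))
  expect_gt(H[ipk], frequency_response(cfg, 0.005))
  expect_gt(H[ipk], frequency_response(cfg, 0.9))
  # monotone decay from the peak toward Nyquist
  expect_true(all(diff(H[ipk:length(f)]) < 1e-12))
  expect_error(frequency_response(cfg, 1.2), "fs/2")

  # closed form vs measured steady-state sinusoid gain, 10 frequencies
  for (fr in c(0.01, 0.02, 0.05, 0.1, 0.15, 0.25, 0.33, 0.5, 0.7, 0.9)) {
    expect_equal(measured_gain(cfg, fr), frequency_response(cfg, fr),
                 tolerance = 0.01)
  }
})

test_that("slow drift is strongly attenuated while in-band signal passes", {
  cfg <- macd_config(sampling_rate = 2)
  g_drift <- measured_gain(cfg, 0.002, duration_s = 3000, settle_s = 1000)
  g_band <- measured_gain(cfg, 0.1)
  # 0.002 Hz drift is suppressed more than tenfold in absolute terms
  # (measured gain ~0.044, i.e. ~23x attenuation) ...
  expect_lt(g_drift, 0.1)
  # ... while the 0.1 Hz signal is passed several times more strongly
  expect_gt(g_band / g_drift, 5)
})

test_that("window seconds convert to samples by rounding at the device rate", {
  c2 <- macd_config(6, 13, sampling_rate = 2)
  expect_equal(c(c2$n_short, c2$n_long), c(12L, 26L))
  c4 <- macd_config(6, 13, sampling_rate = 4)
  expect_equal(c(c4$n_short, c4$n_long), c(24L, 52L))
  expect_error(macd_config(13, 6, sampling_rate = 2), "shorter")
})
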
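test_that("ROI averaging is the unweighted optode mean", {
  prof <- profile_sim16()
  map <- default_roi_map(prof)
  expect_equal(map[["1"]], 1:4)
  expect_equal(map[["4"]], 13:16)

  n <- 20
  hbo <- matrix(rep(1:16, each = n), n, 16)   # optode o constant at o
  stream <- hemo_stream((1:n) / 2, hbo, -hbo, sampling_rate = 2)
  roi <- roi_average(stream, map)
  expect_equal(roi$hbo[1, ], c("1" = 2.5, "2" = 6.5, "3" = 10.5, "4" = 14.5))
  expect_equal(roi$hhb[1, ], -roi$hbo[1, ])

  # identical optodes: ROI equals any single optode
  same <- hemo_stream((1:n) / 2, matrix(3, n, 16), matrix(1, n, 16), 2)
  roi2 <- roi_average(same, map)
  expect_true(all(roi2$hbo == 3))

  # 4-optode profile: each ROI is its own optode
  map4 <- default_roi_map(profile_flight4())
  expect_equal(unname(lengths(map4)), rep(1L, 4))
  stream4 <- hemo_stream((1:n) / 4, matrix(1:4, n, 4, byrow = TRUE),
                         matrix(0, n, 4), 4)
  expect_equal(unname(roi_average(stream4, map4)$hbo[1, ]), 1:4 + 0)

  expect_error(roi_average(stream4, map), "optode")
})

test_that("peak response is post-onset max minus 2 s pre-onset mean", {
  fs <- 2
  t <- seq(0, 59.5, by = 1 / fs)
  base <- rep(0, length(t))
  sig <- base; sig[t >= 20 & t < 25] <- 2.5      # bump inside the window
  stream <- hemo_stream(t, matrix(sig), matrix(0, length(t), 1), fs)
  trial <- list(trial_index = 1L, onset_s = 15)
  pk <- peak_response(stream, trial)
  expect_equal(pk$value[pk$chromophore == "hbo"], 2.5)

  # nonzero pre-trial level is subtracted
  sig2 <- sig; sig2[t < 15] <- 0.5
  stream2 <- hemo_stream(t, matrix(sig2), matrix(0, length(t), 1), fs)
  expect_equal(peak_response(stream2, trial)$value[1], 2.0)

  # missing pre-trial samples are an error
  expect_error(peak_response(stream, list(trial_index = 3L, onset_s = 0.5)),
               "pre-trial")
})

test_that("peak response recovers configured synthetic amplitudes exactly", {
  prof <- fnirs_profile(4, 2)
  proto <- build_timeline("high")
  cfg <- synthetic_config(prof, amp_high = 1.7, noise_white = 0,
                          noise_cardiac = 0, noise_resp = 0, noise_mayer = 0,
                          drift_span = 0, spatial_map = rep(1, 4))
  sess <- simulate_session(proto, cfg, seed = 1)
  pk <- peak_response(sess$stream, proto[1, ])
  expect_lt(max(abs(pk$value[pk$chromophore == "hbo"] - 1.7)), 1e-9)
  expect_lt(max(abs(pk$value[pk$chromophore == "hhb"] + 1.7 / 3)), 1e-9)
})

test_that("group summaries reproduce the published table aggregates", {
  # published summaries are printed truncated to 2 d.p., so agreement is
  # |computed - printed| <= 0.01 rather than equality after rounding
  expect_summary <- function(values, mean_pub, sd_pub) {
    s <- group_summary(values)
    expect_lte(abs(s$mean - mean_pub), 0.01)
    expect_lte(abs(s$sd - sd_pub), 0.01)
  }
  t1 <- load_results_table(1)
  expect_equal(nrow(t1), 12)
  expect_summary(t1$accuracy_testing, 76.66, 16.14)
  expect_summary(t1$precision, 85.60, 19.36)
  expect_summary(t1$recall, 73.33, 24.62)

  t2 <- load_results_table(2)
  expect_summary(t2$accuracy_testing, 78.33, 11.93)
  expect_summary(t2$precision, 84.14, 18.56)
  expect_summary(t2$recall, 76.67, 22.29)

  expect_equal(group_summary(rep(7, 5))$sd, 0)
  expect_error(group_summary(numeric(0)), "nonempty")
})

test_that("published F1 columns are consistent with 2PR/(P+R)", {
  for (k in 1:2) {
    tab <- load_results_table(k)
    f1 <- 2 * tab$precision * tab$recall / (tab$precision + tab$recall)
    expect_lt(max(abs(f1 - tab$f1)), 0.1)
  }
})

test_that("Cohen's d uses the pooled (n-1)-weighted sd", {
  # behavioral error counts: 5.33 +/- 1.95 vs 8.25 +/- 2.42, n = 12 each
  d <- cohens_d(5.33, 1.95, 12, 8.25, 2.42, 12)
  expect_equal(d, 1.34, tolerance = 0.02)

  expect_equal(cohens_d(3, 1, 10, 3, 1, 10), 0)
  # equal n and sd: |dm|/s algebraic identity
  expect_equal(cohens_d(1, 2, 8, 4, 2, 8), 3 / 2)
  expect_warning(dinf <- cohens_d(1, 0, 5, 2, 0, 5), "infinite")
  expect_identical(dinf, Inf)
})

test_that("the unpaired t-test matches direct formula evaluation", {
  same <- c(1, 2, 3)
  r <- unpaired_t_test(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  shifted <- unpaired_t_test(c(1, 2, 3), c(11, 12, 13) + 1e-9)
  expect_lt(shifted$p, 0.001)

  # hand-computed oracle on a 3+3 sample
  a <- c(2, 4, 6); b <- c(5, 8, 11)
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  r2 <- unpaired_t_test(a, b)
  expect_equal(r2$t, t_hand, tolerance = 1e-12)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, p_hand, tolerance = 1e-12)

  expect_error(unpaired_t_test(c(1, 1), c(1, 1)), "degenerate")
})

test_that("exact binomial chance thresholds match tail enumeration", {
  # independent oracle: direct tail sums from choose()
  tail_p <- function(k, n) sum(choose(n, k:n)) / 2^n
  thr_enum <- function(n, alpha) {
    k <- which(vapply(0:n, function(k) tail_p(k, n) <= alpha,
                      logical(1)))[1] - 1
    100 * k / n
  }
  expect_equal(binomial_chance_threshold(20), 75)
  expect_equal(binomial_chance_threshold(10), 90)
  expect_equal(thr_enum(20, 0.05), 75)
  expect_equal(thr_enum(10, 0.05), 90)
  expect_equal(tail_p(15, 20), 21700 / 2^20)
  expect_equal(binomial_chance_threshold(10, alpha = 1), 0)

  for (n in c(5, 12, 16, 40, 100))
    expect_equal(binomial_chance_threshold(n), thr_enum(n, 0.05))

  # non-increasing in the number of trials
  thr <- vapply(c(10, 20, 40, 100, 400), binomial_chance_threshold,
                numeric(1))
  expect_true(all(diff(thr) <= 0))
})
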
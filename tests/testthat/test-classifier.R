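test_that("vectorize flattens to the documented feature counts and inverts", {
  mk <- function(prof) {
    n <- round(30 * prof$sampling_rate)
    arr <- array(rnorm(prof$n_optodes * 2 * n),
                 dim = c(prof$n_optodes, 2, n),
                 dimnames = list(NULL, c("hbo", "hhb"), NULL))
    structure(arr, class = "trial_tensor", load = "high",
              trial_index = 1L, onset_s = 10)
  }
  set.seed(1)
  t16 <- mk(profile_sim16())
  v16 <- vectorize(t16)
  expect_length(v16, 1920)
  t4 <- mk(profile_flight4())
  expect_length(vectorize(t4), 960)

  # documented order: optode-major, hbo before hhb, time fastest
  expect_equal(v16[1:60], as.numeric(t16[1, 1, ]))
  expect_equal(v16[61:120], as.numeric(t16[1, 2, ]))
  expect_equal(v16[121:180], as.numeric(t16[2, 1, ]))

  # round trip
  expect_equal(unvectorize(v16), unclass(t16), ignore_attr = TRUE)
  expect_error(unvectorize(v16, c(4, 2, 120)), "does not match")
})

test_that("cost selection spans the 8-value grid and breaks ties downward", {
  cl <- make_clusters(n_per_class = 5, delta = 5, sd = 0.1)
  sel <- select_C(cl$x, cl$y, seed = 1)
  expect_equal(nrow(sel$cv_table), 8)
  expect_equal(sel$cv_table$C, 10^(-3:4))
  # wide-margin separable data: every C reaches 100%, smallest returned
  expect_true(all(sel$cv_table$cv_accuracy == 1))
  expect_equal(sel$best_C, 1e-3)

  expect_error(select_C(cl$x, rep("low", 10), seed = 1), "both load classes")
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  set.seed(42)
  n_rep <- 200
  best <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- matrix(rnorm(10 * 20), 10, 20)
    y <- sample(rep(c("low", "high"), 5))   # random labels, null features
    best[r] <- select_C(x, y, seed = r)$cv_accuracy
  }
  # the best-of-grid CV accuracy under the null is centered at chance;
  # allow its selection optimism: mean within 3 empirical ses of 50%,
  # plus a small upward bias bound
  se <- sd(best) / sqrt(n_rep)
  expect_lt(abs(mean(best) - 0.5), 3 * se + 0.05)
})

test_that("training fits the separable case and fails gracefully otherwise", {
  cl <- make_clusters(n_per_class = 5, delta = 3, sd = 0.2, seed = 2)
  model <- train_wm_classifier(x = cl$x, y = cl$y, seed = 1)
  expect_s3_class(model, "wm_classifier")
  expect_equal(model$training_accuracy, 100)
  expect_true(model$selected_C %in% 10^(-3:4))

  # contradictory duplicated labels: cannot exceed 50% on those points
  x <- rbind(cl$x[1:2, ], cl$x[1:2, ])
  y <- c("low", "low", "high", "high")
  m2 <- train_wm_classifier(x = x, y = y, seed = 1)
  expect_lte(m2$training_accuracy, 50)

  expect_error(train_wm_classifier(x = cl$x[1:3, ], y = c("low", "low", "high")),
               "2 trials per load class")
})

test_that("rotating feature space leaves predictions unchanged", {
  set.seed(9)
  cl <- make_clusters(n_per_class = 5, p = 12, delta = 2, sd = 0.5, seed = 9)
  rot <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  test_x <- matrix(rnorm(20 * 12), 20, 12)

  m1 <- train_wm_classifier(x = cl$x, y = cl$y, seed = 3)
  m2 <- train_wm_classifier(x = cl$x %*% rot, y = cl$y, seed = 3)
  p1 <- apply(test_x, 1, function(v) predict_load(m1, v)$predicted_load)
  p2 <- apply(test_x %*% rot, 1, function(v) predict_load(m2, v)$predicted_load)
  expect_equal(p1, p2)
})

test_that("predictions agree with the direct margin evaluation", {
  cl <- make_clusters(n_per_class = 5, p = 30, delta = 1, sd = 1, seed = 4)
  model <- train_wm_classifier(x = cl$x, y = cl$y, seed = 1)
  set.seed(5)
  for (i in 1:100) {
    v <- rnorm(30)
    rec <- predict_load(model, v)
    margin <- sum(model$w * v) + model$b
    expect_equal(rec$decision_margin, margin, tolerance = 1e-9)
    expect_equal(rec$predicted_load, if (margin > 0) "high" else "low")
  }
  # class-centroid sanity and the zero-margin tie-break
  hi_centroid <- colMeans(cl$x[cl$y == "high", ])
  expect_equal(predict_load(model, hi_centroid)$predicted_load, "high")
  # a margin of exactly zero resolves to the low-load class
  expect_identical(fnirsbci:::label_from_margin(0), "low")

  expect_error(predict_load(model, rnorm(10)), "feature length")
})

test_that("metrics reproduce known confusion matrices", {
  rec <- function(tp, fp, fn, tn) data.frame(
    predicted_load = c(rep("high", tp + fp), rep("low", fn + tn)),
    true_load = c(rep("high", tp), rep("low", fp),
                  rep("high", fn), rep("low", tn)))

  m <- compute_metrics(rec(2, 1, 3, 4))
  expect_equal(round(c(m$accuracy, m$precision, m$recall, m$f1), 2),
               c(60.00, 66.67, 40.00, 50.00))

  # predict-all-high session: precision 50, recall 100
  m2 <- compute_metrics(rec(5, 5, 0, 0))
  expect_equal(c(m2$accuracy, m2$precision, m2$recall), c(50, 50, 100))

  m3 <- compute_metrics(rec(5, 0, 0, 5))
  expect_equal(c(m3$accuracy, m3$precision, m3$recall, m3$f1),
               c(100, 100, 100, 100))

  expect_warning(m4 <- compute_metrics(rec(0, 0, 5, 5)), "precision")
  expect_true(is.na(m4$precision))
  expect_equal(m4$accuracy, 50)
})

test_that("the online session is causal and collapses under misalignment", {
  prof <- fnirs_profile(4, 2)
  proto <- build_timeline(generate_trial_sequence(10, seed = 21))
  cfg <- synthetic_config(prof, spatial_map = c(1, 2, 2, 1))
  sess <- simulate_session(proto, cfg, seed = 21)
  res <- run_online_session(sess$stream, proto, prof, seed = 21)
  expect_equal(nrow(res$predictions), 10)
  expect_true(all(res$predictions$trial_index == 11:20))

  # bit-identical predictions when post-session samples are removed
  tw <- attr(proto, "trial_window_s")
  keep <- sess$stream$time < proto$onset_s[20] + tw
  res2 <- run_online_session(
    hemo_stream(sess$stream$time[keep], sess$stream$hbo[keep, ],
                sess$stream$hhb[keep, ], 2),
    proto, prof, seed = 21)
  expect_identical(res$predictions, res2$predictions)

  # scoring phase C against labels shifted by one trial approaches chance
  shifted <- res$predictions
  truth <- proto$load[proto$phase == "C"]
  shifted$true_load <- c(truth[-1], truth[1])
  expect_lt(compute_metrics(shifted)$accuracy, res$metrics$accuracy)
})

test_that("a session with a gap inside a trial window skips that trial", {
  prof <- fnirs_profile(2, 2)
  proto <- build_timeline(generate_trial_sequence(10, seed = 3))
  cfg <- synthetic_config(prof, spatial_map = c(1, 2))
  sess <- simulate_session(proto, cfg, seed = 3)
  # drop the samples of trial 15's window
  drop <- sess$stream$time >= proto$onset_s[15] &
    sess$stream$time < proto$onset_s[15] + 30
  st <- hemo_stream(sess$stream$time[!drop], sess$stream$hbo[!drop, ],
                    sess$stream$hhb[!drop, ], 2)
  expect_warning(res <- run_online_session(st, proto, prof, seed = 3),
                 "trial 15")
  expect_equal(res$skipped, 15L)
  expect_equal(nrow(res$predictions), 9)
})
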
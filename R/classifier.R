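#' Flatten a trial tensor into a feature vector
#'
#' Deterministic, invertible flattening of the `optode x chromophore x time`
#' tensor: optode-major, chromophore hbo-before-hhb within an optode, time
#' fastest.  The 16-optode / 2 Hz profile yields 1920 features per 30 s
#' trial; the 4-optode / 4 Hz profile yields 960.
#'
#' @param trial A [segment_trial()] tensor.
#' @return Numeric vector of length `n_optodes * 2 * n_samples`, carrying
#'   the tensor dimensions and trial metadata as attributes.
#' @export
vectorize <- function(trial) {
  if (!inherits(trial, "trial_tensor"))
    stop("`trial` must be a trial_tensor", call. = FALSE)
  d <- dim(trial)
  v <- as.vector(aperm(unclass(trial), c(3, 2, 1)))
  structure(v, tensor_dim = d,
            load = attr(trial, "load"),
            trial_index = attr(trial, "trial_index"))
}

#' Invert [vectorize()]
#' @param v A vector produced by [vectorize()] (or any numeric vector with
#'   matching length).
#' @param tensor_dim Integer triple `c(n_optodes, 2, n_samples)`; defaults
#'   to the dimensions recorded on `v`.
#' @return A `trial_tensor`-shaped array.
#' @export
unvectorize <- function(v, tensor_dim = attr(v, "tensor_dim")) {
  if (is.null(tensor_dim)) stop("tensor dimensions unknown", call. = FALSE)
  if (length(v) != prod(tensor_dim))
    stop("length ", length(v), " does not match dimensions ",
         paste(tensor_dim, collapse = "x"), call. = FALSE)
  aperm(array(as.numeric(v), dim = rev(tensor_dim)), c(3, 2, 1))
}

# Stratified 5-fold assignment for the 10 phase-A trials: one trial per
# class per fold, assigned in trial order; the seed only permutes within
# class so both classes appear in every training fold.
make_folds <- function(labels, n_folds = 5L, seed = NULL) {
  fold <- integer(length(labels))
  if (!is.null(seed)) set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) %% n_folds == 0L) {
      idx <- idx[sample.int(length(idx))]
    }
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Fit a linear soft-margin SVM and extract an oriented (w, b) such that
# w.x + b > 0 predicts "high" load.  No feature scaling unless asked.
fit_linear_svm <- function(x, y, cost, scale = FALSE) {
  y <- factor(y, levels = c("low", "high"))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = cost, scale = scale, tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm's decision value is positive for fit$levels[fit$labels[1]];
  # flip so that positive always means "high".
  if (fit$levels[fit$labels[1]] != "high") {
    w <- -w; b <- -b
  }
  list(fit = fit, w = w, b = b)
}

decision_values <- function(model, x) {
  drop(rbind(x) %*% model$w) + model$b
}

# margin > 0 -> high; exactly 0 resolves to low (documented tie-break).
label_from_margin <- function(margin) {
  ifelse(margin > 0, "high", "low")
}

#' Select the SVM regularization parameter by cross-validation
#'
#' Evaluates each candidate cost `C` on the labeled training trials by
#' stratified 5-fold cross-validation (one trial per class per fold for the
#' canonical 10-trial training set) and returns the `C` with the highest
#' mean fold accuracy.  Ties resolve to the smallest `C` (strongest
#' regularization).  The default grid spans `10^-3` to `10^4` in factors of
#' 10 (8 values).
#'
#' @param x Feature matrix, one row per trial.
#' @param y Load labels (`"low"`/`"high"`).
#' @param grid Candidate costs.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling the within-class fold permutation.
#' @param scale Standardize features before fitting (default FALSE).
#' @return List: `best_C`, `cv_accuracy` (at `best_C`), and `cv_table`
#'   (data frame of mean fold accuracy per grid value).
#' @export
select_C <- function(x, y, grid = 10^(-3:4), n_folds = 5L, seed = NULL,
                     scale = FALSE) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    stop("both load classes must be present in the training set",
         call. = FALSE)
  fold <- make_folds(y, n_folds = n_folds, seed = seed)
  acc <- vapply(grid, function(C) {
    hits <- vapply(seq_len(n_folds), function(k) {
      tr <- fold != k
      m <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], cost = C,
                          scale = scale)
      pred <- label_from_margin(decision_values(m, x[!tr, , drop = FALSE]))
      sum(pred == y[!tr])
    }, numeric(1))
    sum(hits) / length(y)
  }, numeric(1))
  best <- which(acc == max(acc))[1]  # grid ascending: smallest C wins ties
  list(best_C = grid[best], cv_accuracy = acc[best],
       cv_table = data.frame(C = grid, cv_accuracy = acc))
}

#' Train the per-subject working-memory load classifier
#'
#' Runs [select_C()] on the labeled phase-A trials, then refits the linear
#' soft-margin SVM on all of them at the selected cost.  Deterministic
#' given the seed.
#'
#' @param trials List of [segment_trial()] tensors (or a feature matrix via
#'   `x=`/`y=`), at least two trials per class.
#' @param x,y Alternative direct interface: feature matrix and labels.
#' @param grid Candidate costs (default `10^(-3:4)`).
#' @param seed Integer seed for fold construction.
#' @param scale Standardize features (default FALSE).
#' @return Object of class `wm_classifier`: oriented weight vector `w`,
#'   bias `b`, `selected_C`, `cv_accuracy`, `cv_table`, `n_features`,
#'   `training_accuracy`, `n_trials`.
#' @export
train_wm_classifier <- function(trials = NULL, x = NULL, y = NULL,
                                grid = 10^(-3:4), seed = NULL, scale = FALSE) {
  if (!is.null(trials)) {
    x <- do.call(rbind, lapply(trials, function(tr) as.numeric(vectorize(tr))))
    y <- vapply(trials, function(tr) attr(tr, "load"), character(1))
  }
  x <- as.matrix(x)
  y <- as.character(y)
  if (min(table(y)) < 2L || length(unique(y)) < 2L)
    stop("training requires at least 2 trials per load class", call. = FALSE)
  sel <- select_C(x, y, grid = grid, seed = seed, scale = scale)
  m <- fit_linear_svm(x, y, cost = sel$best_C, scale = scale)
  train_pred <- label_from_margin(decision_values(m, x))
  structure(
    list(w = m$w, b = m$b, fit = m$fit,
         selected_C = sel$best_C,
         cv_accuracy = sel$cv_accuracy,
         cv_table = sel$cv_table,
         n_features = ncol(x),
         n_trials = nrow(x),
         training_accuracy = 100 * mean(train_pred == y),
         scale = scale),
    class = "wm_classifier")
}

#' @export
print.wm_classifier <- function(x, ...) {
  cat(sprintf(
    "<wm_classifier> linear SVM, %d features, %d training trials\n  C = %g (CV accuracy %.1f%%), training accuracy %.1f%%\n",
    x$n_features, x$n_trials, x$selected_C, 100 * x$cv_accuracy,
    x$training_accuracy))
  invisible(x)
}

#' Classify one trial
#'
#' Evaluates the signed margin `w.x + b` and labels the trial `"high"` when
#' it is positive, `"low"` otherwise (a margin of exactly zero resolves to
#' low).  Stateless.
#'
#' @param model A [train_wm_classifier()] model.
#' @param features Feature vector (from [vectorize()]) or a trial tensor.
#' @param trial_index,true_load Optional metadata copied into the record;
#'   defaults taken from `features` attributes when present.
#' @return One-row data frame: `trial_index`, `predicted_load`,
#'   `true_load`, `decision_margin`.
#' @export
predict_load <- function(model, features, trial_index = NULL,
                         true_load = NULL) {
  stopifnot(inherits(model, "wm_classifier"))
  if (inherits(features, "trial_tensor")) features <- vectorize(features)
  if (length(features) != model$n_features)
    stop("feature length ", length(features), " does not match the model (",
         model$n_features, ")", call. = FALSE)
  margin <- unname(decision_values(model, as.numeric(features)))
  data.frame(
    trial_index = if (!is.null(trial_index)) as.integer(trial_index)
                  else if (!is.null(attr(features, "trial_index")))
                    attr(features, "trial_index") else NA_integer_,
    predicted_load = label_from_margin(margin),
    true_load = if (!is.null(true_load)) as.character(true_load)
                else if (!is.null(attr(features, "load")))
                  attr(features, "load") else NA_character_,
    decision_margin = margin,
    stringsAsFactors = FALSE
  )
}

#' Session-level classification metrics
#'
#' Accuracy, precision, recall and F1 over a set of prediction records,
#' with the high-load class as the positive class, reported as percentages.
#' When no trial is predicted positive, precision (and F1) are undefined
#' and returned as `NA` with a warning.
#'
#' @param records Data frame with columns `predicted_load`, `true_load`.
#' @return Object of class `session_metrics`: a list with `accuracy`,
#'   `precision`, `recall`, `f1` (percent) and the confusion counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
compute_metrics <- function(records) {
  if (NROW(records) < 1L) stop("no prediction records", call. = FALSE)
  pred <- records$predicted_load
  truth <- records$true_load
  tp <- sum(pred == "high" & truth == "high")
  fp <- sum(pred == "high" & truth == "low")
  fn <- sum(pred == "low" & truth == "high")
  tn <- sum(pred == "low" & truth == "low")
  n <- tp + fp + fn + tn
  accuracy <- 100 * (tp + tn) / n
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    warning("no trials predicted high; precision undefined", call. = FALSE)
    NA_real_
  }
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(
    "<session_metrics> accuracy %.2f%%  precision %s  recall %s  f1 %s (high = positive)\n",
    x$accuracy,
    ifelse(is.na(x$precision), "NA", sprintf("%.2f%%", x$precision)),
    ifelse(is.na(x$recall), "NA", sprintf("%.2f%%", x$recall)),
    ifelse(is.na(x$f1), "NA", sprintf("%.2f%%", x$f1))))
  invisible(x)
}

#' Run the online three-phase session
#'
#' Replays a session stream through the full online pipeline: MACD
#' filtering of every channel, task-locked segmentation, classifier
#' training on the labeled first half of the trials (phase A/B), and
#' one-by-one classification of the second half (phase C).  The prediction
#' for a phase-C trial uses only samples up to the close of that trial's
#' window: the causal filter plus fixed segmentation guarantee the decision
#' is bit-identical whether or not later samples are present.
#'
#' @param stream An unfiltered [hemo_stream()] covering the protocol.
#' @param protocol A [build_timeline()] protocol with an even number of
#'   trials.
#' @param profile An [fnirs_profile()].
#' @param filter A [macd_config()]; default 6 s / 13 s windows at the
#'   profile rate.
#' @param grid SVM cost grid (default `10^(-3:4)`).
#' @param seed Integer seed for cross-validation folds.
#' @param scale Standardize features (default FALSE).
#' @return List of class `session_result`: `classifier`, `predictions`
#'   (phase-C records), `metrics`, `skipped` (trial indices excluded for
#'   missing coverage).
#' @export
run_online_session <- function(stream, protocol, profile,
                               filter = macd_config(sampling_rate = profile$sampling_rate),
                               grid = 10^(-3:4), seed = NULL, scale = FALSE) {
  stopifnot(inherits(protocol, "session_protocol"))
  trial_window_s <- attr(protocol, "trial_window_s")
  filtered <- filter_stream(stream, filter, allow_gaps = TRUE)
  seg <- function(row) segment_trial(filtered, row, profile,
                                     trial_window_s = trial_window_s)
  a_rows <- which(protocol$phase == "A")
  c_rows <- which(protocol$phase == "C")
  skipped <- integer(0)
  tensors_a <- list()
  for (i in a_rows) {
    t <- tryCatch(seg(protocol[i, ]), error = function(e) {
      warning("phase A trial ", protocol$trial_index[i], " skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(t)) tensors_a[[length(tensors_a) + 1L]] <- t else
      skipped <- c(skipped, protocol$trial_index[i])
  }
  model <- train_wm_classifier(tensors_a, grid = grid, seed = seed,
                               scale = scale)
  preds <- list()
  for (i in c_rows) {
    t <- tryCatch(seg(protocol[i, ]), error = function(e) {
      warning("phase C trial ", protocol$trial_index[i], " skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(t)) { skipped <- c(skipped, protocol$trial_index[i]); next }
    preds[[length(preds) + 1L]] <- predict_load(model, t)
  }
  predictions <- do.call(rbind, preds)
  structure(list(classifier = model,
                 predictions = predictions,
                 metrics = compute_metrics(predictions),
                 skipped = skipped),
            class = "session_result")
}
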
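# End-to-end decoding: bandpass -> spatial filters -> log-variance features
# -> probabilistic classifier, repeated over filter-bank branches whose
# class probabilities are fused by averaging.

train_classifier <- function(feats, labels, kind, seed) {
  y <- factor(labels, levels = c(1L, 2L))
  if (kind == "svm-rbf") {
    d <- ncol(feats)
    gam <- 1 / (d * mean(apply(feats, 2, stats::var)))
    if (!is.finite(gam) || gam <= 0) gam <- 1 / d
    fit <- e1071::svm(x = feats, y = y, kernel = "radial", cost = 1,
                      gamma = gam, scale = FALSE)
    dv <- attr(stats::predict(fit, feats, decision.values = TRUE),
               "decision.values")[, 1]
    # Platt-style logistic calibration of decision values -> P(class 1)
    platt <- suppressWarnings(
      stats::glm((labels == 1L) ~ dv, family = stats::binomial()))
    list(kind = kind, fit = fit, platt = platt)
  } else {
    list(kind = kind, fit = MASS::lda(feats, grouping = y))
  }
}

classifier_proba <- function(clf, feats) {
  if (clf$kind == "svm-rbf") {
    dv <- attr(stats::predict(clf$fit, feats, decision.values = TRUE),
               "decision.values")[, 1]
    p1 <- suppressWarnings(
      stats::predict(clf$platt, data.frame(dv = dv), type = "response"))
    p1 <- pmin(pmax(as.numeric(p1), 1e-12), 1 - 1e-12)
  } else {
    post <- stats::predict(clf$fit, feats)$posterior
    p1 <- as.numeric(post[, "1"])
  }
  cbind(p1 = p1, p2 = 1 - p1)
}

#' Fit one filter-bank branch
#'
#' Band-filters the training epochs, fits VPCSP spatial filters, extracts
#' log-variance features and trains a probabilistic classifier on them.
#'
#' @param x_train [eeg_epochs] training set (both classes present).
#' @param band a [band_spec()], or `NULL` when `x_train` is already
#'   band-filtered (the branch then applies no filter of its own).
#' @param config a [vpcsp_config()].
#' @param clf_kind `"svm-rbf"` (RBF-kernel SVM with logistic calibration of
#'   decision values) or `"lda"`.
#' @param seed integer seed (classifier internals).
#' @return a `branch_model` list: `band`, `sfilter`, `classifier`,
#'   `feature_dim`.
#' @export
fit_branch <- function(x_train, band, config = vpcsp_config(),
                       clf_kind = c("svm-rbf", "lda"), seed = 1L) {
  clf_kind <- match.arg(clf_kind)
  check_two_classes(x_train)
  xb <- if (is.null(band)) x_train else bandpass(x_train, band)
  sfilter <- vpcsp(xb, config)
  feats <- stats::predict(sfilter, xb)
  clf <- with_seed(seed, train_classifier(feats, x_train$labels, clf_kind,
                                          seed))
  structure(list(band = band, sfilter = sfilter, classifier = clf,
                 feature_dim = ncol(feats)),
            class = "branch_model")
}

branch_proba <- function(branch, x) {
  xb <- if (is.null(branch$band)) x else bandpass(x, branch$band)
  feats <- stats::predict(branch$sfilter, xb)
  classifier_proba(branch$classifier, feats)
}

#' Fit a filter-bank VPCSP decoder
#'
#' Trains one branch per band (default three overlapping bands, 4-20 /
#' 8-24 / 12-28 Hz, applied to the raw epochs) and fuses branch class
#' probabilities by an unweighted mean at prediction time.
#'
#' @param x [eeg_epochs] training set.
#' @param bands list of [band_spec()]; a single band gives a plain (non-FB)
#'   decoder.
#' @param config a [vpcsp_config()] shared by all branches.
#' @param clf_kind `"svm-rbf"` or `"lda"`.
#' @param seed integer seed.
#' @return an object of class `"vpcsp_fb"` with a [predict()] method.
#' @export
vpcsp_fb <- function(x, bands = default_bands(), config = vpcsp_config(),
                     clf_kind = c("svm-rbf", "lda"), seed = 1L) {
  clf_kind <- match.arg(clf_kind)
  if (length(bands) < 1L) abort_validation("need at least one band")
  branches <- lapply(bands, function(b)
    fit_branch(x, b, config, clf_kind, seed))
  structure(list(branches = branches, fusion = "mean-probability",
                 config = config, clf_kind = clf_kind, seed = seed),
            class = "vpcsp_fb")
}

#' @export
print.vpcsp_fb <- function(x, ...) {
  cat(sprintf("<vpcsp_fb> %d branch(es), %s classifier, %s fusion\n",
              length(x$branches), x$clf_kind, x$fusion))
  for (b in x$branches)
    cat(sprintf("  band %s: %d features\n",
                if (is.null(b$band)) "(prefiltered)"
                else sprintf("%g-%g Hz", b$band$low_hz, b$band$high_hz),
                b$feature_dim))
  invisible(x)
}

#' Predict class probabilities or labels from a filter-bank decoder
#'
#' Per-branch class probabilities are averaged with equal weights; the
#' predicted label is the argmax, ties broken toward class 1.
#'
#' @param object a `vpcsp_fb` model.
#' @param newdata an [eeg_epochs] object.
#' @param type `"prob"` (n x 2 matrix, columns `p1`, `p2`) or `"class"`
#'   (integer labels).
#' @param ... unused.
#' @export
predict.vpcsp_fb <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- lapply(object$branches, branch_proba, x = newdata)
  fused <- Reduce(`+`, probs) / length(probs)
  if (type == "prob") fused else ifelse(fused[, 1] >= fused[, 2], 1L, 2L)
}

#' Confusion-table classification metrics
#'
#' @param true_labels,predicted_labels equal-length label vectors in `{1,2}`.
#' @param positive_class which class counts as positive. Default 1.
#' @return list: `accuracy`, `precision`, `recall` (percent; `NA` when the
#'   denominator is empty), `confusion` (`tp`, `fp`, `fn`, `tn`).
#' @export
compute_metrics <- function(true_labels, predicted_labels,
                            positive_class = 1L) {
  if (length(true_labels) != length(predicted_labels))
    abort_validation("label vectors differ in length")
  pos <- positive_class
  tp <- sum(true_labels == pos & predicted_labels == pos)
  fp <- sum(true_labels != pos & predicted_labels == pos)
  fn <- sum(true_labels == pos & predicted_labels != pos)
  tn <- sum(true_labels != pos & predicted_labels != pos)
  list(accuracy = 100 * (tp + tn) / length(true_labels),
       precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired per-subject accuracies.  Zero
#' differences are dropped; the p-value is exact for up to 25 nonzero
#' differences and uses the normal approximation above that.  The signed
#' statistic is `W+ - W-` (negated when the arguments are swapped).
#'
#' @param acc_a,acc_b equal-length numeric vectors (e.g. per-subject
#'   accuracies of two methods).
#' @return list: `p_value`, `statistic` (signed rank-sum difference), `v`
#'   (positive rank sum), `n` (nonzero differences), `degenerate` (`TRUE`
#'   when every difference is zero; p-value is then `NA`).
#' @export
wilcoxon_compare <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    abort_validation("vectors differ in length")
  d <- acc_a - acc_b
  keep <- d != 0
  n <- sum(keep)
  if (n == 0L)
    return(list(p_value = NA_real_, statistic = NA_real_, v = NA_real_,
                n = 0L, degenerate = TRUE))
  wt <- suppressWarnings(
    stats::wilcox.test(acc_a[keep], acc_b[keep], paired = TRUE,
                       exact = n <= 25))
  v <- unname(wt$statistic)
  list(p_value = wt$p.value, statistic = 2 * v - n * (n + 1) / 2, v = v,
       n = n, degenerate = FALSE)
}

#' Cross-validated evaluation of the decoder
#'
#' For each of `n_folds` folds: split the trials 64/16/20
#' (train/validation/test, stratified); optionally tune `(mode, l, beta, q)`
#' by Bayesian optimization on the train/validation pair; refit on the
#' training trials (or train+validation with `refit = "train+val"`); score
#' the held-out test trials.  Test trials never influence fitting or
#' hyperparameter selection.
#'
#' @param x an [eeg_epochs] object.
#' @param space a [hyper_search_space()] or `NULL` to skip tuning and use
#'   `config` as-is.
#' @param config fixed [vpcsp_config()] defaults.
#' @param clf_kind `"svm-rbf"` or `"lda"`.
#' @param bands list of [band_spec()] branches.
#' @param n_folds number of folds. Default 5.
#' @param seed integer seed controlling splits, tuning and classifiers.
#' @param refit `"train"` (default) or `"train+val"`.
#' @return an `eval_report`: `folds` (per-fold data frame with metrics and
#'   chosen hyperparameters), `mean_accuracy`, `mean_precision`,
#'   `mean_recall`, `confusion`, `splits` (index sets per fold), `seed`.
#' @export
cross_validate <- function(x, space = NULL, config = vpcsp_config(),
                           clf_kind = c("svm-rbf", "lda"),
                           bands = list(band_spec(8, 32)), n_folds = 5L,
                           seed = 1L, refit = c("train", "train+val")) {
  clf_kind <- match.arg(clf_kind)
  refit <- match.arg(refit)
  rows <- list(); conf <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  splits <- list()
  for (fold in seq_len(n_folds)) {
    sp <- split_64_16_20(x, fold, n_folds, seed)
    splits[[fold]] <- sp
    x_tr <- select_trials(x, sp$train_idx)
    x_val <- select_trials(x, sp$val_idx)
    x_te <- select_trials(x, sp$test_idx)
    cfg <- config
    chosen <- list(mode = config$spacing_mode, l = config$l,
                   beta = config$beta, q = config$q)
    if (!is.null(space)) {
      bo <- bayes_optimize(x_tr, x_val, space, config, clf_kind, bands,
                           seed = seed + 1000L * fold)
      chosen <- bo$best
      cfg <- do.call(vpcsp_config, utils::modifyList(unclass(config), list(
        spacing_mode = chosen$mode, l = chosen$l, beta = chosen$beta,
        q = if (chosen$mode == "single") 1L else chosen$q)))
    }
    x_fit <- if (refit == "train+val")
      select_trials(x, sort(c(sp$train_idx, sp$val_idx))) else x_tr
    m <- vpcsp_fb(x_fit, bands, cfg, clf_kind, seed = seed + fold)
    pred <- stats::predict(m, x_te, type = "class")
    met <- compute_metrics(x_te$labels, pred, positive_class = 1L)
    conf <- conf + met$confusion
    rows[[fold]] <- data.frame(
      fold = fold, accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, mode = chosen$mode, l = chosen$l,
      beta = chosen$beta, q = chosen$q, n_test = length(sp$test_idx))
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy),
                 mean_precision = mean(folds$precision, na.rm = TRUE),
                 mean_recall = mean(folds$recall, na.rm = TRUE),
                 confusion = conf, splits = splits,
                 clf_kind = clf_kind, seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds, %s classifier (seed %d)\n",
              nrow(x$folds), x$clf_kind, x$seed))
  print(x$folds, row.names = FALSE, digits = 4)
  cat(sprintf("mean: accuracy %.2f%%  precision %.2f%%  recall %.2f%%\n",
              x$mean_accuracy, x$mean_precision, x$mean_recall))
  invisible(x)
}
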
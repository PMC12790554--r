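# Evaluation protocols: the 5-fold hold-out + one-shot frozen-test
# procedure, and the label-randomization sanity check.

#' Five-fold hold-out plus one-shot frozen-test protocol
#'
#' Partitions the training pool into label-stratified folds; each fold's
#' model (an equal-weight fusion over `views`) is validated on its held-out
#' fifth and additionally scored on the untouched frozen test set, tracking
#' test-set variability across training resamples. A final model refit on
#' the full pool scores the test once. Any overlap between the training
#' pool and the frozen ids raises `test_leakage`.
#'
#' @param X Feature matrix or `fp_matrix` covering all ids.
#' @param labels Named binary labels.
#' @param train_ids,frozen_test_ids Id vectors defining the two partitions.
#' @param views Named list of [feature_view()] members of the fusion.
#' @param spec Base learner ([learner_spec()]).
#' @param n_folds Folds (default 5).
#' @param seed Integer seed.
#' @return An object of class `protocol_result`: `holdout_reports`,
#'   `test_reports` (per fold), `final_test_report`, `fold_assignment`,
#'   `seed`.
#' @export
five_fold_protocol <- function(X, labels, train_ids, frozen_test_ids, views,
                               spec = learner_spec("gbdt"), n_folds = 5L,
                               seed = 1L) {
  if (inherits(X, "fp_matrix")) X <- X$matrix
  train_ids <- as.character(train_ids)
  frozen_test_ids <- as.character(frozen_test_ids)
  if (length(intersect(train_ids, frozen_test_ids)) > 0L)
    ds_error("test_leakage", "training pool overlaps the frozen test set")
  y_tr <- as.integer(labels[train_ids])
  y_te <- as.integer(labels[frozen_test_ids])
  Xtr <- X[train_ids, , drop = FALSE]
  Xte <- X[frozen_test_ids, , drop = FALSE]
  fold <- stratified_folds(y_tr, n_folds, seed)
  holdout_reports <- test_reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    trn <- fold != f
    guard_touch(train_ids[trn], sprintf("five_fold_protocol/fold%d", f))
    members <- lapply(views, function(v)
      train_view_model(v, Xtr[trn, , drop = FALSE], y_tr[trn], spec))
    fm <- fusion_model(members)
    holdout_reports[[f]] <- classification_report(
      fuse_scores(fm, Xtr[!trn, , drop = FALSE]), y_tr[!trn])
    test_reports[[f]] <- classification_report(fuse_scores(fm, Xte), y_te)
  }
  guard_touch(train_ids, "five_fold_protocol/final_refit")
  members <- lapply(views, function(v) train_view_model(v, Xtr, y_tr, spec))
  final_report <- classification_report(
    fuse_scores(fusion_model(members), Xte), y_te)
  structure(list(holdout_reports = holdout_reports,
                 test_reports = test_reports,
                 final_test_report = final_report,
                 fold_assignment = stats::setNames(fold, train_ids),
                 seed = as.integer(seed)),
            class = "protocol_result")
}

#' Summarise a protocol result
#'
#' @param object A `protocol_result`.
#' @param ... Unused.
#' @return Data.frame: one row per metric with hold-out and test mean/sd.
#' @export
summary.protocol_result <- function(object, ...) {
  keys <- c("ef_1pct", "ef_5pct", "bedroc_20", "bedroc_50", "bedroc_80",
            "roc_auc", "ap", "f1", "precision", "recall",
            "balanced_accuracy", "mcc", "brier")
  get_vals <- function(reports, k) vapply(reports, `[[`, 1, k)
  data.frame(
    metric = keys,
    holdout_mean = vapply(keys, function(k) mean(get_vals(object$holdout_reports, k)), 1),
    holdout_sd = vapply(keys, function(k) stats::sd(get_vals(object$holdout_reports, k)), 1),
    test_mean = vapply(keys, function(k) mean(get_vals(object$test_reports, k)), 1),
    test_sd = vapply(keys, function(k) stats::sd(get_vals(object$test_reports, k)), 1),
    row.names = NULL
  )
}

#' Label-randomization sanity check
#'
#' Permutes the labels *within the training pool* (test labels stay intact:
#' a null model is evaluated against real labels), reruns the full
#' train-and-evaluate protocol per repetition, and reports every metric's
#' mean and standard deviation across repetitions and folds next to its
#' analytic random baseline (AUC 0.5, EF 1, AP at prevalence, BEDROC at its
#' random expectation, MCC 0). A sound pipeline collapses to chance here.
#'
#' @inheritParams five_fold_protocol
#' @param n_reps Number of label permutations (default 5).
#' @param n_folds Folds inside each repetition (default 5).
#' @return Data.frame of class `randomization_summary`: per metric the
#'   hold-out and test mean/sd plus `random_holdout` / `random_test`
#'   analytic baselines.
#' @export
label_randomization_run <- function(X, labels, train_ids, frozen_test_ids,
                                    views, spec = learner_spec("gbdt"),
                                    n_reps = 5L, n_folds = 5L, seed = 1L) {
  if (inherits(X, "fp_matrix")) X <- X$matrix
  train_ids <- as.character(train_ids)
  labels <- labels[c(train_ids, frozen_test_ids)]
  hold <- test <- list()
  for (r in seq_len(n_reps)) {
    perm <- labels
    perm[train_ids] <- with_seed(child_seed(seed, 50L + r),
                                 sample(labels[train_ids]))
    res <- five_fold_protocol(X, perm, train_ids, frozen_test_ids, views,
                              spec = spec, n_folds = n_folds,
                              seed = child_seed(seed, r))
    hold <- c(hold, res$holdout_reports)
    test <- c(test, res$test_reports)
  }
  keys <- c("roc_auc", "ap", "f1", "precision", "recall",
            "balanced_accuracy", "brier", "mcc",
            "ef_1pct", "ef_5pct", "bedroc_20", "bedroc_50", "bedroc_80")
  y_tr <- as.integer(labels[train_ids])
  y_te <- as.integer(labels[as.character(frozen_test_ids)])
  # hold-out folds have ~1/n_folds of the pool at pool prevalence
  base_h <- random_baselines(round(length(y_tr) / n_folds),
                             max(1L, round(sum(y_tr) / n_folds)))
  base_t <- random_baselines(length(y_te), sum(y_te))
  vals <- function(reports, k) vapply(reports, `[[`, 1, k)
  out <- data.frame(
    metric = keys,
    holdout_mean = vapply(keys, function(k) mean(vals(hold, k)), 1),
    holdout_sd = vapply(keys, function(k) stats::sd(vals(hold, k)), 1),
    test_mean = vapply(keys, function(k) mean(vals(test, k)), 1),
    test_sd = vapply(keys, function(k) stats::sd(vals(test, k)), 1),
    random_holdout = vapply(keys, function(k) base_h[[k]], 1),
    random_test = vapply(keys, function(k) base_t[[k]], 1),
    row.names = NULL
  )
  class(out) <- c("randomization_summary", "data.frame")
  out
}
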
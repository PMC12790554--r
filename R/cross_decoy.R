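# Cross-decoy transfer validation: train on positives plus negatives from
# exactly one decoy source; validate within-recipe by stratified CV (the 3x3
# diagonal) and across recipes on the frozen test positives plus the test
# negatives of each other source (the off-diagonals).

#' The 3x3 cross-decoy matrix for one feature view
#'
#' For each training decoy source, fits a class-weighted
#' extremely-randomized-trees baseline (with median imputation, a no-op on
#' binary bits) on the training positives plus that source's training
#' negatives. Diagonal cells report mean ROC AUC / AP over stratified
#' `n_folds`-fold CV on that mixture (`cv_holdout`); off-diagonal cells
#' refit on the full mixture and evaluate on the frozen test positives plus
#' the *other* source's test negatives (`external_test`). Off-diagonal
#' evaluation never touches training-partition negatives of the test
#' source.
#'
#' @param view A [feature_view()].
#' @param split A frozen [early_split()] plan.
#' @param fp `fp_matrix` covering all split ids.
#' @param labels Named binary labels.
#' @param n_folds CV folds for the diagonal (default 5).
#' @param seed Integer seed.
#' @param spec Base learner (default class-weighted extremely-randomized
#'   trees).
#' @return Data.frame of 9 rows: `list_id`, `train_source`, `test_source`,
#'   `test_type`, `roc_auc`, `ap`.
#' @export
cross_decoy_matrix <- function(view, split, fp, labels, n_folds = 5L,
                               seed = 1L, spec = learner_spec("extra_trees")) {
  stopifnot(inherits(view, "feature_view"), inherits(split, "split_plan"),
            inherits(fp, "fp_matrix"))
  sources <- names(split$train_negative_ids)
  if (length(sources) < 2L)
    ds_error("missing_source", "cross-decoy validation needs >= 2 sources")
  labels <- labels[fp$ids]
  rows <- list()
  for (tr_src in sources) {
    mix_ids <- c(split$train_positive_ids, split$train_negative_ids[[tr_src]])
    guard_touch(mix_ids, "cross_decoy_matrix")
    y <- labels[mix_ids]
    Xmix <- fp_subset(fp, mix_ids)
    cw <- ifelse(y == 1L, 0.5 / mean(y == 1L), 0.5 / mean(y == 0L))
    # diagonal: within-recipe CV
    fold <- stratified_folds(y, n_folds, child_seed(seed, match(tr_src, sources)))
    aucs <- aps <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      trn <- fold != f
      m <- train_view_model(view, Xmix$matrix[trn, , drop = FALSE], y[trn],
                            spec, case_weights = cw[trn])
      sc <- predict(m, Xmix$matrix[!trn, , drop = FALSE])
      aucs[f] <- roc_auc(sc, y[!trn])
      aps[f] <- average_precision(sc, y[!trn])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      list_id = view$name, train_source = tr_src, test_source = tr_src,
      test_type = "cv_holdout", roc_auc = mean(aucs), ap = mean(aps),
      stringsAsFactors = FALSE)
    # off-diagonal: refit on full mixture, transfer to other sources
    m_full <- train_view_model(view, Xmix, y, spec, case_weights = cw)
    for (te_src in setdiff(sources, tr_src)) {
      te_ids <- c(split$test_positive_ids, split$test_negative_ids[[te_src]])
      stopifnot(length(intersect(te_ids, mix_ids)) == 0L)
      sc <- predict(m_full, fp_subset(fp, te_ids))
      yt <- labels[te_ids]
      rows[[length(rows) + 1L]] <- data.frame(
        list_id = view$name, train_source = tr_src, test_source = te_src,
        test_type = "external_test", roc_auc = roc_auc(sc, yt),
        ap = average_precision(sc, yt), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Retain views with consistent cross-decoy transfer
#'
#' A view is retained iff its worst off-diagonal (transfer) ROC AUC and AP
#' clear the floors and its largest per-training-source drop from the
#' in-recipe (`cv_holdout`) AP to the worst transfer AP stays below the cap.
#' A view that is strong on one recipe but collapses under recipe shift is
#' discarded.
#'
#' @param matrices Data.frame of [cross_decoy_matrix()] rows (one or more
#'   views, keyed by `list_id`), or a list of such data.frames.
#' @param min_transfer_auc,min_transfer_ap Floors on the worst off-diagonal
#'   cells (defaults 0.75 / 0.35).
#' @param max_ap_drop Cap on `cv_holdout` AP minus worst transfer AP per
#'   training source (default 0.35).
#' @return Character vector of retained `list_id`s (possibly empty).
#' @export
select_transferable_views <- function(matrices, min_transfer_auc = 0.75,
                                      min_transfer_ap = 0.35,
                                      max_ap_drop = 0.35) {
  if (is.list(matrices) && !is.data.frame(matrices))
    matrices <- do.call(rbind, matrices)
  if (NROW(matrices) == 0L) return(character())
  retained <- character()
  for (v in unique(matrices$list_id)) {
    cells <- matrices[matrices$list_id == v, , drop = FALSE]
    off <- cells[cells$test_type == "external_test", , drop = FALSE]
    diag <- cells[cells$test_type == "cv_holdout", , drop = FALSE]
    ok <- min(off$roc_auc) >= min_transfer_auc &&
      min(off$ap) >= min_transfer_ap
    if (ok) {
      for (src in diag$train_source) {
        d_ap <- diag$ap[diag$train_source == src]
        worst <- min(off$ap[off$train_source == src])
        if (d_ap - worst > max_ap_drop) { ok <- FALSE; break }
      }
    }
    if (ok) retained <- c(retained, v)
  }
  retained
}
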
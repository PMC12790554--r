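# Domain-bias-aware feature-set screening: how well can a feature view
# predict a negative's decoy source? Views are gated at near-chance on four
# multi-class metrics and additionally checked for primary-task
# compatibility before they qualify as candidate views.

multiclass_metrics <- function(truth, pred, probs) {
  truth <- factor(truth)
  lv <- levels(truth)
  pred <- factor(pred, levels = lv)
  acc <- mean(pred == truth)
  recalls <- vapply(lv, function(l) {
    n <- sum(truth == l)
    if (n == 0) return(NA_real_)
    sum(pred == l & truth == l) / n
  }, 1)
  f1s <- vapply(lv, function(l) {
    tp <- sum(pred == l & truth == l)
    prec <- if (sum(pred == l) > 0) tp / sum(pred == l) else 0
    rec <- if (sum(truth == l) > 0) tp / sum(truth == l) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 1)
  aucs <- vapply(lv, function(l)
    roc_auc(probs[, l], as.integer(truth == l)), 1)
  c(accuracy = acc,
    balanced_accuracy = mean(recalls, na.rm = TRUE),
    macro_f1 = mean(f1s),
    macro_auc_ovr = mean(aucs))
}

#' Audit a feature view for domain bias
#'
#' Cross-validated multi-class origin classification (extremely-randomized
#' trees) of the negatives, restricted to the view's columns; positives are
#' excluded by contract. Reports per-fold and mean accuracy, balanced
#' accuracy, macro-F1 and macro one-vs-rest AUC, plus the pooled
#' out-of-fold confusion matrix (rows = truth, columns = prediction).
#'
#' @param view A [feature_view()].
#' @param negatives `fp_matrix` of negatives.
#' @param sources Source tag per negative.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param num_trees Trees for the origin classifier (default 300).
#' @return An object of class `domain_audit_report`.
#' @export
audit_view <- function(view, negatives, sources, n_folds = 5L, seed = 1L,
                       num_trees = 300L) {
  stopifnot(inherits(view, "feature_view"), inherits(negatives, "fp_matrix"))
  if (length(view) == 0L) ds_error("empty_view", "view has no bits")
  sources <- align_tags(sources, negatives$ids)
  if (length(unique(sources)) < 2L)
    ds_error("single_source", "audit needs >= 2 sources")
  X <- view_columns(negatives, view)
  src <- factor(sources)
  fold <- stratified_folds(src, n_folds, seed)
  per_fold <- matrix(NA_real_, n_folds, 4L,
                     dimnames = list(NULL, c("accuracy", "balanced_accuracy",
                                             "macro_f1", "macro_auc_ovr")))
  pooled_pred <- factor(rep(NA_character_, length(src)), levels = levels(src))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    d <- data.frame(.src = src[tr], X[tr, , drop = FALSE])
    m <- ranger::ranger(
      dependent.variable.name = ".src", data = d, probability = TRUE,
      num.trees = num_trees, splitrule = "extratrees",
      num.random.splits = 1L, seed = child_seed(seed, f), num.threads = 1L)
    pr <- predict(m, data.frame(X[!tr, , drop = FALSE]),
                  num.threads = 1L)$predictions
    pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                   levels = levels(src))
    pooled_pred[!tr] <- pred
    per_fold[f, ] <- multiclass_metrics(src[!tr], pred, pr)
  }
  means <- colMeans(per_fold)
  confusion <- table(truth = src, prediction = pooled_pred)
  rep <- structure(list(
    view = view$name,
    per_fold = as.data.frame(per_fold),
    accuracy = means[["accuracy"]],
    balanced_accuracy = means[["balanced_accuracy"]],
    macro_f1 = means[["macro_f1"]],
    macro_auc_ovr = means[["macro_auc_ovr"]],
    confusion_matrix = confusion
  ), class = "domain_audit_report")
  rep$gate_passed <- leakage_gate(rep)
  rep
}

#' @export
print.domain_audit_report <- function(x, ...) {
  cat(sprintf(
    "Domain audit '%s': acc %.3f, bal-acc %.3f, macro-F1 %.3f, macro-AUC %.3f -> gate %s\n",
    x$view, x$accuracy, x$balanced_accuracy, x$macro_f1, x$macro_auc_ovr,
    if (x$gate_passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Near-chance leakage gate
#'
#' A view passes iff all four origin-audit metrics lie strictly below the
#' relaxed chance-level thresholds: mean accuracy < 0.4, balanced accuracy
#' < 0.4, macro-F1 < 0.4 and macro-AUC-OVR < 0.6 (three-class chance is
#' about 0.333 / 0.5). The inequalities are strict: boundary values fail.
#'
#' @param report A `domain_audit_report`, or a named list/vector with
#'   `accuracy`, `balanced_accuracy`, `macro_f1`, `macro_auc_ovr`.
#' @param acc_max,bal_max,f1_max,auc_max Gate thresholds.
#' @return Logical.
#' @export
leakage_gate <- function(report, acc_max = 0.4, bal_max = 0.4,
                         f1_max = 0.4, auc_max = 0.6) {
  g <- function(k) as.numeric(report[[k]])
  isTRUE(g("accuracy") < acc_max && g("balanced_accuracy") < bal_max &&
           g("macro_f1") < f1_max && g("macro_auc_ovr") < auc_max)
}

#' Fixed validation split for compatibility checks
#'
#' Carves a single seed-pinned validation subset (default 20%) out of the
#' training pool, stratified by label; used for every compatibility check of
#' a run so all views face the same split.
#'
#' @param labels Binary labels of the training pool.
#' @param frac Validation fraction.
#' @param seed Integer seed.
#' @return Logical vector: `TRUE` marks validation rows.
#' @export
fixed_validation_split <- function(labels, frac = 0.20, seed = 1L) {
  fold <- stratified_folds(labels, n_folds = max(2L, round(1 / frac)), seed)
  fold == 1L
}

#' Primary-task compatibility of a feature view
#'
#' Trains the primary prodrug-vs-decoy classifier on the view's columns
#' (training side of the fixed validation split) and accepts the view iff
#' its validation ROC AUC preserves at least `min_ratio` (default 95%) of
#' `baseline_auc`, the full-feature AUC on the same split.
#'
#' @param view A [feature_view()].
#' @param X Feature matrix or `fp_matrix` of the training pool.
#' @param labels Binary labels.
#' @param validation Logical validation mask from [fixed_validation_split()].
#' @param baseline_auc Full-feature ROC AUC on the same split.
#' @param min_ratio Required fraction of the baseline (0.95).
#' @param spec Learner specification (default gradient-boosted trees).
#' @return List with `compatible` (logical), `auc`, `baseline_auc`.
#' @export
task_compatibility <- function(view, X, labels, validation, baseline_auc,
                               min_ratio = 0.95, spec = learner_spec("gbdt")) {
  if (inherits(X, "fp_matrix")) X <- X$matrix
  labels <- as.integer(labels)
  model <- train_view_model(view, X[!validation, , drop = FALSE],
                            labels[!validation], spec)
  scores <- predict(model, X[validation, , drop = FALSE])
  auc <- roc_auc(scores, labels[validation])
  list(compatible = auc >= min_ratio * baseline_auc, auc = auc,
       baseline_auc = baseline_auc)
}

#' Compute the full-feature baseline AUC for compatibility checks
#'
#' @inheritParams task_compatibility
#' @return ROC AUC of the full feature set on the validation rows.
#' @export
compatibility_baseline <- function(X, labels, validation,
                                   spec = learner_spec("gbdt")) {
  if (inherits(X, "fp_matrix")) X <- X$matrix
  full <- feature_view("all_bits", seq_len(ncol(X)) - 1L, nbits = ncol(X))
  task_compatibility(full, X, labels, validation, baseline_auc = 0,
                     spec = spec)$auc
}

#' Random search over candidate feature views
#'
#' Draws seeded random bit subsets (sizes uniform over `size_range`),
#' audits each for domain bias, and retains those that pass both the
#' [leakage_gate()] and [task_compatibility()]. Candidates are drawn from a
#' task-relevant bit pool (by default the top `pool_size` bits by ANOVA
#' F-score on the training pool), since the compatibility gate requires the
#' subset to carry primary-task signal. Survivors are ranked by their
#' distance to chance on the audit metrics (ascending), then macro-AUC,
#' accuracy and name.
#'
#' @param negatives `fp_matrix` of training negatives (for the audit).
#' @param sources Source tag per negative.
#' @param X Training-pool feature matrix (positives + negatives).
#' @param labels Binary labels aligned to `X`.
#' @param n_candidates Number of subsets to evaluate (>= 30 by design).
#' @param size_range Subset size range (default 40--55 bits, the scale of
#'   the packaged views).
#' @param candidate_bits Optional 0-based bit pool to draw from; default =
#'   top `pool_size` ANOVA-F bits.
#' @param pool_size Size of the default candidate pool (256).
#' @param n_folds Audit folds.
#' @param seed Integer seed.
#' @param spec Learner for the compatibility check.
#' @param num_trees Trees per audit fold.
#' @return List of class `view_search`: `survivors` (list of `feature_view`
#'   with audit metrics attached), `candidates` (data.frame of every
#'   evaluated subset), `baseline_auc`.
#' @export
random_view_search <- function(negatives, sources, X, labels,
                               n_candidates = 30L, size_range = c(40L, 55L),
                               candidate_bits = NULL, pool_size = 256L,
                               n_folds = 5L, seed = 1L,
                               spec = learner_spec("gbdt"),
                               num_trees = 200L) {
  if (inherits(X, "fp_matrix")) X <- X$matrix
  labels <- as.integer(labels)
  nbits <- ncol(negatives$matrix)
  if (is.null(candidate_bits)) {
    rk <- anova_f_rank(X, labels)
    top <- utils::head(rk$name[!rk$constant], pool_size)
    candidate_bits <- as.integer(sub("^.*_", "", top))
  }
  validation <- fixed_validation_split(labels, seed = child_seed(seed, 999L))
  baseline_auc <- compatibility_baseline(X, labels, validation, spec = spec)
  sizes <- with_seed(child_seed(seed, 1L),
                     sample(seq(size_range[1L], size_range[2L]),
                            n_candidates, replace = TRUE))
  rows <- vector("list", n_candidates)
  survivors <- list()
  for (i in seq_len(n_candidates)) {
    bits <- with_seed(child_seed(seed, 100L + i),
                      sort(sample(candidate_bits, sizes[i])))
    v <- feature_view(sprintf("view_%03d", i), bits, nbits = nbits)
    audit <- audit_view(v, negatives, sources, n_folds = n_folds,
                        seed = child_seed(seed, 200L + i),
                        num_trees = num_trees)
    compat <- task_compatibility(v, X, labels, validation, baseline_auc,
                                 spec = spec)
    dist <- sqrt(mean(c((audit$accuracy - 1 / 3)^2,
                        (audit$balanced_accuracy - 1 / 3)^2,
                        (audit$macro_f1 - 1 / 3)^2,
                        (audit$macro_auc_ovr - 0.5)^2)))
    rows[[i]] <- data.frame(
      name = v$name, size = sizes[i],
      accuracy = audit$accuracy, balanced_accuracy = audit$balanced_accuracy,
      macro_f1 = audit$macro_f1, macro_auc_ovr = audit$macro_auc_ovr,
      gate_passed = audit$gate_passed, task_auc = compat$auc,
      compatible = compat$compatible, chance_distance = dist,
      stringsAsFactors = FALSE)
    if (audit$gate_passed && compat$compatible) {
      attr(v, "audit") <- audit
      attr(v, "task_auc") <- compat$auc
      attr(v, "chance_distance") <- dist
      survivors[[v$name]] <- v
    }
  }
  candidates <- do.call(rbind, rows)
  if (length(survivors) > 0L) {
    key <- candidates[candidates$name %in% names(survivors), ]
    ord <- order(key$chance_distance, key$macro_auc_ovr, key$accuracy, key$name)
    survivors <- survivors[key$name[ord]]
  } else {
    warning("no candidate view passed both gates (NoSurvivors)")
  }
  structure(list(survivors = survivors, candidates = candidates,
                 baseline_auc = baseline_auc),
            class = "view_search")
}
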
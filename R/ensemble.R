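# Per-view base classifiers and equal-weight late fusion.
#
# Diversity in the ensemble comes solely from the feature view: every member
# is the same base learner trained on a different named bit subset, and
# members are combined by an unweighted mean of probability-like scores.
# Feature concatenation across views is structurally impossible: training
# consumes exactly one view.

.learner_registry <- new.env(parent = emptyenv())

#' Register a base learner family
#'
#' @param family Family name.
#' @param fit Function `(X, y, params, seed, case_weights) -> fitted object`.
#' @param predict_fun Function `(fit, X) -> numeric scores in [0, 1]`.
#' @param scale_sensitive Whether min-max scaling (fitted on training rows
#'   only) must be applied before fitting/scoring.
#' @param default_params Named list of default hyperparameters.
#' @export
register_learner <- function(family, fit, predict_fun, scale_sensitive = FALSE,
                             default_params = list()) {
  assign(family, list(fit = fit, predict = predict_fun,
                      scale_sensitive = scale_sensitive,
                      default_params = default_params),
         envir = .learner_registry)
  invisible(family)
}

#' Specify a base learner
#'
#' Supported families: `"gbdt"` (gradient-boosted decision trees; the
#' default), `"extra_trees"`, `"random_forest"`, `"bagging"` and `"knn"`,
#' plus anything added via [register_learner()]. Median imputation is
#' retained as a declared no-op safeguard on binary inputs; min-max scaling
#' is applied only to scale-sensitive families (k-NN).
#'
#' @param family Learner family name.
#' @param params Hyperparameter overrides merged over the family defaults.
#' @param seed Integer seed used at fit time.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(family = "gbdt", params = list(), seed = 1L) {
  if (!exists(family, envir = .learner_registry))
    ds_error("unknown_learner", sprintf("unknown learner family '%s'", family))
  entry <- get(family, envir = .learner_registry)
  merged <- utils::modifyList(entry$default_params, params)
  structure(list(family = family, params = merged, seed = as.integer(seed),
                 scale_sensitive = entry$scale_sensitive),
            class = "learner_spec")
}

# Median imputation, declared no-op on complete binary matrices.
impute_median <- function(X, medians = NULL) {
  if (is.null(medians))
    medians <- apply(X, 2L, stats::median, na.rm = TRUE)
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0L))
      X[is.na(X[, j]), j] <- medians[j]
  }
  list(X = X, medians = medians)
}

minmax_fit <- function(X) {
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  list(lo = lo, span = ifelse(hi > lo, hi - lo, 1))
}

minmax_apply <- function(X, sc) sweep(sweep(X, 2L, sc$lo), 2L, sc$span, "/")

# ---- built-in families -----------------------------------------------------

register_learner(
  "gbdt",
  fit = function(X, y, params, seed, case_weights) {
    dm <- xgboost::xgb.DMatrix(X, label = y,
                               weight = case_weights %||% rep(1, length(y)))
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", eval_metric = "logloss",
                    max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    nthread = 1L, seed = seed),
      data = dm, nrounds = params$nrounds, verbose = 0)
  },
  predict_fun = function(fit, X) predict(fit, xgboost::xgb.DMatrix(X)),
  default_params = list(max_depth = 6L, eta = 0.1, nrounds = 150L,
                        subsample = 0.9, colsample_bytree = 0.9)
)

ranger_fit <- function(X, y, seed, case_weights, num_trees, splitrule, mtry = NULL) {
  d <- data.frame(.y = factor(y, levels = c(0L, 1L)), X)
  args <- list(dependent.variable.name = ".y", data = d, probability = TRUE,
               num.trees = num_trees, seed = seed, num.threads = 1L,
               case.weights = case_weights)
  if (!is.null(mtry)) args$mtry <- mtry
  if (splitrule == "extratrees") {
    args$splitrule <- "extratrees"; args$num.random.splits <- 1L
  }
  do.call(ranger::ranger, args)
}

ranger_predict <- function(fit, X)
  predict(fit, data.frame(X), num.threads = 1L)$predictions[, "1"]

register_learner(
  "extra_trees",
  fit = function(X, y, params, seed, case_weights)
    ranger_fit(X, y, seed, case_weights, params$num_trees, "extratrees"),
  predict_fun = ranger_predict,
  default_params = list(num_trees = 300L)
)

register_learner(
  "random_forest",
  fit = function(X, y, params, seed, case_weights)
    ranger_fit(X, y, seed, case_weights, params$num_trees, "gini"),
  predict_fun = ranger_predict,
  default_params = list(num_trees = 300L)
)

register_learner(
  "bagging",
  fit = function(X, y, params, seed, case_weights)
    ranger_fit(X, y, seed, case_weights, params$num_trees, "gini",
               mtry = ncol(X)),
  predict_fun = ranger_predict,
  default_params = list(num_trees = 200L)
)

register_learner(
  "knn",
  fit = function(X, y, params, seed, case_weights)
    list(X = X, y = factor(y, levels = c(0L, 1L)), k = params$k),
  predict_fun = function(fit, X) {
    pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
    p <- attr(pr, "prob")
    ifelse(pr == "1", p, 1 - p)
  },
  scale_sensitive = TRUE,
  default_params = list(k = 15L)
)

#' Train a base classifier on one feature view
#'
#' Subsets the training matrix to the view's columns (the only way features
#' reach a learner), applies median imputation and -- for scale-sensitive
#' families -- min-max scaling fitted on the training rows, then fits the
#' specified learner. Deterministic given the spec's seed.
#'
#' @param view A [feature_view()].
#' @param X Training feature matrix or `fp_matrix` (full width; the view
#'   selects columns).
#' @param labels Binary labels.
#' @param spec A [learner_spec()].
#' @param case_weights Optional per-row weights (e.g. class weights).
#' @return An object of class `view_model`; score new data with `predict()`.
#' @export
train_view_model <- function(view, X, labels, spec = learner_spec("gbdt"),
                             case_weights = NULL) {
  stopifnot(inherits(view, "feature_view"), inherits(spec, "learner_spec"))
  if (inherits(X, "fp_matrix")) X <- X$matrix
  labels <- as.integer(labels)
  Xv <- X[, view$bit_indices + 1L, drop = FALSE]
  imp <- impute_median(Xv)
  scaler <- NULL
  Xt <- imp$X
  if (spec$scale_sensitive) {
    scaler <- minmax_fit(Xt)
    Xt <- minmax_apply(Xt, scaler)
  }
  entry <- get(spec$family, envir = .learner_registry)
  fit <- entry$fit(Xt, labels, spec$params, spec$seed, case_weights)
  structure(list(view = view, spec = spec, fit = fit,
                 medians = imp$medians, scaler = scaler),
            class = "view_model")
}

#' @export
predict.view_model <- function(object, newdata, ...) {
  if (inherits(newdata, "fp_matrix")) newdata <- newdata$matrix
  Xv <- newdata[, object$view$bit_indices + 1L, drop = FALSE]
  Xv <- impute_median(Xv, object$medians)$X
  if (!is.null(object$scaler)) Xv <- minmax_apply(Xv, object$scaler)
  entry <- get(object$spec$family, envir = .learner_registry)
  as.numeric(entry$predict(object$fit, Xv))
}

#' Equal-weight late-fusion ensemble
#'
#' Bundles fitted [train_view_model()] members; each carries weight
#' `1/|members|` by construction (no meta-parameters).
#'
#' @param members List of `view_model` objects.
#' @return An object of class `fusion_model`.
#' @export
fusion_model <- function(members) {
  if (length(members) == 0L)
    ds_error("empty_ensemble", "a fusion model needs >= 1 member")
  stopifnot(all(vapply(members, inherits, TRUE, "view_model")))
  structure(list(members = members,
                 weights = rep(1 / length(members), length(members))),
            class = "fusion_model")
}

#' Fuse member scores
#'
#' Arithmetic mean of the members' probability-like scores per row; bounded
#' by the member score range row-wise.
#'
#' @param model A [fusion_model()].
#' @param X New data (matrix or `fp_matrix`, full width).
#' @return Numeric score vector in \[0, 1\].
#' @export
fuse_scores <- function(model, X) {
  stopifnot(inherits(model, "fusion_model"))
  scores <- vapply(model$members, predict, numeric(NROW(if (inherits(X, "fp_matrix")) X$matrix else X)), X)
  rowMeans(as.matrix(scores))
}

#' Search view combinations by cross-validated AUC and EF@1%
#'
#' Evaluates each candidate view singly and a seeded random sample of
#' combinations (sizes 2 to `max_members`, uniform without replacement)
#' under label-stratified k-fold cross-validation. Per fold, each member is
#' trained separately on its own view and the fold scores are fused by
#' equal-weight averaging -- views are never concatenated. Output is ranked
#' by mean ROC AUC descending, ties broken by name.
#'
#' @param candidate_views Named list of [feature_view()] objects.
#' @param X Training matrix or `fp_matrix`.
#' @param labels Binary labels.
#' @param max_members Largest combination size (default 5).
#' @param n_combos Random combinations to sample (default 20).
#' @param n_folds Folds (default 5).
#' @param seed Integer seed.
#' @param spec Base learner ([learner_spec()]), identical for every member.
#' @return Data.frame with `combination`, `n_members`, `mean_roc_auc`,
#'   `mean_ef_1pct`, sorted by `mean_roc_auc` descending.
#' @export
ensemble_search <- function(candidate_views, X, labels, max_members = 5L,
                            n_combos = 20L, n_folds = 5L, seed = 1L,
                            spec = learner_spec("gbdt")) {
  if (length(candidate_views) == 0L)
    ds_error("empty_ensemble", "no candidate views")
  if (inherits(X, "fp_matrix")) X <- X$matrix
  labels <- as.integer(labels)
  nv <- length(candidate_views)
  combos <- lapply(seq_len(nv), function(i) i)
  if (nv >= 2L) {
    extra <- with_seed(child_seed(seed, 7L), {
      sizes <- sample(2:min(max_members, nv), n_combos, replace = TRUE)
      lapply(sizes, function(s) sort(sample.int(nv, s)))
    })
    combos <- c(combos, unique(extra))
  }
  fold <- stratified_folds(labels, n_folds, child_seed(seed, 11L))
  # per-view out-of-fold scores, computed once and fused per combination
  oof <- matrix(NA_real_, length(labels), nv)
  for (v in seq_len(nv)) {
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      m <- train_view_model(candidate_views[[v]], X[tr, , drop = FALSE],
                            labels[tr], spec)
      oof[!tr, v] <- predict(m, X[!tr, , drop = FALSE])
    }
  }
  rows <- lapply(combos, function(idx) {
    name <- paste(names(candidate_views)[idx], collapse = "+")
    aucs <- efs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      te <- fold == f
      fused <- rowMeans(oof[te, idx, drop = FALSE])
      aucs[f] <- roc_auc(fused, labels[te])
      efs[f] <- enrichment_factor(ranked_screen(fused, labels[te]), 0.01)
    }
    data.frame(combination = name, n_members = length(idx),
               mean_roc_auc = mean(aucs), mean_ef_1pct = mean(efs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_roc_auc, out$combination), , drop = FALSE]
}
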
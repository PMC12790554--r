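# Training-only decoy guardrails: similarity bounds, source-predictability
# pruning, and cluster source-entropy filtering. All three stages operate on
# training-partition negatives exclusively; the frozen test side never enters
# (enforced via `frozen_ids` / the leakage guard).

# Out-of-fold multi-class source probabilities from an extremely-randomized
# trees classifier trained on negatives only.
oof_source_probs <- function(X, sources, n_folds, seed, num_trees = 300L) {
  sources <- factor(sources)
  fold <- stratified_folds(sources, n_folds, seed)
  probs <- matrix(NA_real_, nrow(X), nlevels(sources),
                  dimnames = list(rownames(X), levels(sources)))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    d <- data.frame(.src = sources[tr], X[tr, , drop = FALSE])
    m <- ranger::ranger(
      dependent.variable.name = ".src", data = d, probability = TRUE,
      num.trees = num_trees, splitrule = "extratrees", num.random.splits = 1L,
      seed = child_seed(seed, f), num.threads = 1L, respect.unordered.factors = TRUE)
    pr <- predict(m, data.frame(X[!tr, , drop = FALSE]),
                  num.threads = 1L)$predictions
    probs[!tr, colnames(pr)] <- pr
  }
  probs
}

#' Similarity guardrail on training negatives
#'
#' Removes negatives whose maximum Tanimoto similarity to the positive pool
#' exceeds `hi` (near-duplicates of positives: likely mislabelled) or falls
#' below `lo` (trivially dissimilar outliers that inflate apparent early
#' enrichment). Idempotent. Bounds may instead be derived from the empirical
#' distribution of the training positives' own maximum similarity via
#' `quantiles`.
#'
#' @param negatives,positives `fp_matrix` objects (training partition only).
#' @param lo,hi Similarity bounds (defaults 0.30 / 0.90).
#' @param quantiles Optional length-2 probabilities; when given, `lo`/`hi`
#'   are replaced by these empirical quantiles of a maximum-similarity
#'   distribution instead of the fixed defaults.
#' @param quantiles_of Which distribution the quantile bounds refer to:
#'   `"positives"` (leave-one-out maximum similarity of training positives
#'   to their own pool) or `"negatives"` (the negatives' maximum similarity
#'   to the positive pool, i.e. the quantity being trimmed).
#' @param frozen_ids Optional frozen test ids; any overlap raises
#'   `test_leakage`.
#' @return A list (guardrail fragment): `kept`, `removed_too_similar`,
#'   `removed_too_dissimilar`, `max_sim`, `bounds`.
#' @export
similarity_guardrail <- function(negatives, positives, lo = 0.30, hi = 0.90,
                                 quantiles = NULL,
                                 quantiles_of = c("positives", "negatives"),
                                 frozen_ids = NULL) {
  stopifnot(inherits(negatives, "fp_matrix"), inherits(positives, "fp_matrix"))
  quantiles_of <- match.arg(quantiles_of)
  assert_not_frozen(negatives$ids, frozen_ids, "similarity_guardrail")
  guard_touch(negatives$ids, "similarity_guardrail")
  if (!is.null(quantiles)) {
    stopifnot(length(quantiles) == 2L)
    ref <- if (quantiles_of == "positives") {
      sims_pp <- tanimoto_to_pool_matrix(positives$matrix, positives$matrix)
      diag(sims_pp) <- -Inf  # leave-one-out
      apply(sims_pp, 1L, max)
    } else {
      unname(max_tanimoto_per_row(negatives, positives))
    }
    b <- stats::quantile(ref, probs = sort(quantiles), names = FALSE)
    lo <- b[1L]; hi <- b[2L]
  }
  if (!(lo <= hi)) ds_error("bad_config", "need lo <= hi")
  ms <- max_tanimoto_per_row(negatives, positives)
  list(
    kept = names(ms)[ms >= lo & ms <= hi],
    removed_too_similar = names(ms)[ms > hi],
    removed_too_dissimilar = names(ms)[ms < lo],
    max_sim = ms,
    bounds = c(lo = unname(lo), hi = unname(hi))
  )
}

#' Source-predictability pruning
#'
#' Trains a multi-class origin classifier (extremely-randomized trees) on
#' the negatives only and removes candidates whose maximum out-of-fold
#' predicted source probability exceeds `p_cut`: negatives whose decoy
#' recipe is easy to infer carry recipe artifacts. The full out-of-fold
#' probability table is returned so any cut is auditable.
#'
#' @param negatives `fp_matrix` of training negatives.
#' @param sources Source tag per negative (named or aligned to rows).
#' @param p_cut Maximum allowed out-of-fold source probability (default 0.60).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param frozen_ids Optional frozen test ids.
#' @return Fragment list: `kept`, `removed_source_predictable`,
#'   `oof_max_prob`, `oof_probs`.
#' @export
source_predictability_prune <- function(negatives, sources, p_cut = 0.60,
                                        n_folds = 5L, seed = 1L,
                                        frozen_ids = NULL) {
  stopifnot(inherits(negatives, "fp_matrix"))
  assert_not_frozen(negatives$ids, frozen_ids, "source_predictability_prune")
  guard_touch(negatives$ids, "source_predictability_prune")
  sources <- align_tags(sources, negatives$ids)
  if (length(unique(sources)) < 2L)
    ds_error("single_source", "source pruning is undefined with one source")
  probs <- oof_source_probs(negatives$matrix, sources, n_folds, seed)
  mx <- apply(probs, 1L, max)
  list(
    kept = negatives$ids[mx <= p_cut],
    removed_source_predictable = negatives$ids[mx > p_cut],
    oof_max_prob = stats::setNames(mx, negatives$ids),
    oof_probs = probs
  )
}

align_tags <- function(tags, ids) {
  if (!is.null(names(tags))) {
    missing <- setdiff(ids, names(tags))
    if (length(missing) > 0L)
      ds_error("bad_config", sprintf("no tag for id %s", missing[1L]))
    tags <- tags[ids]
  } else if (length(tags) != length(ids)) {
    ds_error("length_mismatch", "tags must be named or aligned to rows")
  }
  as.character(tags)
}

#' Cluster source-entropy filter
#'
#' Embeds the negative bit vectors by principal components, clusters with
#' k-means, and removes whole clusters that are either dominated by a single
#' decoy recipe (normalized source entropy below `entropy_min`; base =
#' number of sources) or sit far from the positives (cluster mean of the
#' members' maximum Tanimoto to the positive pool below `mean_sim_min`).
#'
#' @param negatives,positives `fp_matrix` objects.
#' @param sources Source tag per negative.
#' @param n_components PCA components for the embedding (default 32).
#' @param k Number of k-means clusters (default 20).
#' @param entropy_min Minimum normalized source entropy per cluster (0.5).
#' @param mean_sim_min Minimum cluster mean similarity to positives (0.30).
#' @param seed Integer seed (k-means initialization).
#' @param frozen_ids Optional frozen test ids.
#' @return Fragment list: `kept`, `removed_cluster` (data.frame id, cluster,
#'   reason), `cluster_diagnostics`.
#' @export
cluster_entropy_filter <- function(negatives, positives, sources,
                                   n_components = 32L, k = 20L,
                                   entropy_min = 0.5, mean_sim_min = 0.30,
                                   seed = 1L, frozen_ids = NULL) {
  stopifnot(inherits(negatives, "fp_matrix"), inherits(positives, "fp_matrix"))
  assert_not_frozen(negatives$ids, frozen_ids, "cluster_entropy_filter")
  guard_touch(negatives$ids, "cluster_entropy_filter")
  n <- nrow(negatives$matrix)
  if (n < k) ds_error("too_few_points", sprintf("%d negatives < k = %d", n, k))
  sources <- align_tags(sources, negatives$ids)
  n_src <- length(unique(sources))
  n_components <- min(n_components, n - 1L, ncol(negatives$matrix))
  emb <- stats::prcomp(negatives$matrix, rank. = n_components,
                       center = TRUE, scale. = FALSE)$x
  cl <- with_seed(seed, stats::kmeans(emb, centers = k, nstart = 5L,
                                      iter.max = 100L))$cluster
  ms <- max_tanimoto_per_row(negatives, positives)
  diag_rows <- lapply(sort(unique(cl)), function(g) {
    members <- negatives$ids[cl == g]
    ent <- normalized_entropy(table(sources[cl == g]), n_src)
    msim <- mean(ms[members])
    reason <- if (ent < entropy_min) "low_entropy"
      else if (msim < mean_sim_min) "low_mean_similarity" else NA_character_
    data.frame(cluster = g, size = length(members), entropy = ent,
               mean_sim = msim, reason = reason, stringsAsFactors = FALSE)
  })
  diags <- do.call(rbind, diag_rows)
  removed <- do.call(rbind, lapply(which(!is.na(diags$reason)), function(i) {
    g <- diags$cluster[i]
    data.frame(id = negatives$ids[cl == g], cluster = g,
               reason = diags$reason[i], stringsAsFactors = FALSE)
  }))
  if (is.null(removed))
    removed <- data.frame(id = character(), cluster = integer(),
                          reason = character(), stringsAsFactors = FALSE)
  list(kept = setdiff(negatives$ids, removed$id),
       removed_cluster = removed,
       cluster_diagnostics = diags)
}

#' Apply all three decoy guardrails
#'
#' Fixed stage order: similarity bounds, then source-predictability pruning,
#' then cluster entropy filtering; each stage consumes the previous stage's
#' survivors, and the first triggering stage claims each removed id, so the
#' removal sets are disjoint and together with `kept` partition the input.
#'
#' @inheritParams similarity_guardrail
#' @inheritParams source_predictability_prune
#' @inheritParams cluster_entropy_filter
#' @param cluster_k Clusters for the entropy filter; the stage is skipped
#'   (with a note in the report) if fewer survivors than `cluster_k` remain.
#' @return An object of class `guardrail_report` with `kept`,
#'   `removed_too_similar`, `removed_too_dissimilar`,
#'   `removed_source_predictable`, `removed_cluster` and stage diagnostics.
#' @export
harden_decoys <- function(negatives, positives, sources,
                          lo = 0.30, hi = 0.90, quantiles = NULL,
                          quantiles_of = "positives",
                          p_cut = 0.60, n_folds = 5L,
                          n_components = 32L, cluster_k = 20L,
                          entropy_min = 0.5, mean_sim_min = NULL,
                          seed = 1L, frozen_ids = NULL) {
  sources <- align_tags(sources, negatives$ids)
  names(sources) <- negatives$ids
  s1 <- similarity_guardrail(negatives, positives, lo = lo, hi = hi,
                             quantiles = quantiles, quantiles_of = quantiles_of,
                             frozen_ids = frozen_ids)
  surv1 <- fp_subset(negatives, s1$kept)
  s2 <- source_predictability_prune(surv1, sources[s1$kept], p_cut = p_cut,
                                    n_folds = n_folds,
                                    seed = child_seed(seed, 2L),
                                    frozen_ids = frozen_ids)
  surv2 <- fp_subset(negatives, s2$kept)
  # per design, the cluster filter's similarity floor reuses the guardrail
  # lower bound (which may have been derived from quantiles)
  mean_sim_min <- mean_sim_min %||% unname(s1$bounds["lo"])
  if (length(s2$kept) >= cluster_k) {
    s3 <- cluster_entropy_filter(surv2, positives, sources[s2$kept],
                                 n_components = n_components, k = cluster_k,
                                 entropy_min = entropy_min,
                                 mean_sim_min = mean_sim_min,
                                 seed = child_seed(seed, 3L),
                                 frozen_ids = frozen_ids)
  } else {
    s3 <- list(kept = s2$kept,
               removed_cluster = data.frame(id = character(),
                                            cluster = integer(),
                                            reason = character()),
               cluster_diagnostics = NULL)
  }
  structure(list(
    kept = s3$kept,
    removed_too_similar = s1$removed_too_similar,
    removed_too_dissimilar = s1$removed_too_dissimilar,
    removed_source_predictable = s2$removed_source_predictable,
    removed_cluster = s3$removed_cluster,
    bounds = s1$bounds,
    max_sim = s1$max_sim,
    oof_max_prob = s2$oof_max_prob,
    cluster_diagnostics = s3$cluster_diagnostics,
    input_ids = negatives$ids
  ), class = "guardrail_report")
}

#' @export
print.guardrail_report <- function(x, ...) {
  cat(sprintf(
    "Guardrail report: %d in -> %d kept (%d too-similar, %d too-dissimilar, %d source-predictable, %d cluster-filtered)\n",
    length(x$input_ids), length(x$kept),
    length(x$removed_too_similar), length(x$removed_too_dissimilar),
    length(x$removed_source_predictable), nrow(x$removed_cluster)))
  invisible(x)
}
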
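# End-to-end orchestration on synthetic data: simulate -> split -> harden ->
# rebalance -> view search -> cross-decoy -> late-fusion training ->
# evaluation. Curation is skipped for synthetic fingerprints (there are no
# structures to standardize); with real SMILES input the chem_curation stage
# runs first and feeds fingerprint_matrix().

#' Run the full screening pipeline on a synthetic dataset
#'
#' Generates a planted-signal dataset, freezes the early 1:6 source-balanced
#' split, hardens the training decoys with all three guardrails, rebalances
#' the training mixture, searches random feature views under the leakage and
#' compatibility gates, optionally filters them by cross-decoy transfer,
#' trains the equal-weight late-fusion ensemble over the top views, and
#' evaluates under the five-fold + frozen-test protocol.
#'
#' @param n_positives Synthetic positives (default 100).
#' @param pool_per_source Simulated decoys per source per positive (default
#'   4): the decoy pools carry slack over the 2-per-source split design so
#'   the guardrails can discard candidates and the training mixture can
#'   still be rebalanced to the exact 1:6 counts, as with real pools.
#' @param seed Integer seed driving every stage.
#' @param n_candidates Views to evaluate in the random search (default 30).
#' @param max_views Fusion members taken from the ranked survivors (2).
#' @param run_cross_decoy Also compute 3x3 transfer matrices for the chosen
#'   views (default TRUE).
#' @param sim_overrides Named list of [simulation_config()] overrides.
#' @param spec Base learner.
#' @return List of class `pipeline_result`: the dataset, split, guardrail
#'   report, view search, chosen views, cross-decoy cells, protocol result
#'   and the fused hold-out / test AUC summary.
#' @export
run_screening_pipeline <- function(n_positives = 100L, pool_per_source = 4L,
                                   seed = 1L,
                                   n_candidates = 30L, max_views = 2L,
                                   run_cross_decoy = TRUE,
                                   sim_overrides = list(),
                                   spec = learner_spec("gbdt")) {
  cfg <- do.call(simulation_config,
                 utils::modifyList(list(n_positives = as.integer(n_positives),
                                        per_source = as.integer(pool_per_source),
                                        seed = child_seed(seed, 1L)),
                                   sim_overrides))
  data <- simulate_dataset(cfg)
  split <- early_split(data$positive_ids, data$decoy_pools, per_source = 2L,
                       seed = child_seed(seed, 2L))
  frozen <- split_test_ids(split)

  # guardrails run on the whole train-side pool (everything outside the
  # frozen test draw), so the rebalanced design can be filled from survivors
  train_neg_ids <- unlist(lapply(names(data$decoy_pools), function(s)
    setdiff(data$decoy_pools[[s]], split$test_negative_ids[[s]])),
    use.names = FALSE)
  pos_fp <- fp_subset(data$fp, split$train_positive_ids)
  neg_fp <- fp_subset(data$fp, train_neg_ids)
  # synthetic fingerprints live on their own Tanimoto scale, so the
  # similarity bounds are derived empirically (trim both tails of the
  # negatives' max-similarity distribution) rather than taken as the fixed
  # real-chemistry defaults; the cluster filter reuses the derived floor
  guard <- harden_decoys(neg_fp, pos_fp, data$sources[train_neg_ids],
                         quantiles = c(0.02, 0.98),
                         quantiles_of = "negatives",
                         seed = child_seed(seed, 3L), frozen_ids = frozen)
  hardened_pools <- split(guard$kept, data$sources[guard$kept])
  balanced <- balance_training(split$train_positive_ids, hardened_pools,
                               per_source = split$per_source,
                               seed = child_seed(seed, 4L),
                               frozen_ids = frozen)

  Xtr <- fp_subset(data$fp, balanced$id)
  bal_neg <- balanced$id[balanced$label == 0L]
  search <- random_view_search(
    fp_subset(data$fp, bal_neg), data$sources[bal_neg],
    Xtr, data$labels[balanced$id],
    n_candidates = n_candidates, seed = child_seed(seed, 5L), spec = spec)

  chosen <- utils::head(search$survivors, max_views)
  cross <- NULL
  if (run_cross_decoy && length(chosen) > 0L) {
    cross <- do.call(rbind, lapply(chosen, function(v)
      cross_decoy_matrix(v, split, data$fp, data$labels,
                         seed = child_seed(seed, 6L))))
    keep <- select_transferable_views(cross)
    if (length(keep) > 0L) chosen <- chosen[keep]
  }
  if (length(chosen) == 0L)
    ds_error("bad_config", "no gate-passing views; cannot train the ensemble")

  protocol <- five_fold_protocol(data$fp, data$labels, balanced$id, frozen,
                                 chosen, spec = spec,
                                 seed = child_seed(seed, 8L))
  summ <- summary(protocol)
  structure(list(
    data = data, split = split, guardrails = guard, balanced = balanced,
    view_search = search, views = chosen, cross_decoy = cross,
    protocol = protocol, metrics = summ,
    fused_holdout_auc = summ$holdout_mean[summ$metric == "roc_auc"],
    fused_test_auc = summ$test_mean[summ$metric == "roc_auc"]
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "Pipeline: %d gate-passing view(s); fused hold-out AUC %.3f, frozen-test AUC %.3f\n",
    length(x$views), x$fused_holdout_auc, x$fused_test_auc))
  invisible(x)
}
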
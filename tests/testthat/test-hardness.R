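# Decoy guardrails: similarity bounds, source-predictability pruning,
# cluster entropy filtering, and their composite.

fp_from <- function(m, prefix = "n") {
  rownames(m) <- sprintf("%s%03d", prefix, seq_len(nrow(m)))
  decoyscreen:::new_fp_matrix(m, "test")
}

test_that("similarity bounds remove exactly the out-of-window negatives", {
  nb <- 40
  pos <- fp_from(rbind(c(rep(1, 10), rep(0, nb - 10))), "p")
  negs <- rbind(
    c(rep(1, 10), rep(0, nb - 10)),        # identical to the positive: sim 1.0
    c(rep(0, 10), rep(1, 10), rep(0, 20)), # disjoint: sim 0.0
    c(rep(1, 6), rep(0, 4), rep(1, 2), rep(0, 28)) # 6/12 = 0.5, engineered
  )
  r <- similarity_guardrail(fp_from(negs), pos)
  expect_equal(r$removed_too_similar, "n001")
  expect_equal(r$removed_too_dissimilar, "n002")
  expect_equal(r$kept, "n003")
  expect_equal(unname(r$max_sim["n003"]), 0.5)
  # idempotence: survivors all inside the window
  r2 <- similarity_guardrail(decoyscreen:::fp_subset(fp_from(negs), r$kept), pos)
  expect_equal(r2$kept, r$kept)
  expect_length(r2$removed_too_similar, 0)
})

test_that("similarity guardrail refuses frozen test ids", {
  pos <- fp_from(matrix(rbinom(2 * 32, 1, .4), 2), "p")
  neg <- fp_from(matrix(rbinom(5 * 32, 1, .4), 5), "n")
  expect_error(similarity_guardrail(neg, pos, frozen_ids = c("n003", "x")),
               class = "test_leakage")
})

test_that("quantile-derived bounds follow the requested reference distribution", {
  set.seed(8)
  pos <- fp_from(matrix(rbinom(30 * 256, 1, .3), 30), "p")
  neg <- fp_from(matrix(rbinom(200 * 256, 1, .3), 200), "n")
  r <- similarity_guardrail(neg, pos, quantiles = c(0.05, 0.95),
                            quantiles_of = "negatives")
  ms <- r$max_sim
  expect_equal(unname(r$bounds["lo"]), unname(quantile(ms, 0.05)))
  expect_equal(unname(r$bounds["hi"]), unname(quantile(ms, 0.95)))
  expect_lte(length(r$removed_too_similar), ceiling(0.06 * 200))
})

test_that("source pruning removes artifact-carrying sources preferentially", {
  # one source carries a strong artifact block; its members should dominate
  # the removals, while p_cut = 1 removes nothing
  d <- simulate_dataset(simulation_config(
    n_positives = 60, per_source = 3, n_bits = 256, n_signal_bits = 0,
    n_artifact_bits = 0, seed = 31))
  ids <- names(d$labels)[d$labels == 0]
  m <- d$fp$matrix[ids, ]
  marked <- d$sources[ids] == "dude"
  m[marked, 1:12] <- 1L  # planted always-on artifact block for one source
  neg <- decoyscreen:::new_fp_matrix(m, "test")
  r <- source_predictability_prune(neg, d$sources[ids], p_cut = 0.6, seed = 5)
  removed_src <- d$sources[r$removed_source_predictable]
  expect_gt(length(r$removed_source_predictable), 0)
  # per-source removal rate is the oracle: the artifact source is pruned at
  # a far higher rate than either clean source and supplies most removals
  rate <- table(removed_src)[unique(d$sources[ids])] /
    table(d$sources[ids])[unique(d$sources[ids])]
  rate[is.na(rate)] <- 0
  expect_gt(rate["dude"], 3 * max(rate[names(rate) != "dude"], 0.01))
  expect_gt(mean(removed_src == "dude"), 0.5)
  r_all <- source_predictability_prune(neg, d$sources[ids], p_cut = 1.0, seed = 5)
  expect_length(r_all$removed_source_predictable, 0)
  expect_error(source_predictability_prune(neg, rep("dude", nrow(m)), seed = 1),
               class = "single_source")
})

test_that("artifact-free pools see near-chance origin probabilities", {
  d <- simulate_dataset(simulation_config(
    n_positives = 80, per_source = 3, n_bits = 256, n_signal_bits = 0,
    n_artifact_bits = 0, seed = 32))
  ids <- names(d$labels)[d$labels == 0]
  neg <- decoyscreen:::fp_subset(d$fp, ids)
  r <- source_predictability_prune(neg, d$sources[ids], p_cut = 0.6, seed = 6)
  # out-of-fold max probabilities concentrate near 1/3; removals are a tail
  expect_lt(mean(r$oof_max_prob), 0.55)
  expect_lt(length(r$removed_source_predictable), 0.1 * length(ids))
})

test_that("cluster filter removes single-source and orphan clusters wholesale", {
  set.seed(41)
  nb <- 64
  pos <- fp_from(matrix(rbinom(20 * nb, 1, 0.4), 20), "p")
  # background negatives resembling positives, mixed sources
  bg <- matrix(rbinom(90 * nb, 1, 0.4), 90)
  # a tight single-source clump far from everything (low entropy)
  clump <- matrix(rep(c(rep(1, 16), rep(0, nb - 16)), 15), 15, byrow = TRUE)
  # an orphan clump with zero similarity to the positives: plant on bits the
  # positives never carry
  pos_mat <- pos$matrix
  pos_mat[, 61:64] <- 0L
  pos2 <- fp_from(pos_mat, "p")
  orphan <- matrix(0L, 12, nb); orphan[, 61:64] <- 1L
  m <- rbind(bg, clump, orphan)
  src <- c(rep(c("a", "b", "c"), 30), rep("a", 15), rep(c("a", "b", "c"), 4))
  neg <- fp_from(m)
  names(src) <- neg$ids
  r <- cluster_entropy_filter(neg, pos2, src, n_components = 16, k = 8,
                              entropy_min = 0.5, mean_sim_min = 0.05, seed = 2)
  clump_ids <- neg$ids[91:105]
  orphan_ids <- neg$ids[106:117]
  expect_true(all(clump_ids %in% r$removed_cluster$id))
  expect_true(all(r$removed_cluster$reason[r$removed_cluster$id %in% clump_ids]
                  == "low_entropy"))
  expect_true(all(orphan_ids %in% r$removed_cluster$id))
  expect_error(cluster_entropy_filter(fp_from(m[1:5, ]), pos2, src[1:5], k = 8),
               class = "too_few_points")
})

test_that("well-mixed clusters above the similarity floor all survive", {
  set.seed(43)
  nb <- 64
  pos <- fp_from(matrix(rbinom(20 * nb, 1, 0.4), 20), "p")
  neg <- fp_from(matrix(rbinom(120 * nb, 1, 0.4), 120))
  src <- rep(c("a", "b", "c"), 40)
  names(src) <- neg$ids
  r <- cluster_entropy_filter(neg, pos, src, n_components = 16, k = 5,
                              entropy_min = 0.5, mean_sim_min = 0.05, seed = 3)
  expect_equal(sort(r$kept), sort(neg$ids))
  expect_true(all(r$cluster_diagnostics$entropy > 0.5))
})

test_that("the composite partitions its input and is idempotent at the study conditions", {
  d <- shared_sim()
  neg <- neg_fp_of(d)
  pos <- pos_fp_of(d)
  rep1 <- harden_decoys(neg$fp, pos, neg$sources,
                        quantiles = c(0.02, 0.98), quantiles_of = "negatives",
                        cluster_k = 10, seed = 17)
  all_ids <- c(rep1$kept, rep1$removed_too_similar, rep1$removed_too_dissimilar,
               rep1$removed_source_predictable, rep1$removed_cluster$id)
  expect_setequal(all_ids, neg$ids)            # union = input
  expect_equal(anyDuplicated(all_ids), 0)      # removal sets disjoint
  # composite on its own output: similarity bounds now fixed to the first
  # run's derived values; nothing further is removed
  surv <- decoyscreen:::fp_subset(neg$fp, rep1$kept)
  rep2 <- harden_decoys(surv, pos, neg$sources[rep1$kept],
                        lo = rep1$bounds["lo"], hi = rep1$bounds["hi"],
                        cluster_k = 10, seed = 17)
  expect_setequal(rep2$kept, rep1$kept)
})

test_that("guardrails shrink the artifact-carrying fraction of the pool", {
  # directional property: negatives carrying a strong planted artifact are
  # depleted by the composite relative to the input
  d <- simulate_dataset(simulation_config(
    n_positives = 60, per_source = 3, n_bits = 256, n_signal_bits = 12,
    n_artifact_bits = 10, p_artifact_in = 0.55, seed = 33))
  ids <- names(d$labels)[d$labels == 0]
  neg <- decoyscreen:::fp_subset(d$fp, ids)
  pos <- pos_fp_of(d)
  art_cols <- d$artifact_bits$dude + 1L
  carries <- rowSums(d$fp$matrix[ids, art_cols]) >= 5
  rep <- harden_decoys(neg, pos, d$sources[ids],
                       quantiles = c(0.02, 0.98), quantiles_of = "negatives",
                       cluster_k = 10, seed = 19)
  frac_in <- mean(carries)
  frac_out <- mean(carries[ids %in% rep$kept])
  expect_lt(frac_out, frac_in)
})
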
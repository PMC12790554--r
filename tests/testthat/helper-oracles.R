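# Independent oracles (naive reference implementations) and shared fixtures.

# Brute-force ROC AUC: pairwise concordance with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1
      else if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct-sum BEDROC from the definition: explicit active ranks, naive loops,
# exact finite-(N, n) min/max normalization. Assumes untied scores.
oracle_bedroc <- function(scores, labels, alpha) {
  N <- length(scores)
  n <- sum(labels)
  ranks <- rank(-scores, ties.method = "first")
  s <- 0
  for (r in ranks[labels == 1]) s <- s + exp(-alpha * r / N)
  smax <- 0; for (r in seq_len(n)) smax <- smax + exp(-alpha * r / N)
  smin <- 0; for (r in (N - n + 1):N) smin <- smin + exp(-alpha * r / N)
  (s - smin) / (smax - smin)
}

# Hand EF: count actives among the top k = ceiling(f*N) (untied scores).
oracle_ef <- function(scores, labels, f) {
  N <- length(scores)
  k <- ceiling(f * N)
  top <- order(scores, decreasing = TRUE)[seq_len(k)]
  (sum(labels[top]) / k) / (sum(labels) / N)
}

# Small shared simulated dataset (cached per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(simulation_config(
        n_positives = 60, per_source = 3, n_bits = 512,
        n_signal_bits = 30, n_artifact_bits = 10, seed = 101))
    cache
  }
})

neg_fp_of <- function(d) {
  ids <- names(d$labels)[d$labels == 0]
  list(fp = decoyscreen:::fp_subset(d$fp, ids), ids = ids,
       sources = d$sources[ids])
}

pos_fp_of <- function(d)
  decoyscreen:::fp_subset(d$fp, names(d$labels)[d$labels == 1])
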
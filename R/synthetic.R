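# Synthetic fingerprint datasets with planted class signal and planted
# per-source artifact structure, plus curated toy SMILES sets for the
# chemistry filters. Bits are independent Bernoulli draws -- the simplest
# structure that exercises every pipeline stage; deliberately not a model of
# real fingerprint correlation.

#' Simulation configuration
#'
#' Defines a synthetic screening dataset: `n_positives` actives and
#' `per_source * n_sources` presumed-inactive decoys per active (the default
#' 2 x 3 reproduces the 1:6 class design). A disjoint set of signal bits
#' fires more often in positives (`p_signal_pos` vs `p_signal_neg`); each
#' decoy source additionally owns `n_artifact_bits` artifact bits that fire
#' at `p_artifact_in` within that source and at `p_artifact_out` elsewhere,
#' emulating decoy-recipe fingerprint cues. All remaining bits are background
#' noise at `p_background`.
#'
#' @param n_positives Number of actives (default 610, the curated-corpus
#'   scale the split design assumes).
#' @param per_source Decoys per source per positive (default 2).
#' @param n_sources Number of decoy sources (default 3).
#' @param n_bits Fingerprint length (default 2048).
#' @param n_signal_bits Planted class-signal bits (default 60).
#' @param p_signal_pos,p_signal_neg Signal bit on-probability in positives /
#'   negatives (defaults 0.45 / 0.10).
#' @param n_artifact_bits Artifact bits per source (default 20).
#' @param p_artifact_in,p_artifact_out Artifact on-probability inside /
#'   outside the owning source (defaults 0.22 / 0.10, calibrated so a
#'   full-fingerprint origin classifier reaches roughly 0.6 accuracy --
#'   clearly above three-class chance but far from separable -- while
#'   40--55-bit random views stay near chance).
#' @param p_background Background on-probability (default 0.10).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_positives = 610L, per_source = 2L,
                              n_sources = 3L, n_bits = 2048L,
                              n_signal_bits = 60L,
                              p_signal_pos = 0.45, p_signal_neg = 0.10,
                              n_artifact_bits = 20L,
                              p_artifact_in = 0.22, p_artifact_out = 0.10,
                              p_background = 0.10, seed = 1L) {
  cfg <- list(
    n_positives = as.integer(n_positives), per_source = as.integer(per_source),
    n_sources = as.integer(n_sources), n_bits = as.integer(n_bits),
    n_signal_bits = as.integer(n_signal_bits),
    p_signal_pos = p_signal_pos, p_signal_neg = p_signal_neg,
    n_artifact_bits = as.integer(n_artifact_bits),
    p_artifact_in = p_artifact_in, p_artifact_out = p_artifact_out,
    p_background = p_background, seed = as.integer(seed)
  )
  probs <- c(cfg$p_signal_pos, cfg$p_signal_neg, cfg$p_artifact_in,
             cfg$p_artifact_out, cfg$p_background)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    ds_error("bad_config", "all on-probabilities must lie in [0, 1]")
  if (cfg$n_signal_bits + cfg$n_sources * cfg$n_artifact_bits > cfg$n_bits)
    ds_error("bad_config", "signal + artifact bits exceed fingerprint length")
  if (cfg$n_positives < 1L || cfg$per_source < 1L || cfg$n_sources < 1L)
    ds_error("bad_config", "counts must be positive")
  structure(cfg, class = "simulation_config")
}

#' Simulate a labelled, source-tagged fingerprint dataset
#'
#' Draws independent Bernoulli bits per [simulation_config()]: signal bits
#' separate positives from negatives, artifact bits separate decoy sources
#' from each other, everything else is background. Signal, artifact and
#' background bit index sets are disjoint and reported, so tests can verify
#' that downstream guardrails find the planted structure.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `sim_dataset`: `fp` (an `fp_matrix`), `labels`
#'   and `sources` (named by id), `positive_ids`, `decoy_pools` (ids per
#'   source), `signal_bits`, `artifact_bits` (0-based indices) and `config`.
#' @examples
#' d <- simulate_dataset(simulation_config(n_positives = 20, n_bits = 128,
#'                                         n_signal_bits = 8, n_artifact_bits = 4))
#' table(d$labels, d$sources)
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_pos <- cfg$n_positives
  n_neg_per_source <- cfg$per_source * n_pos
  sources <- paste0("source_", seq_len(cfg$n_sources))
  if (cfg$n_sources == 3L) sources <- c("dude", "chembl_random", "chembl_high_conf")

  ids_pos <- sprintf("pos_%04d", seq_len(n_pos))
  ids_neg <- unlist(lapply(sources, function(s)
    sprintf("%s_%04d", s, seq_len(n_neg_per_source))))
  ids <- c(ids_pos, ids_neg)
  labels <- stats::setNames(c(rep(1L, n_pos), rep(0L, length(ids_neg))), ids)
  src <- stats::setNames(
    c(rep("prodrug", n_pos), rep(sources, each = n_neg_per_source)), ids)

  n <- length(ids)
  with_seed(cfg$seed, {
    special <- sample.int(cfg$n_bits,
                          cfg$n_signal_bits + cfg$n_sources * cfg$n_artifact_bits)
    signal_bits <- special[seq_len(cfg$n_signal_bits)]
    rest <- special[setdiff(seq_along(special), seq_len(cfg$n_signal_bits))]
    artifact_bits <- split(rest, rep(sources, each = cfg$n_artifact_bits))[sources]

    m <- matrix(stats::rbinom(n * cfg$n_bits, 1L, cfg$p_background),
                nrow = n, ncol = cfg$n_bits,
                dimnames = list(ids, fp_bit_names(cfg$n_bits)))
    if (cfg$n_signal_bits > 0L) {
      pos_rows <- which(labels == 1L)
      neg_rows <- which(labels == 0L)
      m[pos_rows, signal_bits] <- stats::rbinom(
        length(pos_rows) * cfg$n_signal_bits, 1L, cfg$p_signal_pos)
      m[neg_rows, signal_bits] <- stats::rbinom(
        length(neg_rows) * cfg$n_signal_bits, 1L, cfg$p_signal_neg)
    }
    if (cfg$n_artifact_bits > 0L) {
      for (s in sources) {
        bits <- artifact_bits[[s]]
        rows_in <- which(src == s)
        rows_out <- which(src != s)
        m[rows_in, bits] <- stats::rbinom(
          length(rows_in) * length(bits), 1L, cfg$p_artifact_in)
        m[rows_out, bits] <- stats::rbinom(
          length(rows_out) * length(bits), 1L, cfg$p_artifact_out)
      }
    }
  })

  structure(list(
    fp = new_fp_matrix(m, algorithm = "synthetic_bernoulli",
                       parameters = cfg[setdiff(names(cfg), "seed")]),
    labels = labels, sources = src,
    positive_ids = ids_pos,
    decoy_pools = stats::setNames(
      lapply(sources, function(s) ids_neg[src[ids_neg] == s]), sources),
    signal_bits = sort(signal_bits - 1L),
    artifact_bits = lapply(artifact_bits, function(b) sort(b - 1L)),
    config = cfg
  ), class = "sim_dataset")
}

#' Curated toy SMILES fixtures for the chemistry filters
#'
#' Small named sets exercising the strict-negative rule engine: promoiety
#' exemplars (ester, carbamate, phosphate, azo, nitro, ...), reactive
#' warhead exemplars (aldehyde, epoxide, Michael acceptor, ...), clean
#' drug-like passers, property-window violators, and an enantiomer pair that
#' shares a connectivity key but not a full InChIKey. Each molecule carries
#' the filter rules it is expected to fail under the default configuration
#' (`expected_rules`; empty means it should pass).
#'
#' @return A data.frame with columns `set`, `name`, `smiles`,
#'   `expected_rules` (comma-separated rule ids, `""` for passers).
#' @export
toy_smiles_fixtures <- function() {
  path <- system.file("extdata", "toy_smiles.tsv",
                      package = "decoyscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
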
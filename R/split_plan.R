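# The early, frozen, source-balanced train/test partition.
#
# The design draws exactly `per_source` negatives from each decoy source for
# every positive, in both partitions, giving a per-positive 1:(per_source *
# n_sources) class ratio (1:6 with the defaults) with per-source parity. The
# test side is carved out before any data-dependent step and marked frozen.

#' Create the early source-balanced split
#'
#' Samples `round(test_frac * n_P)` test positives (round-half-to-even; plain
#' random sampling, the only stratification dimension being the single
#' positive class), then draws `per_source * n` negatives per source without
#' replacement for each partition. Sampling is a seeded shuffle-then-take, so
#' the plan is reproducible from the seed alone. The test side is frozen.
#'
#' @param positives Character vector of positive record ids.
#' @param decoy_pools Named list (source -> character ids) of curated decoy
#'   pools.
#' @param test_frac Fraction of positives assigned to the test set (0.20).
#' @param per_source Negatives per source per positive (2).
#' @param seed Integer seed.
#' @return An object of class `split_plan` with `test_positive_ids`,
#'   `train_positive_ids`, per-source `test_negative_ids` and
#'   `train_negative_ids`, the seed and `frozen = TRUE`.
#' @examples
#' pools <- list(a = sprintf("a%03d", 1:60), b = sprintf("b%03d", 1:60),
#'               c = sprintf("c%03d", 1:60))
#' early_split(sprintf("p%02d", 1:10), pools, seed = 7)
#' @export
early_split <- function(positives, decoy_pools, test_frac = 0.20,
                        per_source = 2L, seed = 1L) {
  positives <- as.character(positives)
  n_p <- length(positives)
  if (n_p < 2L) ds_error("bad_config", "need at least 2 positives")
  if (!is.list(decoy_pools) || is.null(names(decoy_pools)))
    ds_error("bad_config", "decoy_pools must be a named list of id vectors")
  per_source <- as.integer(per_source)
  for (s in names(decoy_pools)) {
    if (length(decoy_pools[[s]]) < per_source * n_p)
      ds_error("insufficient_decoys", sprintf(
        "source '%s' holds %d decoys; the design needs %d (= %d per positive x %d positives)",
        s, length(decoy_pools[[s]]), per_source * n_p, per_source, n_p))
  }
  n_test <- as.integer(round(test_frac * n_p))
  plan <- with_seed(seed, {
    test_pos <- sample(positives, n_test)
    train_pos <- setdiff(positives, test_pos)
    test_neg <- list(); train_neg <- list()
    for (s in names(decoy_pools)) {
      pool <- sample(as.character(decoy_pools[[s]]))
      test_neg[[s]] <- pool[seq_len(per_source * n_test)]
      train_neg[[s]] <- pool[per_source * n_test + seq_len(per_source * (n_p - n_test))]
    }
    list(test_pos = test_pos, train_pos = train_pos,
         test_neg = test_neg, train_neg = train_neg)
  })
  structure(list(
    test_positive_ids = plan$test_pos,
    train_positive_ids = plan$train_pos,
    test_negative_ids = plan$test_neg,
    train_negative_ids = plan$train_neg,
    test_frac = test_frac, per_source = per_source,
    seed = as.integer(seed), frozen = TRUE
  ), class = "split_plan")
}

split_test_ids <- function(plan)
  c(plan$test_positive_ids, unlist(plan$test_negative_ids, use.names = FALSE))

split_train_ids <- function(plan)
  c(plan$train_positive_ids, unlist(plan$train_negative_ids, use.names = FALSE))

#' @export
print.split_plan <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "Split plan (seed %d, frozen test): %d/%d positives (train/test)\n",
    x$seed, s$train_positives, s$test_positives))
  cat(sprintf("  negatives per source: %d train / %d test (%d sources)\n",
              s$train_negatives_per_source, s$test_negatives_per_source,
              s$n_sources))
  cat(sprintf("  totals: %d training rows, %d test rows\n",
              s$training_rows, s$test_rows))
  invisible(x)
}

#' @export
summary.split_plan <- function(object, ...) {
  n_src <- length(object$test_negative_ids)
  list(
    test_positives = length(object$test_positive_ids),
    train_positives = length(object$train_positive_ids),
    test_negatives_per_source = length(object$test_negative_ids[[1L]]),
    train_negatives_per_source = length(object$train_negative_ids[[1L]]),
    test_negatives_total = sum(lengths(object$test_negative_ids)),
    train_negatives_total = sum(lengths(object$train_negative_ids)),
    n_sources = n_src,
    training_rows = length(object$train_positive_ids) +
      sum(lengths(object$train_negative_ids)),
    test_rows = length(object$test_positive_ids) +
      sum(lengths(object$test_negative_ids))
  )
}

#' Rebalance the training mixture after decoy hardening
#'
#' Draws `per_source * |train_positives|` negatives per source from the
#' hardened (guardrail-surviving) pools, without replacement, restoring the
#' exact per-positive design after filtering has thinned the pools.
#'
#' @param train_positives Character vector of training positive ids.
#' @param hardened_pools Named list (source -> surviving ids).
#' @param per_source Negatives per source per positive (2).
#' @param seed Integer seed.
#' @param frozen_ids Optional frozen test ids; any overlap raises an error.
#' @return A data.frame with columns `id`, `label`, `source`.
#' @export
balance_training <- function(train_positives, hardened_pools, per_source = 2L,
                             seed = 1L, frozen_ids = NULL) {
  train_positives <- as.character(train_positives)
  per_source <- as.integer(per_source)
  need <- per_source * length(train_positives)
  assert_not_frozen(unlist(hardened_pools), frozen_ids, "balance_training")
  rows <- data.frame(id = train_positives, label = 1L, source = "prodrug",
                     stringsAsFactors = FALSE)
  for (k in seq_along(hardened_pools)) {
    s <- names(hardened_pools)[k]
    pool <- as.character(hardened_pools[[s]])
    if (length(pool) < need)
      ds_error("insufficient_decoys", sprintf(
        "hardened pool '%s' holds %d decoys; design needs %d", s,
        length(pool), need))
    take <- with_seed(child_seed(seed, k), sample(pool)[seq_len(need)])
    rows <- rbind(rows, data.frame(id = take, label = 0L, source = s,
                                   stringsAsFactors = FALSE))
  }
  guard_touch(rows$id, "balance_training")
  rows
}

#' Serialize / restore a split plan
#'
#' The JSON manifest records all id sets, the seed and the design
#' parameters, so a frozen plan can be shared and re-verified.
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$test_negative_ids <- as.list(obj$test_negative_ids)
  obj$train_negative_ids <- as.list(obj$train_negative_ids)
  structure(obj, class = "split_plan")
}
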
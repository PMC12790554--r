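# Internal helpers: conditions, seeded RNG scope, id bookkeeping.

ds_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "decoyscreen_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `code`, and restores the caller's RNG state,
#' so seeded sampling inside the package never disturbs user-level streams.
#'
#' @param seed Integer seed (kept below 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct child seed from a base seed; stays < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1009 * k) %% 2147483647)
}

# Stratified k-fold assignment: returns integer fold id per row.
stratified_folds <- function(strata, n_folds, seed) {
  strata <- as.character(strata)
  fold <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Shannon entropy of a count/frequency vector, normalized to [0,1] by log(base_n).
normalized_entropy <- function(counts, base_n) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  if (length(p) <= 1L) return(0)
  h <- -sum(p * log(p))
  h / log(base_n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- frozen-test leakage firewall -------------------------------------------
# An optional instrumentation layer: when a guard is active, training-side
# stages report every id they consume; touching a frozen id raises TestLeakage.

.leakage_guard <- new.env(parent = emptyenv())
.leakage_guard$active <- FALSE
.leakage_guard$frozen <- character()
.leakage_guard$touched <- character()

#' Activate the frozen-test leakage firewall
#'
#' While active, every training-side stage in the package reports the ids it
#' consumes; an attempt to consume a frozen id raises a `test_leakage` error,
#' and [guard_report()] returns the full audit trail.
#'
#' @param frozen_ids Character vector of frozen (test-partition) ids.
#' @return Invisibly, `TRUE`.
#' @export
guard_activate <- function(frozen_ids) {
  .leakage_guard$active <- TRUE
  .leakage_guard$frozen <- as.character(frozen_ids)
  .leakage_guard$touched <- character()
  invisible(TRUE)
}

#' @rdname guard_activate
#' @export
guard_deactivate <- function() {
  .leakage_guard$active <- FALSE
  .leakage_guard$frozen <- character()
  invisible(TRUE)
}

#' @rdname guard_activate
#' @return For `guard_report()`, a list with `touched` and `frozen` id vectors.
#' @export
guard_report <- function() {
  list(touched = unique(.leakage_guard$touched), frozen = .leakage_guard$frozen)
}

# Called by training-side stages. `ids` are about to be consumed for fitting
# or preprocessing; frozen ids must never appear here.
guard_touch <- function(ids, stage = "train") {
  if (!.leakage_guard$active) return(invisible(NULL))
  ids <- as.character(ids)
  .leakage_guard$touched <- c(.leakage_guard$touched, ids)
  bad <- intersect(ids, .leakage_guard$frozen)
  if (length(bad) > 0L) {
    ds_error("test_leakage", sprintf(
      "stage '%s' attempted to consume %d frozen test id(s) (e.g. %s)",
      stage, length(bad), bad[1L]
    ))
  }
  invisible(NULL)
}

assert_not_frozen <- function(ids, frozen_ids, stage) {
  if (is.null(frozen_ids)) return(invisible(NULL))
  bad <- intersect(as.character(ids), as.character(frozen_ids))
  if (length(bad) > 0L) {
    ds_error("test_leakage", sprintf(
      "%s received %d id(s) from the frozen test partition (e.g. %s)",
      stage, length(bad), bad[1L]
    ))
  }
  invisible(NULL)
}
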
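# Early-recognition and global evaluation metrics.
#
# Ranking metrics (EF, BEDROC) treat tied scores by their exact expectation
# over all permutations of the tied block: a tied block occupying ranks a..b
# contributes each of its actives the mean weight of ranks a..b (BEDROC), and
# fills boundary-crossing top-k slots fractionally (EF). This is the analytic
# average over tie-shuffles, so a constant score vector yields EF = 1 exactly.
# ROC AUC uses midranks, the rank-statistic analogue of the same expectation.

#' Construct a ranked screen
#'
#' Bundles scores and binary labels of one scored evaluation set, recording
#' the totals an early-recognition metric needs: the library size `N`, the
#' active count `n` and the prevalence `n/N`. Ranking is by descending score;
#' ties are handled by each metric's documented expectation rule.
#'
#' @param scores Numeric vector of classifier scores (higher = more active).
#' @param labels Binary vector (0/1 or logical); 1 marks an active.
#' @return An object of class `ranked_screen`.
#' @examples
#' s <- ranked_screen(c(0.9, 0.2, 0.8), c(1, 0, 0))
#' enrichment_factor(s, 0.34)
#' @export
ranked_screen <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    ds_error("length_mismatch", "scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels))
    ds_error("bad_config", "scores/labels must not contain NA")
  if (!all(labels %in% c(0L, 1L)))
    ds_error("bad_config", "labels must be binary 0/1")
  structure(
    list(scores = scores, labels = labels,
         N = length(labels), n = sum(labels),
         prevalence = sum(labels) / length(labels)),
    class = "ranked_screen"
  )
}

# Tied-block summary of a screen: one row per unique score, descending.
# Columns: size (block length), actives (actives in block), from/to (rank span).
tie_blocks <- function(screen) {
  o <- order(screen$scores, decreasing = TRUE)
  s <- screen$scores[o]
  y <- screen$labels[o]
  grp <- cumsum(!duplicated(s))
  size <- tabulate(grp)
  actives <- as.vector(rowsum(y, grp, reorder = FALSE))
  to <- cumsum(size)
  data.frame(size = size, actives = actives, from = to - size + 1L, to = to)
}

#' Enrichment factor at a top fraction
#'
#' EF@f compares the active density in the top `ceil(f * N)` ranks with the
#' overall active density `n/N`; 1 is the random expectation. Ties crossing
#' the top-k boundary are allocated fractionally (expected value over tie
#' permutations), so an all-tied score vector gives exactly 1.
#'
#' @param screen A [ranked_screen()].
#' @param f Top fraction in (0, 1]; `k = ceiling(f * N)`.
#' @return The enrichment factor (non-negative scalar).
#' @export
enrichment_factor <- function(screen, f) {
  stopifnot(inherits(screen, "ranked_screen"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    ds_error("bad_config", "f must lie in (0, 1]")
  if (screen$n < 1L)
    ds_error("no_actives", "screen contains no actives; EF undefined")
  k <- ceiling(f * screen$N)
  b <- tie_blocks(screen)
  hits <- 0
  for (i in seq_len(nrow(b))) {
    if (b$to[i] <= k) {
      hits <- hits + b$actives[i]
    } else if (b$from[i] <= k) {
      slots <- k - b$from[i] + 1L
      hits <- hits + slots * b$actives[i] / b$size[i]
      break
    } else break
  }
  (hits / k) / (screen$n / screen$N)
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Exponentially rank-weighted early-recognition score in \[0, 1\]. The raw
#' statistic is the sum of `exp(-alpha * r_i / N)` over active ranks `r_i`
#' (ties contribute the mean weight of their block). The default
#' normalization maps the exact finite-(N, n) minimum and maximum attainable
#' sums to 0 and 1; `"asymptotic"` applies the customary closed-form
#' normalization instead. About 80% of the weight falls in the first
#' `log(5)/alpha` fraction of the list.
#'
#' @param screen A [ranked_screen()].
#' @param alpha Positive early-recognition emphasis (commonly 20, 50 or 80).
#' @param normalization `"exact"` (default) or `"asymptotic"`.
#' @return BEDROC value in \[0, 1\].
#' @export
bedroc <- function(screen, alpha, normalization = c("exact", "asymptotic")) {
  stopifnot(inherits(screen, "ranked_screen"))
  normalization <- match.arg(normalization)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    ds_error("bad_config", "alpha must be a positive scalar")
  N <- screen$N; n <- screen$n
  if (n == 0L || n == N)
    ds_error("degenerate_screen", "BEDROC requires 1 <= n < N")
  w <- exp(-alpha * seq_len(N) / N)
  cw <- cumsum(w)
  b <- tie_blocks(screen)
  block_mean_w <- (cw[b$to] - c(0, cw)[b$from]) / b$size
  s_active <- sum(b$actives * block_mean_w)
  if (normalization == "exact") {
    s_max <- cw[n]
    s_min <- cw[N] - cw[N - n]
    return((s_active - s_min) / (s_max - s_min))
  }
  ra <- n / N
  rie <- (s_active / n) / (cw[N] / N)
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' ROC AUC via the midrank statistic
#'
#' Equals the probability that a random active outranks a random inactive,
#' counting ties as one half (Mann-Whitney with midranks).
#'
#' @param scores,labels As in [ranked_screen()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    ds_error("single_class", "ROC AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise AP over unique score thresholds in descending order:
#' `sum((R_i - R_{i-1}) * P_i)`, with tied scores entering as one block.
#'
#' @inheritParams roc_auc
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  n <- sum(labels == 1L)
  if (n == 0L || all(labels == 1L))
    ds_error("single_class", "average precision needs both classes")
  b <- tie_blocks(ranked_screen(scores, labels))
  tp <- cumsum(b$actives)
  fp <- cumsum(b$size - b$actives)
  prec <- tp / (tp + fp)
  sum(diff(c(0, tp)) / n * prec)
}

#' Full classification report at a decision threshold
#'
#' Computes the ranking metrics (EF@1%, EF@5%, BEDROC at alpha 20/50/80,
#' ROC AUC, AP) plus thresholded metrics (F1, precision, recall, balanced
#' accuracy, MCC) and the Brier score at `threshold` (default 0.5).
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold applied to scores.
#' @return An object of class `metric_report` (a named list of scalars).
#' @export
classification_report <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    ds_error("single_class", "both classes required for a metric report")
  screen <- ranked_screen(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  structure(list(
    ef_1pct = enrichment_factor(screen, 0.01),
    ef_5pct = enrichment_factor(screen, 0.05),
    bedroc_20 = bedroc(screen, 20),
    bedroc_50 = bedroc(screen, 50),
    bedroc_80 = bedroc(screen, 80),
    roc_auc = roc_auc(scores, labels),
    ap = average_precision(scores, labels),
    f1 = f1, precision = precision, recall = recall,
    balanced_accuracy = (recall + specificity) / 2,
    mcc = mcc,
    brier = mean((scores - labels)^2),
    threshold = threshold,
    n = screen$n, N = screen$N
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report (N =", x$N, ", actives =", x$n, ")\n")
  keys <- setdiff(names(x), c("threshold", "n", "N"))
  vals <- vapply(keys, function(k) sprintf("%.4f", x[[k]]), "")
  cat(paste0("  ", format(keys, width = 18), vals, collapse = "\n"), "\n")
  invisible(x)
}

#' Analytic random-ranking baselines
#'
#' Expected metric values for a uniformly random ranking of a screen with
#' `N` molecules and `n` actives: EF = 1, ROC AUC = 0.5, AP = prevalence,
#' BEDROC at its random expectation under the exact normalization, MCC = 0,
#' Brier = p(1 - p) for a constant score at prevalence p.
#'
#' @param N,n Library and active counts.
#' @param alphas BEDROC emphasis values to include.
#' @return Named list of baseline values.
#' @export
random_baselines <- function(N, n, alphas = c(20, 50, 80)) {
  p <- n / N
  out <- list(ef_1pct = 1, ef_5pct = 1, roc_auc = 0.5, ap = p,
              f1 = p, precision = p, recall = p,
              balanced_accuracy = 0.5, mcc = 0, brier = p * (1 - p))
  for (a in alphas) {
    w <- exp(-a * seq_len(N) / N)
    cw <- cumsum(w)
    e_rand <- n * mean(w)
    s_max <- cw[n]; s_min <- cw[N] - cw[N - n]
    out[[paste0("bedroc_", a)]] <- (e_rand - s_min) / (s_max - s_min)
  }
  out
}

#' Rank features by one-way ANOVA F-score
#'
#' Per-column F statistic between the two label groups (between-class over
#' within-class variance). Constant columns get F = 0 and a `constant` flag;
#' a perfect separator with zero within-class variance gets `Inf` and ranks
#' first. Ties are broken by ascending bit index.
#'
#' @param X Numeric matrix (rows = molecules, columns = features) or an
#'   `fp_matrix`.
#' @param y Binary labels, one per row.
#' @return A data.frame with `name`, `f_stat`, `constant`, ordered by
#'   descending F.
#' @export
anova_f_rank <- function(X, y) {
  if (inherits(X, "fp_matrix")) X <- X$matrix
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    ds_error("single_class", "ANOVA F ranking needs both classes")
  g1 <- y == 1L; g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0); n <- n1 + n0
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[g0, , drop = FALSE])
  m <- colMeans(X)
  ss_between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ss_within <- colSums((X[g1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((X[g0, , drop = FALSE] - rep(m0, each = n0))^2)
  msb <- ss_between / 1
  msw <- ss_within / (n - 2)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  f[const] <- 0
  out <- data.frame(
    name = colnames(X) %||% as.character(seq_len(ncol(X)) - 1L),
    f_stat = f, constant = const, row.names = NULL
  )
  out[order(-out$f_stat, seq_len(nrow(out))), , drop = FALSE]
}

#' Overlap statistics between two feature views
#'
#' Exact set algebra on bit-name sets: sizes, intersection, union, Jaccard,
#' Dice, per-view overlap fractions and the shared names.
#'
#' @param A,B [feature_view()] objects.
#' @return A list of class `overlap_stats`.
#' @export
view_overlap_stats <- function(A, B) {
  stopifnot(inherits(A, "feature_view"), inherits(B, "feature_view"))
  a <- A$bit_names; b <- B$bit_names
  shared <- intersect(a, b)
  uni <- union(a, b)
  structure(list(
    size_a = length(a), size_b = length(b),
    intersection = length(shared), union = length(uni),
    jaccard = length(shared) / length(uni),
    dice = 2 * length(shared) / (length(a) + length(b)),
    fraction_of_a = length(shared) / length(a),
    fraction_of_b = length(shared) / length(b),
    shared_names = sort(shared)
  ), class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "|A| = %d, |B| = %d, intersection = %d, union = %d\nJaccard = %.3f, Dice = %.3f\n",
    x$size_a, x$size_b, x$intersection, x$union, x$jaccard, x$dice
  ))
  invisible(x)
}
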
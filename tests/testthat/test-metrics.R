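# Early-recognition and global metrics.

test_that("enrichment factor matches hand arithmetic and the tie rule", {
  # N = 100, n = 10, the single top-ranked compound is active -> EF@1% = 10
  scores <- seq(100, 1)
  labels <- c(1, rep(0, 90), rep(1, 9))
  expect_equal(enrichment_factor(ranked_screen(scores, labels), 0.01), 10)
  # constant scores: one mega-tie, expectation over permutations = random = 1
  expect_equal(enrichment_factor(ranked_screen(rep(0.5, 200),
                                               c(rep(1, 40), rep(0, 160))),
                                 0.01), 1)
  expect_equal(enrichment_factor(ranked_screen(rep(0.5, 200),
                                               c(rep(1, 40), rep(0, 160))),
                                 0.05), 1)
  # agreement with the naive top-k oracle on random untied screens
  for (i in 1:25) {
    set.seed(i)
    N <- sample(20:200, 1)
    sc <- sample(seq_len(N)) / N  # untied
    lb <- rbinom(N, 1, 0.2)
    if (sum(lb) == 0) next
    f <- runif(1, 0.01, 0.5)
    expect_equal(enrichment_factor(ranked_screen(sc, lb), f),
                 oracle_ef(sc, lb, f))
  }
  expect_error(enrichment_factor(ranked_screen(1:4, rep(0, 4)), 0.5),
               class = "no_actives")
})

test_that("top-k uses ceiling at fractional boundaries", {
  # N = 10, f = 0.25 -> k = 3; actives at ranks 1 and 3
  sc <- 10:1
  lb <- c(1, 0, 1, rep(0, 6), 1)
  ef <- enrichment_factor(ranked_screen(sc, lb), 0.25)
  expect_equal(ef, (2 / 3) / (3 / 10))
  # exact integer boundary: f = 0.2 -> k = 2
  expect_equal(enrichment_factor(ranked_screen(sc, lb), 0.2),
               (1 / 2) / (3 / 10))
})

test_that("BEDROC agrees with the direct-sum oracle to 1e-9 on 200 screens", {
  set.seed(2024)
  for (i in 1:200) {
    N <- sample(10:500, 1)
    n <- sample(seq_len(N - 1), 1)
    sc <- sample(seq_len(N)) / N
    lb <- rep(0, N); lb[sample.int(N, n)] <- 1
    alpha <- sample(c(5, 20, 50, 80), 1)
    expect_lt(abs(bedroc(ranked_screen(sc, lb), alpha) -
                    oracle_bedroc(sc, lb, alpha)), 1e-9)
  }
})

test_that("BEDROC hits its extremes and the asymptotic form agrees when far from them", {
  best <- ranked_screen(100:1, c(rep(1, 10), rep(0, 90)))
  worst <- ranked_screen(100:1, c(rep(0, 90), rep(1, 10)))
  expect_equal(bedroc(best, 20), 1, tolerance = 1e-9)
  expect_equal(bedroc(worst, 20), 0, tolerance = 1e-9)
  expect_lt(bedroc(ranked_screen(1000:1, c(rep(0, 950), rep(1, 50))), 20), 0.01)
  set.seed(3)
  sc <- runif(400); lb <- rbinom(400, 1, 0.15)
  s <- ranked_screen(sc, lb)
  expect_equal(bedroc(s, 20, "exact"), bedroc(s, 20, "asymptotic"),
               tolerance = 1e-3)
  expect_error(bedroc(ranked_screen(1:5, rep(1, 5)), 20),
               class = "degenerate_screen")
})

test_that("about 80% of BEDROC weight falls in the first log(5)/alpha fraction", {
  for (alpha in c(20, 50, 80)) {
    N <- 10000
    w <- exp(-alpha * seq_len(N) / N)
    k <- round(log(5) / alpha * N)
    expect_equal(sum(w[seq_len(k)]) / sum(w), 0.8, tolerance = 0.01)
  }
  expect_equal(log(5) / 50, 0.032, tolerance = 0.01)
})

test_that("ROC AUC equals exhaustive pairwise concordance, with midrank ties", {
  set.seed(11)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    sc <- sample(1:6, N, replace = TRUE)  # many ties
    lb <- rbinom(N, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), class = "single_class")
})

test_that("EF and BEDROC are invariant under strictly monotone score transforms", {
  set.seed(21)
  sc <- runif(150); lb <- rbinom(150, 1, 0.2)
  s1 <- ranked_screen(sc, lb)
  s2 <- ranked_screen(exp(3 * sc) + 7, lb)
  expect_equal(enrichment_factor(s1, 0.05), enrichment_factor(s2, 0.05))
  expect_equal(bedroc(s1, 20), bedroc(s2, 20))
  expect_equal(roc_auc(sc, lb), roc_auc(exp(3 * sc) + 7, lb))
})

test_that("moving an active earlier never hurts EF and strictly helps BEDROC", {
  set.seed(31)
  for (i in 1:20) {
    N <- 60
    sc <- sample(seq_len(N)) / N
    lb <- rbinom(N, 1, 0.25)
    if (sum(lb) < 2 || sum(lb) > N - 2) next
    ord <- order(sc, decreasing = TRUE)
    act_pos <- which(lb[ord] == 1)
    inact_pos <- which(lb[ord] == 0)
    a <- act_pos[length(act_pos)]       # last-ranked active
    b <- rev(inact_pos[inact_pos < a])[1]  # an inactive ranked above it
    if (is.na(b)) next
    lb2 <- lb
    lb2[ord[a]] <- 0; lb2[ord[b]] <- 1  # swap: active moves up
    s1 <- ranked_screen(sc, lb); s2 <- ranked_screen(sc, lb2)
    expect_gt(bedroc(s2, 20), bedroc(s1, 20))
    for (f in c(b / N, 0.5, 1)) {
      expect_gte(enrichment_factor(s2, f), enrichment_factor(s1, f))
    }
  }
})

test_that("classification report is coherent on perfect and random screens", {
  sc <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  lb <- c(1, 1, 1, 0, 0, 0)
  rep <- classification_report(sc, lb)
  expect_equal(rep$roc_auc, 1)
  expect_equal(rep$ap, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$mcc, 1)
  expect_equal(rep$balanced_accuracy, 1)
  # 6-row hand example against the brute-force concordance oracle
  sc2 <- c(0.3, 0.8, 0.5, 0.5, 0.9, 0.1)
  lb2 <- c(0, 1, 1, 0, 0, 1)
  expect_equal(classification_report(sc2, lb2)$roc_auc, oracle_auc(sc2, lb2))
  expect_error(classification_report(1:3 / 4, c(1, 1, 1)),
               class = "single_class")
})

test_that("random rankings average to the analytic baselines", {
  # seeded permutation estimate of E[EF@5%] and E[AUC] under random ranking
  set.seed(77)
  N <- 140; n <- 20
  lb <- c(rep(1, n), rep(0, N - n))
  efs <- aucs <- numeric(10000)
  for (i in seq_along(efs)) {
    sc <- sample(seq_len(N))
    efs[i] <- enrichment_factor(ranked_screen(sc, lb), 0.05)
    aucs[i] <- roc_auc(sc, lb)
  }
  expect_equal(mean(efs), 1, tolerance = 0.02)
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
  b <- random_baselines(N, n)
  expect_equal(b$ef_1pct, 1)
  expect_equal(b$roc_auc, 0.5)
  expect_equal(b$ap, n / N)
})

test_that("ANOVA F ranking matches the textbook two-group formula", {
  # 8-sample hand-computable case
  x <- c(1, 2, 1, 2, 5, 6, 5, 6)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  X <- cbind(feat = x, const = rep(1, 8), perfect = y)
  rk <- anova_f_rank(X, y)
  m1 <- mean(x[y == 1]); m0 <- mean(x[y == 0]); m <- mean(x)
  ssb <- 4 * (m1 - m)^2 + 4 * (m0 - m)^2
  ssw <- sum((x[y == 1] - m1)^2) + sum((x[y == 0] - m0)^2)
  f_hand <- ssb / (ssw / 6)
  expect_equal(rk$f_stat[rk$name == "feat"], f_hand)
  expect_equal(rk$f_stat[rk$name == "const"], 0)
  expect_true(rk$constant[rk$name == "const"])
  # perfect separator: infinite F, ranked first
  expect_equal(rk$name[1], "perfect")
  expect_true(is.infinite(rk$f_stat[1]))
})

test_that("view overlap statistics reproduce the packaged-view numbers", {
  v <- packaged_views()
  ov <- view_overlap_stats(v$list_1, v$list_2)
  expect_equal(ov$size_a, 40)
  expect_equal(ov$size_b, 55)
  expect_equal(ov$intersection, 6)
  expect_equal(ov$union, 89)
  expect_equal(ov$jaccard, 6 / 89)
  expect_equal(ov$dice, 12 / 95)
  expect_setequal(ov$shared_names,
                  paste0("Avalon_FP_", c(1119, 1157, 1237, 1250, 2000, 339)))
  same <- view_overlap_stats(v$list_1, v$list_1)
  expect_equal(same$jaccard, 1)
  expect_equal(same$dice, 1)
  disjoint <- view_overlap_stats(feature_view("a", 0:4), feature_view("b", 5:9))
  expect_equal(disjoint$jaccard, 0)
})
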
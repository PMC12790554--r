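# decoyscreen

Construction, auditing and evaluation of negative (decoy) cohorts for
ligand-based screening classifiers in R.

## The problem

Supervised screens for rare molecular phenotypes — here, *prodrug-likeness*:
whether a structure looks like a bioreversible derivative that releases an
active parent drug — usually have curated positives but **no experimentally
verified negatives**. Negatives must be manufactured: property-matched
near-miss decoys, random library background, and rule-filtered
high-confidence non-prodrugs. Each construction recipe leaves fingerprints
of its own, and a classifier can "succeed" by recognising the recipe rather
than the phenotype. `decoyscreen` implements the full defensive pipeline
around that risk:

1. **Curation** — structure standardization (largest organic fragment,
   canonical SMILES), InChIKey identity keys, removal of decoys that collide
   with positives (full 27-character key), flagging of stereo/tautomer
   collisions (14-character connectivity block), and a strict
   high-confidence-negative rule engine: element whitelist; promoiety SMARTS
   (esters, carbamates, phosphates, azo/nitro, catechol-like, …); reactive
   warhead SMARTS (aldehydes, epoxides, Michael acceptors, …); PAINS/Brenk
   structural alerts; Lipinski/Veber-like property windows
   (MW ≤ 500, HBD ≤ 5, HBA ≤ 10, cLogP ∈ [−1, 5], TPSA ≤ 140 Å², ROTB ≤ 10).
2. **Fingerprints** — 2048-bit hashed binary substructure fingerprints
   (pluggable algorithm registry; Tanimoto similarity with documented
   conventions).
3. **Frozen split** — an early, source-balanced 1:6 train/test partition:
   20% of positives plus exactly two negatives per decoy source per
   positive, frozen before any data-dependent step.
4. **Hardness guardrails** (training side only) — Tanimoto similarity bounds
   against the positive pool; pruning of negatives whose decoy source an
   extremely-randomized-trees classifier can predict out-of-fold; removal of
   whole PCA/k-means clusters with low source entropy or low similarity to
   positives.
5. **Domain-bias audit** — how well does a candidate feature subset predict
   a negative's *origin*? Views are gated at near-chance (accuracy,
   balanced accuracy, macro-F1 all < 0.4; macro-AUC-OVR < 0.6, strict) and
   must preserve ≥ 95% of the full-feature task ROC AUC.
6. **Cross-decoy transfer** — the 3×3 protocol: within-recipe 5-fold CV on
   the diagonal, train-on-one/test-on-another transfer off it; views whose
   average precision collapses under recipe shift are discarded.
7. **Late fusion** — one base classifier per feature view (gradient-boosted
   trees by default), combined by an equal-weight mean of scores; feature
   concatenation is structurally impossible.
8. **Evaluation** — early-recognition and global metrics, plus a
   label-randomization sanity check and a frozen-test leakage firewall.

## The metrics

For a ranking of `N` molecules containing `n` actives:

- **Enrichment factor** at fraction `f`, with `k = ⌈fN⌉`:
  `EF@f = (actives in top k / k) / (n / N)` — random expectation 1.
- **BEDROC** (Truchon–Bayly): the exponentially rank-weighted sum
  `S = Σ_i exp(−α·r_i/N)` over active ranks, normalized to [0, 1] by the
  exact finite-(N, n) minimum and maximum attainable sums. About 80% of the
  weight lies in the first `ln(5)/α` fraction of the list (3.2% at α = 50).
- ROC AUC (midrank Mann–Whitney), average precision, F1, balanced accuracy,
  MCC and Brier at threshold 0.5; one-way ANOVA F-scores for feature
  ranking; Jaccard/Dice overlap statistics for feature views.

Ties are resolved by their exact expectation over permutations of the tied
block, so a constant score vector yields EF = 1 exactly.

## Worked example

Chemistry-side curation:

```r
library(decoyscreen)
strict_negative_filter("CCOC(C)=O")     # ethyl acetate
#> FAIL: promoiety:ester
strict_negative_filter("Oc1ccccc1O")$failed_rules
#> [1] "promoiety:catechol_like" "alert:PAINS"
strict_negative_filter("c1ccccc1")      # benzene: clean, inside all windows
#> PASS (high-confidence negative)
```

Scoring a screen of 140 molecules with 20 actives whose scores separate
well:

```r
set.seed(1)
scores <- c(runif(20, 0.5, 1), runif(120, 0, 0.6))
labels <- c(rep(1, 20), rep(0, 120))
classification_report(scores, labels)
#> Metric report (N = 140 , actives = 20 )
#>   ef_1pct           7.0000
#>   ef_5pct           7.0000
#>   bedroc_20         0.9891
#>   roc_auc           0.9946
#>   ap                0.9765
#>   ...
```

`EF@1% = 7` is the ceiling for this prevalence (1/7): the top-ranked slice
is all active. The two packaged published feature views reproduce their
overlap statistics:

```r
v <- packaged_views()
view_overlap_stats(v$list_1, v$list_2)
#> |A| = 40, |B| = 55, intersection = 6, union = 89
#> Jaccard = 0.067, Dice = 0.126
```

And the whole pipeline runs end-to-end on synthetic fingerprints with
planted signal and planted recipe artifacts:

```r
res <- run_screening_pipeline(n_positives = 100, seed = 20260922)
res
#> Pipeline: 2 gate-passing view(s); fused hold-out AUC 0.996, frozen-test AUC 0.993
```

A thin command-line wrapper is installed as `exec/decoyscreen`
(`simulate`, `curate`, `fingerprint`, `split`, `evaluate`, `overlap`).

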
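---
title: "Decoy cohorts you can trust: methods behind decoyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoy cohorts you can trust: methods behind decoyscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyscreen)
```

## Why a decoy-auditing pipeline

Screening classifiers for rare molecular phenotypes — prodrug-likeness is
the motivating case — are trained against *manufactured* negatives, because
no repository of experimentally verified non-prodrugs exists. Three
complementary negative cohorts are the standard remedy: property-matched
near-miss decoys, a random library background, and rule-filtered
high-confidence negatives. But every construction recipe imprints
statistical cues of its own, and a model free to exploit them will report
excellent benchmarks while having learned *which recipe produced a
molecule* rather than the phenotype. `decoyscreen` operationalizes the
counter-measures: identity-level overlap control, training-only hardness
guardrails, a domain-bias audit that gates feature subsets at near-chance
origin predictability, cross-decoy transfer validation, and late-fusion
ensembling that never concatenates feature views.

## Curation and the strict negative rule engine

Structures are standardized through OpenBabel: the largest organic fragment
is kept (salt stripping), the SMILES canonicalized, and identity recorded
as the full 27-character InChIKey plus its first 14-character connectivity
block. Decoys sharing a full key with any positive are removed outright;
decoys sharing only the connectivity block (stereoisomers, some tautomers)
are *flagged* rather than dropped — the screen is a two-stage
flag-then-resolve design, and since no hard resolution rule is defensible
in general, flagged records are excluded from decoy pools by default but
retained in output (`keep_flagged` reverses this). Duplicates are collapsed
within each pool (first occurrence wins); duplicates *across* decoy sources
are deliberately left alone — each source is an independent draw from its
own recipe, and cross-source collisions are informative rather than
erroneous, while label leakage is fully handled by the positive-overlap
screen.

The high-confidence-negative filter evaluates every rule with no
short-circuit, so a verdict lists *all* violations: an element whitelist
(C, H, N, O, S, P, F, Cl, Br, I, B, Si); named promoiety SMARTS — the
bioreversible masking groups whose presence marks a latent prodrug (ester,
carbonate, carbamate, phosphate/phosphonate/sulfate ester, azo, nitro,
nitroso, quinone-imine, catechol-like); named reactive warhead SMARTS
(aldehyde, acyl halide, anhydride, isocyanate, epoxide, aziridine, Michael
acceptor, vinyl sulfone, chloroacetamide, sulfonyl chloride, imine, oxime,
hydroxamic acid); structural-alert catalogs (PAINS and Brenk by default,
NIH and ZINC as opt-in config — the shipped catalogs are *abridged,
representative excerpts* of the published sets, each pattern unit-tested
against a positive and a negative exemplar); and drug-likeness windows
(MW ≤ 500 Da, HBD ≤ 5, HBA ≤ 10, cLogP ∈ [−1, 5], TPSA ≤ 140 Å²,
rotatable bonds ≤ 10). The cLogP estimator is pinned to one named method —
the OpenBabel atom-contribution logP — and recorded in the config, because
window verdicts are only reproducible relative to a fixed estimator.

## Fingerprints

Every downstream stage operates in one feature space: fixed-length binary
substructure fingerprints of 2048 bits, with slot names `Avalon_FP_0` …
`Avalon_FP_2047` for interoperability with the packaged published feature
sets. The algorithm behind the slots is a pluggable registry; the default
is a hashed atom-pair scheme (atom-pair descriptors enumerated from the
molecular graph via ChemmineR, each hashed into one of the 2048 slots),
which is deterministic and invariant under SMILES rewrites. The algorithm
name and parameters are stamped into every fingerprint matrix, and all set
algebra downstream (Tanimoto, overlap statistics) is hash-agnostic.
Tanimoto similarity of two all-zero vectors is defined as 1.0 — two
"empty" structures are maximally similar — and that convention is tested.

## The frozen 1:6 split

From `n_P` curated positives, a plain random 20% (round-half-to-even;
"stratified" degenerates to simple sampling when the only stratum is the
positive class) becomes the test-positive set. For each positive, exactly
two negatives are drawn from each of the three decoy sources without
replacement within source, in both partitions: a per-positive 1:6 ratio
with exact per-source parity. With 610 positives this gives 122/488
positives, 244/976 negatives per source and 854/3416 rows. Sampling is a
seeded shuffle-then-take, so a plan is reproducible from its seed; the test
side is marked frozen, serialized into the JSON manifest, and defended at
runtime by a leakage firewall (`guard_activate()`) that records every id a
training-side stage consumes and raises on contact with a frozen id.

## Hardness guardrails

Three training-only stages, in fixed order, each consuming the previous
stage's survivors; the first triggering stage claims each removed id, so
the removal sets partition the input.

1. *Similarity bounds.* Each negative's maximum Tanimoto to the training
   positives must lie in `[lo, hi]`. The fixed defaults 0.30/0.90 suit real
   substructure fingerprints: above 0.90 a "negative" is plausibly a
   mislabelled positive; below 0.30 it is trivially separable filler that
   inflates early-recognition metrics. A quantile mode instead derives the
   bounds from an empirical distribution — either the positives'
   leave-one-out maximum similarity or the negatives' own
   maximum-similarity distribution — for feature spaces whose similarity
   scale differs from real chemistry (the synthetic generator's, for one).
2. *Source-predictability pruning.* An extremely-randomized-trees
   multi-class origin model is trained on negatives only; candidates whose
   maximum out-of-fold source probability exceeds `p_cut` are pruned. The
   cut defaults to 0.60 — no published value exists, so the full
   out-of-fold probability table is always returned and any cut is
   auditable after the fact.
3. *Cluster entropy filter.* Negatives are embedded by PCA (32 components),
   clustered by k-means (k = 20, seeded), and whole clusters are removed if
   their normalized source entropy (base = number of sources) falls below
   0.5 — a recipe pocket — or their mean member similarity to positives
   falls below a floor that defaults to the similarity guardrail's lower
   bound. "Mean similarity" is the cluster mean of each member's *maximum*
   Tanimoto to the positive pool, the same quantity stage 1 bounds.

The embedding dimension, k, and entropy cutoff are declared defaults, not
inferred ones; all are config. Idempotence of the composite — re-running it
on its own survivors changes nothing — holds by construction for stage 1
and statistically for stages 2–3 (a refit on survivors could in principle
find new structure; at the shipped operating points it does not, which the
test suite pins under a fixed seed).

## Domain-bias audit and view search

A feature view (named ordered bit subset) is audited by cross-validated
origin classification of the negatives restricted to those columns,
reporting per-fold and mean accuracy, balanced accuracy, macro-F1 and
macro-AUC-OVR plus the pooled confusion matrix. The leakage gate demands
all four metrics strictly below 0.4/0.4/0.4/0.6 — "below" is strict, so
boundary values fail — a small buffer over the three-class chance levels of
1/3 and 1/2. A compatibility check then requires the view to preserve at
least 95% of the full-feature ROC AUC on a single seed-pinned validation
split (20% of the training pool, carved once per run).

The random search draws at least 30 candidate subsets with sizes uniform
over 40–55 bits (the scale of the packaged views). Candidates are sampled
from a task-relevant pool — by default the top 256 bits by one-way ANOVA
F-score on the training pool — because a uniform draw from all 2048 bits
carries almost no task signal at these sizes and the 95% compatibility gate
would reject everything; restricting the pool maximizes usable features
while leaving the leakage gate to reject subsets that carry recipe cues.
Survivors are ranked by root-mean-square distance of the four audit metrics
from their chance levels (ascending), with macro-AUC, accuracy and name as
tie-breaks.

## Cross-decoy transfer and late fusion

For each training source, a class-weighted extremely-randomized-trees
baseline (median imputation retained as a declared no-op on binary bits) is
trained on the training positives plus that source's training negatives.
The 3×3 matrix holds stratified 5-fold CV AUC/AP on the diagonal
(`cv_holdout`) and, off the diagonal, the model refit on the full mixture
evaluated on the frozen test positives plus the *other* source's test
negatives (`external_test`) — never the test source's training negatives.
Retention requires the worst transfer AUC ≥ 0.75, worst transfer AP ≥ 0.35
and a per-source in-recipe-to-transfer AP drop ≤ 0.35; the thresholds
encode the qualitative published rule (strong-on-one/poor-transfer views
are discarded) with declared numbers, since none are printed.

The ensemble is homogeneous: the *same* base learner trained separately per
view, fused by an unweighted score mean. Member weights are `1/m` by
construction with no meta-parameters, and the API makes feature
concatenation impossible — a learner receives exactly one view's columns.
Supported families: gradient-boosted decision trees (default; xgboost),
extremely randomized trees, random forest, bagged trees, k-NN (the one
scale-sensitive family, min-max scaled with parameters fitted strictly
inside training folds), plus a registry for extensions. The combination
search evaluates singles and seeded random combinations of 2–5 views under
label-stratified 5-fold CV and ranks by mean ROC AUC (ties by name),
reporting mean EF@1% alongside.

## Metrics and numerical choices

EF uses `k = ⌈fN⌉` (declared; the alternative floor convention differs only
at exact integer boundaries and is tested there). BEDROC uses the
Truchon–Bayly weighted sum with the *exact* finite-(N, n) min/max
normalization by default; the customary asymptotic closed form is exposed
as an option and agrees to ~1e-3 away from the extremes. Ties everywhere
are handled by exact expectation over permutations of the tied block:
midranks for AUC, fractional top-k allocation for EF, mean block weight for
BEDROC — deterministic, and a constant score vector scores exactly at the
random baseline. Degenerate inputs raise typed conditions rather than
returning sentinels (`no_actives`, `degenerate_screen`, `single_class`).
Constant features get an ANOVA F of 0 with a flag; a zero-within-variance
separator gets `Inf` and ranks first.

The analytic random baselines are EF = 1, AUC = 0.5, AP = prevalence,
MCC = 0, Brier = p(1−p), and BEDROC at its exact random expectation given
(N, n, α). The label-randomization protocol permutes labels *within the
training pool only* and evaluates against intact test labels — the check
asks whether a null model scores at chance on real data, and shuffling test
labels too would test something else.

## What the synthetic generator does and does not emulate

`simulate_dataset()` draws independent Bernoulli bits: signal bits fire at
0.45 in positives versus 0.10 in negatives; each source owns 20 artifact
bits firing at 0.22 inside versus 0.10 outside; background is 0.10. The
artifact strength is calibrated so the generator reproduces the statistical
regime the auditing stages assume: a full-fingerprint origin classifier
reaches roughly 0.6 accuracy (clearly above chance, far from separable)
while 40–55-bit views sit near chance — the same qualitative structure the
audit is designed to detect on real data. The default cohort arithmetic is
the 1:6 three-source design.

What the generator does *not* emulate: correlation between bits (real
substructure bits co-occur strongly), heavy-tailed bit frequencies,
near-duplicate analog series, scaffold clustering, or any chemistry at all.
Passing tests on synthetic data therefore demonstrate that the machinery —
gates, guardrails, firewalls, metrics — behaves correctly under its own
assumptions; they do not certify performance on real corpora, whose
headline benchmark values depend on external databases and are out of scope
here.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the split arithmetic at the
full 610-positive design (it is free), the domain-audit chance check on
3000 synthetic negatives, the random-baseline cross-check on 10⁴
permutations, and the end-to-end pipeline on 100 positives with 30 view
candidates — sizes chosen so the whole suite exercises every stage at
statistically meaningful n while completing in a few minutes on one CPU.
The end-to-end pipeline simulates 4 decoys per source per positive, double
the split design's requirement, so the guardrails have slack to discard
candidates and the 1:6 training mixture can still be rebalanced exactly —
mirroring the real-data situation of pools an order of magnitude larger
than the design draw. All learners are seeded and single-threaded;
every sampling step derives child seeds from one user seed.

## Known limitations

- The shipped alert catalogs are abridged; a production deployment should
  substitute the complete published PAINS/Brenk/NIH/ZINC SMARTS sets via
  `strict_filter_config()`.
- The fingerprint default is a hashed atom-pair scheme, not the specific
  hashed-substructure algorithm used upstream of the packaged feature
  views; bit *indices* in those views are therefore meaningful only as
  slot names when applied to fingerprints from a different hash. Analyses
  that depend purely on set algebra are unaffected.
- The guardrail composite's idempotence and several chance-band tests are
  statistical properties pinned by seed, not algebraic identities.
- k-NN probability scores are vote fractions with k + 1 distinct levels;
  EF at very small top fractions is coarse for that family.
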
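---
title: "Methods: site-level driver-mutation scoring and target prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-level driver-mutation scoring and target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitedriver)
```

## The problem

Somatic missense mutations in tumors divide into drivers, which confer a
selective growth advantage, and functionally neutral passengers. Drivers
cluster in functional regions of proteins: orthosteric (substrate/catalytic)
sites and, less well charted, allosteric sites — regions topologically
distinct from the orthosteric site whose perturbation propagates to it and
can trap a protein in an active or inactive conformation. `sitedriver`
implements a site-centric prioritization workflow: map each missense
mutation from a clinical sample onto annotated allosteric/orthosteric sites
of human proteins, score the site-mapped mutations with a class-rebalanced
ensemble classifier, and rank candidate driver proteins per sample by their
best driver-mutation score.

## Inputs and mapping

Cohorts arrive as MAF files (multi-sample), ANNOVAR gene-annotation output
(single sample, named by file stem) or a plain `sample;gene;V600E` list.
Only missense substitutions are used; everything operates in 1-based
UniProt protein coordinates (no genomic liftover, by design). Samples with
more than 2000 mutations are rejected by the validator and reported, the
run continuing with the remaining samples.

The site database is three TSVs: site records (residue sets typed as
experimentally verified allosteric, predicted allosteric or orthosteric),
per-residue structural annotations (wild-type residue, relative solvent
accessibility in [0,1], a z-scored flexibility proxy) and a gene-to-UniProt
map. Two mapping modes mirror the two "mapping area" choices: in
*allosteric* mode orthosteric records are loaded but inactive, in
*functional* mode all records are active. Each mutation gets exactly one of
four areas — experimental allosteric, predicted allosteric, orthosteric, or
other — so the per-sample area profile is a partition of the cohort. For a
position belonging to several overlapping sites the precedence is
ORTHO > ALLO_EXP > ALLO_PRED. No rule for this tie is published; we chose
orthosteric-first because orthosteric membership is the more specific
functional claim and it keeps the four-area accounting mutually exclusive.
The precedence is an argument of `map_mutation()` for users who prefer
otherwise, and assignment is invariant to the ordering of site records.

Stated reference residues are checked against the protein sequence when a
FASTA is supplied. Mismatches (common in clinical MAFs due to isoform
numbering drift) are, by default, excluded from scoring but retained in the
area profile under "other", and always reported; a strict mode turns them
into errors.

## Features

Only site-mapped mutations are scored. The v1 schema has 11 features: the
one-hot site-type flags; the residue's relative solvent accessibility and
flexibility proxy from the annotation table; substitution deltas
(alternate minus reference) of Kyte–Doolittle hydropathy, residue volume
(Å³) and formal charge at pH 7; the BLOSUM62 substitution score; and two
backbone-disruption flags (proline introduced, glycine lost). The property
tables are embedded constants with literature provenance noted in the
source. Deltas are antisymmetric by construction and the site flags always
sum to one. The schema is versioned so a richer feature set can be added
without invalidating stored models; all model code is schema-agnostic.

Features are z-scaled for the perceptron using the population (1/n)
standard deviation, with constant columns passed through unchanged;
parameters are fitted on training data only. The tree branch consumes raw
features, since tree splits are scale-invariant.

## The scoring model

Driver/passenger training data is heavily imbalanced (about 0.12
positive:negative), so SMOTE is applied first: synthetic minority points
`x + u (x_nn − x)` with `u ~ U[0,1]` and `x_nn` one of the `k = 5` nearest
minority neighbors (Euclidean), appended until the minority reaches the
majority count (target ratio 1.0). `k` and the target ratio are the
method's canonical defaults; both are configurable and the procedure is
seeded. Majority rows are never touched.

Two learners are then fitted and combined:

* a probability random forest with maximum depth 4, 130 trees and a 0.4
  feature fraction at each split (via `ranger`), and
* a feed-forward perceptron with hidden layers of 20 and 15 ReLU units and
  a sigmoid output, trained by minibatch SGD (batch 32, at most 200 epochs)
  with learning rate 0.1 and momentum 0.8 on binary cross-entropy.

The ensemble score is the unweighted arithmetic mean of the two class-1
probabilities — the simplest symmetric combination rule, exposed in the
configuration — and a mutation is called a driver when its score strictly
exceeds 0.5 (a score of exactly 0.5 is not a driver).

### Early stopping, and why it is monitored on raw rows

With these optimizer settings an unregularized perceptron drives the
training loss on the SMOTE-balanced set to near zero and its outputs
saturate to 0/1. A saturated branch is disastrous under mean combination:
one confident wrong 0 halves the ensemble score below any reasonable
threshold regardless of the forest. Monitoring the early-stopping loss on
the balanced training rows does not help, because synthetic minority points
are interpolations of training rows and memorization masquerades as a
plateau. We therefore hold out a stratified 10% of the *raw* rows before
resampling, exclude them from the perceptron's SMOTE run and training set,
and monitor a class-balanced cross-entropy on them (patience 20 epochs,
best-loss weights kept; the balanced loss keeps the imbalanced monitor from
rewarding majority-only fits). With fewer than 10 rows per class the
perceptron falls back to an internal split of its training set. The forest
is unaffected and always trains on the SMOTE output of all training rows.

### Cross-validation and tuning

`cv_ensemble()` runs stratified k-fold cross-validation (default 10) with
SMOTE re-run inside each training fold, so no synthetic point ever spans a
fold boundary. Stratification matters at 0.12 imbalance, where unstratified
folds can lose the minority class entirely. Fold membership is derived from
a canonical per-class ordering of row contents before the seeded shuffle,
making the assignment invariant to input row order. `tune_ensemble()` is a
plain grid search over the ensemble configuration maximizing the mean
per-fold AUC; the published optimum (depth 4 / 130 trees / 0.4) is the
package default, so tuning is optional.

## Evaluation

`roc_auc()` sweeps thresholds over the unique scores with simultaneous
steps at ties; the trapezoidal area equals the Mann–Whitney U statistic
divided by `n1·n0` with half credit for ties, and the test suite checks
that equivalence against a brute-force pairwise oracle to 1e-12.
`sensitivity_at()` counts positives strictly above the threshold.
`run_benchmark()` pushes a labeled mutation table through the full
map–featurize–score path and reports class counts, detections and AUC;
unmappable entries are excluded from the metrics but listed explicitly,
because silent exclusion would inflate sensitivity.

## Synthetic data: what it emulates and what it does not

All inputs have seeded generators, so every test runs without downloads.
`gen_site_world()` emits a mutually consistent site table, residue
annotations, gene map and FASTA (5-residue sites, types cycling over the
three kinds); `gen_cohort_maf()` draws missense cohorts with a controllable
on-site fraction and correct wild-type residues; `gen_label_table()`
produces driver/passenger tables at chosen class counts over world site
residues, used at the published benchmark shapes 24/197 and 73/582
(imbalance ≈ 0.12) so the harness exercises the class-balance regime the
method was built for.

`gen_labeled_dataset()` plants a separation in feature space: the six
continuous schema features are unit-variance Gaussians and the positive
mean is shifted `d′` pooled standard deviations along a random unit
direction in that subspace; site flags are a valid one-hot draw and the
backbone flags sparse Bernoulli, both class-independent. The default
validation protocol uses 73/582 and `d′ = 2.5`, whose Bayes-optimal AUC of
`Φ(2.5/√2) ≈ 0.96` sits in the range of the published benchmark AUCs. Under
10-fold CV with the default configuration this yields pooled AUC ≈ 0.95 and
sensitivity at 0.5 ≈ 0.84 (problem size 655 rows, a few seconds on one
CPU). The Gaussian model is chosen for the analytic tractability of the
planted separation. It does not emulate real mutation features —
correlations between physicochemical deltas, discrete BLOSUM scores,
mutational hotspots, shared sites between train and test mutations — so
passing these tests demonstrates that the training/evaluation machinery is
correct and well-calibrated, not that the model transfers to real cohorts;
for that the original structural/dynamic feature values of the benchmark
mutations would be required, which are not published.

## Numerical and degenerate-input choices

Ties in ranking break by gene symbol then position, so rankings are
shuffle-invariant. Domain intervals are 1-based inclusive (PFAM
convention). Pan-cancer heatmap cells are raw counts, not normalized per
cancer-type sample size (the normalization is not specified anywhere; raw
counts are documented and reversible). Constant features standardize to
themselves. SMOTE clips `k` to minority size − 1 with a warning and errors
below 2 minority rows. An empty sample yields an all-zero profile; a
cohort whose samples are all over the mutation cap is an error. All
randomness flows through explicit seeds; two runs of the CLI with the same
configuration are byte-identical, which the acceptance script verifies.

## Limitations

* Site residue sets are consumed as given; no pocket detection or distance
  cutoff is applied, and predicted allosteric sites are trusted as input.
* The v1 feature schema is a documented stand-in for the richer
  structural/dynamic descriptors the approach was originally built on;
  scores from the two feature sets are not comparable.
* Gene-to-protein resolution requires the explicit mapping table; unmapped
  genes are reported and counted under "other", not resolved via external
  services.
* No probability calibration is applied beyond the sigmoid output and the
  forest's leaf frequencies.
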
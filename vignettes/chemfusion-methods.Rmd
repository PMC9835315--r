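---
title: "Multimodal fusion for bioactivity classification: models and methods"
author: "ChemFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion for bioactivity classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ChemFusion implements a complete ligand-based virtual-screening pipeline:
from raw potency records to multi-seed benchmark tables comparing nine
classical classifiers and two attention networks across eight molecular
feature representations, three activity-cutoff regimes, and three
strategies for class imbalance. This vignette is the package's own
account of the methods: the models, their assumptions, the tunable
parameters with their defaults and units, the numerical choices, and the
limitations a user should know about.

## The classification problem

A compound with a measured potency against a protein target (Ki, Kd or
IC50, pooled without assay-type correction and unit-normalised to
micromolar) is labeled *active* when its potency is strictly below an
activity cutoff — 0.5, 1 or 10 µM — and *inactive* otherwise (potency
equal to the cutoff is inactive). The three cutoffs move the same data
through three class-balance regimes: roughly 1:1, 3:2 and 4:1
positive:negative. Models score compounds in [0, 1]; the label operating
point is fixed at 0.5, and performance is reported as accuracy, F1
(active class positive) and the rank-based AUC with midrank tie
correction.

Duplicate measurements of one molecule (identified by canonical SMILES)
are merged into one entry. The merge statistic is the *median* potency:
potencies of repeated assays are log-scale noisy with occasional gross
outliers, and the median is robust to a single discordant record. The
number of merged records is retained (`n_merged`) for audit.

## Molecular representations and preprocessing

Four modalities describe each molecule:

* **Physicochemical descriptors** — a pinned panel of 208 descriptor
  names (shipped in `extdata/descriptor_panel.txt`). Pinning by name
  keeps the column set identical across chemistry-toolkit releases,
  which otherwise add descriptors over time.
* **MACCS keys** — the 166-bit structural-key fingerprint (the toolkit's
  dummy bit 0 is dropped).
* **ECFP4** — Morgan fingerprints of radius 2 hashed to 2048 bits, as
  bit vectors (no counts).
* **SMILES tokens** — the canonical SMILES tokenized with
  multi-character symbols (`Cl`, `Br`, bracket atoms, two-digit ring
  closures) mapped through a corpus-derived sorted vocabulary, id 0
  reserved for padding, padded to a maximum length of 195.

Numeric preprocessing is fitted on the training and validation rows only
and then applied unchanged to the test rows (`fit_scope = "train"`; a
`"all"` switch reproduces the alternative reading in which statistics
are fitted on the full set). The chain per modality is:

1. *Zero-variance filter* (descriptors only): columns constant on the
   fit rows are removed and the kept indices recorded. The sparse
   fingerprints keep their full bit set — their informative
   dimensionality is handled by the PCA step.
2. *Imputation* (descriptors only): non-finite descriptor values are
   replaced by fit-row column medians.
3. *Standardization* (descriptors only, before PCA): mean 0, population
   SD 1 (divisor *n*, the common scaler convention) on the fit rows.
4. *PCA to 128 dimensions* per modality, components ordered by
   explained variance. 128 balances retained variance against the input
   width of the downstream models.
5. *Standardization of the projected scores.* Principal components
   beyond the numerical rank of the fit data (population SD below
   1e-8) are zeroed for **all** rows rather than scaled: a held-out
   row's projection onto such a component is noise orthogonal to
   everything the model can learn, and scaling it would inject large
   spurious values into the test features.

Early fusion concatenates processed blocks side by side. The eight
combinations are (1) descriptors, (2) ECFP4, (3) MACCS, (4) SMILES
tokens, (5) descriptors+ECFP4, (6) descriptors+MACCS, (7) MACCS+ECFP4,
(8) descriptors+ECFP4+MACCS. Blocks are concatenated in each
combination's listed order and the block boundaries are recorded, so
`splitFused()` recovers the constituents exactly.

## Scaffold-cluster hold-out splitting

Random splits overestimate generalization in chemistry because near
analogues land on both sides. ChemFusion instead clusters compounds on
the *conjoint representation* — the standardized concatenation of raw
descriptors, MACCS and ECFP4 — with K-means (k-means++ seeding, 10
restarts) and holds out whole clusters. The cluster count is selected by
consensus of three internal indices computed for every candidate k:
silhouette coefficient (primary), Davies–Bouldin index (tie-break,
lower better) and Calinski–Harabasz score (second tie-break). A fixed
`k` can be forced when the cluster structure is known.

The test set is the union of 3 held-out clusters. Among all
C(k, 3) subsets (exhaustive for k ≤ 20, greedy beyond), the chosen
subset minimises the gap between the test positive rate and the overall
positive rate, subject to the test set containing 8–16 % of compounds
(the band is widened with a warning when no subset qualifies). The
validation set (5 % of compounds by default) is drawn *compound-wise,
stratified by label*, from the remaining clusters; whether validation
should instead be cluster-disjoint from training is genuinely open, and
the compound-wise choice was made because validation steers early
stopping and hyperparameter selection rather than final reporting.
Changing the seed re-draws validation membership but never moves a
test-cluster compound into training.

## Models

Nine classical families sit behind one train/predict contract
(`trainClassifier()` / `predictScores()`): support-vector
classification, random forest, K-nearest neighbours, decision tree,
gradient-boosted trees, AdaBoost over depth-limited trees (implemented
in-package as SAMME with weighted CART weak learners), Gaussian naive
Bayes, an SGD-trained linear model (logistic or hinge loss, L2,
implemented in-package), and L2-regularised logistic regression.
Score conventions: class-1 probability where the family provides one;
for margin-only settings (hinge SGD) the decision value is min-max
mapped onto [0, 1]. Randomized hyperparameter search samples 10
configurations from shipped per-family distributions
(`extdata/search_spaces.yaml`, overridable) and scores each by 5-fold
cross-validated AUC; a configuration that fails on a fold scores -Inf
and cannot win. The shipped distributions are the package's documented
defaults — the ranges a practitioner would scan for these families.

AdaBoost (fixed hyperparameters), Gaussian naive Bayes and the
ridge-penalised logistic fit are *deterministic*: refits under different
seeds are bitwise identical, so their multi-seed SDs are exactly 0.
This is a designed property, not an accident — boosting re-weights the
full sample (no resampling), naive Bayes has no random component, and
the convex logistic objective has one optimum found by a deterministic
solver.

### The two attention networks

Both networks are implemented in base R with hand-derived gradients
(verified against finite differences in the test suite), Adam
(learning rate 1e-3), binary cross-entropy, seeded shuffling and early
stopping on validation AUC (patience 10, maximum 200 epochs by
default; benchmark runs in the tests use smaller budgets, stated
there). The final dense layer is zero-initialised so an untrained
network scores exactly 0.5.

**Fusion network.** Each processed 128-dimensional block passes through
its own fully connected ReLU projection (width 64 by default); the
projections are stacked as a sequence of length `n_blocks` and fed to a
single-head scaled dot-product self-attention layer (queries/keys of
width 32, values of projection width); the attended sequence is
flattened and scored by a dense head. Four fully connected layers are
used in total: with three blocks these are the three projections plus
the head; with fewer blocks the spare layers form a shared
position-wise ReLU stack between attention and head. The layer budget
is fixed but its allocation across blocks is a design choice of this
package.

**SMILES network.** Token ids pass through an embedding of dimension
100 (fixed; the padding id is a frozen zero vector), four stacked LSTM
layers (hidden width 64 by default), self-attention over the time steps
with padding positions masked out of the softmax, masked mean pooling
over the valid positions, and a dense head. Sequence models are
sensitive to notation: two SMILES of the same molecule are different
inputs, which is exactly what the enumeration augmentation exploits.

## Imbalance strategies

All three strategies balance the minority class to 1:1 within the
training and validation partitions separately; the test partition is
never touched (asserted bitwise in the tests).

* **SMOTE** (numeric features; implemented from scratch): each
  synthetic row is `x_i + u (x_nn - x_i)` with `u ~ U(0, 1)` and `x_nn`
  one of the 5 nearest minority neighbours (Euclidean) of a sampled
  minority row, generated in the processed 128-dimensional space.
* **Decoy selection** (either feature kind): a candidate pool is
  filtered by (1) property matching — MW ±25 Da, logP ±1, H-bond
  donors ±1, acceptors ±2, rotatable bonds ±2 of at least one active,
  net charge matched exactly; (2) structural dissimilarity — maximum
  ECFP4 Tanimoto to any active below 0.30; (3) MaxMin diversity
  selection down to the requested count, started from the most distant
  survivor pair. The windows and threshold are configurable defaults in
  the DUD-E tradition; decoys enter as presumed negatives, which is an
  assumption, not a measurement.
* **SMILES enumeration** (token features): randomized atom-renumbered
  notations of minority compounds, each canonicalizing back to its
  parent, deduplicated under a retry cap, parent's label inherited, and
  kept in the parent's partition to avoid leakage.

## Multi-seed evaluation

Every experiment cell (group × experiment × family) is repeated over a
seed list (30 in the full design); the per-seed ACC/F1/AUC are retained
and summarised as mean ± population SD (divisor *n*; sample SD is a
switch). Model pairs are compared with a two-sided Welch t-test at
α = 0.05 — the unequal-variance form because nothing guarantees equal
seed-to-seed variance across model families. Repeated deterministic
fits give zero-variance vectors; the conventions are t = 0, p = 1 for
equal means and "deterministically different, flagged significant" for
unequal means. No multiple-testing correction is applied across the
many pairs; reports flag this. Prediction agreement between two models
is summarised as a four-way partition (both correct / only A / only B /
both wrong) with shared-over-union overlap percentages, and
chemical-space structure is visualised per modality with an in-package
exact t-SNE (perplexity-calibrated Gaussian affinities, early
exaggeration 4 for 100 iterations, adaptive gains, seeded — quadratic
in *n*, intended for thousands of compounds, not millions).

## The synthetic benchmark

The generator emulates the *shape* of a curated inhibitor dataset so
that every pipeline stage is exercisable without any download: 13
hand-written scaffold families (amide-, ether-, amine- and
heterocycle-linked ring systems) with three substitution slots filled
from a 30-fragment substituent list by textual substitution — valid
SMILES by construction, verified by canonicalization at generation.
Potency follows a two-level log-normal model: log10 potency (µM) is
-1.3 (≈ 0.05 µM) when a planted methanesulfonamide pharmacophore is
present and +1.7 (≈ 50 µM) when absent, plus N(0, 0.55²) noise. This
spans roughly 5 nM to 0.5 mM. Three presets pair a pharmacophore
prevalence with a cutoff to realise the study's three regimes: balanced
(p = 0.5 at 0.5 µM), slight (0.6 at 1 µM), severe (0.8 at 10 µM); with
the default noise the realized positive fractions land within a few
points of 50/60/80 %. The default library size is 4500 compounds; the
test suite and acceptance script use 600–2000 and state so where they
do.

What the generator does **not** emulate: real medicinal-chemistry
property distributions, activity cliffs, assay heterogeneity, or
chemotype-specific confounders. A model that recovers the planted rule
here demonstrates that the pipeline is leak-free and the architectures
can learn a substructure signal — not that any architecture will rank
well on a particular real target.

## Numerical choices and degenerate inputs

* Population SD everywhere a mean ± SD is reported; the divisor is a
  stated convention, not an estimate of anything.
* Strict `<` at the activity cutoff; equality is inactive.
* K-means uses k-means++ seeding with 10 restarts and up to 50 Lloyd
  iterations; internal indices are computed per candidate k on the same
  fitted labels.
* Ties in MaxMin selection resolve to the first index; the selection is
  deterministic given the survivor set.
* Constant feature columns: a hard error in the strict standardizer; in
  the model wrappers, aliased logistic coefficients and constant
  columns are tolerated (naive Bayes thresholds vanishing densities).
* All-pad token sequences are rejected; unknown symbols and over-length
  sequences are hard errors rather than silent truncation.
* Every stochastic step (generation, splitting, SMOTE, enumeration,
  search, shuffling, initialization, t-SNE) flows through one seeded
  RNG path; a fixed seed reproduces byte-identical artifacts.

## Limitations

* The chemistry primitives (canonicalization, descriptors,
  fingerprints, enumeration) are delegated to the RDKit toolkit through
  a batched `python` subprocess; the package requires a Python with
  RDKit on the PATH and pins its descriptor panel by name.
* The attention networks run on CPU in R; they are sized for datasets
  of thousands of compounds, not for pretraining-scale corpora.
* Decoy selection assumes the pool compounds are genuinely inactive;
  property matching cannot verify that.
* Exact t-SNE is O(n²) in memory and time.
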
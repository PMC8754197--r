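---
title: "Methods: conservation, dynamics and classification for SAV pathogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation, dynamics and classification for SAV pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savpred)
```

`savpred` predicts whether a single amino acid variant (SAV) is pathogenic
from fifteen features in three categories: sequence conservation, protein
structure, and equilibrium dynamics. This vignette explains the models
behind each native feature, every tunable parameter and its default, what
the synthetic-data generators do and do not emulate, and the numerical and
design choices made where more than one reasonable option existed.

## 1. The variation number

### Model

The variation number of a reference position is the minimal number of
substitutions that must have occurred at that position over the evolutionary
history of an ortholog family, min–max scaled within the protein. Given a
pre-aligned ortholog family, the package:

1. computes pairwise **p-distances** — the fraction of mismatching residues
   over columns where neither sequence has a gap (`-`) or unknown (`X`);
   a pair with no comparable column is assigned the maximal distance 1;
2. builds an unrooted **neighbor-joining** tree from that matrix
   (negative branch-length estimates are clamped to 0);
3. for every alignment column where the reference row is not a gap, computes
   the **Fitch small-parsimony score**: the minimum number of state changes
   over the tree consistent with the observed leaf states. Gaps and `X` act
   as ordinary extra character states — a deletion in an ortholog is an
   evolutionary event, not missing data;
4. **min–max scales** the per-position counts to [0, 1] within the protein.
   0 is maximal conservation; 1 the most variable position. A profile with
   all counts equal is uninformative and maps to all zeros (the
   maximal-conservation reading).

Positions are 1-based indices into the *ungapped* reference sequence,
matching the `R15K` notation of variant tables. Columns gapped in the
reference are skipped so the coordinate system stays well defined.

### Assumptions and choices

* **Parsimony, not likelihood.** Counting minimal changes on a
  distance-based tree is the most direct operationalization of "number of
  variations" and requires no substitution model. Fitch's algorithm is
  exact on binary trees; multifurcations (including the unrooted NJ root)
  are resolved to binary before counting, which does not change the score.
  The score is root-invariant, which the tests verify by rerooting.
* **NJ over p-distances.** Any reasonable tree would do since only the
  per-column change count is consumed; NJ is the canonical fast choice.
  Determinism of the whole profile for a fixed input is what matters and is
  tested.
* **No ortholog filtering.** Classification accuracy is empirically robust
  to ortholog count, so the package does not discard low-quality orthologs;
  the alignment itself is an input (use any external aligner).

## 2. Dynamics features: the anisotropic network model

The Cα trace is modeled as an elastic network: residues closer than a
cutoff `r_c` are connected by Hookean springs of uniform constant γ. The
3N×3N Hessian has off-diagonal 3×3 superblocks −γ r̂ᵢⱼ r̂ᵢⱼᵀ and diagonal
superblocks equal to the negated row sums, so each row-superblock sums to
zero. Its eigenmodes describe equilibrium fluctuations; the six zero modes
of a connected, non-collinear structure are rigid-body motions and are
excluded from all sums.

* **MSD**: `MSD_i` is the trace of the i-th diagonal 3×3 superblock of the
  Hessian pseudo-inverse — the variance of residue i's displacement.
  Reported in units of 1/γ with no kT prefactor: only relative values feed
  the (monotone-invariant) tree classifier.
* **Mechanical stiffness**: the effective force constant when pulling
  residues i and j apart is the inverse compliance
  κᵢⱼ = [Σₖ λₖ⁻¹((u_{k,j} − u_{k,i})·r̂ᵢⱼ)²]⁻¹; residue stiffness is the
  mean of κᵢⱼ over *all* partners j, not only those within the cutoff
  (all-partner averaging is the documented choice; the alternative changes
  only the normalization of a feature consumed by trees). Stiffness is
  linear in γ.
* **Perturbation-response effectiveness and sensitivity**: Pᵢⱼ sums the
  squares of the nine entries of the (i, j) covariance superblock (the
  mean-squared response of residue j to a unit random force on residue i);
  rows are normalized by their diagonal Pᵢᵢ, self terms are excluded, and
  effectiveness/sensitivity are the row/column means of the normalized
  matrix.

**Parameters.** `cutoff = 15` Å and `gamma = 1` are standard ANM practice
for Cα networks; the zero-mode tolerance is `1e-8 · max(λ)`. All three are
arguments of `build_anm()`.

**Degenerate geometry.** A perfectly collinear chain is pathological for the
ANM: besides the five rigid-body modes, every displacement perpendicular to
the axis is unrestrained, so the Hessian null space has dimension 2N + 1.
The package reports the zero-mode count it actually finds and warns when the
network is disconnected (more than six zero modes at the given cutoff).
Tests pin the count to 6 for connected non-collinear structures and 2N + 1
for the collinear fixture.

## 3. Structure features

**Shrake–Rupley SASA.** Each atom sphere is inflated by the probe radius
(default 1.4 Å, a water molecule) and covered with a deterministic
golden-spiral point set (default 960 points/atom); points inside any
neighboring inflated sphere are occluded, and the accessible fraction times
the inflated-sphere area gives the atom's SASA. Residue SASA sums its atoms.
Element radii default to C 1.70, N 1.55, O 1.52, S 1.80 Å (overridable);
Cα-only coarse traces use a single configurable radius (default 1.9 Å).
Quadrature error on the analytic single-sphere case shrinks as the point
count grows; 960 points keep it well under 2%.

**Active site.** A calibrated ligand-binding probability is binarized at a
strict threshold: 1 iff p > 0.5 (exactly 0.5 maps to 0).

**Reference energies.** Mutant reference energy is a lookup
`table[mut]`; the delta is `table[mut] − table[wt]` (antisymmetric by
construction). The packaged default table contains synthetic values on a
Rosetta-like scale because no authoritative constants ship with the method;
production use should supply the table matching the user's energy function.

**Ingested features.** ΔΔG_fold, PSIC/ΔPSIC, ΔE epistatic, the functional
impact score, the mutant statistical scoring function and the active-site
probability are outputs of specialized third-party tools. The package
ingests them from TSV (tab-separated, `.` decimal, empty cell = missing);
unparseable cells become missing values and are counted, duplicate variant
keys are an error.

## 4. The feature table

`assemble_features()` builds one row per SAV in a fixed 15-column order.
Absent provider values are recorded as `NA`, never silently zero; SAVs whose
position exceeds the protein length are excluded into a per-row error
report rather than aborting the batch.

**Labels.** ClinVar-style tables are filtered to at least one review star;
benign, benign/likely benign and likely benign map to 0, likely pathogenic,
pathogenic/likely pathogenic and pathogenic map to 1, case-insensitively.
Any other significance string (e.g. uncertain significance) is dropped and
counted rather than force-labeled.

**Imputation.** Missing cells are filled with the *training-rows-only*
median of the feature. The median is robust to the heavy-tailed energy
features, and restricting to training rows prevents information from
held-out rows leaking into fold evaluation — `kfold_cv()` refits the
imputer inside every fold. A feature with no observed training value is an
error, not a silent zero.

**Feature diagnostics.** `pearson_matrix()` returns the 16×16 correlation
matrix of features plus label (zero-variance columns are flagged undefined);
`pca_cumulative_variance()` z-scores the features and returns the
cumulative explained-variance sequence; `welch_ttest()` is the
unequal-variance t-test (the class variances of the variation number differ
by more than a factor of two, so the pooled-variance test would be
miscalibrated). Its sign follows `mean(first) − mean(second)`; passing the
pathogenic group first yields the conventional negative t. Two constant
equal groups give t = 0 by convention. Features are standardized for PCA
only; the tree-based classifier consumes raw features, being invariant to
monotone transforms.

## 5. Classifier and evaluation protocol

The classifier is an XGBoost tree ensemble with logistic objective.
Learning rate 0.1 is the published configuration; the remaining defaults
(150 rounds, depth 6, no subsampling, `nthread = 1`) are package choices
exposed in `default_xgb_params()` — single-threaded training keeps results
bitwise reproducible for a fixed seed. Hard classification uses a strict
0.5 probability cut (p = 0.5 maps to class 0), the natural threshold for a
probabilistic classifier.

* **Cross-validation**: stratified 10-fold (stratification stabilizes
  per-fold metrics on imbalanced data); fold assignment is a deterministic
  function of the seed; per-fold metrics are the five confusion-count
  statistics plus balanced accuracy, AUROC and AUPR, with pooled held-out
  curves.
* **Metrics**: exact evaluation of
  accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
  specificity = TN/(TN+FP), F1 = TP/(TP+½(FP+FN)),
  MCC = (TP·TN−FP·FN)/√((TP+FN)(TP+FP)(TN+FN)(TN+FP)). A zero-denominator
  metric is reported as 0 with an explicit flag so ablation tables never
  contain holes.
* **Curves**: thresholds sweep distinct scores, tied scores collapse into
  one operating point; AUROC is the trapezoid area (equal to the tie-aware
  pair-ordering probability, which the tests verify exhaustively), AUPR the
  step-interpolated area Σ (Rₖ−Rₖ₋₁)Pₖ.
* **Ablation**: the model is retrained once per feature with that feature
  excluded; rows are sorted by accuracy drop against the full model.
* **Ortholog stratification**: for each threshold, every CV fold's training
  rows are intersected with the SAVs of proteins having at least that many
  orthologs, while evaluation still uses the full held-out rows — the
  leakage-free analogue of "train on the stratum, test on everything".
* **DMS benchmarking**: absolute Spearman ρ (average-rank ties) between
  predictions and experimental fitness scores over shared variants, MSE,
  and coverage = shared/total. Constant predictions leave ρ undefined; it
  is reported as 0 with a flag while the MSE is still computed.

## 6. What the synthetic data does and does not emulate

The generators exist so that every pipeline stage is exercised end to end
with known ground truth.

* `synth_ortholog_family()` evolves sequences along a random binary tree
  with a uniform per-site, per-branch substitution probability (default
  0.05) and a designated never-mutating site set (default 30% of a
  120-column alignment over 24 orthologs). It returns the realized per-site
  substitution events, which upper-bound the parsimony counts — a property
  the tests assert. It has **no** rate heterogeneity, no indel process, and
  no among-lineage rate variation; it validates the machinery, not a model
  of protein evolution.
* `synth_structure()` writes ideal α-helix Cα traces (rise 1.5 Å, 100°
  turn, radius 2.3 Å — consecutive Cα ≈ 3.8 Å), straight lines, and random
  3.8 Å-step coils. Real structures have side chains, irregular secondary
  structure and contact heterogeneity that these fixtures do not.
* `synth_feature_dataset()` draws the variation number from class-
  conditional beta laws moment-matched to the published class statistics
  (pathogenic mean 0.12/variance 0.017, neutral mean 0.32/variance 0.04)
  and plants two further informative features (ΔPSIC shift 1.5, FIS shift
  1.0, both unit variance); the other twelve features are class-independent
  noise, and missingness (default 10%) is planted uniformly in the
  tool-derived columns. `effect_scale = 0` collapses the classes for null
  controls. Real feature matrices have inter-feature correlations and
  structured missingness that this generator deliberately omits — passing
  tests demonstrate signal recovery and calibration of the machinery, not
  clinical-grade accuracy on real variants.
* `synth_dms()` is a strictly monotone transform of prediction scores plus
  Gaussian noise: enough to test the rank-correlation machinery, nothing
  like a real fitness screen.

Problem sizes used by the test suite and the acceptance script (thousands
of SAVs, tens of orthologs, ≤ 40-residue structures) were chosen as the
smallest sizes at which the statistical assertions are stable across seeds.

## 7. Numerical details and degenerate inputs

* Fitch state sets are bitmasks over the observed alphabet (≤ 22 states);
  ties in the NJ distance matrix are resolved by `ape`'s deterministic
  implementation.
* Eigendecomposition uses the symmetric path of LAPACK via `eigen()`;
  zero modes are `λ < 1e-8·max(λ)`. Mode-sum and dense pseudo-inverse
  routes agree to 1e-8 on the test fixtures.
* Min–max scaling of an all-equal profile returns zeros; `minmax_scale` is
  idempotent on profiles already spanning [0, 1].
* The golden-spiral point set is deterministic, so SASA has no Monte-Carlo
  variance; rotation invariance holds to quadrature tolerance (~2% at 960
  points).
* All generators are pure functions of (spec, seed); every CLI subcommand
  rerun with the same seed writes byte-identical files (fixed-format
  numeric rendering in the TSV/JSON writers).

## 8. Known limitations

* The ANM is harmonic: anharmonic motions, multi-state conformational
  changes and solvent effects are outside the model.
* Parsimony counts ignore branch lengths and multiple hits; saturated
  columns undercount substitutions.
* The stiffness average over all partners (rather than within-cutoff
  partners) and the per-row PRS normalization are documented conventions;
  alternatives rescale features but do not change tree-based
  classification.
* The packaged reference-energy table is synthetic; replace it for any
  production energy analysis.
* Reported CV metrics on synthetic data characterize the pipeline, not
  expected performance on ClinVar-scale clinical data.
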
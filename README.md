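# savpred

Pathogenicity prediction for missense variants (single amino acid variants,
SAVs) from a 15-feature pipeline spanning evolutionary conservation, protein
structure and equilibrium dynamics, with a gradient-boosted classifier and a
full cross-validated evaluation protocol. The package is aimed at
computational biologists who want the feature computations, the classifier
and the benchmarking machinery as composable, tested R functions rather than
a monolithic web service.

## What it computes

**Variation number** — a per-position conservation score from ortholog
sequences. For an aligned ortholog family, each alignment column (where the
reference has no gap) is assigned the minimal number of substitutions over a
phylogeny of the orthologs, i.e. the Fitch small-parsimony score of that
column on a neighbor-joining tree built from pairwise p-distances. Counts
are min–max scaled to [0, 1] within each protein: 0 = fully conserved,
1 = most variable position. Pathogenic variants concentrate at low variation
numbers.

**Dynamics features** — from the anisotropic network model (ANM) on the Cα
trace: springs of constant γ connect residues within 15 Å; the 3N×3N Hessian
has off-diagonal superblocks −γ r̂ᵢⱼ r̂ᵢⱼᵀ. From its eigenmodes the package
computes per-residue mean squared displacement (diagonal of the Hessian
pseudo-inverse), mechanical stiffness (inverse pairwise compliance
κᵢⱼ = [Σₖ λₖ⁻¹((u_{k,j}−u_{k,i})·r̂ᵢⱼ)²]⁻¹ averaged over partners), and
perturbation-response effectiveness and sensitivity (row/column means of the
diagonal-normalized squared-covariance block sums).

**Structure features** — solvent accessible surface area by the
Shrake–Rupley algorithm (golden-spiral test points, 1.4 Å probe), a
binarized active-site flag (probability strictly > 0.5), and unfolded-state
reference-energy features from a configurable per-amino-acid table.

**Ingested features** — tool-derived quantities (ΔΔG_fold, PSIC and ΔPSIC,
epistatic ΔE, functional impact score, mutant statistical scoring function,
active-site probability) are read from TSV, never recomputed.

**Classifier and evaluation** — an XGBoost ensemble (learning rate 0.1)
trained on the 15-feature matrix with ClinVar-style labels (benign /
likely benign → 0, pathogenic / likely pathogenic → 1, ≥ 1 review star),
with training-fold median imputation, stratified 10-fold cross-validation
reporting accuracy, sensitivity, specificity, F1, MCC, balanced accuracy and
tie-aware ROC/PR curves, leave-one-feature-out ablation, ortholog-count
stratification, and deep-mutational-scanning benchmarking (absolute Spearman
ρ, MSE, coverage).

A synthetic-data module generates ortholog families evolved along random
trees, idealized Cα structures, class-conditional feature datasets
(variation numbers follow beta laws moment-matched to the published class
statistics: pathogenic mean 0.12, variance 0.017; neutral mean 0.32,
variance 0.04) and simulated DMS tables, so the entire pipeline runs and is
tested without any downloads.

## Worked example

```r
library(savpred)

# 1. conservation: simulate an ortholog family, build the profile
fam  <- synth_ortholog_family(fixture_spec(seed = 42, n_orthologs = 20,
                                           seq_length = 60,
                                           conserved_fraction = 0.4,
                                           subst_rate = 0.08))
prof <- variation_profile(fam$alignment)   # NJ tree from p-distances
prof
#> variation-number profile for REF: 60 positions, raw counts 0..7
mean(prof$scaled[fam$conserved_sites])     #> 0     (never-mutating sites)
mean(prof$scaled[-fam$conserved_sites])    #> 0.48  (freely mutating sites)

# 2. dynamics: ANM features on an idealized helix
model <- parse_ca_coords(synth_structure(25, "helix"))
head(dynamics_profile(model), 3)
#>   chain resno      msd stiffness effectiveness sensitivity
#> 1     A     1 5.291598  2.194009     0.0697055   0.3418411
#> 2     A     2 3.676962  2.320923     0.1062676   0.2391229
#> 3     A     3 2.830904  2.381980     0.1152959   0.1742733

# 3. classification: synthetic labeled dataset, 10-fold CV
dat <- synth_feature_dataset(fixture_spec(seed = 42, n_sav_per_class = 1000,
                                          missingness = 0.1))
kfold_cv(dat$features, dat$labels, k = 10, seed = 42)
#> 10-fold CV: accuracy 0.8405±0.0260, AUROC 0.9210±0.0185, AUPR 0.9221±0.0219

m <- train_sav_classifier(impute_features(dat$features), dat$labels,
                          list(seed = 42))
sort(m$importance, decreasing = TRUE)[1:4]
#>       delta_psic variation_number              fis        stiffness
#>            0.350            0.248            0.109            0.034

v <- dat$features$variation_number
welch_ttest(v[dat$labels == 1], v[dat$labels == 0])$t
#> -27.33  (pathogenic SAVs are more conserved)
```

The CV lines read: held-out accuracy ~0.84 and AUROC ~0.92 on a dataset
whose only class signal is the variation-number moments plus two planted
feature shifts; the importance ranking recovers exactly the planted
features; the negative Welch t confirms pathogenic variants sit at lower
variation numbers.

## Command line

A thin Rscript front end wraps the same functions:

```sh
inst/cli/savpred synth --type features --n 500 --seed 7 --out feats.tsv
inst/cli/savpred eval  --features feats.tsv --k 10 --seed 7 --out metrics.json
inst/cli/savpred vn    --fasta orthologs.fa --ref REF --out vn.tsv
```

Subcommands: `synth`, `vn`, `dyn`, `sasa`, `ingest`, `train`, `eval`,
`ablate`, `stratify`, `bench-dms`. Reruns with the same seed produce
byte-identical outputs.

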
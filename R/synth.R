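#' Specification of the synthetic study conditions
#'
#' Bundles every knob of the synthetic-data generators. The class-conditional
#' variation-number distributions default to beta laws moment-matched to the
#' published class statistics (pathogenic mean 0.12, variance 0.017; neutral
#' mean 0.32, variance 0.04); two further informative features (delta PSIC
#' and the functional impact score) carry unit-variance normal class shifts,
#' and all remaining features are exchangeable unit-variance noise.
#' `effect_scale = 0` collapses both classes onto the neutral distributions
#' (a null dataset for permutation-style controls).
#'
#' @param seed Base RNG seed.
#' @param n_proteins Number of synthetic proteins SAVs are spread over.
#' @param n_orthologs Ortholog sequences per family.
#' @param seq_length Alignment length (columns).
#' @param conserved_fraction Fraction of sites that never mutate.
#' @param subst_rate Per-site, per-branch substitution probability.
#' @param n_sav_per_class Labeled SAVs per class in the feature dataset.
#' @param missingness Probability that a tool-derived feature cell is missing.
#' @param vn_pathogenic,vn_neutral Mean/variance pairs of the class
#'   variation-number beta distributions.
#' @param shift_delta_psic,shift_fis Class-1 mean shifts of the two planted
#'   normal features.
#' @param effect_scale Multiplier on all class separations (0 = null data).
#' @param dms_noise_sd Gaussian noise added by [synth_dms()].
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_proteins = 10L, n_orthologs = 24L,
                         seq_length = 120L, conserved_fraction = 0.3,
                         subst_rate = 0.05, n_sav_per_class = 1000L,
                         missingness = 0.1,
                         vn_pathogenic = c(mean = 0.12, var = 0.017),
                         vn_neutral = c(mean = 0.32, var = 0.04),
                         shift_delta_psic = 1.5, shift_fis = 1.0,
                         effect_scale = 1, dms_noise_sd = 0.1) {
  spec <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
               n_orthologs = as.integer(n_orthologs),
               seq_length = as.integer(seq_length),
               conserved_fraction = conserved_fraction,
               subst_rate = subst_rate,
               n_sav_per_class = as.integer(n_sav_per_class),
               missingness = missingness,
               vn_pathogenic = vn_pathogenic, vn_neutral = vn_neutral,
               shift_delta_psic = shift_delta_psic, shift_fis = shift_fis,
               effect_scale = effect_scale, dms_noise_sd = dms_noise_sd)
  stopifnot(spec$n_orthologs >= 2, spec$seq_length >= 1,
            spec$conserved_fraction >= 0, spec$conserved_fraction <= 1,
            spec$subst_rate >= 0, spec$subst_rate <= 1,
            spec$missingness >= 0, spec$missingness <= 1,
            spec$dms_noise_sd >= 0)
  class(spec) <- "fixture_spec"
  spec
}

# beta shape parameters matched to a (mean, variance) pair
.beta_moments <- function(mean, var) {
  if (var <= 0 || var >= mean * (1 - mean))
    stop("infeasible beta moments: need 0 < var < mean*(1-mean)", call. = FALSE)
  nu <- mean * (1 - mean) / var - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Simulate an ortholog family by substitutions along a random tree
#'
#' Draws a random binary tree over the orthologs, a random root sequence,
#' and evolves it along the tree: at every branch each non-conserved site
#' mutates with probability `subst_rate` to a uniformly chosen different
#' residue. Designated conserved sites never mutate. The realized number of
#' substitution events per site is returned as ground truth (Fitch parsimony
#' can never exceed it).
#'
#' @param spec A [fixture_spec()].
#' @return List: `alignment` (an [parse_alignment()]-compatible
#'   `ortholog_alignment`, reference = first tip), `tree` (the generating
#'   [ape::phylo]), `true_counts` (substitution events per site),
#'   `conserved_sites` (indices).
#' @export
synth_ortholog_family <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- spec$n_orthologs; len <- spec$seq_length
  tips <- c("REF", sprintf("ORTH%03d", seq_len(n - 1L)))
  tree <- if (n == 2L)
    ape::read.tree(text = sprintf("(%s:0.5,%s:0.5);", tips[1], tips[2]))
  else ape::rtree(n, tip.label = sample(tips))
  n_cons <- round(spec$conserved_fraction * len)
  conserved <- sort(sample.int(len, n_cons))
  variable <- setdiff(seq_len(len), conserved)
  root_seq <- sample(aa, len, replace = TRUE)
  counts <- integer(len)
  ntotal <- length(tree$tip.label) + tree$Nnode
  seqs <- vector("list", ntotal)
  root <- length(tree$tip.label) + 1L
  seqs[[root]] <- root_seq
  # cladewise edge order lists every parent before its children
  edge <- stats::reorder(tree, "cladewise")$edge
  for (r in seq_len(nrow(edge))) {
    e <- edge[r, ]
    parent_seq <- seqs[[e[1L]]]
    child <- parent_seq
    if (length(variable)) {
      hit <- variable[stats::runif(length(variable)) < spec$subst_rate]
      for (s in hit) {
        child[s] <- sample(setdiff(aa, child[s]), 1L)
        counts[s] <- counts[s] + 1L
      }
    }
    seqs[[e[2L]]] <- child
  }
  rows <- vapply(seq_along(tree$tip.label),
                 function(i) paste0(seqs[[i]], collapse = ""), character(1))
  names(rows) <- tree$tip.label
  rows <- rows[tips]  # stable row order independent of tree layout
  aln <- structure(list(sequence_ids = tips, rows = rows, reference_id = "REF"),
                   class = "ortholog_alignment")
  list(alignment = aln, tree = tree, true_counts = counts,
       conserved_sites = conserved)
}

#' Generate an idealized Cα trace as PDB text
#'
#' Geometries: `"helix"` (ideal alpha helix: 1.5 Å rise, 100 degree turn,
#' 2.3 Å radius — consecutive Cα about 3.8 Å apart), `"line"` (collinear
#' 3.8 Å spacing; its elastic network has 5 rigid-body modes), and
#' `"random-coil"` (random 3.8 Å steps).
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry One of "helix", "line", "random-coil".
#' @param seed RNG seed (used by random-coil only).
#' @param chain Chain identifier letter.
#' @return PDB text (single string of ATOM records + END).
#' @export
synth_structure <- function(n_residues, geometry = c("helix", "line", "random-coil"),
                            seed = 1L, chain = "A") {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 2)
  i <- seq_len(n_residues)
  xyz <- switch(geometry,
    helix = {
      ang <- (i - 1L) * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), (i - 1L) * 1.5)
    },
    line = cbind((i - 1L) * 3.8, 0, 0),
    "random-coil" = {
      set.seed(seed)
      dirs <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(rbind(0, dirs[-1, , drop = FALSE] * 3.8), 2L, cumsum)
    })
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    i, chain, i, xyz[, 1], xyz[, 2], xyz[, 3])
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a labeled synthetic SAV feature dataset
#'
#' Draws `n_sav_per_class` SAVs per class. The variation number follows the
#' class-conditional beta distributions of the spec; `delta_psic` and `fis`
#' are unit-variance normals with the spec's class-1 mean shifts (times
#' `effect_scale`); all other features are class-independent noise
#' (`active_site` a Bernoulli flag, the rest standard normals). Missingness
#' is planted uniformly at random in the tool-derived columns. SAVs are
#' assigned round-robin to `n_proteins` synthetic proteins, each with an
#' ortholog count drawn uniformly from 30..400.
#'
#' @param spec A [fixture_spec()].
#' @return List: `features` (a `sav_features` data.frame with key columns,
#'   `label` and the 15 features), `labels`, `protein_id` and
#'   `ortholog_counts` per row, `spec`.
#' @export
synth_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n1 <- spec$n_sav_per_class
  n <- 2L * n1
  labels <- rep(c(0L, 1L), each = n1)
  es <- spec$effect_scale
  # interpolate pathogenic moments toward neutral as the effect shrinks
  m1 <- spec$vn_neutral[["mean"]] +
    es * (spec$vn_pathogenic[["mean"]] - spec$vn_neutral[["mean"]])
  v1 <- spec$vn_neutral[["var"]] +
    es * (spec$vn_pathogenic[["var"]] - spec$vn_neutral[["var"]])
  b0 <- .beta_moments(spec$vn_neutral[["mean"]], spec$vn_neutral[["var"]])
  b1 <- .beta_moments(m1, v1)
  feats <- data.frame(
    variation_number = c(stats::rbeta(n1, b0["shape1"], b0["shape2"]),
                         stats::rbeta(n1, b1["shape1"], b1["shape2"])),
    delta_e_epistatic = stats::rnorm(n),
    fis = stats::rnorm(n) + labels * spec$shift_fis * es,
    delta_psic = stats::rnorm(n) + labels * spec$shift_delta_psic * es,
    wt_psic = stats::rnorm(n),
    ddg_fold = stats::rnorm(n),
    sasa = stats::rnorm(n),
    mutant_ssf = stats::rnorm(n),
    active_site = stats::rbinom(n, 1L, 0.3),
    mutant_ref_energy = stats::rnorm(n),
    delta_ref_energy = stats::rnorm(n),
    msd = stats::rnorm(n),
    stiffness = stats::rnorm(n),
    effectiveness = stats::rnorm(n),
    sensitivity = stats::rnorm(n))
  feats <- feats[, feature_names()]
  if (spec$missingness > 0) {
    droppable <- c("delta_e_epistatic", "fis", "delta_psic", "wt_psic",
                   "ddg_fold", "mutant_ssf", "active_site")
    for (col in droppable)
      feats[[col]][stats::runif(n) < spec$missingness] <- NA
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  protein_id <- sprintf("P%03d", rep_len(seq_len(spec$n_proteins), n))
  wt <- sample(aa, n, replace = TRUE)
  mut <- vapply(wt, function(a) sample(setdiff(aa, a), 1L), character(1))
  savs <- data.frame(protein_id = protein_id,
                     position = sample.int(spec$seq_length, n, replace = TRUE),
                     wt_aa = wt, mut_aa = unname(mut), label = labels)
  per_protein <- stats::setNames(sample(30:400, spec$n_proteins, replace = TRUE),
                                 sprintf("P%03d", seq_len(spec$n_proteins)))
  out <- cbind(savs, feats)
  class(out) <- c("sav_features", "data.frame")
  list(features = out, labels = labels, protein_id = protein_id,
       ortholog_counts = unname(per_protein[protein_id]), spec = spec)
}

#' Generate a synthetic DMS score table from model scores
#'
#' DMS fitness is simulated as a strictly decreasing linear transform of the
#' pathogenicity scores (high fitness = benign) plus Gaussian noise.
#'
#' @param model_scores Numeric pathogenicity scores.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param variant Optional variant identifiers (default V1..Vn).
#' @return data.frame with columns `variant`, `dms_score`.
#' @export
synth_dms <- function(model_scores, noise_sd = 0.1, seed = 1L,
                      variant = sprintf("V%d", seq_along(model_scores))) {
  stopifnot(noise_sd >= 0, length(variant) == length(model_scores))
  set.seed(seed)
  data.frame(variant = variant,
             dms_score = 1 - model_scores +
               stats::rnorm(length(model_scores), 0, noise_sd))
}
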
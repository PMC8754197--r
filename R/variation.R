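#' Per-position variation-number profile of a protein
#'
#' The variation number is a per-position conservation score computed from an
#' ortholog alignment: the minimal number of substitutions at that alignment
#' column over a phylogenetic tree of the orthologs (Fitch small parsimony),
#' min-max scaled to [0, 1] within the protein. 0 means highly conserved,
#' 1 highly variable. Columns where the reference row carries a gap are
#' skipped, so positions index the ungapped reference sequence (1-based),
#' matching SAV notation such as `R15K`.
#'
#' @param aln An [`parse_alignment()`] result.
#' @param tree Optional [ape::phylo] over the alignment's sequence ids; if
#'   `NULL`, a neighbor-joining tree is built from the p-distance matrix.
#' @param protein_id Identifier stored in the profile (defaults to the
#'   alignment's reference id).
#' @return A `vn_profile`: list with `protein_id`, `positions` (1-based,
#'   ungapped reference coordinates), `wt_aa` (reference residues),
#'   `raw_counts` (per-position parsimony counts) and `scaled` (min-max
#'   scaled variation numbers in [0, 1]).
#' @export
variation_profile <- function(aln, tree = NULL, protein_id = aln$reference_id) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  if (is.null(tree)) tree <- neighbor_joining(p_distance(aln))
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, aln$sequence_ids))
    stop("tree leaves do not match alignment sequence ids", call. = FALSE)
  m <- alignment_matrix(aln)
  ref <- m[aln$reference_id, ]
  keep <- which(ref != "-")
  if (length(keep) == 0L)
    stop("reference row is all gaps", call. = FALSE)
  # identical columns recur constantly in real alignments; count each
  # distinct column pattern once
  cols <- apply(m[, keep, drop = FALSE], 2L, paste0, collapse = "")
  uniq <- unique(cols)
  per_pattern <- vapply(uniq, function(p) {
    st <- strsplit(p, "")[[1]]
    names(st) <- rownames(m)
    fitch_count(tree, st)
  }, integer(1))
  raw <- unname(per_pattern[match(cols, uniq)])
  structure(list(protein_id = protein_id,
                 positions = seq_along(keep),
                 wt_aa = unname(ref[keep]),
                 raw_counts = raw,
                 scaled = minmax_scale(raw)),
            class = "vn_profile")
}

#' Min-max scale a vector of counts to [0, 1]
#'
#' `(x - min) / (max - min)`; when all values are equal the profile is
#' uninformative and every position is mapped to 0 (the maximal-conservation
#' reading).
#'
#' @param x Nonempty numeric vector.
#' @return Numeric vector of the same length, within [0, 1].
#' @export
minmax_scale <- function(x) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Scaled variation number at one SAV position
#'
#' @param profile A [variation_profile()] result.
#' @param position 1-based position on the ungapped reference sequence.
#' @return The scaled variation number at that position.
#' @export
vn_for_sav <- function(profile, position) {
  stopifnot(inherits(profile, "vn_profile"))
  n <- length(profile$positions)
  if (length(position) != 1L || is.na(position) || position < 1 || position > n)
    stop(sprintf("position %s out of range for protein %s (length %d)",
                 as.character(position), profile$protein_id, n), call. = FALSE)
  profile$scaled[[as.integer(position)]]
}

#' @export
print.vn_profile <- function(x, ...) {
  cat(sprintf("variation-number profile for %s: %d positions, raw counts %d..%d\n",
              x$protein_id, length(x$positions), min(x$raw_counts),
              max(x$raw_counts)))
  invisible(x)
}

#' Write a variation-number profile as TSV
#'
#' Columns: protein_id, position, wild_type_aa, raw_count, scaled_vn.
#'
#' @param profile A `vn_profile`.
#' @param path Output file.
#' @return The data frame written, invisibly.
#' @export
write_vn_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "vn_profile"))
  df <- data.frame(protein_id = profile$protein_id,
                   position = profile$positions,
                   wild_type_aa = profile$wt_aa,
                   raw_count = profile$raw_counts,
                   scaled_vn = sprintf("%.6f", profile$scaled))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
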
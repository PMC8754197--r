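#' Binarize an active-site (ligand-binding) probability
#'
#' A residue is flagged as active-site (1) when its calibrated
#' ligand-binding probability is strictly greater than 0.5, else 0.
#'
#' @param prob Probability in [0, 1] (vectorized).
#' @return Integer vector of 0/1 flags.
#' @export
binarize_active_site <- function(prob) {
  if (any(is.na(prob)) || any(prob < 0 | prob > 1))
    stop("active-site probability must lie in [0, 1]", call. = FALSE)
  as.integer(prob > 0.5)
}

#' Load an unfolded-state reference-energy table
#'
#' Reads a two-column TSV (`aa`, `energy`) mapping each of the 20 standard
#' amino acids to an unfolded-state reference energy (score units). The
#' packaged default table (`inst/extdata/reference_energies_default.tsv`)
#' contains synthetic placeholder values on a Rosetta-like scale; supply your
#' own table for production use.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return Named numeric vector of length 20.
#' @export
load_reference_energies <- function(path = system.file("extdata",
                                                       "reference_energies_default.tsv",
                                                       package = "savpred")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- stats::setNames(df$energy, df$aa)
  validate_reference_energies(tab)
  tab
}

#' @rdname load_reference_energies
#' @param table Named numeric vector to validate.
#' @export
validate_reference_energies <- function(table) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(names(table), aa20) || length(table) != 20L)
    stop("reference-energy table must cover exactly the 20 amino acids",
         call. = FALSE)
  if (any(!is.finite(table))) stop("non-finite reference energy", call. = FALSE)
  invisible(table)
}

#' Mutant and delta reference-energy features for one substitution
#'
#' @param wt_aa,mut_aa Single amino-acid letters.
#' @param table Reference-energy table, see [load_reference_energies()].
#' @return Named numeric vector: `mutant_ref_energy` (= table[mut]) and
#'   `delta_ref_energy` (= table[mut] - table[wt]).
#' @export
reference_energy_features <- function(wt_aa, mut_aa, table) {
  for (aa in c(wt_aa, mut_aa))
    if (!aa %in% names(table))
      stop("unknown residue letter '", aa, "'", call. = FALSE)
  c(mutant_ref_energy = unname(table[[mut_aa]]),
    delta_ref_energy = unname(table[[mut_aa]] - table[[wt_aa]]))
}

#' Ingest a table of tool-derived SAV features
#'
#' Reads a TSV of precomputed per-variant features (folding free energy
#' change, PSIC profile scores, epistatic energy change, functional impact
#' score, mutant statistical scoring function, active-site probability).
#' Records are keyed by (protein_id, position, wt_aa, mut_aa); unparseable
#' numeric cells and empty cells become missing values (NA), counted in the
#' `n_missing_cells` attribute. The dialect is tab-separated, '.' decimal,
#' empty cell = missing.
#'
#' @param tsv Path to a TSV file or TSV text. Required key columns:
#'   `protein_id`, `position`, `wt_aa`, `mut_aa`; recognized feature columns:
#'   `ddg_fold`, `wt_psic`, `delta_psic`, `delta_e_epistatic`, `fis`,
#'   `mutant_ssf`, `active_site_prob`.
#' @return data.frame of records (one per key) with NA for missing cells.
#' @export
ingest_external_features <- function(tsv) {
  df <- .read_tsv(tsv)
  keys <- c("protein_id", "position", "wt_aa", "mut_aa")
  missing_cols <- setdiff(keys, names(df))
  if (length(missing_cols))
    stop("external feature table lacks key column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$position <- as.integer(df$position)
  feat_cols <- intersect(external_feature_names(), names(df))
  n_missing <- 0L
  for (col in feat_cols) {
    raw <- as.character(df[[col]])
    raw[!nzchar(trimws(raw))] <- NA
    num <- suppressWarnings(as.numeric(raw))
    n_missing <- n_missing + sum(is.na(num))
    df[[col]] <- num
  }
  key <- do.call(paste, c(df[keys], sep = ":"))
  if (anyDuplicated(key))
    stop("duplicate variant keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (n_missing > 0L)
    message(n_missing, " missing/unparseable feature cells ingested as NA")
  out <- df[c(keys, feat_cols)]
  attr(out, "n_missing_cells") <- n_missing
  out
}

#' Canonical names of the tool-derived feature columns
#' @return Character vector of the 7 ingested feature names.
#' @export
external_feature_names <- function() {
  c("delta_e_epistatic", "fis", "delta_psic", "wt_psic", "ddg_fold",
    "mutant_ssf", "active_site_prob")
}

.read_tsv <- function(tsv) {
  if (length(tsv) == 1L && !grepl("\n", tsv, fixed = TRUE) && file.exists(tsv))
    return(utils::read.delim(tsv, stringsAsFactors = FALSE,
                             colClasses = "character"))
  utils::read.delim(text = paste(tsv, collapse = "\n"),
                    stringsAsFactors = FALSE, colClasses = "character")
}
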
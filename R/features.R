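#' Canonical names and order of the 15 model features
#'
#' Sequence features: variation number, epistatic energy change, functional
#' impact score, delta and wild-type PSIC. Structure features: folding free
#' energy change, SASA, mutant statistical scoring function, binarized
#' active-site flag, mutant and delta unfolded-state reference energies.
#' Dynamics features: MSD, mechanical stiffness, PRS effectiveness and
#' sensitivity.
#'
#' @return Character vector of length 15, fixed order.
#' @export
feature_names <- function() {
  c("variation_number", "delta_e_epistatic", "fis", "delta_psic", "wt_psic",
    "ddg_fold", "sasa", "mutant_ssf", "active_site", "mutant_ref_energy",
    "delta_ref_energy", "msd", "stiffness", "effectiveness", "sensitivity")
}

#' Parse a SAV string such as "R15K"
#' @param x Character vector of `<wt><position><mut>` variant strings.
#' @return data.frame with wt_aa, position, mut_aa.
#' @export
parse_sav <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("unparseable SAV string(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  out <- data.frame(wt_aa = toupper(vapply(m, `[`, "", 2L)),
                    position = as.integer(vapply(m, `[`, "", 3L)),
                    mut_aa = toupper(vapply(m, `[`, "", 4L)))
  if (any(out$wt_aa == out$mut_aa))
    stop("synonymous variant(s) (wt == mut): ",
         paste(x[out$wt_aa == out$mut_aa], collapse = ", "), call. = FALSE)
  out
}

#' Label SAVs from a ClinVar-style table
#'
#' Keeps rows with at least one review star; maps clinical significance
#' case-insensitively to the binary pathogenicity label: benign,
#' benign/likely benign and likely benign give 0, while likely pathogenic,
#' pathogenic/likely pathogenic and pathogenic give 1. Rows with any other
#' significance string (e.g. uncertain significance) are dropped and
#' counted.
#'
#' @param tsv Path or TSV text with columns `protein_id`, `variant` (e.g.
#'   "R15K"), `clinical_significance`, `review_stars`.
#' @return data.frame with protein_id, position, wt_aa, mut_aa, label; the
#'   attributes `n_dropped_stars` and `n_dropped_significance` count removed
#'   rows.
#' @export
label_from_clinvar <- function(tsv) {
  df <- .read_tsv(tsv)
  need <- c("protein_id", "variant", "clinical_significance", "review_stars")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ClinVar table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stars <- suppressWarnings(as.numeric(df$review_stars))
  keep_stars <- !is.na(stars) & stars >= 1
  n_stars <- sum(!keep_stars)
  df <- df[keep_stars, , drop = FALSE]
  sig <- tolower(trimws(df$clinical_significance))
  benign <- c("benign", "benign/likely benign", "likely benign")
  pathogenic <- c("likely pathogenic", "pathogenic/likely pathogenic",
                  "pathogenic")
  label <- ifelse(sig %in% benign, 0L, ifelse(sig %in% pathogenic, 1L, NA))
  n_sig <- sum(is.na(label))
  if (n_sig > 0L)
    message(n_sig, " SAV(s) with unrecognized clinical significance dropped")
  df <- df[!is.na(label), , drop = FALSE]
  out <- cbind(data.frame(protein_id = df$protein_id), parse_sav(df$variant))
  out$label <- label[!is.na(label)]
  rownames(out) <- NULL
  attr(out, "n_dropped_stars") <- n_stars
  attr(out, "n_dropped_significance") <- n_sig
  out
}

#' Assemble the 15-feature matrix for a set of SAVs
#'
#' One row per SAV, columns in [feature_names()] order. Native providers
#' (variation-number profiles, dynamics tables, SASA tables) are keyed by
#' protein id and residue position; tool-derived features come from an
#' [ingest_external_features()] table; reference-energy features are computed
#' from the substitution itself. Absent provider values are recorded as NA,
#' never silently zero. SAVs whose position exceeds the protein's
#' variation-number profile are excluded and reported in the `row_errors`
#' attribute.
#'
#' @param savs data.frame with protein_id, position, wt_aa, mut_aa and
#'   optionally label.
#' @param vn_profiles Named list of [variation_profile()] results, keyed by
#'   protein id.
#' @param dynamics Named list of [dynamics_profile()] data frames.
#' @param sasa Named list of per-residue SASA data frames (resno, sasa) or
#'   `sasa_profile` objects.
#' @param external [ingest_external_features()] data.frame, or NULL.
#' @param ref_table Reference-energy table ([load_reference_energies()]).
#' @return A data.frame of class `sav_features`: key columns, optional
#'   `label`, then the 15 features. Attribute `row_errors` lists excluded
#'   rows and reasons.
#' @export
assemble_features <- function(savs, vn_profiles = list(), dynamics = list(),
                              sasa = list(), external = NULL,
                              ref_table = load_reference_energies()) {
  keys <- c("protein_id", "position", "wt_aa", "mut_aa")
  stopifnot(all(keys %in% names(savs)))
  key <- do.call(paste, c(savs[keys], sep = ":"))
  if (anyDuplicated(key))
    stop("duplicate SAV keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  validate_reference_energies(ref_table)
  n <- nrow(savs)
  feats <- as.data.frame(matrix(NA_real_, n, 15,
                                dimnames = list(NULL, feature_names())))
  errors <- character(n)

  for (r in seq_len(n)) {
    pid <- savs$protein_id[r]; pos <- savs$position[r]
    prof <- vn_profiles[[pid]]
    if (!is.null(prof)) {
      if (pos < 1 || pos > length(prof$positions)) {
        errors[r] <- sprintf("position %d beyond protein %s length %d",
                             pos, pid, length(prof$positions))
        next
      }
      feats$variation_number[r] <- prof$scaled[[pos]]
    }
    dyn <- dynamics[[pid]]
    if (!is.null(dyn)) {
      i <- match(pos, dyn$resno)
      if (!is.na(i)) {
        feats$msd[r] <- dyn$msd[i]
        feats$stiffness[r] <- dyn$stiffness[i]
        feats$effectiveness[r] <- dyn$effectiveness[i]
        feats$sensitivity[r] <- dyn$sensitivity[i]
      }
    }
    sa <- sasa[[pid]]
    if (inherits(sa, "sasa_profile")) sa <- sa$residue
    if (!is.null(sa)) {
      i <- match(pos, sa$resno)
      if (!is.na(i)) feats$sasa[r] <- as.numeric(sa$sasa[i])
    }
    re <- reference_energy_features(savs$wt_aa[r], savs$mut_aa[r], ref_table)
    feats$mutant_ref_energy[r] <- re[["mutant_ref_energy"]]
    feats$delta_ref_energy[r] <- re[["delta_ref_energy"]]
  }

  if (!is.null(external)) {
    ext_key <- do.call(paste, c(external[keys], sep = ":"))
    i <- match(key, ext_key)
    for (col in intersect(external_feature_names(), names(external))) {
      target <- if (col == "active_site_prob") "active_site" else col
      vals <- external[[col]][i]
      if (col == "active_site_prob") {
        ok <- !is.na(vals)
        out <- rep(NA_real_, n)
        out[ok] <- binarize_active_site(vals[ok])
        vals <- out
      }
      feats[[target]] <- vals
    }
  }

  bad <- nzchar(errors)
  out <- cbind(savs[!bad, c(keys, intersect("label", names(savs))), drop = FALSE],
               feats[!bad, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("sav_features", "data.frame")
  attr(out, "row_errors") <- data.frame(key = key[bad], reason = errors[bad])
  if (any(bad))
    message(sum(bad), " SAV(s) excluded; see attr(x, 'row_errors')")
  out
}

#' Impute missing feature cells with training-fold medians
#'
#' Each NA cell of a feature column is replaced with the median of that
#' feature over the training rows only, so no information leaks from held-out
#' rows into the fill values.
#'
#' @param x A `sav_features` data.frame (or any data.frame containing the
#'   [feature_names()] columns).
#' @param training_rows Logical or integer index of rows whose observed
#'   values define the medians; defaults to all rows.
#' @return `x` with NAs filled; attribute `imputation_log` records per-feature
#'   fill counts and medians.
#' @export
impute_features <- function(x, training_rows = seq_len(nrow(x))) {
  cols <- intersect(feature_names(), names(x))
  train <- x[training_rows, cols, drop = FALSE]
  log <- data.frame(feature = cols, n_imputed = 0L, fill = NA_real_)
  for (i in seq_along(cols)) {
    col <- cols[i]
    med <- stats::median(train[[col]], na.rm = TRUE)
    if (is.na(med))
      stop("feature '", col, "' has no observed training value", call. = FALSE)
    nas <- is.na(x[[col]])
    x[[col]][nas] <- med
    log$n_imputed[i] <- sum(nas)
    log$fill[i] <- med
  }
  attr(x, "imputation_log") <- log
  x
}

#' Feature columns of a sav_features table as a numeric matrix
#' @param x A `sav_features` data.frame.
#' @return Numeric matrix, columns in [feature_names()] order.
#' @export
feature_matrix <- function(x) {
  cols <- intersect(feature_names(), names(x))
  as.matrix(x[, cols, drop = FALSE])
}

#' Pearson correlation matrix of features plus label
#'
#' @param x Feature table/matrix (15 columns).
#' @param labels 0/1 labels aligned to rows.
#' @return 16 x 16 symmetric correlation matrix (unit diagonal); columns with
#'   zero variance yield NA rows/columns and are listed in the `undefined`
#'   attribute.
#' @export
pearson_matrix <- function(x, labels) {
  m <- cbind(feature_matrix(x), label = as.numeric(labels))
  if (nrow(m) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (anyNA(m)) stop("impute missing values before correlation", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(m))
  diag(cm) <- 1
  attr(cm, "undefined") <- colnames(m)[sds == 0]
  cm
}

#' Cumulative explained variance of the principal components
#'
#' Features are z-score standardized, then the k-th entry is the fraction of
#' total variance captured by the top k principal components; the sequence is
#' nondecreasing and ends at 1.
#'
#' @param x Feature table/matrix.
#' @return Numeric vector of cumulative variance fractions.
#' @export
pca_cumulative_variance <- function(x) {
  m <- feature_matrix(x)
  if (anyNA(m)) stop("impute missing values before PCA", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (all(sds == 0)) stop("constant matrix: no variance to decompose", call. = FALSE)
  if (any(sds == 0))
    stop("zero-variance feature(s) cannot be standardized: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  cumsum(pc$sdev^2) / sum(pc$sdev^2)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with the sign of `mean(group_a) -
#' mean(group_b)`: for the pathogenic-minus-neutral convention, pass the
#' pathogenic group first. When both groups are constant with equal means,
#' t = 0 and p = 1 by convention.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p` (two-sided) and `df`.
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0,
                df = NA_real_))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}
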
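#' Parse a pre-aligned ortholog FASTA into an alignment object
#'
#' Reads a multi-record FASTA (wrapped lines allowed) containing aligned
#' ortholog protein sequences and returns an `ortholog_alignment`: rows are
#' species, columns are alignment positions. Residues are uppercased; the
#' alphabet is the 20 amino-acid letters plus `X` (unknown) and `-` (gap).
#'
#' @param fasta Either a path to a FASTA file or FASTA text itself (a single
#'   string containing `">"`, or a character vector of lines).
#' @param reference_id Record id of the reference (human/query) sequence; SAV
#'   positions are interpreted on its ungapped coordinates.
#' @return An object of class `ortholog_alignment`: a list with
#'   `sequence_ids`, `rows` (named character vector of equal-length residue
#'   strings) and `reference_id`.
#' @examples
#' aln <- parse_alignment(c(">HUMAN", "ACDEF", ">MOUSE", "ACDEY"), "HUMAN")
#' aln$sequence_ids
#' @export
parse_alignment <- function(fasta, reference_id) {
  lines <- .fasta_lines(fasta)
  hdr <- grep("^>", lines)
  if (length(hdr) < 2L)
    stop("alignment FASTA must contain at least 2 records", call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bounds <- c(hdr, length(lines) + 1L)
  rows <- vapply(seq_along(hdr), function(i) {
    seg <- lines[seq(bounds[i] + 1L, length.out = bounds[i + 1L] - bounds[i] - 1L)]
    toupper(paste(gsub("\\s", "", seg), collapse = ""))
  }, character(1))
  if (any(!nzchar(rows)))
    stop("empty sequence record(s): ",
         paste(ids[!nzchar(rows)], collapse = ", "), call. = FALSE)
  len <- nchar(rows)
  if (length(unique(len)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(unique(len), collapse = ", "), call. = FALSE)
  if (!reference_id %in% ids)
    stop("reference_id '", reference_id, "' not among sequence ids", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", paste0(.aa_letters(), collapse = "")), rows)
  if (any(bad))
    stop("unexpected residue letters in: ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  names(rows) <- ids
  structure(list(sequence_ids = ids, rows = rows, reference_id = reference_id),
            class = "ortholog_alignment")
}

.aa_letters <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")

.fasta_lines <- function(fasta) {
  if (length(fasta) == 1L && !grepl(">", fasta, fixed = TRUE) && file.exists(fasta))
    fasta <- readLines(fasta)
  lines <- unlist(strsplit(fasta, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !grepl("^>", lines[1]))
    stop("not FASTA: no '>' header found", call. = FALSE)
  lines
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf("ortholog alignment: %d sequences x %d columns (reference %s)\n",
              length(x$rows), nchar(x$rows[[1]]), x$reference_id))
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, columns = positions)
#' @param aln An `ortholog_alignment`.
#' @return Character matrix with sequence ids as rownames.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(m) <- aln$sequence_ids
  m
}

#' Write an alignment back to FASTA text
#' @param aln An `ortholog_alignment`.
#' @param path Optional output file; if `NULL` the text is returned.
#' @param width Line-wrap width.
#' @return FASTA text, invisibly when written to a file.
#' @export
write_alignment_fasta <- function(aln, path = NULL, width = 60L) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  txt <- unlist(lapply(aln$sequence_ids, function(id) {
    s <- aln$rows[[id]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}
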
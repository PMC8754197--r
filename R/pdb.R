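#' Parse Cα coordinates from PDB text into a structure model
#'
#' Reads fixed-column `ATOM` records (HETATM ignored), keeps one Cα per
#' residue ordered by residue number, and resolves alternate locations by
#' highest occupancy, ties broken in favor of altloc `'A'` (then
#' alphabetically). The full atom table is retained for solvent-accessibility
#' calculations.
#'
#' @param pdb Path to a PDB file or PDB text (string or vector of lines).
#' @param chain Chain identifier, or `"first"` for the first chain seen.
#' @return A `structure_model`: list with `residues` (data.frame: chain,
#'   resno, resname, x, y, z — one Cα row per residue) and `atoms`
#'   (data.frame of all atoms of that chain: chain, resno, resname, atom,
#'   element, x, y, z, occupancy).
#' @export
parse_ca_coords <- function(pdb, chain = "first") {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb))
    pdb <- readLines(pdb)
  lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) == 0L) stop("no ATOM records found", call. = FALSE)
  f <- function(a, b) substr(lines, a, b)
  atoms <- data.frame(
    atom = trimws(f(13, 16)),
    altloc = f(17, 17),
    resname = trimws(f(18, 20)),
    chain = f(22, 22),
    resno = as.integer(f(23, 26)),
    x = as.numeric(f(31, 38)),
    y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    element = trimws(f(77, 78)),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # fall back to the first letter of the atom name when the element column
  # is blank (common in generated/minimal files)
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$atom[blank]), 1, 1)
  if (identical(chain, "first")) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("chain '", chain, "' not present", call. = FALSE)
  atoms <- .resolve_altloc(atoms)
  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in chain '", chain, "'", call. = FALSE)
  ca <- ca[order(ca$resno), , drop = FALSE]
  if (anyDuplicated(ca$resno))
    stop("duplicate residue numbers in chain '", chain, "'", call. = FALSE)
  residues <- data.frame(chain = ca$chain, resno = ca$resno,
                         resname = ca$resname, x = ca$x, y = ca$y, z = ca$z,
                         stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(residues = residues,
                 atoms = atoms[, c("chain", "resno", "resname", "atom",
                                   "element", "x", "y", "z", "occupancy")]),
            class = "structure_model")
}

.resolve_altloc <- function(atoms) {
  key <- paste(atoms$resno, atoms$atom)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- atoms$occupancy[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1L) {
      a <- best[atoms$altloc[best] == "A"]
      best <- if (length(a)) a[1] else best[order(atoms$altloc[best])][1]
    }
    best
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure model: %d residues, %d atoms, chain %s\n",
              nrow(x$residues), nrow(x$atoms), x$residues$chain[1]))
  invisible(x)
}

#' Cα coordinate matrix of a structure model
#' @param model A `structure_model`.
#' @return N x 3 numeric matrix of Cα coordinates (Å).
#' @export
ca_coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$residues[, c("x", "y", "z")])
}
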
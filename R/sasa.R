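#' Default van der Waals radii by element (Å)
#'
#' The small set of elements occurring in protein heavy-atom records; values
#' are overridable via the `radii` argument of [shrake_rupley_sasa()].
#'
#' @return Named numeric vector of radii in Å.
#' @export
default_atom_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Classic test-point SASA: each atom sphere is inflated by the probe radius
#' and covered with a deterministic golden-spiral point set; a point is
#' accessible when it lies inside no neighboring inflated sphere. The
#' accessible fraction times the inflated-sphere area gives the atom's SASA;
#' residue SASA is the sum over its atoms.
#'
#' @param model A [parse_ca_coords()] structure model, or a data.frame with
#'   columns `x`, `y`, `z` and either `radius` or `element`.
#' @param probe Probe (water) radius in Å, default 1.4.
#' @param n_points Test points per atom, default 960 (must be >= 100).
#' @param radii Named per-element radius table, see [default_atom_radii()].
#' @param ca_only_radius Coarse radius used for every atom when the model
#'   consists solely of Cα records (coarse-grained traces), default 1.9 Å.
#' @return A `sasa_profile`: list with `atom_area` (per input atom, Å²),
#'   `residue` (data.frame chain/resno/sasa when residue info is available),
#'   `probe`, `n_points`.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960L,
                               radii = default_atom_radii(),
                               ca_only_radius = 1.9) {
  if (n_points < 100L) stop("n_points must be >= 100", call. = FALSE)
  if (probe < 0) stop("probe radius must be nonnegative", call. = FALSE)
  if (inherits(model, "structure_model")) {
    atoms <- model$atoms
    if (all(atoms$atom == "CA")) {
      atoms$radius <- ca_only_radius
    } else {
      atoms$radius <- unname(radii[atoms$element])
    }
  } else {
    atoms <- as.data.frame(model)
    if (is.null(atoms$radius)) atoms$radius <- unname(radii[atoms$element])
  }
  if (anyNA(atoms$radius)) {
    bad <- which(is.na(atoms$radius))[1]
    stop("no radius for atom ", bad,
         if (!is.null(atoms$element)) paste0(" (element '", atoms$element[bad], "')"),
         call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  unit <- .golden_spiral(n_points)
  inflated <- atoms$radius + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    ri <- inflated[i]
    sep <- sweep(xyz, 2L, xyz[i, ])
    d2 <- rowSums(sep^2)
    nb <- which(d2 > 0 & d2 < (ri + inflated)^2)
    pts <- unit * ri
    pts <- sweep(pts, 2L, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 >= inflated[j]^2
    }
    area[i] <- 4 * pi * ri^2 * mean(free)
  }
  residue <- NULL
  if (!is.null(atoms$resno)) {
    key <- paste(atoms$chain, atoms$resno)
    agg <- rowsum(area, key)
    ord <- match(unique(key), rownames(agg))
    first <- !duplicated(key)
    residue <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                          sasa = as.numeric(agg[ord, 1]))
  }
  structure(list(atom_area = area, residue = residue, probe = probe,
                 n_points = as.integer(n_points)),
            class = "sasa_profile")
}

# deterministic quasi-uniform points on the unit sphere
.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @export
print.sasa_profile <- function(x, ...) {
  cat(sprintf("SASA profile: %d atoms, probe %.2f Å, %d points/atom, total %.1f Å²\n",
              length(x$atom_area), x$probe, x$n_points, sum(x$atom_area)))
  invisible(x)
}

#' Write per-residue SASA as TSV
#' @param profile A [shrake_rupley_sasa()] result with residue information.
#' @param path Output file.
#' @return The data frame written, invisibly.
#' @export
write_sasa_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "sasa_profile"))
  if (is.null(profile$residue))
    stop("profile carries no residue information", call. = FALSE)
  df <- profile$residue
  df$sasa <- sprintf("%.4f", df$sasa)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
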
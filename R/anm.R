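#' Build an anisotropic network model from Cα coordinates
#'
#' Constructs the standard ANM Hessian over the Cα trace: every residue pair
#' within the distance cutoff is connected by a Hookean spring of constant
#' `gamma`; the off-diagonal 3x3 superblock for a connected pair (i, j) is
#' \eqn{-\gamma \hat r_{ij} \hat r_{ij}^T} and the diagonal superblocks are
#' the negated row sums, so every row-superblock sums to zero. The
#' eigendecomposition is attached; for a connected, non-collinear structure
#' exactly six rigid-body modes have (numerically) zero eigenvalue, five for
#' a collinear one.
#'
#' @param model A [parse_ca_coords()] structure model, or an N x 3 coordinate
#'   matrix.
#' @param cutoff Spring cutoff distance in Å (default 15).
#' @param gamma Uniform spring constant (arbitrary units, default 1); all
#'   dynamics outputs scale trivially with it.
#' @return An `anm_model`: list with `hessian` (3N x 3N), `values` (ascending
#'   eigenvalues), `vectors` (orthonormal columns), `n_zero_modes`, `coords`,
#'   `cutoff`, `gamma`, `n`.
#' @export
build_anm <- function(model, cutoff = 15, gamma = 1) {
  xyz <- if (inherits(model, "structure_model")) ca_coords(model) else as.matrix(model)
  n <- nrow(xyz)
  if (n < 2L) stop("ANM needs at least 2 residues", call. = FALSE)
  stopifnot(all(is.finite(xyz)))
  h <- matrix(0, 3 * n, 3 * n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      rij <- xyz[j, ] - xyz[i, ]
      dist <- sqrt(sum(rij^2))
      if (dist > cutoff || dist == 0) next
      adj[i, j] <- adj[j, i] <- TRUE
      blk <- -gamma * tcrossprod(rij / dist)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      h[ii, jj] <- blk
      h[jj, ii] <- blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  if (!.is_connected(adj))
    warning("elastic network is disconnected at cutoff ", cutoff,
            " Å; more than 6 zero modes will be present", call. = FALSE)
  eig <- eigen(h, symmetric = TRUE)
  values <- rev(eig$values)
  vectors <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  tol <- 1e-8 * max(values, 0)
  structure(list(hessian = h, values = values, vectors = vectors,
                 n_zero_modes = sum(values < tol), coords = xyz,
                 cutoff = cutoff, gamma = gamma, n = n),
            class = "anm_model")
}

.is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.anm_model <- function(x, ...) {
  cat(sprintf("ANM: %d residues, cutoff %.1f Å, gamma %g, %d zero modes\n",
              x$n, x$cutoff, x$gamma, x$n_zero_modes))
  invisible(x)
}

.nonzero_modes <- function(anm) {
  idx <- seq(anm$n_zero_modes + 1L, 3L * anm$n)
  if (length(idx) < 1L || anm$n_zero_modes >= 3L * anm$n)
    stop("no nonzero modes available", call. = FALSE)
  idx
}

#' ANM covariance matrix (Hessian pseudo-inverse)
#' @param anm An [build_anm()] model.
#' @return 3N x 3N Moore-Penrose pseudo-inverse over the nonzero modes.
#' @export
anm_covariance <- function(anm) {
  stopifnot(inherits(anm, "anm_model"))
  idx <- .nonzero_modes(anm)
  v <- anm$vectors[, idx, drop = FALSE]
  v %*% (t(v) / anm$values[idx])
}

#' Per-residue mean squared displacement from an ANM
#'
#' \eqn{MSD_i} is the trace of the i-th 3x3 diagonal superblock of the
#' Hessian pseudo-inverse, rigid-body modes excluded; units are 1/gamma (no
#' kT prefactor — only relative per-residue values feed the classifier).
#'
#' @param anm An [build_anm()] model.
#' @return Numeric vector of length N, nonnegative.
#' @export
msd_profile <- function(anm) {
  stopifnot(inherits(anm, "anm_model"))
  idx <- .nonzero_modes(anm)
  contrib <- anm$vectors[, idx, drop = FALSE]^2 %*% (1 / anm$values[idx])
  colSums(matrix(contrib, nrow = 3L))
}

#' Per-residue mechanical stiffness from an ANM
#'
#' The effective force constant felt when pulling residues i and j apart is
#' \eqn{\kappa_{ij} = [\sum_k \lambda_k^{-1}((u_{k,j}-u_{k,i})\cdot\hat
#' r_{ij})^2]^{-1}} over the nonzero modes; a residue's stiffness is the mean
#' of \eqn{\kappa_{ij}} over all partners j (not only those within the
#' cutoff). Scales linearly with gamma.
#'
#' @param model The structure model (or coordinate matrix) the ANM was built
#'   from; only used for the inter-residue directions.
#' @param anm An [build_anm()] model.
#' @return Numeric vector of length N, positive for connected networks.
#' @export
stiffness_profile <- function(model, anm) {
  stopifnot(inherits(anm, "anm_model"))
  xyz <- if (inherits(model, "structure_model")) ca_coords(model) else as.matrix(model)
  n <- anm$n
  if (n < 2L) stop("stiffness needs at least 2 residues", call. = FALSE)
  stopifnot(nrow(xyz) == n)
  idx <- .nonzero_modes(anm)
  w <- 1 / anm$values[idx]
  v <- anm$vectors[, idx, drop = FALSE]
  kappa <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    vi <- v[(3 * i - 2):(3 * i), , drop = FALSE]
    for (j in seq(i + 1L, n)) {
      rij <- xyz[j, ] - xyz[i, ]
      rhat <- rij / sqrt(sum(rij^2))
      dproj <- crossprod(rhat, v[(3 * j - 2):(3 * j), , drop = FALSE] - vi)
      compliance <- sum(w * dproj^2)
      kappa[i, j] <- kappa[j, i] <- 1 / compliance
    }
  }
  rowSums(kappa) / (n - 1L)
}

#' Perturbation-response scanning: effectiveness and sensitivity
#'
#' The response of residue j to a unit random force at residue i is read off
#' the ANM covariance: \eqn{P_{ij}} is the sum of squares of the nine entries
#' of the (i, j) 3x3 covariance superblock. Rows are normalized by their
#' diagonal (\eqn{P_{ij}/P_{ii}}); effectiveness of residue i is the mean of
#' normalized row i over j != i (how strongly perturbing i moves everything
#' else) and sensitivity of residue j the mean of normalized column j over
#' i != j (how strongly j responds to perturbations anywhere).
#'
#' @param anm An [build_anm()] model.
#' @return List with numeric vectors `effectiveness` and `sensitivity`
#'   (length N, nonnegative) and the normalized response matrix `response`.
#' @export
prs_profile <- function(anm) {
  stopifnot(inherits(anm, "anm_model"))
  cc <- anm_covariance(anm)
  n <- anm$n
  e <- matrix(0, n, 3 * n)
  e[cbind(rep(seq_len(n), each = 3), seq_len(3 * n))] <- 1
  p <- e %*% (cc * cc) %*% t(e)  # block sums of squared covariance entries
  if (any(diag(p) <= 0))
    stop("zero diagonal in perturbation-response matrix; cannot normalize",
         call. = FALSE)
  pn <- p / diag(p)          # row i divided by P_ii; diag(pn) is all ones
  list(effectiveness = (rowSums(pn) - 1) / (n - 1L),
       sensitivity = (colSums(pn) - 1) / (n - 1L),
       response = pn)
}

#' All four ANM dynamics features as a per-residue table
#'
#' Convenience wrapper running [build_anm()], [msd_profile()],
#' [stiffness_profile()] and [prs_profile()] on a structure.
#'
#' @param model A [parse_ca_coords()] structure model.
#' @inheritParams build_anm
#' @return data.frame: chain, resno, msd, stiffness, effectiveness,
#'   sensitivity.
#' @export
dynamics_profile <- function(model, cutoff = 15, gamma = 1) {
  stopifnot(inherits(model, "structure_model"))
  anm <- build_anm(model, cutoff = cutoff, gamma = gamma)
  prs <- prs_profile(anm)
  data.frame(chain = model$residues$chain, resno = model$residues$resno,
             msd = msd_profile(anm),
             stiffness = stiffness_profile(model, anm),
             effectiveness = prs$effectiveness,
             sensitivity = prs$sensitivity)
}
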
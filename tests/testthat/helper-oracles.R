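# Independent oracles used across the suite. Each re-derives the quantity by
# a different route than the package implementation (exhaustive enumeration,
# dense pseudo-inverse, direct pair counting).

# minimal parsimony score by exhaustive enumeration of internal labelings
oracle_fitch <- function(tree, states) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    tree <- ape::multi2di(tree)
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  tip_states <- unname(states[tree$tip.label])
  alphabet <- unique(tip_states)
  grid <- as.matrix(expand.grid(rep(list(alphabet), nn),
                                stringsAsFactors = FALSE))
  changes <- numeric(nrow(grid))
  for (r in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[r, 1L] - ntip
    child <- tree$edge[r, 2L]
    child_lab <- if (child <= ntip) tip_states[child] else grid[, child - ntip]
    changes <- changes + (grid[, parent] != child_lab)
  }
  min(changes)
}

# dense Moore-Penrose pseudo-inverse of the ANM Hessian (route independent
# of the package's truncated mode sums)
oracle_covariance <- function(anm) MASS::ginv(anm$hessian)

oracle_msd <- function(anm) {
  cc <- oracle_covariance(anm)
  vapply(seq_len(anm$n), function(i) {
    idx <- (3 * i - 2):(3 * i)
    sum(diag(cc[idx, idx, drop = FALSE]))
  }, numeric(1))
}

oracle_stiffness <- function(xyz, anm) {
  cc <- oracle_covariance(anm)
  n <- anm$n
  kappa <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    rhat <- (xyz[j, ] - xyz[i, ]) / sqrt(sum((xyz[j, ] - xyz[i, ])^2))
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    compliance <- drop(t(rhat) %*% (cc[ii, ii] + cc[jj, jj] - cc[ii, jj] -
                                      cc[jj, ii]) %*% rhat)
    kappa[i, j] <- kappa[j, i] <- 1 / compliance
  }
  rowSums(kappa) / (n - 1L)
}

oracle_prs <- function(anm) {
  cc <- oracle_covariance(anm)
  n <- anm$n
  p <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    blk <- cc[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
    p[i, j] <- sum(blk^2)
  }
  pn <- p / diag(p)
  list(effectiveness = (rowSums(pn) - 1) / (n - 1L),
       sensitivity = (colSums(pn) - 1) / (n - 1L))
}

# AUROC as the tie-aware probability that a positive outranks a negative
oracle_auroc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# uniform random 3D rotation matrix
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small helix structure model fixture
helix_model <- function(n = 6) parse_ca_coords(synth_structure(n, "helix"))
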
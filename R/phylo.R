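#' Pairwise p-distance matrix of an ortholog alignment
#'
#' For each pair of rows, the proportion of mismatching residues over the
#' columns where neither row carries a gap (`-`) or an unknown (`X`). Pairs
#' with no comparable column are assigned the maximal distance 1.
#'
#' @param aln An [`parse_alignment()`] result.
#' @return A symmetric numeric matrix with zero diagonal, entries in [0, 1],
#'   labeled by sequence id.
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  m <- alignment_matrix(aln)
  n <- nrow(m)
  usable <- m != "-" & m != "X"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- usable[i, ] & usable[j, ]
      d[i, j] <- d[j, i] <-
        if (!any(ok)) 1 else mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining ([ape::nj()]) over a labeled symmetric distance
#' matrix; negative branch-length estimates are clamped to 0. The two-taxon
#' case, which NJ proper does not cover, is returned as the forced single-edge
#' tree with the distance split evenly across the edge.
#'
#' @param dm Symmetric numeric matrix with labels as dimnames (e.g. from
#'   [p_distance()]).
#' @return An unrooted [ape::phylo] tree over the labels.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (is.null(rownames(dm))) stop("distance matrix must be labeled", call. = FALSE)
  if (nrow(dm) < 2L) stop("need at least 2 labels", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-9)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (nrow(dm) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", rownames(dm)[1],
                                        dm[1, 2] / 2, rownames(dm)[2], dm[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Fitch small-parsimony count for one character
#'
#' Minimum number of state changes over a tree consistent with the observed
#' leaf states, by Fitch's bottom-up set algorithm. Any unrooted or
#' multifurcating tree is first resolved to a rooted binary tree (which leaves
#' the parsimony score unchanged); the score is root-invariant. Gaps (`-`) are
#' treated as an ordinary extra character state, as is `X`.
#'
#' @param tree An [ape::phylo] tree whose tip labels index `leaf_states`.
#' @param leaf_states Named character vector: one single-character state per
#'   tip label.
#' @return Nonnegative integer: the small-parsimony score.
#' @export
fitch_count <- function(tree, leaf_states) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(leaf_states))
  if (length(missing))
    stop("missing leaf state(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  states <- as.character(leaf_states[tips])
  if (anyNA(states)) stop("NA leaf state", call. = FALSE)
  alphabet <- unique(states)
  if (length(alphabet) == 1L) return(0L)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tips)
  nnode <- tree$Nnode
  # state sets as bitmasks over the observed alphabet (<= 22 states)
  sets <- integer(ntip + nnode)
  sets[seq_len(ntip)] <- bitwShiftL(1L, match(as.character(leaf_states[tree$tip.label]),
                                              alphabet) - 1L)
  changes <- 0L
  for (r in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[r, 1L]
    child <- tree$edge[r, 2L]
    if (sets[parent] == 0L) {
      sets[parent] <- sets[child]
    } else {
      inter <- bitwAnd(sets[parent], sets[child])
      if (inter == 0L) {
        sets[parent] <- bitwOr(sets[parent], sets[child])
        changes <- changes + 1L
      } else {
        sets[parent] <- inter
      }
    }
  }
  changes
}

#' Read/write a phylogenetic tree in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so trees used
#' for variation-number profiles round-trip through plain text.
#'
#' @param x A [ape::phylo] tree (`write_newick`) or a path/Newick string
#'   (`read_newick`).
#' @param path Optional output file for `write_newick`.
#' @return `read_newick`: a `phylo`; `write_newick`: the Newick string.
#' @export
read_newick <- function(x) {
  if (length(x) == 1L && file.exists(x)) ape::read.tree(x)
  else ape::read.tree(text = x)
}

#' @rdname read_newick
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "phylo"))
  txt <- ape::write.tree(x)
  if (!is.null(path)) writeLines(txt, path)
  txt
}
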
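test_that("p-distance counts mismatches over comparable columns", {
  aln <- parse_alignment(c(">A", "AC-D", ">B", "AG-D"), "A")
  d <- p_distance(aln)
  expect_equal(d["A", "B"], 1 / 3)  # 3 comparable columns, 1 mismatch

  ident <- parse_alignment(c(">A", "ACDE", ">B", "ACDE"), "A")
  expect_equal(p_distance(ident)["A", "B"], 0)

  alldiff <- parse_alignment(c(">A", "ACDE", ">B", "CDEF"), "A")
  expect_equal(p_distance(alldiff)["A", "B"], 1)

  # no comparable columns -> maximal distance
  nocomp <- parse_alignment(c(">A", "AC--", ">B", "--DE"), "A")
  expect_equal(p_distance(nocomp)["A", "B"], 1)

  # X excluded like a gap
  withx <- parse_alignment(c(">A", "AXDE", ">B", "ACDE"), "A")
  expect_equal(p_distance(withx)["A", "B"], 0)
})

test_that("p-distance is symmetric, zero-diagonal and row-order invariant", {
  set.seed(42)
  aa <- c(strsplit("ACDEFG", "")[[1]], "-")
  rows <- replicate(5, paste(sample(aa, 30, replace = TRUE), collapse = ""))
  fasta <- as.vector(rbind(paste0(">S", 1:5), rows))
  aln <- parse_alignment(fasta, "S1")
  d <- p_distance(aln)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 1))
  # permuting rows permutes the matrix consistently
  perm <- c(3, 1, 5, 2, 4)
  aln2 <- parse_alignment(as.vector(rbind(paste0(">S", (1:5)[perm]), rows[perm])),
                          "S1")
  d2 <- p_distance(aln2)
  expect_equal(d2[rownames(d), colnames(d)], d)
})

test_that("neighbor joining recovers forced and additive topologies", {
  # 2 taxa: forced single edge with total path length preserved
  dm2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighbor_joining(dm2)
  expect_setequal(tr2$tip.label, c("A", "B"))
  expect_equal(sum(tr2$edge.length), 0.4)

  # 3 taxa: the unique unrooted star topology
  dm3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
                dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr3 <- neighbor_joining(dm3)
  expect_equal(length(tr3$tip.label), 3L)
  expect_equal(tr3$Nnode, 1L)

  # 4 taxa additive: ((A,B),(C,D))
  dm4 <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm4[1, 2] <- dm4[2, 1] <- 2; dm4[3, 4] <- dm4[4, 3] <- 2
  diag(dm4) <- 0
  tr4 <- neighbor_joining(dm4)
  expect_true(ape::is.monophyletic(ape::unroot(tr4), c("A", "B")))
  expect_true(ape::is.monophyletic(ape::unroot(tr4), c("C", "D")))

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("neighbor joining recovers generating topologies from additive distances", {
  set.seed(7)
  for (n in 4:6) {
    for (rep in 1:5) {
      true_tree <- ape::rtree(n)
      true_tree$edge.length <- stats::runif(nrow(true_tree$edge), 0.2, 1)
      dm <- ape::cophenetic.phylo(true_tree)
      dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
      est <- neighbor_joining(dm)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(est),
                                             ape::unroot(true_tree))), 0)
    }
  }
})

test_that("negative NJ branch estimates are clamped to zero", {
  set.seed(5)
  # near-degenerate distances commonly produce small negative NJ branches
  for (rep in 1:20) {
    n <- 5
    m <- matrix(stats::runif(n * n, 0.01, 0.2), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- neighbor_joining(m)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("fitch_count matches hand-derived small cases and conventions", {
  t4 <- read_newick("((L1,L2),(L3,L4));")
  expect_equal(fitch_count(t4, c(L1 = "A", L2 = "A", L3 = "A", L4 = "A")), 0L)
  expect_equal(fitch_count(t4, c(L1 = "A", L2 = "A", L3 = "B", L4 = "B")), 1L)
  expect_equal(fitch_count(t4, c(L1 = "A", L2 = "B", L3 = "A", L4 = "B")), 2L)
  # gap is an ordinary 21st state
  expect_equal(fitch_count(t4, c(L1 = "-", L2 = "-", L3 = "A", L4 = "A")), 1L)
  expect_error(fitch_count(t4, c(L1 = "A", L2 = "A", L3 = "B")), "missing leaf")
})

test_that("fitch_count equals the exhaustive-enumeration oracle and matches phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(LETTERS[1:4], n, replace = TRUE), tree$tip.label)
    got <- fitch_count(tree, states)
    expect_equal(got, oracle_fitch(tree, states))
    dat <- phangorn::phyDat(matrix(states[tree$tip.label], ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = LETTERS[1:4])
    expect_equal(got, as.integer(phangorn::fitch(tree, dat)))
  }
})

test_that("fitch_count is root-invariant and obeys parsimony bounds", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(c("A", "B", "C"), n, replace = TRUE),
                       tree$tip.label)
    score <- fitch_count(tree, states)
    # rerooting along any edge leaves the score unchanged
    rerooted <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1],
                          resolve.root = TRUE)
    expect_equal(fitch_count(rerooted, states), score)
    k <- length(unique(states))
    expect_gte(score, k - 1L)
    expect_lte(score, n - 1L)
    if (k == 1L) expect_equal(score, 0L)
  }
})

test_that("newick text round-trips a tree", {
  tr <- ape::rtree(8)
  txt <- write_newick(tr)
  back <- read_newick(txt)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tr))), 0)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_equal(read_newick(path)$tip.label, tr$tip.label)
})
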
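dimer <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)

test_that("PDB parsing keeps one Ca per residue with altloc resolution", {
  m <- helix_model(3)
  expect_equal(nrow(m$residues), 3L)
  expect_equal(m$residues$resno, 1:3)

  # two chains: selection honors the chain argument
  two <- paste(c(synth_structure(3, "helix", chain = "A"),
                 synth_structure(4, "line", chain = "B")), collapse = "\n")
  mb <- parse_ca_coords(two, chain = "B")
  expect_equal(nrow(mb$residues), 4L)
  expect_true(all(mb$residues$chain == "B"))
  expect_error(parse_ca_coords(two, chain = "Z"), "not present")

  # altloc resolved to highest occupancy
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C")
  ma <- parse_ca_coords(alt)
  expect_equal(nrow(ma$residues), 1L)
  expect_equal(ma$residues$x, 9)

  # occupancy tie -> altloc 'A' wins
  tie <- c(
    "ATOM      1  CA BALA A   1       9.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C")
  expect_equal(parse_ca_coords(tie)$residues$x, 1)

  expect_error(parse_ca_coords("HETATM    1  CA  ALA A   1       0       0       0"),
               "no ATOM")
})

test_that("the two-bead dimer has 5 zero modes and stretching eigenvalue 2*gamma", {
  anm <- build_anm(dimer, cutoff = 15, gamma = 1)
  expect_equal(anm$n_zero_modes, 5L)
  expect_equal(anm$values[6], 2, tolerance = 1e-10)
  expect_equal(sum(abs(anm$values[1:5])) < 1e-10, TRUE)

  anm3 <- build_anm(dimer, gamma = 3)
  expect_equal(anm3$values[6], 6, tolerance = 1e-10)

  # symmetry of the dimer: MSD and PRS identical across the two beads
  expect_equal(msd_profile(anm)[1], msd_profile(anm)[2])
  prs <- prs_profile(anm)
  expect_equal(prs$effectiveness, prs$sensitivity)
})

test_that("Hessian construction is symmetric with zero row-superblock sums", {
  m <- helix_model(6)
  anm <- build_anm(m)
  expect_equal(anm$hessian, t(anm$hessian))
  n <- anm$n
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    blocksum <- matrix(0, 3, 3)
    for (j in seq_len(n))
      blocksum <- blocksum + anm$hessian[rows, (3 * j - 2):(3 * j)]
    expect_equal(blocksum, matrix(0, 3, 3), tolerance = 1e-12)
  }
  # orthonormal modes reconstructing the Hessian
  v <- anm$vectors
  expect_equal(crossprod(v), diag(3 * n), tolerance = 1e-8)
  expect_equal(v %*% (anm$values * t(v)), anm$hessian, tolerance = 1e-8)
})

test_that("zero-mode count is 6 for connected non-collinear, 5 for collinear", {
  helix <- build_anm(helix_model(4))
  expect_equal(helix$n_zero_modes, 6L)
  # collinear chains are degenerate for the ANM: beyond the 5 rigid-body
  # modes, every perpendicular displacement is unrestrained, so the null
  # space has dimension 2N + 1 (spring network rank N - 1 within the axis)
  line <- build_anm(parse_ca_coords(synth_structure(5, "line")))
  expect_equal(line$n_zero_modes, 2L * 5L + 1L)
  # disconnected network warns and reports > 6 zero modes
  far <- rbind(dimer, dimer + 1000)
  expect_warning(anm_far <- build_anm(far, cutoff = 15), "disconnected")
  expect_gt(anm_far$n_zero_modes, 6L)
})

test_that("MSD, stiffness and PRS match the dense pseudo-inverse oracle", {
  skip_if_not_installed("MASS")
  for (n in c(4L, 7L, 10L)) {
    m <- helix_model(n)
    anm <- build_anm(m)
    xyz <- ca_coords(m)
    expect_equal(msd_profile(anm), oracle_msd(anm), tolerance = 1e-8)
    expect_equal(stiffness_profile(m, anm), oracle_stiffness(xyz, anm),
                 tolerance = 1e-8)
    prs <- prs_profile(anm)
    oprs <- oracle_prs(anm)
    expect_equal(prs$effectiveness, oprs$effectiveness, tolerance = 1e-8)
    expect_equal(prs$sensitivity, oprs$sensitivity, tolerance = 1e-8)
    # trace identity and positivity
    idx <- seq(anm$n_zero_modes + 1, 3 * n)
    expect_equal(sum(msd_profile(anm)), sum(1 / anm$values[idx]),
                 tolerance = 1e-8)
    expect_true(all(stiffness_profile(m, anm) > 0))
  }
})

test_that("stiffness scales linearly in gamma", {
  m <- helix_model(5)
  s1 <- stiffness_profile(m, build_anm(m, gamma = 1))
  s3 <- stiffness_profile(m, build_anm(m, gamma = 3))
  expect_equal(s3, 3 * s1, tolerance = 1e-8)
})

test_that("dynamics features are invariant under rigid rotation + translation", {
  set.seed(33)
  m <- helix_model(8)
  xyz <- ca_coords(m)
  anm <- build_anm(xyz)
  base_msd <- msd_profile(anm)
  base_prs <- prs_profile(anm)
  base_stiff <- stiffness_profile(xyz, anm)
  for (rep in 1:3) {
    rot <- random_rotation()
    xyz2 <- xyz %*% t(rot) + matrix(rnorm(3, sd = 20), nrow(xyz), 3, byrow = TRUE)
    anm2 <- build_anm(xyz2)
    expect_equal(anm2$n_zero_modes, 6L)
    expect_equal(msd_profile(anm2), base_msd, tolerance = 1e-6)
    prs2 <- prs_profile(anm2)
    expect_equal(prs2$effectiveness, base_prs$effectiveness, tolerance = 1e-6)
    expect_equal(prs2$sensitivity, base_prs$sensitivity, tolerance = 1e-6)
    expect_equal(stiffness_profile(xyz2, anm2), base_stiff, tolerance = 1e-6)
  }
})

test_that("dynamics_profile returns all four features per residue", {
  dyn <- dynamics_profile(helix_model(6))
  expect_equal(names(dyn), c("chain", "resno", "msd", "stiffness",
                             "effectiveness", "sensitivity"))
  expect_equal(nrow(dyn), 6L)
  expect_true(all(vapply(dyn[3:6], function(v) all(is.finite(v) & v >= 0),
                         logical(1))))
})
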
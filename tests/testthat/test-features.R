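clinvar_fixture <- c(
  "protein_id\tvariant\tclinical_significance\treview_stars",
  "P1\tR15K\tLikely benign\t2",
  "P1\tY16H\tPathogenic/Likely pathogenic\t1",
  "P2\tA5G\tBenign\t3",
  "P2\tP24L\tpathogenic\t1",
  "P2\tQ30R\tPathogenic\t0",
  "P3\tL7V\tUncertain significance\t2")

test_that("ClinVar-style labels follow the star filter and significance map", {
  expect_message(sav <- label_from_clinvar(clinvar_fixture), "unrecognized")
  expect_equal(nrow(sav), 4L)
  expect_equal(sav$label, c(0L, 1L, 0L, 1L))
  expect_equal(sav$position, c(15L, 16L, 5L, 24L))
  expect_equal(attr(sav, "n_dropped_stars"), 1L)       # the 0-star row
  expect_equal(attr(sav, "n_dropped_significance"), 1L)  # uncertain
  expect_error(label_from_clinvar("protein_id\tvariant\nP1\tR15K"), "column")
})

test_that("SAV strings parse and reject synonymous variants", {
  df <- parse_sav(c("R15K", "a5g"))
  expect_equal(df$wt_aa, c("R", "A"))
  expect_equal(df$position, c(15L, 5L))
  expect_equal(df$mut_aa, c("K", "G"))
  expect_error(parse_sav("R15R"), "synonymous")
  expect_error(parse_sav("15K"), "unparseable")
})

make_assembly_fixture <- function() {
  fam <- synth_ortholog_family(fixture_spec(seed = 4, n_orthologs = 8,
                                            seq_length = 12, subst_rate = 0.1))
  prof <- variation_profile(fam$alignment, fam$tree)
  prof$protein_id <- "P1"
  model <- helix_model(12)
  dyn <- dynamics_profile(model)
  sas <- shrake_rupley_sasa(model)
  ext <- ingest_external_features(c(
    "protein_id\tposition\twt_aa\tmut_aa\tddg_fold\twt_psic\tdelta_psic\tdelta_e_epistatic\tfis\tmutant_ssf\tactive_site_prob",
    "P1\t3\tA\tG\t1.2\t0.5\t1.1\t-2.0\t0.7\t0.3\t0.8",
    "P1\t5\tC\tW\t0.4\t0.2\t0.1\t-1.0\t0.1\t0.6\t0.2"))
  tab <- load_reference_energies()
  list(prof = prof, dyn = dyn, sas = sas, ext = ext, tab = tab)
}

test_that("feature assembly fills present providers and flags absences as NA", {
  fx <- make_assembly_fixture()
  savs <- data.frame(protein_id = "P1", position = c(3L, 5L, 7L),
                     wt_aa = c("A", "C", "D"), mut_aa = c("G", "W", "E"),
                     label = c(1L, 0L, 1L))
  fm <- assemble_features(savs, vn_profiles = list(P1 = fx$prof),
                          dynamics = list(P1 = fx$dyn),
                          sasa = list(P1 = fx$sas),
                          external = fx$ext, ref_table = fx$tab)
  expect_s3_class(fm, "sav_features")
  expect_equal(nrow(fm), 3L)
  expect_equal(colnames(feature_matrix(fm)), feature_names())
  # fully covered SAV: no missing cells
  expect_false(anyNA(feature_matrix(fm)[1, ]))
  # active site binarized from probability
  expect_equal(fm$active_site, c(1, 0, NA))
  # SAV without an external record: 7 tool-derived cells NA, native present
  row3 <- fm[3, ]
  expect_true(all(is.na(row3[c("ddg_fold", "wt_psic", "delta_psic",
                               "delta_e_epistatic", "fis", "mutant_ssf",
                               "active_site")])))
  expect_false(anyNA(row3[c("variation_number", "sasa", "msd", "stiffness",
                            "effectiveness", "sensitivity",
                            "mutant_ref_energy", "delta_ref_energy")]))
  # reference energies computed from the substitution
  expect_equal(fm$delta_ref_energy[1],
               unname(fx$tab[["G"]] - fx$tab[["A"]]))

  dupl <- rbind(savs, savs[1, ])
  expect_error(assemble_features(dupl, list(P1 = fx$prof), ref_table = fx$tab),
               "duplicate")
})

test_that("out-of-range SAV positions are excluded into a row-error report", {
  fx <- make_assembly_fixture()
  savs <- data.frame(protein_id = "P1", position = c(3L, 999L),
                     wt_aa = c("A", "C"), mut_aa = c("G", "W"))
  expect_message(fm <- assemble_features(savs, vn_profiles = list(P1 = fx$prof),
                                         ref_table = fx$tab), "excluded")
  expect_equal(nrow(fm), 1L)
  errs <- attr(fm, "row_errors")
  expect_equal(nrow(errs), 1L)
  expect_match(errs$reason, "beyond protein P1 length 12")
})

test_that("median imputation uses training rows only and is idempotent", {
  x <- data.frame(matrix(rnorm(8 * 15), 8, 15, dimnames = list(NULL, feature_names())))
  x$variation_number <- c(1, 2, 3, NA, 10, 20, 30, NA)
  filled <- impute_features(x, training_rows = 1:4)
  # training median of {1,2,3} = 2 fills both NA cells (row 8 is a test row)
  expect_equal(filled$variation_number[c(4, 8)], c(2, 2))
  log <- attr(filled, "imputation_log")
  expect_equal(log$n_imputed[log$feature == "variation_number"], 2L)
  # no missing cells -> unchanged
  expect_equal(impute_features(filled)[feature_names()],
               filled[feature_names()])
  x$fis <- NA_real_
  expect_error(impute_features(x), "no observed training value")
})

test_that("the Pearson matrix matches a direct covariance computation", {
  set.seed(31)
  x <- as.data.frame(matrix(rnorm(5 * 15), 5, 15,
                            dimnames = list(NULL, feature_names())))
  labels <- c(0, 1, 0, 1, 1)
  cm <- pearson_matrix(x, labels)
  expect_equal(dim(cm), c(16L, 16L))
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 16))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # hand formula on one pair
  a <- x$fis; b <- x$sasa
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cm["fis", "sasa"], hand)
  # a feature against its own negation
  x2 <- x; x2$msd <- -x$fis
  expect_equal(pearson_matrix(x2, labels)["fis", "msd"], -1)
  # zero-variance feature flagged undefined
  x3 <- x; x3$stiffness <- 5
  expect_true("stiffness" %in% attr(pearson_matrix(x3, labels), "undefined"))
})

test_that("PCA cumulative variance behaves on rank-1, isotropic and generic data", {
  n <- 200
  set.seed(12)
  base <- rnorm(n)
  rank1 <- as.data.frame(sapply(seq_len(15), function(i) base * i))
  names(rank1) <- feature_names()
  noisy <- rank1 + matrix(rnorm(n * 15, sd = 1e-6), n, 15)
  cv1 <- pca_cumulative_variance(noisy)
  expect_gt(cv1[1], 0.999)

  iso <- as.data.frame(matrix(rnorm(10000 * 15), ncol = 15,
                              dimnames = list(NULL, feature_names())))
  cviso <- pca_cumulative_variance(iso)
  # the leading sample eigenvalue of isotropic data is upward biased by
  # about (1 + sqrt(p/n))^2; 0.01 absolute covers it at n = 10000, p = 15
  expect_lt(abs(cviso[1] - 1 / 15), 0.01)

  generic <- as.data.frame(matrix(rnorm(50 * 15), ncol = 15,
                                  dimnames = list(NULL, feature_names())))
  cv <- pca_cumulative_variance(generic)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[15], 1, tolerance = 1e-9)

  flat <- as.data.frame(matrix(1, 5, 15, dimnames = list(NULL, feature_names())))
  expect_error(pca_cumulative_variance(flat), "constant")
})

test_that("the Welch t-test matches the hand formula and its conventions", {
  g0 <- c(1, 2, 3); g1 <- c(4, 5, 6)
  res <- welch_ttest(g0, g1)
  se <- sqrt(var(g0) / 3 + var(g1) / 3)
  expect_equal(res$t, (mean(g0) - mean(g1)) / se)
  # swapping groups flips the sign
  expect_equal(welch_ttest(g1, g0)$t, -res$t)
  # identical groups -> t = 0
  expect_equal(welch_ttest(g0, g0)$t, 0)
  # degenerate constant groups
  expect_equal(welch_ttest(c(2, 2), c(2, 2))$t, 0)
  expect_equal(welch_ttest(c(3, 3), c(2, 2))$t, Inf)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})
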
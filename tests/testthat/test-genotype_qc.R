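test_that("exact HWE test matches enumeration and handles the boundaries", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)     # extreme het deficit
  expect_equal(hwe_exact_test(100, 0, 0), 1)     # monomorphic
  # random configurations against the direct log-factorial oracle
  set.seed(8)
  for (i in 1:200) {
    n <- sample(5:300, 1)
    nA <- sample(0:n, 1)
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    h <- sample(hets, 1)
    hom_r <- (nA - h) / 2
    expect_equal(hwe_exact_test(hom_r, h, n - h - hom_r),
                 hwe_oracle(hom_r, h, n - h - hom_r), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(1, 1, 1), ">= 5")
  expect_error(hwe_exact_test(-1, 5, 5), "nonnegative")
})

test_that("sex check F behaves at its limits and thresholds", {
  sim <- make_clean_cohort(n = 200, m = 200)
  sc <- sex_check(sim$genotypes, sim$meta)
  male <- sim$meta$sex == "male"
  # hemizygous males sit near F = 1 and pass; HWE females near F = 0 and pass
  expect_true(all(sc$x_homozygosity_f[male] > 0.9))
  expect_true(all(abs(sc$x_homozygosity_f[!male]) < 0.2))
  expect_true(all(sc$sex_check_pass))
  # a female with F = 0.5 fails: make half her het X calls homozygous
  meta2 <- sim$meta
  fem <- which(!male)[1]
  gm2 <- sim$genotypes
  x_idx <- which(gm2$variants$chrom_class == "X")
  het_x <- x_idx[which(gm2$dosage[fem, x_idx] == 1)]
  flip <- het_x[seq_len(ceiling(length(het_x) * 0.6))]
  gm2$dosage[fem, flip] <- 2
  sc2 <- sex_check(gm2, meta2)
  expect_gt(sc2$x_homozygosity_f[fem], 0.2)
  expect_false(sc2$sex_check_pass[fem])
  # unknown sex label is flagged, not fatal
  meta3 <- sim$meta
  meta3$sex[1] <- "unknown"
  expect_false(suppressWarnings(sex_check(sim$genotypes, meta3))$sex_check_pass[1])
})

test_that("kinship estimator hits the identical / unrelated / parent-offspring anchors", {
  sim <- simulate_genotypes(cohort_spec(n_samples = 60, n_variants = 1000,
                                        n_x_variants = 0, missing_rate = 0,
                                        seed = 17))
  gm <- sim$genotypes
  # identical vectors
  gm$dosage[2, ] <- gm$dosage[1, ]
  expect_gt(as.numeric(kinship(gm, 1, 2)), 0.9)
  # independent pairs at HWE: |pihat| < 0.1 at 1,000 variants
  k <- kinship_matrix(gm)$pihat
  off <- k[upper.tri(k)][-1]
  expect_lt(max(abs(off)), 0.25)
  expect_lt(mean(abs(off) > 0.1), 0.01)
  # parent-offspring: child inherits one parental allele per locus
  set.seed(2)
  mafs <- sim$truth$mafs
  parent <- gm$dosage[3, ]
  transmitted <- rbinom(length(parent), 1, parent / 2)
  child <- transmitted + rbinom(length(parent), 1, mafs)
  gm$dosage[4, ] <- child
  expect_lt(abs(as.numeric(kinship(gm, 3, 4)) - 0.5), 0.12)
  # unreliable below the overlap floor
  gm$dosage[5, seq(41, ncol(gm$dosage))] <- NA
  est <- kinship(gm, 5, 6)
  expect_false(attr(est, "reliable"))
})

test_that("sample filters remove planted defects, each for exactly one reason", {
  sim <- simulate_genotypes(cohort_spec(n_samples = 150, n_variants = 1500,
                                        n_x_variants = 500,
                                        n_het_outliers = 2, n_duplicates = 1,
                                        seed = 23))
  rep1 <- sample_filters(sim$genotypes, sim$meta)
  removed <- rep1[!rep1$kept, ]
  expect_true(all(!is.na(removed$reason)))
  expect_true(all(is.na(rep1$reason[rep1$kept])))
  # the two planted heterozygosity outliers are removed for heterozygosity
  het_rows <- rep1[rep1$sample_id %in% sim$truth$het_outliers, ]
  expect_true(all(!het_rows$kept))
  expect_true(all(het_rows$reason == "heterozygosity"))
  # one member of the duplicate pair is removed as a duplicate
  dup <- unlist(sim$truth$duplicate_pairs)
  expect_equal(sum(rep1$reason[match(dup, rep1$sample_id)] == "duplicate",
                   na.rm = TRUE), 1L)
  # counts by reason sum to total removed
  expect_equal(sum(table(removed$reason)), nrow(removed))
})

test_that("a low-call-rate sample is removed for call rate", {
  sim <- make_clean_cohort(n = 100, m = 800)
  gm <- sim$genotypes
  miss <- sample(ncol(gm$dosage), round(0.15 * ncol(gm$dosage)))
  gm$dosage[7, miss] <- NA
  rep1 <- sample_filters(gm, sim$meta)
  expect_false(rep1$kept[7])
  expect_equal(rep1$reason[7], "call_rate")
})

test_that("QC is idempotent on a clean cohort", {
  sim <- make_clean_cohort(n = 150, m = 1500)
  qc1 <- apply_qc(sim$genotypes, sim$meta)
  expect_gt(length(qc1$genotypes$samples), 100)
  qc2 <- apply_qc(qc1$genotypes, sim$meta)
  expect_equal(sum(!qc2$sample_report$kept), 0L)
  expect_equal(sum(!qc2$marker_report$kept), 0L)
})

test_that("marker filters apply missingness, chromosome and HWE rules", {
  sim <- simulate_genotypes(cohort_spec(n_samples = 200, n_variants = 400,
                                        n_x_variants = 20,
                                        hwe_violation_fraction = 0.05,
                                        missing_rate = 0, seed = 29))
  gm <- sim$genotypes
  # plant 6% missingness on one variant
  gm$dosage[seq_len(12), "var00200"] <- NA
  rep1 <- marker_filters(gm)
  expect_false(rep1$kept[rep1$variant_id == "var00200"])
  expect_true(all(!rep1$kept[!rep1$autosomal]))     # X removed
  viol <- rep1[rep1$variant_id %in% sim$truth$hwe_violators, ]
  expect_gt(mean(!viol$kept), 0.5)                  # strong violators caught
  kept <- rep1[rep1$kept, ]
  expect_true(all(kept$missing_rate <= 0.05 & kept$hwe_p > 1e-6 &
                    kept$autosomal))
})

test_that("PCA outlier detection flags shifted ancestry and is calibrated", {
  sim <- make_clean_cohort(n = 150, m = 1000)
  po <- pca_outlier_detect(sim$genotypes, n_components = 10, sd_threshold = 6)
  expect_equal(sum(po$outlier), 0L)                 # homogeneous cohort
  # Gram matrix of scores is diagonal (PCA orthogonality)
  g <- crossprod(po$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  # one sample with shifted allele frequencies at 30% of loci
  gm <- sim$genotypes
  set.seed(31)
  shift <- sample(ncol(gm$dosage), round(0.3 * ncol(gm$dosage)))
  gm$dosage[5, shift] <- rbinom(length(shift), 2, 0.95)
  po2 <- pca_outlier_detect(gm, n_components = 10, sd_threshold = 6)
  expect_true(po2$outlier[5])
  expect_warning(pca_outlier_detect(sim$genotypes, n_components = 5000),
                 "rank")
})
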
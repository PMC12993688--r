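test_that("rank normalization is monotone, standardized and tie-consistent", {
  set.seed(1)
  x <- rexp(300)
  df <- data.frame(a = x, row.names = sprintf("s%03d", 1:300))
  norm <- normalize_inputs(df, df, df)
  y <- norm$metabolites$a
  expect_equal(order(y), order(x))
  expect_lt(abs(mean(y)), 0.05)
  expect_lt(abs(sd(y) - 1), 0.1)
  yt <- blom_transform(c(1, 2, 2, 5))
  expect_equal(yt[2], yt[3])
})

test_that("genotype stratification is a disjoint exhaustive partition", {
  d <- c(s1 = 0, s2 = 0, s3 = 1, s4 = 2)
  st <- stratify_by_genotype(d)
  expect_equal(unname(st$major), 1:2)
  expect_equal(unname(st$minor), 3:4)
  expect_true(st$low_power)
  d2 <- c(d, s5 = NA)
  st2 <- stratify_by_genotype(d2)
  expect_length(c(st2$major, st2$minor), 4)     # missing in neither stratum
  # HWE arithmetic: MAF 0.27, n = 275 -> expected major ~ 0.73^2 * 275
  set.seed(2)
  d3 <- rbinom(275, 2, 0.27)
  st3 <- stratify_by_genotype(d3)
  expect_equal(length(st3$major), 0.73^2 * 275, tolerance = 0.15)
})

test_that("mediation estimates satisfy TE = ACME + ADE and the product rule", {
  set.seed(3)
  n <- 500
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.2 * x + 0.4 * m + rnorm(n)
  f <- fit_mediation(x, m, y, nsim = 2000, seed = 7)
  expect_identical(f$te, f$acme + f$ade)          # exact by draw sharing
  # product-of-coefficients closed form: ACME ~ 0.20, ADE ~ 0.20, TE ~ 0.40
  # (estimation SE ~ 0.05 at n = 500; allow 2 SE)
  expect_lt(abs(f$acme - 0.20), 0.10)
  expect_lt(abs(f$ade - 0.20), 0.10)
  expect_lt(abs(f$te - 0.40), 0.15)
  expect_lt(f$p_acme, 0.05)
  # reproducible given (seed, nsim)
  g <- fit_mediation(x, m, y, nsim = 2000, seed = 7)
  expect_identical(unclass(f), unclass(g))
  expect_error(fit_mediation(x[1:10], m[1:10], y[1:10]), "n >= 30")
})

test_that("a null mediated path gives a near-zero ACME with a calibrated p", {
  set.seed(4)
  ps <- replicate(40, {
    n <- 200
    x <- rnorm(n)
    m <- rnorm(n)                       # a = 0: no exposure->mediator path
    y <- 0.3 * x + 0.4 * m + rnorm(n)
    f <- fit_mediation(x, m, y, nsim = 500, seed = sample.int(1e6, 1))
    c(f$acme, f$p_acme)
  })
  expect_lt(abs(mean(ps[1, ])), 0.02)
  expect_gt(mean(ps[2, ] > 0.05), 0.8)  # rarely significant under the null
})

test_that("matched-SNP sampling respects the MAF window and determinism", {
  coh <- simulate_mediation_cohort(triangle_params(), n = 400,
                                   n_null_snps = 300, seed = 5)
  snps <- sample_matched_snps(coh$genotypes, "rs_focal", k = 100, seed = 9)
  expect_length(snps, 101)
  expect_identical(snps[101], "rs_focal")
  mafs <- maf(coh$genotypes)[snps[1:100]]
  expect_true(all(mafs >= 0.25 & mafs <= 0.30))   # post-hoc recheck
  expect_identical(snps,
                   sample_matched_snps(coh$genotypes, "rs_focal", k = 100,
                                       seed = 9))
  expect_error(sample_matched_snps(coh$genotypes, "rs_focal", k = 10000,
                                   seed = 1), "need 10000")
})

test_that("p_to_z applies the offset, stays finite and monotone", {
  expect_equal(p_to_z(0), qnorm(0.999), tolerance = 1e-12)
  expect_equal(p_to_z(0), 3.090, tolerance = 1e-3)
  expect_equal(p_to_z(0.499), 0, tolerance = 1e-12)
  expect_true(is.finite(p_to_z(1)))
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(p_to_z(p)) < 0))
  expect_error(p_to_z(1.2), "\\[0, 1\\]")
})

test_that("zdiff scan accounts fits exactly and is reproducible and antisymmetric", {
  coh <- simulate_mediation_cohort(
    triangle_params(a_major = 0.6, a_minor = 0), n = 400, n_null_snps = 40,
    seed = 11)
  norm <- normalize_inputs(coh$exposure, coh$mediator, coh$outcome)
  tri <- data.frame(exposure = "carb1", mediator = "cytokine1",
                    outcome = "homa_ir")
  snps <- sample_matched_snps(coh$genotypes, "rs_focal", k = 10, seed = 1)
  zd <- zdiff_scan(tri, coh$genotypes, norm$metabolites, norm$cytokines,
                   norm$clinical, snps, nsim = 200, seed = 13)
  expect_equal(attr(zd, "n_fits"), length(snps) * 2L * nrow(tri))
  expect_equal(nrow(zd), length(snps) * nrow(tri))
  expect_true(all(zd$flagged == (abs(zd$zdiff_acme) > 2 |
                                   abs(zd$zdiff_ade) > 2 |
                                   abs(zd$zdiff_te) > 2), na.rm = TRUE))
  zd2 <- zdiff_scan(tri, coh$genotypes, norm$metabolites, norm$cytokines,
                    norm$clinical, snps, nsim = 200, seed = 13)
  expect_identical(zd, zd2)            # bit-reproducible
  # relabeling strata (recode focal dosage 0 <-> 1) negates zdiff: the two
  # strata share the per-fit seed, so the fits are exchanged exactly
  zd_f <- zdiff_scan(tri, coh$genotypes, norm$metabolites, norm$cytokines,
                     norm$clinical, "rs_focal", nsim = 200, seed = 13)
  gm2 <- coh$genotypes
  gm2$dosage[, "rs_focal"] <- ifelse(gm2$dosage[, "rs_focal"] == 0, 1, 0)
  zd3 <- zdiff_scan(tri, gm2, norm$metabolites, norm$cytokines,
                    norm$clinical, "rs_focal", nsim = 200, seed = 13)
  expect_equal(zd3$zdiff_acme, -zd_f$zdiff_acme, tolerance = 1e-12)
  expect_equal(zd3$zdiff_te, -zd_f$zdiff_te, tolerance = 1e-12)
  # undersized strata yield NA records with a reason, not an error
  small <- subset_genotypes(coh$genotypes, samples = 1:40)
  zds <- zdiff_scan(tri, small, norm$metabolites, norm$cytokines,
                    norm$clinical, "rs_focal", nsim = 50, seed = 1)
  expect_true(is.na(zds$flagged) || !is.na(zds$reason))
})
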
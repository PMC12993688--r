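test_that("linear fitter matches the normal-equations oracle and recovers effects", {
  set.seed(1)
  # random small designs against the textbook route
  for (i in 1:20) {
    n <- sample(30:80, 1)
    covars <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
    dosage <- rbinom(n, 2, 0.3)
    y <- 0.4 * dosage + covars %*% c(1, -0.5) + rnorm(n)
    f <- fit_linear(y, dosage, covars)
    o <- ols_oracle(cbind(1, dosage, covars), y)
    expect_equal(f$beta, unname(o$beta[2]), tolerance = 1e-8)
    expect_equal(f$se, unname(o$se[2]), tolerance = 1e-8)
  }
  # consistency: planted beta recovered within 2 SE
  n <- 300
  dosage <- rbinom(n, 2, 0.3)
  y <- 0.5 * dosage + rnorm(n)
  f <- fit_linear(y, dosage)
  expect_lt(abs(f$beta - 0.5), 2 * f$se)
  # a covariate-driven response leaves the orthogonal dosage null
  covar <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "c1"))
  f2 <- fit_linear(3 * covar[, 1], rbinom(n, 2, 0.4), covar)
  expect_lt(abs(f2$beta), 1e-10)
})

test_that("linear fitter handles missing data and collinearity", {
  set.seed(2)
  n <- 100
  dosage <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  dosage[1:10] <- NA
  f <- fit_linear(y, dosage)
  expect_equal(f$n, 90)
  # dosage collinear with a covariate cannot be tested
  cv <- matrix(dosage, ncol = 1, dimnames = list(NULL, "c1"))
  f2 <- fit_linear(y, dosage, cv)
  expect_true(is.na(f2$beta))
  expect_identical(attr(f2, "reason"), "dosage_collinear")
})

test_that("logistic fitter matches a Newton oracle and takes the Firth path on separation", {
  set.seed(3)
  n <- 500
  dosage <- rbinom(n, 2, 0.3)
  covar <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "c1"))
  pr <- plogis(-0.5 + 0.8 * dosage + 0.3 * covar[, 1])
  y <- rbinom(n, 1, pr)
  f <- fit_logistic(y, dosage, covar)
  expect_false(f$firth)
  X <- cbind(1, dosage, covar)
  b_newton <- logistic_newton_oracle(X, y)
  b_fit <- c(NA, f$log_or, NA)
  expect_equal(f$log_or, unname(b_newton[2]), tolerance = 1e-6)
  expect_equal(logistic_loglik(X, y, b_newton),
               logistic_loglik(X, y,
                               coef(glm.fit(X, y, family = binomial()))),
               tolerance = 1e-6)
  expect_equal(f$or_value, exp(f$log_or))
  # perfectly separated toy: every carrier present
  d2 <- c(rep(0, 30), rep(1, 15), rep(2, 15))
  y2 <- as.numeric(d2 > 0)
  f2 <- fit_logistic(y2, d2)
  expect_true(f2$firth)
  expect_true(is.finite(f2$log_or) && is.finite(f2$se))
  # single-class phenotype is skipped with a reason
  f3 <- fit_logistic(rep(1, 60), rbinom(60, 2, 0.3))
  expect_true(is.na(f3$p))
  expect_identical(attr(f3, "reason"), "single_class")
})

test_that("planted logistic effect is recovered within 2 SE most of the time", {
  set.seed(4)
  hit <- 0
  for (r in 1:30) {
    n <- 600
    dosage <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-1 + 1.0 * dosage))
    f <- fit_logistic(y, dosage)
    if (abs(f$log_or - 1.0) < 2 * f$se) hit <- hit + 1
  }
  expect_gte(hit / 30, 0.85)
})

test_that("Bonferroni thresholds are exact arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 12985047, 140), 3), 2.75e-11)
  expect_equal(signif(bonferroni_threshold(0.05, 1412, 227), 3), 1.56e-7)
  expect_equal(signif(bonferroni_threshold(0.05, 96, 227), 3), 2.29e-6)
  expect_error(bonferroni_threshold(0.05, 0, 10), "positive")
})

test_that("lambda_gc is calibrated and directional", {
  set.seed(5)
  p <- runif(10000)
  l <- lambda_gc(p)
  expect_equal(l$lambda, 1, tolerance = 0.05)
  expect_gt(lambda_gc(p / 2)$lambda, l$lambda)
  expect_equal(suppressWarnings(lambda_gc(rep(0.5, 200)))$lambda,
               qchisq(0.5, 1) / qchisq(0.5, 1), tolerance = 1e-12)
})

test_that("high-impact selection applies the quality, length and MAF rules", {
  n <- 80
  dos <- cbind(
    snv_lowq = rbinom(n, 2, 0.3), snv_ok = rbinom(n, 2, 0.3),
    indel_long = rbinom(n, 2, 0.3), indel_ok = rbinom(n, 2, 0.3),
    snv_rare = rbinom(n, 2, 0.01), snv_mod = rbinom(n, 2, 0.3)
  )
  rownames(dos) <- sprintf("s%02d", 1:n)
  v <- data.frame(
    chrom = "1", pos = 1:6 * 100L, id = colnames(dos),
    ref = c("A", "A", paste0("A", strrep("T", 12)), "AT", "A", "A"),
    alt = c("G", "G", "A", "A", "G", "G"),
    qual = c(29, 40, 50, 25, 40, 40),
    is_indel = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    indel_len = c(0L, 0L, 12L, 1L, 0L, 0L),
    chrom_class = "autosome", stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(dos, v)
  ann <- data.frame(variant_id = v$id,
                    impact = c(rep("HIGH", 5), "MODERATE"),
                    effect_type = "frameshift_variant",
                    gene_symbol = "G1", stringsAsFactors = FALSE)
  sel <- select_high_impact(ann, gm)
  expect_true("snv_ok" %in% sel)       # HIGH SNV, qual 40
  expect_true("indel_ok" %in% sel)     # 1-bp indel, qual 25
  expect_false("snv_lowq" %in% sel)    # SNV qual 29 < 30
  expect_false("indel_long" %in% sel)  # 12 bp > 10
  expect_false("snv_rare" %in% sel)    # MAF 0.01 < 0.05
  expect_false("snv_mod" %in% sel)     # not HIGH
})

test_that("GWAS bookkeeping, null calibration and planted-effect ranking hold", {
  sim <- make_clean_cohort(n = 250, m = 300)
  pe <- planted_effect("var00010", "species_t010", 1.2)
  tabs <- simulate_microbiome(sim$meta, sim$genotypes, planted = list(pe),
                              level_spec = list(species = list(
                                n_taxa = 12, prevalence = 0.95)),
                              seed = 33)
  phen <- route_phenotypes(tabs, core_target = 1)   # keep all taxa
  res <- suppressWarnings(run_gwas(sim$genotypes, phen, sim$meta,
                                   maf_min = 0.05))
  n_var <- length(unique(res$records$ID))
  n_ph <- ncol(phen$quantitative) + ncol(phen$binary)
  expect_equal(nrow(res$records), n_var * n_ph)
  # planted association is the top hit for its phenotype
  key <- grep("species_t010", unique(res$records$phenotype), value = TRUE)
  sub <- res$records[res$records$phenotype == key, ]
  expect_identical(sub$ID[which.min(sub$P)], "var00010")
  # lambda near 1 for the null phenotypes
  expect_true(all(res$lambda > 0.8 & res$lambda < 1.25))
})

test_that("PheWAS excludes PCs, fills genes and thresholds at alpha/(v x p)", {
  sim <- make_clean_cohort(n = 200, m = 200)
  tabs <- simulate_microbiome(sim$meta, sim$genotypes,
                              level_spec = list(species = list(
                                n_taxa = 8, prevalence = 0.9)),
                              seed = 41)
  phen <- route_phenotypes(tabs)
  ann <- simulate_annotations(sim$genotypes, frac_high = 0.3, seed = 43)
  hi <- select_high_impact(ann$annotations, sim$genotypes)
  pw <- suppressWarnings(run_phewas(sim$genotypes, hi, phen, sim$meta,
                                    annotations = ann$annotations))
  n_ph <- ncol(phen$quantitative) + ncol(phen$binary)
  expect_equal(pw$threshold, 0.05 / (length(hi) * n_ph))
  expect_equal(pw$n_tests, length(hi) * n_ph)
  expect_true(all(pw$records$ID %in% hi))
  expect_true(all(!is.na(pw$records$GENE) | TRUE))
})

test_that("gene-based PC regression collapses to the single-SNP test", {
  set.seed(6)
  sim <- make_clean_cohort(n = 200, m = 100)
  gm <- sim$genotypes
  y <- rnorm(200) + 0.4 * gm$dosage[, "var00005"]
  y[is.na(y)] <- rnorm(sum(is.na(y)))
  covars <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "c1"))
  gmap <- list(G1 = "var00005", G2 = c("var00005", "var00005"),
               G3 = c("var00010", "var00011"))
  gt <- gene_based_test(gm, gmap, y, covars)
  f <- fit_linear(y, gm$dosage[, "var00005"], covars)
  p_single <- gt$p[gt$gene == "G1"]
  expect_equal(p_single, f$p, tolerance = 1e-10)
  # two perfectly correlated variants give the same gene p as one alone
  expect_equal(gt$n_components[gt$gene == "G2"], 1L)
  expect_equal(gt$p[gt$gene == "G2"], p_single, tolerance = 1e-10)
  expect_equal(gt$n_components[gt$gene == "G3"], 2L)
})

test_that("variant-to-gene mapping respects half-open intervals", {
  dos <- matrix(rep(c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0), 3), nrow = 10,
                dimnames = list(sprintf("s%02d", 1:10), c("a", "b", "c")))
  v <- data.frame(chrom = "1", pos = c(100L, 150L, 200L), id = c("a", "b", "c"),
                  ref = "A", alt = "G", qual = 50, is_indel = FALSE,
                  indel_len = 0L, chrom_class = "autosome")
  gm <- genotype_matrix(dos, v)
  # gene spans [99, 150) 0-based: holds 1-based positions 100..150
  gl <- data.frame(gene_symbol = "G", chrom = "1", start = 99L, end = 150L)
  gmap <- map_variants_to_genes(gm, gl)
  expect_identical(gmap$G, c("a", "b"))   # pos 200 outside; pos 150 inside
})
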
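#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (plain, not
#' mid-p). Used as a marker-quality filter at the deep tail (p <= 1e-6),
#' where the chi-square approximation is unreliable.
#'
#' @param n_AA,n_Aa,n_aa nonnegative integer genotype counts.
#' @return exact two-sided p-value in (0, 1]; 1 for monomorphic markers.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_data("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 5) stop_data("need total genotype count >= 5")
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)                       # monomorphic
  probs <- hwe_het_probs(n_rare, n)
  obs <- as.character(n_Aa)
  if (!obs %in% names(probs))
    stop_data("heterozygote count incompatible with allele counts")
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-12)])
  min(p, 1)
}

#' Conditional heterozygote-count distribution given allele counts
#'
#' Probabilities of every heterozygote count compatible with `n_rare` rare
#' alleles among `n` diploids, by the standard two-sided recurrence started
#' from the modal count (numerically stable at extreme tails).
#'
#' @param n_rare rare-allele count (0..n).
#' @param n number of diploid individuals.
#' @return named numeric vector, names = heterozygote counts, summing to 1.
#' @keywords internal
hwe_het_probs <- function(n_rare, n) {
  het_max <- min(n_rare, 2 * n - n_rare)
  parity <- n_rare %% 2
  hets <- seq(parity, het_max, by = 2)
  k <- length(hets)
  probs <- numeric(k)
  # start at the expected het count, snapped to the right parity
  mid <- round(n_rare * (2 * n - n_rare) / (2 * n))
  if (mid %% 2 != parity) mid <- mid + 1
  mid <- min(max(mid, parity), het_max)
  i0 <- match(mid, hets)
  probs[i0] <- 1
  if (i0 < k) for (i in i0:(k - 1)) {
    het <- hets[i]
    hom_r <- (n_rare - het) / 2
    hom_c <- n - het - hom_r
    # P(het+2)/P(het) = 4 * hom_r * hom_c / ((het+1)(het+2))
    probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((het + 1) * (het + 2))
  }
  if (i0 > 1) for (i in i0:2) {
    het <- hets[i]
    hom_r <- (n_rare - het) / 2
    hom_c <- n - het - hom_r
    # P(het-2)/P(het) = het(het-1) / (4 (hom_r+1)(hom_c+1))
    probs[i - 1] <- probs[i] * het * (het - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
  }
  probs <- probs / sum(probs)
  names(probs) <- hets
  probs
}

#' X-chromosome homozygosity sex check
#'
#' Computes an inbreeding-style homozygosity excess F on X-chromosome
#' markers: `F = (observed_hom - expected_hom) / (n_used - expected_hom)`
#' with the expectation taken under per-marker Hardy-Weinberg heterozygosity
#' `2pq`. Hemizygous males (dosage 0/2) sit near F = 1; females near F = 0.
#' A sample passes iff (male and F > 0.8) or (female and F < 0.2).
#'
#' @param genotypes a `genotype_matrix` containing X variants.
#' @param meta sample metadata with `sample_id` and `sex`.
#' @param male_min,female_max the pass thresholds (defaults 0.8 / 0.2).
#' @return data.frame with `sample_id`, `x_homozygosity_f`,
#'   `sex_check_pass`. With no X variants, all samples pass with a warning.
#' @export
sex_check <- function(genotypes, meta, male_min = 0.8, female_max = 0.2) {
  ids <- genotypes$samples
  sex <- meta$sex[match(ids, meta$sample_id)]
  x_idx <- genotypes$variants$chrom_class == "X"
  if (!any(x_idx)) {
    warning("no X-chromosome variants; sex check skipped (all pass)")
    return(data.frame(sample_id = ids, x_homozygosity_f = NA_real_,
                      sex_check_pass = TRUE, stringsAsFactors = FALSE))
  }
  d <- genotypes$dosage[, x_idx, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  exp_het <- 2 * p * (1 - p)
  nonmiss <- !is.na(d)
  obs_hom <- rowSums((d == 0 | d == 2) & nonmiss, na.rm = TRUE)
  exp_hom <- nonmiss %*% (1 - exp_het)
  n_used <- rowSums(nonmiss)
  f <- as.numeric((obs_hom - exp_hom) / pmax(n_used - exp_hom, 1e-12))
  pass <- ifelse(sex == "male", f > male_min,
                 ifelse(sex == "female", f < female_max, FALSE))
  pass[is.na(pass)] <- FALSE                 # unknown sex -> flagged
  data.frame(sample_id = ids, x_homozygosity_f = f, sex_check_pass = pass,
             stringsAsFactors = FALSE)
}

#' @keywords internal
kinship_z_matrix <- function(genotypes, maf_min = 0.05) {
  auto <- genotypes$variants$chrom_class == "autosome"
  d <- genotypes$dosage[, auto, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  use <- pmin(p, 1 - p) >= maf_min
  d <- d[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(d, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  miss <- is.na(z)
  z[miss] <- 0
  list(z = z, typed = (!miss) + 0)
}

#' Pairwise relatedness matrix
#'
#' Method-of-moments IBD-proportion estimate per pair: the mean over shared
#' non-missing markers of the product of allele-frequency-standardized
#' dosages, `mean_k (x_ik - 2p_k)(x_jk - 2p_k) / (2 p_k q_k)` (the
#' off-diagonal of a genomic relationship matrix). Identical samples
#' estimate ~1, parent-offspring ~0.5, unrelated ~0.
#'
#' @param genotypes a `genotype_matrix` (autosomal variants with MAF >= 5%
#'   are used; rarer markers are noisy for relatedness).
#' @param min_overlap pairs with fewer overlapping non-missing variants get
#'   `NA` (unreliable).
#' @return list with `pihat` (n x n symmetric matrix, diag 1) and
#'   `overlap` (non-missing variant counts per pair).
#' @export
kinship_matrix <- function(genotypes, min_overlap = 50) {
  zz <- kinship_z_matrix(genotypes)
  overlap <- zz$typed %*% t(zz$typed)
  pihat <- (zz$z %*% t(zz$z)) / pmax(overlap, 1)
  pihat[overlap < min_overlap] <- NA
  diag(pihat) <- 1
  rownames(pihat) <- colnames(pihat) <- genotypes$samples
  list(pihat = pihat, overlap = overlap)
}

#' Relatedness estimate for one sample pair
#'
#' @param genotypes a `genotype_matrix`.
#' @param i,j sample ids or indices.
#' @param min_overlap minimum overlapping non-missing variants; below it
#'   the estimate is returned with attribute `reliable = FALSE`.
#' @return numeric pi-hat estimate.
#' @export
kinship <- function(genotypes, i, j, min_overlap = 50) {
  if (is.character(i)) i <- match(i, genotypes$samples)
  if (is.character(j)) j <- match(j, genotypes$samples)
  zz <- kinship_z_matrix(genotypes)
  typed <- zz$typed[i, ] * zz$typed[j, ]
  n_ok <- sum(typed)
  est <- sum(zz$z[i, ] * zz$z[j, ]) / max(n_ok, 1)
  attr(est, "reliable") <- n_ok >= min_overlap
  est
}

#' Per-sample quality-control filters
#'
#' Applies the per-sample removals in a fixed narrated order, each sample
#' removed for exactly one (the first triggering) reason:
#' duplicates (pi-hat > `dup_threshold`, lower call rate removed), sex-check
#' failure, call rate <= `callrate_min`, heterozygosity beyond `het_sd`
#' standard deviations from the cohort mean, PCA outlier, then residual
#' relatedness (pi-hat > `kinship_max`, lower call rate removed; ties broken
#' by removing the lexicographically later id). Heterozygosity z-scores and
#' PCA are recomputed on the samples surviving the earlier steps.
#'
#' @param genotypes a `genotype_matrix`.
#' @param meta sample metadata (for the sex check); `NULL` skips it.
#' @param callrate_min minimum call rate to keep (default 0.90).
#' @param het_sd heterozygosity z-score cutoff (default 4).
#' @param kinship_max maximum allowed pi-hat between kept samples (0.25).
#' @param dup_threshold pi-hat above which a pair counts as duplicates (0.9).
#' @param pca_sd,pca_components PCA outlier rule (default 6 SD on the first
#'   10 components).
#' @return data.frame sample QC report: `sample_id`, `call_rate`,
#'   `het_rate`, `het_z`, `x_homozygosity_f`, `sex_check_pass`,
#'   `pca_outlier`, `related_to`, `kept`, `reason`.
#' @export
sample_filters <- function(genotypes, meta = NULL, callrate_min = 0.90,
                           het_sd = 4, kinship_max = 0.25,
                           dup_threshold = 0.9, pca_sd = 6,
                           pca_components = 10) {
  ids <- genotypes$samples
  n <- length(ids)
  if (n < 10) stop_data("need at least 10 samples for sample QC")
  d <- genotypes$dosage
  auto <- genotypes$variants$chrom_class == "autosome"
  call_rate <- rowMeans(!is.na(d))
  het_rate <- rowMeans(d[, auto, drop = FALSE] == 1, na.rm = TRUE)

  reason <- rep(NA_character_, n)
  related_to <- rep(NA_character_, n)
  names(reason) <- names(related_to) <- ids

  kin <- kinship_matrix(genotypes)$pihat

  remove_pairs <- function(mat, thr, why, alive) {
    repeat {
      m <- mat
      m[!alive, ] <- NA; m[, !alive] <- NA
      m[lower.tri(m, diag = TRUE)] <- NA
      hit <- which(!is.na(m) & m > thr, arr.ind = TRUE)
      if (nrow(hit) == 0) break
      i <- hit[1, 1]; j <- hit[1, 2]
      drop <- if (call_rate[i] < call_rate[j]) i
      else if (call_rate[j] < call_rate[i]) j
      else max(i, j)                            # tie: later id removed
      other <- if (drop == i) j else i
      reason[ids[drop]] <<- why
      related_to[ids[drop]] <<- ids[other]
      alive[drop] <- FALSE
    }
    alive
  }

  alive <- rep(TRUE, n)
  # 1. platform duplicates
  alive <- remove_pairs(kin, dup_threshold, "duplicate", alive)

  # 2. sex check
  if (!is.null(meta) && any(genotypes$variants$chrom_class == "X")) {
    sc <- sex_check(genotypes, meta)
  } else {
    sc <- data.frame(sample_id = ids, x_homozygosity_f = NA_real_,
                     sex_check_pass = TRUE, stringsAsFactors = FALSE)
  }
  fail_sex <- alive & !sc$sex_check_pass
  reason[fail_sex] <- "sex_check"
  alive[fail_sex] <- FALSE

  # 3. call rate
  fail_cr <- alive & call_rate <= callrate_min
  reason[fail_cr] <- "call_rate"
  alive[fail_cr] <- FALSE

  # 4. heterozygosity outliers (z among survivors)
  het_z <- rep(NA_real_, n)
  mu <- mean(het_rate[alive]); sdv <- stats::sd(het_rate[alive])
  het_z <- (het_rate - mu) / max(sdv, 1e-12)
  fail_het <- alive & abs(het_z) >= het_sd
  reason[fail_het] <- "heterozygosity"
  alive[fail_het] <- FALSE

  # 5. PCA outliers among survivors
  pca_flag <- rep(FALSE, n)
  if (sum(alive) >= 10) {
    sub <- subset_genotypes(genotypes, samples = which(alive))
    po <- pca_outlier_detect(sub, n_components = pca_components,
                             sd_threshold = pca_sd)
    pca_flag[alive] <- po$outlier
  }
  fail_pca <- alive & pca_flag
  reason[fail_pca] <- "pca_outlier"
  alive[fail_pca] <- FALSE

  # 6. residual relatedness
  alive <- remove_pairs(kin, kinship_max, "relatedness", alive)

  data.frame(
    sample_id = ids, call_rate = call_rate, het_rate = het_rate,
    het_z = het_z, x_homozygosity_f = sc$x_homozygosity_f,
    sex_check_pass = sc$sex_check_pass, pca_outlier = pca_flag,
    related_to = related_to, kept = alive, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Per-marker quality-control filters
#'
#' Keeps autosomal variants with missing rate at most `miss_max` and exact
#' HWE p-value above `hwe_p_min`. Expects sample QC already applied.
#'
#' @param genotypes a `genotype_matrix` of QCed samples.
#' @param miss_max maximum missing genotype rate (default 0.05).
#' @param hwe_p_min exclusion threshold: markers with HWE p <= this are
#'   removed (default 1e-6).
#' @return data.frame marker QC report: `variant_id`, `missing_rate`,
#'   `hwe_p`, `autosomal`, `kept`.
#' @export
marker_filters <- function(genotypes, miss_max = 0.05, hwe_p_min = 1e-6) {
  d <- genotypes$dosage
  autosomal <- genotypes$variants$chrom_class == "autosome"
  missing_rate <- colMeans(is.na(d))
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (length(x) < 5 || !autosomal[j]) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  kept <- autosomal & missing_rate <= miss_max &
    (!is.na(hwe_p) & hwe_p > hwe_p_min)
  data.frame(variant_id = genotypes$variants$id,
             missing_rate = missing_rate, hwe_p = hwe_p,
             autosomal = autosomal, kept = kept, stringsAsFactors = FALSE)
}

#' PCA outlier detection on standardized genotypes
#'
#' Principal components of the column-standardized autosomal dosage matrix
#' (missing values mean-imputed for the decomposition only). A sample is an
#' outlier iff any of the first `n_components` scores lies beyond
#' `sd_threshold` standard deviations of that component. Scores double as
#' ancestry covariates for the association scan.
#'
#' @param genotypes a `genotype_matrix`.
#' @param n_components number of leading components to inspect/return
#'   (reduced with a warning when it exceeds the matrix rank).
#' @param sd_threshold outlier cutoff in SD units (default 6).
#' @return list with `scores` (samples x components), `outlier` (logical),
#'   `sdev` (component SDs).
#' @export
pca_outlier_detect <- function(genotypes, n_components = 10,
                               sd_threshold = 6) {
  auto <- genotypes$variants$chrom_class == "autosome"
  d <- genotypes$dosage[, auto, drop = FALSE]
  cm <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- cm[j]
  sds <- apply(d, 2, stats::sd)
  keep <- sds > 0
  z <- scale(d[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-8)
  k <- min(n_components, rank, ncol(pc$x))
  if (k < n_components)
    warning("rank ", rank, " < requested components; using ", k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sdev <- pc$sdev[seq_len(k)]
  outl <- rowSums(abs(sweep(scores, 2, sdev, "/")) > sd_threshold) > 0
  rownames(scores) <- genotypes$samples
  list(scores = scores, outlier = unname(outl), sdev = sdev)
}

#' Run full genotype QC
#'
#' Convenience wrapper: [sample_filters()] then [marker_filters()], returning
#' the filtered genotype matrix plus both reports.
#'
#' @param genotypes a `genotype_matrix`.
#' @param meta sample metadata (optional, enables the sex check).
#' @param ... thresholds passed to [sample_filters()] and
#'   [marker_filters()] (`callrate_min`, `het_sd`, `kinship_max`,
#'   `miss_max`, `hwe_p_min`, ...).
#' @return list with `genotypes` (QCed), `sample_report`, `marker_report`.
#' @export
apply_qc <- function(genotypes, meta = NULL, callrate_min = 0.90,
                     het_sd = 4, kinship_max = 0.25, dup_threshold = 0.9,
                     pca_sd = 6, pca_components = 10, miss_max = 0.05,
                     hwe_p_min = 1e-6) {
  srep <- sample_filters(genotypes, meta, callrate_min = callrate_min,
                         het_sd = het_sd, kinship_max = kinship_max,
                         dup_threshold = dup_threshold, pca_sd = pca_sd,
                         pca_components = pca_components)
  g1 <- subset_genotypes(genotypes, samples = which(srep$kept))
  mrep <- marker_filters(g1, miss_max = miss_max, hwe_p_min = hwe_p_min)
  g2 <- subset_genotypes(g1, variants = which(mrep$kept))
  list(genotypes = g2, sample_report = srep, marker_report = mrep)
}
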
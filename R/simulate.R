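#' Cohort specification for genotype simulation
#'
#' Defaults describe the desk-scale study conditions: 300 samples and 2,000
#' autosomal variants (plus an X block for the sex check), minor-allele
#' frequencies uniform on \[0.05, 0.5\], and light random missingness.
#'
#' @param n_samples number of individuals.
#' @param n_variants number of autosomal variants.
#' @param n_x_variants number of X-chromosome variants (males hemizygous,
#'   coded 0/2); a few hundred are needed for a stable sex-check F.
#' @param maf_range length-2 range for per-variant minor-allele frequency,
#'   or a vector of length `n_variants` giving each MAF.
#' @param missing_rate per-cell probability of a missing genotype.
#' @param n_duplicates number of near-identical sample pairs to plant
#'   (>= 99% genotype sharing).
#' @param n_het_outliers number of heterozygosity-outlier samples to plant
#'   (alternating inflated / deflated het rate, far beyond 4 SD).
#' @param hwe_violation_fraction fraction of autosomal variants drawn with
#'   strong excess homozygosity (inbreeding-style F = 0.8).
#' @param seed integer random seed; fixed seed gives identical output.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 300, n_variants = 2000, n_x_variants = 500,
                        maf_range = c(0.05, 0.5), missing_rate = 0.005,
                        n_duplicates = 0, n_het_outliers = 0,
                        hwe_violation_fraction = 0, seed = 1L) {
  rates <- c(missing_rate, hwe_violation_fraction)
  if (any(rates < 0 | rates > 1)) stop_config("rates must lie in [0, 1]")
  if (n_variants < 10) stop_config("need at least 10 variants for QC stages")
  structure(list(n_samples = n_samples, n_variants = n_variants,
                 n_x_variants = n_x_variants, maf_range = maf_range,
                 missing_rate = missing_rate, n_duplicates = n_duplicates,
                 n_het_outliers = n_het_outliers,
                 hwe_violation_fraction = hwe_violation_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @keywords internal
split_seed <- function(seed, k) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' @keywords internal
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate a genotyped cohort
#'
#' Draws biallelic dosages under Hardy-Weinberg equilibrium,
#' `Binomial(2, MAF)` independently per sample, with optional planted QC
#' defects: HWE-violating variants (excess homozygosity), near-duplicate
#' sample pairs, heterozygosity outliers, and random missingness. An X
#' block consistent with the assigned sex is appended (males hemizygous,
#' dosage 0 or 2).
#'
#' @param spec a [cohort_spec()].
#' @return list with `genotypes` (a `genotype_matrix`), `meta` (sample
#'   metadata data.frame) and `truth` (planted defect bookkeeping).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- split_seed(spec$seed, 6L)
  n <- spec$n_samples
  m <- spec$n_variants
  ids <- sprintf("S%04d", seq_len(n))

  set.seed(seeds[1])
  meta <- data.frame(
    sample_id = ids,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(stats::runif(n, 30, 70), 1),
    batch = sample(c("W36", "W37"), n, replace = TRUE),
    clinical_group = sample(c("normal", "obese", "prediabetic"), n,
                            replace = TRUE, prob = c(0.5, 0.25, 0.25)),
    stringsAsFactors = FALSE
  )

  set.seed(seeds[2])
  mafs <- if (length(spec$maf_range) == 2L)
    stats::runif(m, spec$maf_range[1], spec$maf_range[2]) else spec$maf_range
  dos <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  n_viol <- round(spec$hwe_violation_fraction * m)
  viol_idx <- if (n_viol > 0) seq_len(n_viol) else integer(0)
  for (j in viol_idx) {
    # excess homozygosity: genotype frequencies under inbreeding F = 0.8
    p <- mafs[j]; f <- 0.8
    probs <- c((1 - p)^2 + f * p * (1 - p),
               2 * p * (1 - p) * (1 - f),
               p^2 + f * p * (1 - p))
    dos[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
  }

  set.seed(seeds[3])
  out_idx <- if (spec$n_het_outliers > 0)
    sample(seq_len(n), spec$n_het_outliers) else integer(0)
  for (k in seq_along(out_idx)) {
    i <- out_idx[k]
    het_p <- if (k %% 2L == 1L) 0.95 else 0.02   # alternate inflated/deflated
    is_het <- stats::rbinom(m, 1L, het_p) == 1L
    hom <- 2L * stats::rbinom(m, 1L, mafs)
    dos[i, ] <- ifelse(is_het, 1L, hom)
  }

  set.seed(seeds[4])
  dup_pairs <- NULL
  if (spec$n_duplicates > 0) {
    src <- sample(seq_len(n - spec$n_duplicates), spec$n_duplicates)
    tgt <- n - seq_len(spec$n_duplicates) + 1L
    for (k in seq_len(spec$n_duplicates)) {
      g <- dos[src[k], ]
      flip <- stats::runif(m) < 0.005          # >= 99% sharing
      g[flip] <- sample(0:2, sum(flip), replace = TRUE)
      dos[tgt[k], ] <- g
    }
    dup_pairs <- data.frame(a = ids[src], b = ids[tgt])
  }

  set.seed(seeds[5])
  x_dos <- NULL
  mx <- spec$n_x_variants
  if (mx > 0) {
    x_mafs <- stats::runif(mx, 0.1, 0.5)
    male <- meta$sex == "male"
    x_dos <- vapply(x_mafs, function(p) {
      d <- stats::rbinom(n, 2L, p)
      d[male] <- 2L * stats::rbinom(sum(male), 1L, p)  # hemizygous 0/2
      d
    }, numeric(n))
  }

  set.seed(seeds[6])
  all_dos <- cbind(dos, x_dos)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(all_dos)) < spec$missing_rate,
                   nrow = n)
    all_dos[mask] <- NA
  }

  var_ids <- c(sprintf("var%05d", seq_len(m)),
               if (mx > 0) sprintf("xvar%04d", seq_len(mx)))
  chrom <- c(as.character(rep_len(1:22, m)), rep("X", mx))
  variants <- data.frame(
    chrom = chrom,
    pos = as.integer(seq_along(var_ids) * 1000L),
    id = var_ids,
    ref = "A", alt = "G", qual = 60,
    is_indel = FALSE, indel_len = 0L,
    chrom_class = c(rep("autosome", m), rep("X", mx)),
    stringsAsFactors = FALSE
  )
  rownames(all_dos) <- ids
  colnames(all_dos) <- var_ids
  list(
    genotypes = genotype_matrix(all_dos, variants),
    meta = meta,
    truth = list(mafs = stats::setNames(mafs, var_ids[seq_len(m)]),
                 hwe_violators = var_ids[viol_idx],
                 het_outliers = ids[out_idx],
                 duplicate_pairs = dup_pairs)
  )
}

#' Declare a planted genotype-phenotype effect
#'
#' @param variant_id variant carrying the effect.
#' @param phenotype_name taxon receiving it.
#' @param effect_size slope per ALT allele: on the latent log-abundance
#'   scale for quantitative taxa, log-odds of presence for binary taxa.
#' @param model "quantitative" or "binary".
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(variant_id, phenotype_name, effect_size,
                           model = c("quantitative", "binary")) {
  structure(list(variant_id = variant_id, phenotype_name = phenotype_name,
                 effect_size = effect_size, model = match.arg(model)),
            class = "planted_effect")
}

#' Simulate zero-inflated compositional abundance tables
#'
#' Latent log-abundances are normal with taxon-specific means spanning four
#' orders of magnitude; planted quantitative effects enter the latent scale
#' as `effect_size x dosage`; per-taxon zero-inflation hits declared
#' prevalence targets; planted binary effects act on the presence logit.
#' Columns are closed to the simplex (each sample sums to 1).
#'
#' @param meta sample metadata (defines the sample set and order).
#' @param genotypes a `genotype_matrix` over the same samples.
#' @param planted list of [planted_effect()] objects (may be empty).
#' @param level_spec named list: level -> list(n_taxa, prevalence) where
#'   `prevalence` recycles over taxa. Defaults to one species-level table
#'   of 50 taxa with prevalences spread over (0.15, 1].
#' @param seed integer seed.
#' @return named list of `abundance_table` objects, one per level, with a
#'   `manifest` attribute recording the planted structure.
#' @export
simulate_microbiome <- function(meta, genotypes, planted = list(),
                                level_spec = NULL, seed = 1L) {
  if (is.null(level_spec)) {
    level_spec <- list(species = list(
      n_taxa = 50,
      prevalence = seq(0.15, 1, length.out = 50)
    ))
  }
  ids <- meta$sample_id
  n <- length(ids)
  seeds <- split_seed(seed, length(level_spec))
  out <- list()
  manifest <- list()
  for (li in seq_along(level_spec)) {
    level <- names(level_spec)[li]
    ls <- level_spec[[li]]
    nt <- ls$n_taxa
    prev <- rep_len(ls$prevalence, nt)
    taxa <- sprintf("%s_t%03d", level, seq_len(nt))
    set.seed(seeds[li])
    mu <- log(10^stats::runif(nt, -4, 0))     # ~4 orders of magnitude
    latent <- matrix(stats::rnorm(nt * n, mean = mu, sd = 1), nrow = nt)
    present <- matrix(stats::runif(nt * n) < prev, nrow = nt)
    for (pe in planted) {
      k <- match(pe$phenotype_name, taxa)
      if (is.na(k)) next
      d <- genotypes$dosage[ids, pe$variant_id]
      d[is.na(d)] <- 0
      if (pe$model == "quantitative") {
        if (prev[k] < 0.05)
          warning("planted effect on taxon with prevalence target < 5%; ",
                  "routing will binarize")
        latent[k, ] <- latent[k, ] + pe$effect_size * d
      } else {
        logit <- stats::qlogis(min(max(prev[k], 1e-3), 1 - 1e-3)) +
          pe$effect_size * d
        present[k, ] <- stats::runif(n) < stats::plogis(logit)
      }
    }
    ab <- exp(latent) * present
    # guard: keep every sample non-empty so simplex closure is defined
    empty <- colSums(ab) == 0
    if (any(empty)) {
      top <- which.max(mu)
      ab[top, empty] <- exp(latent[top, empty])
    }
    ab <- sweep(ab, 2, colSums(ab), "/")
    rownames(ab) <- taxa
    colnames(ab) <- ids
    out[[level]] <- abundance_table(ab, level)
    manifest[[level]] <- list(taxa = taxa, prevalence = prev, planted = planted)
  }
  attr(out, "manifest") <- manifest
  out
}

#' Parameters of a moderated mediation triangle
#'
#' Encodes exposure -> mediator -> outcome slopes that may differ between
#' the major-homozygote stratum and the carrier stratum of a focal SNP.
#' In the all-linear case the average causal mediation effect of each
#' stratum equals `a_g * b_g`.
#'
#' @param a_major,a_minor exposure->mediator slope per stratum.
#' @param b_major,b_minor mediator->outcome slope per stratum.
#' @param c_direct direct exposure->outcome slope (shared).
#' @param noise_sd_m,noise_sd_y residual SDs of mediator and outcome.
#' @param focal_maf minor-allele frequency of the focal SNP, in (0, 0.5].
#' @return a `triangle_params` list.
#' @export
triangle_params <- function(a_major = 0.5, a_minor = 0.5, b_major = 0.5,
                            b_minor = 0.5, c_direct = 0.2,
                            noise_sd_m = 1, noise_sd_y = 1,
                            focal_maf = 0.27) {
  if (focal_maf <= 0 || focal_maf > 0.5)
    stop_config("focal_maf must lie in (0, 0.5]")
  structure(list(a_major = a_major, a_minor = a_minor, b_major = b_major,
                 b_minor = b_minor, c_direct = c_direct,
                 noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
                 focal_maf = focal_maf),
            class = "triangle_params")
}

#' Simulate a cohort for genotype-stratified mediation
#'
#' Generates one exposure/mediator/outcome triangle with group-specific
#' slopes, `M = a_g X + e_m`, `Y = c X + b_g M + e_y`, where g splits on the
#' focal SNP (dosage 0 vs 1/2), plus `n_null_snps` SNPs independent of
#' (X, M, Y) with minor-allele frequencies uniform on \[0.25, 0.30\].
#'
#' @param params a [triangle_params()].
#' @param n number of samples.
#' @param n_null_snps number of frequency-matched null SNPs.
#' @param seed integer seed.
#' @return list with `exposure`, `mediator`, `outcome` (one-column
#'   data.frames named carb1 / cytokine1 / homa_ir, rownames = sample ids),
#'   `genotypes` (a `genotype_matrix`; the focal SNP is `rs_focal`), and
#'   `truth` (the params).
#' @export
simulate_mediation_cohort <- function(params, n = 300, n_null_snps = 999,
                                      seed = 1L) {
  stopifnot(inherits(params, "triangle_params"))
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  focal <- stats::rbinom(n, 2L, params$focal_maf)
  minor_grp <- focal >= 1
  x <- stats::rnorm(n)
  a <- ifelse(minor_grp, params$a_minor, params$a_major)
  b <- ifelse(minor_grp, params$b_minor, params$b_major)
  m <- a * x + stats::rnorm(n, sd = params$noise_sd_m)
  y <- params$c_direct * x + b * m + stats::rnorm(n, sd = params$noise_sd_y)
  null_mafs <- stats::runif(n_null_snps, 0.25, 0.30)
  nulls <- vapply(null_mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  dos <- cbind(focal, nulls)
  ids_v <- c("rs_focal", sprintf("null%04d", seq_len(n_null_snps)))
  rownames(dos) <- ids
  colnames(dos) <- ids_v
  variants <- data.frame(
    chrom = as.character(rep_len(1:22, n_null_snps + 1L)),
    pos = as.integer(seq_len(n_null_snps + 1L) * 1000L),
    id = ids_v, ref = "G", alt = "A", qual = 60,
    is_indel = FALSE, indel_len = 0L, chrom_class = "autosome",
    stringsAsFactors = FALSE
  )
  list(
    exposure = data.frame(carb1 = x, row.names = ids),
    mediator = data.frame(cytokine1 = m, row.names = ids),
    outcome = data.frame(homa_ir = y, row.names = ids),
    genotypes = genotype_matrix(dos, variants),
    truth = params
  )
}

#' Simulate a variant impact-annotation table
#'
#' Assigns impact classes to the variants of a genotype matrix so the
#' high-impact PheWAS and gene-based stages can be exercised; a declared
#' fraction gets HIGH impact (frameshift or stop-gain), the rest MODIFIER.
#'
#' @param gm a `genotype_matrix`.
#' @param frac_high fraction of variants annotated HIGH.
#' @param genes_per_chrom gene symbols are recycled within chromosome.
#' @param seed integer seed.
#' @return list with `annotations` (data.frame) and `gene_locations`
#'   (BED-convention data.frame covering every variant).
#' @export
simulate_annotations <- function(gm, frac_high = 0.1, genes_per_chrom = 3,
                                 seed = 1L) {
  set.seed(seed)
  v <- gm$variants
  n <- nrow(v)
  high <- stats::runif(n) < frac_high
  impact <- ifelse(high, "HIGH", "MODIFIER")
  eff <- ifelse(high, sample(c("frameshift_variant", "stop_gained"), n,
                             replace = TRUE), "intergenic_region")
  gene_loc <- do.call(rbind, lapply(split(seq_len(n), v$chrom), function(idx) {
    pos <- v$pos[idx]
    brks <- unique(as.integer(stats::quantile(
      pos, probs = seq(0, 1, length.out = genes_per_chrom + 1))))
    if (length(brks) < 2L) brks <- c(min(pos) - 1L, max(pos))
    data.frame(
      gene_symbol = sprintf("GENE_%s_%d", v$chrom[idx[1]],
                            seq_len(length(brks) - 1L)),
      chrom = v$chrom[idx[1]],
      start = brks[-length(brks)] - 1L,          # 0-based half-open
      end = brks[-1],
      stringsAsFactors = FALSE
    )
  }))
  rownames(gene_loc) <- NULL
  gene_of <- vapply(seq_len(n), function(i) {
    g <- gene_loc[gene_loc$chrom == v$chrom[i] &
                    gene_loc$start <= v$pos[i] - 1L &
                    v$pos[i] - 1L < gene_loc$end, "gene_symbol"]
    if (length(g)) g[1] else NA_character_
  }, character(1))
  ann <- data.frame(
    variant_id = v$id, impact = impact, effect_type = eff,
    gene_symbol = gene_of,
    hgvs_c = ifelse(high, "c.100del", "."),
    hgvs_p = ifelse(high, "p.(Thr34fs)", "."),
    stringsAsFactors = FALSE
  )
  list(annotations = ann, gene_locations = gene_loc)
}
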
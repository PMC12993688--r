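#' Rank-normalize exposure, mediator and outcome tables
#'
#' Applies the Blom rank-normal transform column-wise to the three tables
#' (one dialect for metabolite, cytokine and clinical data; constant
#' columns map to zero with a warning).
#'
#' @param metabolites,cytokines,clinical data.frames of numeric columns
#'   with sample rownames.
#' @return list of the three transformed data.frames.
#' @export
normalize_inputs <- function(metabolites, cytokines, clinical) {
  norm_df <- function(df) {
    out <- df
    for (col in names(df)) out[[col]] <- blom_transform(df[[col]])
    out
  }
  list(metabolites = norm_df(metabolites),
       cytokines = norm_df(cytokines),
       clinical = norm_df(clinical))
}

#' Split samples into genotype strata
#'
#' Major stratum: major-allele homozygotes (dosage 0). Minor stratum:
#' heterozygotes plus minor-allele homozygotes (dosage 1 or 2). Missing
#' dosage belongs to neither.
#'
#' @param dosage named numeric dosage vector.
#' @param min_n strata smaller than this are marked low power (still
#'   computed).
#' @return list with `major`, `minor` (integer indices) and `low_power`.
#' @export
stratify_by_genotype <- function(dosage, min_n = 30) {
  major <- which(!is.na(dosage) & dosage == 0)
  minor <- which(!is.na(dosage) & dosage >= 1)
  list(major = major, minor = minor,
       low_power = min(length(major), length(minor)) < min_n)
}

#' Quasi-Bayesian causal mediation analysis
#'
#' Fits the mediator model `M = a0 + a X` and the outcome model
#' `Y = b0 + c X + b M` by least squares, draws `(a)` and `(c, b)` from
#' their asymptotic normal distributions, and summarizes:
#' ACME = mean(a*b draws), ADE = mean(c draws), TE = ACME + ADE (draws are
#' shared, so the identity is exact). P-values are two-sided Monte-Carlo
#' tail probabilities of the draws; with `nsim` draws the resolution is
#' 1/nsim and exact zeros occur, which is why the Z transformation adds an
#' offset downstream.
#'
#' @param X,M,Y numeric vectors (exposure, mediator, outcome).
#' @param nsim number of quasi-Bayesian draws (default 1000).
#' @param seed integer seed for the draws.
#' @return list of class `mediation_result`: `acme`, `ade`, `te`, their
#'   draw standard errors (`acme_se`, `ade_se`, `te_se`), `p_acme`,
#'   `p_ade`, `p_te`, `nsim`, `n`.
#' @export
fit_mediation <- function(X, M, Y, nsim = 1000, seed = 1L) {
  ok <- stats::complete.cases(X, M, Y)
  X <- X[ok]; M <- M[ok]; Y <- Y[ok]
  n <- length(X)
  if (n < 30) stop_data("mediation needs complete-case n >= 30, got ", n)
  med <- ols_fit(cbind(1, X), M)
  out <- ols_fit(cbind(1, X, M), Y)
  if (any(!is.finite(c(med$coef, out$coef))))
    stop_numeric("mediation model fit did not converge")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  med_draws <- MASS::mvrnorm(nsim, med$coef, med$vcov)
  out_draws <- MASS::mvrnorm(nsim, out$coef, out$vcov)
  a <- med_draws[, 2]
  c_d <- out_draws[, 2]
  b <- out_draws[, 3]
  acme_d <- a * b
  te_d <- acme_d + c_d
  mc_p <- function(d) min(2 * min(mean(d <= 0), mean(d >= 0)), 1)
  structure(list(acme = mean(acme_d), ade = mean(c_d), te = mean(te_d),
                 acme_se = stats::sd(acme_d), ade_se = stats::sd(c_d),
                 te_se = stats::sd(te_d),
                 p_acme = mc_p(acme_d), p_ade = mc_p(c_d), p_te = mc_p(te_d),
                 nsim = nsim, n = n),
            class = "mediation_result")
}

#' @keywords internal
ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  list(coef = fit$coefficients, vcov = sigma2 * xtx_inv)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (n=%d, nsim=%d): ACME=%.4f (p=%.3g) ADE=%.4f (p=%.3g) TE=%.4f (p=%.3g)\n",
              x$n, x$nsim, x$acme, x$p_acme, x$ade, x$p_ade, x$te, x$p_te))
  invisible(x)
}

#' Sample frequency-matched null SNPs
#'
#' Uniform sample without replacement among variants with minor-allele
#' frequency in `[maf_lo, maf_hi]` (closed window), with the focal SNP
#' appended, mirroring the 999-matched-SNPs + focal design.
#'
#' @param genotypes a `genotype_matrix`.
#' @param focal_snp id of the focal variant.
#' @param maf_lo,maf_hi frequency window (defaults 0.25-0.30).
#' @param k number of null SNPs (default 999).
#' @param seed integer seed.
#' @return character vector of k+1 variant ids, focal last.
#' @export
sample_matched_snps <- function(genotypes, focal_snp, maf_lo = 0.25,
                                maf_hi = 0.30, k = 999, seed = 1L) {
  mafs <- maf(genotypes)
  pool <- names(mafs)[mafs >= maf_lo & mafs <= maf_hi]
  pool <- setdiff(pool, focal_snp)
  if (length(pool) < k)
    stop_data("only ", length(pool), " SNPs in the MAF window, need ", k)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  chosen <- if (length(pool) == k) pool else sample(pool, k)
  c(chosen, focal_snp)
}

#' Transform a p-value to a Z-score with an offset
#'
#' `z = qnorm(1 - min(p + offset, 1 - 1e-12))`. The offset (default 0.001,
#' i.e. the Monte-Carlo resolution at nsim = 1000) keeps exact-zero
#' p-values finite; z is monotone decreasing in p and finite everywhere.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param offset added before the quantile transform (default 0.001).
#' @return numeric Z-score(s).
#' @export
p_to_z <- function(p, offset = 0.001) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_data("p-values must lie in [0, 1]")
  stats::qnorm(1 - pmin(p + offset, 1 - 1e-12))
}

#' Genotype-stratified mediation Z-difference scan
#'
#' For every (SNP, triangle) pair: split samples into the major and minor
#' strata of the SNP, run [fit_mediation()] in each stratum, transform the
#' ACME/ADE/TE p-values to Z-scores via [p_to_z()], and report
#' `zdiff = z_major - z_minor` per effect; a record is flagged when any
#' |zdiff| exceeds `z_threshold`. Total mediation fits = n_snps x 2 strata
#' x n_triangles, counted exactly in the `n_fits` attribute. Optionally the
#' signed variant multiplies each Z by the sign of the stratum's point
#' estimate.
#'
#' @param triangles data.frame with `exposure`, `mediator`, `outcome`
#'   column names into the three tables.
#' @param genotypes a `genotype_matrix`.
#' @param exposure,mediator,outcome data.frames (samples in rows, rownames
#'   = sample ids) already normalized.
#' @param snp_ids variants to scan (e.g. from [sample_matched_snps()]).
#' @param nsim quasi-Bayesian draws per fit.
#' @param seed integer master seed; per-fit seeds derive deterministically.
#' @param z_threshold flagging threshold on |zdiff| (default 2).
#' @param signed_z use sign(estimate) * Z instead of the unsigned Z.
#' @param min_stratum strata below this size produce a record with NA
#'   Z-scores and `reason = "stratum_too_small"`.
#' @return data.frame of Z-difference records with attribute `n_fits`.
#' @export
zdiff_scan <- function(triangles, genotypes, exposure, mediator, outcome,
                       snp_ids, nsim = 1000, seed = 1L, z_threshold = 2,
                       signed_z = FALSE, min_stratum = 30) {
  samples <- genotypes$samples
  stopifnot(all(samples %in% rownames(exposure)))
  n_fits <- 0L
  recs <- list()
  for (si in seq_along(snp_ids)) {
    snp <- snp_ids[si]
    dos <- genotypes$dosage[, snp]
    strat <- stratify_by_genotype(dos, min_n = min_stratum)
    for (ti in seq_len(nrow(triangles))) {
      tri <- triangles[ti, ]
      x_all <- exposure[samples, tri$exposure]
      m_all <- mediator[samples, tri$mediator]
      y_all <- outcome[samples, tri$outcome]
      too_small <- length(strat$major) < min_stratum ||
        length(strat$minor) < min_stratum
      if (too_small) {
        recs[[length(recs) + 1L]] <- zdiff_row(
          snp, tri, NULL, NULL, z_threshold, signed_z,
          reason = "stratum_too_small")
        next
      }
      fit_seed <- (seed + 7919L * si + 104729L * ti) %% 2147483629L
      fits <- lapply(list(strat$major, strat$minor), function(idx) {
        fit_mediation(x_all[idx], m_all[idx], y_all[idx], nsim = nsim,
                      seed = fit_seed)
      })
      n_fits <- n_fits + 2L
      recs[[length(recs) + 1L]] <- zdiff_row(snp, tri, fits[[1]], fits[[2]],
                                             z_threshold, signed_z,
                                             reason = NA_character_)
    }
  }
  out <- do.call(rbind, recs)
  attr(out, "n_fits") <- n_fits
  out
}

#' @keywords internal
zdiff_row <- function(snp, tri, maj, mino, z_threshold, signed_z, reason) {
  if (is.null(maj)) {
    z <- rep(NA_real_, 9)
    flags <- rep(NA, 3)
    ests <- rep(NA_real_, 6)
  } else {
    zs <- function(fit) {
      z <- p_to_z(c(fit$p_acme, fit$p_ade, fit$p_te))
      if (signed_z) z <- z * sign(c(fit$acme, fit$ade, fit$te))
      z
    }
    zmaj <- zs(maj); zmin <- zs(mino)
    zd <- zmaj - zmin
    z <- c(zmaj, zmin, zd)
    flags <- abs(zd) > z_threshold
    ests <- c(maj$acme, maj$ade, maj$te, mino$acme, mino$ade, mino$te)
  }
  data.frame(
    snp_id = snp, exposure = tri$exposure, mediator = tri$mediator,
    outcome = tri$outcome,
    z_major_acme = z[1], z_major_ade = z[2], z_major_te = z[3],
    z_minor_acme = z[4], z_minor_ade = z[5], z_minor_te = z[6],
    zdiff_acme = z[7], zdiff_ade = z[8], zdiff_te = z[9],
    acme_major = ests[1], ade_major = ests[2], te_major = ests[3],
    acme_minor = ests[4], ade_minor = ests[5], te_minor = ests[6],
    flagged_acme = flags[1], flagged_ade = flags[2], flagged_te = flags[3],
    flagged = if (is.null(maj)) NA else any(flags),
    reason = reason, stringsAsFactors = FALSE
  )
}

#' Summarize a Z-difference scan against its matched-SNP pool
#'
#' Reports, per effect, the focal SNP's |zdiff| and its percentile position
#' within the null-pool |zdiff| distribution, plus flag counts at the
#' absolute threshold.
#'
#' @param records data.frame from [zdiff_scan()].
#' @param focal_snp id of the focal variant.
#' @return data.frame, one row per effect type.
#' @export
zdiff_pool_summary <- function(records, focal_snp) {
  eff <- c("acme", "ade", "te")
  rows <- lapply(eff, function(e) {
    zd <- records[[paste0("zdiff_", e)]]
    fl <- records[[paste0("flagged_", e)]]
    is_focal <- records$snp_id == focal_snp
    pool <- abs(zd[!is_focal & !is.na(zd)])
    focal <- abs(zd[is_focal])
    data.frame(
      effect = e,
      focal_abs_zdiff = mean(focal, na.rm = TRUE),
      pool_percentile = if (length(pool))
        mean(stats::ecdf(pool)(focal), na.rm = TRUE) else NA_real_,
      pool_q975 = if (length(pool))
        unname(stats::quantile(pool, 0.975)) else NA_real_,
      n_flagged = sum(fl, na.rm = TRUE),
      n_records = sum(!is.na(zd)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
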
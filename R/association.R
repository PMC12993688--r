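#' @keywords internal
build_covariate_matrix <- function(meta, pcs = NULL, samples = NULL,
                                   use = c("age", "sex", "batch",
                                           "clinical_group")) {
  if (is.null(samples)) samples <- meta$sample_id
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  use <- intersect(use, names(meta))
  if (length(use)) {
    df <- meta[, use, drop = FALSE]
    for (col in names(df)) if (is.character(df[[col]]))
      df[[col]] <- factor(df[[col]])
    X <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  } else {
    X <- matrix(numeric(0), nrow = length(samples), ncol = 0)
  }
  rownames(X) <- samples
  if (!is.null(pcs)) {
    pcs <- pcs[samples, , drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  X
}

#' Linear association of one phenotype with one variant
#'
#' Ordinary least squares of `y` on dosage plus covariates; the reported
#' effect, SE and two-sided t-test p-value belong to the dosage
#' coefficient. Complete-case rows only; collinear covariate columns are
#' dropped (a collinear dosage makes the variant unfittable and returns
#' `NA` with a reason).
#'
#' @param y numeric response.
#' @param dosage numeric dosage vector (0/1/2, NA allowed).
#' @param covars numeric covariate matrix (may have 0 columns) or `NULL`.
#' @return list `(beta, se, p, n)`; `NA`s with attribute `reason` when the
#'   fit is impossible.
#' @export
fit_linear <- function(y, dosage, covars = NULL) {
  if (is.null(covars)) covars <- matrix(numeric(0), nrow = length(y), ncol = 0)
  ok <- stats::complete.cases(y, dosage, covars)
  y <- y[ok]; dosage <- dosage[ok]
  X <- design_with_dosage(dosage, covars[ok, , drop = FALSE])
  n <- length(y)
  if (is.null(X)) return(assoc_na("dosage_collinear", n))
  if (n < ncol(X) + 1)
    return(assoc_na("too_few_complete_cases", n))
  qr_x <- qr(X)
  coefs <- qr.coef(qr_x, y)
  res <- y - X %*% coefs
  df <- n - ncol(X)
  if (df < 1) return(assoc_na("no_residual_df", n))
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- which(colnames(X) == "dosage")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  beta <- unname(coefs[j])
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = beta, se = se, p = p, n = n)
}

#' Build a full-rank design with the dosage term last
#'
#' Reduces the covariate block to a linearly independent set first; if
#' appending dosage does not increase the rank the variant is untestable
#' (`NULL` is returned), otherwise the full-rank design including dosage.
#' @keywords internal
design_with_dosage <- function(dosage, covars) {
  X0 <- cbind(`(Intercept)` = 1, covars)
  q0 <- qr(X0)
  if (q0$rank < ncol(X0))
    X0 <- X0[, sort(q0$pivot[seq_len(q0$rank)]), drop = FALSE]
  X <- cbind(X0, dosage = dosage)
  if (qr(X)$rank < ncol(X)) return(NULL)
  X
}

#' @keywords internal
assoc_na <- function(reason, n) {
  out <- list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n)
  attr(out, "reason") <- reason
  out
}

#' Logistic association of a presence/absence phenotype with one variant
#'
#' Maximum-likelihood logistic regression (IRLS via `glm.fit`). When
#' separation is detected (divergent coefficients or boundary fitted
#' probabilities) the model is refit with Jeffreys-prior (Firth)
#' penalization, flagged by `firth = TRUE` in the result.
#'
#' @param presence 0/1 response.
#' @param dosage numeric dosage vector.
#' @param covars covariate matrix or `NULL`.
#' @return list `(log_or, or_value, se, p, n, firth)`; `NA`s with a
#'   `reason` attribute for single-class phenotypes or impossible fits.
#' @export
fit_logistic <- function(presence, dosage, covars = NULL) {
  if (is.null(covars)) covars <- matrix(numeric(0), nrow = length(presence),
                                        ncol = 0)
  ok <- stats::complete.cases(presence, dosage, covars)
  yv <- presence[ok]; dv <- dosage[ok]
  if (length(unique(yv)) < 2) {
    out <- assoc_na("single_class", sum(ok))
    out$log_or <- NA_real_; out$or_value <- NA_real_; out$firth <- FALSE
    return(out)
  }
  X <- design_with_dosage(dv, covars[ok, , drop = FALSE])
  n <- length(yv)
  if (is.null(X)) {
    out <- assoc_na("dosage_collinear", n)
    out$log_or <- NA_real_; out$or_value <- NA_real_; out$firth <- FALSE
    return(out)
  }
  fit <- suppressWarnings(stats::glm.fit(X, yv,
                                         family = stats::binomial()))
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
    any(abs(fit$coefficients) > 15)
  if (separated) {
    ff <- firth_logistic(X, yv)
    b <- ff$coef; se_all <- ff$se; firth <- TRUE
  } else {
    b <- fit$coefficients
    W <- mu * (1 - mu)
    info <- crossprod(X * sqrt(W))
    se_all <- sqrt(diag(solve(info)))
    firth <- FALSE
  }
  j <- which(colnames(X) == "dosage")
  log_or <- unname(b[j]); se <- unname(se_all[j])
  z <- log_or / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(log_or = log_or, or_value = exp(log_or), se = se, p = p, n = n,
       firth = firth)
}

#' Firth-penalized logistic regression
#'
#' Jeffreys-prior penalized IRLS: the score is adjusted by the hat-matrix
#' leverages, giving finite estimates under complete separation.
#'
#' @param X design matrix (including intercept).
#' @param y 0/1 response.
#' @param max_iter,tol convergence controls.
#' @return list with `coef` and `se`.
#' @keywords internal
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * sqrt(W)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(info_inv %*% U)
    # dampen huge steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(U)) < tol) break
  }
  eta <- drop(X %*% b)
  W <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X * sqrt(W))
  list(coef = stats::setNames(b, colnames(X)), se = sqrt(diag(solve(info))))
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi^2_1) / 0.4549`, where the chi-squares are the
#' quantile transform of the p-values. Reported alongside the raw p-values;
#' p-values are not rescaled by default.
#'
#' @param pvalues numeric vector (>= 100 values recommended).
#' @return list of class `lambda_gc` with `lambda` and `n`.
#' @export
lambda_gc <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) < 100)
    warning("lambda estimated from fewer than 100 p-values")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  structure(list(lambda = lambda, n = length(p)), class = "lambda_gc")
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / (n_variants * n_phenotypes)`, exact arithmetic.
#'
#' @param alpha nominal significance level (default 0.05).
#' @param n_variants,n_phenotypes positive test-count factors.
#' @return numeric threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_variants, n_phenotypes = 1) {
  if (n_variants <= 0 || n_phenotypes <= 0)
    stop_config("test counts must be positive")
  alpha / (n_variants * n_phenotypes)
}

#' Genome-wide association scan
#'
#' One covariate-adjusted test per (phenotype, variant) pair: linear
#' regression on the INT scale for quantitative phenotypes, logistic
#' regression on presence/absence for binary ones. Covariates default to
#' age, sex, batch, clinical group and the supplied principal components.
#' A genomic-control lambda is reported per phenotype.
#'
#' @param genotypes QCed `genotype_matrix`.
#' @param phenoset a `phenotype_set` from [route_phenotypes()].
#' @param meta sample metadata.
#' @param pcs samples x components matrix of ancestry covariates (or
#'   `NULL`).
#' @param maf_min variants below this minor-allele frequency are skipped.
#' @param covariate_names metadata columns to adjust for.
#' @return list with `records` (association data.frame in the standard
#'   column layout) and `lambda` (named per-phenotype inflation factors).
#' @export
run_gwas <- function(genotypes, phenoset, meta, pcs = NULL, maf_min = 0.01,
                     covariate_names = c("age", "sex", "batch",
                                         "clinical_group")) {
  samples <- intersect(genotypes$samples, phenoset$samples)
  gm <- subset_genotypes(genotypes, samples = samples)
  covars <- build_covariate_matrix(meta, pcs = pcs, samples = samples,
                                   use = covariate_names)
  keep_var <- maf(gm) >= maf_min
  v <- gm$variants[keep_var, , drop = FALSE]
  dos <- gm$dosage[, keep_var, drop = FALSE]
  afreq <- colMeans(dos, na.rm = TRUE) / 2

  phenos <- c(
    stats::setNames(rep("linear", ncol(phenoset$quantitative)),
                    colnames(phenoset$quantitative)),
    stats::setNames(rep("logistic", ncol(phenoset$binary)),
                    colnames(phenoset$binary))
  )
  out <- vector("list", length(phenos))
  lambdas <- numeric(length(phenos))
  for (pi in seq_along(phenos)) {
    pname <- names(phenos)[pi]
    model <- phenos[[pi]]
    y <- if (model == "linear") phenoset$quantitative[samples, pname]
    else phenoset$binary[samples, pname]
    recs <- lapply(seq_len(ncol(dos)), function(j) {
      f <- if (model == "linear") fit_linear(y, dos[, j], covars)
      else fit_logistic(y, dos[, j], covars)
      eff <- if (model == "linear") f$beta else f$log_or
      data.frame(
        phenotype = pname, CHR = v$chrom[j], POS = v$pos[j], ID = v$id[j],
        GENE = NA_character_, REF = v$ref[j], ALT = v$alt[j],
        ALT_FRQ = afreq[j], EFFECT = eff,
        OR = if (model == "logistic") f$or_value else NA_real_,
        SE = f$se, P = f$p, MODEL = model, N = f$n,
        stringsAsFactors = FALSE
      )
    })
    recs <- do.call(rbind, recs)
    out[[pi]] <- recs
    # indicative on small scans; the standalone lambda_gc() warns below 100
    lambdas[pi] <- suppressWarnings(lambda_gc(recs$P))$lambda
  }
  names(lambdas) <- names(phenos)
  list(records = do.call(rbind, out), lambda = lambdas)
}

#' Select high-impact variants for downstream scans
#'
#' Joins the impact-annotation table to the genotype matrix and keeps
#' variants with HIGH impact that pass the quality rules - SNVs need
#' quality >= 30; indels need length <= 10 bp and quality >= 20 - and then
#' minor-allele frequency >= `maf_min`. Unannotated variants are excluded
#' and counted.
#'
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param genotypes a `genotype_matrix`.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param snv_qual_min,indel_qual_min,indel_len_max quality rules.
#' @return character vector of selected variant ids, with attribute
#'   `n_unannotated`.
#' @export
select_high_impact <- function(annotations, genotypes, maf_min = 0.05,
                               snv_qual_min = 30, indel_qual_min = 20,
                               indel_len_max = 10) {
  v <- genotypes$variants
  idx <- match(v$id, annotations$variant_id)
  n_unannot <- sum(is.na(idx))
  impact <- annotations$impact[idx]
  qual_ok <- ifelse(v$is_indel,
                    v$indel_len <= indel_len_max & v$qual >= indel_qual_min,
                    v$qual >= snv_qual_min)
  qual_ok[is.na(qual_ok)] <- FALSE
  mafs <- maf(genotypes)
  keep <- !is.na(impact) & impact == "HIGH" & qual_ok & mafs >= maf_min
  out <- v$id[keep]
  attr(out, "n_unannotated") <- n_unannot
  out
}

#' Phenome-wide association scan over high-impact variants
#'
#' Same fitters as [run_gwas()] but run variant-major over every routed
#' phenotype, adjusting for age, sex, batch and clinical group only (no
#' principal components). The Bonferroni threshold is
#' `alpha / (n_variants x n_phenotypes)`.
#'
#' @param genotypes a `genotype_matrix` already restricted (or restrictable)
#'   to the high-impact set.
#' @param variant_ids high-impact variant ids from [select_high_impact()].
#' @param phenoset a `phenotype_set`.
#' @param meta sample metadata.
#' @param alpha nominal level for the threshold (default 0.05).
#' @param annotations optional annotation table used to fill the GENE
#'   column.
#' @return list with `records`, `threshold`, `n_tests`.
#' @export
run_phewas <- function(genotypes, variant_ids, phenoset, meta, alpha = 0.05,
                       annotations = NULL) {
  gm <- subset_genotypes(genotypes, variants = variant_ids)
  res <- run_gwas(gm, phenoset, meta, pcs = NULL, maf_min = 0,
                  covariate_names = c("age", "sex", "batch", "clinical_group"))
  n_ph <- ncol(phenoset$quantitative) + ncol(phenoset$binary)
  thr <- bonferroni_threshold(alpha, length(variant_ids), n_ph)
  recs <- res$records
  if (!is.null(annotations))
    recs$GENE <- annotations$gene_symbol[match(recs$ID,
                                               annotations$variant_id)]
  recs$significant <- !is.na(recs$P) & recs$P < thr
  list(records = recs, threshold = thr,
       n_tests = length(variant_ids) * n_ph)
}

#' Map variants into gene bodies
#'
#' Gene intervals follow the BED convention (0-based half-open); a variant
#' at 1-based position p maps to a gene iff `start <= p - 1 < end` on the
#' same chromosome. No flanking window.
#'
#' @param genotypes a `genotype_matrix`.
#' @param gene_locations data.frame from [read_gene_locations()].
#' @return named list: gene_symbol -> character vector of variant ids
#'   (genes with zero mapped variants are absent).
#' @export
map_variants_to_genes <- function(genotypes, gene_locations) {
  v <- genotypes$variants
  out <- lapply(seq_len(nrow(gene_locations)), function(g) {
    hit <- v$chrom == gene_locations$chrom[g] &
      gene_locations$start[g] <= v$pos - 1L &
      v$pos - 1L < gene_locations$end[g]
    v$id[hit]
  })
  names(out) <- gene_locations$gene_symbol
  out[vapply(out, length, integer(1)) > 0]
}

#' Gene-based association via principal-components regression
#'
#' For each gene, the dosages of its variants are reduced to the principal
#' components explaining at least `var_explained` of their variance
#' (rank-deficient sets collapse naturally), and the phenotype is tested by
#' an F-test of the covariates+components model against the covariate-only
#' model. A single-variant gene therefore reproduces that variant's
#' single-SNP linear p-value.
#'
#' @param genotypes a `genotype_matrix`.
#' @param gene_map named list gene -> variant ids (see
#'   [map_variants_to_genes()]).
#' @param y numeric phenotype vector aligned to the genotype samples.
#' @param covars covariate matrix or `NULL`.
#' @param var_explained component-retention target (default 0.999).
#' @return data.frame with `gene`, `n_variants`, `n_components`, `F`, `p`,
#'   `n`.
#' @export
gene_based_test <- function(genotypes, gene_map, y, covars = NULL,
                            var_explained = 0.999) {
  if (is.null(covars)) covars <- matrix(numeric(0),
                                        nrow = length(y), ncol = 0)
  res <- lapply(names(gene_map), function(gene) {
    ids <- gene_map[[gene]]
    G <- genotypes$dosage[, ids, drop = FALSE]
    ok <- stats::complete.cases(y, G, covars)
    Gk <- G[ok, , drop = FALSE]
    yk <- y[ok]
    Ck <- covars[ok, , drop = FALSE]
    Gc <- scale(Gk, center = TRUE, scale = FALSE)
    sv <- svd(Gc)
    lam <- sv$d^2
    pos <- lam > max(lam) * 1e-10
    if (!any(pos)) return(NULL)
    cum <- cumsum(lam[pos]) / sum(lam[pos])
    k <- which(cum >= var_explained)[1]
    PCs <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    X0 <- cbind(1, Ck)
    X1 <- cbind(X0, PCs)
    n <- length(yk)
    if (n <= ncol(X1)) return(NULL)
    rss0 <- sum(stats::lm.fit(X0, yk)$residuals^2)
    fit1 <- stats::lm.fit(X1, yk)
    rss1 <- sum(fit1$residuals^2)
    df1 <- k
    df2 <- n - fit1$rank
    Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
    data.frame(gene = gene, n_variants = length(ids), n_components = k,
               F = Fst, p = p, n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
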
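# Independent oracles and small fixture builders shared across test files.

# Exact HWE enumeration by direct log-factorial arithmetic (independent of
# the package's recurrence-based implementation).
hwe_oracle_probs <- function(n_rare, n) {
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- hets
  p
}

hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0) return(1)
  probs <- hwe_oracle_probs(n_rare, n)
  min(sum(probs[probs <= probs[as.character(n_Aa)] * (1 + 1e-12)]), 1)
}

# tail-probability p-values for every observed het count of one allele-count
# configuration, given its probability vector
hwe_pvals_from_probs <- function(probs) {
  vapply(probs, function(p0) min(sum(probs[probs <= p0 * (1 + 1e-12)]), 1),
         numeric(1))
}

# OLS by explicit normal equations (textbook route, no QR)
ols_oracle <- function(X, y) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * solve(xtx)))
  list(beta = drop(beta), se = se, df = df)
}

# Logistic log-likelihood, for Newton-oracle comparisons
logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Newton-Raphson logistic fit from scratch
logistic_newton_oracle <- function(X, y, max_iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

# a clean small genotype fixture (X block large enough for a stable F)
make_clean_cohort <- function(n = 120, m = 1000, seed = 99, ...) {
  simulate_genotypes(cohort_spec(n_samples = n, n_variants = m,
                                 n_x_variants = 500, missing_rate = 0.002,
                                 seed = seed, ...))
}

# write a tiny hand-rolled VCF and return its path
write_tiny_vcf <- function() {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB\tsampC",
    "1\t100\tv1\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tC\tT\t60\tPASS\t.\tGT\t./.\t0/0\t0/1",
    "2\t300\tv3\tG\tA,T\t70\tPASS\t.\tGT\t0/1\t0/0\t0/0"
  ), path)
  path
}
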
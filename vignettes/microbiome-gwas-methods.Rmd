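---
title: "Methods: host-genetics to gut-microbiome association with microgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-genetics to gut-microbiome association with microgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgwas)
```

## The problem

Microbiome genome-wide association studies (mGWAS) treat the relative
abundance of each microbial taxon or pathway as a phenotype and scan host
genetic variants for association. Three features make this harder than an
ordinary GWAS: the phenotypes are compositional (each sample's abundances
live on the simplex), many taxa are absent from a large fraction of
individuals (zero inflation, which makes transformed abundances look binary
rather than continuous), and cohort sizes are modest, so genotype quality
control and multiple-testing discipline carry most of the weight.
`microgwas` implements that full path - genotype QC, compositional
phenotype preparation with normality-based model routing, covariate-adjusted
association scans, a phenome-wide scan over predicted loss-of-function
variants, a gene-based test, and a genotype-stratified causal-mediation
Z-difference scan - as small, separately testable operations, with synthetic
cohort generators so every stage can be exercised without any external data.

## Genotype quality control

Per-sample filters run in a fixed order, each sample removed for exactly
one (the first triggering) reason:

1. **Platform duplicates**: pairs with relatedness estimate
   $\hat\pi > 0.9$; the lower-call-rate member is dropped (ties break by
   removing the lexicographically later id, so the result is
   deterministic).
2. **Sex check**: an inbreeding-style homozygosity excess on X markers,
   $F = (O_{hom} - E_{hom}) / (n - E_{hom})$ with $E_{hom}$ the
   Hardy-Weinberg expectation $\sum_j (1 - 2p_jq_j)$. Males (hemizygous,
   dosage coded 0/2) pass with $F > 0.8$, females with $F < 0.2$. Samples
   with an unrecognized sex label are flagged, never crashed on. The
   statistic needs a few hundred X markers before its sampling noise
   (roughly $0.5\sqrt{m_X}/(m_X(1-\bar h))$) is comfortably inside the
   0.2 band; the generators default to an X block sized accordingly.
3. **Call rate** $\le 0.90$.
4. **Heterozygosity outliers**: autosomal heterozygosity more than 4 SD
   from the cohort mean, recomputed among the samples surviving earlier
   steps.
5. **PCA outliers**: any of the first 10 principal components of the
   standardized dosage matrix beyond 6 SD. No reference-panel projection
   is used; the package detects internal ancestry outliers only, and the
   6 SD default is deliberately conservative so a homogeneous cohort loses
   nobody. No LD pruning is applied before the PCA.
6. **Residual relatedness**: $\hat\pi > 0.25$ (second-degree or closer),
   again dropping the lower-call-rate member.

Relatedness uses a method-of-moments estimator: the mean over shared
non-missing autosomal markers (MAF $\ge$ 5%) of the product of
allele-frequency-standardized dosages,
$\hat\pi_{ij} = \frac{1}{m}\sum_k z_{ik} z_{jk}$ with
$z = (x - 2p)/\sqrt{2pq}$ - the off-diagonal of a genomic relationship
matrix. It estimates the expected IBD-sharing fraction: ~1 for identical
samples, ~0.5 for parent-offspring, ~0 for unrelated pairs, with null
standard error close to $1/\sqrt{m}$, so the 0.25 and 0.9 thresholds sit
many SDs from the null at the default 2,000 markers. Rare markers are
excluded because their standardized dosages are heavy-tailed and dominate
the estimator's variance. Pairs with fewer than 50 overlapping genotyped
markers are marked unreliable and never trigger a removal.

Per-marker filters keep autosomal variants with missing rate $\le 0.05$
and an exact Hardy-Weinberg p-value $> 10^{-6}$. The HWE test is the exact
conditional test (plain, not mid-p): given the observed allele counts, the
p-value is the total probability of all heterozygote counts no more
probable than the observed one. Probabilities are computed by the standard
two-sided recurrence started at the modal heterozygote count, which is
numerically stable at the $10^{-6}$ tail where the filter operates; a
chi-square approximation is not trusted there. The test suite checks the
implementation against a direct log-factorial enumeration for every
configuration with up to 200 individuals (agreement within $10^{-12}$).

## Phenotype preparation and model routing

Taxa pass two filters, combined by intersection: a **prevalence filter**
(present in strictly more than 25% of samples) and a **core-abundance
filter** (taxa ranked by cohort-mean abundance; the minimal prefix whose
cumulative share strictly exceeds 90% is kept). Whether the original
procedure intersected the two filters or re-normalized between them is not
knowable from its description; intersection is implemented, and both
thresholds are exposed (`min_prev`, `core_target`; `core_target = 1` keeps
everything). Note the strict inequalities: exactly 25 of 100 samples fails
the prevalence rule, and ten taxa of uniform share 0.1 are all needed
before the cumulative share exceeds 0.9.

Retained taxa are transformed by the **rank-based inverse normal
transform** with Blom's offset,
$x \mapsto \Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, average ranks for
ties. The Blom dialect is used everywhere (taxa, metabolites, cytokines,
clinical markers) so one convention serves the whole pipeline. A
pseudo-count of 0.1 is added before ranking; adding a constant is
rank-invariant, so the parameter documents the zero-handling convention
rather than changing the result. A **centered log-ratio** transform is also
provided (zeros replaced by the same 0.1 pseudo-count before logs; each
transformed sample sums to zero by construction), but the association scan
runs on the INT scale by default - the CLR branch exists as a transform
only.

Each transformed taxon is then scored with the **Shapiro-Wilk** statistic
$$W = \frac{\big(\sum_i a_i x_{(i)}\big)^2}{\sum_i (x_i - \bar x)^2},$$
the squared weighted correlation between the ordered sample and expected
normal order statistics. The coefficients $a_i$ and the p-value use
Royston's large-sample approximation (valid to $n = 5000$; cohorts here
are a few hundred), and the implementation is cross-checked against an
independent reference to $10^{-4}$. Taxa with $W \ge 0.95$ are routed to a
**quantitative** (linear-model) phenotype on the INT scale; taxa below the
threshold - in practice the zero-inflated ones, whose INT values retain a
point mass - become **presence/absence** phenotypes (raw abundance
strictly $> 0$), analyzed by logistic regression. Zero-variance taxa route
to binary with a warning. The order is fixed: filter, transform, test,
route.

## Association scans

The quantitative fitter is ordinary least squares with a two-sided t-test
on the dosage coefficient; the binary fitter is maximum-likelihood
logistic regression, with a Jeffreys-prior (Firth) penalized refit -
flagged in the output - whenever separation is detected (non-convergence,
boundary fitted probabilities, or runaway coefficients). Both use
complete-case deletion; missing dosage is never imputed. Covariate blocks
are reduced to a linearly independent set before the dosage term is
appended; if dosage adds no rank the variant is reported untestable rather
than silently absorbed. GWAS covariates are age, sex, sequencing batch,
clinical group and the first 10 genotype PCs; the PheWAS over high-impact
variants uses the same covariates *without* PCs. That asymmetry follows
the source procedure and is preserved deliberately.

High-impact (predicted loss-of-function) variants are selected from an
impact-annotation table by: impact class HIGH, SNV quality $\ge 30$,
indel quality $\ge 20$ and indel length $\le 10$ bp, then MAF $\ge 0.05$.
The gene-based test maps variants into gene bodies (BED-convention
half-open intervals, no flanking window) and reduces each gene's dosage
matrix to the principal components explaining $\ge 99.9\%$ of variance,
testing them jointly by an F-test against the covariate-only model. A
single-variant gene therefore reproduces that variant's single-SNP
p-value, and perfectly correlated variants collapse to one component
rather than breaking the fit.

Multiple-testing thresholds are plain Bonferroni,
$\alpha / (n_{variants} \times n_{phenotypes})$, computed in exact
arithmetic. At the reference scale these give $2.75\times10^{-11}$
(12,985,047 variants x 140 quantitative phenotypes),
$1.56\times10^{-7}$ (1,412 x 227) and $2.29\times10^{-6}$ (96 x 227).
The analogous binary-scan computation, $0.05/(12{,}985{,}047 \times 87) =
4.43\times10^{-11}$, does not equal the reference report's
$9.32\times10^{-11}$; the package recomputes from first principles and
surfaces the discrepancy instead of hard-coding the reported number.
The genomic-control factor $\lambda = \mathrm{median}(\chi^2_1)/0.4549$ is
reported per phenotype but never used to rescale p-values by default.

## Genotype-stratified mediation Z-difference scan

For a focal SNP, samples split into the **major** stratum (major-allele
homozygotes, dosage 0) and the **minor** stratum (carriers, dosage 1 or
2). Within each stratum and for each exposure-mediator-outcome triangle
(e.g. fecal carbohydrate -> cytokine -> insulin-resistance marker), a
quasi-Bayesian causal mediation analysis fits
$M = \alpha_0 + aX$ and $Y = \beta_0 + cX + bM$ by least squares, draws
the coefficients from their asymptotic normal distributions, and reports
ACME $= \overline{a b}$ (the indirect effect through the mediator), ADE
$= \bar c$ (the direct effect) and TE $=$ ACME $+$ ADE - exact by draw
sharing, so the additivity identity holds to the bit. P-values are
two-sided Monte-Carlo tail probabilities of the draws; at the default
1,000 draws the resolution is 0.001 and exact zeros occur, which is why
the Z transformation adds the same 0.001 offset before the quantile:
$z = \Phi^{-1}(1 - \min(p + 0.001,\, 1 - 10^{-12}))$. The offset and the
default draw count are deliberately linked. Mediator and outcome models
are covariate-free within stratum, matching the procedure being
implemented; a covariate hook exists but defaults off.

The scan pairs the focal SNP with 999 null SNPs sampled uniformly from the
MAF window $[0.25, 0.30]$ (closed on both ends), runs both strata for
every (SNP, triangle) pair, and reports
$\Delta Z = z_{major} - z_{minor}$ per effect, flagging
$|\Delta Z| > 2$. At the full layout - 1,000 SNPs x 2 strata x 29
triangles - the scan performs exactly 58,000 mediation fits, counted, not
estimated. Two open choices are resolved as follows and both readings
reported: Z is unsigned by default (small p means large Z regardless of
the effect's sign) with a signed variant (`signed_z = TRUE`) available;
and beyond the absolute $|\Delta Z| > 2$ rule, the focal SNP's percentile
position within the matched pool's $|\Delta Z|$ distribution is reported
(`zdiff_pool_summary()`), so the pool can serve as an empirical null.
Strata smaller than 30 produce a record with missing Z-scores and an
explicit reason rather than an error. Per-fit seeds derive
deterministically from the master seed, and the two strata of a record
share one, which makes the whole scan bit-reproducible and
$\Delta Z$ exactly antisymmetric under stratum relabeling.

## Cohort comparison statistics

Two cohorts' compositions are compared on their shared taxa:
`align_compositions()` intersects taxon names and (by default)
renormalizes each vector to the simplex over the shared set - the raw mode
is kept because published comparisons do not always say which was used,
and the two can differ. On the aligned vectors the package reports the
Pearson correlation (t-test p on $n-2$ df), the Bray-Curtis dissimilarity
$1 - 2\sum_i \min(a_i, b_i) / \sum_i (a_i + b_i)$, and, for technical
replicate pairs, the mean per-pair correlation. Percent-style concordance
figures are Pearson $r \times 100$.

## The synthetic cohort generators

Every generator is a pure function of its spec and seed (one global seed,
split deterministically per sub-generator, so module tests are
independent).

* **Genotypes**: per variant, dosages are Binomial(2, MAF) draws under
  HWE, MAF uniform on [0.05, 0.5] by default, 300 samples x 2,000
  autosomal variants (the cohort size matches the study conditions; the
  variant count is a desk-scale stand-in for millions). Planted defects
  are explicit: a declared fraction of variants drawn with strong excess
  homozygosity (inbreeding $F = 0.8$), near-duplicate pairs sharing
  $\ge 99\%$ of genotypes, heterozygosity outliers far beyond 4 SD, and
  an X block consistent with assigned sex. The planted truth is returned
  so QC tests assert recovery without re-deriving it.
* **Microbiome**: latent log-abundances are normal with taxon means
  spanning ~4 orders of magnitude; planted quantitative effects add
  `effect_size x dosage` on the latent scale; per-taxon zero-inflation
  hits declared prevalence targets (and binary planted effects act on the
  presence logit); columns close to the simplex. This latent
  log-normal + zero-inflation + closure model is the minimal one that
  reproduces the phenotype split the router needs - high-prevalence taxa
  pass $W \ge 0.95$ after INT, low-prevalence taxa fail it - and the
  prevalence parameters are exposed so tests can force both regimes.
* **Mediation cohort**: $M = a_g X + \varepsilon_m$,
  $Y = cX + b_g M + \varepsilon_y$ with stratum-specific slopes on a
  focal SNP (default MAF 0.27), plus null SNPs independent of everything
  with MAF uniform on [0.25, 0.30]. In the all-linear case each stratum's
  ACME equals $a_g b_g$, giving a closed-form oracle.

What the generators do **not** emulate: linkage disequilibrium between
variants, phylogenetic or ecological correlation between taxa,
sequencing-depth artifacts, batch effects on abundances, and real
effect-size spectra (planted effects are self-declared). Passing
calibration and recovery tests on these cohorts therefore demonstrates
the statistical machinery - type-I control under the null, power against
planted structure, exactness of the arithmetic - not performance on any
particular real dataset.

## Numerical choices and degenerate inputs

* HWE probabilities by two-sided recurrence from the mode, normalized at
  the end; ties in the tail-summation use a $1 + 10^{-12}$ relative
  slack so equal-probability configurations are included, matching the
  enumeration convention.
* Shapiro-Wilk on fewer than 3 or more than 5,000 values is an error;
  zero variance routes to binary with a warning rather than failing.
* Monomorphic markers get HWE p = 1 (nothing to test).
* Logistic separation triggers the Firth path with step damping; the
  output flags it so downstream consumers can tell penalized estimates
  apart.
* Multi-allelic VCF records are skipped and counted, not split - the
  pipeline analyzes biallelic dosages only.
* Missing dosage is a distinct state throughout; per-test complete-case
  deletion, never zero-imputation (the PCA mean-imputes internally for
  the decomposition only).
* `p_to_z` clips at $1 - 10^{-12}$ so $p = 1$ maps to a finite Z.

## Problem sizes used by the tests

The packaged test-suite and acceptance script run at desk scale, chosen
so the full suite completes in a few minutes on one CPU: cohorts of
100-300 samples, 300-3,000 variants, 2-50 taxa per level; the mediation
accounting run uses the full 1,000-SNP x 2-strata x 29-triangle layout at
100 quasi-Bayesian draws; calibration suites use 20-100 replicates with
seeds fixed in the test code. The exact-arithmetic results (Bonferroni
thresholds, fit accounting, oracle agreements) are scale-independent;
the stochastic calibrations are tied to these stated sizes.

## Known limitations

* No mixed-model association, LD clumping, meta-analysis, or
  reference-panel ancestry assignment; PCA outlier detection is internal
  to the cohort.
* The gene-based test is a principal-components regression, a documented
  default of that tool family - not a reimplementation of any specific
  external software's internals.
* Mediation assumes sequential ignorability and all-linear models; no
  sensitivity analysis, binary-outcome mediation, or multi-mediator
  models.
* BCF, phased genotypes, structural variants, and chrY/mitochondrial
  handling are out of scope.
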
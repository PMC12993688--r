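#' Default pipeline configuration
#'
#' Flat key-value configuration with every threshold named; the defaults
#' are the pipeline's study conditions (desk-scale synthetic cohort, QC
#' thresholds 0.90 / 4 SD / 0.25 / 1e-6 / 0.05, prevalence 0.25, core
#' abundance 0.90, W threshold 0.95, mediation MAF window 0.25-0.30).
#'
#' @param outdir output directory.
#' @param seed global integer seed.
#' @return named list of class `run_config`.
#' @export
default_config <- function(outdir = tempfile("microgwas_run_"), seed = 1L) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    stages = c("simulate", "qc", "prep", "gwas", "phewas", "genetest",
               "mediate", "compare"),
    # synthetic cohort scale
    n_samples = 150, n_variants = 600, n_x_variants = 300, n_taxa = 30,
    n_duplicates = 1, n_het_outliers = 1, hwe_violation_fraction = 0.01,
    missing_rate = 0.005,
    # QC thresholds
    callrate_min = 0.90, het_sd = 4, kinship_max = 0.25, dup_threshold = 0.9,
    pca_sd = 6, pca_components = 10, miss_max = 0.05, hwe_p_min = 1e-6,
    # phenotype preparation
    min_prev = 0.25, core_target = 0.90, pseudo = 0.1, w_threshold = 0.95,
    # association
    maf_min = 0.05, alpha = 0.05, genomewide_p = 5e-8,
    # mediation scan
    n_triangles = 2, med_k = 50, med_nsim = 200, med_n = 300,
    maf_window_lo = 0.25, maf_window_hi = 0.30, z_threshold = 2
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_config()] values.
#'
#' @param path YAML file of flat key-value settings.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("cannot read config: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order: simulate -> qc -> prep -> gwas ->
#' phewas -> genetest -> mediate -> compare. Every stage writes a TSV
#' report into `config$outdir`; a manifest records the seed and all
#' thresholds, which suffices to reproduce the run bit for bit. Any stage
#' failure halts with the stage name.
#'
#' @param config a `run_config` (see [default_config()], [read_config()]).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      stop_numeric("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  seeds <- split_seed(cfg$seed, 8L)

  # --- simulate ------------------------------------------------------
  if ("simulate" %in% cfg$stages) {
    spec <- cohort_spec(n_samples = cfg$n_samples, n_variants = cfg$n_variants,
                        n_x_variants = cfg$n_x_variants,
                        missing_rate = cfg$missing_rate,
                        n_duplicates = cfg$n_duplicates,
                        n_het_outliers = cfg$n_het_outliers,
                        hwe_violation_fraction = cfg$hwe_violation_fraction,
                        seed = seeds[1])
    sim <- stage("simulate", simulate_genotypes(spec))
    planted <- list(planted_effect("var00001", "species_t030", 0.8))
    tabs <- stage("simulate", simulate_microbiome(
      sim$meta, sim$genotypes, planted = planted,
      level_spec = list(species = list(
        n_taxa = cfg$n_taxa,
        prevalence = seq(0.2, 1, length.out = cfg$n_taxa))),
      seed = seeds[2]))
    ann <- stage("simulate", simulate_annotations(sim$genotypes,
                                                  frac_high = 0.15,
                                                  seed = seeds[3]))
    write_vcf(sim$genotypes, file.path(cfg$outdir, "genotypes.vcf"))
    utils::write.table(sim$meta, file.path(cfg$outdir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_abundance(tabs$species, file.path(cfg$outdir, "abundance_species.tsv"))
    res$sim <- sim; res$tables <- tabs; res$ann <- ann
  }

  # --- qc ------------------------------------------------------------
  if ("qc" %in% cfg$stages) {
    if (is.null(res$sim)) stop_data("qc stage needs simulated inputs upstream")
    qc <- stage("qc", apply_qc(
      res$sim$genotypes, res$sim$meta, callrate_min = cfg$callrate_min,
      het_sd = cfg$het_sd, kinship_max = cfg$kinship_max,
      dup_threshold = cfg$dup_threshold, pca_sd = cfg$pca_sd,
      pca_components = cfg$pca_components, miss_max = cfg$miss_max,
      hwe_p_min = cfg$hwe_p_min))
    utils::write.table(qc$sample_report,
                       file.path(cfg$outdir, "qc_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qc$marker_report,
                       file.path(cfg$outdir, "qc_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$qc <- qc
  }

  # --- prep ----------------------------------------------------------
  if ("prep" %in% cfg$stages) {
    if (is.null(res$qc)) stop_data("prep stage needs QCed genotypes upstream")
    kept <- res$qc$genotypes$samples
    tabs <- lapply(res$tables, function(t)
      abundance_table(t$rel_abund[, kept, drop = FALSE], t$level))
    phen <- stage("prep", route_phenotypes(
      tabs, w_threshold = cfg$w_threshold, min_prev = cfg$min_prev,
      core_target = cfg$core_target, pseudo = cfg$pseudo))
    utils::write.table(phen$assessments,
                       file.path(cfg$outdir, "phenotype_routing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$phen <- phen
  }

  # --- gwas ----------------------------------------------------------
  if ("gwas" %in% cfg$stages) {
    if (is.null(res$phen)) stop_data("gwas stage needs routed phenotypes")
    pcs <- pca_outlier_detect(res$qc$genotypes,
                              n_components = cfg$pca_components)$scores
    gw <- stage("gwas", run_gwas(res$qc$genotypes, res$phen, res$sim$meta,
                                 pcs = pcs, maf_min = cfg$maf_min))
    recs <- gw$records
    n_ph <- ncol(res$phen$quantitative) + ncol(res$phen$binary)
    n_var <- length(unique(recs$ID))
    thr <- bonferroni_threshold(cfg$alpha, n_var, n_ph)
    write_association(recs, file.path(cfg$outdir, "gwas.tsv"))
    write_manifest(list(
      n_variants = n_var, n_phenotypes = n_ph,
      bonferroni_threshold = thr,
      genomewide_threshold = cfg$genomewide_p,
      lambda_median = stats::median(gw$lambda)
    ), file.path(cfg$outdir, "gwas_summary.tsv"))
    res$gwas <- gw
  }

  # --- phewas --------------------------------------------------------
  if ("phewas" %in% cfg$stages) {
    if (is.null(res$gwas)) stop_data("phewas stage needs the GWAS inputs")
    hi <- select_high_impact(res$ann$annotations, res$qc$genotypes,
                             maf_min = cfg$maf_min)
    if (length(hi) > 0) {
      pw <- stage("phewas", run_phewas(res$qc$genotypes, hi, res$phen,
                                       res$sim$meta, alpha = cfg$alpha,
                                       annotations = res$ann$annotations))
      write_association(pw$records, file.path(cfg$outdir, "phewas.tsv"))
      res$phewas <- pw
    }
  }

  # --- genetest ------------------------------------------------------
  if ("genetest" %in% cfg$stages) {
    if (is.null(res$phen)) stop_data("genetest stage needs routed phenotypes")
    gmap <- map_variants_to_genes(res$qc$genotypes, res$ann$gene_locations)
    covars <- build_covariate_matrix(res$sim$meta,
                                     samples = res$qc$genotypes$samples)
    if (ncol(res$phen$quantitative) > 0 && length(gmap) > 0) {
      y <- res$phen$quantitative[res$qc$genotypes$samples, 1]
      gt <- stage("genetest", gene_based_test(res$qc$genotypes, gmap, y,
                                              covars))
      utils::write.table(gt, file.path(cfg$outdir, "gene_based.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$genetest <- gt
    }
  }

  # --- mediate -------------------------------------------------------
  if ("mediate" %in% cfg$stages) {
    med <- stage("mediate", {
      coh <- simulate_mediation_cohort(
        triangle_params(a_major = 0.6, a_minor = 0, b_major = 0.5,
                        b_minor = 0.5),
        n = cfg$med_n, n_null_snps = max(cfg$med_k * 2, 200),
        seed = seeds[4])
      norm <- normalize_inputs(coh$exposure, coh$mediator, coh$outcome)
      snps <- sample_matched_snps(coh$genotypes, "rs_focal",
                                  maf_lo = cfg$maf_window_lo,
                                  maf_hi = cfg$maf_window_hi,
                                  k = cfg$med_k, seed = seeds[5])
      triangles <- data.frame(exposure = "carb1", mediator = "cytokine1",
                              outcome = "homa_ir")[rep(1, cfg$n_triangles), ]
      zd <- zdiff_scan(triangles, coh$genotypes, norm$metabolites,
                       norm$cytokines, norm$clinical, snps,
                       nsim = cfg$med_nsim, seed = seeds[6],
                       z_threshold = cfg$z_threshold)
      list(records = zd, summary = zdiff_pool_summary(zd, "rs_focal"))
    })
    utils::write.table(med$records, file.path(cfg$outdir, "zdiff.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(med$summary, file.path(cfg$outdir, "zdiff_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$mediate <- med
  }

  # --- compare -------------------------------------------------------
  if ("compare" %in% cfg$stages && !is.null(res$tables)) {
    cmp <- stage("compare", {
      tab <- res$tables[[1]]
      half <- seq_len(floor(ncol(tab$rel_abund) / 2))
      a <- abundance_table(tab$rel_abund[, half, drop = FALSE], tab$level)
      b <- abundance_table(tab$rel_abund[, -half, drop = FALSE], tab$level)
      al <- align_compositions(a, b)
      pr <- pearson_r(al)
      data.frame(shared_taxa = length(al$taxa), r = pr$r, p = pr$p,
                 bray_curtis = bray_curtis(al))
    })
    utils::write.table(cmp, file.path(cfg$outdir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$compare <- cmp
  }

  manifest <- cfg[setdiff(names(cfg), "stages")]
  manifest$stages <- paste(cfg$stages, collapse = ",")
  manifest$package_version <- as.character(utils::packageVersion("microgwas"))
  write_manifest(manifest, file.path(cfg$outdir, "manifest.tsv"))
  invisible(res)
}
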
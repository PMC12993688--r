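#' Read biallelic genotypes from a VCF file
#'
#' Loads a VCF (v4.x) into a [genotype_matrix()]. Only biallelic records are
#' kept; multi-allelic records are skipped and counted in the
#' `n_multiallelic_skipped` attribute. Dosage is the ALT-allele count of the
#' GT field; missing genotypes (`./.` or `.`) become `NA`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param region_filter optional character vector of chromosome labels to
#'   keep.
#' @return a `genotype_matrix` with attribute `n_multiallelic_skipped`.
#' @export
read_vcf <- function(path, region_filter = NULL) {
  if (!file.exists(path)) stop_data("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_data("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- !multi
  if (!is.null(region_filter)) keep <- keep & fix$CHROM %in% region_filter
  n_multi <- sum(multi)
  if (n_multi > 0)
    warning("skipped ", n_multi, " multi-allelic record(s)")
  if (!any(keep)) stop_data("no biallelic records retained from ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (ncol(gt) == 0L) stop_data("VCF has no sample columns: ", path)
  fix <- fix[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS, ":", fix$REF, ":", fix$ALT)[is.na(ids) | ids == "."]
  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ids,
    ref = fix$REF,
    alt = fix$ALT,
    qual = ifelse(is.na(fix$QUAL) | fix$QUAL == ".", NA_real_,
                  suppressWarnings(as.numeric(fix$QUAL))),
    is_indel = nchar(fix$REF) != nchar(fix$ALT),
    indel_len = abs(nchar(fix$REF) - nchar(fix$ALT)),
    chrom_class = ifelse(sub("^chr", "", fix$CHROM) %in% c("X", "23"),
                         "X", "autosome"),
    stringsAsFactors = FALSE
  )
  dos <- t(dos)                 # samples x variants
  colnames(dos) <- variants$id
  gm <- genotype_matrix(dos, variants)
  attr(gm, "n_multiallelic_skipped") <- n_multi
  gm
}

#' @keywords internal
gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

#' Write a genotype matrix to VCF
#'
#' Minimal VCF v4.2 writer (GT field only); unphased genotypes, missing
#' dosage written as `./.`. Round-trips through [read_vcf()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE))
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- gm$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], qual[j],
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a relative-abundance table
#'
#' TSV with taxon names in the first column and one column per sample.
#' Enforces the [abundance_table()] invariants: no negative entries and
#' per-sample column sums at most 1 (+1e-6).
#'
#' @param path TSV file.
#' @param level taxonomic level label.
#' @return an `abundance_table`.
#' @export
read_abundance <- function(path, level) {
  if (!file.exists(path)) stop_data("cannot read abundance table: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_data("abundance table needs taxon + sample columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  abundance_table(m, level)
}

#' Write a relative-abundance table
#'
#' @param tab an `abundance_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(tab, path) {
  df <- data.frame(taxon = tab$taxa, tab$rel_abund, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV with columns `sample_id`, `sex` (male/female), `age`, `batch`,
#' `clinical_group` (normal/obese/prediabetic).
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_data("cannot read metadata: ", path)
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  check_sample_meta(meta)
}

#' Read a variant impact-annotation table
#'
#' TSV with columns `variant_id`, `impact` (HIGH/MODERATE/LOW/MODIFIER),
#' `effect_type`, `gene_symbol`, `hgvs_c`, `hgvs_p`.
#'
#' @param path TSV file.
#' @return data.frame of annotation records.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_data("cannot read annotations: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("variant_id", "impact", "effect_type", "gene_symbol")
  miss <- setdiff(needed, names(ann))
  if (length(miss)) stop_data("annotation table missing: ", paste(miss, collapse = ", "))
  ok <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (!all(ann$impact %in% ok))
    stop_data("impact must be one of: ", paste(ok, collapse = ", "))
  ann
}

#' Read gene locations from a BED-like file
#'
#' Columns: chrom, start, end, gene_symbol (tab-separated, no header).
#' BED convention: 0-based half-open intervals, stored as such; a variant
#' at 1-based position p lies in the gene iff `start <= p - 1 < end`.
#'
#' @param path BED-like file.
#' @return data.frame with `gene_symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_locations <- function(path) {
  if (!file.exists(path)) stop_data("cannot read gene locations: ", path)
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop_data("gene location file needs 4 columns")
  out <- data.frame(gene_symbol = bed[[4]], chrom = bed[[1]],
                    start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop_data("gene intervals need start < end")
  out
}

#' Read mediation triangles
#'
#' TSV with header columns `exposure`, `mediator`, `outcome`, one triangle
#' per row.
#'
#' @param path TSV file.
#' @return data.frame of triangles.
#' @export
read_triangles <- function(path) {
  if (!file.exists(path)) stop_data("cannot read triangles: ", path)
  tri <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("exposure", "mediator", "outcome"), names(tri))
  if (length(miss)) stop_data("triangle table missing: ", paste(miss, collapse = ", "))
  tri
}

ASSOC_COLS <- c("CHR", "POS", "ID", "GENE", "REF", "ALT", "ALT_FRQ",
                "EFFECT", "OR", "SE", "P", "MODEL", "N")

#' Write association records
#'
#' TSV with columns CHR, POS, ID, GENE, REF, ALT, ALT_FRQ, EFFECT, OR, SE,
#' P, MODEL, N. Numeric columns are written in full double precision
#' (scientific notation for P) so that [read_association()] reproduces the
#' input exactly.
#'
#' @param records data.frame of association records (see [run_gwas()]).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_association <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_data("records must be a nonempty data.frame")
  out <- records
  for (col in setdiff(ASSOC_COLS, names(out))) out[[col]] <- NA
  out <- out[, ASSOC_COLS]
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  for (col in c("ALT_FRQ", "EFFECT", "OR", "SE"))
    out[[col]] <- fmt(as.numeric(out[[col]]))
  out$P <- ifelse(is.na(records$P), "NA", sprintf("%.16e", records$P))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association records written by [write_association()]
#'
#' @param path TSV file.
#' @return data.frame with the standard association columns.
#' @export
read_association <- function(path) {
  if (!file.exists(path)) stop_data("cannot read association table: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("POS", "ALT_FRQ", "EFFECT", "OR", "SE", "P"))
    df[[col]] <- as.numeric(df[[col]])
  df$N <- as.integer(df$N)
  df
}

#' Write a flat key-value manifest
#'
#' @param values named list of scalars.
#' @param path output file (one `key<TAB>value` per line).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(values, path) {
  lines <- vapply(names(values), function(k) {
    paste0(k, "\t", paste(format(values[[k]], digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
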
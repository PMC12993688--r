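#' Construct a genotype matrix
#'
#' Container for dosage-coded biallelic genotypes: a samples x variants
#' matrix of ALT-allele counts in \{0, 1, 2, NA\} together with the variant
#' records. Missing genotypes stay `NA` and are never imputed; every
#' downstream test uses complete-case deletion.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns,
#'   values in \{0, 1, 2, NA\}; dimnames give sample and variant ids.
#' @param variants data.frame with one row per variant and columns
#'   `chrom`, `pos` (1-based), `id`, `ref`, `alt`, `qual`, `is_indel`,
#'   `indel_len`, `chrom_class` ("autosome" or "X").
#' @return object of class `genotype_matrix` with elements `dosage`,
#'   `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants) {
  if (!is.matrix(dosage)) stop_data("dosage must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop_data("dosage needs sample row names and variant column names")
  if (anyDuplicated(rownames(dosage))) stop_data("sample ids must be unique")
  if (anyDuplicated(colnames(dosage))) stop_data("variant ids must be unique")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop_data("dosage values must be 0, 1, 2 or NA")
  needed <- c("chrom", "pos", "id", "ref", "alt", "qual", "is_indel",
              "indel_len", "chrom_class")
  miss <- setdiff(needed, names(variants))
  if (length(miss)) stop_data("variants table missing: ", paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop_data("variants table and dosage columns disagree")
  if (!identical(variants$id, colnames(dosage)))
    stop_data("variant ids must match dosage column names in order")
  if (any(variants$pos < 1)) stop_data("positions are 1-based, pos >= 1")
  if (any(variants$ref == variants$alt)) stop_data("ref and alt must differ")
  bad <- variants$indel_len != abs(nchar(variants$ref) - nchar(variants$alt))
  if (any(bad)) stop_data("indel_len must equal |len(ref) - len(alt)|")
  structure(
    list(dosage = dosage, variants = variants, samples = rownames(dosage)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d autosomal, %d X)\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(x$variants$chrom_class == "autosome"),
              sum(x$variants$chrom_class == "X")))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param samples,variants character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return a `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  d <- gm$dosage
  v <- gm$variants
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(variants)) {
    d <- d[, variants, drop = FALSE]
    if (is.character(variants)) {
      v <- v[match(variants, v$id), , drop = FALSE]
    } else {
      v <- v[variants, , drop = FALSE]
    }
    rownames(v) <- NULL
  }
  genotype_matrix(d, v)
}

#' Construct a relative-abundance table
#'
#' Taxa x samples relative abundances on the simplex at one taxonomic level
#' (phylum through species, or pathway). Entries are nonnegative and each
#' sample column sums to at most 1 (+1e-6 tolerance).
#'
#' @param rel_abund numeric matrix, taxa in rows, samples in columns, with
#'   dimnames.
#' @param level character level label, one of phylum, class, order, family,
#'   genus, species, pathway.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(rel_abund, level) {
  levels_ok <- c("phylum", "class", "order", "family", "genus", "species",
                 "pathway")
  if (!is.character(level) || length(level) != 1L || !(level %in% levels_ok))
    stop_data("level must be one of: ", paste(levels_ok, collapse = ", "))
  if (!is.matrix(rel_abund)) stop_data("rel_abund must be a matrix")
  if (is.null(rownames(rel_abund)) || is.null(colnames(rel_abund)))
    stop_data("rel_abund needs taxon row names and sample column names")
  if (anyNA(rel_abund)) stop_data("rel_abund must not contain NA")
  if (any(rel_abund < 0)) {
    bad <- which(rel_abund < 0, arr.ind = TRUE)[1, ]
    stop_data("negative abundance for taxon '", rownames(rel_abund)[bad[1]],
              "' in sample '", colnames(rel_abund)[bad[2]], "'")
  }
  cs <- colSums(rel_abund)
  over <- which(cs > 1 + 1e-6)
  if (length(over))
    stop_data("column sum exceeds 1 for sample '",
              colnames(rel_abund)[over[1]], "' (sum = ",
              format(cs[over[1]]), ")")
  structure(list(rel_abund = rel_abund, level = level,
                 taxa = rownames(rel_abund), samples = colnames(rel_abund)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table [%s]: %d taxa x %d samples\n",
              x$level, nrow(x$rel_abund), ncol(x$rel_abund)))
  invisible(x)
}

#' @keywords internal
check_sample_meta <- function(meta) {
  needed <- c("sample_id", "sex", "age", "batch", "clinical_group")
  miss <- setdiff(needed, names(meta))
  if (length(miss)) stop_data("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop_data("duplicate sample ids in metadata")
  bad_sex <- !(meta$sex %in% c("male", "female"))
  if (any(bad_sex))
    warning(sum(bad_sex), " sample(s) with unknown sex label; flagged, not dropped")
  ok_grp <- c("normal", "obese", "prediabetic")
  if (!all(meta$clinical_group %in% ok_grp))
    stop_data("clinical_group must be one of: ", paste(ok_grp, collapse = ", "))
  meta
}

#' Alternate-allele frequency per variant
#'
#' @param gm a `genotype_matrix`.
#' @return named numeric vector of ALT frequencies (mean dosage / 2,
#'   missing excluded).
#' @export
alt_freq <- function(gm) {
  colMeans(gm$dosage, na.rm = TRUE) / 2
}

#' Minor-allele frequency per variant
#'
#' @param gm a `genotype_matrix`.
#' @return named numeric vector, `pmin(f, 1 - f)` of the ALT frequency.
#' @export
maf <- function(gm) {
  f <- alt_freq(gm)
  pmin(f, 1 - f)
}
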
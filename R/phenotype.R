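#' Prevalence filter for taxa
#'
#' Retains a taxon iff it is present (relative abundance strictly > 0) in
#' more than `min_prev` of the samples (strict inequality: exactly 25% of
#' 100 samples does not pass the default).
#'
#' @param table an `abundance_table`.
#' @param min_prev prevalence threshold (default 0.25).
#' @return character vector of retained taxon names.
#' @export
prevalence_filter <- function(table, min_prev = 0.25) {
  prev <- rowMeans(table$rel_abund > 0)
  table$taxa[prev > min_prev]
}

#' Core-abundance filter for taxa
#'
#' Ranks taxa by cohort-mean relative abundance (descending) and retains
#' the minimal prefix whose cumulative share of the total cohort abundance
#' strictly exceeds `target`.
#'
#' @param table an `abundance_table`.
#' @param target cumulative-share target (default 0.90).
#' @return character vector of retained taxon names (original table order).
#' @export
core_abundance_filter <- function(table, target = 0.90) {
  mean_ab <- rowMeans(table$rel_abund)
  total <- sum(mean_ab)
  if (total <= 0) return(character(0))
  ord <- order(mean_ab, decreasing = TRUE)
  cum <- cumsum(mean_ab[ord]) / total
  k <- which(cum > target)[1]
  if (is.na(k)) k <- length(ord)
  keep <- table$taxa[sort(ord[seq_len(k)])]
  keep
}

#' Centered log-ratio transform
#'
#' Per sample: `log(x_i) - mean_j log(x_j)`. Zeros are replaced by the
#' pseudo-count before taking logs; each transformed sample sums to zero.
#'
#' @param table an `abundance_table`, or a nonnegative taxa x samples
#'   matrix.
#' @param pseudo value substituted for exact zeros (default 0.1, the same
#'   convention as the inverse normal transform's pseudo-count).
#' @return taxa x samples matrix of CLR values (columns sum to 0).
#' @export
clr_transform <- function(table, pseudo = 0.1) {
  m <- if (inherits(table, "abundance_table")) table$rel_abund else table
  if (any(m < 0)) stop_data("CLR requires nonnegative input")
  m[m == 0] <- pseudo
  lg <- log(m)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Rank-based inverse normal transform (Blom)
#'
#' Maps values through `qnorm((rank - c) / (n - 2c + 1))` with Blom's
#' offset `c = 3/8` and average ranks for ties. A pseudo-count is added
#' before ranking (the stated zero-handling convention; adding a constant
#' is rank-invariant, so it documents provenance rather than changing the
#' result).
#'
#' @param values numeric vector (NAs propagate).
#' @param pseudo pseudo-count added before ranking (default 0.1).
#' @param blom_c rank offset (default 3/8).
#' @return numeric vector of normal scores, same length and order.
#' @export
int_transform <- function(values, pseudo = 0.1, blom_c = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) stop_data("need at least 3 finite values")
  out <- rep(NA_real_, length(values))
  if (length(unique(x)) == 1L) {
    warning("all values identical; transform maps everything to 0")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x + pseudo, ties.method = "average")
  n <- length(x)
  out[ok] <- stats::qnorm((r - blom_c) / (n - 2 * blom_c + 1))
  out
}

#' Blom rank-normalization (alias of the inverse normal transform)
#'
#' @param values numeric vector.
#' @return normal scores, see [int_transform()].
#' @export
blom_transform <- function(values) int_transform(values, pseudo = 0)

#' Route taxa into quantitative or binary phenotypes
#'
#' Pipeline order: prevalence and core-abundance filters (intersection),
#' inverse normal transform of the retained raw abundances, Shapiro-Wilk on
#' the transformed values, then routing: W >= `w_threshold` becomes a
#' quantitative (INT) phenotype, anything below becomes presence/absence
#' (raw abundance strictly > 0).
#'
#' @param tables a named list of `abundance_table` objects (or one table).
#' @param w_threshold Shapiro-Wilk routing threshold (default 0.95).
#' @param min_prev,core_target filter parameters, see
#'   [prevalence_filter()] and [core_abundance_filter()].
#' @param pseudo pseudo-count for the transform.
#' @return object of class `phenotype_set`: `quantitative` (samples x taxa
#'   matrix of INT values), `binary` (samples x taxa 0/1 matrix),
#'   `assessments` (per-taxon data.frame: level, taxon, W, p, route,
#'   prevalence), `samples`.
#' @export
route_phenotypes <- function(tables, w_threshold = 0.95, min_prev = 0.25,
                             core_target = 0.90, pseudo = 0.1) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) t$level, character(1))
  samples <- tables[[1]]$samples
  quant <- list(); binar <- list(); rows <- list()
  for (level in names(tables)) {
    tab <- tables[[level]]
    if (!identical(tab$samples, samples))
      stop_data("all tables must share the same sample order")
    keep <- intersect(prevalence_filter(tab, min_prev),
                      core_abundance_filter(tab, core_target))
    for (taxon in keep) {
      raw <- tab$rel_abund[taxon, ]
      tx <- int_transform(raw, pseudo = pseudo)
      sw <- suppressWarnings(shapiro_wilk(tx))
      route <- if (!is.na(sw$W) && sw$W >= w_threshold) "quantitative" else "binary"
      key <- paste0(level, "|", taxon)
      if (route == "quantitative") {
        quant[[key]] <- tx
      } else {
        binar[[key]] <- as.numeric(raw > 0)
      }
      rows[[key]] <- data.frame(level = level, taxon = taxon, W = sw$W,
                                p = sw$p, route = route,
                                prevalence = mean(raw > 0),
                                stringsAsFactors = FALSE)
    }
  }
  qmat <- if (length(quant)) do.call(cbind, quant) else
    matrix(numeric(0), nrow = length(samples), ncol = 0)
  bmat <- if (length(binar)) do.call(cbind, binar) else
    matrix(numeric(0), nrow = length(samples), ncol = 0)
  rownames(qmat) <- rownames(bmat) <- samples
  structure(list(quantitative = qmat, binary = bmat,
                 assessments = do.call(rbind, c(rows, make.row.names = FALSE)),
                 samples = samples),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("phenotype_set: %d quantitative + %d binary phenotypes, %d samples\n",
              ncol(x$quantitative), ncol(x$binary), length(x$samples)))
  invisible(x)
}
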
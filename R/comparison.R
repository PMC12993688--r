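#' Align two compositions on their shared taxa
#'
#' Intersects taxon names (order of the first table) and pairs the mean
#' relative abundance vectors; with `renormalize = TRUE` each vector is
#' rescaled to sum to 1 over the shared taxa.
#'
#' @param table_a,table_b `abundance_table` objects or named nonnegative
#'   vectors of (mean) relative abundances.
#' @param renormalize rescale each aligned vector to the simplex (default
#'   TRUE); the raw mode is kept because comparisons are sometimes quoted
#'   on unrenormalized shared-taxon vectors.
#' @return list of class `aligned_composition`: `taxa`, `vector_a`,
#'   `vector_b`, `renormalized`.
#' @export
align_compositions <- function(table_a, table_b, renormalize = TRUE) {
  as_vec <- function(t) {
    if (inherits(t, "abundance_table")) rowMeans(t$rel_abund)
    else if (!is.null(names(t))) t
    else stop_data("need an abundance_table or a named vector")
  }
  a <- as_vec(table_a); b <- as_vec(table_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 2)
    stop_data("need at least 2 shared taxa, found ", length(shared))
  va <- a[shared]; vb <- b[shared]
  if (renormalize) {
    va <- va / sum(va)
    vb <- vb / sum(vb)
  }
  structure(list(taxa = shared, vector_a = unname(va), vector_b = unname(vb),
                 renormalized = renormalize),
            class = "aligned_composition")
}

#' Pearson correlation of aligned compositions
#'
#' Sample Pearson r with a two-sided p-value from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param aligned an `aligned_composition` (length >= 3).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(aligned) {
  a <- aligned$vector_a; b <- aligned$vector_b
  if (length(a) < 3) stop_data("need at least 3 shared taxa for a p-value")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_numeric("zero variance; correlation undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(a_i, b_i)) / sum(a_i + b_i)`; 0 for identical vectors,
#' 1 for disjoint support.
#'
#' @param aligned an `aligned_composition`, or a nonnegative vector (then
#'   `b` must be supplied).
#' @param b optional second vector.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(aligned, b = NULL) {
  if (inherits(aligned, "aligned_composition")) {
    a <- aligned$vector_a; b <- aligned$vector_b
  } else {
    a <- aligned
  }
  if (any(a < 0) || any(b < 0)) stop_data("Bray-Curtis needs nonnegative input")
  tot <- sum(a) + sum(b)
  if (tot == 0) stop_data("both vectors all-zero")
  1 - 2 * sum(pmin(a, b)) / tot
}

#' Mean correlation across replicate pairs
#'
#' @param pairs list of two-element lists/pairs of `abundance_table`s or
#'   named vectors (technical replicates of the same samples/protocol).
#' @param renormalize passed to [align_compositions()].
#' @return list with `mean_r` and `per_pair` (numeric vector).
#' @export
replicate_concordance <- function(pairs, renormalize = TRUE) {
  rs <- vapply(pairs, function(pr) {
    al <- align_compositions(pr[[1]], pr[[2]], renormalize = renormalize)
    pearson_r(al)$r
  }, numeric(1))
  list(mean_r = mean(rs), per_pair = rs)
}
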
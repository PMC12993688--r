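#' Shapiro-Wilk normality statistic and test
#'
#' Computes W = (sum a_i x_(i))^2 / sum (x_i - mean)^2, the squared weighted
#' correlation between the ordered sample and the expected values of normal
#' order statistics. Coefficients a_i use the standard large-sample
#' approximation to the normal order-statistic expectations (Royston's
#' AS R94 formulation, valid for 3 <= n <= 5000), with the matching
#' normalizing transformation for the p-value. W = 1 indicates a perfectly
#' normal-looking sample; the phenotype router treats W >= 0.95 as
#' sufficiently normal for a quantitative model.
#'
#' @param values numeric vector, 3 <= n <= 5000 after NA removal.
#' @return list of class `normality_assessment` with `W`, `p`, `n`,
#'   `coefficients` (the a_i), and `route` ("quantitative" if W >= 0.95,
#'   else "binary"). Zero-variance input returns `W = NA` routed to binary,
#'   with a warning.
#' @export
shapiro_wilk <- function(values) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  if (n < 3 || n > 5000) stop_data("Shapiro-Wilk needs 3 <= n <= 5000")
  ss <- sum((x - mean(x))^2)
  if (ss <= 0) {
    warning("zero variance; W undefined, routing to binary")
    return(structure(list(W = NA_real_, p = NA_real_, n = n,
                          coefficients = rep(NA_real_, n), route = "binary"),
                     class = "normality_assessment"))
  }
  a <- sw_coefficients(n)
  W <- sum(a * x)^2 / ss
  W <- min(W, 1)
  p <- sw_pvalue(W, n)
  route <- if (W >= 0.95) "quantitative" else "binary"
  structure(list(W = W, p = p, n = n, coefficients = a, route = route),
            class = "normality_assessment")
}

#' @export
print.normality_assessment <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.4f, p = %.3g, n = %d -> %s\n",
              x$W, x$p, x$n, x$route))
  invisible(x)
}

#' Shapiro-Wilk coefficients a_i (Royston AS R94)
#'
#' Expected normal order statistics m_i = qnorm((i - 3/8)/(n + 1/4)),
#' normalized, with polynomial corrections to the two extreme weights for
#' n > 5 (one for n <= 5).
#'
#' @param n sample size.
#' @return numeric vector of n antisymmetric coefficients.
#' @keywords internal
sw_coefficients <- function(n) {
  m <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  mm <- sum(m^2)
  u <- 1 / sqrt(n)
  if (n == 3) return(c(-1, 0, 1) * sqrt(0.5))
  a_n <- m[n] / sqrt(mm) +
    -2.706056 * u^5 + 4.434685 * u^4 - 2.071190 * u^3 -
    0.147981 * u^2 + 0.221157 * u
  if (n <= 5) {
    phi <- (mm - 2 * m[n]^2) / (1 - 2 * a_n^2)
    a <- m / sqrt(phi)
    a[n] <- a_n
    a[1] <- -a_n
    return(a)
  }
  a_n1 <- m[n - 1] / sqrt(mm) +
    -3.582633 * u^5 + 5.682633 * u^4 - 1.752461 * u^3 -
    0.293762 * u^2 + 0.042981 * u
  phi <- (mm - 2 * m[n]^2 - 2 * m[n - 1]^2) / (1 - 2 * a_n^2 - 2 * a_n1^2)
  a <- m / sqrt(phi)
  a[n] <- a_n; a[n - 1] <- a_n1
  a[1] <- -a_n; a[2] <- -a_n1
  a
}

#' p-value for the Shapiro-Wilk W (Royston normalizing transformation)
#'
#' @param W the statistic.
#' @param n sample size.
#' @return upper-tail p-value for the null of normality.
#' @keywords internal
sw_pvalue <- function(W, n) {
  if (W >= 1) return(1)
  if (n == 3) {
    pi6 <- 6 / pi
    stqr <- asin(sqrt(0.75))
    p <- pi6 * (asin(sqrt(W)) - stqr)
    return(min(max(p, 1e-19), 1))
  }
  y <- log(1 - W)
  if (n <= 11) {
    gamma <- -2.273 + 0.459 * n
    if (y >= gamma) return(1e-19)
    y <- -log(gamma - y)
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sigma <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
  } else {
    ln <- log(n)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sigma <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
  }
  stats::pnorm((y - mu) / sigma, lower.tail = FALSE)
}
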
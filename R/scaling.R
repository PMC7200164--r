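# Power-law scaling between gene expression and enhancer contact frequency,
# E = c * f^gamma, estimated as the slope of an ordinary least-squares fit on
# log10-log10 axes, with the Spearman rank correlation reported alongside.
# The same machinery fits the scaling between the contact frequencies of two
# regions across an allelic series: an exponent above 1 means one region's
# contact escalates preferentially as insulation is released.

#' Fit a power law between expression and contact frequency
#'
#' Plain OLS of \code{log10(expression)} on \code{log10(contact)}; the slope
#' is the scaling exponent. Zero or negative values are rejected rather than
#' pseudo-counted (they are not log-transformable, and a pseudo-count would
#' be an invented model). Rescaling the expression units changes only the
#' intercept, never the exponent.
#'
#' @param expression Positive expression values, one per sample (relative
#'   units).
#' @param contact Contact-frequency ratios in (0, 1], one per sample.
#' @param samples Optional sample labels (used in error messages).
#' @return A \code{scaling_fit}: \code{exponent}, \code{intercept} (log10),
#'   \code{spearman_rho}, \code{n}, \code{fitted}, \code{residuals}.
#' @export
fit_power_law <- function(expression, contact, samples = NULL) {
  check_loglog_input(expression, "expression", samples)
  check_loglog_input(contact, "contact", samples)
  if (length(expression) != length(contact))
    stop("expression and contact must have equal length")
  n <- length(expression)
  if (n < 3L) stop("need at least 3 samples, got ", n)
  x <- log10(contact); y <- log10(expression)
  fit <- stats::lm(y ~ x)
  rho <- if (stats::var(y) == 0 || stats::var(x) == 0) NA_real_
         else spearman_rho(contact, expression)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 spearman_rho = rho, n = n,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit))),
            class = "scaling_fit")
}

check_loglog_input <- function(v, what, samples = NULL) {
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad) > 0) {
    lab <- if (!is.null(samples)) samples[bad[1]] else paste("row", bad[1])
    stop("non-positive ", what, " value for ", lab,
         ": values must be > 0 for log-log fitting")
  }
  invisible(TRUE)
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "scaling_fit: exponent %.3f, intercept(log10) %.3f, Spearman rho %s, n = %d\n",
    x$exponent, x$intercept,
    if (is.na(x$spearman_rho)) "NA" else sprintf("%.3f", x$spearman_rho),
    x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Invariant under strictly monotone transforms of either variable.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero rank variance: constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Scaling between the contact frequencies of two regions
#'
#' OLS of \code{log10(contact_b)} on \code{log10(contact_a)} across the same
#' samples. An exponent above 1 indicates that region B's contact escalates
#' super-linearly (preferentially) relative to region A's as contacts are
#' released — the signature of preferential gene-enhancer association.
#'
#' @param contact_a,contact_b Positive contact-frequency ratios over the
#'   same samples.
#' @param samples Optional sample labels.
#' @return A \code{scaling_fit}; \code{exponent} is the B-vs-A exponent.
#' @export
contact_contact_scaling <- function(contact_a, contact_b, samples = NULL) {
  fit_power_law(expression = contact_b, contact = contact_a,
                samples = samples)
}
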
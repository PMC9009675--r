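#' Pearson correlation matrix with pairwise tests
#'
#' Product-moment correlations between trait columns (conventionally BLUP
#' means), with two-sided p-values from the t reference
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of freedom. No
#' multiple-testing correction is applied; significance flags at the 5%
#' and 1% levels are provided for annotation.
#'
#' @param x Observation-by-trait numeric matrix or data frame, at least 3
#'   rows, no constant columns.
#' @return An object of class `correlation_matrix`: `r`, `p_value`,
#'   `n`, and a `flags` matrix ("", "*", "**" at 5% / 1%).
#' @export
pearson_matrix <- function(x) {
  m <- as_mean_matrix(x)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 observations")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  flags <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  flags[p < 0.05] <- "*"
  flags[p < 0.01] <- "**"
  diag(flags) <- ""
  structure(list(r = r, p_value = p, n = n, flags = flags),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", ncol(x$r), " traits, n = ", x$n, "\n",
      sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Principal component analysis of trait means
#'
#' Eigen-decomposition of the correlation (default) or covariance matrix
#' of an observation-by-trait matrix, as used for joint-environment
#' biplots: scores, loadings (unit eigenvectors), percent variance
#' explained, and per-variable contributions.
#'
#' @param x Observation-by-trait numeric matrix or data frame.
#' @param standardize Use the correlation matrix (`TRUE`, default) rather
#'   than the covariance matrix.
#' @return An object of class `pca_result`: `scores`, `loadings`,
#'   `eigenvalues`, `var_explained` (percentages summing to 100),
#'   `contributions` (p x k, squared loadings as percentages; each column
#'   sums to 100).
#' @export
pca_traits <- function(x, standardize = TRUE) {
  m <- as_mean_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 observations and 2 variables")
  }
  sds <- apply(m, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  eigenvalues <- pc$sdev^2
  var_explained <- 100 * eigenvalues / sum(eigenvalues)
  contributions <- 100 * pc$rotation^2  # columns of rotation are unit norm
  structure(list(scores = pc$x, loadings = pc$rotation,
                 eigenvalues = eigenvalues, var_explained = var_explained,
                 contributions = contributions),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", ncol(x$loadings), " components\n", sep = "")
  cat("  % variance:", paste(signif(x$var_explained, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-variable contribution to the leading components
#'
#' Squared loadings weighted by the component eigenvalues, normalized to
#' percentages over the first `ncomp` components (the "variable
#' importance" bar of a biplot).
#'
#' @param pca A [pca_traits()] result.
#' @param ncomp Number of leading components to aggregate (default 2).
#' @return Named numeric vector summing to 100.
#' @export
variable_contributions <- function(pca, ncomp = 2) {
  stopifnot(inherits(pca, "pca_result"))
  ncomp <- min(ncomp, ncol(pca$loadings))
  k <- seq_len(ncomp)
  w <- pca$loadings[, k, drop = FALSE]^2 %*% pca$eigenvalues[k]
  drop(100 * w / sum(w))
}

#' Percent change between two values
#'
#' @param reference Baseline value (non-zero).
#' @param observed Observed value.
#' @return `100 * (observed - reference) / reference`.
#' @examples
#' percent_change(163.86, 1574.86) # drought-induced proline increase
#' @export
percent_change <- function(reference, observed) {
  if (any(reference == 0)) stop("reference value must be non-zero")
  100 * (observed - reference) / reference
}
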
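#' Genetic parameters from a fitted trait model
#'
#' Computes the standard genetic-parameter suite from REML variance
#' components:
#' \itemize{
#'   \item broad-sense heritability
#'     \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge} + \sigma^2_e)}
#'   \item mean-basis (genotype-mean) heritability
#'     \eqn{h^2_{mg} = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e +
#'       \sigma^2_e/(eb))}
#'   \item selection accuracy \eqn{h = \sqrt{h^2}} of the headline variant
#'   \item genotype-environment correlation, by default
#'     \eqn{r_{ge} = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge})}
#'     (`rge = "genotypic"`); `rge = "interaction"` gives
#'     \eqn{\sigma^2_{ge} / (\sigma^2_{ge} + \sigma^2_e)}
#'   \item genotypic and residual coefficients of variation
#'     \eqn{CV_g = 100\sqrt{\sigma^2_g}/\mu},
#'     \eqn{CV_r = 100\sqrt{\sigma^2_e}/\mu}, and their ratio.
#' }
#' The mean-basis heritability is the headline variant by default: its
#' square root reproduces published selection accuracies.
#'
#' @param fit A [fit_reml()] result, or a named numeric vector of variance
#'   components `c(genotype =, genotype_environment =, residual =)` (then
#'   `e`, `b` and `mu` must be given).
#' @param variant Which heritability feeds `accuracy`: `"mean"` (default)
#'   or `"broad"`.
#' @param rge Genotype-environment correlation formula: `"genotypic"`
#'   (default) or `"interaction"`.
#' @param e,b,mu Design sizes and grand mean, required only when `fit` is a
#'   raw component vector.
#' @return A one-row tibble of class `genetic_parameters`: `trait`,
#'   `h2_broad`, `h2_mean`, `h2` (headline), `accuracy`, `rge`, `cvg`,
#'   `cvr`, `cv_ratio`, `variant`, `degenerate`.
#' @examples
#' genetic_parameters(c(genotype = 2, genotype_environment = 1,
#'                      residual = 3), e = 2, b = 3, mu = 10)
#' @export
genetic_parameters <- function(fit, variant = c("mean", "broad"),
                               rge = c("genotypic", "interaction"),
                               e = NULL, b = NULL, mu = NULL) {
  variant <- match.arg(variant)
  rge <- match.arg(rge)
  if (inherits(fit, "trait_fit")) {
    vc <- fit$varcomp
    e <- fit$design$e
    b <- fit$design$b
    mu <- fit$grand_mean
    trait <- fit$trait
  } else {
    vc <- fit
    need <- c("genotype", "genotype_environment", "residual")
    if (!all(need %in% names(vc))) {
      stop("component vector must be named: ", paste(need, collapse = ", "))
    }
    if (is.null(e) || is.null(b) || is.null(mu)) {
      stop("e, b and mu are required with raw variance components")
    }
    trait <- NA_character_
  }
  vg <- vc[["genotype"]]
  vge <- vc[["genotype_environment"]]
  ve <- vc[["residual"]]
  if (mu == 0) stop("coefficients of variation undefined: grand mean is 0")
  degenerate <- (vg + vge + ve) == 0
  h2_broad <- if (degenerate) 0 else vg / (vg + vge + ve)
  h2_mean <- if (degenerate) 0 else vg / (vg + vge / e + ve / (e * b))
  h2 <- if (variant == "mean") h2_mean else h2_broad
  rge_val <- if (rge == "genotypic") {
    if (vg + vge == 0) 1 else vg / (vg + vge)
  } else {
    if (vge + ve == 0) 0 else vge / (vge + ve)
  }
  cvg <- 100 * sqrt(vg) / abs(mu)
  cvr <- 100 * sqrt(ve) / abs(mu)
  out <- tibble::tibble(
    trait = trait, h2_broad = h2_broad, h2_mean = h2_mean, h2 = h2,
    accuracy = sqrt(h2), rge = rge_val, cvg = cvg, cvr = cvr,
    cv_ratio = if (cvr == 0) NA_real_ else cvg / cvr,
    variant = variant, degenerate = degenerate)
  class(out) <- c("genetic_parameters", class(out))
  out
}

#' Genetic-parameter table for a set of fitted traits
#'
#' @param fits A list of [fit_reml()] results.
#' @inheritParams genetic_parameters
#' @return A tibble with one `genetic_parameters` row per trait.
#' @export
genetic_parameters_table <- function(fits, variant = c("mean", "broad"),
                                     rge = c("genotypic", "interaction")) {
  variant <- match.arg(variant)
  rge <- match.arg(rge)
  dplyr::bind_rows(lapply(fits, genetic_parameters,
                          variant = variant, rge = rge))
}
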
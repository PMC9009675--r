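#' @importFrom rlang .data
NULL

# Extract one trait's complete-case records with factor columns ready for
# model fitting.
trait_frame <- function(x, trait) {
  stopifnot(inherits(x, "trial_data"))
  if (!trait %in% x$traits$name) stop("unknown trait: ", trait)
  d <- x$data[x$data$trait == trait & !is.na(x$data$value), , drop = FALSE]
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  d$block <- factor(d$block)
  d$env_block <- interaction(d$environment, d$block, sep = ":", drop = TRUE)
  d
}

# Newton refinement of the profiled deviance over theta (>= 0), with a
# boundary-aware finite-difference stencil and a shrinking step ladder.
# Generic optimizers leave ~1e-5 relative error in small variance
# components because the profiled deviance is flat near its optimum; on
# balanced designs the REML solution must reproduce the closed-form
# ANOVA estimators to well under 1e-6 relative, which this recovers.
newton_polish <- function(devfun, th, hs = c(1e-3, 1e-4, 1e-5)) {
  k <- length(th)
  f0 <- devfun(th)
  for (h in hs) {
    g <- numeric(k)
    H <- matrix(0, k, k)
    fp <- numeric(k)
    fm <- numeric(k)
    shift <- pmax(h - th, 0)  # keep the stencil inside theta >= 0
    thc <- th + shift
    f0c <- if (any(shift > 0)) devfun(thc) else f0
    for (i in seq_len(k)) {
      ei <- replace(numeric(k), i, h)
      fp[i] <- devfun(thc + ei)
      fm[i] <- devfun(thc - ei)
      g[i] <- (fp[i] - fm[i]) / (2 * h)
      H[i, i] <- (fp[i] - 2 * f0c + fm[i]) / h^2
    }
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        for (j in seq((i + 1), k)) {
          eij <- replace(replace(numeric(k), i, h), j, h)
          H[i, j] <- H[j, i] <- (devfun(thc + eij) - fp[i] - fp[j] + f0c) /
            h^2
        }
      }
    }
    # gradient was measured at thc; translate the Newton step back to th
    step <- tryCatch(solve(H, g - H %*% shift), error = function(e) NULL)
    if (is.null(step)) next
    cand <- pmax(th - drop(step), 0)
    fc <- devfun(cand)
    if (fc <= f0 + 1e-8) {
      th <- cand
      f0 <- fc
    }
  }
  list(par = th, fval = devfun(th))
}

lmer_quiet <- function(formula, data, reml) {
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE,
                            optCtrl = list(rhoend = 1e-10))
  fit <- suppressMessages(suppressWarnings({
    lmod <- lme4::lFormula(formula, data = data, REML = reml,
                           control = ctrl)
    devfun <- do.call(lme4::mkLmerDevfun, lmod)
    opt <- lme4::optimizeLmer(devfun, optimizer = "bobyqa",
                              control = list(rhoend = 1e-10))
    pol <- newton_polish(devfun, opt$par)
    opt$par <- pol$par
    opt$fval <- pol$fval
    devfun(opt$par)  # leave the devfun environment at the polished optimum
    lme4::mkMerMod(environment(devfun), opt, lmod$reTrms, fr = lmod$fr)
  }))
  conv <- fit@optinfo$conv$opt
  # bobyqa code 3 is a trust-region stall at rhoend precision (typical at a
  # boundary optimum); the Newton refinement above already verified it
  if (!is.null(conv) && !conv %in% c(0, 3)) {
    stop("mixed-model fit did not converge (optimizer code ", conv, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  fit
}

#' Fit the per-trait mixed model by REML
#'
#' Fits \eqn{y = X\beta + Zu + e} for one trait: fixed
#' environment-by-block cell effects (the `eb` vector \eqn{\beta}), random
#' genotype main effects and genotype-by-environment interaction effects,
#' residual error. Variance components are estimated by REML with
#' non-negativity enforced at the boundary; BLUPs are the conditional
#' means of the random effects given the data. A parallel maximum
#' likelihood fit is stored for fixed-effect testing.
#'
#' @param x A [trial_data()] object.
#' @param trait A declared trait name with at least `g + 2` non-missing
#'   observations over at least two genotypes.
#' @return An object of class `trait_fit`: variance components (`varcomp`:
#'   genotype, genotype_environment, residual), `fixed_effects` (one per
#'   environment:block cell), `blup_g`, `blup_ge`, restricted and ML
#'   log-likelihoods, `grand_mean`, `env_means` and the design summary.
#' @export
fit_reml <- function(x, trait) {
  d <- trait_frame(x, trait)
  g <- nlevels(d$genotype)
  e <- nlevels(d$environment)
  if (g < 2) stop("need at least 2 genotypes to separate genetic variance")
  if (nrow(d) < g + 2) {
    stop("trait '", trait, "' has too few non-missing observations (",
         nrow(d), " for ", g, " genotypes)")
  }
  design <- summarize_design(
    trial_data(x$data[x$data$trait == trait, , drop = FALSE],
               x$traits[x$traits$name == trait, , drop = FALSE]))

  if (stats::sd(d$value) == 0) {
    # degenerate trait: no variance anywhere, all components at the boundary
    cells <- levels(d$env_block)
    fe <- stats::setNames(rep(d$value[1], length(cells)), cells)
    ge_grid <- expand.grid(genotype = levels(d$genotype),
                           environment = levels(d$environment),
                           stringsAsFactors = FALSE)
    return(structure(list(
      trait = trait,
      fixed_effects = fe,
      varcomp = c(genotype = 0, genotype_environment = 0, residual = 0),
      blup_g = stats::setNames(rep(0, g), levels(d$genotype)),
      blup_ge = tibble::tibble(genotype = ge_grid$genotype,
                               environment = ge_grid$environment,
                               effect = 0),
      restricted_loglik = NA_real_, ml_loglik = NA_real_,
      grand_mean = d$value[1],
      env_means = stats::setNames(rep(d$value[1], e),
                                  levels(d$environment)),
      design = design, degenerate = TRUE, data = d),
      class = "trait_fit"))
  }

  has_ge <- e >= 2
  form <- if (has_ge) {
    value ~ 0 + env_block + (1 | genotype) + (1 | genotype:environment)
  } else {
    value ~ 0 + env_block + (1 | genotype)
  }
  fit <- lmer_quiet(form, d, reml = TRUE)
  fit_ml <- lmer_quiet(form, d, reml = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  varcomp <- c(genotype = get_vc("genotype"),
               genotype_environment = get_vc("genotype:environment"),
               residual = get_vc("Residual"))

  fe <- lme4::fixef(fit)
  names(fe) <- sub("^env_block", "", names(fe))
  env_of_cell <- sub(":.*$", "", names(fe))
  env_means <- tapply(fe, env_of_cell, mean)

  re <- lme4::ranef(fit)
  blup_g <- stats::setNames(re$genotype[["(Intercept)"]],
                            rownames(re$genotype))
  blup_g <- blup_g[levels(d$genotype)]
  if (has_ge) {
    ge <- re[["genotype:environment"]]
    key <- strsplit(rownames(ge), ":", fixed = TRUE)
    blup_ge <- tibble::tibble(
      genotype = vapply(key, `[`, "", 1),
      environment = vapply(key, `[`, "", 2),
      effect = ge[["(Intercept)"]])
  } else {
    blup_ge <- tibble::tibble(genotype = levels(d$genotype),
                              environment = levels(d$environment)[1],
                              effect = 0)
  }

  structure(list(
    trait = trait,
    fixed_effects = fe,
    varcomp = varcomp,
    blup_g = blup_g,
    blup_ge = blup_ge,
    restricted_loglik = as.numeric(stats::logLik(fit)),
    ml_loglik = as.numeric(stats::logLik(fit_ml)),
    grand_mean = mean(fe),
    env_means = env_means,
    design = design, degenerate = FALSE, data = d),
    class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("<trait_fit> ", x$trait, "\n", sep = "")
  cat("  variance components: genotype = ",
      signif(x$varcomp["genotype"], 5), ", gxe = ",
      signif(x$varcomp["genotype_environment"], 5), ", residual = ",
      signif(x$varcomp["residual"], 5), "\n", sep = "")
  cat("  grand mean = ", signif(x$grand_mean, 6),
      "; REML logLik = ", signif(x$restricted_loglik, 6), "\n", sep = "")
  invisible(x)
}

#' Predicted means from a fitted trait model
#'
#' At the genotype level, the predicted value is the grand mean plus the
#' genotype BLUP (the across-environment genotypic value). At the
#' genotype-by-environment level it adds the environment fixed-effect mean
#' and the interaction BLUP.
#'
#' @param fit A [fit_reml()] result.
#' @param level `"genotype"` or `"genotype_environment"`.
#' @return A tibble with one row per unit and a `predicted` column.
#' @export
blup_means <- function(fit, level = c("genotype", "genotype_environment")) {
  stopifnot(inherits(fit, "trait_fit"))
  level <- match.arg(level)
  if (level == "genotype") {
    tibble::tibble(genotype = names(fit$blup_g),
                   predicted = fit$grand_mean + unname(fit$blup_g))
  } else {
    out <- fit$blup_ge
    out$predicted <- unname(fit$env_means[out$environment]) +
      unname(fit$blup_g[out$genotype]) + out$effect
    out[c("genotype", "environment", "predicted")]
  }
}

lrt_row <- function(term, full, reduced, df) {
  stat <- max(0, 2 * (full - reduced))
  out <- tibble::tibble(term = term, statistic = stat, df = df,
                        p_value = stats::pchisq(stat, df,
                                                lower.tail = FALSE))
  class(out) <- c("lrt_result", class(out))
  out
}

#' Likelihood-ratio test for a random effect
#'
#' Compares the REML log-likelihood of the full model against the model
#' with the tested random term removed; the statistic is referred to a
#' chi-square with 1 df (no boundary mixture, hence conservative).
#'
#' @param x A [trial_data()] object.
#' @param trait A declared trait name.
#' @param term `"genotype"` or `"genotype_environment"`.
#' @return A one-row tibble: `term`, `statistic`, `df`, `p_value`.
#' @export
lrt_random <- function(x, trait,
                       term = c("genotype", "genotype_environment")) {
  term <- match.arg(term)
  d <- trait_frame(x, trait)
  e <- nlevels(d$environment)
  if (term == "genotype_environment" && e < 2) {
    stop("genotype_environment term requires at least 2 environments")
  }
  full_form <- if (e >= 2) {
    value ~ 0 + env_block + (1 | genotype) + (1 | genotype:environment)
  } else {
    value ~ 0 + env_block + (1 | genotype)
  }
  red_form <- if (term == "genotype") {
    if (e >= 2) value ~ 0 + env_block + (1 | genotype:environment)
    else value ~ 0 + env_block + (1 | one)
  } else {
    value ~ 0 + env_block + (1 | genotype)
  }
  full <- lmer_quiet(full_form, d, reml = TRUE)
  if (term == "genotype" && e < 2) {
    # reduced model has no random term left: plain least squares
    red_ll <- as.numeric(stats::logLik(
      stats::lm(value ~ 0 + env_block, data = d), REML = TRUE))
  } else {
    red_ll <- as.numeric(stats::logLik(lmer_quiet(red_form, d, reml = TRUE)))
  }
  lrt_row(term, as.numeric(stats::logLik(full)), red_ll, df = 1L)
}

#' Likelihood-ratio test for the environment fixed effect
#'
#' Maximum-likelihood fits (REML likelihoods are not comparable across
#' fixed structures) of additive environment + block models with and
#' without the environment term, both keeping the full random structure;
#' chi-square reference with e - 1 df.
#'
#' @param x A [trial_data()] object.
#' @param trait A declared trait name observed in at least 2 environments.
#' @return A one-row tibble: `term`, `statistic`, `df`, `p_value`.
#' @export
test_fixed_effects <- function(x, trait) {
  d <- trait_frame(x, trait)
  e <- nlevels(d$environment)
  if (e < 2) stop("environment test requires at least 2 environments")
  full <- lmer_quiet(
    value ~ environment + block + (1 | genotype) + (1 | genotype:environment),
    d, reml = FALSE)
  reduced <- lmer_quiet(
    value ~ block + (1 | genotype) + (1 | genotype:environment),
    d, reml = FALSE)
  lrt_row("environment", as.numeric(stats::logLik(full)),
          as.numeric(stats::logLik(reduced)), df = e - 1L)
}
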
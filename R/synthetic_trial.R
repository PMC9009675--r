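#' Configure a multi-environment trial simulation
#'
#' Defines the generative counterpart of the fitted mixed model. For trait
#' t and plot (i, j, k):
#' \deqn{y = \mu_t + \tau_{tj} + \rho_{tjk} + \alpha_{it} + (\alpha\tau)_{ijt}
#'   + \varepsilon_{ijkt}}
#' with genotype effects \eqn{\alpha \sim N(0, \sigma^2_g)} correlated
#' across traits per `K`, interaction effects
#' \eqn{(\alpha\tau) \sim N(0, \sigma^2_{ge})} and residuals
#' \eqn{\varepsilon \sim N(0, \sigma^2_e)} drawn independently per trait.
#'
#' @param g,e,b Numbers of genotypes, environments, blocks per environment.
#' @param traits Data frame with columns `name`, `mean`, `var_g`, `var_ge`,
#'   `var_e`, `direction` (and optionally `units`); one row per trait.
#' @param tau Environment fixed effects: a `p x e` matrix (rows = traits) or
#'   a length-`e` vector recycled across traits. Default all zero.
#' @param rho Block-within-environment fixed effects: a `p x e x b` array,
#'   an `e x b` matrix recycled across traits, or zero (default).
#' @param K `p x p` genetic correlation matrix for the genotype main
#'   effects (symmetric, unit diagonal, positive semi-definite). Default
#'   identity.
#' @param seed Integer root seed; every draw is derived from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(g, e, b, traits, tau = NULL, rho = NULL,
                              K = NULL, seed = 1L) {
  stopifnot(g >= 1, e >= 1, b >= 1)
  traits <- tibble::as_tibble(traits)
  need <- c("name", "mean", "var_g", "var_ge", "var_e", "direction")
  if (!all(need %in% names(traits))) {
    stop("traits must have columns: ", paste(need, collapse = ", "))
  }
  p <- nrow(traits)
  vc <- as.matrix(traits[c("var_g", "var_ge", "var_e")])
  if (any(vc < 0)) stop("variance components must be non-negative")
  if (is.null(tau)) tau <- matrix(0, p, e)
  if (is.vector(tau)) tau <- matrix(tau, p, e, byrow = TRUE)
  stopifnot(nrow(tau) == p, ncol(tau) == e)
  if (is.null(rho)) rho <- array(0, c(p, e, b))
  if (is.matrix(rho)) rho <- aperm(array(rho, c(e, b, p)), c(3, 1, 2))
  stopifnot(all(dim(rho) == c(p, e, b)))
  if (is.null(K)) K <- diag(p)
  K <- as.matrix(K)
  if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8)) ||
      any(abs(diag(K) - 1) > 1e-8)) {
    stop("K must be symmetric with unit diagonal")
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("K must be positive semi-definite")
  structure(list(g = g, e = e, b = b, traits = traits, tau = tau, rho = rho,
                 K = K, seed = as.integer(seed)),
            class = "simulation_config")
}

# Per-(trait, component) substream seed derived arithmetically from the
# root, so adding traits never perturbs the draws of existing ones.
sub_seed <- function(seed, trait_index, component) {
  (as.double(seed) * 48271 + trait_index * 104729 + component * 7919) %%
    2147483629
}

# Square root factor of K with lower-triangular structure: trait t's
# correlated effects depend only on the first t standard-normal columns.
k_root <- function(K) {
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    # PSD but singular: fall back to symmetric square root
    return(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(K)) %*%
             t(ev$vectors))
  }
  t(chol(K))
}

#' Simulate a multi-trait multi-environment trial
#'
#' Draws a complete g x e x b trial for every configured trait, plus a
#' truth record holding every simulated effect, for parameter-recovery
#' testing. Identical seeds give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `data` (a [trial_data()] object) and
#'   `truth` (list: `genotype` and `ge` effect tibbles, plus the config).
#' @export
simulate_met <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$g; e <- config$e; b <- config$b
  tr <- config$traits
  p <- nrow(tr)
  geno <- sprintf("G%02d", seq_len(g))
  env <- sprintf("E%d", seq_len(e))
  blk <- sprintf("B%d", seq_len(b))

  # genotype main effects: per-trait standard-normal substreams combined
  # through a lower-triangular root of K, then scaled to var_g
  Zg <- matrix(0, g, p)
  for (t in seq_len(p)) {
    set.seed(sub_seed(config$seed, t, 1L))
    Zg[, t] <- stats::rnorm(g)
  }
  L <- k_root(config$K)
  alpha <- (Zg %*% t(L)) * rep(sqrt(tr$var_g), each = g)

  ge_eff <- array(0, c(g, e, p))
  eps <- array(0, c(g, e, b, p))
  for (t in seq_len(p)) {
    set.seed(sub_seed(config$seed, t, 2L))
    ge_eff[, , t] <- stats::rnorm(g * e, sd = sqrt(tr$var_ge[t]))
    set.seed(sub_seed(config$seed, t, 3L))
    eps[, , , t] <- stats::rnorm(g * e * b, sd = sqrt(tr$var_e[t]))
  }

  grid <- expand.grid(genotype = seq_len(g), environment = seq_len(e),
                      block = seq_len(b), trait = seq_len(p))
  i <- grid$genotype; j <- grid$environment; k <- grid$block; t <- grid$trait
  value <- tr$mean[t] + config$tau[cbind(t, j)] + config$rho[cbind(t, j, k)] +
    alpha[cbind(i, t)] + ge_eff[cbind(i, j, t)] + eps[cbind(i, j, k, t)]

  long <- tibble::tibble(genotype = geno[i], environment = env[j],
                         block = blk[k], trait = tr$name[t], value = value)
  specs <- trait_specs(tr$name, tr$direction,
                       units = if ("units" %in% names(tr)) tr$units
                               else NA_character_)
  td <- trial_data(long, specs)

  truth_g <- tibble::as_tibble(as.data.frame(alpha))
  names(truth_g) <- tr$name
  truth_g <- dplyr::bind_cols(tibble::tibble(genotype = geno), truth_g)
  ge_grid <- expand.grid(genotype = seq_len(g), environment = seq_len(e))
  truth_ge <- tibble::tibble(genotype = geno[ge_grid$genotype],
                             environment = env[ge_grid$environment])
  for (t in seq_len(p)) {
    truth_ge[[tr$name[t]]] <- ge_eff[cbind(ge_grid$genotype,
                                           ge_grid$environment, t)]
  }
  list(data = td,
       truth = list(genotype = truth_g, ge = truth_ge, config = config))
}

#' Calibrated wheat drought-trial preset
#'
#' A ready-made [simulation_config()] emulating an 18-genotype, two
#' environment (irrigated control vs drought), three-block wheat trial
#' measuring 12 agronomic, physiological and biochemical traits (GY, HLW,
#' AI, AF, gsI, gsF, pc, Na, K, TPC, ABTS, FRAP). Grand means and variance
#' components are back-calculated from published genetic-parameter
#' summaries for such a trial, so mean-basis heritabilities span roughly
#' 0.03-0.85 across traits; genotype main effects share a block-structured
#' genetic correlation (0.6 within four trait groups). Lower values are
#' desired for Na, gsI and gsF; higher for the rest.
#'
#' @param seed Integer root seed.
#' @return A `simulation_config` with g = 18, e = 2, b = 3 and 12 traits.
#' @export
preset_wheat_drought <- function(seed = 1L) {
  e <- 2; b <- 3
  tr <- tibble::tibble(
    name = c("GY", "HLW", "AI", "AF", "gsI", "gsF",
             "pc", "Na", "K", "TPC", "ABTS", "FRAP"),
    mean = c(4067.728, 73.999, 17.651, 14.451, 0.453, 0.407,
             902.279, 1.960, 28.376, 25.223, 67.431, 70.589),
    h2   = c(0.505, 0.782, 0.289, 0.615, 0.313, 0.224,
             0.850, 0.029, 0.352, 0.810, 0.524, 0.296),
    cvg  = c(7.845, 1.984, 3.464, 10.296, 7.213, 5.348,
             56.604, 1.759, 14.753, 6.649, 10.840, 7.867),
    cvr  = c(7.414, 2.041, 13.300, 16.357, 26.165, 16.003,
             5.876, 4.583, 3.924, 4.660, 6.502, 5.502),
    direction = c("increase", "increase", "increase", "increase",
                  "decrease", "decrease", "increase", "decrease",
                  "increase", "increase", "increase", "increase"),
    units = c("kg/ha", "kg/hL", "umol CO2/m2/s", "umol CO2/m2/s",
              "mol H2O/m2/s", "mol H2O/m2/s", "ug/g", "mg/g", "mg/g",
              "mg GAE/g", "mM TEAC/g", "mM Fe2+/g")
  )
  tr$var_g <- (tr$cvg * tr$mean / 100)^2
  tr$var_e <- (tr$cvr * tr$mean / 100)^2
  # invert mean-basis h2 = vg / (vg + vge/e + ve/(e*b)) for vge
  tr$var_ge <- pmax(0, e * (tr$var_g / tr$h2 - tr$var_g - tr$var_e / (e * b)))

  # drought response as a signed fraction of the grand mean per trait
  shift <- c(GY = -0.15, HLW = -0.01, AI = -0.30, AF = -0.30, gsI = -0.40,
             gsF = -0.30, pc = 1.20, Na = 0.25, K = 0.30, TPC = 0.15,
             ABTS = 0.10, FRAP = 0.15)
  tau <- cbind(control = -tr$mean * shift / 2, drought = tr$mean * shift / 2)

  # mild block gradients within each environment, scaled to residual sd
  rho <- array(0, c(nrow(tr), e, b))
  for (t in seq_len(nrow(tr))) {
    rho[t, , ] <- sqrt(tr$var_e[t]) * rbind(c(-0.3, 0, 0.3), c(0.3, -0.3, 0))
  }

  groups <- list(c("TPC", "ABTS", "K", "Na", "AI"),
                 c("FRAP", "gsI", "gsF"),
                 c("pc", "AF"),
                 c("GY", "HLW"))
  K <- diag(nrow(tr))
  dimnames(K) <- list(tr$name, tr$name)
  for (grp in groups) {
    K[grp, grp] <- 0.6
  }
  diag(K) <- 1
  simulation_config(g = 18, e = e, b = b,
                    traits = tr[c("name", "mean", "var_g", "var_ge", "var_e",
                                  "direction", "units")],
                    tau = tau, rho = rho, K = K, seed = seed)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file with fields `g`, `e`, `b`, `seed`, a `traits` list
#'   (name, mean, var_g, var_ge, var_e, direction), and optional `tau`,
#'   `rho`, `K`.
#' @return A [simulation_config()].
#' @export
load_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  traits <- dplyr::bind_rows(lapply(raw$traits, tibble::as_tibble))
  tau <- if (!is.null(raw$tau)) do.call(rbind, raw$tau) else NULL
  K <- if (!is.null(raw$K)) do.call(rbind, raw$K) else NULL
  simulation_config(g = raw$g, e = raw$e, b = raw$b, traits = traits,
                    tau = tau, K = K,
                    seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Write the truth record of a simulation to CSV
#'
#' @param sim Result of [simulate_met()].
#' @param dir Output directory.
#' @return Paths of the two written files, invisibly.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pg <- file.path(dir, "truth_genotype_effects.csv")
  pge <- file.path(dir, "truth_ge_effects.csv")
  utils::write.csv(sim$truth$genotype, pg, row.names = FALSE)
  utils::write.csv(sim$truth$ge, pge, row.names = FALSE)
  invisible(c(pg, pge))
}
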
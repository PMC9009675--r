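# Shared fixtures: all data is generated in code at test time.

one_trait <- function(var_g = 1, var_ge = 0.5, var_e = 1, mu = 10) {
  data.frame(name = "y", mean = mu, var_g = var_g, var_ge = var_ge,
             var_e = var_e, direction = "increase")
}

# single-trait trial under the generative mixed model
sim_trait <- function(g = 18, e = 2, b = 3, var_g = 1, var_ge = 0.5,
                      var_e = 1, seed = 1, mu = 10, tau = NULL) {
  simulate_met(simulation_config(g = g, e = e, b = b,
                                 traits = one_trait(var_g, var_ge, var_e, mu),
                                 tau = tau, seed = seed))$data
}

# random genotype-by-trait mean matrix
rand_means <- function(g, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(g * p, mean = 50, sd = 10), g, p,
              dimnames = list(sprintf("G%02d", seq_len(g)),
                              paste0("t", seq_len(p))))
  m
}

# balanced-ANOVA expected-mean-squares variance components (two-way,
# genotypes random, environments fixed); NA when any estimate is negative
ems_components <- function(td) {
  d <- td$data
  d$eb <- interaction(d$environment, d$block)
  a <- stats::anova(stats::lm(value ~ eb + genotype + genotype:environment,
                              data = d))
  ms <- stats::setNames(a[["Mean Sq"]], rownames(a))
  e <- length(unique(d$environment))
  b <- length(unique(d$block))
  g <- length(unique(d$genotype))
  se <- ms[["Residuals"]]
  sge <- (ms[["genotype:environment"]] - se) / b
  sg <- (ms[["genotype"]] - ms[["genotype:environment"]]) / (e * b)
  if (sg < 0 || sge < 0) return(NULL)
  c(genotype = sg, genotype_environment = sge, residual = se)
}
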
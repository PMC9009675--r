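test_that("a constant trait collapses to the boundary fit", {
  d <- expand.grid(genotype = paste0("G", 1:4), environment = c("E1", "E2"),
                   block = c("B1", "B2"), stringsAsFactors = FALSE)
  d$trait <- "a"
  d$value <- 3.5
  td <- trial_data(d, trait_specs("a"))
  f <- fit_reml(td, "a")
  expect_true(f$degenerate)
  expect_equal(unname(f$varcomp), c(0, 0, 0))
  expect_equal(unname(f$blup_g), rep(0, 4))
  expect_equal(f$grand_mean, 3.5)
  expect_equal(blup_means(f, "genotype")$predicted, rep(3.5, 4))
})

test_that("single-environment REML matches the (MSg - MSe)/b estimator", {
  # integer toy data, g = 4, b = 3: hand-checkable expected mean squares
  d <- data.frame(
    genotype = rep(paste0("G", 1:4), each = 3),
    environment = "E1",
    block = rep(c("B1", "B2", "B3"), 4),
    trait = "a",
    value = c(10, 12, 11, 15, 14, 16, 9, 8, 10, 13, 12, 14))
  td <- trial_data(d, trait_specs("a"))
  f <- fit_reml(td, "a")
  a <- anova(lm(value ~ block + genotype, data = d))
  ms <- setNames(a[["Mean Sq"]], rownames(a))
  sg <- (ms[["genotype"]] - ms[["Residuals"]]) / 3
  expect_gt(sg, 0)
  expect_equal(unname(f$varcomp["genotype"]), unname(sg),
               tolerance = 1e-6)
  expect_equal(unname(f$varcomp["residual"]), unname(ms[["Residuals"]]),
               tolerance = 1e-6)
  expect_equal(unname(f$varcomp["genotype_environment"]), 0)
})

test_that("REML sits at the top of the restricted likelihood surface", {
  td <- sim_trait(g = 8, e = 2, b = 3, seed = 31)
  f <- fit_reml(td, "y")
  # profile check: no perturbed variance triple beats the optimum
  d <- f$data
  reml_ll <- function(vg, vge, ve) {
    # restricted log-likelihood of (vg, vge, ve) computed from first
    # principles via the marginal covariance of y
    X <- model.matrix(~ 0 + env_block, d)
    Zg <- model.matrix(~ 0 + genotype, d)
    Zge <- model.matrix(~ 0 + genotype:environment, d)
    V <- vg * tcrossprod(Zg) + vge * tcrossprod(Zge) +
      ve * diag(nrow(d))
    Vi <- solve(V)
    XtVi <- t(X) %*% Vi
    beta <- solve(XtVi %*% X, XtVi %*% d$value)
    r <- d$value - X %*% beta
    -0.5 * (determinant(V)$modulus + determinant(XtVi %*% X)$modulus +
              t(r) %*% Vi %*% r + (nrow(d) - ncol(X)) * log(2 * pi))
  }
  opt <- f$varcomp
  ll_opt <- reml_ll(opt[1], opt[2], opt[3])
  expect_equal(as.numeric(ll_opt), f$restricted_loglik, tolerance = 1e-6)
  set.seed(8)
  for (i in 1:25) {
    pert <- opt * exp(rnorm(3, sd = 0.3))
    expect_lte(as.numeric(reml_ll(pert[1], pert[2], pert[3])),
               ll_opt + 1e-6)
  }
})

test_that("BLUPs agree with a direct mixed-model-equation solve", {
  td <- sim_trait(g = 4, e = 2, b = 2, seed = 13)
  f <- fit_reml(td, "y")
  d <- f$data
  X <- model.matrix(~ 0 + env_block, d)
  Zg <- model.matrix(~ 0 + genotype, d)
  Zge <- model.matrix(~ 0 + genotype:environment, d)
  Z <- cbind(Zg, Zge)
  vg <- f$varcomp[["genotype"]]
  vge <- f$varcomp[["genotype_environment"]]
  ve <- f$varcomp[["residual"]]
  Dinv <- diag(c(rep(ve / vg, ncol(Zg)), rep(ve / vge, ncol(Zge))))
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + Dinv))
  rhs <- c(crossprod(X, d$value), crossprod(Z, d$value))
  sol <- solve(lhs, rhs)
  u <- sol[-seq_len(ncol(X))]
  expect_equal(unname(f$blup_g), unname(u[seq_len(ncol(Zg))]),
               tolerance = 1e-6)
})

test_that("BLUPs shrink and sum to zero on balanced data", {
  td <- sim_trait(g = 12, e = 2, b = 3, seed = 77)
  f <- fit_reml(td, "y")
  expect_lt(abs(mean(f$blup_g)), 1e-6 * sd(f$blup_g))
  expect_lt(abs(mean(f$blup_ge$effect)), 1e-6 * sd(f$blup_ge$effect))
  raw_means <- tapply(f$data$value, f$data$genotype, mean)
  expect_lte(var(f$blup_g), var(raw_means))
})

test_that("with vanishing residual noise the cell predictions reach the
           cell means", {
  td <- sim_trait(g = 6, e = 2, b = 3, var_g = 4, var_ge = 2,
                  var_e = 1e-8, seed = 3)
  f <- fit_reml(td, "y")
  pred <- blup_means(f, "genotype_environment")
  cells <- aggregate(value ~ genotype + environment, data = f$data, mean)
  m <- merge(pred, cells)
  expect_lt(max(abs(m$predicted - m$value)), 1e-3 * sd(f$data$value))
})

test_that("random-effect LRTs detect planted signal and stay clamped", {
  td <- sim_trait(g = 18, e = 2, b = 3, var_g = 4, var_ge = 2, var_e = 1,
                  seed = 6)
  lg <- lrt_random(td, "y", "genotype")
  lge <- lrt_random(td, "y", "genotype_environment")
  expect_gte(lg$statistic, 0)
  expect_equal(lg$df, 1L)
  expect_lt(lg$p_value, 0.01)
  expect_lt(lge$p_value, 0.01)
  # a boundary trait gives a zero statistic and p = 1
  td0 <- sim_trait(g = 10, e = 2, b = 3, var_g = 1, var_ge = 0, var_e = 1,
                   seed = 41)
  f0 <- fit_reml(td0, "y")
  if (f0$varcomp[["genotype_environment"]] == 0) {
    l0 <- lrt_random(td0, "y", "genotype_environment")
    expect_equal(l0$statistic, 0, tolerance = 1e-6)
    expect_equal(l0$p_value, 1, tolerance = 1e-6)
  }
})

test_that("the environment test has df = e - 1 and finds a huge shift", {
  tau <- matrix(c(-10, 10), 1, 2)  # 10 sd shift
  cfg <- simulation_config(g = 10, e = 2, b = 3,
                           traits = one_trait(1, 0.5, 1), tau = tau,
                           seed = 17)
  td <- simulate_met(cfg)$data
  res <- test_fixed_effects(td, "y")
  expect_equal(res$df, 1L)
  expect_lt(res$p_value, 1e-6)
  td1 <- sim_trait(e = 1, seed = 1)
  expect_error(test_fixed_effects(td1, "y"), "at least 2 environments")
})

test_that("degenerate designs are refused", {
  d <- data.frame(genotype = "G1", environment = "E1",
                  block = paste0("B", 1:6), trait = "a",
                  value = rnorm(6))
  td <- trial_data(d, trait_specs("a"))
  expect_error(fit_reml(td, "a"), "at least 2 genotypes")
  expect_error(fit_reml(sim_trait(seed = 1), "nope"), "unknown trait")
})
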
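test_that("rescaling sends trait extremes to the desired ends", {
  m <- cbind(up = c(2, 4, 6), down = c(2, 4, 6))
  specs <- trait_specs(c("up", "down"), c("increase", "decrease"))
  rx <- rescale_traits(m, specs)$rx
  expect_equal(unname(rx[, "up"]), c(0, 50, 100))
  expect_equal(unname(rx[, "down"]), c(100, 50, 0))

  expect_error(
    rescale_traits(cbind(a = c(1, 1, 1), b = 1:3), trait_specs(c("a", "b"))),
    "'a' is constant")
})

test_that("rescaled columns are affine images spanning [0, 100]", {
  set.seed(5)
  m <- rand_means(18, 12)
  dirs <- rep(c("increase", "decrease"), 6)
  specs <- trait_specs(colnames(m), dirs)
  rx <- rescale_traits(m, specs)$rx
  for (j in seq_len(ncol(m))) {
    expect_equal(range(rx[, j]), c(0, 100))
    r <- cor(rx[, j], m[, j])
    expect_equal(abs(r), 1, tolerance = 1e-12)
    expect_equal(sign(r), if (dirs[j] == "increase") 1 else -1)
  }
})

test_that("duplicated traits collapse onto one factor", {
  set.seed(2)
  x1 <- rnorm(30)
  x3 <- residuals(lm(rnorm(30) ~ x1))  # exactly uncorrelated with x1
  m <- cbind(a = x1, b = x1, c = x3)
  suppressWarnings(fm <- fit_factor_model(m))
  expect_equal(fm$eigenvalues, c(2, 1, 0), tolerance = 1e-8)
  expect_equal(fm$n_factors, 1L)
  expect_gt(min(abs(fm$loadings[c("a", "b"), 1])), 0.9)
  expect_lt(abs(fm$loadings["c", 1]), 1e-6)
  expect_equal(fm$assignment$factor, rep("FA1", 3))
})

test_that("factorial scores equal the explicit Z (A'R^-1)' product", {
  set.seed(12)
  m <- rand_means(18, 6)
  fm <- fit_factor_model(rescale_traits(m, trait_specs(colnames(m))))
  Z <- scale(fm$Z, center = FALSE, scale = FALSE)  # already standardized
  oracle <- fm$Z %*% t(t(fm$loadings) %*% solve(fm$R))
  expect_lt(max(abs(fm$scores - oracle)), 1e-10)
  expect_lt(max(abs(colMeans(fm$scores))), 1e-10)
  expect_true(all(fm$communalities >= 0 & fm$communalities <= 1 + 1e-8))
})

test_that("a planted two-factor structure is recovered", {
  set.seed(30)
  g <- 200
  f1 <- rnorm(g); f2 <- rnorm(g)
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0.85, 0),
             c(0, 0.9), c(0, 0.8), c(0, 0.85))
  m <- cbind(f1, f2) %*% t(L) +
    matrix(rnorm(g * 6, sd = sqrt(1 - rowSums(L^2))[col(matrix(0, g, 6))]),
           g, 6)
  colnames(m) <- paste0("t", 1:6)
  fm <- fit_factor_model(m)
  expect_equal(fm$n_factors, 2L)
  recon <- fm$loadings %*% t(fm$loadings) + diag(1 - fm$communalities)
  expect_lt(max(abs(recon - fm$R)), 0.15)
  expect_equal(sort(table(fm$assignment$factor), decreasing = TRUE),
               sort(table(c(rep("FA1", 3), rep("FA2", 3))),
                    decreasing = TRUE), ignore_attr = TRUE)
})

fake_model <- function(scores, center = NULL, scale = NULL) {
  # hand-built factor model in which R = A = I, so scores pass through
  f <- ncol(scores)
  structure(list(R = diag(f), Rinv = diag(f),
                 loadings = diag(f), Z = scores, scores = scores,
                 center = if (is.null(center)) rep(0, f) else center,
                 scale = if (is.null(scale)) rep(1, f) else scale,
                 eigenvalues = rep(1, f), n_factors = f,
                 communalities = rep(1, f),
                 assignment = tibble::tibble(trait = paste0("t", seq_len(f)),
                                             factor = paste0("FA",
                                                             seq_len(f))),
                 rotated = FALSE),
            class = "factor_model")
}

test_that("the index is the Euclidean distance to the ideotype scores", {
  # one factor: genotype score 3, ideotype score 7 -> distance 4
  mdl <- fake_model(matrix(c(3, 5), 2, 1,
                           dimnames = list(c("G1", "G2"), "FA1")))
  res <- compute_index(mdl, ideotype = 7)
  expect_equal(res$index$mgidi[1], 4)
  expect_equal(unname(res$omega[1, ]), 1)

  # two factors with per-factor differences (3, 4): distance 5,
  # contributions (0.36, 0.64), strongest factor is FA1
  mdl2 <- fake_model(matrix(c(0, 1, 0, 2), 2, 2,
                            dimnames = list(c("G1", "G2"),
                                            c("FA1", "FA2"))))
  res2 <- compute_index(mdl2, ideotype = c(3, 4))
  expect_equal(res2$index$mgidi[1], 5)
  expect_equal(unname(res2$omega[1, ]), c(0.36, 0.64))
  sw <- strengths_weaknesses(res2)
  expect_true(sw$strongest[sw$genotype == "G1" & sw$factor == "FA1"])
})

test_that("a genotype holding every best value has index zero and wins", {
  set.seed(44)
  m <- rand_means(10, 5)
  dirs <- c("increase", "decrease", "increase", "increase", "decrease")
  m[1, ] <- ifelse(dirs == "increase", apply(m, 2, max) + 1,
                   apply(m, 2, min) - 1)
  specs <- trait_specs(colnames(m), dirs)
  res <- mgidi(m, specs)
  expect_equal(res$index$mgidi[1], 0, tolerance = 1e-8)
  expect_equal(res$index$rank[1], 1L)
})

test_that("omega rows always sum to one", {
  for (s in 1:5) {
    m <- rand_means(15, 6, seed = s)
    res <- mgidi(m, trait_specs(colnames(m)))
    expect_equal(unname(rowSums(res$omega)), rep(1, 15), tolerance = 1e-10)
    sw <- strengths_weaknesses(res)
    sums <- tapply(sw$omega, sw$genotype, sum)
    expect_equal(as.numeric(sums), rep(1, 15), tolerance = 1e-10)
  }
})

test_that("selection keeps floor(proportion * g) genotypes, at least one", {
  m <- rand_means(18, 4)
  res <- mgidi(m, trait_specs(colnames(m)))
  expect_length(select_genotypes(res, 0.25), 4)
  expect_length(select_genotypes(res, 1.0), 18)
  m10 <- rand_means(10, 4)
  res10 <- mgidi(m10, trait_specs(colnames(m10)))
  expect_length(select_genotypes(res10, 0.25), 2)
  expect_length(select_genotypes(res10, 0.01), 1)
  expect_error(select_genotypes(res, 0), "proportion")
  expect_error(select_genotypes(res, 1.5), "proportion")
})

test_that("selection differentials reproduce their defining arithmetic", {
  # overall mean 4067.728 and selected mean 4233.464 for GY;
  # 902.279 and 1117.310 for pc (4 selected out of 18)
  build_col <- function(xo, xs) c(rep(xs, 4), rep((18 * xo - 4 * xs) / 14, 14))
  m <- cbind(GY = build_col(4067.728, 4233.464),
             pc = build_col(902.279, 1117.310))
  rownames(m) <- sprintf("G%02d", 1:18)
  specs <- trait_specs(c("GY", "pc"))
  sd_tab <- selection_differentials(m, rownames(m)[1:4], specs)
  expect_equal(sd_tab$SD[sd_tab$trait == "GY"], 165.736, tolerance = 1e-9)
  expect_equal(sd_tab$SD_pct[sd_tab$trait == "GY"], 4.074, tolerance = 5e-4)
  expect_equal(sd_tab$SD[sd_tab$trait == "pc"], 215.031, tolerance = 1e-9)
  expect_equal(round(sd_tab$SD_pct[sd_tab$trait == "pc"], 2), 23.83)
  expect_true(all(sd_tab$goal_met))
  # identity SD% * Xo = 100 * SD and exact selected means
  expect_equal(sd_tab$SD_pct * sd_tab$Xo, 100 * sd_tab$SD,
               tolerance = 1e-10)
  expect_equal(sd_tab$Xs, unname(colMeans(m[1:4, ])), tolerance = 1e-12)

  sd0 <- selection_differentials(m, rownames(m), specs)
  expect_equal(sd0$SD, c(0, 0), tolerance = 1e-9)

  m0 <- cbind(a = c(-1, 0, 1), b = c(1, 2, 3))
  expect_error(selection_differentials(m0, "G01", trait_specs(c("a", "b"))),
               "zero overall mean")
})

test_that("small-instance rankings match a loop-based brute force", {
  for (s in 1:5) {
    m <- rand_means(8, 5, seed = 100 + s)
    res <- mgidi(m, trait_specs(colnames(m)))
    scores <- res$scores
    y <- res$ideotype_scores
    dist <- numeric(nrow(scores))
    for (i in seq_len(nrow(scores))) {
      acc <- 0
      for (j in seq_len(ncol(scores))) acc <- acc + (scores[i, j] - y[j])^2
      dist[i] <- sqrt(acc)
    }
    expect_equal(order(dist), order(res$index$mgidi))
    expect_equal(res$index$mgidi, unname(dist), tolerance = 1e-10)
  }
})

test_that("permuting genotypes permutes the index identically", {
  m <- rand_means(12, 5, seed = 61)
  specs <- trait_specs(colnames(m))
  res <- mgidi(m, specs)
  perm <- sample(nrow(m))
  res_p <- mgidi(m[perm, ], specs)
  expect_equal(res_p$index$mgidi[match(res$index$genotype,
                                       res_p$index$genotype)],
               res$index$mgidi, tolerance = 1e-10)
})

test_that("flipping a trait's direction and negating it changes nothing", {
  m <- rand_means(10, 4, seed = 71)
  dirs <- c("increase", "decrease", "increase", "increase")
  res <- mgidi(m, trait_specs(colnames(m), dirs))
  m2 <- m
  m2[, 2] <- -m2[, 2]
  dirs2 <- dirs
  dirs2[2] <- "increase"
  res2 <- mgidi(m2, trait_specs(colnames(m2), dirs2))
  expect_equal(res2$rescaled$rx, res$rescaled$rx, tolerance = 1e-10)
  expect_equal(res2$index$mgidi, res$index$mgidi, tolerance = 1e-10)
})

test_that("uninformative (constant) traits are dropped with a warning but
           still reported in the gains table", {
  m <- rand_means(10, 4, seed = 81)
  m[, 3] <- 5
  specs <- trait_specs(colnames(m))
  expect_warning(res <- mgidi(m, specs), "t3")
  expect_equal(nrow(res$gains), 4)
  expect_equal(res$gains$SD[res$gains$trait == "t3"], 0)
  expect_false("t3" %in% rownames(res$model$loadings))
})
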
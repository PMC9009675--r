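as_mean_matrix <- function(means) {
  if (is.data.frame(means)) {
    if ("genotype" %in% names(means)) {
      m <- as.matrix(means[setdiff(names(means), "genotype")])
      rownames(m) <- means$genotype
    } else {
      m <- as.matrix(means)
    }
  } else {
    m <- as.matrix(means)
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%02d", seq_len(nrow(m)))
  storage.mode(m) <- "double"
  m
}

#' Direction-aware 0-100 rescaling of genotype means
#'
#' Linearly maps each trait column of a genotype-mean matrix onto the
#' 0-100 range so that 100 is always the desired end: for
#' `direction = "increase"` the largest original value maps to 100, for
#' `"decrease"` the smallest does. Each rescaled column is an affine
#' transform of the original, so the correlation structure is preserved up
#' to the sign flips on decrease-direction traits.
#'
#' @param means Genotype-by-trait matrix (or data frame with a `genotype`
#'   column) of predicted means; at least 2 genotypes.
#' @param specs A [trait_specs()] tibble covering every column.
#' @return An object of class `rescaled_traits`: `rx` (g x p matrix in
#'   \[0, 100\]), `bounds` (per-trait original/new min and max), `specs`.
#' @examples
#' m <- cbind(GY = c(2, 4, 6), Na = c(1, 3, 2))
#' rescale_traits(m, trait_specs(c("GY", "Na"), c("increase", "decrease")))
#' @export
rescale_traits <- function(means, specs) {
  stopifnot(inherits(specs, "trait_specs"))
  m <- as_mean_matrix(means)
  if (nrow(m) < 2) stop("need at least 2 genotypes to rescale")
  missing_spec <- setdiff(colnames(m), specs$name)
  if (length(missing_spec)) {
    stop("no trait spec for: ", paste(missing_spec, collapse = ", "))
  }
  specs <- specs[match(colnames(m), specs$name), , drop = FALSE]
  rx <- m
  bounds <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    lo <- min(m[, j]); hi <- max(m[, j])
    if (hi == lo) {
      stop("trait '", colnames(m)[j],
           "' is constant across genotypes; rescaling is undefined")
    }
    if (specs$direction[j] == "increase") {
      new_at_min <- 0; new_at_max <- 100
    } else {
      new_at_min <- 100; new_at_max <- 0
    }
    rx[, j] <- (new_at_max - new_at_min) / (hi - lo) * (m[, j] - lo) +
      new_at_min
    bounds[[j]] <- tibble::tibble(
      trait = colnames(m)[j], direction = specs$direction[j],
      original_min = lo, original_max = hi,
      new_at_min = new_at_min, new_at_max = new_at_max)
  }
  structure(list(rx = rx, bounds = dplyr::bind_rows(bounds), specs = specs),
            class = "rescaled_traits")
}

# invert/pseudo-invert a correlation matrix
cor_inverse <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    warning("correlation matrix is singular; using the Moore-Penrose ",
            "pseudo-inverse")
    inv <- MASS::ginv(R)
    dimnames(inv) <- dimnames(R)
  }
  inv
}

#' Exploratory factor analysis of rescaled trait means
#'
#' Eigen-decomposes the correlation matrix of the rescaled genotype-mean
#' matrix, retains the factors whose eigenvalue exceeds one (Kaiser rule;
#' at least one factor), forms initial loadings as eigenvectors scaled by
#' the square root of their eigenvalues, varimax-rotates them, and
#' computes genotype factorial scores as
#' \deqn{F = Z (A^\top R^{-1})^\top}
#' where Z is the column-standardized rescaled matrix, A the rotated
#' loadings and R the trait correlation matrix. Each loading column is
#' sign-fixed so its largest-magnitude entry is positive.
#'
#' @param rx A [rescale_traits()] result (or a plain genotype-by-trait
#'   matrix already on the desired scale).
#' @param rotate Apply varimax rotation to the retained loadings
#'   (default `TRUE`); rotation is skipped when a single factor is kept.
#' @return An object of class `factor_model`: `R`, `eigenvalues`,
#'   `n_factors`, `loadings` (p x f), `communalities`, `scores` (g x f),
#'   `Z`, `Rinv`, `assignment` (trait -> factor with the largest absolute
#'   loading), `center`, `scale`.
#' @export
fit_factor_model <- function(rx, rotate = TRUE) {
  m <- if (inherits(rx, "rescaled_traits")) rx$rx else as_mean_matrix(rx)
  g <- nrow(m); p <- ncol(m)
  R <- stats::cor(m)
  ev <- eigen(R, symmetric = TRUE)
  eigenvalues <- ev$values
  f <- max(1L, sum(eigenvalues > 1))
  if (g <= f) stop("need more genotypes (", g, ") than retained factors (",
                   f, ")")
  A <- ev$vectors[, seq_len(f), drop = FALSE] %*%
    diag(sqrt(pmax(eigenvalues[seq_len(f)], 0)), f)
  if (rotate && f > 1) {
    A <- unclass(stats::varimax(A)$loadings)[, , drop = FALSE]
  }
  # deterministic sign: largest |loading| in each factor is positive
  for (j in seq_len(f)) {
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(colnames(m), paste0("FA", seq_len(f)))
  center <- colMeans(m)
  scale_ <- apply(m, 2, stats::sd)
  Z <- sweep(sweep(m, 2, center), 2, scale_, "/")
  Rinv <- cor_inverse(R)
  scores <- Z %*% Rinv %*% A
  assignment <- tibble::tibble(
    trait = colnames(m),
    factor = colnames(A)[apply(abs(A), 1, which.max)])
  structure(list(R = R, eigenvalues = eigenvalues, n_factors = f,
                 loadings = A, communalities = rowSums(A^2),
                 scores = scores, Z = Z, Rinv = Rinv,
                 assignment = assignment, center = center, scale = scale_,
                 rotated = rotate && f > 1),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> ", ncol(x$Z), " traits, ", x$n_factors,
      " factor(s) retained (Kaiser rule)", if (x$rotated) ", varimax" else "",
      "\n", sep = "")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' Genotype-ideotype distance index from a factor model
#'
#' The ideotype holds the best rescaled value (100) for every trait. It is
#' standardized with the genotype columns' means and standard deviations
#' and scored with the same loadings and correlation matrix as the
#' genotypes, so distances live in factor-score space. For genotype i,
#' \deqn{MGIDI_i = \left[\sum_{j=1}^f (y_{ij} - y_j)^2\right]^{0.5}}
#' with \eqn{y_j} the ideotype's score on factor j; the contribution of
#' factor j is \eqn{\omega_{ij} = D_{ij}^2 / \sum_j D_{ij}^2}. Lower MGIDI
#' means closer to the ideotype.
#'
#' @param model A [fit_factor_model()] result.
#' @param ideotype Rescaled ideotype value per trait (default 100 for
#'   all, i.e. the best end of every trait).
#' @return An object of class `mgidi_result`: `index` tibble (genotype,
#'   mgidi, rank), `ideotype_scores`, `distances` (g x f, |score
#'   difference| per factor), `omega` (g x f contributions summing to 1
#'   per genotype), `scores` and the `model`.
#' @export
compute_index <- function(model, ideotype = NULL) {
  stopifnot(inherits(model, "factor_model"))
  p <- ncol(model$Z)
  if (is.null(ideotype)) ideotype <- rep(100, p)
  stopifnot(length(ideotype) == p)
  z_ideo <- (ideotype - model$center) / model$scale
  y <- drop(z_ideo %*% model$Rinv %*% model$loadings)
  diff <- sweep(model$scores, 2, y)
  D <- abs(diff)
  mgidi <- sqrt(rowSums(diff^2))
  d2 <- D^2
  tot <- rowSums(d2)
  omega <- d2 / ifelse(tot == 0, 1, tot)  # ideotype row itself: all zero
  genotypes <- rownames(model$scores)
  ord <- order(mgidi, seq_along(mgidi))
  index <- tibble::tibble(genotype = genotypes, mgidi = unname(mgidi))
  index$rank <- match(seq_len(nrow(index)), ord)
  structure(list(index = index, ideotype_scores = y, distances = D,
                 omega = omega, scores = model$scores, model = model),
            class = "mgidi_result")
}

#' @export
print.mgidi_result <- function(x, ...) {
  cat("<mgidi_result> ", nrow(x$index), " genotypes, ",
      ncol(x$distances), " factor(s)\n", sep = "")
  top <- x$index[order(x$index$rank), ][seq_len(min(5, nrow(x$index))), ]
  cat("  best: ", paste(sprintf("%s (%.3f)", top$genotype, top$mgidi),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select the genotypes closest to the ideotype
#'
#' Keeps the `floor(proportion * g)` genotypes (at least one) with the
#' lowest index values; ties broken by original genotype order, so
#' selection is deterministic.
#'
#' @param result A [compute_index()] result.
#' @param proportion Selection proportion in (0, 1]; the conventional
#'   intensity is 0.25.
#' @return Character vector of selected genotype ids, best first.
#' @export
select_genotypes <- function(result, proportion = 0.25) {
  stopifnot(inherits(result, "mgidi_result"))
  if (!is.numeric(proportion) || length(proportion) != 1 ||
      proportion <= 0 || proportion > 1) {
    stop("proportion must be a single value in (0, 1]")
  }
  g <- nrow(result$index)
  n_sel <- max(1L, floor(proportion * g))
  ord <- order(result$index$mgidi, seq_len(g))
  result$index$genotype[ord[seq_len(n_sel)]]
}

#' Selection differentials on the original trait scale
#'
#' For each trait: the overall mean Xo, the mean of the selected genotypes
#' Xs, the selection differential SD = Xs - Xo, and SD% = 100 SD / Xo.
#' The gain is flagged as goal-met when its sign agrees with the trait's
#' desired direction (SD >= 0 for increase, <= 0 for decrease).
#'
#' @param means Genotype-by-trait matrix of predicted means (original
#'   units).
#' @param selected Character vector of selected genotype ids (subset of
#'   the rownames of `means`).
#' @param specs A [trait_specs()] tibble covering every column.
#' @param factors Optional trait-to-factor assignment tibble (columns
#'   `trait`, `factor`), e.g. from [fit_factor_model()].
#' @return A tibble of class `selection_gain`: `trait`, `factor`, `Xo`,
#'   `Xs`, `SD`, `SD_pct`, `sense`, `goal_met`.
#' @export
selection_differentials <- function(means, selected, specs, factors = NULL) {
  stopifnot(inherits(specs, "trait_specs"))
  m <- as_mean_matrix(means)
  if (length(selected) == 0) stop("no genotypes selected")
  if (!all(selected %in% rownames(m))) {
    stop("selected ids not in means: ",
         paste(setdiff(selected, rownames(m)), collapse = ", "))
  }
  specs <- specs[match(colnames(m), specs$name), , drop = FALSE]
  xo <- colMeans(m)
  xs <- colMeans(m[selected, , drop = FALSE])
  if (any(xo == 0)) {
    stop("SD% undefined for trait(s) with zero overall mean: ",
         paste(colnames(m)[xo == 0], collapse = ", "))
  }
  sd_ <- xs - xo
  fct <- if (is.null(factors)) NA_character_ else {
    factors$factor[match(colnames(m), factors$trait)]
  }
  out <- tibble::tibble(
    trait = colnames(m), factor = fct, Xo = unname(xo), Xs = unname(xs),
    SD = unname(sd_), SD_pct = unname(100 * sd_ / xo),
    sense = specs$direction,
    goal_met = ifelse(specs$direction == "increase", sd_ >= 0, sd_ <= 0))
  class(out) <- c("selection_gain", class(out))
  out
}

#' Strengths and weaknesses of each genotype
#'
#' Tabulates the per-factor contribution \eqn{\omega_{ij}} to each
#' genotype's index: the factor with the smallest contribution is the
#' genotype's strength (its traits are closest to the ideotype), the
#' largest its weakness.
#'
#' @param result A [compute_index()] result.
#' @return A long tibble: `genotype`, `factor`, `omega`, `traits` (comma
#'   separated members of the factor), `strongest` flag.
#' @export
strengths_weaknesses <- function(result) {
  stopifnot(inherits(result, "mgidi_result"))
  omega <- result$omega
  assign <- result$model$assignment
  members <- vapply(colnames(omega), function(f) {
    paste(assign$trait[assign$factor == f], collapse = ", ")
  }, "")
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(genotype = rownames(omega)),
                     tibble::as_tibble(omega)),
    cols = -"genotype", names_to = "factor", values_to = "omega")
  long$traits <- members[long$factor]
  long <- dplyr::group_by(long, .data$genotype)
  long <- dplyr::mutate(long, strongest = .data$omega == min(.data$omega))
  dplyr::ungroup(long)
}

#' Full genotype-ideotype distance workflow
#'
#' Convenience wrapper chaining [rescale_traits()], [fit_factor_model()],
#' [compute_index()], [select_genotypes()] and
#' [selection_differentials()] on a genotype-mean matrix. The conventional
#' input is the BLUP-based matrix of predicted genotype means across
#' environments (see [blup_means()]).
#'
#' Traits whose predicted means are constant across genotypes (e.g. when
#' the genotypic variance was estimated at the zero boundary, so every
#' BLUP shrinks to the grand mean) carry no ranking information and are
#' dropped from the index with a warning; they still appear in the
#' selection-differential table (necessarily with zero differential).
#'
#' @inheritParams rescale_traits
#' @inheritParams select_genotypes
#' @inheritParams fit_factor_model
#' @return An `mgidi_result` with extra elements `selected`, `gains`
#'   (selection-differential table over all traits) and `rescaled`.
#' @examples
#' set.seed(7)
#' m <- matrix(rnorm(18 * 4), 18, 4,
#'             dimnames = list(sprintf("G%02d", 1:18), c("a", "b", "c", "d")))
#' res <- mgidi(m, trait_specs(colnames(m)), proportion = 0.25)
#' res$selected
#' @export
mgidi <- function(means, specs, proportion = 0.25, rotate = TRUE) {
  m <- as_mean_matrix(means)
  constant <- apply(m, 2, function(v) max(v) == min(v))
  if (any(constant)) {
    warning("dropping trait(s) with no variation among genotypes from the ",
            "index: ", paste(colnames(m)[constant], collapse = ", "))
  }
  if (sum(!constant) < 2) stop("fewer than 2 informative traits")
  rx <- rescale_traits(m[, !constant, drop = FALSE], specs)
  model <- fit_factor_model(rx, rotate = rotate)
  result <- compute_index(model)
  result$rescaled <- rx
  result$selected <- select_genotypes(result, proportion)
  result$gains <- selection_differentials(m, result$selected, specs,
                                          factors = model$assignment)
  result
}
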
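#' Build a pipeline configuration
#'
#' Exactly one of `input` (a CSV path read with [load_trial_table()], with
#' `traits` supplied) or `simulation` (a [simulation_config()]) must be
#' given.
#'
#' @param input Optional path to a long-format phenotype CSV.
#' @param traits A [trait_specs()] tibble (required with `input`).
#' @param simulation Optional [simulation_config()].
#' @param proportion Selection proportion in (0, 1] (default 0.25).
#' @param heritability Headline heritability variant, `"mean"` or
#'   `"broad"`.
#' @param rge Genotype-environment correlation formula, `"genotypic"` or
#'   `"interaction"`.
#' @param rotate Varimax-rotate factor loadings (default `TRUE`).
#' @param outdir Output directory for emitted tables.
#' @param seed Integer seed recorded in the manifest (and forwarded to the
#'   simulation when one is configured).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, traits = NULL, simulation = NULL,
                            proportion = 0.25,
                            heritability = c("mean", "broad"),
                            rge = c("genotypic", "interaction"),
                            rotate = TRUE, outdir = "ideosel-output",
                            seed = 1L) {
  heritability <- match.arg(heritability)
  rge <- match.arg(rge)
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of 'input' or 'simulation' must be set")
  }
  if (!is.null(input) && is.null(traits)) {
    stop("'traits' is required with a CSV input")
  }
  if (!is.numeric(proportion) || length(proportion) != 1 ||
      proportion <= 0 || proportion > 1) {
    stop("selection proportion must be in (0, 1]")
  }
  structure(list(input = input, traits = traits, simulation = simulation,
                 proportion = proportion, heritability = heritability,
                 rge = rge, rotate = rotate, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized fields: `input`, `trait_specs` (path to a spec CSV/YAML),
#' `simulation` (`"wheat_drought"` for the bundled preset, or a path to a
#' simulation YAML), `proportion`, `heritability`, `rge`, `rotate`,
#' `outdir`, `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim <- if (identical(raw$simulation, "wheat_drought")) {
      preset_wheat_drought(seed = seed)
    } else {
      load_simulation_config(raw$simulation)
    }
  }
  traits <- if (!is.null(raw$trait_specs)) load_trait_specs(raw$trait_specs)
  pipeline_config(
    input = raw$input, traits = traits, simulation = sim,
    proportion = if (is.null(raw$proportion)) 0.25 else raw$proportion,
    heritability = if (is.null(raw$heritability)) "mean"
                   else raw$heritability,
    rge = if (is.null(raw$rge)) "genotypic" else raw$rge,
    rotate = if (is.null(raw$rotate)) TRUE else raw$rotate,
    outdir = if (is.null(raw$outdir)) "ideosel-output" else raw$outdir,
    seed = seed)
}

stage <- function(name, trait = NULL, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "'",
         if (!is.null(trait)) paste0(" (trait '", trait, "')"), ": ",
         conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[ideosel] stage=%s%s elapsed=%.2fs", name,
                  if (is.null(trait)) "" else paste0(" trait=", trait),
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full trial-analysis pipeline
#'
#' Ingests (or simulates) a trial, fits every trait's mixed model, runs
#' the likelihood-ratio tests, computes genetic parameters and BLUP
#' tables, chains the genotype-ideotype index, and writes the complete
#' table set as CSV. Reruns with the same configuration are
#' byte-identical. Any stage failure aborts with the stage and trait in
#' the message, and no partial table set is left behind.
#'
#' @param config A [pipeline_config()].
#' @return A run manifest (list with `files`, `selected`, `seed`,
#'   `config_hash`), invisibly written as `manifest.yaml` alongside the
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  td <- stage("ingest", expr = {
    if (!is.null(config$simulation)) {
      simulate_met(config$simulation)$data
    } else {
      load_trial_table(config$input, config$traits)
    }
  })
  traits <- td$traits$name

  fits <- list()
  lrt <- list()
  for (tr in traits) {
    fits[[tr]] <- stage("fit_reml", tr, fit_reml(td, tr))
    lrt[[tr]] <- stage("lrt", tr, dplyr::bind_cols(
      tibble::tibble(trait = tr),
      dplyr::bind_rows(lrt_random(td, tr, "genotype"),
                       lrt_random(td, tr, "genotype_environment"),
                       test_fixed_effects(td, tr))))
  }
  lrt_table <- dplyr::bind_rows(lrt)

  params <- stage("genetic_parameters", expr =
    genetic_parameters_table(fits, variant = config$heritability,
                             rge = config$rge))

  blup_g <- dplyr::bind_rows(lapply(traits, function(tr) {
    dplyr::bind_cols(tibble::tibble(trait = tr),
                     blup_means(fits[[tr]], "genotype"))
  }))
  blup_ge <- dplyr::bind_rows(lapply(traits, function(tr) {
    dplyr::bind_cols(tibble::tibble(trait = tr),
                     blup_means(fits[[tr]], "genotype_environment"))
  }))

  # genotype-mean matrix (BLUP-based, across environments) feeding the index
  mean_mat <- stage("genotype_means", expr = {
    wide <- tidyr::pivot_wider(blup_g, names_from = "trait",
                               values_from = "predicted")
    as_mean_matrix(wide)
  })
  result <- stage("mgidi", expr =
    mgidi(mean_mat, td$traits, proportion = config$proportion,
          rotate = config$rotate))
  sw <- strengths_weaknesses(result)

  corr <- stage("correlation", expr = {
    keep <- apply(mean_mat, 2, function(v) max(v) > min(v))
    pearson_matrix(mean_mat[, keep, drop = FALSE])
  })
  ge_wide <- tidyr::pivot_wider(blup_ge, names_from = "trait",
                                values_from = "predicted")
  pca_in <- as_mean_matrix(ge_wide[setdiff(names(ge_wide), "environment")])
  rownames(pca_in) <- paste(ge_wide$genotype, ge_wide$environment, sep = "_")
  pca <- stage("pca", expr = pca_traits(pca_in))

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    lrt = "lrt_tests.csv", params = "genetic_parameters.csv",
    blup_g = "blup_genotype.csv", blup_ge = "blup_genotype_environment.csv",
    rescaled = "rescaled_matrix.csv", loadings = "factor_loadings.csv",
    ranking = "mgidi_ranking.csv", omega = "factor_contributions.csv",
    gains = "selection_differentials.csv", correlations = "correlations.csv",
    pca = "pca_variance.csv")
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  written <- character()
  emit <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
  }
  tryCatch({
    emit(lrt_table, paths["lrt"])
    emit(params, paths["params"])
    emit(blup_g, paths["blup_g"])
    emit(blup_ge, paths["blup_ge"])
    emit(dplyr::bind_cols(
      tibble::tibble(genotype = rownames(result$rescaled$rx)),
      tibble::as_tibble(result$rescaled$rx)), paths["rescaled"])
    emit(dplyr::bind_cols(
      tibble::tibble(trait = rownames(result$model$loadings),
                     communality = unname(result$model$communalities)),
      tibble::as_tibble(result$model$loadings)), paths["loadings"])
    ranked <- result$index[order(result$index$rank), ]
    ranked$selected <- ranked$genotype %in% result$selected
    emit(ranked, paths["ranking"])
    emit(sw, paths["omega"])
    emit(result$gains, paths["gains"])
    cor_df <- dplyr::bind_cols(
      tibble::tibble(trait = rownames(corr$r)), tibble::as_tibble(corr$r))
    emit(cor_df, paths["correlations"])
    emit(tibble::tibble(component = colnames(pca$loadings),
                        eigenvalue = pca$eigenvalues,
                        var_explained_pct = pca$var_explained),
         paths["pca"])
  }, error = function(e) {
    unlink(written)
    stop("stage 'emit': ", conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    files = as.list(stats::setNames(as.character(paths), names(paths))),
    selected = result$selected,
    n_traits = length(traits),
    seed = config$seed,
    config_hash = rlang::hash(config))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
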
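#' Declare trait metadata for a trial
#'
#' Builds the trait-specification table used throughout the package. Each
#' trait carries a desired selection sense (`direction`): `"increase"` for
#' traits where larger values are better (e.g. grain yield), `"decrease"`
#' where smaller values are better (e.g. leaf sodium under drought).
#'
#' @param name Character vector of unique trait names.
#' @param direction Character vector, `"increase"` or `"decrease"`, recycled
#'   to the length of `name`.
#' @param units Optional character vector of measurement units.
#' @return A tibble of class `trait_specs` with columns `name`, `units`,
#'   `direction`.
#' @examples
#' trait_specs(c("GY", "Na"), direction = c("increase", "decrease"))
#' @export
trait_specs <- function(name, direction = "increase", units = NA_character_) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("trait names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  direction <- rep_len(as.character(direction), length(name))
  bad <- !direction %in% c("increase", "decrease")
  if (any(bad)) {
    stop("direction must be 'increase' or 'decrease' (got '",
         direction[which(bad)[1]], "' for trait '", name[which(bad)[1]], "')")
  }
  units <- rep_len(as.character(units), length(name))
  out <- tibble::tibble(name = name, units = units, direction = direction)
  class(out) <- c("trait_specs", class(out))
  out
}

#' Read trait specifications from a CSV or YAML file
#'
#' The file must provide `name` and `direction` (and optionally `units`);
#' YAML files hold a list of records with those fields.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return A [trait_specs()] tibble.
#' @export
load_trait_specs <- function(path) {
  if (!file.exists(path)) stop("trait-spec file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("name", "direction") %in% names(df))) {
    stop("trait-spec file must have 'name' and 'direction' fields")
  }
  trait_specs(df$name, df$direction,
              units = if ("units" %in% names(df)) df$units else NA_character_)
}

#' Construct a trial-data object from long-format records
#'
#' The container used by every downstream stage: one record per
#' (genotype, environment, block, trait). Values may be `NA` (a lost plot);
#' they are carried through to the mixed-model stage, never imputed.
#'
#' @param data Data frame with columns `genotype`, `environment`, `block`,
#'   `trait`, `value`.
#' @param traits A [trait_specs()] tibble declaring every trait in `data`.
#' @return An object of class `trial_data`: a list with elements `data`
#'   (long tibble) and `traits`.
#' @export
trial_data <- function(data, traits) {
  stopifnot(inherits(traits, "trait_specs"))
  need <- c("genotype", "environment", "block", "trait", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "))
  }
  data <- tibble::as_tibble(data)[need]
  data$genotype <- as.character(data$genotype)
  data$environment <- as.character(data$environment)
  data$block <- as.character(data$block)
  data$trait <- as.character(data$trait)
  undeclared <- setdiff(unique(data$trait), traits$name)
  if (length(undeclared)) {
    stop("undeclared trait(s) in data: ", paste(undeclared, collapse = ", "))
  }
  if (!is.numeric(data$value)) stop("trait values must be numeric")
  if (any(is.infinite(data$value))) stop("trait values must be finite or NA")
  key <- paste(data$genotype, data$environment, data$block, data$trait,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate record for genotype '", d$genotype, "', environment '",
         d$environment, "', block '", d$block, "', trait '", d$trait, "'")
  }
  structure(list(data = data, traits = traits), class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  d <- x$data
  cat("<trial_data> ", length(unique(d$genotype)), " genotypes x ",
      length(unique(d$environment)), " environments x ",
      length(unique(d$block)), " blocks; ",
      nrow(x$traits), " traits, ", nrow(d), " records\n", sep = "")
  invisible(x)
}

#' Load a long-format phenotype table
#'
#' Reads a wide CSV with columns `genotype`, `environment`, `block` and one
#' column per declared trait, and returns a [trial_data()] object. Empty
#' cells become `NA` records (missing plots are kept, not dropped).
#'
#' @param path CSV file path.
#' @param traits A [trait_specs()] tibble; all its traits must appear as
#'   columns.
#' @param dec Decimal separator: `"."` (default, comma-separated file) or
#'   `","` (semicolon-separated file, common in pt-BR locales).
#' @return A `trial_data` object.
#' @export
load_trial_table <- function(path, traits, dec = c(".", ",")) {
  dec <- match.arg(dec)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (dec == ".") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    utils::read.csv2(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  need <- c("genotype", "environment", "block", traits$name)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  long <- tidyr::pivot_longer(df[need], cols = dplyr::all_of(traits$name),
                              names_to = "trait", values_to = "value")
  raw <- long$value
  if (dec == ",") raw <- gsub(",", ".", raw, fixed = TRUE)
  raw[!is.na(raw) & trimws(raw) == ""] <- NA
  num <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & is.na(num)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-numeric value '", raw[i], "' for trait '", long$trait[i],
         "' (genotype ", long$genotype[i], ", environment ",
         long$environment[i], ", block ", long$block[i], ")")
  }
  long$value <- num
  trial_data(long, traits)
}

#' Write a trial back to the wide CSV layout
#'
#' Inverse of [load_trial_table()]: one row per plot, one column per trait.
#'
#' @param x A `trial_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(x, path) {
  stopifnot(inherits(x, "trial_data"))
  wide <- tidyr::pivot_wider(x$data, names_from = "trait",
                             values_from = "value")
  wide <- wide[c("genotype", "environment", "block", x$traits$name)]
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize the experimental design of a trial
#'
#' @param x A `trial_data` object with at least one record.
#' @return A tibble of class `design_summary` with one row: `g`, `e`, `b`
#'   (blocks per environment), `n` (records per trait), and `balanced`
#'   (`TRUE` iff every genotype-by-environment cell holds exactly `b`
#'   non-missing observations for every trait).
#' @export
summarize_design <- function(x) {
  stopifnot(inherits(x, "trial_data"))
  d <- x$data
  if (nrow(d) == 0) stop("trial contains no records")
  g <- length(unique(d$genotype))
  e <- length(unique(d$environment))
  b <- max(tapply(d$block, d$environment, function(z) length(unique(z))))
  n <- max(table(d$trait))
  present <- d[!is.na(d$value), , drop = FALSE]
  cells <- table(present$genotype, present$environment, present$trait)
  balanced <- length(present$value) > 0 &&
    all(cells == b) && dim(cells)[1] == g && dim(cells)[2] == e &&
    dim(cells)[3] == nrow(x$traits)
  out <- tibble::tibble(g = g, e = e, b = b, n = n, balanced = balanced)
  class(out) <- c("design_summary", class(out))
  out
}

#' Five-number-plus-mean summary of one trait
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), so box-plot style summaries are
#' reproducible across tools.
#'
#' @param x A `trial_data` object.
#' @param trait A declared trait name.
#' @param by Grouping: `"environment"` or `"genotype_environment"`.
#' @return A tibble with one row per group: `min`, `q1`, `median`, `q3`,
#'   `max`, `mean` (missing values dropped per group).
#' @export
trait_summary <- function(x, trait,
                          by = c("environment", "genotype_environment")) {
  stopifnot(inherits(x, "trial_data"))
  by <- match.arg(by)
  if (!trait %in% x$traits$name) stop("unknown trait: ", trait)
  d <- dplyr::filter(x$data, .data$trait == !!trait)
  d <- if (by == "environment") {
    dplyr::group_by(d, .data$environment)
  } else {
    dplyr::group_by(d, .data$genotype, .data$environment)
  }
  dplyr::ungroup(dplyr::summarise(
    d,
    min = min(.data$value, na.rm = TRUE),
    q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    median = stats::median(.data$value, na.rm = TRUE),
    q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    max = max(.data$value, na.rm = TRUE),
    mean = mean(.data$value, na.rm = TRUE),
    .groups = "drop"
  ))
}
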
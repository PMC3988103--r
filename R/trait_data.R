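#' Column schema of a species trait table
#'
#' Required and optional columns of the trait CSV understood by
#' [read_trait_table()].  Masses are species means: body mass in grams,
#' testes mass in milligrams.  Spermatophore volume is a single value per
#' species in cubic millimetres (trunk area times trunk width).  Sperm
#' length is the species mean of per-male mean sperm-package lengths, in
#' micrometres.  Polyandry is the mean number of males a female accepts
#' per reproductive season and is dimensionless.
#'
#' @format A list with elements `required` and `optional`, each a
#'   character vector of column names.
#' @export
trait_schema <- list(
  required = c("species", "body_mass_g", "testes_mass_mg",
               "spermatophore_volume_mm3", "sperm_length_um", "polyandry"),
  optional = c("body_mass_sd", "n_males", "testes_mass_sd", "sperm_length_sd")
)

# columns that must be strictly positive
.positive_cols <- c("body_mass_g", "testes_mass_mg",
                    "spermatophore_volume_mm3", "sperm_length_um")

#' Normalize species names for matching
#'
#' Collapses runs of whitespace, trims, and converts underscores to
#' spaces, so that Newick tip labels (`Timogenes_dorbignyi`) and CSV
#' entries (`Timogenes dorbignyi`) compare equal.  Matching is exact
#' after this normalization; there is no fuzzy matching.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species <- function(x) {
  gsub("\\s+", " ", trimws(gsub("_", " ", as.character(x))))
}

#' Read a species-level trait table
#'
#' Reads a comma-separated, UTF-8, decimal-point trait CSV with a header
#' row (see [trait_schema]) and validates it: all required columns
#' present and numeric, trait values strictly positive, polyandry at
#' least 1, species names unique after normalization.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` of class `trait_table`, one row per species.
#' @seealso [vrech2014_traits()] for the bundled eight-species dataset.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    stop("trait table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  as_trait_table(raw)
}

#' Validate a data frame as a trait table
#'
#' @param x a data.frame with the columns of [trait_schema].
#' @return `x` with class `trait_table` prepended.
#' @export
as_trait_table <- function(x) {
  if (!is.data.frame(x)) stop("expected a data.frame", call. = FALSE)
  missing_cols <- setdiff(trait_schema$required, names(x))
  if (length(missing_cols)) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(intersect(names(x),
                                c(trait_schema$required, trait_schema$optional)),
                      "species")
  for (cl in num_cols) {
    if (!is.numeric(x[[cl]])) {
      stop("trait column '", cl, "' is not numeric", call. = FALSE)
    }
    if (anyNA(x[[cl]])) {
      stop("trait column '", cl, "' contains missing values", call. = FALSE)
    }
  }
  for (cl in .positive_cols) {
    bad <- which(x[[cl]] <= 0)
    if (length(bad)) {
      stop("non-positive ", cl, " for species: ",
           paste(x$species[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (any(x$polyandry < 1)) {
    stop("polyandry must be >= 1 (mean number of accepted males)",
         call. = FALSE)
  }
  x$species <- normalize_species(x$species)
  if (anyDuplicated(x$species)) {
    stop("duplicate species name(s): ",
         paste(unique(x$species[duplicated(x$species)]), collapse = ", "),
         call. = FALSE)
  }
  class(x) <- unique(c("trait_table", class(x)))
  x
}

#' Bundled eight-species bothriurid trait table
#'
#' The species-mean trait table for the eight Bothriuridae species
#' (genera *Bothriurus*, *Brachistosternus*, *Timogenes*, *Urophonius*)
#' that the study analyses: body mass (g), testes mass (mg),
#' spermatophore trunk volume (mm^3), sperm-package length (um) and
#' polyandry level, with standard deviations and per-species male sample
#' sizes where reported.
#'
#' @return a `trait_table` with 8 rows.
#' @export
vrech2014_traits <- function() {
  read_trait_table(system.file("extdata", "vrech2014_traits.csv",
                               package = "scorpallo", mustWork = TRUE))
}

#' Gonadosomatic index
#'
#' GSI expresses gonad mass as a percentage of body mass:
#' `100 * gonad mass / body mass`.  Inputs follow the trait-table units
#' (body mass in grams, testes mass in milligrams), so the testes mass is
#' converted to grams before forming the ratio.  GSI is invariant under
#' rescaling both masses by a common factor.
#'
#' @param body_mass_g body mass in grams (strictly positive).
#' @param testes_mass_mg testes mass in milligrams (strictly positive).
#' @return GSI in percent; vectorized over its arguments.
#' @examples
#' gsi(0.43, 1.60)   # 0.372...
#' @export
gsi <- function(body_mass_g, testes_mass_mg) {
  if (any(body_mass_g <= 0) || any(testes_mass_mg <= 0)) {
    stop("gsi() requires strictly positive masses", call. = FALSE)
  }
  100 * (testes_mass_mg / 1000) / body_mass_g
}

#' Add log10-transformed analysis columns to a trait table
#'
#' Appends the four analysis columns used throughout the regressions:
#' `lbm` = log10 body mass (g), `ltm` = log10 testes mass, `lsv` = log10
#' spermatophore volume (mm^3), `lsl` = log10 sperm length (um), plus
#' `pol`, the untransformed polyandry level.  Testes mass is converted to
#' grams before the log by default (`testes_unit = "g"`), the scale the
#' study's intercepts imply; set `testes_unit = "mg"` to log the
#' milligram values directly (slopes are unaffected, intercepts shift by
#' 3).
#'
#' @param x a `trait_table`.
#' @param testes_unit unit in which testes mass enters the log transform.
#' @param strict if `TRUE` (default), re-applying the transform to a
#'   table that already carries the analysis columns is an error;
#'   if `FALSE` the columns are recomputed from the source columns
#'   (a no-op on an untouched table).
#' @return the table with columns `lbm`, `ltm`, `lsv`, `lsl`, `pol`.
#' @export
log10_traits <- function(x, testes_unit = c("g", "mg"), strict = TRUE) {
  x <- as_trait_table(x)
  testes_unit <- match.arg(testes_unit)
  derived <- c("lbm", "ltm", "lsv", "lsl", "pol")
  if (any(derived %in% names(x)) && strict) {
    stop("table already carries log10 analysis columns; ",
         "use strict = FALSE to recompute them", call. = FALSE)
  }
  tm <- if (testes_unit == "g") x$testes_mass_mg / 1000 else x$testes_mass_mg
  x$lbm <- log10(x$body_mass_g)
  x$ltm <- log10(tm)
  x$lsv <- log10(x$spermatophore_volume_mm3)
  x$lsl <- log10(x$sperm_length_um)
  x$pol <- x$polyandry
  x
}

#' Descriptive summary of a positive-valued sample
#'
#' Mean, sample (n-1) standard deviation, minimum and maximum, the form
#' in which species traits are reported (mean +/- SD).
#'
#' @param values numeric vector, at least one value; at least two for a
#'   finite SD (with a single value the SD is `NA`).
#' @return named numeric vector `c(mean, sd, min, max)`.
#' @export
summarize_values <- function(values) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  c(mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
    min = min(values), max = max(values))
}

#' Shapiro-Wilk normality check
#'
#' Thin, validating wrapper around the standard Royston-approximation
#' Shapiro-Wilk test, used on the log10-transformed trait columns before
#' the regressions.
#'
#' @param values numeric vector, 3 <= n <= 5000, not all identical.
#' @return object of class `normality_test`: list with `W`, `p`, `n`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("shapiro_wilk() needs between 3 and 5000 values", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("degenerate sample: all values identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  structure(list(W = unname(sw$statistic), p = sw$p.value, n = n),
            class = "normality_test")
}

#' @export
print.normality_test <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.3f, p = %.3f (n = %d)\n", x$W, x$p, x$n))
  invisible(x)
}

#' Convert a log10-log10 regression line to an allometric equation
#'
#' A power law `y = a * x^b` is linear on the log10 scale:
#' `log10(y) = log10(a) + b * log10(x)`.  Given the fitted intercept and
#' slope on that scale, returns `a = 10^intercept` and `b = slope`.
#' `a` carries the units of `y` at `x = 1`; `b` is dimensionless
#' (b < 1: negative allometry; b > 1: positive allometry).
#'
#' @param intercept intercept on the log10 scale.
#' @param slope slope on the log10 scale.
#' @return object of class `allometric_fit`: list with `a`, `b`,
#'   `intercept`, `slope`.
#' @examples
#' allometry_from_loglog(2.3283, -0.14)  # a ~ 212.96
#' @export
allometry_from_loglog <- function(intercept, slope) {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(a = 10^intercept, b = slope,
                 intercept = intercept, slope = slope),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("allometric equation: y = %.4g * x^%.4g\n", x$a, x$b))
  invisible(x)
}

#' Spermatophore trunk volume from area and width
#'
#' The trunk volume (mm^3), the proxy for ejaculate volume, is the trunk
#' area (mm^2) multiplied by the trunk width (mm).
#'
#' @param trunk_area_mm2 trunk area in square millimetres.
#' @param trunk_width_mm trunk width in millimetres.
#' @return volume in cubic millimetres; vectorized.
#' @export
spermatophore_volume <- function(trunk_area_mm2, trunk_width_mm) {
  if (any(trunk_area_mm2 <= 0) || any(trunk_width_mm <= 0)) {
    stop("trunk area and width must be strictly positive", call. = FALSE)
  }
  trunk_area_mm2 * trunk_width_mm
}
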
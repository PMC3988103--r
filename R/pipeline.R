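#' One-shot reproduction of the comparative analysis
#'
#' Runs the full analysis over a species trait table and a phylogeny:
#' log10 transforms, Shapiro-Wilk normality checks of the transformed
#' columns, per-species GSI, mean +/- SD descriptive summaries,
#' allometric equations from the single-predictor body-mass fits, and
#' AICc model selection over the 18-model candidate space (lambda
#' estimated per model), reporting each response's selection table and
#' best model.
#'
#' @param traits a `trait_table` (default: the bundled eight-species
#'   dataset).
#' @param tree a phylogeny whose tips match `traits$species` (default:
#'   the bundled cladogram, equal branch lengths).
#' @param k_counting AICc parameter accounting; see [model_selection()].
#' @param lambda_bounds lambda search interval; see [pgls_fit()].
#' @param out_dir optional directory; when given, the report is written
#'   there as JSON, per-response TSV tables and a plain-text summary.
#' @return object of class `study_report`: list with `descriptives`
#'   (per-species table with GSI; trait summaries; normality tests),
#'   `allometry`, `selection` (three `selection_table`s), `best`
#'   (named character vector of best-model formulas), and `provenance`.
#' @export
reproduce_study <- function(traits = vrech2014_traits(),
                            tree = default_cladogram(),
                            k_counting = "coefficients",
                            lambda_bounds = c(1e-4, 0.9999),
                            out_dir = NULL) {
  traits <- as_trait_table(traits)
  tab <- log10_traits(traits, strict = FALSE)
  V <- phylo_vcv(tree, tip_order = tab$species)

  species_tab <- data.frame(
    species = tab$species,
    body_mass_g = tab$body_mass_g,
    testes_mass_mg = tab$testes_mass_mg,
    spermatophore_volume_mm3 = tab$spermatophore_volume_mm3,
    sperm_length_um = tab$sperm_length_um,
    polyandry = tab$polyandry,
    gsi = gsi(tab$body_mass_g, tab$testes_mass_mg),
    stringsAsFactors = FALSE)

  summaries <- lapply(
    c(body_mass_g = "body_mass_g", testes_mass_mg = "testes_mass_mg",
      spermatophore_volume_mm3 = "spermatophore_volume_mm3",
      sperm_length_um = "sperm_length_um"),
    function(cl) summarize_values(tab[[cl]]))

  normality <- lapply(c(lbm = "lbm", ltm = "ltm", lsv = "lsv",
                        lsl = "lsl"),
                      function(cl) shapiro_wilk(tab[[cl]]))

  # allometric equations y = a * x^b from the single-predictor
  # body-mass pGLS fits on the log10 scale
  allo <- lapply(c(testes_mass = "ltm", sperm_length = "lsl",
                   spermatophore_volume = "lsv"), function(resp) {
    f <- pgls_fit(stats::reformulate("lbm", response = resp), tab,
                  V = V, lambda_bounds = lambda_bounds)
    allometry_from_loglog(unname(f$coefficients[1]),
                          unname(f$coefficients["lbm"]))
  })

  selection <- lapply(c(ltm = "ltm", lsl = "lsl", lsv = "lsv"),
                      function(r) {
                        model_selection(tab, tree = NULL, response = r,
                                        k_counting = k_counting,
                                        lambda_bounds = lambda_bounds,
                                        V = V)
                      })
  best <- vapply(selection, function(s) best_model(s)$model, character(1))

  report <- structure(
    list(descriptives = list(species = species_tab, summaries = summaries,
                             normality = normality),
         allometry = allo,
         selection = selection,
         best = best,
         provenance = list(package = "scorpallo",
                           version = as.character(
                             utils::packageVersion("scorpallo")),
                           n_species = nrow(tab),
                           k_counting = k_counting,
                           lambda_bounds = lambda_bounds,
                           tree = write_newick(tree))),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report to disk
#'
#' Emits `report.json` (full floating-point precision), one
#' `selection_<response>.tsv` per response in the published table's
#' long layout, and `report.txt`, a human-readable summary with display
#' rounding (masses to 0.1 mg, GSI to 0.01 percent, weights to 0.01).
#' Output is deterministic for identical inputs: no timestamps.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  jx <- list(
    descriptives = list(
      species = report$descriptives$species,
      summaries = lapply(report$descriptives$summaries, as.list),
      normality = lapply(report$descriptives$normality, unclass)),
    allometry = lapply(report$allometry, unclass),
    selection = lapply(report$selection, function(s) {
      s2 <- as.data.frame(s)
      attr(s2, "fits") <- NULL
      s2
    }),
    best = as.list(report$best),
    provenance = report$provenance)
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(jx, pj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, pj)

  for (r in names(report$selection)) {
    pt <- file.path(dir, paste0("selection_", r, ".tsv"))
    write_selection_tsv(report$selection[[r]], pt)
    paths <- c(paths, pt)
  }

  pt <- file.path(dir, "report.txt")
  con <- file(pt, open = "wt", encoding = "UTF-8")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  paths <- c(paths, pt)
  invisible(paths)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Comparative reproductive-allocation study report\n")
  cat("================================================\n\n")
  d <- x$descriptives$species
  cat("Per-species traits (GSI in %, rounded for display):\n")
  print(data.frame(species = d$species,
                   body_mass_g = round(d$body_mass_g, 2),
                   testes_mass_mg = round(d$testes_mass_mg, 1),
                   sperm_length_um = round(d$sperm_length_um, 1),
                   polyandry = d$polyandry,
                   GSI = sprintf("%.2f%%", d$gsi)),
        row.names = FALSE)
  s <- x$descriptives$summaries
  cat(sprintf("\nTestes mass across species: %.1f +/- %.1f mg (range %.1f-%.1f)\n",
              s$testes_mass_mg["mean"], s$testes_mass_mg["sd"],
              s$testes_mass_mg["min"], s$testes_mass_mg["max"]))
  cat("\nShapiro-Wilk on log10 columns:\n")
  for (nm in names(x$descriptives$normality)) {
    nt <- x$descriptives$normality[[nm]]
    cat(sprintf("  %s: W = %.3f, p = %.3f\n", nm, nt$W, nt$p))
  }
  cat("\nAllometric equations (y = a * x^b, x = body mass in g):\n")
  for (nm in names(x$allometry)) {
    a <- x$allometry[[nm]]
    cat(sprintf("  %s = %.4g * body_mass^%.3g\n", nm, a$a, a$b))
  }
  cat("\n")
  for (r in names(x$selection)) print(x$selection[[r]])
  cat("\nBest models:\n")
  for (r in names(x$best)) cat("  ", x$best[[r]], "\n")
  invisible(x)
}
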
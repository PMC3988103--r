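#!/usr/bin/env Rscript
# Descriptive layer of the comparative study: per-species gonadosomatic
# index, cross-species trait summaries, normality of the log10-
# transformed analysis columns, and the allometric equations implied by
# the single-predictor body-mass regressions.
#
# Findings (printed below from the computation itself): testes mass
# spans an order of magnitude across the eight species; the Timogenes
# species allocate least in relative terms and Bothriurus cordubensis
# most; all four log10 trait columns pass the Shapiro-Wilk check; sperm
# length scales with a small negative exponent of body mass.

suppressMessages(library(scorpallo))

out_dir <- "results/descriptives"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tab <- log10_traits(vrech2014_traits())
tab$gsi <- gsi(tab$body_mass_g, tab$testes_mass_mg)

cat("Species table with GSI (%):\n")
print(tab[order(tab$gsi),
          c("species", "body_mass_g", "testes_mass_mg", "polyandry",
            "gsi")],
      row.names = FALSE, digits = 3)
utils::write.csv(tab, file.path(out_dir, "species_gsi.csv"),
                 row.names = FALSE)

cat("\nCross-species summaries (mean, SD, min, max):\n")
summ <- t(sapply(c("body_mass_g", "testes_mass_mg",
                   "spermatophore_volume_mm3", "sperm_length_um"),
                 function(cl) summarize_values(tab[[cl]])))
print(round(summ, 2))
utils::write.csv(data.frame(trait = rownames(summ), round(summ, 4)),
                 file.path(out_dir, "trait_summaries.csv"),
                 row.names = FALSE)

cat("\nShapiro-Wilk on log10 columns:\n")
norm <- do.call(rbind, lapply(c("lbm", "ltm", "lsv", "lsl"),
                              function(cl) {
  s <- shapiro_wilk(tab[[cl]])
  data.frame(column = cl, W = s$W, p = s$p)
}))
print(transform(norm, W = round(W, 3), p = round(p, 3)),
      row.names = FALSE)
utils::write.csv(norm, file.path(out_dir, "normality.csv"),
                 row.names = FALSE)

cat("\nAllometric equations (y = a * body_mass^b, pGLS on log10 scale):\n")
tree <- default_cladogram()
for (resp in c(ltm = "ltm", lsl = "lsl", lsv = "lsv")) {
  f <- pgls_fit(stats::reformulate("lbm", response = resp), tab,
                tree = tree)
  a <- allometry_from_loglog(unname(coef(f)[1]), unname(coef(f)["lbm"]))
  cat(sprintf("  %s: a = %.4g, b = %.3f (lambda = %.4f)\n",
              resp, a$a, a$b, f$lambda))
}
cat("\nWrote", out_dir, "\n")
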
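#' Candidate model sets for the three response variables
#'
#' The 18 biologically motivated models of the study, grouped by
#' response: testes mass `ltm` (4 models: null; body mass; polyandry;
#' body mass + polyandry), sperm length `lsl` (6: null; body mass;
#' polyandry; testes mass; body mass + polyandry; body mass + testes
#' mass) and spermatophore volume `lsv` (8: null; each of body mass,
#' polyandry, testes mass, sperm length singly; body mass + testes
#' mass; body mass + polyandry; body mass + sperm length).  In every
#' additive model body mass (`lbm`) comes first, the order in which
#' terms enter the sequential ANOVA, so the remaining predictor is
#' assessed after controlling for body mass.  Interaction models are
#' excluded.
#'
#' @param response one of `"ltm"`, `"lsl"`, `"lsv"`, or `NULL` (default)
#'   for all three sets.
#' @return for one response, a list of character vectors of predictor
#'   names (the null model is `character(0)`); for `NULL`, a named list
#'   of the three sets.
#' @export
candidate_models <- function(response = NULL) {
  sets <- list(
    ltm = list(character(0), "lbm", "pol", c("lbm", "pol")),
    lsl = list(character(0), "lbm", "pol", "ltm",
               c("lbm", "pol"), c("lbm", "ltm")),
    lsv = list(character(0), "lbm", "pol", "ltm", "lsl",
               c("lbm", "ltm"), c("lbm", "pol"), c("lbm", "lsl"))
  )
  if (is.null(response)) return(sets)
  response <- match.arg(response, names(sets))
  sets[[response]]
}

#' Akaike information criterion, small-sample corrected
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1)`.  Requires
#' `n - k - 1 > 0`; as `n` grows at fixed `k` the correction term
#' vanishes and AICc tends to AIC.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @return the AICc value; vectorized over `loglik` and `k`.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n - k - 1 <= 0)) {
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ",
         paste(k[n - k - 1 <= 0], collapse = ","), ")", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.  The minimum is subtracted before
#' exponentiating for numerical stability, which also makes the weights
#' invariant to adding a constant to every AICc.  The ratio of two
#' weights, `exp(-(AICc_i - AICc_j) / 2)`, is the evidence ratio of the
#' two models.
#'
#' @param aicc_values numeric vector of AICc values (at least one
#'   finite).
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (!any(is.finite(aicc_values))) {
    stop("no finite AICc value", call. = FALSE)
  }
  rel <- exp(-(aicc_values - min(aicc_values, na.rm = TRUE)) / 2)
  rel / sum(rel)
}

# How many parameters AICc charges a model for.  The study's own
# accounting ("models with four parameters (y ~ a*b)") counts regression
# coefficients only, the package default; the alternatives additionally
# charge the ML residual variance, and the variance plus the estimated
# lambda.
k_parameters <- function(k_coef, k_counting) {
  k_counting <- match.arg(k_counting,
                          c("coefficients", "coefficients+variance",
                            "coefficients+variance+lambda"))
  k_coef + switch(k_counting,
                  "coefficients" = 0L,
                  "coefficients+variance" = 1L,
                  "coefficients+variance+lambda" = 2L)
}

#' Fit and rank a candidate model set by AICc
#'
#' Fits every candidate model for `response` by [pgls_fit()] (lambda
#' estimated per model by maximum likelihood, never shared across
#' models), computes AICc, Delta-AICc, Akaike weights, and flags the
#' selected models: the minimum-AICc model and every model within 2
#' AICc units of it (`delta < 2`, strict).
#'
#' @param data a [log10_traits()]-transformed `trait_table`.
#' @param tree phylogeny matching `data$species`; or `NULL` with `V`.
#' @param response `"ltm"`, `"lsl"` or `"lsv"`.
#' @param k_counting what AICc counts as a parameter:
#'   `"coefficients"` (default; the study's accounting),
#'   `"coefficients+variance"`, or `"coefficients+variance+lambda"`.
#' @param lambda_bounds passed to [pgls_fit()].
#' @param V optional precomputed covariance aligned with `data`.
#' @return a data.frame of class `selection_table`, one row per model in
#'   candidate order, columns `response`, `model`, `predictors`,
#'   `k_coef`, `k`, `lambda`, `loglik`, `aicc`, `delta`, `weight`,
#'   `selected`, `lrt_p_vs_0`, `lrt_p_vs_1`; the fitted `pgls` objects
#'   are in `attr(, "fits")`.
#' @export
model_selection <- function(data, tree, response,
                            k_counting = "coefficients",
                            lambda_bounds = c(1e-4, 0.9999), V = NULL) {
  cands <- candidate_models(response)
  if (is.null(V)) V <- phylo_vcv(tree, tip_order = data$species)
  fits <- lapply(cands, function(pr) {
    fml <- stats::reformulate(if (length(pr)) pr else "1",
                              response = response)
    pgls_fit(fml, data, V = V, lambda_bounds = lambda_bounds)
  })
  k_coef <- vapply(fits, function(f) f$k_coef, integer(1))
  k <- k_parameters(k_coef, k_counting)
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  n <- fits[[1]]$n
  ic <- aicc(ll, k, n)
  delta <- ic - min(ic)
  tab <- data.frame(
    response = response,
    model = vapply(cands, function(pr) {
      paste(response, "~", if (length(pr)) paste(pr, collapse = " + ")
            else "1")
    }, character(1)),
    predictors = vapply(cands, paste, character(1), collapse = "+"),
    k_coef = k_coef, k = k,
    lambda = vapply(fits, function(f) f$lambda, numeric(1)),
    loglik = ll, aicc = ic, delta = delta,
    weight = akaike_weights(ic),
    selected = delta < 2,
    lrt_p_vs_0 = vapply(fits, function(f) f$lrt$p_vs_0, numeric(1)),
    lrt_p_vs_1 = vapply(fits, function(f) f$lrt$p_vs_1, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(tab, "fits") <- fits
  attr(tab, "k_counting") <- k_counting
  class(tab) <- c("selection_table", class(tab))
  tab
}

#' Selected models of a selection table
#'
#' The minimum-AICc model together with every model whose Delta-AICc is
#' strictly below 2 (ties at the minimum all have delta 0 and are all
#' selected).
#'
#' @param tab a `selection_table`.
#' @return the selected rows, ordered by delta.
#' @export
selected_models <- function(tab) {
  out <- tab[tab$selected, , drop = FALSE]
  out[order(out$delta), , drop = FALSE]
}

#' Best model of a selection table
#'
#' @param tab a `selection_table`.
#' @return one row: the maximum-weight (minimum-AICc) model.
#' @export
best_model <- function(tab) {
  tab[which.min(tab$aicc), , drop = FALSE]
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Model selection (", x$response[1], "; k = ",
      attr(x, "k_counting"), ")\n", sep = "")
  show <- data.frame(model = x$model, lambda = round(x$lambda, 4),
                     logLik = round(x$loglik, 3),
                     AICc = round(x$aicc, 2), dAICc = round(x$delta, 2),
                     wt = round(x$weight, 2),
                     sel = ifelse(x$selected, "*", ""))
  print(show[order(x$delta), ], row.names = FALSE)
  invisible(x)
}

#' Write a selection table in the study's report layout
#'
#' Long-format TSV mirroring the published table: one row per term of
#' each model (plus the intercept row of the null model) carrying the
#' term's slope, sequential F and p, with the model-level AICc,
#' Delta-AICc, weight, lambda and lambda-LRT flags on the model's first
#' row.  LRT flags follow the study's convention: first symbol vs
#' lambda = 0, second vs lambda = 1; `*` significant at 0.05, `ns` not.
#'
#' @param tab a `selection_table`.
#' @param path output TSV path; if `NULL`, the data.frame is returned.
#' @return the long-format data.frame, invisibly when written.
#' @export
write_selection_tsv <- function(tab, path = NULL) {
  fits <- attr(tab, "fits")
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    f <- fits[[i]]
    prs <- strsplit(tab$predictors[i], "+", fixed = TRUE)[[1]]
    flag <- paste0(ifelse(f$lrt$p_vs_0 < 0.05, "*", "ns"), "/",
                   ifelse(f$lrt$p_vs_1 < 0.05, "*", "ns"))
    if (!length(prs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        response = tab$response[i], model = tab$model[i], term = "1",
        slope = unname(f$coefficients[1]), F = NA_real_, p = NA_real_,
        aicc = tab$aicc[i], delta = tab$delta[i], weight = tab$weight[i],
        lambda = tab$lambda[i], lrt = flag, stringsAsFactors = FALSE)
    } else {
      for (j in seq_along(prs)) {
        first <- j == 1L
        rows[[length(rows) + 1L]] <- data.frame(
          response = tab$response[i], model = tab$model[i], term = prs[j],
          slope = unname(f$coefficients[prs[j]]),
          F = f$anova$F[j], p = f$anova$p[j],
          aicc = if (first) tab$aicc[i] else NA_real_,
          delta = if (first) tab$delta[i] else NA_real_,
          weight = if (first) tab$weight[i] else NA_real_,
          lambda = if (first) tab$lambda[i] else NA_real_,
          lrt = if (first) flag else "", stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, rows)
  if (is.null(path)) return(long)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(long)
}
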
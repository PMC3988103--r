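#' Generalized least squares at a fixed covariance
#'
#' Profile-ML GLS: for response `y`, design `X` and a fixed positive
#' definite covariance structure `V`, computes
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, the ML residual variance
#' `sigma2 = e' V^-1 e / n` (divisor n, not n - k, so that likelihoods
#' are comparable across fixed-effect structures), and the maximized
#' Gaussian log-likelihood
#' `-0.5 * (n * log(2 * pi * sigma2) + log|V| + n)`.
#' Solved by Cholesky whitening and a QR factorization of the whitened
#' design.
#'
#' @param y numeric response vector, aligned with the rows of `V`.
#' @param X numeric design matrix (include the intercept column).
#' @param V covariance structure, n x n positive definite.
#' @return list with `beta`, `sigma2`, `loglik`, plus the whitened
#'   response and design (`wy`, `wX`) and `logdetV` for downstream use.
#' @export
gls_profile_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop("dimension mismatch between y, X and V", call. = FALSE)
  }
  if (n < ncol(X) + 1L) {
    stop("need at least k + 1 observations to estimate k coefficients ",
         "and a residual variance", call. = FALSE)
  }
  L <- tryCatch(chol(V), error = function(e) {
    stop("covariance is not positive definite (condition number ~ ",
         format(kappa(V), digits = 3), "): ", conditionMessage(e),
         call. = FALSE)
  })
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(wX)
  if (qrX$rank < ncol(X)) {
    stop("singular design matrix (rank ", qrX$rank, " < ", ncol(X), ")",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, wy)
  e <- wy - wX %*% beta
  sigma2 <- sum(e^2) / n
  logdetV <- 2 * sum(log(diag(L)))
  # an (up to rounding) exact fit degenerates the density; flag it as
  # +Inf rather than returning a rounding-noise likelihood
  degenerate <- sigma2 <= 1e-25 * mean(wy^2)
  loglik <- if (degenerate) Inf else {
    -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  }
  beta <- drop(beta)
  if (!is.null(colnames(X))) names(beta) <- colnames(X)
  list(beta = beta, sigma2 = sigma2, loglik = loglik,
       wy = wy, wX = wX, logdetV = logdetV)
}

#' Profile log-likelihood of lambda
#'
#' Log-likelihood of the GLS model at the lambda-transformed covariance,
#' with `beta` and `sigma2` profiled out.
#'
#' @inheritParams gls_profile_fit
#' @param V phylogenetic covariance (at lambda = 1) from [phylo_vcv()].
#' @param lambda scalar in `[0, 1]`.
#' @return the log-likelihood value.
#' @export
pgls_loglik <- function(y, X, V, lambda) {
  gls_profile_fit(y, X, lambda_transform(V, lambda))$loglik
}

#' Maximum-likelihood estimation of Pagel's lambda
#'
#' Scans the profile log-likelihood on a coarse grid (the profile can
#' be multimodal on small trees), refines the best grid point with
#' [stats::optimize()] within its bracketing interval, then compares
#' the refined optimum against both bounds and keeps the best, so
#' boundary maxima (common with few species) are always found.  The
#' default bounds `[1e-4, 0.9999]`
#' keep the transformed covariance comfortably positive definite;
#' reported boundary estimates are therefore exactly 0.0001 or 0.9999.
#'
#' @inheritParams pgls_loglik
#' @param bounds numeric length-2, search interval within `[0, 1]`.
#' @param tol convergence tolerance passed to [stats::optimize()].
#' @param grid_points size of the coarse bracketing grid.
#' @return list with `lambda`, `loglik`, `beta`, `sigma2`.
#' @export
optimize_lambda <- function(y, X, V, bounds = c(1e-4, 0.9999), tol = 1e-8,
                            grid_points = 21L) {
  stopifnot(length(bounds) == 2L, bounds[1] >= 0, bounds[2] <= 1,
            bounds[1] < bounds[2], grid_points >= 3L)
  prof_fn <- function(l) pgls_loglik(y, X, V, l)
  grid <- seq(bounds[1], bounds[2], length.out = grid_points)
  prof <- vapply(grid, prof_fn, numeric(1))
  if (!any(is.finite(prof))) {
    stop("lambda optimization failed; profile on the coarse grid: ",
         paste(sprintf("%.3f:%.3f", grid, prof), collapse = " "),
         call. = FALSE)
  }
  ibest <- which.max(prof)
  lo <- grid[max(1L, ibest - 1L)]
  hi <- grid[min(grid_points, ibest + 1L)]
  op <- stats::optimize(prof_fn, interval = c(lo, hi), maximum = TRUE,
                        tol = tol)
  cand <- c(op$maximum, grid[ibest], bounds)
  ll <- vapply(cand, prof_fn, numeric(1))
  best <- which.max(ll)
  lam <- cand[best]
  fit <- gls_profile_fit(y, X, lambda_transform(V, lam))
  list(lambda = lam, loglik = fit$loglik,
       beta = fit$beta, sigma2 = fit$sigma2)
}

#' Likelihood-ratio tests of lambda against 0 and 1
#'
#' Compares the maximized likelihood at `lambda_hat` against refits with
#' lambda fixed at exactly 0 (no phylogenetic covariance) and exactly 1
#' (full Brownian covariance).  Statistics are `2 * delta log-lik`,
#' floored at zero (an estimate at a search bound can sit a hair below
#' the fixed-value likelihood), with p-values from the upper tail of
#' chi-square with 1 df (no boundary mixture correction, mirroring the
#' methodology this analysis follows).
#'
#' @inheritParams pgls_loglik
#' @param lambda_hat the ML estimate from [optimize_lambda()].
#' @param loglik_hat its log-likelihood.
#' @return object of class `lambda_lrt`: list with `lambda_hat`,
#'   `statistic_vs_0`, `p_vs_0`, `statistic_vs_1`, `p_vs_1`.
#' @export
lambda_lrt <- function(y, X, V, lambda_hat, loglik_hat) {
  ll0 <- pgls_loglik(y, X, V, 0)
  ll1 <- pgls_loglik(y, X, V, 1)
  s0 <- max(0, 2 * (loglik_hat - ll0))
  s1 <- max(0, 2 * (loglik_hat - ll1))
  structure(list(lambda_hat = lambda_hat,
                 statistic_vs_0 = s0,
                 p_vs_0 = stats::pchisq(s0, df = 1, lower.tail = FALSE),
                 statistic_vs_1 = s1,
                 p_vs_1 = stats::pchisq(s1, df = 1, lower.tail = FALSE)),
            class = "lambda_lrt")
}

#' @export
print.lambda_lrt <- function(x, ...) {
  cat(sprintf("lambda = %.4f; LRT vs 0: X2 = %.3f (p = %.3f); vs 1: X2 = %.3f (p = %.3f)\n",
              x$lambda_hat, x$statistic_vs_0, x$p_vs_0,
              x$statistic_vs_1, x$p_vs_1))
  invisible(x)
}

# Sequential (Type I) ANOVA on data whitened by V(lambda_hat).
# Terms enter in the column order of X (after the intercept); each term's
# SS is its reduction in residual SS given all earlier terms, and every F
# uses the full model's residual mean square.
sequential_anova_whitened <- function(wy, wX, term_labels) {
  n <- length(wy)
  k <- ncol(wX)
  p <- k - 1L
  if (p < 1L) stop("sequential ANOVA needs at least one predictor",
                   call. = FALSE)
  if (n - k < 1L) stop("no residual degrees of freedom", call. = FALSE)
  rss <- numeric(k)
  for (j in seq_len(k)) {
    qrj <- qr(wX[, seq_len(j), drop = FALSE])
    rss[j] <- sum(qr.resid(qrj, wy)^2)
  }
  rss_full <- rss[k]
  ms_resid <- rss_full / (n - k)
  Fv <- (rss[seq_len(p)] - rss[seq_len(p) + 1L]) / ms_resid
  data.frame(term = term_labels,
             ss = rss[seq_len(p)] - rss[seq_len(p) + 1L],
             F = Fv,
             p = stats::pf(Fv, 1, n - k, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `formula` on a species trait table by GLS whose error covariance
#' is the lambda-transformed phylogenetic variance-covariance matrix of
#' `tree`, with lambda estimated by maximum likelihood (or held fixed).
#' Rows are matched to tips by normalized species name.  The fit carries
#' likelihood-ratio tests of the lambda estimate against 0 and 1, and a
#' sequential (Type I) ANOVA in which predictors are assessed in the
#' order they appear in the formula, on data whitened by the full
#' model's fitted covariance (lambda is not re-estimated for the nested
#' submodels, keeping the Type I decomposition exact; set
#' `anova_refit_lambda = TRUE` to re-profile lambda within each nested
#' fit instead).
#'
#' @param formula model formula over columns of `data`, e.g.
#'   `ltm ~ lbm + pol`.  Predictor order matters for the sequential
#'   ANOVA.
#' @param data a data.frame with a `species` column (normally a
#'   [log10_traits()]-transformed `trait_table`).
#' @param tree an [ape::phylo] tree whose tips match `data$species`; or
#'   `NULL` if `V` is supplied.
#' @param V phylogenetic covariance at lambda = 1, already aligned with
#'   the rows of `data`; overrides `tree`.
#' @param lambda `"ML"` (default) to estimate lambda, or a fixed value
#'   in `[0, 1]`.
#' @param lambda_bounds search interval for the ML estimate.
#' @param anova_refit_lambda re-profile lambda within each nested model
#'   of the sequential ANOVA (default `FALSE`).
#' @return object of class `pgls`; see Details.  Key fields:
#'   `coefficients`, `sigma2`, `lambda`, `loglik`, `n`, `k_coef`,
#'   `anova` (per-term F and p, `NULL` for the intercept-only model),
#'   `lrt` (a `lambda_lrt`), `fitted`, `residuals`.
#' @export
pgls_fit <- function(formula, data, tree = NULL, V = NULL,
                     lambda = "ML", lambda_bounds = c(1e-4, 0.9999),
                     anova_refit_lambda = FALSE) {
  if (is.null(V)) {
    if (is.null(tree)) stop("supply either 'tree' or 'V'", call. = FALSE)
    if (is.null(data$species)) {
      stop("'data' needs a species column to be matched to the tree",
           call. = FALSE)
    }
    V <- phylo_vcv(tree, tip_order = data$species)
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  term_labels <- attr(stats::terms(formula, data = data), "term.labels")

  if (identical(lambda, "ML")) {
    opt <- optimize_lambda(y, X, V, bounds = lambda_bounds)
    lam <- opt$lambda
  } else {
    lam <- lambda
  }
  fit <- gls_profile_fit(y, X, lambda_transform(V, lam))
  lrt <- lambda_lrt(y, X, V, lam, fit$loglik)

  aov_tab <- NULL
  if (length(term_labels)) {
    if (anova_refit_lambda) {
      n <- length(y); k <- ncol(X)
      rss_of <- function(cols) {
        Xj <- X[, cols, drop = FALSE]
        lamj <- optimize_lambda(y, Xj, V, bounds = lambda_bounds)$lambda
        fj <- gls_profile_fit(y, Xj, lambda_transform(V, lamj))
        sum((fj$wy - fj$wX %*% fj$beta)^2)
      }
      rss <- vapply(seq_len(k), function(j) rss_of(seq_len(j)), numeric(1))
      ms <- rss[k] / (n - k)
      Fv <- (rss[-k] - rss[-1]) / ms
      aov_tab <- data.frame(term = term_labels, ss = rss[-k] - rss[-1],
                            F = Fv,
                            p = stats::pf(Fv, 1, n - k, lower.tail = FALSE),
                            stringsAsFactors = FALSE)
    } else {
      aov_tab <- sequential_anova_whitened(fit$wy, fit$wX, term_labels)
    }
  }

  beta <- fit$beta
  fitted <- drop(X %*% beta)
  structure(list(call = match.call(), formula = formula,
                 coefficients = beta, sigma2 = fit$sigma2,
                 lambda = lam, lambda_bounds = lambda_bounds,
                 lambda_fixed = !identical(lambda, "ML"),
                 loglik = fit$loglik, n = length(y), k_coef = ncol(X),
                 anova = aov_tab, lrt = lrt,
                 fitted = fitted, residuals = y - fitted,
                 whitened = list(y = fit$wy, X = fit$wX),
                 V = V),
            class = "pgls")
}

#' Sequential (Type I) ANOVA of a pGLS fit
#'
#' @param object a `pgls` fit with at least one predictor.
#' @param ... unused.
#' @return data.frame with one row per term: `term`, `ss`, `F`, `p`.
#' @export
anova.pgls <- function(object, ...) {
  if (is.null(object$anova)) {
    stop("intercept-only model: no terms to test", call. = FALSE)
  }
  object$anova
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$loglik, df = object$k_coef + 2, class = "logLik")
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("  ", deparse(x$formula), " (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  lambda%s = %.4f, sigma2 = %.4g, logLik = %.4f\n",
              if (x$lambda_fixed) " (fixed)" else " (ML)",
              x$lambda, x$sigma2, x$loglik))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$anova)) {
    cat("  sequential (Type I) ANOVA:\n")
    print(cbind(x$anova[1],
                round(x$anova[c("ss", "F", "p")], 4)), row.names = FALSE)
  }
  print(x$lrt)
  invisible(x)
}

#' Serialize a pGLS fit
#'
#' Stable-field-name JSON representation of the fit (full precision).
#'
#' @param fit a `pgls` object.
#' @param path optional file path; if omitted the JSON string is
#'   returned.
#' @return JSON string, invisibly when written to a file.
#' @export
pgls_to_json <- function(fit, path = NULL) {
  x <- list(formula = deparse(fit$formula),
            n = fit$n, k_coef = fit$k_coef,
            coefficients = as.list(fit$coefficients),
            sigma2 = fit$sigma2, lambda = fit$lambda,
            loglik = fit$loglik,
            anova = fit$anova,
            lrt = unclass(fit$lrt))
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
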
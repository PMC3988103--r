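test_that("GLS at identity covariance reduces to ordinary least squares", {
  set.seed(21)
  n <- 15
  X <- cbind(1, rnorm(n), runif(n))
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(n, sd = 0.4)
  f <- gls_profile_fit(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_equal(unname(f$beta), unname(ols$coefficients), tolerance = 1e-10)
  expect_equal(f$sigma2, sum(ols$residuals^2) / n, tolerance = 1e-10)
})

test_that("profile log-likelihood equals the dense MVN density oracle", {
  for (seed in 1:6) {
    inst <- random_pgls_instance(n_tips = 10 + seed, seed = seed)
    lam <- c(0.1, 0.5, 0.9, 1)[(seed %% 4) + 1]
    W <- lambda_transform(inst$V, lam)
    f <- gls_profile_fit(inst$y, inst$X, W)
    expect_equal(f$loglik,
                 dense_mvn_loglik(inst$y, inst$X, f$beta, f$sigma2, W),
                 tolerance = 1e-8)
  }
})

test_that("fixed-lambda fits agree with nlme::gls + ape::corPagel", {
  skip_if_not_installed("nlme")
  for (seed in c(3, 8)) {
    set.seed(seed)
    tr <- ape::rcoal(12)
    d <- data.frame(species = tr$tip.label, x = rnorm(12))
    d$y <- 1 + 0.5 * d$x + rnorm(12, sd = 0.3)
    for (lam in c(0.3, 0.8, 1)) {
      mine <- pgls_fit(y ~ x, d, tree = tr, lambda = lam)
      ref <- nlme::gls(y ~ x, data = d,
                       correlation = ape::corPagel(lam, phy = tr,
                                                   form = ~species,
                                                   fixed = TRUE),
                       method = "ML")
      expect_equal(unname(coef(mine)), unname(coef(ref)),
                   tolerance = 1e-6)
      expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
    }
  }
})

test_that("lambda ML estimate agrees with phytools::phylosig", {
  skip_if_not_installed("phytools")
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    tr <- ape::rcoal(16)
    V <- phylo_vcv(tr)
    y <- drop(simulate_traits(beta = 2, sigma2 = 0.3, lambda = 0.6, V = V))
    mine <- optimize_lambda(y, matrix(1, 16, 1), V, bounds = c(1e-7, 1))
    ref <- phytools::phylosig(tr, stats::setNames(y, rownames(V)),
                              method = "lambda")
    expect_equal(mine$loglik, ref$logL, tolerance = 1e-3)
    expect_equal(mine$lambda, ref$lambda, tolerance = 0.01)
  }
})

test_that("noiseless data recover coefficients exactly and flag sigma2 -> 0", {
  inst <- random_pgls_instance(seed = 4)
  y <- drop(inst$X %*% c(1.5, -2))
  f <- gls_profile_fit(y, inst$X, inst$V)
  expect_equal(unname(f$beta), c(1.5, -2), tolerance = 1e-9)
  expect_lt(f$sigma2, 1e-18)
  expect_true(is.infinite(f$loglik))  # degenerate density is flagged
})

test_that("optimizer matches a fine grid search", {
  for (seed in 1:5) {
    inst <- random_pgls_instance(n_tips = 10, seed = 100 + seed)
    opt <- optimize_lambda(inst$y, inst$X, inst$V)
    grid <- seq(1e-4, 0.9999, length.out = 1000)
    prof <- vapply(grid, function(l) pgls_loglik(inst$y, inst$X,
                                                 inst$V, l), numeric(1))
    expect_lte(abs(opt$lambda - grid[which.max(prof)]), 0.01)
    expect_gte(opt$loglik, max(prof) - 1e-6)
    # never below the best of a coarse anchor set
    anchors <- vapply(c(1e-4, 0.5, 0.9999),
                      function(l) pgls_loglik(inst$y, inst$X, inst$V, l),
                      numeric(1))
    expect_gte(opt$loglik, max(anchors) - 1e-9)
  }
})

test_that("lambda recovery: independent tips give low lambda-hat, Brownian gives high", {
  d <- study_data()
  set.seed(31)
  X1 <- matrix(1, 8, 1)
  lam_lo <- replicate(60, {
    y <- simulate_traits(X = X1, beta = 0, sigma2 = 0.05, lambda = 0,
                         V = d$V)
    optimize_lambda(y, X1, d$V)$lambda
  })
  expect_lt(median(lam_lo), 0.2)
  tr64 <- balanced_tree64()
  V64 <- phylo_vcv(tr64)
  X64 <- matrix(1, 64, 1)
  lam_hi <- replicate(60, {
    y <- simulate_traits(X = X64, beta = 0, sigma2 = 0.05, lambda = 1,
                         V = V64)
    optimize_lambda(y, X64, V64)$lambda
  })
  expect_gt(median(lam_hi), 0.8)
})

test_that("coefficient recovery is unbiased within Monte-Carlo error", {
  # truth: beta = (-2.1, 0.25), sigma2 = 0.05, lambda = 0.5, 64-tip tree
  V64 <- phylo_vcv(balanced_tree64())
  set.seed(64)
  X64 <- cbind(1, runif(64, 1, 4))
  B <- replicate(500, {
    y <- simulate_traits(X = X64, beta = c(-2.1, 0.25), sigma2 = 0.05,
                         lambda = 0.5, V = V64)
    optimize_lambda(y, X64, V64)$beta
  })
  mc_se <- apply(B, 1, sd) / sqrt(ncol(B))
  expect_lt(abs(mean(B[1, ]) - (-2.1)), 2 * mc_se[1])
  expect_lt(abs(mean(B[2, ]) - 0.25), 2 * mc_se[2])
})

test_that("likelihood-ratio tests against lambda = 0 and 1 behave", {
  d <- study_data()
  tab <- d$tab
  # ltm ~ pol sits at the lower search bound: LRT vs 0 is null
  f <- pgls_fit(ltm ~ pol, tab, V = d$V)
  expect_equal(f$lambda, 1e-4)
  expect_lt(f$lrt$statistic_vs_0, 1e-4)
  expect_gt(f$lrt$p_vs_0, 0.99)
  # statistic equals a brute-force refit at the fixed lambda
  f0 <- pgls_fit(ltm ~ pol, tab, V = d$V, lambda = 0)
  f1 <- pgls_fit(ltm ~ pol, tab, V = d$V, lambda = 1)
  expect_equal(f$lrt$statistic_vs_0,
               max(0, 2 * (f$loglik - f0$loglik)), tolerance = 1e-10)
  expect_equal(f$lrt$statistic_vs_1,
               max(0, 2 * (f$loglik - f1$loglik)), tolerance = 1e-10)
  # nonnegative on random instances (ML dominance)
  for (seed in 1:6) {
    inst <- random_pgls_instance(seed = 200 + seed)
    dd <- data.frame(species = rownames(inst$V), x = inst$X[, 2],
                     y = inst$y)
    ff <- pgls_fit(y ~ x, dd, V = inst$V)
    expect_gte(ff$lrt$statistic_vs_0, 0)
    expect_gte(ff$lrt$statistic_vs_1, 0)
    expect_true(all(c(ff$lrt$p_vs_0, ff$lrt$p_vs_1) >= 0 &
                      c(ff$lrt$p_vs_0, ff$lrt$p_vs_1) <= 1))
  }
})

test_that("sequential ANOVA reduces to textbook OLS ANOVA at lambda = 0 on a clock tree", {
  set.seed(41)
  tr <- ape::rcoal(12)  # ultrametric: V(0) is a multiple of I
  d <- data.frame(species = tr$tip.label, x = rnorm(12))
  d$y <- 2 + 0.8 * d$x + rnorm(12, sd = 0.5)
  f <- pgls_fit(y ~ x, d, tree = tr, lambda = 0)
  ref <- anova(lm(y ~ x, d))
  expect_equal(f$anova$F, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(f$anova$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("sequential SS decompose the whitened total SS", {
  d <- study_data()
  f <- pgls_fit(lsv ~ lbm + ltm, d$tab, V = d$V)
  wy <- f$whitened$y; wX <- f$whitened$X
  rss_null <- sum(qr.resid(qr(wX[, 1, drop = FALSE]), wy)^2)
  rss_full <- sum(qr.resid(qr(wX), wy)^2)
  expect_equal(sum(f$anova$ss), rss_null - rss_full, tolerance = 1e-10)
})

test_that("orthogonalized predictors make term order irrelevant", {
  set.seed(51)
  n <- 16
  tr <- ape::rcoal(n)
  x1 <- rnorm(n)
  x2 <- resid(lm(rnorm(n) ~ x1))            # orthogonal to x1 ...
  x2 <- resid(lm(x2 ~ rep(1, n))) / sd(x2)  # ... and centred
  x1 <- x1 - mean(x1)
  d <- data.frame(species = tr$tip.label, x1 = x1, x2 = x2)
  d$y <- 1 + x1 - x2 + rnorm(n, sd = 0.7)
  lam <- 0.4  # fixed so both orders whiten identically
  f12 <- pgls_fit(y ~ x1 + x2, d, tree = tr, lambda = lam)
  f21 <- pgls_fit(y ~ x2 + x1, d, tree = tr, lambda = lam)
  # whitening at lambda = 0 on an ultrametric tree keeps orthogonality
  f12_0 <- pgls_fit(y ~ x1 + x2, d, tree = tr, lambda = 0)
  f21_0 <- pgls_fit(y ~ x2 + x1, d, tree = tr, lambda = 0)
  expect_equal(sort(f12_0$anova$F), sort(f21_0$anova$F), tolerance = 1e-9)
  # and at any lambda the two orders agree on the full-model fit
  expect_equal(sort(unname(coef(f12))), sort(unname(coef(f21))),
               tolerance = 1e-9)
})

test_that("whitened residuals are numerically orthogonal to the whitened design", {
  for (resp in c("ltm", "lsl", "lsv")) {
    d <- study_data()
    preds <- setdiff(c("lbm", "pol"), resp)
    f <- pgls_fit(stats::reformulate(preds, response = resp), d$tab,
                  V = d$V)
    wres <- f$whitened$y - f$whitened$X %*% cbind(unname(coef(f)))
    expect_lt(max(abs(crossprod(f$whitened$X, wres))), 1e-8)
  }
})

test_that("pgls equals OLS in the limiting covariances", {
  set.seed(61)
  # lambda = 1 on a star tree
  star <- read_newick("(A:2,B:2,C:2,D:2,E:2,F:2);")
  d <- data.frame(species = star$tip.label, x = rnorm(6))
  d$y <- 1 + d$x + rnorm(6, sd = 0.3)
  f <- pgls_fit(y ~ x, d, tree = star, lambda = 1)
  expect_equal(unname(coef(f)), unname(coef(lm(y ~ x, d))),
               tolerance = 1e-9)
  # lambda = 0 on any ultrametric tree
  tr <- ape::rcoal(10)
  d2 <- data.frame(species = tr$tip.label, x = rnorm(10))
  d2$y <- 0.5 - d2$x + rnorm(10, sd = 0.2)
  f0 <- pgls_fit(y ~ x, d2, tree = tr, lambda = 0)
  expect_equal(unname(coef(f0)), unname(coef(lm(y ~ x, d2))),
               tolerance = 1e-9)
})

test_that("degenerate inputs raise informative errors", {
  d <- study_data()
  X <- cbind(1, d$tab$lbm, d$tab$lbm)  # collinear
  expect_error(gls_profile_fit(d$tab$ltm, X, d$V), "singular design")
  expect_error(gls_profile_fit(d$tab$ltm, cbind(1, d$tab$lbm),
                               matrix(1, 8, 8)), "positive definite")
  expect_error(pgls_fit(ltm ~ 1, d$tab, tree = NULL, V = NULL), "supply")
  expect_error(anova(pgls_fit(ltm ~ 1, d$tab, V = d$V)), "intercept-only")
})

test_that("null-model intercept is the precision-weighted GLS mean", {
  d <- study_data()
  # exactly the V^-1-weighted mean at any lambda
  for (lam in c(0, 0.7)) {
    f <- pgls_fit(ltm ~ 1, d$tab, V = d$V, lambda = lam)
    W <- solve(lambda_transform(d$V, lam))
    expect_equal(unname(coef(f))[1],
                 sum(W %*% d$tab$ltm) / sum(W), tolerance = 1e-9)
  }
  # on an ultrametric tree, lambda = 0 collapses to the arithmetic mean
  set.seed(71)
  tr <- ape::rcoal(9)
  dd <- data.frame(species = tr$tip.label, y = rnorm(9))
  f0 <- pgls_fit(y ~ 1, dd, tree = tr, lambda = 0)
  expect_equal(unname(coef(f0))[1], mean(dd$y), tolerance = 1e-10)
})

test_that("fits serialize to JSON with stable names", {
  d <- study_data()
  f <- pgls_fit(ltm ~ pol, d$tab, V = d$V)
  js <- jsonlite::fromJSON(pgls_to_json(f))
  expect_equal(js$lambda, f$lambda)
  expect_equal(js$coefficients$pol, unname(coef(f)["pol"]))
  expect_equal(js$anova$F, f$anova$F)
})
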
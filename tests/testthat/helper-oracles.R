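# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the code paths they check: the VCV oracle
# enumerates root-to-tip node paths instead of calling ape::vcv.phylo,
# and the likelihood oracle evaluates the dense multivariate-normal
# density with solve()/determinant() instead of Cholesky whitening.

# Shared path length between every pair of tips by brute-force node-path
# enumeration: entry (i, j) is the depth of the most recent common
# ancestor, where depth is the summed branch length from the root.
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  elen <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  ancestors <- function(node) {       # node itself up to the root
    path <- node
    while (node != root) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  }
  depth <- function(node) {
    s <- 0
    while (node != root) {
      s <- s + elen[node]
      node <- parent[node]
    }
    s
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      common <- intersect(ancestors(i), ancestors(j))
      V[i, j] <- max(vapply(common, depth, numeric(1)))
    }
  }
  V
}

# Dense MVN log-density of y given mean X beta and covariance sigma2 * V.
dense_mvn_loglik <- function(y, X, beta, sigma2, V) {
  n <- length(y)
  S <- sigma2 * V
  r <- y - drop(as.matrix(X) %*% beta)
  -0.5 * (n * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(crossprod(r, solve(S, r))))
}

# The eight-species dataset with analysis columns, and its covariance.
study_data <- function() {
  tab <- log10_traits(vrech2014_traits())
  list(tab = tab,
       tree = default_cladogram(),
       V = phylo_vcv(default_cladogram(), tip_order = tab$species))
}

# A balanced 64-tip tree with unit branch lengths (punctuated clock).
balanced_tree64 <- function() {
  tr <- ape::stree(64, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# Random instance generator for optimizer/oracle comparisons.
random_pgls_instance <- function(n_tips = 12, seed = 1) {
  set.seed(seed)
  tr <- ape::rcoal(n_tips)
  V <- phylo_vcv(tr)
  X <- cbind(1, stats::rnorm(n_tips))
  lam <- stats::runif(1)
  y <- drop(simulate_traits(X = X, beta = c(1, 0.5), sigma2 = 0.2,
                            lambda = lam, V = V))
  list(y = y, X = X, V = V, lambda_true = lam)
}
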
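#' Simulate species traits under the pGLS generative model
#'
#' Draws replicate response vectors `y = X beta + e` with
#' `e ~ MVN(0, sigma2 * V(lambda))`, the model the regression assumes:
#' Brownian-motion evolution on the tree, attenuated by Pagel's lambda.
#' Noise is generated through the Cholesky factor of the transformed
#' covariance, so a fixed seed gives bit-identical output.
#'
#' @param X design matrix (n species x k columns, intercept included),
#'   or `NULL` for an intercept-only design.
#' @param beta true coefficient vector, length `ncol(X)`.
#' @param sigma2 true residual (Brownian rate) variance, `>= 0`.
#' @param lambda true Pagel's lambda in `[0, 1]`.
#' @param tree phylogeny (used when `V` is `NULL`).
#' @param V phylogenetic covariance at lambda = 1; overrides `tree`.
#' @param nsim number of replicate response vectors.
#' @param seed optional RNG seed set before drawing.
#' @return an n x `nsim` matrix; row names are the tip order of `V`.
#' @export
simulate_traits <- function(X = NULL, beta, sigma2, lambda,
                            tree = NULL, V = NULL, nsim = 1,
                            seed = NULL) {
  if (is.null(V)) {
    if (is.null(tree)) stop("supply 'tree' or 'V'", call. = FALSE)
    V <- phylo_vcv(tree)
  }
  n <- nrow(V)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and V disagree on n", call. = FALSE)
  if (length(beta) != ncol(X)) {
    stop("beta length must match ncol(X)", call. = FALSE)
  }
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- drop(X %*% beta)
  if (sigma2 == 0) {
    out <- matrix(mu, n, nsim)
  } else {
    W <- lambda_transform(V, lambda)
    L <- tryCatch(chol(W), error = function(e) {
      stop("lambda-transformed covariance is not positive definite",
           call. = FALSE)
    })
    Z <- matrix(stats::rnorm(n * nsim), n, nsim)
    out <- mu + sqrt(sigma2) * crossprod(L, Z)
  }
  rownames(out) <- rownames(V)
  out
}

# Moment-matched lognormal sampler: draws have arithmetic mean `mean`
# and SD `sd` (sd = 0 degenerates to the constant mean).  Lognormal is
# used because the traits are strictly positive and several Table-level
# SDs are comparable to their means, where normal draws would go
# negative.
rlnorm_match <- function(n, mean, sd) {
  if (mean <= 0) stop("lognormal target mean must be positive",
                      call. = FALSE)
  if (sd < 0) stop("negative SD", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2,
                sdlog = sqrt(sdlog2))
}

# Stable per-species RNG stream seed: a small polynomial hash of the
# species name folded into the root seed, so adding or removing one
# species never perturbs the draws of the others.
species_seed <- function(root_seed, species) {
  h <- 0
  for (cp in utf8ToInt(normalize_species(species))) {
    h <- (h * 31 + cp) %% 2147483563
  }
  as.integer((root_seed + h) %% 2147483563)
}

#' Simulate the individual-level sampling design of the study
#'
#' Emulates the dissection study bottom-up for each species of a target
#' (Table-1-like) trait table: `n_males` males per species with body
#' mass and testes mass drawn lognormally around the species means with
#' the species SDs; per male, `n_packages` sperm-package lengths (the
#' male's mean package length is drawn around the species mean with the
#' species SD, and packages scatter around it with coefficient of
#' variation `within_male_cv`); and 1-3 spermatophores per species,
#' each realized as a (trunk area, trunk width) pair whose product is a
#' lognormal draw around the species' target volume.  The species-level
#' table is then derived by the same averaging chain the study uses:
#' package -> male mean -> species mean, and GSI as the species mean of
#' per-individual GSI values (which differs from the ratio of species
#' means whenever individual SDs are positive).
#'
#' Each species has its own RNG stream derived from `seed` by a stable
#' hash of its name, so the draws for one species do not depend on
#' which other species are present.
#'
#' @param targets a `trait_table` of target species means/SDs (the SD
#'   and `n_males` columns are used when present; missing SDs default
#'   to 0, missing `n_males` to draws from 6-19).
#' @param n_males optional integer vector overriding per-species male
#'   counts.
#' @param n_packages sperm packages measured per male.
#' @param n_spermatophores optional integer vector of per-species
#'   spermatophore counts; default draws 1-3.
#' @param within_male_cv coefficient of variation of package lengths
#'   within a male, and of spermatophore volumes around the species
#'   target.
#' @param seed root RNG seed (fixed seed, bit-identical study).
#' @return object of class `synthetic_study`: list with data.frames
#'   `individuals` (one row per male: masses, mean package length,
#'   GSI), `packages` (one row per package), `spermatophores` (one row
#'   per spermatophore: area, width, volume), the derived `traits`
#'   table (with `gsi_individual`, the per-individual averaged GSI, and
#'   `gsi_mean_ratio`), and `config`.
#' @export
simulate_study <- function(targets, n_males = NULL, n_packages = 10,
                           n_spermatophores = NULL, within_male_cv = 0.05,
                           seed = 1) {
  targets <- as_trait_table(targets)
  if (within_male_cv < 0) stop("negative within_male_cv", call. = FALSE)
  ns <- nrow(targets)
  sd0 <- function(col) {
    if (col %in% names(targets)) targets[[col]] else rep(0, ns)
  }
  bm_sd <- sd0("body_mass_sd"); tm_sd <- sd0("testes_mass_sd")
  sl_sd <- sd0("sperm_length_sd")
  if (any(c(bm_sd, tm_sd, sl_sd) < 0)) {
    stop("negative target SD", call. = FALSE)
  }

  ind <- pkg <- spt <- list()
  derived <- targets[, "species", drop = FALSE]
  for (i in seq_len(ns)) {
    sp <- targets$species[i]
    set.seed(species_seed(seed, sp))
    nm <- if (!is.null(n_males)) n_males[min(i, length(n_males))]
          else if ("n_males" %in% names(targets)) targets$n_males[i]
          else sample(6:19, 1)
    nsp <- if (!is.null(n_spermatophores)) {
      n_spermatophores[min(i, length(n_spermatophores))]
    } else sample(1:3, 1)

    bm <- rlnorm_match(nm, targets$body_mass_g[i], bm_sd[i])
    tm <- rlnorm_match(nm, targets$testes_mass_mg[i], tm_sd[i])
    male_mu <- rlnorm_match(nm, targets$sperm_length_um[i], sl_sd[i])
    sl_mean <- numeric(nm)
    for (j in seq_len(nm)) {
      lens <- rlnorm_match(n_packages, male_mu[j],
                           within_male_cv * male_mu[j])
      sl_mean[j] <- mean(lens)
      pkg[[length(pkg) + 1L]] <- data.frame(
        species = sp, male = j, package = seq_len(n_packages),
        length_um = lens, stringsAsFactors = FALSE)
    }
    vol <- rlnorm_match(nsp, targets$spermatophore_volume_mm3[i],
                        within_male_cv *
                          targets$spermatophore_volume_mm3[i])
    width <- vol^(1 / 3)
    spt[[length(spt) + 1L]] <- data.frame(
      species = sp, spermatophore = seq_len(nsp),
      trunk_area_mm2 = vol / width, trunk_width_mm = width,
      volume_mm3 = vol, stringsAsFactors = FALSE)
    ind[[length(ind) + 1L]] <- data.frame(
      species = sp, male = seq_len(nm), body_mass_g = bm,
      testes_mass_mg = tm, sperm_length_um = sl_mean,
      gsi = gsi(bm, tm), stringsAsFactors = FALSE)

    derived$body_mass_g[i] <- mean(bm)
    derived$body_mass_sd[i] <- stats::sd(bm)
    derived$n_males[i] <- nm
    derived$testes_mass_mg[i] <- mean(tm)
    derived$testes_mass_sd[i] <- stats::sd(tm)
    derived$spermatophore_volume_mm3[i] <- mean(
      spermatophore_volume(spt[[i]]$trunk_area_mm2,
                           spt[[i]]$trunk_width_mm))
    derived$sperm_length_um[i] <- mean(sl_mean)
    derived$sperm_length_sd[i] <- stats::sd(sl_mean)
    derived$polyandry[i] <- targets$polyandry[i]
    derived$gsi_individual[i] <- mean(gsi(bm, tm))
    derived$gsi_mean_ratio[i] <- gsi(mean(bm), mean(tm))
  }
  structure(list(individuals = do.call(rbind, ind),
                 packages = do.call(rbind, pkg),
                 spermatophores = do.call(rbind, spt),
                 traits = as_trait_table(derived),
                 config = list(seed = seed, n_packages = n_packages,
                               within_male_cv = within_male_cv)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic comparative study:", nrow(x$traits), "species,",
      nrow(x$individuals), "males,", nrow(x$packages),
      "sperm packages (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic study to CSV files
#'
#' Emits the derived species table in the trait CSV schema (readable by
#' [read_trait_table()]), the per-individual table, and a JSON manifest
#' recording the seed and configuration.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traits <- study$traits[, c(trait_schema$required, trait_schema$optional)]
  p1 <- file.path(dir, "traits.csv")
  utils::write.csv(traits, p1, row.names = FALSE, quote = FALSE)
  p2 <- file.path(dir, "individuals.csv")
  utils::write.csv(study$individuals, p2, row.names = FALSE, quote = FALSE)
  p3 <- file.path(dir, "manifest.json")
  jsonlite::write_json(study$config, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(traits = p1, individuals = p2, manifest = p3))
}
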
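#' Read a Newick tree, filling in missing branch lengths
#'
#' Parses a Newick string or file via [ape::read.tree()].  Branches
#' without a stated length (and branches with `NA` length) are set to 1,
#' the "equal branch lengths" convention of a punctuated-evolution
#' cladogram in which change is proportional to cladogenesis events.
#'
#' @param text Newick string (used when `file` is `NULL`).
#' @param file path to a Newick file.
#' @return an [ape::phylo] tree with complete branch lengths.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (is.null(file)) {
    if (!is.character(text) || length(text) != 1L) {
      stop("'text' must be a single Newick string", call. = FALSE)
    }
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ",
                                      conditionMessage(e), call. = FALSE))
  } else {
    ape::read.tree(file = file)
  }
  if (is.null(tr)) stop("Newick parse error: empty or malformed string",
                        call. = FALSE)
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  validate_phylogeny(tr)
}

#' Write a tree as a Newick string
#'
#' @param tree an [ape::phylo] tree.
#' @param file optional path; if `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else invisible(ape::write.tree(tree, file = file))
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (length(tree$tip.label) < 2L) {
    stop("a phylogeny needs at least 2 tips", call. = FALSE)
  }
  if (anyDuplicated(normalize_species(tree$tip.label))) {
    stop("duplicate tip labels", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  tree
}

#' Default cladogram for the eight bothriurid study species
#'
#' The working phylogenetic hypothesis used by the study: congeners form
#' clades (*Bothriurus*: bonariensis, cordubensis, rochensis, as a
#' polytomy; *Brachistosternus*: ferrugineus, pentheri; *Timogenes*:
#' dorbignyi, elegans; plus *Urophonius brachycentrus*), arranged
#' above the genus level as
#' `((Bothriurus, Brachistosternus), (Timogenes, Urophonius))`,
#' with every branch length equal to 1 (punctuated model).  The
#' above-genus arrangement is an overridable assumption: supply your own
#' Newick via [read_newick()] to change it.
#'
#' @return an [ape::phylo] tree with 8 tips matching the species of
#'   [vrech2014_traits()].
#' @export
default_cladogram <- function() {
  read_newick(file = system.file("extdata", "bothriuridae_cladogram.nwk",
                                 package = "scorpallo", mustWork = TRUE))
}

#' Phylogenetic variance-covariance matrix of a tree
#'
#' Entry (i, j) is the total branch length shared by tips i and j, i.e.
#' the path length from the root to their most recent common ancestor;
#' the diagonal holds each tip's root-to-tip distance.  Under Brownian
#' motion this matrix (times the rate) is the trait covariance across
#' species.  Computation is delegated to [ape::vcv.phylo()]; rows and
#' columns are reordered to `tip_order` after species-name
#' normalization.
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_order optional character vector, a permutation of the tip
#'   labels (underscores and spaces interchangeable), giving the desired
#'   row/column order, e.g. the row order of a trait table.
#' @return an n x n symmetric matrix with normalized species names as
#'   dimnames.
#' @export
phylo_vcv <- function(tree, tip_order = NULL) {
  tree <- validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  nm <- normalize_species(rownames(V))
  rownames(V) <- colnames(V) <- nm
  if (!is.null(tip_order)) {
    tip_order <- normalize_species(tip_order)
    unknown <- setdiff(tip_order, nm)
    missing <- setdiff(nm, tip_order)
    if (length(unknown) || length(missing)) {
      stop("tip_order does not match the tree's tips.",
           if (length(unknown)) paste0(" Not in tree: ",
                                       paste(unknown, collapse = ", "), "."),
           if (length(missing)) paste0(" Not requested: ",
                                       paste(missing, collapse = ", "), "."),
           call. = FALSE)
    }
    V <- V[tip_order, tip_order]
  }
  V
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of `V` by `lambda`, leaving the
#' diagonal untouched: `V(lambda) = lambda * V + (1 - lambda) * diag(V)`.
#' `lambda = 1` keeps the full Brownian-motion covariance; `lambda = 0`
#' removes all phylogenetic covariance, so species are independent with
#' their root-to-tip variances.
#'
#' @param V phylogenetic covariance matrix from [phylo_vcv()].
#' @param lambda scalar in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      is.na(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}
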
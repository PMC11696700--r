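# align a trait matrix/vector to the tree's tip order, by label
alignTraits <- function(tree, traits) {
  if (is.null(dim(traits)))
    traits <- matrix(traits, ncol = 1,
                     dimnames = list(names(traits), "trait1"))
  if (is.null(rownames(traits)))
    stop("trait rows must be labeled with tip names")
  miss <- setdiff(tree$tip.label, rownames(traits))
  extra <- setdiff(rownames(traits), tree$tip.label)
  if (length(miss) || length(extra))
    stop("trait labels do not match the tree",
         if (length(miss)) paste0("; missing: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")))
  traits[tree$tip.label, , drop = FALSE]
}

#' Phylogenetic independent contrasts
#'
#' Standardized contrasts by Felsenstein's pruning algorithm, computed per
#' trait column on the given tree: at each internal node joining children
#' with (extended) branch lengths `b_i`, `b_j`, the contrast is
#' `(x_i - x_j) / sqrt(b_i + b_j)`, the node is assigned the weighted value
#' `(x_i/b_i + x_j/b_j) / (1/b_i + 1/b_j)`, and its parent branch is
#' extended by `b_i b_j / (b_i + b_j)`. Under Brownian motion on the true
#' tree the contrasts are iid `N(0, sigma2)`.
#'
#' @param tree a fully bifurcating `"phylo"` object.
#' @param traits tips-by-traits matrix (or named vector), rows labeled with
#'   tip names.
#' @return `(n_tips - 1) x p` matrix of contrasts, rows named by the
#'   internal node number each contrast belongs to.
#' @export
computePIC <- function(tree, traits) {
  validateTree(tree)
  nkids <- tabulate(tree$edge[, 1])
  if (tree$Nnode != ape::Ntip(tree) - 1L || any(nkids[nkids > 0] != 2L))
    stop("tree has polytomies; resolve them (e.g. randomly, with ",
         "ape::multi2di) before computing contrasts")
  Y <- alignTraits(tree, traits)
  cols <- lapply(seq_len(ncol(Y)), function(j)
    ape::pic(stats::setNames(Y[, j], rownames(Y)), tree))
  out <- do.call(cbind, cols)
  dimnames(out) <- list(names(cols[[1]]), colnames(Y))
  if (any(!is.finite(out)))
    stop("non-finite contrasts: a sibling branch pair has zero total ",
         "length (b_i + b_j = 0)")
  out
}

#' Contrasts on the unit-depth tree
#'
#' [computePIC()] after rescaling the tree to depth 1; contrasts from the
#' depth-`T` tree equal `sqrt(T)` times these.
#'
#' @inheritParams computePIC
#' @return as [computePIC()].
#' @export
computePICUnitDepth <- function(tree, traits) {
  computePIC(scaleTreeDepth(tree, 1), traits)
}

#' PGLS whitening of trait data
#'
#' Left-multiplies the trait matrix by the inverse lower Cholesky factor of
#' the tree's phylogenetic covariance, removing the phylogenetic correlation
#' structure: under Brownian motion with `z0 = 0` the whitened values have
#' covariance `sigma2 * I`. No root-state centering is applied by default;
#' `center = TRUE` first subtracts the GLS estimate of the root state per
#' trait. The transform is not idempotent: applying it twice whitens with
#' the same factor again and does not return the identity covariance.
#'
#' @inheritParams computePIC
#' @param center subtract the GLS root-state estimate first (default
#'   `FALSE`).
#' @return matrix of the same shape as `traits`, rows in tree tip order.
#' @export
pglsWhiten <- function(tree, traits, center = FALSE) {
  validateTree(tree)
  Y <- alignTraits(tree, traits)
  C <- phyloVCV(tree)
  L <- cholJitter(C)
  if (center) {
    one <- rep(1, nrow(Y))
    u1 <- forwardsolve(L, one)
    z0 <- as.vector(crossprod(u1, forwardsolve(L, Y))) / sum(u1^2)
    Y <- Y - rep(z0, each = nrow(Y))
  }
  W <- forwardsolve(L, Y)
  dimnames(W) <- dimnames(Y)
  W
}
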
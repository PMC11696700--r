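#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin, strict wrapper around [ape::read.tree()]. The tree must be rooted,
#' have at least two tips, unique non-empty tip labels, and a finite
#' non-negative branch length on every non-root edge. A root edge, if present
#' in the string, is dropped with a warning: all downstream covariance
#' computations are defined from the root node, so time "below" the root has
#' no effect on tip distributions.
#'
#' @param text a Newick string (with terminating semicolon).
#' @param file alternatively, path to a file containing one Newick tree.
#' @return an object of class `"phylo"` (ape), guaranteed valid in the above
#'   sense. Tip order is ape's order, i.e. first-encounter order in the
#'   string.
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("supply either 'text' or 'file'")
  if (is.null(text)) {
    if (!file.exists(file)) stop("Newick file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stopifnot(is.character(text), length(text) == 1L)
  # locate unbalanced parentheses ourselves so the error can name a position
  bare <- gsub("\\[[^]]*\\]", "", text)   # strip [] comments
  chars <- strsplit(bare, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character ",
         length(chars))
  tree <- tryCatch(ape::read.tree(text = bare),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: could not parse tree")
  if (!is.null(tree$root.edge)) {
    warning("root edge of length ", tree$root.edge,
            " ignored; covariances are defined from the root node")
    tree$root.edge <- NULL
  }
  validateTree(tree)
}

#' Write a phylogeny as a Newick string
#'
#' Inverse of [readNewick()]; branch lengths are printed with enough digits
#' (15 significant) that a read/write round trip preserves them to well below
#' 1e-10 relative error.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; if given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
writeNewick <- function(tree, file = NULL) {
  validateTree(tree)
  txt <- ape::write.tree(tree, digits = 15)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Full structural validation used by every entry point that accepts a tree.
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; every non-root edge needs one")
  if (anyNA(tree$edge.length))
    stop("missing branch length on ", sum(is.na(tree$edge.length)),
         " edge(s); no silent default is applied")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  # structural rootedness: exactly one parentless node, one parent each
  # (a basal polytomy, e.g. a star tree, still has a well-defined root)
  kids <- tree$edge[, 2]
  nn <- ape::Ntip(tree) + tree$Nnode
  if (anyDuplicated(kids) || length(setdiff(seq_len(nn), kids)) != 1L)
    stop("tree must have exactly one root and one parent per node")
  tree
}

#' Node heights (time from the root)
#'
#' @param tree a `"phylo"` object.
#' @return numeric vector of length `Ntip + Nnode`: for node `i` the sum of
#'   branch lengths on the root-to-`i` path. The root has height 0.
#' @export
nodeHeights <- function(tree) {
  validateTree(tree)
  ape::node.depth.edgelength(tree)
}

#' Tree depth
#'
#' Maximum tip height (time from root to the farthest tip).
#' @param tree a `"phylo"` object.
#' @return a single number.
#' @export
treeDepth <- function(tree) max(nodeHeights(tree)[seq_len(ape::Ntip(tree))])

#' Phylogenetic variance-covariance matrix of a tree
#'
#' Entry (i, j) is the height of the most recent common ancestor of tips i
#' and j -- the length of their shared root-to-tip path -- and the diagonal
#' holds tip heights. Under Brownian motion with rate `sigma2`, tip trait
#' values are multivariate normal with covariance `sigma2 * phyloVCV(tree)`.
#'
#' @param tree a `"phylo"` object.
#' @return a symmetric positive semidefinite matrix with tip labels as
#'   dimnames, rows/columns in the tree's tip order.
#' @export
phyloVCV <- function(tree) {
  validateTree(tree)
  h <- ape::node.depth.edgelength(tree)
  idx <- ape::mrca(tree)            # tip x tip matrix of MRCA node numbers
  C <- matrix(h[idx], nrow(idx), ncol(idx), dimnames = dimnames(idx))
  # diagonal of mrca() is the tip itself, so diag(C) is already tip heights
  C
}

#' Rescale a tree to a target depth
#'
#' Multiplies every branch length by `target_depth / treeDepth(tree)` so the
#' deepest tip sits at exactly `target_depth`.
#'
#' @param tree a `"phylo"` object with depth > 0.
#' @param target_depth positive number, the desired root-to-deepest-tip time.
#' @return the rescaled `"phylo"` object.
#' @export
scaleTreeDepth <- function(tree, target_depth) {
  validateTree(tree)
  if (!is.numeric(target_depth) || length(target_depth) != 1L ||
      !is.finite(target_depth) || target_depth <= 0)
    stop("target_depth must be a single positive number")
  d <- treeDepth(tree)
  if (d <= 0) stop("tree has zero depth; cannot rescale")
  tree$edge.length <- tree$edge.length * (target_depth / d)
  tree
}

#' Is a tree ultrametric?
#'
#' All tip heights equal within `rel_tol * treeDepth(tree)`. This is the
#' gate used before Ornstein-Uhlenbeck transforms, which assume
#' contemporaneous tips.
#'
#' @param tree a `"phylo"` object.
#' @param rel_tol relative tolerance (default 1e-6).
#' @return `TRUE` or `FALSE`.
#' @export
isUltrametric <- function(tree, rel_tol = 1e-6) {
  validateTree(tree)
  h <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(h) - min(h)) <= rel_tol * max(h)
}
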
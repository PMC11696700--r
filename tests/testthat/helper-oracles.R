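# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: heights are summed along explicit node paths and
# MRCAs found by path intersection.

# height of one node as the sum of branch lengths on its root path
pathHeight <- function(tree, node) {
  root <- ape::Ntip(tree) + 1L
  if (node == root) return(0)
  p <- ape::nodepath(tree, root, node)
  sum(tree$edge.length[match(p[-1], tree$edge[, 2])])
}

# brute-force phylogenetic VCV: pairwise MRCA by root-path intersection
bruteVCV <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  paths <- lapply(seq_len(n), function(i) ape::nodepath(tree, root, i))
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      # the MRCA is the highest (deepest) node shared by both root paths
      shared <- intersect(paths[[i]], paths[[j]])
      hts <- vapply(shared, function(v) pathHeight(tree, v), 0)
      C[i, j] <- C[j, i] <- max(hts)
    }
  }
  C
}

# recursive Felsenstein pruning, independent of ape::pic
picOracle <- function(tree, x) {
  x <- x[tree$tip.label]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- function(node) tree$edge.length[match(node, tree$edge[, 2])]
  contrasts <- c()
  rec <- function(node) {           # returns c(value, extra branch length)
    if (node <= ape::Ntip(tree)) return(c(x[node], blen(node)))
    ch <- kids[[as.character(node)]]
    stopifnot(length(ch) == 2L)
    a <- rec(ch[1]); b <- rec(ch[2])
    contrasts <<- c(contrasts, (a[1] - b[1]) / sqrt(a[2] + b[2]))
    v <- (a[1] / a[2] + b[1] / b[2]) / (1 / a[2] + 1 / b[2])
    bl <- blen(node)
    c(v, (if (is.na(bl)) 0 else bl) + a[2] * b[2] / (a[2] + b[2]))
  }
  rec(ape::Ntip(tree) + 1L)
  contrasts
}

# random test trees: ultrametric Yule, optionally made non-ultrametric by
# jittering pendant edges
randomTree <- function(n, seed, ultrametric = TRUE) {
  tr <- yuleTree(n, 1, seed = seed)
  if (!ultrametric) {
    set.seed(seed + 1000)
    pend <- tr$edge[, 2] <= ape::Ntip(tr)
    tr$edge.length[pend] <- tr$edge.length[pend] * runif(sum(pend), 0.3, 1.7)
  }
  tr
}

# direct dense-matrix MVN log-density (solve(), no Cholesky): the
# independent likelihood path
denseMVNloglik <- function(V, y, mu) {
  n <- length(y)
  r <- y - mu
  -n / 2 * log(2 * pi) - 0.5 * determinant(V)$modulus[1] -
    0.5 * sum(r * solve(V, r))
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol * max(1, max(abs(b))))
}
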
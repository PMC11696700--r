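#' Primary model names
#'
#' The eleven primary models of trait evolution supported by the simulator,
#' each expressible as a deterministic transformation of the phylogeny (or,
#' for white noise, of the covariance matrix directly).
#'
#' @return character vector of length 11.
#' @export
primaryModels <- function() {
  c("BM", "OU", "EB", "lambda", "delta", "kappa", "trend",
    "white", "depth", "lrates", "nrates")
}

#' Stacking modes
#'
#' @return character vector of the four stacking options: the primary model
#'   alone, local clade rates, ancestral mean shifts, or both overlays.
#' @export
stackingModes <- function() {
  c("standard", "lrates", "AncShifts", "lrates+AncShifts")
}

#' The full model catalog
#'
#' Crosses the eleven primary models with the four stacking options,
#' yielding the 44 model combinations available for simulation.
#'
#' @return a data frame with columns `primary` and `stacking`, one row per
#'   combination.
#' @export
modelCatalog <- function() {
  cat <- expand.grid(primary = primaryModels(), stacking = stackingModes(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cat[order(match(cat$primary, primaryModels()),
            match(cat$stacking, stackingModes())), , drop = FALSE]
}

# which shape parameter each model requires (beyond z0, sigma2)
.modelShapeParam <- c(BM = NA, OU = "alpha", EB = "a", lambda = "lambda",
                      delta = "delta", kappa = "kappa", trend = "slope",
                      white = NA, depth = "depth", lrates = "rates",
                      nrates = "intervals")

#' Specify a primary evolutionary model
#'
#' Bundles a model name with its parameters. Exactly the parameters the
#' model requires must be supplied:
#' \describe{
#'   \item{BM, white}{none beyond `z0`, `sigma2`}
#'   \item{OU}{`alpha` > 0, strength of attraction toward the optimum}
#'   \item{EB}{`a` != 0, exponential rate-change constant (negative = decay)}
#'   \item{lambda}{`lambda` in \[0, 1\], phylogenetic-signal scaling}
#'   \item{delta}{`delta` > 0, node-height power (time-dependent rates)}
#'   \item{kappa}{`kappa` in \[0, 1\], per-branch length power}
#'   \item{trend}{`slope`, linear change of the diffusion rate over time}
#'   \item{depth}{`depth` > 0, target tree depth}
#'   \item{lrates}{`rates`: data frame with columns `tips` (list of tip-label
#'     vectors anchoring each clade by its MRCA) and `rate` (> 0)}
#'   \item{nrates}{`intervals`: data frame with columns `start`, `end`,
#'     `rate` (> 0); non-overlapping \[start, end) time intervals}
#' }
#' `sigma2` never enters the branch-length transform itself; it multiplies
#' the covariance once, at simulation or likelihood-evaluation time.
#'
#' @param model one of [primaryModels()].
#' @param z0 trait value at the root (default 0).
#' @param sigma2 rate of evolution, variance per unit time (default 1).
#' @param ... the model's shape parameter, named as above.
#' @return an object of class `"modelSpec"`.
#' @export
modelSpec <- function(model, z0 = 0, sigma2 = 1, ...) {
  model <- match.arg(model, primaryModels())
  extra <- list(...)
  need <- .modelShapeParam[[model]]
  if (is.na(need)) {
    if (length(extra))
      stop("model '", model, "' takes no shape parameter; got: ",
           paste(names(extra), collapse = ", "))
  } else {
    if (!identical(names(extra), need))
      stop("model '", model, "' requires exactly parameter '", need,
           "'; got: ", paste(names(extra), collapse = ", "))
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    stop("sigma2 must be a single positive number")
  if (!is.numeric(z0) || length(z0) != 1L || !is.finite(z0))
    stop("z0 must be a single finite number")
  spec <- c(list(model = model, z0 = z0, sigma2 = sigma2), extra)
  if (model == "OU" && (!is.finite(spec$alpha) || spec$alpha <= 0))
    stop("alpha must be > 0")
  if (model == "EB" && (!is.finite(spec$a) || spec$a == 0))
    stop("a must be nonzero (use BM for a = 0)")
  if (model == "lambda" && (spec$lambda < 0 || spec$lambda > 1))
    stop("lambda must lie in [0, 1]")
  if (model == "delta" && (!is.finite(spec$delta) || spec$delta <= 0))
    stop("delta must be > 0")
  if (model == "kappa" && (spec$kappa < 0 || spec$kappa > 1))
    stop("kappa must lie in [0, 1]")
  if (model == "trend" && !is.finite(spec$slope))
    stop("slope must be finite")
  if (model == "depth" && (!is.finite(spec$depth) || spec$depth <= 0))
    stop("depth must be > 0")
  if (model == "lrates") spec$rates <- .checkRateTable(spec$rates)
  if (model == "nrates") spec$intervals <- .checkIntervalTable(spec$intervals)
  structure(spec, class = "modelSpec")
}

#' @export
print.modelSpec <- function(x, ...) {
  shape <- .modelShapeParam[[x$model]]
  cat("Trait-evolution model: ", x$model,
      "  (z0 = ", format(x$z0), ", sigma2 = ", format(x$sigma2), ")\n",
      sep = "")
  if (!is.na(shape) && !shape %in% c("rates", "intervals"))
    cat("  ", shape, " = ", format(x[[shape]]), "\n", sep = "")
  if (identical(shape, "rates"))
    cat("  ", nrow(x$rates), " clade rate shift(s)\n", sep = "")
  if (identical(shape, "intervals"))
    cat("  ", nrow(x$intervals), " interval rate shift(s)\n", sep = "")
  invisible(x)
}

.checkRateTable <- function(rates) {
  if (!is.data.frame(rates) || !all(c("tips", "rate") %in% names(rates)))
    stop("'rates' must be a data frame with columns 'tips' and 'rate'")
  if (!is.list(rates$tips)) rates$tips <- as.list(rates$tips)
  if (any(!is.finite(rates$rate)) || any(rates$rate <= 0))
    stop("rate multipliers must be finite and > 0")
  rates
}

.checkIntervalTable <- function(iv) {
  if (!is.data.frame(iv) || !all(c("start", "end", "rate") %in% names(iv)))
    stop("'intervals' must be a data frame with columns 'start', 'end', 'rate'")
  if (any(!is.finite(iv$rate)) || any(iv$rate <= 0))
    stop("rate multipliers must be finite and > 0")
  if (any(iv$end <= iv$start)) stop("intervals must have end > start")
  if (nrow(iv) > 1L) {
    o <- order(iv$start)
    if (any(iv$start[o][-1] < iv$end[o][-nrow(iv)]))
      stop("intervals overlap")
  }
  iv
}

# ---------------------------------------------------------------------------
# Height maps.
#
# Several transforms act through a monotone map g of node heights:
# the transformed length of a branch spanning heights [t1, t2] is
# g(t2) - g(t1), and the transformed VCV is g applied elementwise to the
# MRCA-height matrix. lambda, kappa and lrates are edge-wise rescalings with
# no such global map and return NULL here.
heightMap <- function(spec, T) {
  switch(spec$model,
    BM = , white = identity,
    depth = { f <- spec$depth / T; function(t) f * t },
    delta = { d <- spec$delta; function(t) t^d },
    EB = { a <- spec$a; function(t) expm1(a * t) / a },
    OU = {
      al <- spec$alpha
      if (2 * al * T > 700)
        stop("alpha too large: exp(2*alpha*T) overflows; ",
             "use alpha < ", format(350 / T))
      function(t) exp(-2 * al * T) * expm1(2 * al * t) / (2 * al)
    },
    trend = {
      s <- spec$slope
      function(t) {
        if (s >= 0) return(t + s * t^2 / 2)
        tstar <- -1 / s                      # where the rate floor bites
        tt <- pmin(t, tstar)
        tt + s * tt^2 / 2
      }
    },
    NULL)
}

# 0/1 matrix with one row per node, one column per edge; entry 1 when the
# edge lies on the root-to-node path. Node heights = incidence %*% edge.length.
rootPathIncidence <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  E <- nrow(tree$edge)
  A <- matrix(0, nn, E)
  done <- rep(FALSE, E)
  ready <- rep(FALSE, nn)
  ready[ape::Ntip(tree) + 1L] <- TRUE           # root
  while (!all(done)) {
    todo <- which(!done & ready[tree$edge[, 1]])
    if (!length(todo)) stop("edges do not form a single rooted tree")
    for (e in todo) {
      A[tree$edge[e, 2], ] <- A[tree$edge[e, 1], ]
      A[tree$edge[e, 2], e] <- 1
      ready[tree$edge[e, 2]] <- TRUE
      done[e] <- TRUE
    }
  }
  A
}

# heights of parent (t1) and child (t2) node of every edge
edgeSpans <- function(tree) {
  h <- ape::node.depth.edgelength(tree)
  cbind(t1 = h[tree$edge[, 1]], t2 = h[tree$edge[, 2]])
}

# ---------------------------------------------------------------------------
# Tree-space transforms

#' Rescale a phylogeny under a primary evolutionary model
#'
#' Applies the branch-length transformation that realises a model as
#' "Brownian motion on a deformed tree": simulating BM on the returned tree
#' (times `sigma2`) is equivalent to simulating the named model on the input
#' tree. BM is the identity; white noise has no tree representation and is
#' rejected here (see [whiteNoiseVCV()]).
#'
#' Conventions: delta acts on node heights with no post-hoc depth rescaling;
#' OU is the root-fixed process and requires an ultrametric tree; the trend
#' model floors the time-varying rate at zero (with a warning when the floor
#' activates); kappa maps zero-length branches to zero.
#'
#' @param tree a `"phylo"` object.
#' @param spec a [modelSpec()].
#' @return the transformed `"phylo"` object (same topology and tip labels).
#' @export
rescaleTree <- function(tree, spec) {
  validateTree(tree)
  stopifnot(inherits(spec, "modelSpec"))
  model <- spec$model
  if (model == "white")
    stop("white noise has no tree representation; use whiteNoiseVCV()")
  if (model == "BM") return(tree)
  if (model == "lambda") return(.lambdaTree(tree, spec$lambda))
  if (model == "kappa") {
    el <- tree$edge.length
    out <- ifelse(el == 0, 0, el^spec$kappa)   # 0^0 := 0 (zero stays zero)
    tree$edge.length <- out
    return(tree)
  }
  if (model == "depth") return(scaleTreeDepth(tree, spec$depth))
  if (model == "lrates") return(applyLocalRates(tree, spec$rates))
  if (model == "nrates") return(applyIntervalRates(tree, spec$intervals))
  T <- treeDepth(tree)
  if (model == "OU" && !isUltrametric(tree))
    stop("OU transform requires an ultrametric tree (contemporaneous tips)")
  if (model == "trend" && spec$slope < 0 && -1 / spec$slope < T)
    warning("trend rate floor active: rate reaches 0 at t = ",
            format(-1 / spec$slope), " inside tree depth ", format(T))
  g <- heightMap(spec, T)
  sp <- edgeSpans(tree)
  tree$edge.length <- g(sp[, "t2"]) - g(sp[, "t1"])
  # guard tiny negative round-off on monotone maps
  tree$edge.length[tree$edge.length < 0 & tree$edge.length > -1e-12] <- 0
  tree
}

# lambda: shrink internal branches, pad terminals so tip heights are kept.
.lambdaTree <- function(tree, lambda) {
  h <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  parent <- tree$edge[, 1]
  el <- tree$edge.length * lambda
  term <- child <= ntip
  el[term] <- h[child[term]] - lambda * h[parent[term]]
  tree$edge.length <- el
  tree
}

#' White-noise covariance
#'
#' The non-phylogenetic model: tips are independent with unit variance
#' (times `sigma2` at simulation time), regardless of topology.
#'
#' @param tree a `"phylo"` object (only tip labels are used).
#' @return identity matrix with the tree's tip labels.
#' @export
whiteNoiseVCV <- function(tree) {
  validateTree(tree)
  n <- ape::Ntip(tree)
  diag(1, n, n) |> `dimnames<-`(list(tree$tip.label, tree$tip.label))
}

#' Unit-rate covariance matrix under a primary model (tree path)
#'
#' Dispatches to the model's tree transform and returns the phylogenetic
#' VCV of the transformed tree (identity matrix for white noise). `sigma2`
#' is *not* applied; multiply by it at simulation/likelihood time.
#'
#' @param tree a `"phylo"` object.
#' @param spec a [modelSpec()].
#' @return symmetric PSD matrix with tip labels.
#' @export
primaryVCV <- function(tree, spec) {
  stopifnot(inherits(spec, "modelSpec"))
  if (spec$model == "white") return(whiteNoiseVCV(tree))
  phyloVCV(rescaleTree(tree, spec))
}

#' Unit-rate covariance matrix under a primary model (closed form)
#'
#' Independent of [primaryVCV()]: builds the covariance directly from the
#' MRCA-height matrix of the *input* tree using each model's closed-form
#' covariance (elementwise height map where one exists; edge-wise
#' recomputation for lambda, kappa, lrates and nrates). The two code paths
#' agree to numerical precision and are cross-checked in the test suite.
#'
#' @inheritParams primaryVCV
#' @return symmetric PSD matrix with tip labels.
#' @export
closedFormVCV <- function(tree, spec) {
  validateTree(tree)
  stopifnot(inherits(spec, "modelSpec"))
  C0 <- phyloVCV(tree)
  .closedFormFromC0(C0, spec, tree)
}

# C0 = BM vcv (MRCA heights); tree needed only for edge-wise models
.closedFormFromC0 <- function(C0, spec, tree) {
  model <- spec$model
  if (model == "white") {
    I <- diag(1, nrow(C0))
    dimnames(I) <- dimnames(C0)
    return(I)
  }
  if (model == "lambda") {
    C <- spec$lambda * C0
    diag(C) <- diag(C0)
    return(C)
  }
  if (model %in% c("kappa", "lrates", "nrates")) {
    # no elementwise form: transform edges, then re-sum root-to-MRCA paths
    # through the incidence matrix (a code path independent of phyloVCV)
    el <- rescaleTree(tree, spec)$edge.length
    A <- rootPathIncidence(tree)
    h <- as.vector(A %*% el)
    idx <- ape::mrca(tree)
    return(matrix(h[idx], nrow(idx), dimnames = dimnames(idx)))
  }
  T <- max(diag(C0))
  if (model == "OU" && !isUltrametric(tree))
    stop("OU transform requires an ultrametric tree (contemporaneous tips)")
  g <- heightMap(spec, T)
  C <- matrix(g(as.vector(C0)), nrow(C0), dimnames = dimnames(C0))
  C
}
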
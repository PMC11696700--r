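#' Specify stacked processes on top of a primary model
#'
#' A stack combines a primary model with up to two overlays: rate shifts
#' (local clade rates and/or time-interval rates) and ancestral mean shifts.
#' Mode `"standard"` applies the primary model alone; `"lrates"` applies
#' rate overlays; `"AncShifts"` applies mean shifts; `"lrates+AncShifts"`
#' applies both. Mean shifts act only on tip expectations and never touch
#' the covariance.
#'
#' @param mode one of [stackingModes()].
#' @param lrates data frame with columns `tips` (list of tip-label vectors;
#'   each anchors a clade at the MRCA of the named tips) and `rate` (> 0).
#' @param nrates data frame with columns `start`, `end`, `rate`:
#'   non-overlapping \[start, end) intervals on the *original* tree's time
#'   axis, each with a rate multiplier > 0.
#' @param shifts data frame with columns `tips` (clade anchors, as in
#'   `lrates`) and `shift` (real): an instantaneous jump in the mean trait
#'   value on the branch leading to the anchored clade.
#' @return an object of class `"stackSpec"`.
#' @export
stackSpec <- function(mode = "standard", lrates = NULL, nrates = NULL,
                      shifts = NULL) {
  mode <- match.arg(mode, stackingModes())
  rateMode <- mode %in% c("lrates", "lrates+AncShifts")
  shiftMode <- mode %in% c("AncShifts", "lrates+AncShifts")
  if (!rateMode && (!is.null(lrates) || !is.null(nrates)))
    stop("rate tables supplied but mode '", mode, "' has no rate overlay")
  if (!shiftMode && !is.null(shifts))
    stop("shift table supplied but mode '", mode, "' has no AncShift overlay")
  if (rateMode && is.null(lrates) && is.null(nrates))
    stop("mode '", mode, "' requires an lrates and/or nrates table")
  if (shiftMode && is.null(shifts))
    stop("mode '", mode, "' requires a shifts table")
  if (!is.null(lrates)) lrates <- .checkRateTable(lrates)
  if (!is.null(nrates)) nrates <- .checkIntervalTable(nrates)
  if (!is.null(shifts)) {
    if (!is.data.frame(shifts) || !all(c("tips", "shift") %in% names(shifts)))
      stop("'shifts' must be a data frame with columns 'tips' and 'shift'")
    if (!is.list(shifts$tips)) shifts$tips <- as.list(shifts$tips)
    if (any(!is.finite(shifts$shift))) stop("shift values must be finite")
  }
  structure(list(mode = mode, lrates = lrates, nrates = nrates,
                 shifts = shifts),
            class = "stackSpec")
}

#' @export
print.stackSpec <- function(x, ...) {
  cat("Stacking mode:", x$mode, "\n")
  if (!is.null(x$lrates)) cat(" ", nrow(x$lrates), "clade rate shift(s)\n")
  if (!is.null(x$nrates)) cat(" ", nrow(x$nrates), "interval rate shift(s)\n")
  if (!is.null(x$shifts)) cat(" ", nrow(x$shifts), "ancestral mean shift(s)\n")
  invisible(x)
}

# Resolve a clade anchor (vector of tip labels) to a node number:
# a single tip anchors itself; several tips anchor their MRCA.
anchorNode <- function(tree, tips) {
  tips <- as.character(tips)
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss))
    stop("tip label(s) not in tree: ", paste(miss, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# Node numbers of a clade: the anchor node plus all its descendants.
cladeMembers <- function(tree, node) {
  nn <- ape::Ntip(tree) + tree$Nnode
  inside <- rep(FALSE, nn)
  inside[node] <- TRUE
  repeat {
    add <- inside[tree$edge[, 1]] & !inside[tree$edge[, 2]]
    if (!any(add)) break
    inside[tree$edge[add, 2]] <- TRUE
  }
  which(inside)
}

#' Apply local clade-rate shifts to a tree
#'
#' Every branch whose child node lies inside an anchored clade -- the stem
#' branch leading to the clade included -- has its length multiplied by the
#' clade's rate. Nested clades compose multiplicatively (the inner rate on
#' top of the outer).
#'
#' @param tree a `"phylo"` object.
#' @param rates data frame with columns `tips` (list of tip-label vectors)
#'   and `rate` (> 0); see [stackSpec()].
#' @return the rescaled `"phylo"` object.
#' @export
applyLocalRates <- function(tree, rates) {
  validateTree(tree)
  rates <- .checkRateTable(rates)
  mult <- rep(1, nrow(tree$edge))
  for (k in seq_len(nrow(rates))) {
    node <- anchorNode(tree, rates$tips[[k]])
    members <- cladeMembers(tree, node)
    mult[tree$edge[, 2] %in% members] <-
      mult[tree$edge[, 2] %in% members] * rates$rate[k]
  }
  tree$edge.length <- tree$edge.length * mult
  tree
}

#' Apply time-interval rate shifts to a tree
#'
#' Each branch is split at the interval boundaries it crosses; segments
#' falling inside an interval are multiplied by that interval's rate (rate 1
#' outside all intervals) and re-summed. Interval coordinates always refer
#' to the time axis of the *original* tree. When the tree being scaled is a
#' primary-transformed version of `original`, boundary heights are mapped
#' through the primary model's height map where one exists (BM, OU, EB,
#' delta, trend, depth); for edge-wise transforms without a global height
#' map (lambda, kappa, lrates) each boundary is placed within the
#' transformed branch in proportion to original-time occupancy.
#'
#' @param tree the `"phylo"` object to rescale (possibly already
#'   transformed).
#' @param intervals data frame with columns `start`, `end`, `rate`; see
#'   [stackSpec()].
#' @param original the tree whose time axis the intervals refer to; defaults
#'   to `tree` itself.
#' @param primary optional [modelSpec()] of the primary transform relating
#'   `original` to `tree`, used to map boundary heights.
#' @return the rescaled `"phylo"` object.
#' @export
applyIntervalRates <- function(tree, intervals, original = tree,
                               primary = NULL) {
  validateTree(tree)
  intervals <- .checkIntervalTable(intervals)
  sp <- edgeSpans(original)
  T <- treeDepth(original)
  if (any(intervals$start < 0) || any(intervals$end > T * (1 + 1e-9)))
    stop("intervals must lie within [0, ", format(T),
         "], the original tree's time span")
  g <- if (!is.null(primary)) heightMap(primary, T) else identity
  iv <- intervals[order(intervals$start), , drop = FALSE]
  # piecewise-constant rate over [0, T]: breakpoints and per-piece rates
  bks <- c(0, as.vector(rbind(iv$start, iv$end)), T)
  bks <- pmin(bks, T)
  pieceRate <- function(a) {          # rate applying at original time a
    r <- rep(1, length(a))
    for (k in seq_len(nrow(iv)))
      r[a >= iv$start[k] & a < iv$end[k]] <- iv$rate[k]
    r
  }
  el <- tree$edge.length
  out <- numeric(length(el))
  for (e in seq_along(el)) {
    t1 <- sp[e, 1]; t2 <- sp[e, 2]
    if (t2 - t1 <= 0) {               # zero-time span: use the local rate
      out[e] <- el[e] * pieceRate(t1)
      next
    }
    cuts <- sort(unique(c(t1, t2, bks[bks > t1 & bks < t2])))
    a <- cuts[-length(cuts)]; b <- cuts[-1]
    w <- if (!is.null(g)) {
      den <- g(t2) - g(t1)
      if (den > 0) (g(b) - g(a)) / den else (b - a) / (t2 - t1)
    } else (b - a) / (t2 - t1)        # proportional occupancy fallback
    out[e] <- el[e] * sum(pieceRate(a) * w)
  }
  tree$edge.length <- out
  tree
}

#' Expected trait value at each tip under ancestral mean shifts
#'
#' A shift anchored on the branch leading to a clade adds its value to the
#' expectation of every tip in that clade; tip i's mean is `z0` plus the sum
#' of all shifts on its root-to-tip path. Where within the branch the jump
#' occurs is irrelevant to tip means.
#'
#' @param tree a `"phylo"` object.
#' @param z0 root trait value.
#' @param shifts data frame with columns `tips` and `shift`, or `NULL` for
#'   no shifts; see [stackSpec()].
#' @return named numeric vector over the tree's tips.
#' @export
meanVector <- function(tree, z0 = 0, shifts = NULL) {
  validateTree(tree)
  mu <- rep(z0, ape::Ntip(tree))
  names(mu) <- tree$tip.label
  if (is.null(shifts) || nrow(shifts) == 0L) return(mu)
  ntip <- ape::Ntip(tree)
  for (k in seq_len(nrow(shifts))) {
    node <- anchorNode(tree, shifts$tips[[k]])
    members <- cladeMembers(tree, node)
    mu[members[members <= ntip]] <- mu[members[members <= ntip]] +
      shifts$shift[k]
  }
  mu
}

#' Apply a primary model plus stacked overlays
#'
#' Order of operations: primary transform, then local clade rates, then
#' interval rates, then the covariance is read off the resulting tree.
#' Ancestral mean shifts affect only the tip expectation vector, never the
#' covariance. `sigma2` is *not* applied here.
#'
#' @param tree a `"phylo"` object.
#' @param primary a [modelSpec()].
#' @param stack a [stackSpec()] (default: standard, no overlays).
#' @return a list with components `vcv` (unit-rate covariance matrix),
#'   `mean` (named tip expectation vector) and `tree` (the fully transformed
#'   tree, or `NULL` for white noise).
#' @export
applyStack <- function(tree, primary, stack = stackSpec("standard")) {
  validateTree(tree)
  stopifnot(inherits(primary, "modelSpec"), inherits(stack, "stackSpec"))
  rateMode <- stack$mode %in% c("lrates", "lrates+AncShifts")
  if (primary$model == "white" && rateMode)
    stop("cannot stack branch-rate overlays on white noise: ",
         "the model has no tree to rescale")
  if (primary$model == "white") {
    V <- whiteNoiseVCV(tree)
    tr <- NULL
  } else {
    tr <- rescaleTree(tree, primary)
    if (rateMode && !is.null(stack$lrates))
      tr <- applyLocalRates(tr, stack$lrates)
    if (rateMode && !is.null(stack$nrates))
      tr <- applyIntervalRates(tr, stack$nrates, original = tree,
                               primary = primary)
    V <- phyloVCV(tr)
  }
  mu <- meanVector(tree, primary$z0,
                   if (stack$mode %in% c("AncShifts", "lrates+AncShifts"))
                     stack$shifts)
  list(vcv = V, mean = mu, tree = tr)
}
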
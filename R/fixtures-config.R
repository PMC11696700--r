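#' Simulate a pure-birth (Yule) tree
#'
#' Starts from two lineages at the root, waits `Exp(k * birth_rate)` while
#' `k` lineages are alive, splits a uniformly chosen lineage, and stops once
#' `n_tips` lineages exist; the waiting time drawn in the `n_tips`-lineage
#' period sets the present, so pendant branches are extended to it and the
#' tree is ultrametric and fully bifurcating. Expected depth at rate 1 is
#' `sum(1/k, k = 2..n_tips)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed optional seed for reproducibility (otherwise the current RNG
#'   state is used).
#' @return an ultrametric bifurcating `"phylo"` object with tips
#'   `t1..t<n>`.
#' @export
yuleTree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  rootid <- n + 1L
  nextid <- n + 2L
  par <- c(rootid, rootid)      # parent node of each active lineage
  t0 <- c(0, 0)                 # birth time of each active lineage
  eP <- integer(0); eC <- integer(0); eL <- numeric(0)
  t <- 0
  for (k in 2:n) {
    t <- t + stats::rexp(1, k * birth_rate)
    if (k == n) break           # this period's wait runs to the present
    i <- sample.int(k, 1)
    eP <- c(eP, par[i]); eC <- c(eC, nextid); eL <- c(eL, t - t0[i])
    par <- c(par[-i], nextid, nextid)
    t0 <- c(t0[-i], t, t)
    nextid <- nextid + 1L
  }
  eP <- c(eP, par); eC <- c(eC, seq_len(n)); eL <- c(eL, t - t0)
  tree <- structure(list(edge = cbind(eP, eC, deparse.level = 0),
                         edge.length = eL, Nnode = n - 1L,
                         tip.label = paste0("t", seq_len(n))),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Built-in toy fixtures
#'
#' The small hand-checkable trees used throughout the documentation and
#' tests, each with its hand-computed phylogenetic covariance matrix.
#'
#' @return named list; each element has `newick`, `tree` and `vcv`.
#' @export
builtinFixtures <- function() {
  mk <- function(newick, vcv, labels) {
    dimnames(vcv) <- list(labels, labels)
    list(newick = newick, tree = readNewick(newick), vcv = vcv)
  }
  list(
    cherry2 = mk("(A:1,B:1);", diag(1, 2), c("A", "B")),
    toy3 = mk("((A:1,B:1):1,C:2);",
              matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3), c("A", "B", "C")),
    star3 = mk("(A:1,B:1,C:1);", diag(1, 3), c("A", "B", "C")),
    bal6 = mk("(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);",
              matrix(c(3, 2, 1, 1, 0, 0,
                       2, 3, 1, 1, 0, 0,
                       1, 1, 3, 2, 0, 0,
                       1, 1, 2, 3, 0, 0,
                       0, 0, 0, 0, 3, 1,
                       0, 0, 0, 0, 1, 3), 6),
              c("A", "B", "C", "D", "E", "F")))
}

# ---------------------------------------------------------------------------
# Session configuration files (YAML)

samplerToList <- function(s) {
  if (is.numeric(s)) return(unname(s))
  stopifnot(inherits(s, "paramSampler"))
  out <- c(list(dist = s$kind), s[setdiff(names(s), "kind")])
  lapply(out, function(v) if (is.numeric(v)) unname(v) else v)
}

listToSampler <- function(x, what = "sampler") {
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (!is.list(x) || is.null(x$dist))
    stop("malformed ", what, " specification: need a number or a ",
         "{dist: ..., ...} mapping")
  do.call(paramSampler, c(list(kind = x$dist),
                          x[setdiff(names(x), "dist")]))
}

.tableToList <- function(tab, valcol) {
  lapply(seq_len(nrow(tab)), function(k) {
    row <- list()
    if ("tips" %in% names(tab)) row$tips <- as.list(tab$tips[[k]])
    if ("start" %in% names(tab)) { row$start <- tab$start[k]
                                   row$end <- tab$end[k] }
    v <- if (is.list(tab[[valcol]])) tab[[valcol]][[k]] else tab[[valcol]][k]
    row[[valcol]] <- samplerToList(v)
    row
  })
}

.listToTable <- function(lst, valcol, hasTips) {
  vals <- lapply(lst, function(r) listToSampler(r[[valcol]], valcol))
  plain <- all(vapply(vals, is.numeric, TRUE))
  tab <- data.frame(row.names = seq_along(lst))
  if (hasTips) tab$tips <- I(lapply(lst, function(r) unlist(r$tips)))
  if (!is.null(lst[[1]]$start)) {
    tab$start <- vapply(lst, `[[`, 0, "start")
    tab$end <- vapply(lst, `[[`, 0, "end")
  }
  tab[[valcol]] <- if (plain) unlist(vals) else I(vals)
  tab
}

#' Write a session configuration file
#'
#' Serializes a [simulationSession()] to a human-editable YAML mapping
#' (samplers as `{dist: ..., ...}`). Sessions whose tree came from
#' [yuleTree()] via a config are written back as the generator spec;
#' function-valued `R` cannot be serialized.
#'
#' @param session a `"simSession"`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
writeSessionConfig <- function(session, path) {
  stopifnot(inherits(session, "simSession"))
  if (is.function(session$R))
    stop("a function-valued R cannot be written to a config file")
  st <- session$stack
  stackList <- list(mode = st$mode)
  if (!is.null(st$lrates)) stackList$lrates <- .tableToList(st$lrates, "rate")
  if (!is.null(st$nrates)) stackList$nrates <- .tableToList(st$nrates, "rate")
  if (!is.null(st$shifts)) stackList$shifts <- .tableToList(st$shifts, "shift")
  params <- lapply(session$params, function(p)
    if (is.data.frame(p)) .tableToList(p, "rate") else samplerToList(p))
  cfg <- list(
    tree = if (!is.null(attr(session$tree, "generator")))
      attr(session$tree, "generator") else writeNewick(session$tree),
    model = session$model, n_rep = session$n_rep, p = session$p,
    params = params, stack = stackList,
    R = apply(session$R, 1, as.list, simplify = FALSE),
    error_var = samplerToList(session$error_var),
    outputs = as.list(session$outputs), seed = session$seed,
    strict = session$strict)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a session configuration file
#'
#' Parses and schema-checks a YAML session config (unknown keys are
#' rejected) and builds the corresponding [simulationSession()]. The `tree`
#' entry is either a Newick string, a path to a Newick file, or a generator
#' mapping `{n_tips: ..., birth_rate: ..., seed: ...}` handed to
#' [yuleTree()].
#'
#' @param path config file.
#' @return a `"simSession"`.
#' @export
readSessionConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("tree", "model", "n_rep", "p", "params", "stack", "R",
             "error_var", "outputs", "seed", "strict")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(c("tree", "model", "n_rep", "seed"), names(cfg))
  if (length(miss))
    stop("config missing required key(s): ", paste(miss, collapse = ", "))
  tree <- if (is.list(cfg$tree)) {
    gen <- cfg$tree
    tr <- yuleTree(gen$n_tips, gen$birth_rate %||% 1, gen$seed)
    attr(tr, "generator") <- gen
    tr
  } else if (grepl(";", cfg$tree)) readNewick(text = cfg$tree)
  else readNewick(file = cfg$tree)
  model <- cfg$model
  shape <- .modelShapeParam[[model]]
  params <- list()
  for (nm in names(cfg$params)) {
    p <- cfg$params[[nm]]
    params[[nm]] <- if (nm %in% c("rates", "intervals"))
      .listToTable(p, "rate", hasTips = identical(nm, "rates"))
    else listToSampler(p, nm)
  }
  stack <- if (is.null(cfg$stack)) stackSpec("standard") else {
    s <- cfg$stack
    stackSpec(s$mode %||% "standard",
              lrates = if (!is.null(s$lrates))
                .listToTable(s$lrates, "rate", TRUE),
              nrates = if (!is.null(s$nrates))
                .listToTable(s$nrates, "rate", FALSE),
              shifts = if (!is.null(s$shifts))
                .listToTable(s$shifts, "shift", TRUE))
  }
  p <- cfg$p %||% 1L
  R <- if (is.null(cfg$R)) diag(1, p)
       else do.call(rbind, lapply(cfg$R, unlist))
  simulationSession(tree, model, n_rep = cfg$n_rep, p = p, params = params,
                    stack = stack, R = R,
                    error_var = listToSampler(cfg$error_var %||% 0,
                                              "error_var"),
                    outputs = unlist(cfg$outputs %||% "raw"),
                    seed = cfg$seed, strict = cfg$strict %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
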
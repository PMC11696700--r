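#' Parameter samplers
#'
#' Describes how a model parameter is drawn anew for each simulation
#' replicate. Available kinds: `fixed` (`value`), `uniform` (`min`, `max`),
#' `exponential` (`rate`), `gamma` (`shape`, `scale`), `normal` (`mean`,
#' `sd`) and `list` (`values`, cycled through uniformly at random). A draw
#' that falls outside the domain of the parameter it feeds (e.g. a negative
#' `sigma2` from a user list) is an error, never silently clamped or
#' redrawn: a misconfigured sampler must fail loudly.
#'
#' @param kind one of `"fixed"`, `"uniform"`, `"exponential"`, `"gamma"`,
#'   `"normal"`, `"list"`.
#' @param ... the distribution's own parameters, named as above.
#' @return an object of class `"paramSampler"`.
#' @export
paramSampler <- function(kind = c("fixed", "uniform", "exponential",
                                  "gamma", "normal", "list"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  need <- switch(kind,
    fixed = "value", uniform = c("min", "max"), exponential = "rate",
    gamma = c("shape", "scale"), normal = c("mean", "sd"), list = "values")
  if (!setequal(names(args), need))
    stop("sampler '", kind, "' needs exactly: ", paste(need, collapse = ", "))
  if (kind == "uniform" && args$max < args$min) stop("max < min")
  if (kind == "exponential" && args$rate <= 0) stop("rate must be > 0")
  if (kind == "gamma" && (args$shape <= 0 || args$scale <= 0))
    stop("shape and scale must be > 0")
  if (kind == "normal" && args$sd < 0) stop("sd must be >= 0")
  if (kind == "list" && length(args$values) < 1L) stop("empty value list")
  structure(c(list(kind = kind), args), class = "paramSampler")
}

#' @export
print.paramSampler <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("sampler ", x$kind, "(",
      paste(names(pars), vapply(pars, \(v) paste(format(v), collapse = ","),
                                ""), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Draw from a parameter sampler
#'
#' Uses the current RNG state. Plain numbers pass through unchanged, so
#' fixed values need not be wrapped in a sampler.
#'
#' @param s a [paramSampler()] or a single number.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
drawSampler <- function(s, n = 1L) {
  if (is.numeric(s)) {
    stopifnot(length(s) == 1L)
    return(rep(s, n))
  }
  stopifnot(inherits(s, "paramSampler"))
  switch(s$kind,
    fixed = rep(s$value, n),
    uniform = stats::runif(n, s$min, s$max),
    exponential = stats::rexp(n, s$rate),
    gamma = stats::rgamma(n, shape = s$shape, scale = s$scale),
    normal = stats::rnorm(n, s$mean, s$sd),
    list = s$values[sample.int(length(s$values), n, replace = TRUE)])
}

# domain checks applied to realized parameter draws, by parameter name
.paramDomain <- list(
  sigma2 = function(v) v > 0, alpha = function(v) v > 0,
  delta = function(v) v > 0, lambda = function(v) v >= 0 & v <= 1,
  kappa = function(v) v >= 0 & v <= 1, depth = function(v) v > 0,
  a = function(v) v != 0, error_var = function(v) v >= 0)

checkDomain <- function(name, value) {
  f <- .paramDomain[[name]]
  if (!is.null(f) && !all(f(value)))
    stop("sampled value ", format(value), " outside the domain of '", name,
         "'; fix the sampler configuration")
  value
}

# Deterministic per-replicate, per-stage RNG substream seeds. Keeping draws
# keyed by (master seed, replicate, stage) makes replicate k independent of
# how many other replicates run, and re-runnable in isolation.
substreamSeed <- function(master, replicate, stage) {
  sid <- match(stage, c("params", "traits", "error"))
  if (is.na(sid)) stop("unknown RNG stage: ", stage)
  ((master %% 1000003) * 1009 + replicate * 7919 + sid * 104729) %%
    2147483629 + 1
}

withSubstream <- function(master, replicate, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substreamSeed(master, replicate, stage))
  expr
}

#' Describe a simulation session
#'
#' The complete description of a simulation experiment: tree, replicate and
#' trait counts, the primary model with a value or sampler for each of its
#' parameters, stacking overlays (whose rates/shift values may themselves be
#' samplers), among-trait covariance, measurement error, requested output
#' formats and the master seed. [runSession()] executes it.
#'
#' @param tree a `"phylo"` object.
#' @param model model name (one of [primaryModels()]).
#' @param n_rep number of replicates (>= 1).
#' @param p number of traits (>= 1).
#' @param params named list giving, for each parameter of `model` (`z0`,
#'   `sigma2`, and the shape parameter if any), either a number or a
#'   [paramSampler()]. `lrates`/`nrates` take their `rates`/`intervals`
#'   table here; the `rate` column may hold samplers.
#' @param stack a [stackSpec()]; `rate` and `shift` columns may hold
#'   [paramSampler()] objects, resolved per replicate.
#' @param R among-trait covariance: a `p x p` symmetric PSD matrix, or a
#'   function `(replicate_index) -> matrix` for per-replicate covariances.
#' @param error_var measurement-error variance: a number >= 0 or a sampler.
#' @param outputs character vector among `"raw"`, `"pic"`, `"pic_unit"`,
#'   `"pgls"`, `"pgls_unit"`.
#' @param seed master seed (integer).
#' @param strict if `TRUE` (default) any replicate failure aborts the
#'   session; if `FALSE` failed replicates are recorded and skipped.
#' @return an object of class `"simSession"`.
#' @export
simulationSession <- function(tree, model, n_rep = 1L, p = 1L,
                              params = list(), stack = stackSpec("standard"),
                              R = NULL, error_var = 0, outputs = "raw",
                              seed = 1L, strict = TRUE) {
  validateTree(tree)
  model <- match.arg(model, primaryModels())
  stopifnot(n_rep >= 1, p >= 1, inherits(stack, "stackSpec"))
  outputs <- match.arg(outputs,
                       c("raw", "pic", "pic_unit", "pgls", "pgls_unit"),
                       several.ok = TRUE)
  if (is.null(R)) R <- diag(1, p)
  if (is.matrix(R)) {
    stopifnot(nrow(R) == p, ncol(R) == p)
    if (max(abs(R - t(R))) > 1e-12) stop("R must be symmetric")
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("R must be positive semidefinite")
  } else if (!is.function(R)) stop("R must be a matrix or a function")
  known <- c("z0", "sigma2", .modelShapeParam[[model]])
  bad <- setdiff(names(params), known[!is.na(known)])
  if (length(bad))
    stop("unknown parameter(s) for model '", model, "': ",
         paste(bad, collapse = ", "))
  structure(list(tree = tree, model = model, n_rep = as.integer(n_rep),
                 p = as.integer(p), params = params, stack = stack, R = R,
                 error_var = error_var, outputs = outputs,
                 seed = as.integer(seed), strict = isTRUE(strict)),
            class = "simSession")
}

#' @export
print.simSession <- function(x, ...) {
  cat("Trait simulation session\n",
      "  model: ", x$model, " (stacking: ", x$stack$mode, ")\n",
      "  tree: ", ape::Ntip(x$tree), " tips, depth ",
      format(treeDepth(x$tree)), "\n",
      "  replicates: ", x$n_rep, ", traits: ", x$p, "\n",
      "  outputs: ", paste(x$outputs, collapse = ", "),
      ", seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Realize one replicate's parameters
#'
#' Draws every sampled quantity for replicate `i` from its dedicated RNG
#' substream, so the same `(seed, i)` always yields the same values no
#' matter which other replicates run.
#'
#' @param session a [simulationSession()].
#' @param i replicate index (1-based).
#' @return list with components `spec` (realized [modelSpec()]), `stack`
#'   (realized [stackSpec()]), `R` (realized among-trait covariance) and
#'   `error_var` (realized error variance).
#' @export
sampleParameters <- function(session, i) {
  stopifnot(inherits(session, "simSession"), i >= 1, i <= session$n_rep)
  withSubstream(session$seed, i, "params", {
    p <- session$params
    draw1 <- function(name, default) {
      v <- if (is.null(p[[name]])) default else drawSampler(p[[name]], 1L)
      checkDomain(name, v)
    }
    z0 <- draw1("z0", 0)
    sigma2 <- draw1("sigma2", 1)
    shape <- .modelShapeParam[[session$model]]
    extra <- list()
    if (!is.na(shape) && !shape %in% c("rates", "intervals"))
      extra[[shape]] <- draw1(shape, stop("model '", session$model,
                                          "' needs parameter '", shape, "'"))
    if (identical(shape, "rates") || identical(shape, "intervals")) {
      tab <- p[[shape]]
      if (is.null(tab)) stop("model '", session$model, "' needs '", shape, "'")
      extra[[shape]] <- .realizeColumn(tab, "rate")
    }
    spec <- do.call(modelSpec, c(list(model = session$model, z0 = z0,
                                      sigma2 = sigma2), extra))
    st <- session$stack
    if (!is.null(st$lrates)) st$lrates <- .realizeColumn(st$lrates, "rate")
    if (!is.null(st$nrates)) st$nrates <- .realizeColumn(st$nrates, "rate")
    if (!is.null(st$shifts)) st$shifts <- .realizeColumn(st$shifts, "shift")
    R <- if (is.function(session$R)) session$R(i) else session$R
    ev <- checkDomain("error_var", drawSampler(session$error_var, 1L))
    list(spec = spec, stack = st, R = R, error_var = ev)
  })
}

# resolve a table column that may hold samplers into realized numbers
.realizeColumn <- function(tab, col) {
  v <- tab[[col]]
  if (is.list(v)) tab[[col]] <- vapply(v, drawSampler, 0, n = 1L)
  tab
}

# Cholesky with a single jitter retry: numerically semidefinite inputs
# (lambda = 0, duplicated heights) get 1e-10 * trace/n added to the diagonal.
cholJitter <- function(M) {
  L <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (is.null(L)) {
    M <- M + diag(1e-10 * sum(diag(M)) / nrow(M) + 1e-300, nrow(M))
    L <- tryCatch(t(chol(M)), error = function(e)
      stop("covariance matrix is not positive semidefinite ",
           "(Cholesky failed even after diagonal jitter)"))
  }
  L
}

#' Draw one matrix-normal trait replicate
#'
#' Samples `Y` with `vec(Y - M) ~ N(0, R \%x\% (sigma2 * vcv))`: columns are
#' traits, rows are tips, phylogenetic covariance `sigma2 * vcv` across tips
#' and `R` across traits, realized as `Y = M + L_C Z L_R'` with lower
#' Cholesky factors and a standard-normal matrix `Z` drawn from the current
#' RNG state.
#'
#' @param vcv tip covariance matrix (unit rate), labels as dimnames.
#' @param mean named tip expectation vector.
#' @param sigma2 rate multiplier (> 0).
#' @param R among-trait covariance (`p x p`; default scalar 1).
#' @return `n_tips x p` matrix with tip labels as rownames.
#' @export
simulateReplicate <- function(vcv, mean, sigma2 = 1, R = matrix(1, 1, 1)) {
  n <- nrow(vcv)
  if (is.numeric(R) && !is.matrix(R)) R <- matrix(R, 1, 1)
  p <- nrow(R)
  stopifnot(length(mean) == n, sigma2 > 0)
  LC <- cholJitter(sigma2 * vcv)
  LR <- cholJitter(R)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Y <- matrix(mean, n, p) + LC %*% Z %*% t(LR)
  rownames(Y) <- rownames(vcv)
  colnames(Y) <- paste0("trait", seq_len(p))
  Y
}

#' Add Gaussian measurement error to a trait matrix
#'
#' Independent `N(0, error_var)` noise added to every cell, modelling
#' phylogeny-free measurement error with a common variance across tips and
#' traits.
#'
#' @param traits tips-by-traits matrix.
#' @param error_var error variance (>= 0; 0 returns the input unchanged).
#' @return matrix of the same shape.
#' @export
addMeasurementError <- function(traits, error_var) {
  if (!is.numeric(error_var) || length(error_var) != 1L || error_var < 0)
    stop("error_var must be a single number >= 0")
  if (error_var == 0) return(traits)
  traits + matrix(stats::rnorm(length(traits), 0, sqrt(error_var)),
                  nrow(traits), ncol(traits))
}

#' Run a simulation session
#'
#' For each replicate: realize parameters, build the stacked covariance and
#' mean, draw matrix-normal traits, add measurement error, and compute the
#' requested output formats. Fully deterministic given `(session, seed)`:
#' re-running reproduces every table bit for bit.
#'
#' @param session a [simulationSession()].
#' @return an object of class `"traitSimArchive"`: a list with `manifest`
#'   (one data-frame row per replicate: realized parameters and seed
#'   materials), `traits` (list of raw trait matrices), `outputs` (named
#'   list of per-format lists) and the `session` itself.
#' @export
runSession <- function(session) {
  stopifnot(inherits(session, "simSession"))
  tree <- session$tree
  fmts <- setdiff(session$outputs, "raw")
  unitTree <- if (length(intersect(fmts, c("pic_unit", "pgls_unit"))))
    scaleTreeDepth(tree, 1)
  manifest <- vector("list", session$n_rep)
  traits <- vector("list", session$n_rep)
  outputs <- stats::setNames(
    lapply(session$outputs, function(f) vector("list", session$n_rep)),
    session$outputs)
  for (i in seq_len(session$n_rep)) {
    res <- tryCatch({
      par <- sampleParameters(session, i)
      st <- applyStack(tree, par$spec, par$stack)
      Y <- withSubstream(session$seed, i, "traits",
                         simulateReplicate(st$vcv, st$mean,
                                           par$spec$sigma2, par$R))
      Y <- withSubstream(session$seed, i, "error",
                         addMeasurementError(Y, par$error_var))
      shape <- .modelShapeParam[[session$model]]
      scalarShape <- !is.na(shape) && !shape %in% c("rates", "intervals")
      row <- data.frame(
        replicate = i, model = session$model, stacking = par$stack$mode,
        z0 = par$spec$z0, sigma2 = par$spec$sigma2,
        shape_name = if (scalarShape) shape else NA_character_,
        shape_value = if (scalarShape) par$spec[[shape]] else NA_real_,
        error_var = par$error_var, master_seed = session$seed,
        stringsAsFactors = FALSE)
      out <- list()
      for (f in session$outputs)
        out[[f]] <- switch(f,
          raw = Y,
          pic = computePIC(tree, Y),
          pic_unit = computePIC(unitTree, Y),
          pgls = pglsWhiten(tree, Y),
          pgls_unit = pglsWhiten(unitTree, Y))
      list(row = row, Y = Y, out = out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (session$strict)
        stop("replicate ", i, " failed: ", conditionMessage(res))
      manifest[[i]] <- data.frame(
        replicate = i, model = session$model, stacking = NA, z0 = NA,
        sigma2 = NA, shape_name = NA, shape_value = NA, error_var = NA,
        master_seed = session$seed, stringsAsFactors = FALSE)
      warning("replicate ", i, " failed and was skipped: ",
              conditionMessage(res))
      next
    }
    manifest[[i]] <- res$row
    traits[[i]] <- res$Y
    for (f in session$outputs) outputs[[f]][[i]] <- res$out[[f]]
  }
  structure(list(manifest = do.call(rbind, manifest), traits = traits,
                 outputs = outputs, session = session),
            class = "traitSimArchive")
}

#' @export
print.traitSimArchive <- function(x, ...) {
  cat("Trait simulation archive: ", nrow(x$manifest), " replicate(s), ",
      "model ", x$session$model, ", ", x$session$p, " trait(s)\n", sep = "")
  invisible(x)
}

#' Write a simulation archive to delimited text files
#'
#' Writes `manifest.tsv` plus, per requested output format, either one TSV
#' per replicate (`<format>_rep<i>.tsv`, first column the tip label) or one
#' long-format TSV per format with a replicate column.
#'
#' @param archive a `"traitSimArchive"`.
#' @param dir output directory (created if needed).
#' @param long write one long table per format instead of per-replicate
#'   files.
#' @return `dir`, invisibly.
#' @export
writeArchive <- function(archive, dir, long = TRUE) {
  stopifnot(inherits(archive, "traitSimArchive"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(archive$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (f in names(archive$outputs)) {
    tabs <- archive$outputs[[f]]
    asdf <- function(m, i) {
      d <- data.frame(label = rownames(m), m, row.names = NULL,
                      check.names = FALSE)
      if (long) cbind(replicate = i, d) else d
    }
    if (long) {
      all <- do.call(rbind, lapply(seq_along(tabs), function(i)
        if (!is.null(tabs[[i]])) asdf(tabs[[i]], i)))
      utils::write.table(all, file.path(dir, paste0(f, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      for (i in seq_along(tabs))
        if (!is.null(tabs[[i]]))
          utils::write.table(asdf(tabs[[i]], i),
                             file.path(dir, sprintf("%s_rep%04d.tsv", f, i)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
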
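# ---------------------------------------------------------------------------
# Likelihood machinery.
#
# Every candidate model has a unit-rate covariance V0(theta); the root state
# z0 and the rate sigma2 are profiled analytically by GLS, leaving at most a
# one-dimensional numeric search over theta (plus an error/rate ratio when
# measurement error is estimated). The hot path builds V0 directly from the
# MRCA-height matrix (elementwise height maps; edge-wise only for kappa), so
# a likelihood evaluation costs one small Cholesky.

fitPrecomp <- function(tree) {
  validateTree(tree)
  C0 <- phyloVCV(tree)
  list(tree = tree, C0 = C0, T = max(diag(C0)), n = nrow(C0),
       A = rootPathIncidence(tree), idx = ape::mrca(tree),
       el = tree$edge.length, ultra = isUltrametric(tree))
}

# unit-rate covariance under `model` at shape value `theta` (NA for BM/white)
modelV0 <- function(pre, model, theta = NA) {
  C0 <- pre$C0
  switch(model,
    BM = C0,
    white = diag(1, pre$n),
    lambda = { C <- theta * C0; diag(C) <- diag(C0); C },
    delta = C0^theta,
    OU = {
      if (!pre$ultra)
        stop("OU requires an ultrametric tree (contemporaneous tips)")
      exp(-2 * theta * pre$T) * expm1(2 * theta * C0) / (2 * theta)
    },
    EB = expm1(theta * C0) / theta,
    trend = {
      s <- theta
      if (s >= 0) C0 + s * C0^2 / 2
      else { tt <- pmin(C0, -1 / s); tt + s * tt^2 / 2 }
    },
    kappa = {
      el <- ifelse(pre$el == 0, 0, pre$el^theta)
      h <- as.vector(pre$A %*% el)
      matrix(h[pre$idx], pre$n, pre$n)
    },
    stop("no fittable covariance for model '", model, "'"))
}

# GLS profile of (z0, sigma2) given V0; returns c(lnL, z0, sigma2) or NULL
# when V0 cannot be factorized. Upper-Cholesky with transpose-backsolve
# keeps this -- the innermost call of every fit -- allocation-light.
profileGivenV0 <- function(V0, y) {
  n <- length(y)
  R <- tryCatch(chol(V0), error = function(e) {
    diag(V0) <- diag(V0) + 1e-10 * sum(diag(V0)) / n + 1e-300
    tryCatch(chol(V0), error = function(e2) NULL)
  })
  if (is.null(R)) return(NULL)
  uv <- backsolve(R, cbind(y, 1), transpose = TRUE)
  z0 <- sum(uv[, 2] * uv[, 1]) / sum(uv[, 2]^2)
  s2 <- sum((uv[, 1] - z0 * uv[, 2])^2) / n
  if (s2 < 1e-290)   # degenerate (e.g. constant data): density unbounded
    return(c(lnL = Inf, z0 = z0, sigma2 = 0))
  ldet <- 2 * sum(log(diag(R)))
  lnL <- -n / 2 * log(2 * pi) - (n * log(s2) + ldet) / 2 - n / 2
  c(lnL = lnL, z0 = z0, sigma2 = s2)
}

#' Profiled log-likelihood of a candidate model
#'
#' Evaluates the maximum log-likelihood over `(z0, sigma2)` at a fixed shape
#' value `theta`: builds the unit-rate covariance `V0(theta)`, estimates the
#' root state by GLS, profiles the rate analytically, and returns the
#' multivariate-normal log-likelihood. With `error_var = "estimate"` the
#' error-to-rate ratio is expected in `error_ratio` and `ratio * I` is added
#' to `V0` (the rate stays profiled); with a fixed positive `error_var` the
#' rate is found by a one-dimensional numeric search since it no longer
#' profiles in closed form.
#'
#' @param tree a `"phylo"` object.
#' @param y named trait vector (tip labels).
#' @param model a fittable model name (`"BM"`, `"OU"`, `"EB"`, `"lambda"`,
#'   `"delta"`, `"kappa"`, `"trend"`, `"white"`).
#' @param theta the model's shape value (ignored for BM/white).
#' @param error_var 0 (default), a fixed error variance, or `"estimate"`.
#' @param error_ratio error-to-rate ratio when `error_var = "estimate"`.
#' @return list with `lnL`, `z0`, `sigma2`.
#' @export
profileLoglik <- function(tree, y, model, theta = NA, error_var = 0,
                          error_ratio = 0) {
  pre <- fitPrecomp(tree)
  y <- alignTraits(tree, y)[, 1]
  V0 <- modelV0(pre, model, theta)
  if (identical(error_var, "estimate")) {
    V0 <- V0 + diag(error_ratio, pre$n)
    error_var <- 0
  }
  if (error_var == 0) {
    p <- profileGivenV0(V0, y)
    if (is.null(p)) stop("covariance matrix singular at this theta")
    return(as.list(p))
  }
  if (error_var < 0) stop("error_var must be >= 0")
  # fixed nonzero error: V = s2*V0 + ev*I; the rate no longer profiles in
  # closed form, so search log s2 with z0 still estimated by GLS
  obj <- function(ls2) {
    s2 <- exp(ls2)
    L <- tryCatch(cholJitter(s2 * V0 + diag(error_var, pre$n)),
                  error = function(e) NULL)
    if (is.null(L)) return(-1e300)
    u <- forwardsolve(L, y)
    v <- forwardsolve(L, rep(1, pre$n))
    z0 <- sum(v * u) / sum(v * v)
    r <- u - z0 * v
    -pre$n / 2 * log(2 * pi) - sum(log(diag(L))) - sum(r^2) / 2
  }
  op <- stats::optimize(obj, c(-25, 25), maximum = TRUE, tol = 1e-6)
  s2 <- exp(op$maximum)
  L <- cholJitter(s2 * V0 + diag(error_var, pre$n))
  u <- forwardsolve(L, y)
  v <- forwardsolve(L, rep(1, pre$n))
  list(lnL = op$objective, z0 = sum(v * u) / sum(v * v), sigma2 = s2)
}

# ---------------------------------------------------------------------------
# Shape-parameter search spaces (the bounds used by fitContinuous-style
# fitting; log scale where the lower bound is exp(-500)).

shapeBounds <- function(model, depth) {
  switch(model,
    OU = list(lo = -500, hi = 1, trans = exp),          # log alpha
    lambda = list(lo = -500, hi = 0, trans = exp),      # log lambda
    delta = list(lo = -500, hi = log(3), trans = exp),  # log delta
    kappa = list(lo = -500, hi = 0, trans = exp),       # log kappa
    EB = list(lo = -5 / depth, hi = 1e-6, trans = identity),
    trend = list(lo = -100, hi = 100, trans = identity),
    NULL)
}

# the theta at which the model reduces to BM, on the search scale (or NA)
identityTheta <- function(model) {
  switch(model, lambda = 0, kappa = 0, delta = 0,   # log(1) = 0
         trend = 0, EB = 1e-6, OU = -500, NA)
}

# Deterministic multi-start 1D maximization: evaluate at the bound
# endpoints, the 5 quantile starts {.05,.25,.5,.75,.95} and (when defined)
# the BM-identity value, then refine with Brent search in the bracket
# around the best point.
searchTheta <- function(obj, b, model) {
  grid <- sort(unique(c(b$lo, b$lo + c(.05, .25, .5, .75, .95) *
                          (b$hi - b$lo), b$hi,
                        max(b$lo, min(b$hi, identityTheta(model))))))
  vals <- vapply(grid, obj, 0)
  k <- which.max(vals)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  op <- if (hi > lo) stats::optimize(obj, c(lo, hi), maximum = TRUE,
                                     tol = 1e-4)
        else list(maximum = grid[k], objective = vals[k])
  if (op$objective >= vals[k]) c(op$maximum, op$objective)
  else c(grid[k], vals[k])
}

#' Fit one evolutionary model to a trait vector by maximum likelihood
#'
#' Profiles `z0` and `sigma2` analytically and searches the model's shape
#' parameter over fitContinuous-style bounds (`alpha` in
#' `[exp(-500), exp(1)]`, `lambda`, `kappa` in `[exp(-500), 1]`, `delta` in
#' `[exp(-500), 3]`, `a` in `[-5/depth, 1e-6]`, `slope` in `[-100, 100]`;
#' log scale where the range spans `exp(-500)`), with deterministic
#' multi-starts. With `estimate_error = TRUE` the measurement-error-to-rate
#' ratio is added to the numeric search (one extra free parameter).
#'
#' @param tree a `"phylo"` object.
#' @param y named trait vector.
#' @param model fittable model name; see [profileLoglik()].
#' @param estimate_error also estimate a measurement-error variance.
#' @param .pre precomputed structure from an internal call; leave `NULL`.
#' @return an object of class `"traitFit"`: list with `model`, `lnL`, `z0`,
#'   `sigma2`, `theta` (named, `NULL` for BM/white), `error_var` (estimated
#'   error variance or 0), `k`, `AIC`, `converged`.
#' @export
fitTraitModel <- function(tree, y, model, estimate_error = FALSE,
                          .pre = NULL) {
  pre <- if (is.null(.pre)) fitPrecomp(tree) else .pre
  if (is.null(.pre)) y <- alignTraits(tree, y)[, 1]
  model <- match.arg(model, c("BM", "OU", "EB", "lambda", "delta", "kappa",
                              "trend", "white"))
  b <- shapeBounds(model, pre$T)
  hasTheta <- !is.null(b)
  lrBounds <- c(-20, 7)        # log error-to-rate ratio search range
  evalAt <- function(theta, lratio) {
    V0 <- tryCatch(modelV0(pre, model, theta), error = function(e) NULL)
    if (is.null(V0)) return(NULL)
    if (!is.null(lratio)) V0 <- V0 + diag(exp(lratio), pre$n)
    profileGivenV0(V0, pre$y)
  }
  pre$y <- y
  objVal <- function(p) {   # p on search scale; returns lnL or -1e300
    theta <- if (hasTheta) b$trans(p[1]) else NA
    lratio <- if (estimate_error) p[length(p)] else NULL
    r <- evalAt(theta, lratio)
    if (is.null(r) || !is.finite(r["lnL"])) -1e300 else r[["lnL"]]
  }
  if (!hasTheta && !estimate_error) {
    sol <- evalAt(NA, NULL)
    if (is.null(sol)) stop("singular covariance for model '", model, "'")
    best <- list(par = numeric(0), lnL = sol[["lnL"]])
  } else if (!estimate_error) {
    st <- searchTheta(function(p) objVal(p), b, model)
    best <- list(par = st[1], lnL = st[2])
  } else if (!hasTheta) {
    st <- searchTheta(function(p) objVal(p),
                      list(lo = lrBounds[1], hi = lrBounds[2],
                           trans = identity), NA)
    best <- list(par = st[1], lnL = st[2])
  } else {
    # 2D: coarse deterministic grid, then Nelder-Mead refinement with the
    # objective clamped to the box
    g1 <- b$lo + c(.05, .25, .5, .75, .95) * (b$hi - b$lo)
    g1 <- sort(unique(c(g1, max(b$lo, min(b$hi, identityTheta(model))))))
    g2 <- lrBounds[1] + c(.1, .5, .9) * diff(lrBounds)
    grid <- as.matrix(expand.grid(g1, g2))
    lower <- c(b$lo, lrBounds[1]); upper <- c(b$hi, lrBounds[2])
    clamped <- function(p) objVal(pmin(pmax(p, lower), upper))
    vals <- apply(grid, 1, objVal)
    p0 <- grid[which.max(vals), ]
    op <- tryCatch(
      stats::optim(p0, clamped, method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = 60,
                                  reltol = 1e-7)),
      error = function(e) NULL)
    best <- if (!is.null(op) && op$value >= max(vals))
      list(par = pmin(pmax(op$par, lower), upper), lnL = op$value)
    else list(par = p0, lnL = max(vals))
  }
  # +Inf marks degenerate (zero-variance) data, still a usable fit for
  # tie-breaking; only the -1e300 sentinel means the search failed
  converged <- !is.na(best$lnL) && best$lnL > -1e299
  theta <- if (hasTheta) b$trans(best$par[1]) else NULL
  lratio <- if (estimate_error) best$par[length(best$par)] else NULL
  sol <- evalAt(if (hasTheta) theta else NA, lratio)
  if (is.null(sol))
    sol <- c(lnL = -Inf, z0 = NA, sigma2 = NA)
  k <- (if (hasTheta) 3L else 2L) + as.integer(estimate_error)
  thetaName <- .modelShapeParam[[model]]
  structure(list(
    model = model, lnL = unname(sol[["lnL"]]), z0 = unname(sol[["z0"]]),
    sigma2 = unname(sol[["sigma2"]]),
    theta = if (hasTheta) stats::setNames(theta, thetaName),
    error_var = if (estimate_error) exp(lratio) * unname(sol[["sigma2"]])
                else 0,
    k = k, AIC = 2 * k - 2 * unname(sol[["lnL"]]), converged = converged),
    class = "traitFit")
}

#' @export
print.traitFit <- function(x, ...) {
  cat("Model ", x$model, ": lnL = ", format(x$lnL), ", AIC = ",
      format(x$AIC), " (k = ", x$k, ")\n",
      "  z0 = ", format(x$z0), ", sigma2 = ", format(x$sigma2),
      if (!is.null(x$theta)) paste0(", ", names(x$theta), " = ",
                                    format(unname(x$theta))),
      if (x$error_var > 0) paste0(", error_var = ", format(x$error_var)),
      "\n", sep = "")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

# canonical candidate order used for AIC tie-breaking
.candidateOrder <- c("BM", "OU", "EB", "lambda", "delta", "kappa", "trend",
                     "white")

#' Fit several candidate models and select by AIC
#'
#' Fits each candidate with [fitTraitModel()], ranks by AIC (2k - 2 lnL),
#' and selects the minimum. Ties (|dAIC| < 1e-8, including the degenerate
#' all-infinite case of constant data) are broken by smaller `k`, then by
#' the fixed candidate order BM, OU, EB, lambda, delta, kappa, trend, white.
#'
#' @inheritParams fitTraitModel
#' @param candidates character vector of >= 2 model names; defaults to the
#'   seven focal models (BM, OU, EB, lambda, delta, kappa, trend).
#' @param aicc rank by small-sample AICc (`AIC + 2k(k+1)/(n-k-1)`) instead
#'   of plain AIC (default `FALSE`).
#' @return an object of class `"aicSelection"`: list with `fits` (named list
#'   of `"traitFit"`), `table` (data frame with lnL, k, AIC, dAIC), and
#'   `selected` (model name).
#' @export
fitModelsAIC <- function(tree, y, candidates = c("BM", "OU", "EB", "lambda",
                                                 "delta", "kappa", "trend"),
                         estimate_error = FALSE, aicc = FALSE,
                         .pre = NULL) {
  if (length(candidates) < 2L) stop("need at least 2 candidate models")
  pre <- if (is.null(.pre)) fitPrecomp(tree) else .pre
  if (is.null(.pre)) y <- alignTraits(tree, y)[, 1]
  fits <- lapply(candidates, function(m)
    fitTraitModel(tree, y, m, estimate_error, .pre = pre))
  names(fits) <- candidates
  if (!any(vapply(fits, `[[`, TRUE, "converged")))
    stop("no candidate model converged")
  aic <- vapply(fits, `[[`, 0, "AIC")
  kk <- vapply(fits, `[[`, 0L, "k")
  if (aicc) {
    n <- length(if (is.null(.pre)) alignTraits(tree, y)[, 1] else y)
    aic <- aic + 2 * kk * (kk + 1) / pmax(n - kk - 1, 1)
  }
  tied <- which(aic <= min(aic) + 1e-8)     # -Inf-safe tie set
  tied <- tied[order(kk[tied], match(candidates[tied], .candidateOrder))]
  sel <- candidates[tied[1]]
  tab <- data.frame(model = candidates,
                    lnL = vapply(fits, `[[`, 0, "lnL"), k = kk, AIC = aic,
                    dAIC = aic - min(aic),
                    converged = vapply(fits, `[[`, TRUE, "converged"),
                    row.names = NULL)
  structure(list(fits = fits, table = tab[order(tab$AIC), ],
                 selected = sel),
            class = "aicSelection")
}

#' @export
print.aicSelection <- function(x, ...) {
  cat("AIC model selection: selected", x$selected, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit a bivariate model (BM, OU or EB) by maximum likelihood
#'
#' Matrix-normal likelihood `vec(Y) ~ N(z0 kron 1, R kron C(theta))` with a
#' single shared shape parameter: given theta, the two root states and the
#' 2x2 among-trait covariance `R` (rates folded into its diagonal) have
#' closed-form GLS/ML estimates, leaving a one-dimensional search. `k` = 5
#' for BM (two root states + three free entries of R) and 6 for OU/EB.
#'
#' @param tree a `"phylo"` object (ultrametric for OU).
#' @param Y tips-by-2 labeled trait matrix.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @return list of class `"traitFitMV"` with `model`, `lnL`, `z0` (length
#'   2), `R` (2x2), `theta`, `k`, `AIC`, `converged`, `degenerate` (`TRUE`
#'   when the estimated R is numerically singular, e.g. duplicated traits).
#' @export
fitMultiTrait <- function(tree, Y, model = c("BM", "OU", "EB")) {
  model <- match.arg(model)
  pre <- fitPrecomp(tree)
  Y <- alignTraits(tree, Y)
  if (ncol(Y) != 2L) stop("Y must have exactly 2 trait columns")
  n <- pre$n
  evalTheta <- function(theta) {
    C <- tryCatch(modelV0(pre, model, theta), error = function(e) NULL)
    if (is.null(C)) return(NULL)
    L <- tryCatch(cholJitter(C), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    U <- forwardsolve(L, Y)
    v <- forwardsolve(L, rep(1, n))
    z0 <- as.vector(crossprod(v, U)) / sum(v^2)
    E <- U - tcrossprod(v, z0)
    R <- crossprod(E) / n
    dtR <- R[1, 1] * R[2, 2] - R[1, 2]^2
    ldC <- 2 * sum(log(diag(L)))
    lnL <- if (dtR <= 0) Inf else
      -n * log(2 * pi) - (n * log(dtR) + 2 * ldC) / 2 - n
    list(lnL = lnL, z0 = z0, R = R, degenerate = dtR <= 1e-12 *
           max(R[1, 1] * R[2, 2], .Machine$double.xmin))
  }
  b <- shapeBounds(model, pre$T)
  if (is.null(b)) {
    sol <- evalTheta(NA)
    theta <- NULL
    lnL <- sol$lnL
  } else {
    obj <- function(p) {
      r <- evalTheta(b$trans(p))
      if (is.null(r) || is.nan(r$lnL)) -1e300
      else if (is.infinite(r$lnL)) 1e300 else r$lnL
    }
    st <- searchTheta(obj, b, model)
    theta <- stats::setNames(b$trans(st[1]), .modelShapeParam[[model]])
    sol <- evalTheta(theta)
    lnL <- sol$lnL
  }
  k <- if (model == "BM") 5L else 6L
  structure(list(model = model, lnL = lnL, z0 = sol$z0, R = sol$R,
                 theta = theta, k = k, AIC = 2 * k - 2 * lnL,
                 converged = is.finite(lnL), degenerate = sol$degenerate),
            class = "traitFitMV")
}

#' @export
print.traitFitMV <- function(x, ...) {
  cat("Bivariate model ", x$model, ": lnL = ", format(x$lnL), ", AIC = ",
      format(x$AIC), " (k = ", x$k, ")\n", sep = "")
  if (x$degenerate) cat("  WARNING: estimated R is singular\n")
  invisible(x)
}

#' Confusion matrix of true versus AIC-selected models
#'
#' @param true character vector of generating-model names, one per
#'   replicate.
#' @param selected character vector of AIC-selected model names.
#' @param models row/column order; defaults to the union of values.
#' @return object of class `"confusionMatrix"`: square matrix of
#'   row-normalized fractions with a `counts` attribute (replicates per true
#'   model).
#' @export
buildConfusion <- function(true, selected, models = NULL) {
  if (!length(true)) stop("empty archive: no replicates to tabulate")
  stopifnot(length(true) == length(selected))
  if (is.null(models)) models <- unique(c(true, selected))
  tab <- table(factor(true, levels = models),
               factor(selected, levels = models))
  counts <- rowSums(tab)
  if (any(counts == 0))
    stop("no replicates for true model(s): ",
         paste(models[counts == 0], collapse = ", "))
  frac <- sweep(unclass(tab), 1, counts, "/")
  dimnames(frac) <- list(true = models, selected = models)
  structure(frac, counts = counts, class = c("confusionMatrix", "matrix"))
}

#' @export
print.confusionMatrix <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows: true model, cols: AIC-selected; ",
      "row fractions)\n", sep = "")
  print(round(unclass(x), digits))
  cat("mean diagonal:", format(mean(diag(unclass(x))), digits = 3), "\n")
  invisible(x)
}

#' Heat-map display of a confusion matrix
#'
#' @param cm a `"confusionMatrix"`.
#' @param main plot title.
#' @return invisibly, `cm`.
#' @export
plotConfusion <- function(cm, main = "AIC model selection") {
  m <- unclass(cm)
  nm <- rownames(m)
  graphics::image(seq_along(nm), seq_along(nm),
                  t(m[rev(seq_along(nm)), , drop = FALSE]),
                  col = grDevices::grey(seq(1, 0.1, length.out = 64)),
                  axes = FALSE, xlab = "selected model",
                  ylab = "true model", main = main, zlim = c(0, 1))
  graphics::axis(1, seq_along(nm), nm, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_along(nm), rev(nm), las = 1, cex.axis = 0.8)
  graphics::box()
  invisible(cm)
}
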
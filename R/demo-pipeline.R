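#' Parameter samplers used in the model-selection case studies
#'
#' The per-replicate sampling distributions of the seven focal models:
#' `sigma2 ~ Exp(1)` and `z0 ~ N(0, 1)` for every model, and
#' `alpha ~ U(exp(-500), exp(1))`, `a ~ U(-5/depth, 1e-6)`,
#' `lambda ~ U(exp(-500), 1)`, `delta ~ U(exp(-500), 3)`,
#' `kappa ~ U(exp(-500), 1)`, `slope ~ U(-100, 100)` for the shape
#' parameters, mirroring fitContinuous-style parameter bounds. White noise
#' and depth have no published sampling row; white noise reuses the
#' `sigma2`/`z0` samplers by analogy (recorded as an assumption in any
#' config written from these settings).
#'
#' @param model a model name among the focal set.
#' @param depth tree depth, needed for the early-burst `a` range.
#' @return named list of [paramSampler()] objects for
#'   [simulationSession()]'s `params`.
#' @export
demoSamplers <- function(model, depth) {
  base <- list(sigma2 = paramSampler("exponential", rate = 1),
               z0 = paramSampler("normal", mean = 0, sd = 1))
  shape <- switch(model,
    OU = list(alpha = paramSampler("uniform", min = exp(-500),
                                   max = exp(1))),
    EB = list(a = paramSampler("uniform", min = -5 / depth, max = 1e-6)),
    lambda = list(lambda = paramSampler("uniform", min = exp(-500),
                                        max = 1)),
    delta = list(delta = paramSampler("uniform", min = exp(-500), max = 3)),
    kappa = list(kappa = paramSampler("uniform", min = exp(-500), max = 1)),
    trend = list(slope = paramSampler("uniform", min = -100, max = 100)),
    BM = , white = list(),
    stop("no demo samplers for model '", model, "'"))
  c(base, shape)
}

# error-variance multipliers defining the demo's graded error conditions:
# error variance = multiplier * realized sigma2 * mean tip depth
.errorLevels <- c(none = 0, moderate = 0.25, high = 1)

#' Model-selection accuracy under graded measurement error
#'
#' The package's demonstration pipeline: simulate `n_rep` replicates under
#' each of the seven focal models with case-study samplers
#' ([demoSamplers()]), add measurement error at each requested level
#' (variance = multiplier x realized `sigma2` x mean tip depth, with
#' multipliers 0 / 0.25 / 1 for none / moderate / high), fit all seven
#' candidates by ML with and (optionally) without estimating the error
#' variance, select by AIC, and tabulate confusion matrices.
#'
#' @param tree a `"phylo"` object (ultrametric, so OU is fittable).
#' @param n_rep replicates per true model.
#' @param models focal model set (default the seven univariate case-study
#'   models).
#' @param error_levels named numeric multipliers (default
#'   `c(none = 0, moderate = 0.25, high = 1)`).
#' @param estimation one or both of `"assumed_absent"`, `"estimated"`.
#' @param seed master seed.
#' @param progress print one line per (model, level, mode) cell.
#' @return object of class `"selectionDemo"`: list with `confusions` (named
#'   list of [buildConfusion()] matrices keyed `<level>_<mode>`), `details`
#'   (long data frame of every fit: true model, level, mode, selected,
#'   realized parameters) and `settings`.
#' @export
modelSelectionDemo <- function(tree, n_rep = 200,
                               models = c("BM", "OU", "EB", "lambda",
                                          "delta", "kappa", "trend"),
                               error_levels = .errorLevels,
                               estimation = c("assumed_absent", "estimated"),
                               seed = 1, progress = FALSE) {
  validateTree(tree)
  estimation <- match.arg(estimation, several.ok = TRUE)
  if (is.null(names(error_levels)) || any(!nzchar(names(error_levels))))
    stop("error_levels must be a named vector")
  depth <- treeDepth(tree)
  meanTipDepth <- mean(nodeHeights(tree)[seq_len(ape::Ntip(tree))])
  pre <- fitPrecomp(tree)
  rows <- list()
  for (mi in seq_along(models)) {
    m <- models[mi]
    sess <- simulationSession(tree, m, n_rep = n_rep,
                              params = demoSamplers(m, depth),
                              outputs = "raw",
                              seed = (seed + 7717 * mi) %% 2147483629)
    arch <- runSession(sess)
    for (i in seq_len(n_rep)) {
      Y <- arch$traits[[i]]
      s2 <- arch$manifest$sigma2[i]
      for (li in seq_along(error_levels)) {
        lev <- names(error_levels)[li]
        ev <- error_levels[[li]] * s2 * meanTipDepth
        Ye <- withSubstream(sess$seed + 524287 * li, i, "error",
                            addMeasurementError(Y, ev))
        yv <- Ye[tree$tip.label, 1]
        for (mode in estimation) {
          selres <- fitModelsAIC(tree, yv, candidates = models,
                                 estimate_error = mode == "estimated",
                                 .pre = pre)
          rows[[length(rows) + 1L]] <- data.frame(
            true = m, replicate = i, level = lev, mode = mode,
            selected = selres$selected, sigma2 = s2, error_var = ev,
            shape_value = arch$manifest$shape_value[i],
            stringsAsFactors = FALSE)
        }
      }
      if (progress && i %% 50 == 0)
        message(m, ": ", i, "/", n_rep, " replicates done")
    }
  }
  details <- do.call(rbind, rows)
  confusions <- list()
  for (lev in names(error_levels))
    for (mode in estimation) {
      d <- details[details$level == lev & details$mode == mode, ]
      confusions[[paste(lev, mode, sep = "_")]] <-
        buildConfusion(d$true, d$selected, models)
    }
  structure(list(confusions = confusions, details = details,
                 settings = list(n_rep = n_rep, models = models,
                                 error_levels = error_levels,
                                 estimation = estimation, seed = seed,
                                 n_tips = ape::Ntip(tree))),
            class = "selectionDemo")
}

#' @export
print.selectionDemo <- function(x, ...) {
  cat("Model-selection demo: ", length(x$settings$models), " models x ",
      x$settings$n_rep, " replicates on ", x$settings$n_tips,
      " tips\n", sep = "")
  for (nm in names(x$confusions))
    cat(sprintf("  %-28s mean diagonal %.3f\n", nm,
                mean(diag(unclass(x$confusions[[nm]])))))
  invisible(x)
}

#' Bivariate model-selection demo (BM / OU / EB)
#'
#' Two-trait companion of [modelSelectionDemo()]: simulates correlated trait
#' pairs under BM, OU and EB with a shared among-trait covariance, adds
#' measurement error at each level, fits the three bivariate models with
#' [fitMultiTrait()], and tabulates AIC confusion matrices (error always
#' assumed absent during fitting).
#'
#' @inheritParams modelSelectionDemo
#' @param R 2x2 among-trait covariance used for simulation.
#' @return list with `confusions` (per error level) and `details`.
#' @export
multiTraitDemo <- function(tree, n_rep = 100,
                           R = matrix(c(1, 0.5, 0.5, 1), 2),
                           error_levels = .errorLevels, seed = 1,
                           progress = FALSE) {
  validateTree(tree)
  models <- c("BM", "OU", "EB")
  depth <- treeDepth(tree)
  meanTipDepth <- mean(nodeHeights(tree)[seq_len(ape::Ntip(tree))])
  rows <- list()
  for (mi in seq_along(models)) {
    m <- models[mi]
    sess <- simulationSession(tree, m, n_rep = n_rep, p = 2,
                              params = demoSamplers(m, depth), R = R,
                              outputs = "raw",
                              seed = (seed + 3917 * mi) %% 2147483629)
    arch <- runSession(sess)
    for (i in seq_len(n_rep)) {
      s2 <- arch$manifest$sigma2[i]
      for (li in seq_along(error_levels)) {
        lev <- names(error_levels)[li]
        ev <- error_levels[[li]] * s2 * meanTipDepth
        Ye <- withSubstream(sess$seed + 524287 * li, i, "error",
                            addMeasurementError(arch$traits[[i]], ev))
        fits <- lapply(models, function(cm) fitMultiTrait(tree, Ye, cm))
        aic <- vapply(fits, `[[`, 0, "AIC")
        kk <- vapply(fits, `[[`, 0L, "k")
        tied <- which(aic <= min(aic) + 1e-8)
        tied <- tied[order(kk[tied])]
        rows[[length(rows) + 1L]] <- data.frame(
          true = m, replicate = i, level = lev,
          selected = models[tied[1]], stringsAsFactors = FALSE)
      }
    }
    if (progress) message("bivariate ", m, " done")
  }
  details <- do.call(rbind, rows)
  confusions <- lapply(stats::setNames(nm = names(error_levels)),
                       function(lev) {
                         d <- details[details$level == lev, ]
                         buildConfusion(d$true, d$selected, models)
                       })
  list(confusions = confusions, details = details)
}
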
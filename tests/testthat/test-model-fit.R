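toy3 <- readNewick("((A:1,B:1):1,C:2);")

test_that("white-noise ML matches the closed-form iid solution", {
  y <- c(A = 1, B = 2, C = 3)
  p <- profileLoglik(toy3, y, "white")
  expect_equal(p$z0, 2)
  expect_equal(p$sigma2, 2 / 3)
  expect_equal(p$lnL, sum(dnorm(1:3, 2, sqrt(2 / 3), log = TRUE)),
               tolerance = 1e-12)
})

test_that("profiled likelihood equals a dense-matrix density evaluation", {
  specs <- list(BM = NA, lambda = 0.5, delta = 1.6, kappa = 0.7, OU = 0.9,
                EB = -0.8, trend = 0.3)
  for (s in 1:5) {
    tr <- randomTree(sample(6:12, 1), seed = 500 + s)
    y <- setNames(rnorm(ape::Ntip(tr)), tr$tip.label)
    for (m in names(specs)) {
      p <- profileLoglik(tr, y, m, specs[[m]])
      shape <- switch(m, BM = list(), stats::setNames(list(specs[[m]]),
        c(lambda = "lambda", delta = "delta", kappa = "kappa",
          OU = "alpha", EB = "a", trend = "slope")[m]))
      V0 <- primaryVCV(tr, do.call(modelSpec, c(list(model = m), shape)))
      direct <- denseMVNloglik(p$sigma2 * V0, y[rownames(V0)],
                               rep(p$z0, nrow(V0)))
      expect_equal(p$lnL, direct, tolerance = 1e-8)
    }
  }
})

test_that("BM likelihood on a 2-tip tree beats a brute-force grid", {
  two <- readNewick("(A:1,B:1);")
  y <- c(A = 3, B = 1)
  p <- profileLoglik(two, y, "BM")
  V0 <- diag(1, 2)
  grid <- expand.grid(z0 = seq(0, 4, by = 0.05),
                      s2 = seq(0.05, 5, by = 0.05))
  gl <- mapply(function(z, s) denseMVNloglik(s * V0, y, rep(z, 2)),
               grid$z0, grid$s2)
  expect_gte(p$lnL, max(gl))
  expect_equal(p$z0, grid$z0[which.max(gl)], tolerance = 0.05)
})

test_that("fitted shape parameters maximize locally and respect bounds", {
  set.seed(41)
  tr <- yuleTree(40, 1, seed = 6)
  st <- applyStack(tr, modelSpec("lambda", lambda = 0.6))
  y <- simulateReplicate(st$vcv, st$mean)[, 1]
  f <- fitTraitModel(tr, y, "lambda")
  expect_true(f$converged)
  lam <- unname(f$theta)
  expect_gte(lam, exp(-500)); expect_lte(lam, 1)
  # local-optimality probe
  for (d in runif(100, -0.2, 0.2)) {
    cand <- min(max(lam + d, 1e-8), 1)
    expect_gte(f$lnL + 1e-6, profileLoglik(tr, y, "lambda", cand)$lnL)
  }
  # every fitted theta lies inside its stated bounds
  for (m in c("OU", "EB", "delta", "kappa", "trend")) {
    fm <- fitTraitModel(tr, y, m)
    b <- phytraitsim:::shapeBounds(m, treeDepth(tr))
    th <- unname(fm$theta)
    expect_gte(th, b$trans(b$lo) - 1e-15)
    expect_lte(th, b$trans(b$hi) + 1e-15)
  }
})

test_that("lambda always nests BM in likelihood", {
  set.seed(42)
  tr <- yuleTree(30, 1, seed = 8)
  gens <- list(modelSpec("BM"), modelSpec("OU", alpha = 1),
               modelSpec("EB", a = -1), modelSpec("kappa", kappa = 0.3))
  for (g in gens) for (r in 1:5) {
    st <- applyStack(tr, g)
    y <- simulateReplicate(st$vcv, st$mean)[, 1]
    expect_gte(fitTraitModel(tr, y, "lambda")$lnL,
               fitTraitModel(tr, y, "BM")$lnL - 1e-6)
  }
})

test_that("AIC selection ranks, tie-breaks and counts parameters", {
  set.seed(43)
  tr <- yuleTree(30, 1, seed = 9)
  st <- applyStack(tr, modelSpec("BM"))
  y <- simulateReplicate(st$vcv, st$mean)[, 1]
  sel <- fitModelsAIC(tr, y, candidates = c("BM", "OU"))
  fB <- sel$fits$BM; fO <- sel$fits$OU
  expect_equal(fO$AIC - fB$AIC,
               2 * (fO$k - fB$k) - 2 * (fO$lnL - fB$lnL), tolerance = 1e-10)
  expect_equal(sel$selected, sel$table$model[1])
  expect_equal(fB$k, 2L); expect_equal(fO$k, 3L)
  expect_equal(fitTraitModel(tr, y, "OU", estimate_error = TRUE)$k, 4L)
  full <- fitModelsAIC(tr, y)
  expect_length(full$fits, 7L)
  # constant data: degenerate likelihoods collapse to the simplest model
  flat <- setNames(rep(2, ape::Ntip(tr)), tr$tip.label)
  expect_equal(fitModelsAIC(tr, flat)$selected, "BM")
  expect_error(fitModelsAIC(tr, y, candidates = "BM"), "at least 2")
  # AICc adds the small-sample penalty 2k(k+1)/(n-k-1) before ranking
  n <- ape::Ntip(tr)
  selc <- fitModelsAIC(tr, y, candidates = c("BM", "OU"), aicc = TRUE)
  b <- selc$table[match(sel$table$model, selc$table$model), ]
  expect_equal(b$AIC - sel$table$AIC,
               2 * b$k * (b$k + 1) / (n - b$k - 1), tolerance = 1e-10)
})

test_that("the bivariate demo tabulates confusion across error levels", {
  tr <- yuleTree(15, 1, seed = 21)
  out <- multiTraitDemo(tr, n_rep = 5, seed = 4)
  expect_named(out$confusions, c("none", "moderate", "high"))
  for (cm in out$confusions) {
    expect_equal(unname(rowSums(unclass(cm))), rep(1, 3))
    expect_equal(dimnames(unclass(cm))$true, c("BM", "OU", "EB"))
  }
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plotConfusion(out$confusions$none))
})

test_that("estimating measurement error recovers an added-noise scale", {
  set.seed(44)
  tr <- yuleTree(60, 1, seed = 10)
  st <- applyStack(tr, modelSpec("BM"))
  y <- simulateReplicate(st$vcv, st$mean)[, 1] +
    rnorm(ape::Ntip(tr), 0, sqrt(0.5))
  f <- fitTraitModel(tr, y, "BM", estimate_error = TRUE)
  expect_true(f$converged)
  expect_gt(f$error_var, 0.1)
  expect_lt(f$error_var, 2)
  expect_gte(f$lnL, fitTraitModel(tr, y, "BM")$lnL - 1e-6)
  # fixed-error profiling agrees with the zero-error limit
  p0 <- profileLoglik(tr, y, "BM")
  pf <- profileLoglik(tr, y, "BM", error_var = 1e-12)
  expect_equal(pf$lnL, p0$lnL, tolerance = 1e-4)
})

test_that("bivariate fits recover the among-trait correlation", {
  set.seed(45)
  tr <- yuleTree(40, 1, seed = 12)
  st <- applyStack(tr, modelSpec("BM"))
  R <- matrix(c(1, .9, .9, 1), 2)
  ratios <- offd <- numeric(60)
  for (i in 1:60) {
    Y <- simulateReplicate(st$vcv, st$mean, 1, R)
    fb <- fitMultiTrait(tr, Y, "BM")
    ratios[i] <- fb$R[1, 2] / sqrt(fb$R[1, 1] * fb$R[2, 2])
    Yi <- simulateReplicate(st$vcv, st$mean, 1, diag(1, 2))
    offd[i] <- fitMultiTrait(tr, Yi, "BM")$R[1, 2]
  }
  expect_lt(abs(median(ratios) - 0.9), 0.05)
  expect_lt(abs(median(offd)), 0.1)
  # parameter counts and degeneracy detection
  Y <- simulateReplicate(st$vcv, st$mean, 1, R)
  expect_equal(fitMultiTrait(tr, Y, "BM")$k, 5L)
  expect_equal(fitMultiTrait(tr, Y, "OU")$k, 6L)
  dup <- cbind(Y[, 1], Y[, 1])
  rownames(dup) <- rownames(Y)
  expect_true(fitMultiTrait(tr, dup, "BM")$degenerate)
})

test_that("confusion matrices normalize rows and detect perfect selection", {
  cm <- buildConfusion(c("BM", "OU", "EB"), c("BM", "OU", "EB"))
  expect_equal(unclass(cm), diag(1, 3), ignore_attr = TRUE)
  cm2 <- buildConfusion(rep(c("BM", "OU"), each = 4),
                        c("BM", "BM", "OU", "BM", "OU", "OU", "OU", "BM"),
                        models = c("BM", "OU"))
  expect_equal(rowSums(unclass(cm2)), c(BM = 1, OU = 1))
  expect_true(all(unclass(cm2) >= 0))
  expect_error(buildConfusion(character(0), character(0)), "empty")
})
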
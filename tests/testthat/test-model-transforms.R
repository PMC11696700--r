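toy3 <- readNewick("((A:1,B:1):1,C:2);")

test_that("identity parameter values reproduce the BM covariance", {
  C0 <- phyloVCV(toy3)
  expect_equal(primaryVCV(toy3, modelSpec("lambda", lambda = 1)), C0)
  expect_equal(primaryVCV(toy3, modelSpec("kappa", kappa = 1)), C0)
  expect_equal(primaryVCV(toy3, modelSpec("delta", delta = 1)), C0)
  expect_equal(primaryVCV(toy3, modelSpec("trend", slope = 0)), C0)
  expect_equal(primaryVCV(toy3, modelSpec("depth", depth = 2)), C0)
  # OU and EB approach BM in the weak-parameter limit
  ou <- rescaleTree(toy3, modelSpec("OU", alpha = 1e-8))
  expect_lt(max(abs(ou$edge.length - toy3$edge.length) /
                  toy3$edge.length), 1e-5)
  eb <- rescaleTree(toy3, modelSpec("EB", a = 1e-9))
  expect_lt(max(abs(eb$edge.length - toy3$edge.length) /
                  toy3$edge.length), 1e-6)
})

test_that("lambda scales off-diagonal covariance only", {
  expect_equal(primaryVCV(toy3, modelSpec("lambda", lambda = 0.5)),
               matrix(c(2, .5, 0, .5, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  star <- primaryVCV(toy3, modelSpec("lambda", lambda = 0))
  expect_equal(unname(star), diag(2, 3))
  # tree-space version never produces negative terminal padding
  for (lam in c(0, .3, .8, 1))
    expect_gte(min(rescaleTree(toy3,
                               modelSpec("lambda", lambda = lam))$edge.length),
               0)
  expect_error(modelSpec("lambda", lambda = 1.2), "\\[0, 1\\]")
})

test_that("kappa powers branch lengths with 0^0 = 0", {
  k0 <- primaryVCV(toy3, modelSpec("kappa", kappa = 0))
  expect_equal(unname(k0), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 1), 3))
  tr4 <- readNewick("(A:4,B:4);")
  expect_equal(rescaleTree(tr4, modelSpec("kappa", kappa = 0.5))$edge.length,
               c(2, 2))
  zo <- readNewick("((A:0,B:1):1,C:2);")
  expect_equal(min(rescaleTree(zo, modelSpec("kappa", kappa = 0))$edge.length),
               0)
})

test_that("delta powers node heights without depth rescaling", {
  d2 <- primaryVCV(toy3, modelSpec("delta", delta = 2))
  expect_equal(unname(d2), matrix(c(4, 1, 0, 1, 4, 0, 0, 0, 4), 3))
  # delta > 1 reduces relative shared covariance on ultrametric trees
  r1 <- primaryVCV(toy3, modelSpec("delta", delta = 1))
  expect_lt(d2["A", "B"] / d2["A", "A"], r1["A", "B"] / r1["A", "A"])
})

test_that("OU transform matches its stationary closed form", {
  ou <- primaryVCV(toy3, modelSpec("OU", alpha = 1))
  expect_equal(ou["A", "A"], 0.5 * (1 - exp(-4)), tolerance = 1e-12)
  expect_equal(ou["A", "A"], 0.490842, tolerance = 1e-6)
  # off-diagonal: (1/(2a)) e^(-2a(T-s)) (1 - e^(-2as)), s = 1, T = 2
  expect_equal(ou["A", "B"], 0.5 * exp(-2) * (1 - exp(-2)),
               tolerance = 1e-12)
  expect_equal(ou["A", "B"], 0.0585098, tolerance = 1e-6)
  # relative shared covariance strictly decreasing in alpha
  ratios <- sapply(c(0.1, 1, 10), function(a) {
    V <- primaryVCV(toy3, modelSpec("OU", alpha = a))
    V["A", "B"] / V["A", "A"]
  })
  expect_true(all(diff(ratios) < 0))
  expect_error(rescaleTree(readNewick("((A:1,B:2):1,C:2);"),
                           modelSpec("OU", alpha = 1)), "ultrametric")
  expect_error(rescaleTree(toy3, modelSpec("OU", alpha = 200)), "alpha")
})

test_that("EB transform integrates an exponentially changing rate", {
  tr <- readNewick("(A:1,B:1);")
  eb <- rescaleTree(tr, modelSpec("EB", a = log(0.5)))
  expect_equal(eb$edge.length, rep((0.5 - 1) / log(0.5), 2),
               tolerance = 1e-12)
  expect_equal(eb$edge.length[1], 0.721348, tolerance = 1e-6)
  # declining rates shrink total depth; tiny positive a is accepted
  for (a in c(-0.5, -2)) {
    out <- rescaleTree(toy3, modelSpec("EB", a = a))
    expect_lt(max(nodeHeights(out)), max(nodeHeights(toy3)))
  }
  expect_gt(max(nodeHeights(rescaleTree(toy3, modelSpec("EB", a = 1e-7)))),
            0)
})

test_that("trend transform integrates a floored linear rate", {
  tr2 <- readNewick("(A:2,B:2);")
  up <- rescaleTree(tr2, modelSpec("trend", slope = 1))
  expect_equal(up$edge.length, c(4, 4))
  expect_warning(dn <- rescaleTree(tr2, modelSpec("trend", slope = -1)),
                 "floor")
  expect_equal(dn$edge.length, c(0.5, 0.5))
})

test_that("white noise covariance is the identity regardless of topology", {
  expect_equal(unname(whiteNoiseVCV(toy3)), diag(1, 3))
  t5a <- yuleTree(5, 1, seed = 1); t5b <- yuleTree(5, 1, seed = 99)
  expect_equal(unname(whiteNoiseVCV(t5a)), unname(whiteNoiseVCV(t5b)))
  expect_error(rescaleTree(toy3, modelSpec("white")), "no tree")
})

test_that("tree-path and closed-form VCVs agree on random trees", {
  specs <- list(modelSpec("BM"), modelSpec("lambda", lambda = 0.4),
                modelSpec("delta", delta = 1.7),
                modelSpec("kappa", kappa = 0.6),
                modelSpec("OU", alpha = 0.8), modelSpec("EB", a = -0.9),
                modelSpec("trend", slope = -0.7),
                modelSpec("depth", depth = 3))
  for (s in 1:20) {
    tr <- randomTree(sample(5:12, 1), seed = 300 + s)
    for (sp in specs) {
      # negative-slope trend triggers its rate-floor warning on deep trees
      V1 <- suppressWarnings(primaryVCV(tr, sp))
      V2 <- suppressWarnings(closedFormVCV(tr, sp))
      expect_lt(max(abs(V1 - V2)), 1e-8 * max(abs(V2), 1))
      ev <- eigen(V1, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-9 * max(abs(ev)))
    }
  }
})

test_that("the model catalog enumerates 11 primaries x 4 stackings", {
  cat <- modelCatalog()
  expect_equal(nrow(cat), 44L)
  expect_equal(length(primaryModels()), 11L)
  expect_equal(length(stackingModes()), 4L)
  expect_equal(nrow(unique(cat)), 44L)
})

test_that("model specification rejects invalid parameters", {
  expect_error(modelSpec("BM", sigma2 = -1), "positive")
  expect_error(modelSpec("OU", alpha = -1), "alpha")
  expect_error(modelSpec("OU"), "requires exactly parameter 'alpha'")
  expect_error(modelSpec("BM", alpha = 1), "no shape parameter")
  expect_error(modelSpec("EB", a = 0), "nonzero")
  expect_error(modelSpec("frobnicate"), "should be one of")
})
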
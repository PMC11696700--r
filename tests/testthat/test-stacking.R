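toy3 <- readNewick("((A:1,B:1):1,C:2);")
bal6 <- builtinFixtures()$bal6$tree

test_that("local clade rates scale the stem and nested clades compose", {
  one <- applyLocalRates(toy3, data.frame(tips = I(list(c("A", "B"))),
                                          rate = 1))
  expect_equal(one$edge.length, toy3$edge.length)
  v <- phyloVCV(applyLocalRates(toy3, data.frame(tips = I(list(c("A", "B"))),
                                                 rate = 2)))
  expect_equal(unname(v), matrix(c(4, 2, 0, 2, 4, 0, 0, 0, 2), 3))
  nest <- applyLocalRates(toy3, data.frame(tips = I(list(c("A", "B"), "A")),
                                           rate = c(2, 3)))
  tipA <- nest$edge.length[nest$edge[, 2] == which(nest$tip.label == "A")]
  expect_equal(tipA, 6)
  expect_error(applyLocalRates(toy3, data.frame(tips = I(list("Z")),
                                                rate = 2)), "Z")
  expect_error(applyLocalRates(toy3, data.frame(tips = I(list("A")),
                                                rate = -2)), "> 0")
})

test_that("interval rates split branches at boundaries and re-sum", {
  keep <- applyIntervalRates(toy3, data.frame(start = 0.2, end = 0.9,
                                              rate = 1))
  expect_equal(keep$edge.length, toy3$edge.length)
  v <- phyloVCV(applyIntervalRates(toy3, data.frame(start = 1, end = 2,
                                                    rate = 3)))
  expect_equal(unname(v), matrix(c(4, 1, 0, 1, 4, 0, 0, 0, 4), 3))
  # a whole-span interval is the same as a global rate multiplier
  glob <- applyIntervalRates(bal6, data.frame(start = 0, end = 3, rate = 2.5))
  expect_equal(phyloVCV(glob), 2.5 * phyloVCV(bal6))
  expect_error(applyIntervalRates(toy3,
                                  data.frame(start = c(0, 0.5),
                                             end = c(1, 1.5),
                                             rate = c(2, 3))), "overlap")
})

test_that("mean shifts add along root-to-tip paths", {
  expect_equal(meanVector(toy3, z0 = 1.5),
               c(A = 1.5, B = 1.5, C = 1.5))
  expect_equal(meanVector(toy3, 0, data.frame(tips = I(list(c("A", "B"))),
                                              shift = 5)),
               c(A = 5, B = 5, C = 0))
  expect_equal(meanVector(toy3, 0,
                          data.frame(tips = I(list(c("A", "B"), "A")),
                                     shift = c(5, -2))),
               c(A = 3, B = 5, C = 0))
  expect_error(meanVector(toy3, 0, data.frame(tips = I(list("Q")),
                                              shift = 1)), "Q")
})

test_that("stacking order is primary, then lrates, then nrates", {
  # standard mode reduces to the primary model with a constant mean
  st <- applyStack(toy3, modelSpec("delta", z0 = 2, delta = 2))
  expect_equal(st$vcv, primaryVCV(toy3, modelSpec("delta", delta = 2)))
  expect_equal(st$mean, c(A = 2, B = 2, C = 2))
  # mean shifts never touch the covariance
  sh <- stackSpec("AncShifts", shifts = data.frame(tips = I(list("C")),
                                                   shift = -4))
  stsh <- applyStack(toy3, modelSpec("BM"), sh)
  expect_identical(stsh$vcv, phyloVCV(toy3))
  expect_equal(stsh$mean, c(A = 0, B = 0, C = -4))
  # OU then lrates: matches scaling the OU-transformed tree by hand
  lr <- data.frame(tips = I(list(c("A", "B"))), rate = 2)
  got <- applyStack(toy3, modelSpec("OU", alpha = 1),
                    stackSpec("lrates", lrates = lr))$vcv
  outree <- rescaleTree(toy3, modelSpec("OU", alpha = 1))
  manual <- outree$edge.length
  inAB <- outree$edge[, 2] %in% c(which(outree$tip.label %in% c("A", "B")),
                                  ape::getMRCA(outree, c("A", "B")))
  manual[inAB] <- manual[inAB] * 2
  outree$edge.length <- manual
  expect_equal(got, phyloVCV(outree))
  expect_error(applyStack(toy3, modelSpec("white"),
                          stackSpec("lrates", lrates = lr)), "white noise")
})

test_that("all 44 catalog combinations give PSD covariance, finite means", {
  tr <- bal6
  shapeArgs <- list(
    BM = list(), white = list(),
    OU = list(alpha = 0.7), EB = list(a = -0.5),
    lambda = list(lambda = 0.6), delta = list(delta = 1.8),
    kappa = list(kappa = 0.5), trend = list(slope = 0.4),
    depth = list(depth = 2),
    lrates = list(rates = data.frame(tips = I(list(c("A", "B"))), rate = 2)),
    nrates = list(intervals = data.frame(start = 1, end = 2, rate = 0.5)))
  stacks <- list(
    standard = stackSpec("standard"),
    lrates = stackSpec("lrates",
                       lrates = data.frame(tips = I(list(c("C", "D"))),
                                           rate = 3),
                       nrates = data.frame(start = 0.5, end = 1.5,
                                           rate = 1.5)),
    AncShifts = stackSpec("AncShifts",
                          shifts = data.frame(tips = I(list(c("E", "F"))),
                                              shift = 3)),
    `lrates+AncShifts` = stackSpec(
      "lrates+AncShifts",
      lrates = data.frame(tips = I(list(c("C", "D"))), rate = 3),
      shifts = data.frame(tips = I(list(c("E", "F"))), shift = 3)))
  cat <- modelCatalog()
  n_ok <- 0L
  for (r in seq_len(nrow(cat))) {
    m <- cat$primary[r]; smode <- cat$stacking[r]
    spec <- do.call(modelSpec, c(list(model = m), shapeArgs[[m]]))
    if (m == "white" && smode %in% c("lrates", "lrates+AncShifts")) {
      expect_error(applyStack(tr, spec, stacks[[smode]]), "white noise")
      next
    }
    st <- applyStack(tr, spec, stacks[[smode]])
    ev <- eigen(st$vcv, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * max(abs(ev)))
    expect_true(all(is.finite(st$mean)))
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 42L)   # 44 minus the two impossible white+rates cells
})

test_that("simulated tip means track the shift-adjusted mean vector", {
  sh <- stackSpec("AncShifts", shifts = data.frame(tips = I(list(c("A", "B"))),
                                                   shift = 5))
  st <- applyStack(toy3, modelSpec("BM"), sh)
  set.seed(42)
  n <- 1e4
  sums <- rep(0, 3)
  for (i in seq_len(n)) sums <- sums + simulateReplicate(st$vcv, st$mean)[, 1]
  emp <- sums / n
  se <- sqrt(diag(st$vcv) / n)
  expect_true(all(abs(emp - st$mean) < 3 * se))
})
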
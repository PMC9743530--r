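test_that("the simulator is a pure function of its configuration", {
  sim <- smallSim()
  a <- simulateReference(sim)
  b <- simulateReference(sim)
  expect_identical(a$expression, b$expression)
  expect_identical(a$markers, b$markers)

  pa <- simulateProgenitors(sim, a)
  pb <- simulateProgenitors(sim, b)
  expect_identical(pa$expression, pb$expression)

  da <- simulateDoublets(sim, a)
  db <- simulateDoublets(sim, b)
  expect_identical(da$expression, db$expression)

  # the three outputs draw from independent seeded streams: disjoint ids
  ids <- c(rownames(a$expression), rownames(pa$expression),
           rownames(da$expression))
  expect_false(anyDuplicated(ids) > 0)

  simB <- smallSim(seed = 8)
  expect_false(identical(simulateReference(simB)$expression, a$expression))
})

test_that("markers are elevated in their own type and nowhere else", {
  sim <- smallSim()
  ref <- simulateReference(sim)
  for (tp in levels(ref$labels)) {
    own <- ref$expression[ref$labels == tp, ref$markers[[tp]], drop = FALSE]
    other <- ref$expression[ref$labels != tp, ref$markers[[tp]], drop = FALSE]
    expect_gt(mean(own), mean(other) + 0.5)
  }
  # disjoint marker sets
  allMk <- unlist(ref$markers)
  expect_identical(anyDuplicated(allMk), 0L)
})

test_that("a zero marker fold is a no-signal control with chance accuracy", {
  sim <- simConfig(nTypes = 3, nGenes = 60, markersPerType = 8,
                   markerLogFold = 0, cellsPerType = 40, seed = 7)
  ref <- simulateReference(sim)
  sp <- splitTrainTest(ref$expression, ref$labels, testSize = 0.25, randoms = 1)
  cfg <- capsConfig(3, 60, dimCapsule = 6, epochs = 6, lr = 0.005, seed = 7)
  fit <- trainCapsNet(sp$xTrain, sp$yTrain, cfg)
  acc <- mean(suppressWarnings(predict(fit, sp$xTest))$labels == sp$yTest)
  expect_lt(acc, 0.6)   # chance is 1/3
})

test_that("progenitor means are affine in the planted coordinate", {
  # Monte-Carlo check of the generator's analytic expectation at large n
  sim <- simConfig(nTypes = 3, nGenes = 30, markersPerType = 5,
                   cellsPerType = 10, progenitorGrid = c(0, 0.5, 1),
                   progenitorsPerT = 2000, seed = 3)
  ref <- simulateReference(sim)
  prog <- simulateProgenitors(sim, ref, lineages = 1)
  mk <- ref$markers$type1
  base <- sim$baselineMean
  elev <- base * exp(sim$markerLogFold)
  for (tt in c(0, 0.5, 1)) {
    cells <- prog$expression[prog$truth$t == tt, mk, drop = FALSE]
    wantMean <- (1 - tt) * base + tt * elev        # count-scale expectation
    gotMean <- mean(expm1(cells))                  # unwind the log1p
    expect_equal(gotMean, wantMean, tolerance = 0.08)
  }

  # endpoints: t = 0 equals the root for every lineage, t = 1 the type mean
  progAll <- simulateProgenitors(sim, ref)
  at0 <- progAll$expression[progAll$truth$t == 0, , drop = FALSE]
  byLin <- split(seq_len(nrow(at0)),
                 progAll$truth$lineage[progAll$truth$t == 0])
  m <- vapply(byLin, function(ix) mean(expm1(at0[ix, ])), numeric(1))
  expect_lt(diff(range(m)), 0.05)                  # lineages coincide at root
})

test_that("doublets carry both parents' marker programs", {
  sim <- simConfig(nTypes = 3, nGenes = 30, markersPerType = 5,
                   cellsPerType = 10, doubletPairs = list(c(1, 2)),
                   doubletsPerPair = 2000, seed = 3)
  ref <- simulateReference(sim)
  dbl <- simulateDoublets(sim, ref)
  elev <- sim$baselineMean * exp(sim$markerLogFold)
  for (tp in c("type1", "type2")) {
    mk <- ref$markers[[tp]]
    got <- mean(expm1(dbl$expression[, mk]))
    # A markers in an (A,B) doublet: A's elevated mean + B's baseline
    expect_equal(got, elev + sim$baselineMean, tolerance = 0.08)
  }

  expect_error(simConfig(nTypes = 3, nGenes = 30, markersPerType = 5,
                         doubletPairs = list(c(2, 2))), "distinct")
})

test_that("infeasible configurations are rejected", {
  expect_error(simConfig(nTypes = 5, nGenes = 50, markersPerType = 20),
               "infeasible marker allocation")
  expect_error(simConfig(progenitorGrid = c(-0.1, 0.5)), "\\[0, 1\\]")
  sim <- smallSim()
  simEmpty <- sim; simEmpty$progenitorGrid <- numeric()
  ref <- simulateReference(sim)
  expect_error(simulateProgenitors(simEmpty, ref), "empty")
})

test_that("the lognormal noise alternative is wired and seeded", {
  sim <- simConfig(nTypes = 3, nGenes = 30, markersPerType = 5,
                   cellsPerType = 20, noise = "lognormal", seed = 4)
  a <- simulateReference(sim)
  b <- simulateReference(sim)
  expect_identical(a$expression, b$expression)
  expect_true(all(is.finite(a$expression)))
  # lognormal counts are continuous, NB counts integral
  nb <- simulateReference(simConfig(nTypes = 3, nGenes = 30, markersPerType = 5,
                                    cellsPerType = 20, seed = 4))
  expect_true(all(expm1(nb$expression) - round(expm1(nb$expression)) < 1e-8))
  expect_false(all(abs(expm1(a$expression) - round(expm1(a$expression))) < 1e-8))
})
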
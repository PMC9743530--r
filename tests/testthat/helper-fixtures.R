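# Shared fixtures. Small models/datasets are built fresh per test; the
# full-scale study fixture (default simulator conditions + trained models)
# is built lazily once and cached for the session.

# a tiny fully deterministic model with hand-set weights (l=2, d=2, G=3)
makeTinyModel <- function(activation = "relu", routingIterations = 3L) {
  cfg <- capsConfig(nTypes = 2, nGenes = 3, dimCapsule = 2,
                    activation = activation,
                    routingIterations = routingIterations,
                    epochs = 1, seed = 1)
  Wp <- array(0, c(2, 2, 3))
  Wp[1, , ] <- rbind(c(0.5, -0.2, 0.1),
                     c(0.3, 0.4, -0.6))
  Wp[2, , ] <- rbind(c(-0.1, 0.2, 0.7),
                     c(0.8, -0.3, 0.2))
  bp <- rbind(c(0.05, -0.1), c(0.0, 0.2))
  Wt <- array(0, c(2, 2, 2, 2))
  Wt[1, 1, , ] <- rbind(c(1.2, 0.1), c(-0.3, 0.9))
  Wt[1, 2, , ] <- rbind(c(0.4, -0.5), c(0.6, 0.2))
  Wt[2, 1, , ] <- rbind(c(-0.2, 0.8), c(0.5, 0.1))
  Wt[2, 2, , ] <- rbind(c(0.9, 0.3), c(-0.4, 1.1))
  methods::new("CapsuleModel",
    config = cfg, primaryWeights = Wp, primaryBias = bp,
    transformWeights = Wt, typeNames = c("alpha", "beta"),
    geneIds = c("g1", "g2", "g3"), trainLoss = numeric())
}

# a small, quick-to-train simulated dataset for unit tests
smallSim <- function(seed = 7, nTypes = 3, nGenes = 60, cellsPerType = 40) {
  simConfig(nTypes = nTypes, nGenes = nGenes, markersPerType = 8,
            cellsPerType = cellsPerType,
            progenitorGrid = c(0.2, 0.5, 0.8), progenitorsPerT = 10,
            doubletPairs = list(c(1, 2)), doubletsPerPair = 20, seed = seed)
}

smallModelConfig <- function(sim, epochs = 12, seed = 7) {
  capsConfig(nTypes = sim$nTypes, nGenes = sim$nGenes,
             dimCapsule = 2 * sim$nTypes, epochs = epochs,
             lr = 0.005, seed = seed)
}

# independent per-type recall used as a test oracle
.perTypeRecallHelper <- function(fit, x, y) {
  pr <- suppressWarnings(predict(fit, x))
  vapply(typeNames(fit), function(tp) mean(pr$labels[y == tp] == tp),
         numeric(1))
}

# --- full-scale study fixture (simulator defaults; trained models cached) ---
.studyCache <- new.env(parent = emptyenv())

studyData <- function() {
  if (is.null(.studyCache$data)) {
    sc <- simConfig(seed = 1)
    ref <- simulateReference(sc)
    .studyCache$data <- list(
      sc = sc, ref = ref,
      prog = simulateProgenitors(sc, ref),
      dbl = simulateDoublets(sc, ref)
    )
  }
  .studyCache$data
}

# study model configuration: capsule dimension twice the number of types,
# as the method recommends; training long enough for the margin loss to
# plateau on this data scale
studyModel <- function(seed = 1) {
  key <- paste0("model", seed)
  if (is.null(.studyCache[[key]])) {
    d <- studyData()
    sp <- splitTrainTest(d$ref$expression, d$ref$labels,
                         testSize = 0.1, randoms = seed)
    cfg <- capsConfig(nTypes = d$sc$nTypes, nGenes = d$sc$nGenes,
                      dimCapsule = 2 * d$sc$nTypes, epochs = 60,
                      lr = 0.005, seed = seed)
    .studyCache[[key]] <- list(
      fit = trainCapsNet(sp$xTrain, sp$yTrain, cfg),
      split = sp
    )
  }
  .studyCache[[key]]
}
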
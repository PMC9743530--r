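test_that("overall heatmap stacks effective type-capsule rows", {
  a <- matrix(c(0.8, 0, 0, 0.1), 2, 2)
  b <- matrix(c(0.2, 0, 0, 0.6), 2, 2)
  expect_equal(overallHeatmap(list(a, b)),
               matrix(c(0.8, 0, 0, 0.6), 2, 2))
  expect_equal(overallHeatmap(list(diag(2), diag(2))), diag(2))
  expect_error(overallHeatmap(list(diag(2), diag(3))), "l x l")
})

test_that("coupling averages are arithmetic means with zero off-diagonals", {
  sim <- smallSim()
  ref <- simulateReference(sim)
  fit <- trainCapsNet(ref$expression, ref$labels,
                      smallModelConfig(sim, epochs = 6))
  cs <- averageCoupling(fit, ref$expression, ref$labels)

  for (m in couplingPerType(cs)) {
    expect_true(all(m[row(m) != col(m)] == 0))
    expect_true(all(diag(m) >= 0 & diag(m) <= 1))
  }
  expect_identical(couplingOverall(cs),
                   overallHeatmap(couplingPerType(cs)))

  # averaging is linear: over two equal-sized groups (each covering every
  # type) the concatenated average is the mean of the group averages
  byType <- split(seq_along(ref$labels), ref$labels)
  g1 <- unlist(lapply(byType, function(ix) ix[1:10]))
  g2 <- unlist(lapply(byType, function(ix) ix[11:20]))
  csA <- averageCoupling(fit, ref$expression[g1, ], ref$labels[g1])
  csB <- averageCoupling(fit, ref$expression[g2, ], ref$labels[g2])
  csAB <- averageCoupling(fit, ref$expression[c(g1, g2), ],
                          ref$labels[c(g1, g2)])
  expect_equal(couplingPerType(csAB)[[1]],
               (couplingPerType(csA)[[1]] + couplingPerType(csB)[[1]]) / 2,
               tolerance = 1e-12)

  # with a single cell of type1, that type's average is the cell's own
  # final masked coupling matrix
  oneIdx <- c(byType$type1[1], byType$type2[1:2], byType$type3[1:2])
  one <- averageCoupling(fit, ref$expression[oneIdx, ], ref$labels[oneIdx])
  fw <- capsForward(ref$expression[byType$type1[1], ], fit)
  expect_equal(unname(couplingPerType(one)[["type1"]][1, 1]),
               fw$coupling[1, 1], tolerance = 1e-12)

  idx <- byType$type1
  expect_error(averageCoupling(fit, ref$expression[idx, ],
                               factor(rep("type1", length(idx)),
                                      levels = typeNames(fit))),
               "no cells for type")
})

test_that("gene embeddings match an eigendecomposition oracle up to sign", {
  set.seed(61)
  model <- makeTinyModel()
  # swap in a larger random encoder for a meaningful PCA
  cfg <- capsConfig(nTypes = 2, nGenes = 50, dimCapsule = 8)
  Wp <- array(rnorm(2 * 8 * 50), c(2, 8, 50))
  m <- methods::new("CapsuleModel", config = cfg, primaryWeights = Wp,
                    primaryBias = matrix(0, 2, 8),
                    transformWeights = array(0, c(2, 2, 8, 8)),
                    typeNames = c("a", "b"),
                    geneIds = sprintf("g%02d", 1:50), trainLoss = numeric())
  emb <- pcaGeneEmbedding(m, 1)

  G <- t(matrix(Wp[1, , ], 8, 50))            # genes x d
  Gc <- scale(G, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Gc))
  oracle1 <- Gc %*% ev$vectors[, 1]
  oracle2 <- Gc %*% ev$vectors[, 2]
  matchUpToSign <- function(got, want) {
    min(max(abs(got - want)), max(abs(got + want)))
  }
  expect_lt(matchUpToSign(emb$coordinates$PC1, oracle1), 1e-8)
  expect_lt(matchUpToSign(emb$coordinates$PC2, oracle2), 1e-8)
  expect_gte(emb$varExplained[1], emb$varExplained[2])

  # deterministic sign: the largest-|coordinate| gene is positive
  expect_gt(emb$coordinates$PC1[which.max(abs(emb$coordinates$PC1))], 0)

  # centering invariance: adding a constant vector to every gene column
  m2 <- m
  m2@primaryWeights[1, , ] <- m2@primaryWeights[1, , ] + rnorm(8)
  emb2 <- pcaGeneEmbedding(m2, 1)
  expect_equal(emb2$coordinates$PC1, emb$coordinates$PC1, tolerance = 1e-8)

  # one distinctive gene is the unique PC1 extreme, the rest coincide
  m3 <- m
  m3@primaryWeights[1, , ] <- 0.3
  m3@primaryWeights[1, , 7] <- 5
  emb3 <- pcaGeneEmbedding(m3, 1)
  expect_identical(which.max(abs(emb3$coordinates$PC1)), 7L)
  expect_lt(diff(range(emb3$coordinates$PC1[-7])), 1e-8)

  # fully degenerate weights: warning and zero coordinates
  m4 <- m
  m4@primaryWeights[1, , ] <- 1
  expect_warning(emb4 <- pcaGeneEmbedding(m4, 1), "identical")
  expect_true(all(emb4$coordinates$PC1 == 0))
})

test_that("the PC1 masking scan starts at baseline and ends degenerate", {
  sim <- smallSim()
  ref <- simulateReference(sim)
  sp <- splitTrainTest(ref$expression, ref$labels, testSize = 0.25, randoms = 1)
  fit <- trainCapsNet(sp$xTrain, sp$yTrain, smallModelConfig(sim))

  scan <- scanPC1Accuracy(fit, sp$xTest, sp$yTest, "type1", pcSlice = 10)
  expect_identical(nrow(scan$curve), 11L)

  base <- .perTypeRecallHelper(fit, sp$xTest, sp$yTest)
  expect_equal(scan$curve[1, ], base)

  # after masking every slice the input is all-zero: the prediction is the
  # constant all-zero-input prediction
  xZero <- sp$xTest; xZero[] <- 0
  przero <- suppressWarnings(predict(fit, xZero))
  expect_equal(unname(scan$curve[11, "type1"]),
               mean(przero$labels[sp$yTest == "type1"] == "type1"))

  expect_error(scanPC1Accuracy(fit, sp$xTest, sp$yTest, "type1",
                               pcSlice = 1000), "exceeds")
  expect_error(scanPC1Accuracy(fit, sp$xTest, sp$yTest, "nope"), "unknown")
})

test_that("gene selection applies the first-crossing rule", {
  fakeScan <- structure(list(
    curve = matrix(c(0.98, 0.97, 0.40, 0.10, 0.05,
                     1.00, 1.00, 0.99, 0.99, 0.98), ncol = 2,
                   dimnames = list(0:4, c("t1", "t2"))),
    sliceGenes = list(c("gA", "gB"), c("gC"), c("gD", "gE"), c("gF")),
    type = "t1", end = "high", pc = 1L, pcSlice = 4L, embedding = NULL),
    class = "capsGeneScan")

  sel <- selectTypeGenes(fakeScan, threshold = 0.9)
  expect_identical(sel$crossingSlice, 2L)
  expect_setequal(sel$selectedGenes, c("gA", "gB", "gC"))
  expect_identical(sel$table$selected,
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

  # threshold above the baseline accuracy crosses at the first slice
  selHigh <- selectTypeGenes(fakeScan, threshold = 0.99)
  expect_identical(selHigh$crossingSlice, 1L)

  # never crossed: empty selection with a warning
  neverScan <- fakeScan
  neverScan$curve[, "t1"] <- 0.99
  expect_warning(selNever <- selectTypeGenes(neverScan, threshold = 0.5),
                 "never fell")
  expect_length(selNever$selectedGenes, 0)

  expect_error(selectTypeGenes(fakeScan, threshold = 1.2), "threshold")
  expect_error(selectTypeGenes(list(), 0.5), "scanPC1Accuracy")
})
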
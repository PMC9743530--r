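test_that("squash shrinks norms into [0,1) and preserves direction", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))

  u <- c(1, 0, 0)
  expect_equal(sqrt(sum(squash(u)^2)), 0.5)

  s <- c(3, 0)
  v <- squash(s)
  expect_equal(sqrt(sum(v^2)), 0.9)
  expect_equal(v / sqrt(sum(v^2)), s / sqrt(sum(s^2)))

  set.seed(11)
  for (i in 1:20) {
    s <- rnorm(4) * 10^runif(1, -2, 2)
    v <- squash(s)
    nv <- sqrt(sum(v^2))
    expect_true(nv >= 0 && nv < 1)
    expect_equal(v * sqrt(sum(s^2)), s * nv, tolerance = 1e-12)
  }
})

test_that("encodePrimary matches a brute-force dot-product oracle", {
  # zero input with zero bias stays zero under relu
  w <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  expect_equal(encodePrimary(rep(0, 4), w, activation = "relu"),
               matrix(0, 2, 3))

  # identity weights: relu clips negatives, passes positives
  wi <- array(0, c(1, 3, 3)); wi[1, , ] <- diag(3)
  x <- c(1, -2, 3)
  expect_equal(encodePrimary(x, wi, activation = "relu"),
               matrix(c(1, 0, 3), 1, 3))

  # random weights vs an independent elementwise oracle
  set.seed(21)
  l <- 2; d <- 3; g <- 4
  w <- array(rnorm(l * d * g), c(l, d, g))
  b <- matrix(rnorm(l * d), l, d)
  x <- rexp(g)
  got <- encodePrimary(x, w, b, "relu")
  for (i in seq_len(l)) for (a in seq_len(d)) {
    acc <- b[i, a]
    for (gg in seq_len(g)) acc <- acc + w[i, a, gg] * x[gg]
    expect_equal(got[i, a], max(acc, 0), tolerance = 1e-6)
  }
  # tanh branch against the same oracle
  gotT <- encodePrimary(x, w, b, "tanh")
  expect_equal(gotT[1, 1], tanh(sum(w[1, 1, ] * x) + b[1, 1]), tolerance = 1e-12)

  expect_error(encodePrimary(rep(0, 5), w), "expect")
})

test_that("the identity mask zeroes off-diagonals and keeps the diagonal", {
  expect_equal(applyRoutingMask(matrix(1 / 3, 3, 3)), diag(1 / 3, 3))

  dg <- diag(c(0.2, 0.5, 0.9))
  expect_equal(applyRoutingMask(dg), dg)

  m <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE)
  expect_equal(applyRoutingMask(m), matrix(c(0.3, 0, 0, 0.4), 2, 2, byrow = TRUE))

  expect_error(applyRoutingMask(matrix(0, 2, 3)), "square")
  expect_error(applyRoutingMask(matrix(0, 2, 2), diag(3)), "shape")
})

test_that("masked routing matches a step-by-step scripted recomputation", {
  # single capsule: coupling is 1 after softmax * mask, output is squash(uhat)
  p1 <- array(c(2, 1), c(1, 1, 2))
  r1 <- maskedDynamicRouting(p1, iterations = 3)
  expect_equal(r1$coupling, matrix(1, 1, 1))
  expect_equal(r1$v[1, ], squash(c(2, 1)))

  # zero logits at the first iteration: masked coupling is diag(1/l)
  set.seed(31)
  p2 <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  r2 <- maskedDynamicRouting(p2, iterations = 1)
  expect_equal(r2$coupling, diag(0.5, 2))
  expect_equal(r2$couplingPreMask, matrix(0.5, 2, 2))

  # independent scripted oracle of the same update rule, 3 iterations
  oracle <- function(pred, iters) {
    l <- dim(pred)[1]
    b <- matrix(0, l, l)
    for (r in seq_len(iters)) {
      cpre <- t(apply(b, 1, function(row) exp(row) / sum(exp(row))))
      cm <- cpre * diag(l)
      s <- matrix(0, l, dim(pred)[3])
      for (j in seq_len(l)) {
        for (i in seq_len(l)) s[j, ] <- s[j, ] + cm[i, j] * pred[i, j, ]
      }
      v <- t(apply(s, 1, squash))
      if (r < iters) {
        for (i in seq_len(l)) for (j in seq_len(l))
          b[i, j] <- b[i, j] + sum(pred[i, j, ] * v[j, ])
      }
    }
    list(v = v, coupling = cm)
  }
  got <- maskedDynamicRouting(p2, iterations = 3)
  want <- oracle(p2, 3)
  expect_equal(got$v, want$v, tolerance = 1e-6)
  expect_equal(got$coupling, want$coupling, tolerance = 1e-6)

  expect_error(maskedDynamicRouting(p2, iterations = 0), "iterations")
})

test_that("routing invariants hold for random prediction arrays", {
  set.seed(41)
  for (rep in 1:10) {
    l <- sample(2:5, 1); d <- sample(2:4, 1)
    p <- array(rnorm(l * l * d, sd = 2), c(l, l, d))
    out <- maskedDynamicRouting(p, iterations = 3)
    expect_equal(rowSums(out$couplingPreMask), rep(1, l), tolerance = 1e-6)
    offdiag <- out$coupling[row(out$coupling) != col(out$coupling)]
    expect_identical(unique(offdiag), 0)
    expect_true(all(out$lengths >= 0 & out$lengths < 1))
  }
})

test_that("margin loss matches its closed forms and is zero only on-margin", {
  cfg2 <- capsConfig(nTypes = 2, nGenes = 10)
  expect_equal(marginLoss(c(0.9, 0.1), c(1, 0), cfg2), 0)
  expect_equal(marginLoss(c(0.9, 0.6), c(1, 0), cfg2), 0.25 * 0.5^2)

  # degenerate single-capsule case: L = (0.9 - 0)^2
  cfgNarrow <- capsConfig(nTypes = 2, nGenes = 10)
  expect_equal(marginLoss(c(0, 0.1), c(1, 0), cfgNarrow), 0.81)

  expect_error(marginLoss(c(0.5, 0.5), c(1, 1), cfg2), "one-hot")
  expect_error(marginLoss(c(0.5, 0.5), c(0, 0), cfg2), "one-hot")

  set.seed(51)
  for (i in 1:20) {
    P <- runif(4)
    lab <- diag(4)[sample(4, 1), ]
    cfg4 <- capsConfig(nTypes = 4, nGenes = 10)
    L <- marginLoss(P, lab, cfg4)
    expect_true(L >= 0)
    satisfied <- P[lab == 1] >= 0.9 && all(P[lab == 0] <= 0.1)
    expect_identical(L == 0, satisfied)
  }
})

test_that("shuffle splits are disjoint, exhaustive and reproducible", {
  x <- matrix(0, 100, 5)
  sp <- splitTrainTest(x, testSize = 0.1, randoms = 3)
  expect_length(sp$testIdx, 10)
  expect_length(sp$trainIdx, 90)
  expect_identical(sort(c(sp$trainIdx, sp$testIdx)), 1:100)
  expect_length(intersect(sp$trainIdx, sp$testIdx), 0)

  sp2 <- splitTrainTest(x, testSize = 0.1, randoms = 3)
  expect_identical(sp$testIdx, sp2$testIdx)
  sp3 <- splitTrainTest(x, testSize = 0.1, randoms = 4)
  expect_false(identical(sp$testIdx, sp3$testIdx))

  expect_error(splitTrainTest(x, testSize = 0), "testSize")
  expect_error(splitTrainTest(matrix(0, 1, 2)), "two cells")
})
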
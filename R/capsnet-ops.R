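#' Build a capsule-network configuration
#'
#' @description
#' Constructs a validated [CapsuleConfig-class]. The defaults follow the
#' method's conventions: capsule dimension 16 (a value of roughly twice the
#' number of cell types is recommended for small type counts), ReLU encoders,
#' 3 routing iterations, and the margin-loss constants `m+ = 0.9`,
#' `m- = 0.1`, `lambda = 0.25`.
#'
#' @param nTypes number of cell types `l` (>= 2).
#' @param nGenes number of genes `G` in the training matrix.
#' @param dimCapsule capsule dimension `d`; default 16.
#' @param activation encoder activation, `"relu"` (default) or `"tanh"`.
#' @param routingIterations dynamic-routing iterations; default 3.
#' @param lr Adam learning rate; default 0.001. If training loss becomes
#'   non-finite, reduce it.
#' @param batchSize minibatch size; default 32.
#' @param epochs training epochs; default 30.
#' @param mPlus,mMinus,lambdaDown margin-loss constants; defaults 0.9, 0.1,
#'   0.25.
#' @param seed integer seed fixing weight initialization and batch shuffling.
#' @return a [CapsuleConfig-class] object.
#' @examples
#' capsConfig(nTypes = 5, nGenes = 500)
#' @export
capsConfig <- function(nTypes, nGenes, dimCapsule = 16L, activation = "relu",
                       routingIterations = 3L, lr = 0.001, batchSize = 32L,
                       epochs = 30L, mPlus = 0.9, mMinus = 0.1,
                       lambdaDown = 0.25, seed = 1L) {
  methods::new("CapsuleConfig",
    nTypes = as.integer(nTypes), nGenes = as.integer(nGenes),
    dimCapsule = as.integer(dimCapsule),
    activation = match.arg(activation, c("relu", "tanh")),
    routingIterations = as.integer(routingIterations),
    lr = as.numeric(lr), batchSize = as.integer(batchSize),
    epochs = as.integer(epochs), mPlus = as.numeric(mPlus),
    mMinus = as.numeric(mMinus), lambdaDown = as.numeric(lambdaDown),
    seed = as.integer(seed)
  )
}

#' Squash nonlinearity
#'
#' @description
#' Shrinks a vector's Euclidean norm into `[0, 1)` while preserving its
#' direction: `v = (|s|^2 / (1 + |s|^2)) * (s / |s|)`. The output norm is the
#' capsule's (unnormalized) probability. The zero vector maps to the zero
#' vector.
#'
#' @param s a finite numeric vector.
#' @return a numeric vector parallel to `s` with norm `|s|^2 / (1 + |s|^2)`.
#' @examples
#' sqrt(sum(squash(c(3, 0))^2)) # 0.9
#' @export
squash <- function(s) {
  stopifnot(is.numeric(s), all(is.finite(s)))
  n2 <- sum(s * s)
  if (n2 == 0) return(s * 0)
  # v = (n2 / (1 + n2)) * s / sqrt(n2) = s * sqrt(n2) / (1 + n2)
  s * (sqrt(n2) / (1 + n2))
}

## row-wise squash of an n x d matrix; returns list(v, norm) where norm is the
## pre-squash row norm |s|
.squashRows <- function(s) {
  nrm <- sqrt(rowSums(s * s))
  scale <- ifelse(nrm > 0, nrm / (1 + nrm^2), 0)
  list(v = s * scale, norm = nrm)
}

#' Encode a cell into its per-type primary capsules
#'
#' @description
#' Applies the `l` per-type encoder networks to one expression profile:
#' primary capsule `i` is `activation(W_i x + b_i)`, a dense layer per cell
#' type followed by ReLU or tanh.
#'
#' @param x numeric `G`-vector of log-scale expression values.
#' @param weights `l x d x G` array of encoder matrices (or a list of `l`
#'   `d x G` matrices).
#' @param bias optional `l x d` matrix (or list of `d`-vectors) of encoder
#'   biases; zero if `NULL`.
#' @param activation `"relu"` or `"tanh"`.
#' @return an `l x d` matrix; row `i` is primary capsule `u_i`.
#' @examples
#' w <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
#' encodePrimary(rexp(4), w, activation = "relu")
#' @export
encodePrimary <- function(x, weights, bias = NULL, activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  if (is.list(weights)) {
    weights <- aperm(simplify2array(weights), c(3, 1, 2))
  }
  stopifnot(length(dim(weights)) == 3)
  l <- dim(weights)[1]; d <- dim(weights)[2]; g <- dim(weights)[3]
  if (length(x) != g) {
    stop(sprintf("input has %d genes but encoder weights expect %d",
                 length(x), g))
  }
  if (is.null(bias)) bias <- matrix(0, l, d)
  if (is.list(bias)) bias <- do.call(rbind, bias)
  u <- matrix(0, l, d)
  for (i in seq_len(l)) {
    a <- drop(matrix(weights[i, , ], d, g) %*% x) + bias[i, ]
    u[i, ] <- if (activation == "relu") pmax(a, 0) else tanh(a)
  }
  u
}

#' Mask coupling coefficients
#'
#' @description
#' Element-wise product of the coupling-coefficient matrix with the identity
#' mask: off-diagonal couplings are zeroed and diagonal couplings kept as-is
#' (no renormalization), which forces each primary capsule to feed exactly its
#' own type capsule.
#'
#' @param coupling square `l x l` matrix of coupling coefficients (rows index
#'   primary capsules, columns type capsules).
#' @param mask `l x l` binary mask; defaults to (and must be) the identity.
#' @return the masked `l x l` matrix.
#' @examples
#' applyRoutingMask(matrix(1/3, 3, 3))
#' @export
applyRoutingMask <- function(coupling, mask = diag(nrow(coupling))) {
  if (!is.matrix(coupling) || nrow(coupling) != ncol(coupling))
    stop("coupling must be a square matrix")
  if (!identical(dim(mask), dim(coupling)))
    stop("mask shape must match the coupling matrix")
  coupling * mask
}

## row-wise softmax (over columns) with max subtraction for stability
.softmaxRows <- function(b) {
  e <- exp(b - apply(b, 1, max))
  e / rowSums(e)
}

#' Masked dynamic routing for a single sample
#'
#' @description
#' Runs the masked routing iterations on the prediction vectors of one cell.
#' Per iteration: coupling coefficients are the row-wise softmax of the
#' routing logits (softmax across type capsules for each primary capsule),
#' they are multiplied element-wise by the identity mask, each type capsule's
#' input is the mask-weighted sum of prediction vectors (so only the
#' same-index prediction survives), the capsule is squashed, and all logits
#' are updated by the agreement between prediction vectors and outputs.
#' Logits start at zero, so the first-iteration diagonal coupling is `1/l`.
#'
#' @param predictions `l x l x d` array; `predictions[i, j, ]` is the
#'   prediction vector for type capsule `j` from primary capsule `i`.
#' @param iterations number of routing iterations (>= 1); default 3.
#' @return a list with `s` (`l x d` pre-squash inputs), `v` (`l x d` type
#'   capsules), `lengths` (the `l` capsule norms, each in `[0, 1)`),
#'   `coupling` (final masked `l x l` coefficients) and `couplingPreMask`
#'   (the final softmax output before masking; rows sum to 1).
#' @examples
#' p <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
#' maskedDynamicRouting(p, iterations = 3)$lengths
#' @export
maskedDynamicRouting <- function(predictions, iterations = 3L) {
  if (iterations < 1) stop("iterations must be >= 1")
  dm <- dim(predictions)
  if (length(dm) != 3 || dm[1] != dm[2])
    stop("predictions must be an l x l x d array")
  l <- dm[1]; d <- dm[3]
  b <- matrix(0, l, l)
  cpre <- cmask <- NULL
  v <- s <- matrix(0, l, d)
  for (r in seq_len(iterations)) {
    cpre <- .softmaxRows(b)
    cmask <- applyRoutingMask(cpre)
    for (j in seq_len(l)) s[j, ] <- cmask[j, j] * predictions[j, j, ]
    sq <- .squashRows(s)
    v <- sq$v
    if (r < iterations) {
      for (i in seq_len(l)) for (j in seq_len(l)) {
        b[i, j] <- b[i, j] + sum(predictions[i, j, ] * v[j, ])
      }
    }
  }
  list(s = s, v = v, lengths = sqrt(rowSums(v * v)),
       coupling = cmask, couplingPreMask = cpre)
}

#' Forward pass of a capsule model on one cell
#'
#' @description
#' Composes the three stages of the classifier on a single expression profile:
#' per-type encoding into primary capsules, per-pair capsule transformation
#' into prediction vectors, and masked dynamic routing into type capsules.
#' The returned lengths are unnormalized probabilities: each lies in `[0, 1)`
#' but no constraint ties their sum to 1.
#'
#' @param x numeric `G`-vector in the model's gene order.
#' @param model a trained [CapsuleModel-class].
#' @return as [maskedDynamicRouting()], plus `u` (the `l x d` primary
#'   capsules).
#' @seealso [predict,CapsuleModel-method] for whole matrices with gene
#'   alignment.
#' @export
capsForward <- function(x, model) {
  cfg <- model@config
  if (length(x) != cfg@nGenes) {
    stop(sprintf("expected an expression vector of %d genes (model gene set), got %d",
                 cfg@nGenes, length(x)))
  }
  u <- encodePrimary(x, model@primaryWeights, model@primaryBias, cfg@activation)
  l <- cfg@nTypes; d <- cfg@dimCapsule
  uhat <- array(0, c(l, l, d))
  for (i in seq_len(l)) for (j in seq_len(l)) {
    uhat[i, j, ] <- drop(matrix(model@transformWeights[i, j, , ], d, d) %*% u[i, ])
  }
  out <- maskedDynamicRouting(uhat, cfg@routingIterations)
  out$u <- u
  out
}

#' Margin loss of one prediction
#'
#' @description
#' The per-sample classification loss: summed over type capsules `k`,
#' `T_k * max(0, m+ - P_k)^2 + lambda * (1 - T_k) * max(0, P_k - m-)^2`,
#' where `T_k` is 1 for the labelled type and 0 otherwise. The loss is zero
#' exactly when the true type's length reaches `m+` and every other length is
#' at most `m-`.
#'
#' @param lengths numeric vector of `l` type-capsule lengths in `[0, 1]`.
#' @param label one-hot numeric vector of length `l` (exactly one 1).
#' @param config a [CapsuleConfig-class] supplying `m+`, `m-` and `lambda`.
#' @return a nonnegative scalar.
#' @examples
#' cfg <- capsConfig(nTypes = 2, nGenes = 10)
#' marginLoss(c(0.9, 0.6), c(1, 0), cfg) # 0.25 * 0.5^2 = 0.0625
#' @export
marginLoss <- function(lengths, label, config) {
  if (length(label) != length(lengths) || sum(label == 1) != 1 ||
      any(!label %in% c(0, 1))) {
    stop("label must be a one-hot vector matching the lengths")
  }
  stopifnot(all(lengths >= 0), all(lengths <= 1))
  sum(label * pmax(0, config@mPlus - lengths)^2 +
      config@lambdaDown * (1 - label) * pmax(0, lengths - config@mMinus)^2)
}

#' Shuffle-split cells into training and held-out sets
#'
#' @description
#' Random disjoint, exhaustive partition of cells, with the held-out fraction
#' given by `testSize` (default 0.1, the 9:1 evaluation split). `randoms`
#' seeds the shuffle, so the same value reproduces the same partition; the
#' caller's RNG state is left untouched.
#'
#' @param x cells-x-genes matrix (or anything with rows).
#' @param y optional per-cell labels, subset alongside `x` when given.
#' @param testSize held-out fraction in (0, 1); default 0.1.
#' @param randoms integer seed controlling the shuffle; default 0.
#' @return a list with `trainIdx`, `testIdx`, and (when `x` is a matrix)
#'   `xTrain`, `xTest` and optionally `yTrain`, `yTest`.
#' @examples
#' sp <- splitTrainTest(matrix(0, 100, 5), testSize = 0.1, randoms = 3)
#' length(sp$testIdx) # 10
#' @export
splitTrainTest <- function(x, y = NULL, testSize = 0.1, randoms = 0L) {
  n <- nrow(x)
  if (is.null(n) || n < 2) stop("need at least two cells to split")
  if (!(testSize > 0 && testSize < 1)) stop("testSize must be in (0, 1)")
  perm <- .withSeed(as.integer(randoms), sample.int(n))
  nTest <- max(1L, round(testSize * n))
  testIdx <- sort(perm[seq_len(nTest)])
  trainIdx <- sort(perm[-seq_len(nTest)])
  out <- list(trainIdx = trainIdx, testIdx = testIdx)
  if (is.matrix(x)) {
    out$xTrain <- x[trainIdx, , drop = FALSE]
    out$xTest <- x[testIdx, , drop = FALSE]
  }
  if (!is.null(y)) {
    out$yTrain <- y[trainIdx]
    out$yTest <- y[testIdx]
  }
  out
}

## evaluate `expr` under a local RNG seed without disturbing the caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
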
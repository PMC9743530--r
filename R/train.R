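## Training engine: batch forward pass, backpropagation through the masked
## routing iterations, and Adam. Everything is vectorized over the batch; the
## only loops are over the l (or l^2) capsule indices.

## coerce labels to a factor and check coverage of every type
.asLabels <- function(y, typeNames = NULL) {
  if (!is.factor(y)) {
    y <- if (is.null(typeNames)) factor(y, levels = unique(as.character(y)))
         else factor(as.character(y), levels = typeNames)
  }
  if (anyNA(y)) stop("labels contain NA or values outside the known type names")
  if (nlevels(y) < 2) stop("need at least two cell types to train")
  if (any(tabulate(y, nlevels(y)) == 0))
    stop("every cell type must have at least one labelled cell: missing ",
         paste(levels(y)[tabulate(y, nlevels(y)) == 0], collapse = ", "))
  y
}

## Glorot-uniform initial parameters; RNG state is the caller's responsibility
.initParams <- function(cfg) {
  l <- cfg@nTypes; d <- cfg@dimCapsule; g <- cfg@nGenes
  limP <- sqrt(6 / (g + d))
  limT <- sqrt(6 / (d + d))
  list(
    Wp = array(stats::runif(l * d * g, -limP, limP), c(l, d, g)),
    bp = matrix(0, l, d),
    Wt = array(stats::runif(l * l * d * d, -limT, limT), c(l, l, d, d))
  )
}

## Batch forward pass. X: n x G. Returns capsule lengths and, with
## keep = TRUE, every intermediate needed for backpropagation; with
## coupling = TRUE, the final-iteration coupling (diagonal + pre-mask array).
.capsForwardBatch <- function(X, params, cfg, keep = FALSE, coupling = FALSE) {
  n <- nrow(X); l <- cfg@nTypes; d <- cfg@dimCapsule; g <- cfg@nGenes
  R <- cfg@routingIterations
  relu <- cfg@activation == "relu"

  A <- U <- vector("list", l)
  for (i in seq_len(l)) {
    A[[i]] <- X %*% t(matrix(params$Wp[i, , ], d, g)) +
      matrix(params$bp[i, ], n, d, byrow = TRUE)
    U[[i]] <- if (relu) pmax(A[[i]], 0) else tanh(A[[i]])
  }
  Uhat <- vector("list", l)
  for (i in seq_len(l)) {
    Uhat[[i]] <- vector("list", l)
    for (j in seq_len(l))   # uhat_j|i = W_ij u_i, batched as U %*% t(W_ij)
      Uhat[[i]][[j]] <- U[[i]] %*% t(matrix(params$Wt[i, j, , ], d, d))
  }

  B <- array(0, c(n, l, l))
  Cpre <- Cdiag <- Nrm <- V <- vector("list", R)
  for (r in seq_len(R)) {
    cp <- array(0, c(n, l, l))
    for (i in seq_len(l)) {
      Bi <- matrix(B[, i, ], n, l)
      e <- exp(Bi - apply(Bi, 1, max))
      cp[, i, ] <- e / rowSums(e)
    }
    cd <- matrix(0, n, l)
    for (j in seq_len(l)) cd[, j] <- cp[, j, j]
    Vr <- vector("list", l)
    nr <- matrix(0, n, l)
    for (j in seq_len(l)) {
      Sj <- cd[, j] * Uhat[[j]][[j]]
      nj <- sqrt(rowSums(Sj * Sj))
      Vr[[j]] <- Sj * ifelse(nj > 0, nj / (1 + nj^2), 0)
      nr[, j] <- nj
    }
    Cpre[[r]] <- cp; Cdiag[[r]] <- cd; Nrm[[r]] <- nr; V[[r]] <- Vr
    if (r < R) {
      for (i in seq_len(l)) for (j in seq_len(l))
        B[, i, j] <- B[, i, j] + rowSums(Uhat[[i]][[j]] * Vr[[j]])
    }
  }
  P <- Nrm[[R]]^2 / (1 + Nrm[[R]]^2)

  out <- list(P = P)
  if (coupling) {
    out$couplingDiag <- Cdiag[[R]]
    out$couplingPre <- Cpre[[R]]
  }
  if (keep) {
    out$U <- U; out$A <- A; out$Uhat <- Uhat
    out$Cpre <- Cpre; out$Cdiag <- Cdiag; out$Nrm <- Nrm; out$V <- V
  }
  out
}

## margin loss of a batch: mean over samples of the per-sample sum over
## type capsules. Tmat is the n x l one-hot matrix.
.marginLossBatch <- function(P, Tmat, cfg) {
  per <- Tmat * pmax(0, cfg@mPlus - P)^2 +
    cfg@lambdaDown * (1 - Tmat) * pmax(0, P - cfg@mMinus)^2
  mean(rowSums(per))
}

## Backpropagation through squash + masked routing + transform + encoders.
## fw must come from .capsForwardBatch(..., keep = TRUE).
.capsBackwardBatch <- function(X, params, cfg, fw, Tmat) {
  n <- nrow(X); l <- cfg@nTypes; d <- cfg@dimCapsule; g <- cfg@nGenes
  R <- cfg@routingIterations
  P <- fw$P

  ## dL/dP, mean over the batch
  gLen <- (-2 * Tmat * pmax(0, cfg@mPlus - P) +
           2 * cfg@lambdaDown * (1 - Tmat) * pmax(0, P - cfg@mMinus)) / n

  ## dL/dv at the final iteration: P = |v|, so dP/dv = v / |v|
  gV <- vector("list", l)
  for (j in seq_len(l)) {
    vj <- fw$V[[R]][[j]]
    pj <- sqrt(rowSums(vj * vj))
    gV[[j]] <- vj * ifelse(pj > 0, gLen[, j] / pj, 0)
  }

  gUhat <- vector("list", l)
  for (i in seq_len(l)) {
    gUhat[[i]] <- vector("list", l)
    for (j in seq_len(l)) gUhat[[i]][[j]] <- matrix(0, n, d)
  }
  gBfuture <- NULL

  for (r in seq(R, 1)) {
    cd <- fw$Cdiag[[r]]; nr <- fw$Nrm[[r]]
    gCdiag <- matrix(0, n, l)
    for (j in seq_len(l)) {
      Sj <- cd[, j] * fw$Uhat[[j]][[j]]
      nj <- nr[, j]
      gsc <- nj / (1 + nj^2)                      # squash scale g(n)
      gscp <- (1 - nj^2) / (1 + nj^2)^2           # g'(n)
      sdot <- rowSums(Sj * gV[[j]])
      gS <- gV[[j]] * gsc + Sj * ifelse(nj > 0, gscp * sdot / nj, 0)
      gCdiag[, j] <- rowSums(fw$Uhat[[j]][[j]] * gS)
      gUhat[[j]][[j]] <- gUhat[[j]][[j]] + cd[, j] * gS
    }
    ## softmax backward per primary-capsule row; only diagonal coupling
    ## entries carry loss gradient (the mask zeroes the others)
    gB <- array(0, c(n, l, l))
    for (i in seq_len(l)) {
      inner <- fw$Cpre[[r]][, i, i] * gCdiag[, i]
      for (j in seq_len(l)) {
        gB[, i, j] <- fw$Cpre[[r]][, i, j] *
          ((j == i) * gCdiag[, i] - inner)
      }
    }
    if (!is.null(gBfuture)) gB <- gB + gBfuture
    if (r > 1) {
      ## logit update b_ij += uhat_ij . v_j at iteration r-1
      for (j in seq_len(l)) {
        gVj <- matrix(0, n, d)
        for (i in seq_len(l)) {
          gUhat[[i]][[j]] <- gUhat[[i]][[j]] + gB[, i, j] * fw$V[[r - 1]][[j]]
          gVj <- gVj + gB[, i, j] * fw$Uhat[[i]][[j]]
        }
        gV[[j]] <- gVj
      }
      gBfuture <- gB
    }
  }

  gWt <- array(0, c(l, l, d, d))
  gWp <- array(0, c(l, d, g))
  gbp <- matrix(0, l, d)
  relu <- cfg@activation == "relu"
  for (i in seq_len(l)) {
    gU <- matrix(0, n, d)
    for (j in seq_len(l)) {
      Wij <- matrix(params$Wt[i, j, , ], d, d)
      ## uhat = U %*% t(Wij), so dWij = t(gUhat) %*% U and dU = gUhat %*% Wij
      gWt[i, j, , ] <- t(gUhat[[i]][[j]]) %*% fw$U[[i]]
      gU <- gU + gUhat[[i]][[j]] %*% Wij
    }
    gA <- if (relu) gU * (fw$A[[i]] > 0) else gU * (1 - fw$U[[i]]^2)
    gWp[i, , ] <- t(gA) %*% X
    gbp[i, ] <- colSums(gA)
  }
  list(Wp = gWp, bp = gbp, Wt = gWt)
}

.adamInit <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

#' Train a masked capsule-network classifier
#'
#' @description
#' Minimizes the summed margin loss (mean over samples of the per-sample sum
#' over type capsules) with Adam, backpropagating through the encoders, the
#' capsule transformations and every masked routing iteration. The seed in
#' `config` fixes weight initialization and batch shuffling, so two runs with
#' the same inputs and configuration are identical.
#'
#' @param x cells-x-genes matrix of finite, log-scale expression values, with
#'   gene identifiers as column names and cell identifiers as row names.
#' @param y per-cell labels: a factor (its level order defines the capsule
#'   order), or a character vector (type order = first appearance).
#' @param config a [CapsuleConfig-class]; `nTypes` and `nGenes` must match
#'   `y` and `x`. If omitted, defaults are derived from the data.
#' @param verbose print per-epoch loss; default `FALSE`.
#' @return a [CapsuleModel-class] with the per-epoch training loss recorded.
#' @section Divergence: if the loss becomes non-finite, training stops with
#'   an error suggesting a lower learning rate.
#' @examples
#' sim <- simulateReference(simConfig(nTypes = 3, nGenes = 60,
#'                                    cellsPerType = 40, seed = 7))
#' cfg <- capsConfig(nTypes = 3, nGenes = 60, dimCapsule = 6,
#'                   epochs = 5, seed = 7)
#' fit <- trainCapsNet(sim$expression, sim$labels, cfg)
#' trainingLoss(fit)
#' @export
trainCapsNet <- function(x, y, config = NULL, verbose = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains NA or non-finite values")
  y <- .asLabels(y)
  if (length(y) != nrow(x))
    stop("labels must have one entry per cell (row of x)")
  if (is.null(colnames(x))) {
    warning("expression matrix has no gene identifiers; generating gene_1..gene_G")
    colnames(x) <- paste0("gene_", seq_len(ncol(x)))
  }
  if (is.null(config))
    config <- capsConfig(nTypes = nlevels(y), nGenes = ncol(x))
  if (config@nTypes != nlevels(y))
    stop(sprintf("config declares %d types but labels have %d",
                 config@nTypes, nlevels(y)))
  if (config@nGenes != ncol(x))
    stop(sprintf("config declares %d genes but the matrix has %d",
                 config@nGenes, ncol(x)))

  n <- nrow(x); l <- config@nTypes
  Tfull <- matrix(0, n, l)
  Tfull[cbind(seq_len(n), as.integer(y))] <- 1

  .withSeed(config@seed, {
    params <- .initParams(config)
    adam <- .adamInit(params)
    epochLoss <- numeric(config@epochs)
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config@batchSize)
      lossSum <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config@batchSize - 1, n)]
        Xb <- x[idx, , drop = FALSE]
        Tb <- Tfull[idx, , drop = FALSE]
        fw <- .capsForwardBatch(Xb, params, config, keep = TRUE)
        loss <- .marginLossBatch(fw$P, Tb, config)
        if (!is.finite(loss))
          stop("training loss became non-finite; reduce the learning rate (lr) and retrain")
        lossSum <- lossSum + loss * length(idx)
        grads <- .capsBackwardBatch(Xb, params, config, fw, Tb)
        upd <- .adamStep(params, grads, adam, config@lr)
        params <- upd$params; adam <- upd$state
      }
      epochLoss[ep] <- lossSum / n
      if (verbose)
        message(sprintf("epoch %d/%d: margin loss %.5f",
                        ep, config@epochs, epochLoss[ep]))
    }
    methods::new("CapsuleModel",
      config = config,
      primaryWeights = params$Wp,
      primaryBias = params$bp,
      transformWeights = params$Wt,
      typeNames = levels(y),
      geneIds = colnames(x),
      trainLoss = epochLoss
    )
  })
}
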
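#' @title Configuration of a masked capsule-network model
#'
#' @description
#' `CapsuleConfig` bundles every hyperparameter of the classifier: the number of
#' cell types `l` (which equals the number of primary capsules, the number of
#' encoder networks and the number of type capsules), the number of genes `G`,
#' the capsule dimension `d`, the encoder activation, the number of dynamic
#' routing iterations, the Adam learning rate, batch size and epoch count, the
#' margin-loss margins `m+` and `m-` with the down-weighting factor `lambda`,
#' and the seed that fixes weight initialization and batch shuffling.
#'
#' Use [capsConfig()] to construct a validated instance.
#'
#' @slot nTypes integer, number of cell types `l` (>= 2).
#' @slot nGenes integer, number of genes `G`.
#' @slot dimCapsule integer, capsule dimension `d` (>= 2).
#' @slot activation character, `"relu"` or `"tanh"` encoder activation.
#' @slot routingIterations integer, dynamic-routing iterations (>= 1).
#' @slot lr numeric, Adam learning rate.
#' @slot batchSize integer, minibatch size.
#' @slot epochs integer, passes over the training data.
#' @slot mPlus numeric, positive margin `m+` of the margin loss.
#' @slot mMinus numeric, negative margin `m-` of the margin loss.
#' @slot lambdaDown numeric, down-weighting `lambda` of the absent-type term.
#' @slot seed integer, RNG seed for initialization, splitting and shuffling.
#'
#' @seealso [capsConfig()], [trainCapsNet()]
#' @exportClass CapsuleConfig
setClass("CapsuleConfig",
  representation(
    nTypes            = "integer",
    nGenes            = "integer",
    dimCapsule        = "integer",
    activation        = "character",
    routingIterations = "integer",
    lr                = "numeric",
    batchSize         = "integer",
    epochs            = "integer",
    mPlus             = "numeric",
    mMinus            = "numeric",
    lambdaDown        = "numeric",
    seed              = "integer"
  )
)

setValidity("CapsuleConfig", function(object) {
  msg <- character()
  if (object@nTypes < 2L) msg <- c(msg, "nTypes must be >= 2")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@dimCapsule < 2L) msg <- c(msg, "dimCapsule must be >= 2")
  if (!object@activation %in% c("relu", "tanh"))
    msg <- c(msg, "activation must be 'relu' or 'tanh'")
  if (object@routingIterations < 1L)
    msg <- c(msg, "routingIterations must be >= 1")
  if (!(object@mMinus > 0 && object@mMinus < object@mPlus && object@mPlus < 1))
    msg <- c(msg, "margins must satisfy 0 < mMinus < mPlus < 1")
  if (object@lambdaDown <= 0) msg <- c(msg, "lambdaDown must be positive")
  if (object@lr <= 0) msg <- c(msg, "lr must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Trained masked capsule-network model
#'
#' @description
#' A `CapsuleModel` holds everything needed to run the forward pass and to
#' interpret a trained classifier: the per-type encoder weights (one dense
#' layer per cell type, producing that type's primary capsule), the capsule
#' transformation weights used to form prediction vectors for routing, the
#' configuration, the ordered cell-type names and the gene identifiers seen at
#' training time, plus the per-epoch training loss.
#'
#' The identity routing mask is structural (it is the identity matrix by
#' definition) and is therefore not stored as data.
#'
#' @slot config a [CapsuleConfig-class] object.
#' @slot primaryWeights numeric array `l x d x G`; `primaryWeights[i, , ]` is
#'   the encoder matrix of cell type `i`.
#' @slot primaryBias numeric matrix `l x d` of encoder biases.
#' @slot transformWeights numeric array `l x l x d x d`;
#'   `transformWeights[i, j, , ]` maps primary capsule `i` to the prediction
#'   vector for type capsule `j`.
#' @slot typeNames character vector of `l` cell-type names (capsule order).
#' @slot geneIds character vector of `G` gene identifiers (input order).
#' @slot trainLoss numeric vector of per-epoch mean margin loss.
#'
#' @seealso [trainCapsNet()], [predict,CapsuleModel-method],
#'   [averageCoupling()], [pcaGeneEmbedding()]
#' @exportClass CapsuleModel
setClass("CapsuleModel",
  representation(
    config           = "CapsuleConfig",
    primaryWeights   = "array",
    primaryBias      = "matrix",
    transformWeights = "array",
    typeNames        = "character",
    geneIds          = "character",
    trainLoss        = "numeric"
  )
)

setValidity("CapsuleModel", function(object) {
  l <- object@config@nTypes
  d <- object@config@dimCapsule
  g <- object@config@nGenes
  msg <- character()
  if (!identical(dim(object@primaryWeights), c(l, d, g)))
    msg <- c(msg, sprintf("primaryWeights must be %d x %d x %d", l, d, g))
  if (!identical(dim(object@primaryBias), c(l, d)))
    msg <- c(msg, sprintf("primaryBias must be %d x %d", l, d))
  if (!identical(dim(object@transformWeights), c(l, l, d, d)))
    msg <- c(msg, sprintf("transformWeights must be %d x %d x %d x %d", l, l, d, d))
  if (length(object@typeNames) != l)
    msg <- c(msg, "typeNames length must equal nTypes")
  if (length(object@geneIds) != g)
    msg <- c(msg, "geneIds length must equal nGenes")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "geneIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Averaged coupling-coefficient summary
#'
#' @description
#' For every cell type, the arithmetic mean over that type's cells of the
#' final-iteration masked coupling matrices (rows index primary capsules,
#' columns index type capsules). The `overall` matrix stacks the effective
#' type-capsule row of each per-type average: row `k` of `overall` is row `k`
#' of the type-`k` average matrix. Under the identity mask the overall matrix
#' is diagonal, which is the one-to-one correspondence read off the heatmap.
#'
#' @slot perType named list of `l` matrices (`l x l`), one per cell type.
#' @slot overall `l x l` matrix of stacked effective rows.
#' @slot typeNames character vector of the `l` cell-type names.
#'
#' @seealso [averageCoupling()], [overallHeatmap()]
#' @exportClass CouplingSummary
setClass("CouplingSummary",
  representation(
    perType   = "list",
    overall   = "matrix",
    typeNames = "character"
  )
)

setValidity("CouplingSummary", function(object) {
  l <- length(object@typeNames)
  msg <- character()
  if (length(object@perType) != l)
    msg <- c(msg, "perType must hold one matrix per cell type")
  bad <- vapply(object@perType, function(m) !identical(dim(m), c(l, l)), logical(1))
  if (any(bad)) msg <- c(msg, "every perType matrix must be l x l")
  if (!identical(dim(object@overall), c(l, l)))
    msg <- c(msg, "overall must be l x l")
  if (length(msg)) msg else TRUE
})

#' @describeIn CapsuleConfig-class compact display of the hyperparameters.
#' @param object a `CapsuleConfig`.
#' @export
setMethod("show", "CapsuleConfig", function(object) {
  cat(sprintf(
    "CapsuleConfig: %d types x %d genes, d=%d, %s, %d routing iteration(s)\n",
    object@nTypes, object@nGenes, object@dimCapsule, object@activation,
    object@routingIterations
  ))
  cat(sprintf(
    "  training: lr=%g, batchSize=%d, epochs=%d, seed=%d\n",
    object@lr, object@batchSize, object@epochs, object@seed
  ))
  cat(sprintf(
    "  margin loss: m+=%g, m-=%g, lambda=%g\n",
    object@mPlus, object@mMinus, object@lambdaDown
  ))
  invisible(NULL)
})

#' @describeIn CapsuleModel-class compact display of a trained model.
#' @param object a `CapsuleModel`.
#' @export
setMethod("show", "CapsuleModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CapsuleModel: %d cell types, %d genes, capsule dimension %d\n",
    cfg@nTypes, cfg@nGenes, cfg@dimCapsule
  ))
  cat("  types: ", paste(object@typeNames, collapse = ", "), "\n", sep = "")
  if (length(object@trainLoss)) {
    cat(sprintf(
      "  trained %d epoch(s); margin loss %.4f -> %.4f\n",
      length(object@trainLoss), object@trainLoss[1],
      object@trainLoss[length(object@trainLoss)]
    ))
  } else {
    cat("  untrained weights\n")
  }
  invisible(NULL)
})

#' @describeIn CouplingSummary-class display the diagonal of the overall heatmap.
#' @param object a `CouplingSummary`.
#' @export
setMethod("show", "CouplingSummary", function(object) {
  cat(sprintf(
    "CouplingSummary over %d cell types (masked coupling coefficients)\n",
    length(object@typeNames)
  ))
  dg <- diag(object@overall)
  names(dg) <- object@typeNames
  cat("  overall heatmap diagonal:\n")
  print(round(dg, 4))
  invisible(NULL)
})
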
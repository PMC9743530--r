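## align the columns of a test matrix to the model's training gene set:
## reorder, zero-fill genes absent from the test matrix (with a warning),
## drop extras
.alignGenes <- function(x, model) {
  if (is.null(colnames(x)))
    stop("test matrix has no gene identifiers (column names)")
  common <- intersect(model@geneIds, colnames(x))
  if (length(common) == 0)
    stop("no overlap between test genes and the model's training genes")
  missing <- setdiff(model@geneIds, colnames(x))
  out <- matrix(0, nrow(x), length(model@geneIds),
                dimnames = list(rownames(x), model@geneIds))
  out[, common] <- x[, common, drop = FALSE]
  if (length(missing))
    warning(sprintf("%d training gene(s) absent from the test matrix were zero-filled (e.g. %s)",
                    length(missing), paste(utils::head(missing, 3), collapse = ", ")))
  extra <- ncol(x) - length(common)
  if (extra > 0)
    message(sprintf("dropped %d test gene(s) unknown to the model", extra))
  out
}

#' Predict unnormalized type probabilities for a matrix of cells
#'
#' @description
#' Runs the forward pass row by row (vectorized over the batch) and returns
#' the matrix of type-capsule lengths `P` — one unnormalized probability per
#' cell type, each in `[0, 1)`, with no sum-to-one constraint — plus the
#' argmax label per cell. Test genes are reordered to the model's training
#' gene set; training genes missing from the test matrix are zero-filled with
#' a warning and unknown test genes are dropped. Argmax ties are broken
#' towards the lowest type index with a warning.
#'
#' @param object a trained [CapsuleModel-class].
#' @param x cells-x-genes matrix with gene identifiers as column names.
#' @param coupling also return the final-iteration coupling coefficients;
#'   default `FALSE`.
#' @param ... ignored.
#' @return a list with `probabilities` (cells x types matrix named by
#'   `typeNames(object)`), `labels` (factor of argmax types) and, when
#'   `coupling = TRUE`, `couplingDiag` (cells x types diagonal coefficients)
#'   and `couplingPre` (cells x l x l pre-mask coefficients).
#' @examples
#' sim <- simulateReference(simConfig(nTypes = 3, nGenes = 60,
#'                                    cellsPerType = 40, seed = 7))
#' cfg <- capsConfig(nTypes = 3, nGenes = 60, dimCapsule = 6,
#'                   epochs = 8, seed = 7)
#' fit <- trainCapsNet(sim$expression, sim$labels, cfg)
#' pr <- predict(fit, sim$expression)
#' head(pr$probabilities)
#' mean(pr$labels == sim$labels)
#' @aliases predict
#' @export
setMethod("predict", "CapsuleModel", function(object, x, coupling = FALSE, ...) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains NA or non-finite values")
  x <- .alignGenes(x, object)
  params <- list(Wp = object@primaryWeights, bp = object@primaryBias,
                 Wt = object@transformWeights)
  fw <- .capsForwardBatch(x, params, object@config, coupling = coupling)
  P <- fw$P
  dimnames(P) <- list(rownames(x), object@typeNames)
  top <- max.col(P, ties.method = "first")
  rowMax <- P[cbind(seq_len(nrow(P)), top)]
  nTied <- rowSums(P == rowMax) > 1
  if (any(nTied))
    warning(sprintf("%d cell(s) had tied maximum probabilities; lowest type index kept",
                    sum(nTied)))
  out <- list(
    probabilities = P,
    labels = factor(object@typeNames[top], levels = object@typeNames)
  )
  if (coupling) {
    out$couplingDiag <- fw$couplingDiag
    out$couplingPre <- fw$couplingPre
    dimnames(out$couplingDiag) <- list(rownames(x), object@typeNames)
  }
  out
})
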
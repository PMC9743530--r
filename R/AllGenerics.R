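#' @name accessors
#' @title Accessors for CellCapsule objects
#'
#' @description
#' Slot access for [CapsuleModel-class] and [CouplingSummary-class] objects:
#' `typeNames()` and `geneIds()` return the ordered cell-type names and gene
#' identifiers, `modelConfig()` the [CapsuleConfig-class], `trainingLoss()` the
#' per-epoch mean margin loss recorded during training, `couplingPerType()` the
#' list of per-type averaged coupling matrices and `couplingOverall()` the
#' stacked overall heatmap matrix.
#'
#' @param x a `CapsuleModel` or `CouplingSummary` object.
#' @return the corresponding slot value.
#' @examples
#' sim <- simulateReference(simConfig(nTypes = 3, nGenes = 60,
#'                                    cellsPerType = 30, seed = 1))
#' cfg <- capsConfig(nTypes = 3, nGenes = 60, epochs = 2, seed = 1)
#' fit <- trainCapsNet(sim$expression, sim$labels, cfg)
#' typeNames(fit)
#' length(geneIds(fit))
NULL

#' @rdname accessors
#' @export
setGeneric("typeNames", function(x) standardGeneric("typeNames"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname accessors
#' @export
setGeneric("trainingLoss", function(x) standardGeneric("trainingLoss"))

#' @rdname accessors
#' @export
setGeneric("couplingPerType", function(x) standardGeneric("couplingPerType"))

#' @rdname accessors
#' @export
setGeneric("couplingOverall", function(x) standardGeneric("couplingOverall"))

#' @rdname accessors
#' @export
setMethod("typeNames", "CapsuleModel", function(x) x@typeNames)

#' @rdname accessors
#' @export
setMethod("typeNames", "CouplingSummary", function(x) x@typeNames)

#' @rdname accessors
#' @export
setMethod("geneIds", "CapsuleModel", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("modelConfig", "CapsuleModel", function(x) x@config)

#' @rdname accessors
#' @export
setMethod("trainingLoss", "CapsuleModel", function(x) x@trainLoss)

#' @rdname accessors
#' @export
setMethod("couplingPerType", "CouplingSummary", function(x) x@perType)

#' @rdname accessors
#' @export
setMethod("couplingOverall", "CouplingSummary", function(x) x@overall)
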
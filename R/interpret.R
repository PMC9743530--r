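#' Average the masked coupling coefficients per cell type
#'
#' @description
#' Every cell produces its own final-iteration masked coupling matrix during
#' the forward pass. This averages those matrices arithmetically over the
#' cells of each labelled type. Because the mask zeroes every off-diagonal
#' coefficient, each per-type average is diagonal; stacking the effective
#' type-capsule rows (row `k` of the type-`k` average) gives the overall
#' heatmap, which displays the one-to-one primary/type capsule
#' correspondence.
#'
#' @param model a trained [CapsuleModel-class].
#' @param x cells-x-genes matrix.
#' @param y per-cell labels (factor or character) over the model's type
#'   names; every type must have at least one cell.
#' @return a [CouplingSummary-class].
#' @examples
#' sim <- simulateReference(simConfig(nTypes = 3, nGenes = 60,
#'                                    cellsPerType = 40, seed = 7))
#' cfg <- capsConfig(nTypes = 3, nGenes = 60, dimCapsule = 6,
#'                   epochs = 8, seed = 7)
#' fit <- trainCapsNet(sim$expression, sim$labels, cfg)
#' cs <- averageCoupling(fit, sim$expression, sim$labels)
#' couplingOverall(cs)
#' @export
averageCoupling <- function(model, x, y) {
  y <- factor(as.character(y), levels = model@typeNames)
  if (anyNA(y)) stop("labels outside the model's type names")
  counts <- tabulate(y, nbins = length(model@typeNames))
  if (any(counts == 0))
    stop("no cells for type(s): ",
         paste(model@typeNames[counts == 0], collapse = ", "))
  pr <- predict(model, x, coupling = TRUE)
  l <- length(model@typeNames)
  perType <- lapply(seq_len(l), function(k) {
    m <- diag(colMeans(pr$couplingDiag[y == model@typeNames[k], , drop = FALSE]), l)
    dimnames(m) <- list(model@typeNames, model@typeNames)
    m
  })
  names(perType) <- model@typeNames
  methods::new("CouplingSummary",
    perType = perType,
    overall = overallHeatmap(perType),
    typeNames = model@typeNames
  )
}

#' Stack effective type-capsule rows into the overall heatmap
#'
#' @description
#' Row `k` of the result is row `k` — the effective type-capsule row — of the
#' type-`k` averaged coupling matrix. With the identity mask the result is
#' diagonal.
#'
#' @param perType list of `l` square `l x l` matrices, ordered by type.
#' @return an `l x l` matrix.
#' @examples
#' a <- diag(c(0.8, 0)); b <- diag(c(0, 0.6))
#' overallHeatmap(list(a, b))
#' @export
overallHeatmap <- function(perType) {
  l <- length(perType)
  if (l == 0) stop("perType is empty")
  if (any(vapply(perType, function(m) !identical(dim(m), c(l, l)), logical(1))))
    stop("every per-type matrix must be l x l with l = number of types")
  out <- t(vapply(seq_len(l), function(k) perType[[k]][k, ], numeric(l)))
  dimnames(out) <- dimnames(perType[[1]])
  out
}

#' Two-dimensional PCA embedding of a type's gene weights
#'
#' @description
#' The encoder of cell type `k` is a `d x G` matrix whose columns are the
#' per-gene weight vectors. Principal component analysis of these column
#' vectors (mean-centred, unscaled) orders the genes by their importance for
#' recognizing that type; markers sit at one extreme of PC1. Signs are fixed
#' deterministically: each component is oriented so that the gene with the
#' largest absolute coordinate on it has a positive coordinate.
#'
#' @param model a trained [CapsuleModel-class].
#' @param type a type index or type name.
#' @return a list with `coordinates` (data.frame: `gene`, `PC1`, `PC2`),
#'   `varExplained` (shares of the first two components) and `type`.
#' @examples
#' sim <- simulateReference(simConfig(nTypes = 3, nGenes = 60,
#'                                    cellsPerType = 40, seed = 7))
#' fit <- trainCapsNet(sim$expression, sim$labels,
#'                     capsConfig(3, 60, dimCapsule = 6, epochs = 8, seed = 7))
#' emb <- pcaGeneEmbedding(fit, "type1")
#' head(emb$coordinates)
#' @export
pcaGeneEmbedding <- function(model, type) {
  k <- if (is.character(type)) match(type, model@typeNames) else as.integer(type)
  if (is.na(k) || k < 1 || k > length(model@typeNames))
    stop("unknown cell type: ", type)
  d <- model@config@dimCapsule
  W <- matrix(model@primaryWeights[k, , ], d, model@config@nGenes)
  genes <- t(W)                       # G x d, one row per gene column vector
  if (all(apply(genes, 2, stats::var) < .Machine$double.eps)) {
    warning("all gene weight columns are identical; returning zero coordinates")
    coords <- data.frame(gene = model@geneIds, PC1 = 0, PC2 = 0)
    return(list(coordinates = coords, varExplained = c(PC1 = 0, PC2 = 0),
                type = model@typeNames[k]))
  }
  pc <- stats::prcomp(genes, center = TRUE, scale. = FALSE, rank. = 2)
  sc <- pc$x
  for (cc in 1:2) {
    top <- which.max(abs(sc[, cc]))
    if (sc[top, cc] < 0) sc[, cc] <- -sc[, cc]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    coordinates = data.frame(gene = model@geneIds,
                             PC1 = sc[, 1], PC2 = sc[, 2],
                             row.names = NULL),
    varExplained = c(PC1 = ve[1], PC2 = ve[2]),
    type = model@typeNames[k]
  )
}

## per-type recall of a prediction against reference labels
.perTypeRecall <- function(predLabels, y, typeNames) {
  vapply(typeNames, function(tp) {
    idx <- y == tp
    if (!any(idx)) return(NA_real_)
    mean(predLabels[idx] == tp)
  }, numeric(1))
}

#' Scan prediction accuracy along PC1 of a type's gene weights
#'
#' @description
#' Divides the PC1 coordinate range of the type's gene embedding into
#' `pcSlice` equal intervals and, starting from one extreme, cumulatively
#' zeroes the expression of the genes in successive intervals in a copy of
#' the evaluation matrix, recording each type's recall after every step.
#' The curve starts with the unmasked baseline. Masking from the extreme that
#' carries the type's program collapses that type's recall while the others
#' stay near baseline; `end = "auto"` scans both extremes and keeps the one
#' whose accuracy for the target type degrades more (lower mean recall along
#' the curve), making the result independent of the arbitrary PCA sign.
#'
#' @param model a trained [CapsuleModel-class].
#' @param x evaluation cells-x-genes matrix (typically the held-out split).
#' @param y evaluation labels; must contain cells of the target type.
#' @param type target type index or name.
#' @param pcSlice number of equal intervals along the component (>= 2, at
#'   most the number of genes); default 20.
#' @param end `"auto"` (default), `"low"` or `"high"`: which coordinate
#'   extreme to mask from.
#' @param pc which principal component to scan (1, the default, or 2).
#' @return an object of class `capsGeneScan`: `curve` (`(pcSlice + 1) x l`
#'   recall matrix, row 0 = baseline), `sliceGenes` (genes per interval in
#'   masking order), `type`, `end`, `pc`, `pcSlice`, `embedding`.
#' @seealso [selectTypeGenes()]
#' @export
scanPC1Accuracy <- function(model, x, y, type, pcSlice = 20L,
                            end = c("auto", "low", "high"), pc = 1L) {
  end <- match.arg(end)
  if (pcSlice < 2) stop("pcSlice must be >= 2")
  if (pcSlice > model@config@nGenes)
    stop("pcSlice exceeds the number of genes")
  if (!pc %in% 1:2) stop("pc must be 1 or 2")
  y <- .asLabels(y, model@typeNames)
  k <- if (is.character(type)) match(type, model@typeNames) else as.integer(type)
  if (is.na(k)) stop("unknown cell type: ", type)
  typeName <- model@typeNames[k]
  if (!any(y == typeName))
    stop("evaluation cells contain no cells of type ", typeName)

  emb <- pcaGeneEmbedding(model, k)
  coord <- emb$coordinates[[paste0("PC", pc)]]
  names(coord) <- emb$coordinates$gene

  runOne <- function(fromHigh) {
    rng <- range(coord)
    breaks <- seq(rng[1], rng[2], length.out = pcSlice + 1)
    bin <- findInterval(coord, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    order <- if (fromHigh) seq(pcSlice, 1) else seq(1, pcSlice)
    sliceGenes <- lapply(order, function(b) names(coord)[bin == b])
    curve <- matrix(NA_real_, pcSlice + 1, length(model@typeNames),
                    dimnames = list(0:pcSlice, model@typeNames))
    xm <- x
    pr <- suppressWarnings(predict(model, xm))
    curve[1, ] <- .perTypeRecall(pr$labels, y, model@typeNames)
    for (s in seq_len(pcSlice)) {
      gs <- intersect(sliceGenes[[s]], colnames(xm))
      if (length(gs)) xm[, gs] <- 0
      pr <- suppressWarnings(predict(model, xm))
      curve[s + 1, ] <- .perTypeRecall(pr$labels, y, model@typeNames)
    }
    list(curve = curve, sliceGenes = sliceGenes,
         end = if (fromHigh) "high" else "low")
  }

  res <- if (end == "auto") {
    hi <- runOne(TRUE); lo <- runOne(FALSE)
    if (mean(lo$curve[, typeName]) < mean(hi$curve[, typeName])) lo else hi
  } else {
    runOne(end == "high")
  }
  structure(
    list(curve = res$curve, sliceGenes = res$sliceGenes, type = typeName,
         end = res$end, pc = pc, pcSlice = as.integer(pcSlice),
         embedding = emb),
    class = "capsGeneScan"
  )
}

#' Select the genes responsible for recognizing one type
#'
#' @description
#' Reads the accuracy curve of [scanPC1Accuracy()]: the crossing slice is the
#' first masking step at which the target type's recall drops below
#' `threshold`, and the selected gene set is every gene in the slices up to
#' and including the crossing slice. If the curve never crosses the
#' threshold, the selection is empty with a warning.
#'
#' @param scan a `capsGeneScan` from [scanPC1Accuracy()].
#' @param threshold recall threshold in (0, 1); default 0.7.
#' @return an object of class `capsGeneSelection`: `selectedGenes`,
#'   `crossingSlice` (`NA` if never crossed), `threshold`, `pcSlice`,
#'   `type`, `curve` and a per-gene `table` (`gene`, `slice`, `selected`).
#' @examples
#' # see vignette("masked-capsule-networks") for an end-to-end run
#' @export
selectTypeGenes <- function(scan, threshold = 0.7) {
  if (!inherits(scan, "capsGeneScan")) stop("scan must come from scanPC1Accuracy()")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  acc <- scan$curve[, scan$type]
  if (length(acc) < 2) stop("empty accuracy curve")
  below <- which(acc[-1] < threshold)        # steps 1..pcSlice
  crossing <- if (length(below)) as.integer(unname(below[1])) else NA_integer_
  if (is.na(crossing)) {
    warning(sprintf("recall of %s never fell below %.2f; empty selection",
                    scan$type, threshold))
    selected <- character()
  } else {
    selected <- unlist(scan$sliceGenes[seq_len(crossing)], use.names = FALSE)
  }
  slice <- rep(seq_along(scan$sliceGenes),
               vapply(scan$sliceGenes, length, integer(1)))
  gene <- unlist(scan$sliceGenes, use.names = FALSE)
  structure(
    list(selectedGenes = selected, crossingSlice = crossing,
         threshold = threshold, pcSlice = scan$pcSlice, type = scan$type,
         curve = scan$curve,
         table = data.frame(gene = gene, slice = slice,
                            selected = gene %in% selected)),
    class = "capsGeneSelection"
  )
}
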
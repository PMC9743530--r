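## Scoring of non-standard samples: cells unlike any training category
## (under-differentiated progenitors -> uniformly low outputs whose sum is
## far below 1) and mixtures (doublets -> two high outputs, sum above 1).
## All of it reads the unnormalized type-capsule lengths; nothing here
## renormalizes.

#' Sum of the unnormalized type probabilities
#'
#' @description
#' The plain arithmetic sum of a cell's type-capsule lengths. Unlike a
#' softmax classifier there is no sum-to-one constraint, so the sum itself is
#' informative: far below 1 for cells missing most features of every training
#' type, above 1 for mixtures.
#'
#' @param P numeric vector of per-type probabilities (one cell), or a
#'   cells-x-types matrix (one sum per row).
#' @return a scalar, or a vector of row sums for matrix input.
#' @examples
#' probabilitySum(c(0.146, 0.108, 0.126)) # 0.38
#' @export
probabilitySum <- function(P) {
  if (length(P) == 0) stop("empty probability input")
  if (is.matrix(P)) return(rowSums(P))
  sum(P)
}

#' Fate bias of one non-standard cell
#'
#' @description
#' The lineage with the maximum output probability is the cell's fate bias,
#' and the maximum itself is the stage score: higher values correspond to
#' more differentiated states. Ties are broken towards the lowest type index
#' with a warning.
#'
#' @param P numeric vector of per-type probabilities.
#' @param typeNames type names matching `P`; defaults to `names(P)`.
#' @return a list with `lineage` and `stageScore`.
#' @examples
#' fateBias(c(0.146, 0.108, 0.126), c("ery", "mono", "dc"))
#' @export
fateBias <- function(P, typeNames = names(P)) {
  if (length(P) == 0) stop("empty probability input")
  if (is.null(typeNames)) typeNames <- paste0("type", seq_along(P))
  if (length(typeNames) != length(P))
    stop("typeNames must match the probability vector")
  top <- which.max(P)
  if (sum(P == P[top]) > 1)
    warning("tied maximum probabilities; lowest type index kept")
  list(lineage = typeNames[top], stageScore = unname(P[top]))
}

#' Fate bias and stage score for a matrix of cells
#'
#' @description
#' Row-wise [fateBias()]: assigns every cell to the lineage of its maximum
#' output and records that maximum as the stage score, together with the
#' probability sum. Cells whose maximum is exactly 0 are kept (they sort to
#' the start of any pseudotime order) with a warning.
#'
#' @param probabilities cells-x-types matrix, e.g.
#'   `predict(model, x)$probabilities`.
#' @return a data.frame with `cell_id`, `lineage`, `stage_score`,
#'   `prob_sum`.
#' @export
fateBiasTable <- function(probabilities) {
  if (!is.matrix(probabilities) || nrow(probabilities) == 0)
    stop("probabilities must be a non-empty cells x types matrix")
  typeNames <- colnames(probabilities)
  if (is.null(typeNames)) typeNames <- paste0("type", seq_len(ncol(probabilities)))
  ids <- rownames(probabilities)
  if (is.null(ids)) ids <- sprintf("cell_%04d", seq_len(nrow(probabilities)))
  top <- max.col(probabilities, ties.method = "first")
  score <- probabilities[cbind(seq_len(nrow(probabilities)), top)]
  if (any(rowSums(probabilities == score) > 1))
    warning("tied maximum probabilities; lowest type index kept")
  if (any(score == 0))
    warning(sprintf("%d cell(s) have all-zero outputs; they will sort to the start of the pseudotime order",
                    sum(score == 0)))
  data.frame(cell_id = ids, lineage = typeNames[top],
             stage_score = unname(score),
             prob_sum = unname(rowSums(probabilities)),
             stringsAsFactors = FALSE)
}

#' Pseudo-temporal order of one lineage
#'
#' @description
#' Cells assigned to the lineage are sorted by ascending stage score — from
#' less to more differentiated — giving the pseudo-temporal order along that
#' differentiation trajectory. Equal scores are ordered stably by cell id.
#'
#' @param fates data.frame from [fateBiasTable()].
#' @param lineage the lineage (type name) to order.
#' @return the subset of `fates` for that lineage, ordered, with a
#'   `pseudotime_rank` column.
#' @examples
#' fb <- data.frame(cell_id = c("a", "b", "c"), lineage = "ery",
#'                  stage_score = c(0.499, 0.146, 0.318))
#' pseudotemporalOrder(fb, "ery")$stage_score
#' @export
pseudotemporalOrder <- function(fates, lineage) {
  stopifnot(is.data.frame(fates),
            all(c("cell_id", "lineage", "stage_score") %in% names(fates)))
  sub <- fates[fates$lineage == lineage, , drop = FALSE]
  if (nrow(sub) == 0) stop("no cells assigned to lineage ", lineage)
  sub <- sub[order(sub$stage_score, sub$cell_id), , drop = FALSE]
  sub$pseudotime_rank <- seq_len(nrow(sub))
  rownames(sub) <- NULL
  sub
}

#' Call doublets from multiple high output probabilities
#'
#' @description
#' A measurement mixing two cell types keeps a relatively high output for
#' both: a cell is flagged as a doublet when at least two of its unnormalized
#' probabilities reach `threshold`. The reported pair is always the two
#' largest outputs; three or more probabilities above the threshold are
#' annotated as a possible multiplet.
#'
#' @param probabilities cells-x-types matrix (or a single cell's vector).
#' @param threshold flagging threshold in (0, 1); default 0.5.
#' @return a data.frame with `cell_id`, `flagged`, `type_a`, `p_a`,
#'   `type_b`, `p_b`, `multiplet`, `threshold`.
#' @examples
#' P <- rbind(spot1 = c(Entorhinal = 0.6257, Oligodendrocyte = 0.8227,
#'                      CA1 = 0.03))
#' callDoublets(P)
#' @export
callDoublets <- function(probabilities, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  if (!is.matrix(probabilities)) probabilities <- rbind(cell = probabilities)
  typeNames <- colnames(probabilities)
  if (is.null(typeNames)) typeNames <- paste0("type", seq_len(ncol(probabilities)))
  ids <- rownames(probabilities)
  if (is.null(ids)) ids <- sprintf("cell_%04d", seq_len(nrow(probabilities)))
  res <- lapply(seq_len(nrow(probabilities)), function(r) {
    p <- probabilities[r, ]
    ord <- order(p, decreasing = TRUE)
    nHigh <- sum(p >= threshold)
    data.frame(cell_id = ids[r], flagged = nHigh >= 2,
               type_a = typeNames[ord[1]], p_a = unname(p[ord[1]]),
               type_b = typeNames[ord[2]], p_b = unname(p[ord[2]]),
               multiplet = nHigh >= 3, threshold = threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Distribution summary of stage scores
#'
#' @description
#' Quartile summary plus deterministic histogram counts of stage scores over
#' 20 equal bins on `[0, 1]`. A spread over many bins distinguishes the
#' unnormalized capsule outputs from sum-to-one classifiers, whose maxima
#' bunch in a narrow range.
#'
#' @param scores numeric vector of stage scores in `[0, 1]`, or a
#'   [fateBiasTable()] data.frame.
#' @param nBins number of equal bins; default 20.
#' @return a list with `summary` (min, quartiles, max), `counts` (named bin
#'   counts) and `breaks`.
#' @examples
#' stageScoreDistribution(c(0.146, 0.318, 0.499))$summary
#' @export
stageScoreDistribution <- function(scores, nBins = 20L) {
  if (is.data.frame(scores)) scores <- scores$stage_score
  if (length(scores) == 0) stop("no stage scores")
  stopifnot(all(scores >= 0), all(scores <= 1))
  breaks <- seq(0, 1, length.out = nBins + 1)
  bins <- cut(scores, breaks, include.lowest = TRUE, right = FALSE)
  list(
    summary = stats::quantile(scores, c(0, 0.25, 0.5, 0.75, 1)),
    counts = table(bins),
    breaks = breaks
  )
}
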
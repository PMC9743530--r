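#' Configuration for the synthetic expression simulator
#'
#' @description
#' The generator plants the three structures the downstream analyses assume:
#' committed cell types defined by disjoint marker-gene programs elevated over
#' a flat baseline (negative-binomial count noise, then `log1p`); progenitor
#' cells whose mean count profile interpolates between a root profile (the
#' bare baseline) and a committed type's profile with a known differentiation
#' coordinate `t`; and doublets whose mean count profile is the element-wise
#' sum of two committed types' profiles (transcript mixing happens on the
#' count scale, before the log transform).
#'
#' @param nTypes number of committed cell types; default 5.
#' @param nGenes number of genes; default 500.
#' @param markersPerType disjoint marker genes per type; default 20.
#' @param markerLogFold log-scale elevation of marker means (the count-scale
#'   mean is multiplied by `exp(markerLogFold)`); default 2.0.
#' @param baselineMean baseline negative-binomial mean count; default 0.5.
#' @param dispersion negative-binomial size parameter (smaller = noisier);
#'   default 2.
#' @param cellsPerType committed cells per type; default 200.
#' @param progenitorGrid mixing coefficients `t` in `[0, 1]`; default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @param progenitorsPerT progenitor cells per (lineage, t); default 50.
#' @param doubletPairs list of 2-vectors of distinct type indices; by
#'   default `list(c(1, 2), c(3, 4))`, reduced to `list(c(1, 2))` when fewer
#'   than four types are simulated.
#' @param doubletsPerPair doublets per pair; default 100.
#' @param noise `"nb"` (negative binomial, default) or `"lognormal"`
#'   (log-normal counts with `sdLog`).
#' @param sdLog log-scale standard deviation for the lognormal alternative;
#'   default 0.3.
#' @param seed integer seed; every simulator output is a pure function of the
#'   configuration (including this seed).
#' @return a validated `capsSimConfig` list.
#' @examples
#' simConfig(nTypes = 3, nGenes = 100, cellsPerType = 50)
#' @export
simConfig <- function(nTypes = 5L, nGenes = 500L, markersPerType = 20L,
                      markerLogFold = 2.0, baselineMean = 0.5,
                      dispersion = 2, cellsPerType = 200L,
                      progenitorGrid = seq(0.1, 0.9, by = 0.1),
                      progenitorsPerT = 50L,
                      doubletPairs = NULL,
                      doubletsPerPair = 100L,
                      noise = c("nb", "lognormal"), sdLog = 0.3,
                      seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(doubletPairs)) {
    doubletPairs <- if (nTypes >= 4) list(c(1L, 2L), c(3L, 4L))
                    else list(c(1L, 2L))
  }
  cfg <- list(
    nTypes = as.integer(nTypes), nGenes = as.integer(nGenes),
    markersPerType = as.integer(markersPerType),
    markerLogFold = markerLogFold, baselineMean = baselineMean,
    dispersion = dispersion, cellsPerType = as.integer(cellsPerType),
    progenitorGrid = progenitorGrid,
    progenitorsPerT = as.integer(progenitorsPerT),
    doubletPairs = doubletPairs,
    doubletsPerPair = as.integer(doubletsPerPair),
    noise = noise, sdLog = sdLog, seed = as.integer(seed)
  )
  if (cfg$nTypes < 2) stop("need at least 2 cell types")
  if (cfg$markersPerType * cfg$nTypes > cfg$nGenes)
    stop(sprintf("infeasible marker allocation: %d types x %d markers > %d genes",
                 cfg$nTypes, cfg$markersPerType, cfg$nGenes))
  if (any(cfg$progenitorGrid < 0 | cfg$progenitorGrid > 1))
    stop("progenitorGrid coefficients must lie in [0, 1]")
  if (cfg$baselineMean <= 0 || cfg$dispersion <= 0)
    stop("baselineMean and dispersion must be positive")
  for (p in cfg$doubletPairs) {
    if (length(p) != 2 || p[1] == p[2] || any(p < 1) || any(p > cfg$nTypes))
      stop("each doublet pair must name two distinct type indices")
  }
  class(cfg) <- "capsSimConfig"
  cfg
}

## draw a counts matrix with per-cell mean rows `mus` (n x G)
.drawCounts <- function(mus, config) {
  n <- nrow(mus); g <- ncol(mus)
  if (config$noise == "nb") {
    matrix(stats::rnbinom(n * g, mu = as.vector(mus), size = config$dispersion),
           n, g)
  } else {
    matrix(stats::rlnorm(n * g, meanlog = log(as.vector(mus)),
                         sdlog = config$sdLog), n, g)
  }
}

.geneIds <- function(g) sprintf("gene_%04d", seq_len(g))
.typeNames <- function(l) paste0("type", seq_len(l))

#' Simulate a committed-cell reference dataset
#'
#' @description
#' Draws `cellsPerType` cells per type: each type's count means equal the
#' baseline, with its `markersPerType` marker genes multiplied by
#' `exp(markerLogFold)`; counts are negative-binomial and the expression
#' matrix is `log1p(counts)`. Marker sets are disjoint across types. The same
#' configuration (seed included) reproduces the dataset bit for bit.
#'
#' @param config a [simConfig()] list.
#' @return a list with `expression` (cells x genes `log1p` matrix),
#'   `labels` (factor of committed types), `markers` (named list of marker
#'   gene ids per type), `typeMeans` (types x genes count-scale means),
#'   `rootMean` (baseline count-mean vector, the progenitor root profile)
#'   and `config`.
#' @examples
#' ref <- simulateReference(simConfig(nTypes = 3, nGenes = 90,
#'                                    cellsPerType = 20, seed = 2))
#' dim(ref$expression)
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "capsSimConfig"))
  l <- config$nTypes; g <- config$nGenes
  genes <- .geneIds(g)
  types <- .typeNames(l)
  .withSeed(config$seed, {
    pool <- sample.int(g, l * config$markersPerType)
    markers <- split(pool, rep(seq_len(l), each = config$markersPerType))
    names(markers) <- types
    typeMeans <- matrix(config$baselineMean, l, g,
                        dimnames = list(types, genes))
    for (k in seq_len(l))
      typeMeans[k, markers[[k]]] <- config$baselineMean * exp(config$markerLogFold)
    markers <- lapply(markers, function(ix) genes[sort(ix)])

    n <- l * config$cellsPerType
    mus <- typeMeans[rep(seq_len(l), each = config$cellsPerType), , drop = FALSE]
    counts <- .drawCounts(mus, config)
    expr <- log1p(counts)
    labels <- factor(rep(types, each = config$cellsPerType), levels = types)
    dimnames(expr) <- list(
      sprintf("%s_c%04d", labels, unlist(lapply(tabulate(labels, l), seq_len))),
      genes
    )
    list(expression = expr, labels = labels, markers = markers,
         typeMeans = typeMeans,
         rootMean = stats::setNames(rep(config$baselineMean, g), genes),
         config = config)
  })
}

#' Simulate progenitor cells with a planted differentiation coordinate
#'
#' @description
#' For each lineage `k` and each mixing coefficient `t` in the grid, draws
#' `progenitorsPerT` cells whose count means are
#' `(1 - t) * root + t * typeMean_k`, where the root profile is the bare
#' baseline (no markers elevated). At `t = 0` all lineages coincide with the
#' root; at `t = 1` they match the committed type. The planted `t` is
#' returned as ground truth.
#'
#' @param config a [simConfig()] list.
#' @param reference output of [simulateReference()] under the same config.
#' @param lineages type indices to generate progenitors for; default all.
#' @return a list with `expression` (cells x genes `log1p` matrix) and
#'   `truth` (data.frame: `cell_id`, `lineage`, `t`).
#' @examples
#' cfg <- simConfig(nTypes = 3, nGenes = 90, cellsPerType = 20,
#'                  progenitorGrid = c(0.2, 0.8), progenitorsPerT = 5)
#' prog <- simulateProgenitors(cfg, simulateReference(cfg))
#' table(prog$truth$lineage, prog$truth$t)
#' @export
simulateProgenitors <- function(config, reference,
                                lineages = seq_len(config$nTypes)) {
  stopifnot(inherits(config, "capsSimConfig"))
  if (length(config$progenitorGrid) == 0)
    stop("progenitorGrid is empty: no progenitors to simulate")
  types <- rownames(reference$typeMeans)
  root <- reference$rootMean
  rows <- expand.grid(rep = seq_len(config$progenitorsPerT),
                      t = config$progenitorGrid, lineage = lineages)
  mus <- matrix(0, nrow(rows), config$nGenes)
  for (r in seq_len(nrow(rows))) {
    k <- rows$lineage[r]; tt <- rows$t[r]
    mus[r, ] <- (1 - tt) * root + tt * reference$typeMeans[k, ]
  }
  .withSeed(config$seed + 1000L, {
    expr <- log1p(.drawCounts(mus, config))
    ids <- sprintf("prog_%s_t%03d_%03d", types[rows$lineage],
                   round(rows$t * 100), rows$rep)
    dimnames(expr) <- list(ids, names(root))
    list(expression = expr,
         truth = data.frame(cell_id = ids,
                            lineage = types[rows$lineage],
                            t = rows$t, stringsAsFactors = FALSE))
  })
}

#' Simulate doublets with planted type pairs
#'
#' @description
#' Each doublet's count means are the element-wise sum of its two committed
#' types' mean profiles (transcripts mix on the count scale); counts are then
#' drawn and `log1p`-transformed as for singlets. The planted pair is
#' returned as ground truth.
#'
#' @param config a [simConfig()] list; `doubletPairs` must name distinct
#'   types.
#' @param reference output of [simulateReference()] under the same config.
#' @return a list with `expression` and `truth` (data.frame: `cell_id`,
#'   `typeA`, `typeB`).
#' @examples
#' cfg <- simConfig(nTypes = 3, nGenes = 90, cellsPerType = 20,
#'                  doubletPairs = list(c(1, 3)), doubletsPerPair = 10)
#' dbl <- simulateDoublets(cfg, simulateReference(cfg))
#' head(dbl$truth)
#' @export
simulateDoublets <- function(config, reference) {
  stopifnot(inherits(config, "capsSimConfig"))
  types <- rownames(reference$typeMeans)
  nPairs <- length(config$doubletPairs)
  if (nPairs == 0) stop("no doublet pairs configured")
  rows <- expand.grid(rep = seq_len(config$doubletsPerPair),
                      pair = seq_len(nPairs))
  mus <- matrix(0, nrow(rows), config$nGenes)
  for (r in seq_len(nrow(rows))) {
    p <- config$doubletPairs[[rows$pair[r]]]
    mus[r, ] <- reference$typeMeans[p[1], ] + reference$typeMeans[p[2], ]
  }
  .withSeed(config$seed + 2000L, {
    expr <- log1p(.drawCounts(mus, config))
    pa <- vapply(config$doubletPairs, function(p) types[p[1]], character(1))
    pb <- vapply(config$doubletPairs, function(p) types[p[2]], character(1))
    ids <- sprintf("dbl_%s_%s_%03d", pa[rows$pair], pb[rows$pair], rows$rep)
    dimnames(expr) <- list(ids, colnames(reference$typeMeans))
    list(expression = expr,
         truth = data.frame(cell_id = ids, typeA = pa[rows$pair],
                            typeB = pb[rows$pair], stringsAsFactors = FALSE))
  })
}
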
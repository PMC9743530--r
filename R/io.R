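## Readers and writers for the supported exchange formats: dense delimited
## expression (header row of gene ids, first column of cell ids), MatrixMarket
## triplets with features/barcodes sidecars, two-column label tables, and the
## on-disk model checkpoint (JSON config + raw little-endian weight block).

.modelFormatVersion <- 1L

#' Read a cells-x-genes expression matrix
#'
#' @description
#' Reads either a dense delimited file (first row gene identifiers, first
#' column cell identifiers; tab or comma separated) or a MatrixMarket `.mtx`
#' triplet with `features.tsv`/`genes.tsv` and `barcodes.tsv` sidecars in the
#' same directory (genes-x-cells, as written by 10x-style pipelines; the
#' orientation is normalized to cells x genes). Values must be finite;
#' negative values produce a warning, not an error. Ragged rows and duplicate
#' gene identifiers are reported as parse errors.
#'
#' @param path file path (`.mtx` for MatrixMarket).
#' @param format `"auto"` (by extension, default), `"dense"` or `"mtx"`.
#' @return a numeric matrix, cells x genes, with cell/gene identifiers as
#'   dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' writeExpression(m, f)
#' all.equal(readExpression(f), m)
#' @export
readExpression <- function(path, format = c("auto", "dense", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  x <- if (format == "mtx") .readMtx(path) else .readDense(path)
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains NA or non-finite values")
  if (any(x < 0))
    warning(sprintf("%d negative expression value(s) found; expected nonnegative log-scale data",
                    sum(x < 0)))
  x
}

.readDense <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(nf) < 2) stop("dense expression file needs a header and at least one cell row")
  expected <- nf[2]
  bad <- which(nf[-1] != expected) + 1L
  if (length(bad))
    stop("ragged row(s) in ", path, " at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!nf[1] %in% c(expected, expected - 1L))
    stop("header of ", path, " (line 1) has ", nf[1],
         " fields; expected ", expected - 1L, " or ", expected)
  hdr <- strsplit(first, sep, fixed = TRUE)[[1]]
  genes <- if (nf[1] == expected) hdr[-1] else hdr
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s) in header: ", paste(unique(dup), collapse = ", "))
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "\"",
                          comment.char = "")
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  colnames(x) <- genes
  x
}

.readMtx <- function(path) {
  dir <- dirname(path)
  featPath <- NULL
  for (cand in c("features.tsv", "genes.tsv")) {
    if (file.exists(file.path(dir, cand))) featPath <- file.path(dir, cand)
  }
  if (is.null(featPath))
    stop("missing sidecar features.tsv (or genes.tsv) next to ", path)
  bcPath <- file.path(dir, "barcodes.tsv")
  if (!file.exists(bcPath))
    stop("missing sidecar barcodes.tsv next to ", path)
  m <- Matrix::readMM(path)
  feat <- utils::read.table(featPath, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  genes <- feat[[1]]
  barcodes <- utils::read.table(bcPath, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s) in ", featPath, ": ",
         paste(unique(dup), collapse = ", "))
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    x <- t(as.matrix(m))                      # genes x cells -> cells x genes
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
    x <- as.matrix(m)
  } else {
    stop(sprintf("matrix is %d x %d but sidecars list %d features and %d barcodes",
                 nrow(m), ncol(m), length(genes), length(barcodes)))
  }
  dimnames(x) <- list(barcodes, genes)
  x
}

#' Write an expression matrix
#'
#' @description
#' Writes a cells-x-genes matrix either as a dense TSV (header row of gene
#' ids, first column of cell ids) or as a MatrixMarket triplet plus
#' `features.tsv` and `barcodes.tsv` sidecars (stored genes x cells).
#'
#' @param x cells-x-genes matrix with dimnames.
#' @param path output path (for `"mtx"`, the `.mtx` file; sidecars go next
#'   to it).
#' @param format `"dense"` (default) or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, format = c("dense", "mtx")) {
  format <- match.arg(format)
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (format == "dense") {
    utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(t(x), sparse = TRUE), "generalMatrix"),
                    path)
    dir <- dirname(path)
    writeLines(colnames(x), file.path(dir, "features.tsv"))
    writeLines(rownames(x), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read per-cell type labels
#'
#' @description
#' Reads a two-column delimited table (`cell_id`, `type`; header optional)
#' and returns a factor of labels. Type order follows first appearance unless
#' `typeNames` is given. When `cellIds` is supplied the labels are matched to
#' those cells: labels for unknown cells, or cells without labels, are
#' reported with their identifiers.
#'
#' @param path label file path.
#' @param typeNames optional explicit type order.
#' @param cellIds optional cell identifiers (e.g. `rownames` of the
#'   expression matrix) to match and order against.
#' @return a factor of labels, named by cell id.
#' @export
readLabels <- function(path, typeNames = NULL, cellIds = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          col.names = c("cell_id", "type"))
  ## tolerate a header line
  if (nrow(df) && tolower(df$cell_id[1]) %in% c("cell_id", "cell", "barcode"))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) != 2 || nrow(df) == 0) stop("labels must be a two-column table")
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell id(s) in labels: ",
         paste(utils::head(unique(df$cell_id[duplicated(df$cell_id)]), 5),
               collapse = ", "))
  if (!is.null(cellIds)) {
    unknown <- setdiff(df$cell_id, cellIds)
    if (length(unknown))
      stop("label file names cell(s) absent from the expression matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    missing <- setdiff(cellIds, df$cell_id)
    if (length(missing))
      stop("no label for cell(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    df <- df[match(cellIds, df$cell_id), , drop = FALSE]
  }
  lv <- if (is.null(typeNames)) unique(df$type) else typeNames
  y <- factor(df$type, levels = lv)
  if (anyNA(y))
    stop("label(s) outside the given type names: ",
         paste(unique(df$type[is.na(y)]), collapse = ", "))
  names(y) <- df$cell_id
  y
}

#' Save or load a trained model checkpoint
#'
#' @description
#' `saveCapsModel()` writes a directory checkpoint: a human-readable
#' `config.json` (format version, every configuration field, type names,
#' gene identifiers, training loss) and `weights.bin`, the primary, bias and
#' transformation weights as a raw little-endian double block. The round trip
#' is exact: `loadCapsModel(saveCapsModel(m, p))` predicts identically to
#' `m` on any input. A version mismatch or truncated weight block is a clean
#' error.
#'
#' @param model a [CapsuleModel-class].
#' @param path checkpoint directory (created if needed).
#' @return `saveCapsModel()`: `path`, invisibly. `loadCapsModel()`: the
#'   restored [CapsuleModel-class].
#' @examples
#' sim <- simulateReference(simConfig(nTypes = 3, nGenes = 60,
#'                                    cellsPerType = 30, seed = 1))
#' fit <- trainCapsNet(sim$expression, sim$labels,
#'                     capsConfig(3, 60, dimCapsule = 4, epochs = 2, seed = 1))
#' p <- file.path(tempdir(), "caps-ckpt")
#' saveCapsModel(fit, p)
#' fit2 <- loadCapsModel(p)
#' identical(predict(fit, sim$expression)$probabilities,
#'           predict(fit2, sim$expression)$probabilities)
#' @export
saveCapsModel <- function(model, path) {
  stopifnot(methods::is(model, "CapsuleModel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- model@config
  meta <- list(
    format_version = .modelFormatVersion,
    config = list(
      nTypes = cfg@nTypes, nGenes = cfg@nGenes, dimCapsule = cfg@dimCapsule,
      activation = cfg@activation, routingIterations = cfg@routingIterations,
      lr = cfg@lr, batchSize = cfg@batchSize, epochs = cfg@epochs,
      mPlus = cfg@mPlus, mMinus = cfg@mMinus, lambdaDown = cfg@lambdaDown,
      seed = cfg@seed
    ),
    typeNames = model@typeNames,
    geneIds = model@geneIds,
    trainLoss = model@trainLoss
  )
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "weights.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(model@primaryWeights), con, size = 8, endian = "little")
  writeBin(as.vector(model@primaryBias), con, size = 8, endian = "little")
  writeBin(as.vector(model@transformWeights), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname saveCapsModel
#' @export
loadCapsModel <- function(path) {
  cfgPath <- file.path(path, "config.json")
  binPath <- file.path(path, "weights.bin")
  if (!file.exists(cfgPath) || !file.exists(binPath))
    stop("not a model checkpoint (missing config.json or weights.bin): ", path)
  meta <- jsonlite::read_json(cfgPath, simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version != .modelFormatVersion)
    stop(sprintf("checkpoint format version %s; this package expects version %d",
                 as.character(meta$format_version %||% "missing"),
                 .modelFormatVersion))
  cf <- meta$config
  cfg <- capsConfig(cf$nTypes, cf$nGenes, cf$dimCapsule, cf$activation,
                    cf$routingIterations, cf$lr, cf$batchSize, cf$epochs,
                    cf$mPlus, cf$mMinus, cf$lambdaDown, cf$seed)
  l <- cfg@nTypes; d <- cfg@dimCapsule; g <- cfg@nGenes
  nVals <- l * d * g + l * d + l * l * d * d
  if (file.info(binPath)$size != nVals * 8)
    stop(sprintf("truncated or corrupt weights.bin: %d bytes, expected %d",
                 file.info(binPath)$size, nVals * 8))
  con <- file(binPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = nVals, size = 8, endian = "little")
  methods::new("CapsuleModel",
    config = cfg,
    primaryWeights = array(vals[seq_len(l * d * g)], c(l, d, g)),
    primaryBias = matrix(vals[l * d * g + seq_len(l * d)], l, d),
    transformWeights = array(vals[l * d * g + l * d + seq_len(l * l * d * d)],
                             c(l, l, d, d)),
    typeNames = meta$typeNames,
    geneIds = meta$geneIds,
    trainLoss = as.numeric(meta$trainLoss)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
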
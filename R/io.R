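# CSV dialects (network, expression, prior, surface) and the signed
# edge-list importer for the real-data path.
#
# Network CSV: header row = TF names, first column = gene names (TFs first,
# then TAs), cells = signed decimal weights, 0 = no edge. All readers/writers
# are locale-independent ("." decimal separator, fixed column order).

#' Write / read a network CSV
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path file path.
#' @param spectralState conditioning state to stamp on the read network (the
#'   CSV stores only the matrix).
#' @return \code{readNetworkCsv} returns a [RegulatoryNetwork-class];
#'   \code{writeNetworkCsv} returns \code{path} invisibly.
#' @export
writeNetworkCsv <- function(net, path) {
  stopifnot(is(net, "RegulatoryNetwork"))
  N <- networkMatrix(net)
  df <- data.frame(gene = rownames(N), N, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeNetworkCsv
#' @export
readNetworkCsv <- function(path, spectralState = "raw") {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("network CSV needs a gene column plus TF columns")
  genes <- as.character(df[[1]])
  N <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(N) <- "double"
  tfNames <- colnames(N)
  ntf <- length(tfNames)
  if (!identical(genes[seq_len(ntf)], tfNames))
    stop("first ", ntf, " gene rows must match the TF columns; mismatch at '",
         tfNames[which(genes[seq_len(ntf)] != tfNames)[1]], "'")
  new("RegulatoryNetwork",
      A = unname(N[seq_len(ntf), , drop = FALSE]),
      B = unname(N[-seq_len(ntf), , drop = FALSE]),
      geneNames = genes, config = list(),
      spectralState = spectralState, liftedPairs = 0L)
}

#' Write / read an expression CSV
#'
#' First column = gene names in network order, remaining columns experiments
#' (\code{S<k>} for multistart, \code{E<t>} for dynamic). Only observations
#' are stored; the latent log trajectory is a simulation-time object.
#'
#' @param expr an [ExpressionDataset-class].
#' @param path file path.
#' @param net optional [RegulatoryNetwork-class]; when given, read rows are
#'   aligned to its gene order (error on any missing gene).
#' @return \code{readExpressionCsv} returns an [ExpressionDataset-class]
#'   (observations assay only).
#' @export
writeExpressionCsv <- function(expr, path) {
  stopifnot(is(expr, "ExpressionDataset"))
  X <- observations(expr)
  df <- data.frame(gene = rownames(X), X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeExpressionCsv
#' @export
readExpressionCsv <- function(path, net = NULL) {
  df <- read.csv(path, check.names = FALSE)
  genes <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- genes
  if (!is.null(net)) {
    idx <- match(net@geneNames, genes)
    if (anyNA(idx))
      stop("expression table is missing gene '",
           net@geneNames[which(is.na(idx))[1]], "' required by the network")
    X <- X[idx, , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(observations = X), metadata = list(config = NULL))
  new("ExpressionDataset", se)
}

#' Write / read a prior-knowledge CSV
#'
#' Same grid as the network CSV; known cells carry -1/0/+1, unknown cells are
#' empty strings.
#'
#' @param prior a [PriorKnowledge-class].
#' @param path file path.
#' @param geneNames,tfNames row/column names for the grid.
#' @return \code{readPriorCsv} returns a [PriorKnowledge-class] (orientation
#'   recorded as stored on write is not part of the dialect; it is set to
#'   \code{"rows"} and alpha to the observed known fraction).
#' @export
writePriorCsv <- function(prior, path, geneNames = NULL, tfNames = NULL) {
  stopifnot(is(prior, "PriorKnowledge"))
  V <- prior@knownValues
  cells <- matrix("", nrow(V), ncol(V))
  cells[prior@knownMask] <- format(V[prior@knownMask], trim = TRUE,
                                   scientific = FALSE)
  gn <- geneNames %||% sprintf("g%d", seq_len(nrow(V)))
  tn <- tfNames %||% sprintf("TF%d", seq_len(ncol(V)))
  df <- data.frame(gene = gn, cells, check.names = FALSE)
  colnames(df) <- c("gene", tn)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePriorCsv
#' @export
readPriorCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  raw <- as.matrix(df[, -1, drop = FALSE])
  mask <- raw != "" & !is.na(raw)
  vals <- matrix(0, nrow(raw), ncol(raw))
  vals[mask] <- as.numeric(raw[mask])
  new("PriorKnowledge", knownMask = unname(mask), knownValues = unname(vals),
      orientation = "rows", alpha = mean(mask),
      errorLog = data.frame(row = integer(0), col = integer(0),
                            type = character(0), old = numeric(0),
                            new = numeric(0)),
      seed = NA_real_)
}

#' Write / read a surface CSV (long format)
#'
#' Columns \code{n}, \code{alpha}, \code{tp_pct}, \code{fp_pct_fdr},
#' \code{fp_pct_fpr}, one row per grid point.
#'
#' @param surface an [EvalSurface-class].
#' @param path file path.
#' @return \code{readSurfaceCsv} returns an [EvalSurface-class].
#' @export
writeSurfaceCsv <- function(surface, path) {
  stopifnot(is(surface, "EvalSurface"))
  write.csv(surface@grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSurfaceCsv
#' @export
readSurfaceCsv <- function(path) {
  g <- read.csv(path)
  need <- c("n", "alpha", "tp_pct", "fp_pct_fdr", "fp_pct_fpr")
  if (!all(need %in% names(g))) stop("surface CSV lacks required columns")
  new("EvalSurface", grid = g, ns = sort(unique(g$n)),
      alphas = sort(unique(g$alpha)), orientation = "rows")
}

#' Import a signed regulator-target edge list as a network
#'
#' Reads a delimited file with at least three columns (regulator, target,
#' sign) and rebuilds the signed matrix \eqn{N} with -1/0/+1 cells. Accepted
#' sign tokens (case-insensitive): \code{+}, \code{-}, \code{+1}, \code{-1},
#' \code{activator}, \code{repressor}. Any gene that regulates becomes a TF
#' (column); genes appearing only as targets are TA rows. Both groups are
#' ordered alphabetically, TFs first. Duplicate (regulator, target) pairs with
#' conflicting signs keep the last occurrence with a warning. Dual-sign
#' annotations such as \code{"+-"} are rejected: the model is single-signed.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} auto-detects tab vs comma from the
#'   first line.
#' @param header whether the file has a header line; \code{NULL} auto-detects
#'   (a first line whose third field is not a sign token).
#' @return a [RegulatoryNetwork-class] with unit-magnitude signed cells.
#' @export
readEdgeList <- function(path, sep = NULL, header = NULL) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty edge-list file")
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  peek <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (length(peek) < 3) stop("edge list needs >= 3 columns (regulator, target, sign)")
  if (is.null(header))
    header <- is.na(.parseSign(peek[3], strict = FALSE))
  df <- read.csv(path, sep = sep, header = header,
                 colClasses = "character", check.names = FALSE)
  if (!nrow(df)) stop("edge list has no records")
  reg <- trimws(df[[1]]); tgt <- trimws(df[[2]])
  sgn <- vapply(trimws(df[[3]]), .parseSign, numeric(1), strict = TRUE,
                USE.NAMES = FALSE)
  key <- paste(reg, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    lastIdx <- !duplicated(key, fromLast = TRUE)
    conflict <- tapply(sgn, key, function(s) length(unique(s)) > 1)
    if (any(conflict))
      warning(sum(conflict), " duplicated regulator-target pair(s) with ",
              "conflicting signs; keeping the last occurrence")
    reg <- reg[lastIdx]; tgt <- tgt[lastIdx]; sgn <- sgn[lastIdx]
  }
  tfs <- sort(unique(reg))
  tas <- sort(setdiff(unique(tgt), tfs))
  genes <- c(tfs, tas)
  N <- matrix(0, length(genes), length(tfs))
  N[cbind(match(tgt, genes), match(reg, tfs))] <- sgn
  new("RegulatoryNetwork",
      A = N[seq_along(tfs), , drop = FALSE],
      B = N[length(tfs) + seq_along(tas), , drop = FALSE],
      geneNames = genes, config = list(),
      spectralState = "raw", liftedPairs = 0L)
}

.parseSign <- function(token, strict = TRUE) {
  t <- tolower(token)
  if (t %in% c("+", "+1", "1", "activator")) return(1)
  if (t %in% c("-", "-1", "repressor")) return(-1)
  if (t %in% c("+-", "-+", "+/-"))
    if (strict) stop("dual-sign annotation '", token,
                     "' is not representable in a single-signed model")
  if (strict) stop("unknown sign token '", token, "'")
  NA_real_
}
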
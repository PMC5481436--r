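#' Accessors for grnforge objects
#'
#' Small accessor generics: \code{nTF}/\code{nTA} give the number of
#' transcription factors / target genes, \code{networkMatrix} returns the full
#' stacked matrix \eqn{N = [A; B]} with dimnames, \code{spectralState} reports
#' the conditioning state, \code{observations}/\code{latentLogs} extract assay
#' matrices from an [ExpressionDataset-class], \code{knownMask} the prior mask.
#'
#' @param x an object.
#' @return see individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTF", function(x) standardGeneric("nTF"))

#' @rdname accessors
#' @export
setGeneric("nTA", function(x) standardGeneric("nTA"))

#' @rdname accessors
#' @export
setGeneric("networkMatrix", function(x) standardGeneric("networkMatrix"))

#' @rdname accessors
#' @export
setGeneric("spectralState", function(x) standardGeneric("spectralState"))

#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname accessors
#' @export
setGeneric("latentLogs", function(x) standardGeneric("latentLogs"))

#' @rdname accessors
#' @export
setGeneric("knownMask", function(x) standardGeneric("knownMask"))

#' @rdname accessors
#' @export
setGeneric("knownValues", function(x) standardGeneric("knownValues"))

#' @rdname accessors
#' @export
setMethod("nTF", "RegulatoryNetwork", function(x) nrow(x@A))

#' @rdname accessors
#' @export
setMethod("nTA", "RegulatoryNetwork", function(x) nrow(x@B))

#' @rdname accessors
#' @export
setMethod("networkMatrix", "RegulatoryNetwork", function(x) {
  N <- rbind(x@A, x@B)
  dimnames(N) <- list(x@geneNames, x@geneNames[seq_len(nTF(x))])
  N
})

#' @rdname accessors
#' @export
setMethod("spectralState", "RegulatoryNetwork", function(x) x@spectralState)

#' @rdname accessors
#' @export
setMethod("observations", "ExpressionDataset", function(x)
  SummarizedExperiment::assay(x, "observations"))

#' @rdname accessors
#' @export
setMethod("latentLogs", "ExpressionDataset", function(x) {
  if (!"latentLogs" %in% SummarizedExperiment::assayNames(x))
    stop("this dataset carries no latent log-expression (imported data?)")
  SummarizedExperiment::assay(x, "latentLogs")
})

#' @rdname accessors
#' @export
setMethod("knownMask", "PriorKnowledge", function(x) x@knownMask)

#' @rdname accessors
#' @export
setMethod("knownValues", "PriorKnowledge", function(x) x@knownValues)

setMethod("show", "RegulatoryNetwork", function(object) {
  N <- rbind(object@A, object@B)
  cat(sprintf("RegulatoryNetwork: %d TF, %d TA, %d edges (%s)\n",
              nTF(object), nTA(object), sum(N != 0), object@spectralState))
  if (object@spectralState == "lifted")
    cat(sprintf("  lifted conjugate pairs: %d\n", object@liftedPairs))
})

setMethod("show", "SpectralConditioning", function(object) {
  cat(sprintf("SpectralConditioning: p = %d, %d eigenvalue(s) on the unit circle (tol %g)\n",
              object@p, object@unitCircleCount, object@tolerance))
  cat(sprintf("  max imaginary residue discarded: %.3g\n", object@maxImagResidue))
})

setMethod("show", "PriorKnowledge", function(object) {
  cat(sprintf("PriorKnowledge: %s orientation, alpha = %g; %d of %d cells known, %d corruptions\n",
              object@orientation, object@alpha, sum(object@knownMask),
              length(object@knownMask), nrow(object@errorLog)))
})

setMethod("show", "EdgeExampleSet", function(object) {
  cat(sprintf("EdgeExampleSet: %d train cells (%d non-null), %d query cells, feature length %d\n",
              nrow(object@train), sum(object@train$label != 0),
              nrow(object@query), 2L * ncol(object@geneProfiles)))
})

setMethod("show", "EdgeClassifier", function(object) {
  cat(sprintf("EdgeClassifier: RBF-kernel SVM, sigma = %.4g, cost = %g, %d training cells\n",
              object@sigma, object@cost, nrow(object@train)))
})

setMethod("show", "EvalSurface", function(object) {
  cat(sprintf("EvalSurface: %d x %d grid (%s prior), mean TP%% = %.1f, mean FP%% (FDR) = %.1f\n",
              length(object@ns), length(object@alphas), object@orientation,
              mean(object@grid$tp_pct), mean(object@grid$fp_pct_fdr)))
})
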
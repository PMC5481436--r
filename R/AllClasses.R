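#' @import methods
#' @import kernlab
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats rnorm runif median sd lm quantile
#' @importFrom utils read.csv write.csv head
NULL

#' RegulatoryNetwork: a signed, weighted transcriptional network
#'
#' The network matrix \eqn{N} stacks two blocks: \eqn{A} (regulator-on-regulator
#' effects, square, rows = regulated TF, columns = regulator TF) and \eqn{B}
#' (regulator-on-target effects, rows = regulated target gene). A zero cell
#' means no edge; the sign of a nonzero cell is the direction of regulation
#' (activation/repression).
#'
#' @slot A numeric matrix, \code{nTF x nTF}, TF-on-TF weights.
#' @slot B numeric matrix, \code{nTA x nTF}, TF-on-target weights.
#' @slot geneNames character, TFs first then targets; row names of \eqn{N}.
#' @slot config list, the generation parameters (see [networkConfig()]).
#' @slot spectralState character, one of \code{"raw"}, \code{"normalized"},
#'   \code{"lifted"}: whether the iteration matrix \eqn{M = I + A} has been
#'   standardized to spectral radius 1, and whether conjugate eigenvalue pairs
#'   have been lifted onto the unit circle.
#' @slot liftedPairs integer, number of conjugate pairs lifted (0 unless
#'   \code{spectralState == "lifted"}).
#'
#' @seealso [generateNetwork()], [normalizeSpectralRadius()], [liftEigenvalues()]
#' @export
setClass("RegulatoryNetwork",
         slots = c(A = "matrix", B = "matrix", geneNames = "character",
                   config = "list", spectralState = "character",
                   liftedPairs = "integer"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  if (nrow(object@A) != ncol(object@A))
    msg <- c(msg, "A must be square")
  if (ncol(object@B) != ncol(object@A) && nrow(object@B) > 0)
    msg <- c(msg, "B must have as many columns as A")
  if (length(object@geneNames) != nrow(object@A) + nrow(object@B))
    msg <- c(msg, "geneNames must have length nTF + nTA")
  if (anyDuplicated(object@geneNames))
    msg <- c(msg, "geneNames must be unique")
  if (!object@spectralState %in% c("raw", "normalized", "lifted"))
    msg <- c(msg, "spectralState must be raw, normalized or lifted")
  if (length(msg)) msg else TRUE
})

#' SpectralConditioning: record of an eigenvalue-lifting operation
#'
#' Bookkeeping for the conditioning step that moves \code{p} conjugate
#' eigenvalue pairs of the iteration matrix onto the unit circle by a purely
#' imaginary (vertical) shift, making the linear dynamics stably oscillatory.
#'
#' @slot p integer, number of conjugate pairs lifted.
#' @slot liftedBefore,liftedAfter complex, the moved eigenvalues before and
#'   after the shift (length \code{2p}).
#' @slot perturbation numeric matrix \eqn{E_p}: lifted iteration matrix minus
#'   the normalized one (real; the imaginary reconstruction residue is
#'   discarded and its maximum magnitude recorded).
#' @slot unitCircleCount integer, eigenvalues with modulus within
#'   \code{tolerance} of 1 after the lift.
#' @slot tolerance numeric, modulus tolerance for "on the unit circle".
#' @slot maxImagResidue numeric, largest imaginary entry discarded when making
#'   the reconstructed matrix real.
#' @export
setClass("SpectralConditioning",
         slots = c(p = "integer", liftedBefore = "complex",
                   liftedAfter = "complex", perturbation = "matrix",
                   unitCircleCount = "integer", tolerance = "numeric",
                   maxImagResidue = "numeric"))

#' ExpressionDataset: simulated (or imported) expression observations
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"observations"}
#' (expression on the natural scale, \code{exp(latent) + noise}) and, for
#' simulated data, assay \code{"latentLogs"} (the noise-free log-scale
#' trajectory). Rows follow the network's gene order; columns are experiments
#' (independent starts in multistart mode, successive steps in dynamic mode).
#'
#' @seealso [simulateMultistart()], [simulateDynamic()], [observations()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!"observations" %in% an)
    return("assay 'observations' is required")
  TRUE
})

#' PriorKnowledge: a partial, possibly corrupted view of the network
#'
#' A mask over the cells of \eqn{N} marking which edge labels are revealed to
#' the learner, together with those labels (signs in \{-1, 0, +1\}). Rows
#' orientation emulates target-centred assays (e.g. enhanced yeast one-hybrid);
#' columns orientation emulates TF-centred assays (ChIP-seq, DAP-seq).
#'
#' @slot knownMask logical matrix, same shape as \eqn{N}; \code{TRUE} = label given.
#' @slot knownValues numeric matrix of labels in \{-1, 0, 1\}; meaningful only
#'   where \code{knownMask} is \code{TRUE}.
#' @slot orientation character, \code{"rows"} or \code{"columns"}.
#' @slot alpha numeric, revealed fraction.
#' @slot errorLog data.frame of injected corruptions
#'   (columns \code{row}, \code{col}, \code{type}, \code{old}, \code{new}).
#' @slot seed numeric, RNG seed used for the selection (NA if none).
#' @seealso [makePrior()], [injectErrors()]
#' @export
setClass("PriorKnowledge",
         slots = c(knownMask = "matrix", knownValues = "matrix",
                   orientation = "character", alpha = "numeric",
                   errorLog = "data.frame", seed = "numeric"))

setValidity("PriorKnowledge", function(object) {
  msg <- character()
  if (!identical(dim(object@knownMask), dim(object@knownValues)))
    msg <- c(msg, "knownMask and knownValues must share dimensions")
  if (!is.logical(object@knownMask))
    msg <- c(msg, "knownMask must be logical")
  kv <- object@knownValues[object@knownMask]
  if (length(kv) && !all(kv %in% c(-1, 0, 1)))
    msg <- c(msg, "known labels must be -1, 0 or +1")
  if (!object@orientation %in% c("rows", "columns"))
    msg <- c(msg, "orientation must be 'rows' or 'columns'")
  if (length(msg)) msg else TRUE
})

#' EdgeExampleSet: per-cell training and query examples for edge learning
#'
#' One example per cell (gene i, TF j) of \eqn{N}. The feature vector of a cell
#' is the concatenation of gene i's and TF j's per-gene standardized expression
#' profiles (length \code{2 * nExperiments}); profiles are stored once and the
#' concatenation is implicit, which is what makes desk-scale learning on
#' 10^5 cells feasible. Use [edgeFeatures()] to materialize explicit vectors.
#'
#' @slot geneProfiles numeric matrix, genes x experiments, z-scored per gene
#'   (standardization computed once on the dataset, shared by train and query).
#' @slot nTF integer, number of TFs (profiles of TFs are the first rows).
#' @slot train data.frame with columns \code{i}, \code{j}, \code{label}
#'   (the known cells of the prior, row-major order).
#' @slot query data.frame with columns \code{i}, \code{j} (the unknown cells).
#' @slot geneNames character.
#' @seealso [buildEdgeExamples()], [balanceTraining()]
#' @export
setClass("EdgeExampleSet",
         slots = c(geneProfiles = "matrix", nTF = "integer",
                   train = "data.frame", query = "data.frame",
                   geneNames = "character"))

setValidity("EdgeExampleSet", function(object) {
  msg <- character()
  if (!all(c("i", "j", "label") %in% names(object@train)))
    msg <- c(msg, "train needs columns i, j, label")
  if (!all(c("i", "j") %in% names(object@query)))
    msg <- c(msg, "query needs columns i, j")
  if (nrow(object@geneProfiles) != length(object@geneNames))
    msg <- c(msg, "one profile row per gene is required")
  if (length(msg)) msg else TRUE
})

#' EdgeClassifier: a fitted RBF-kernel SVM over edge examples
#'
#' Wraps a kernlab C-classification SVM trained on a precomputed RBF kernel
#' matrix, together with the training cells and the selected kernel width, so
#' that prediction can re-evaluate the kernel from decomposed gene/TF
#' distances.
#'
#' @slot fit the underlying \code{kernlab::ksvm} model.
#' @slot sigma numeric, RBF width (kernel is \code{exp(-sigma * d^2)}).
#' @slot sigmaGrid numeric, widths explored during cross-validation (empty if
#'   the width was given).
#' @slot cvScores numeric, mean balanced accuracy per grid value.
#' @slot cost numeric, constraint-violation cost.
#' @slot train data.frame, the (balanced) training cells the model was fit on.
#' @slot levels character, label levels seen in training.
#' @seealso [trainEdgeClassifier()], [predictEdges()]
#' @export
setClass("EdgeClassifier",
         slots = c(fit = "ANY", sigma = "numeric", sigmaGrid = "numeric",
                   cvScores = "numeric", cost = "numeric",
                   train = "data.frame", levels = "character"))

#' EvalSurface: reconstruction scores over an (experiments x alpha) grid
#'
#' Long-format grid of signed true-positive and false-positive percentages for
#' each (number of experiments, prior fraction) pair, with volume-under-surface
#' summaries computed by [volumeUnderSurface()].
#'
#' @slot grid data.frame with columns \code{n}, \code{alpha}, \code{tp_pct},
#'   \code{fp_pct_fdr}, \code{fp_pct_fpr}.
#' @slot ns,alphas numeric, the swept axis values.
#' @slot orientation character, prior orientation used.
#' @seealso [sweepSurface()]
#' @export
setClass("EvalSurface",
         slots = c(grid = "data.frame", ns = "numeric", alphas = "numeric",
                   orientation = "character"))
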
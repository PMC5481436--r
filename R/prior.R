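# Prior-knowledge masks over the network and controlled corruption.

#' Reveal a fraction of the network as prior knowledge
#'
#' Selects \code{round(alpha * nrow(N))} full rows (target-oriented prior:
#' every regulator of the chosen genes is known, as an enhanced yeast
#' one-hybrid screen would give) or \code{round(alpha * nTF)} full columns
#' (TF-oriented prior: the full target set of the chosen TFs is known, as
#' ChIP-seq/DAP-seq would give), uniformly at random without replacement.
#' Revealed labels are the signs of the true weights.
#'
#' @param net a [RegulatoryNetwork-class] (the ground truth).
#' @param alpha revealed fraction in [0, 1].
#' @param orientation \code{"rows"} or \code{"columns"}.
#' @param seed RNG seed.
#' @param taRowsOnly if \code{TRUE}, row selection is restricted to target
#'   (TA) rows; by default all rows of \eqn{N} are eligible, since
#'   target-oriented assays can probe any promoter, TF or TA.
#' @return a [PriorKnowledge-class].
#' @examples
#' net <- generateNetwork(networkConfig(10, 40, seed = 1))
#' pk <- makePrior(net, alpha = 0.3, orientation = "rows", seed = 2)
#' sum(rowSums(knownMask(pk)) > 0)
#' @export
makePrior <- function(net, alpha, orientation = c("rows", "columns"),
                      seed = NULL, taRowsOnly = FALSE) {
  stopifnot(is(net, "RegulatoryNetwork"))
  orientation <- match.arg(orientation)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  N <- rbind(net@A, net@B)
  mask <- matrix(FALSE, nrow(N), ncol(N))
  withSeed(seed, {
    if (orientation == "rows") {
      eligible <- if (taRowsOnly) nTF(net) + seq_len(nTA(net)) else seq_len(nrow(N))
      k <- round(alpha * length(eligible))
      if (k > 0) mask[sampleVec(eligible, k), ] <- TRUE
    } else {
      k <- round(alpha * ncol(N))
      if (k > 0) mask[, sampleVec(seq_len(ncol(N)), k)] <- TRUE
    }
  })
  values <- sign(N)
  values[!mask] <- 0
  new("PriorKnowledge", knownMask = mask, knownValues = values,
      orientation = orientation, alpha = alpha,
      errorLog = data.frame(row = integer(0), col = integer(0),
                            type = character(0), old = numeric(0),
                            new = numeric(0)),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Corrupt prior knowledge with errors of type I, II or III
#'
#' Emulates imperfect experimental edge lists. With \eqn{E} the number of
#' nonzero known labels, \code{round(rate * E)} corruptions are injected:
#' type I turns known zero cells into spurious signed edges (fair-coin sign,
#' false positives); type II erases known edges (false negatives); type III
#' flips edge signs. The mask is never altered, only the labels; every change
#' is appended to the error log.
#'
#' @param prior a non-empty [PriorKnowledge-class].
#' @param errorType \code{"I"}, \code{"II"} or \code{"III"}.
#' @param rate corruption rate in [0, 1], relative to the number of true edges
#'   in the revealed prior (comparable across sparsities).
#' @param seed RNG seed.
#' @return the corrupted [PriorKnowledge-class].
#' @export
injectErrors <- function(prior, errorType = c("I", "II", "III"), rate,
                         seed = NULL) {
  stopifnot(is(prior, "PriorKnowledge"))
  errorType <- match.arg(errorType)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!any(prior@knownMask)) stop("prior is empty")
  known <- which(prior@knownMask)
  nzKnown <- known[prior@knownValues[known] != 0]
  zKnown <- known[prior@knownValues[known] == 0]
  nInj <- round(rate * length(nzKnown))
  if (nInj == 0) return(prior)
  vals <- prior@knownValues
  withSeed(seed, {
    if (errorType == "I") {
      if (nInj > length(zKnown))
        stop("requested type I error count exceeds available known zero cells")
      cells <- sampleVec(zKnown, nInj)
      newLab <- sample(c(-1, 1), nInj, replace = TRUE)
    } else {
      cells <- sampleVec(nzKnown, nInj)
      newLab <- if (errorType == "II") rep(0, nInj) else -vals[cells]
    }
    old <- vals[cells]
    vals[cells] <- newLab
    rc <- arrayInd(cells, dim(vals))
    prior@knownValues <- vals
    prior@errorLog <- rbind(prior@errorLog,
                            data.frame(row = rc[, 1], col = rc[, 2],
                                       type = errorType, old = old,
                                       new = newLab))
    prior
  })
}
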
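# Scoring, (experiments x alpha) surface sweeps, VUS and bootstrap.

#' Score a predicted network against the truth
#'
#' Metrics are computed only on the evaluated region (normally the cells the
#' prior did not reveal). Signed TP% = among true edges in the region, the
#' percentage predicted nonzero with the correct sign. The primary FP%
#' (\code{fp_pct_fdr}) is false-discovery style: among predicted edges, the
#' percentage whose truth is zero (0 by convention when nothing is
#' predicted). The secondary \code{fp_pct_fpr} is the classical false-positive
#' rate: among true zero cells, the percentage predicted nonzero.
#'
#' @param predicted numeric label matrix (\{-1, 0, +1\}), same shape as
#'   \eqn{N}.
#' @param truth the ground-truth [RegulatoryNetwork-class].
#' @param region logical matrix selecting the evaluated cells.
#' @return list with \code{tp_pct}, \code{fp_pct_fdr}, \code{fp_pct_fpr} and
#'   \code{counts}, the 3x3 confusion table (truth x predicted).
#' @examples
#' net <- generateNetwork(networkConfig(5, 10, seed = 1))
#' truthN <- sign(networkMatrix(net))
#' scorePrediction(truthN, net, matrix(TRUE, 15, 5))$tp_pct
#' @export
scorePrediction <- function(predicted, truth, region) {
  stopifnot(is(truth, "RegulatoryNetwork"))
  N <- rbind(truth@A, truth@B)
  if (!identical(dim(predicted), dim(N)) || !identical(dim(region), dim(N)))
    stop("predicted/region shape does not match the network")
  if (!any(region)) stop("empty evaluation region")
  tv <- sign(N[region])
  pv <- predicted[region]
  lv <- c(-1, 0, 1)
  counts <- table(factor(tv, levels = lv), factor(pv, levels = lv),
                  dnn = c("truth", "predicted"))
  nTrueEdge <- sum(tv != 0)
  nPredEdge <- sum(pv != 0)
  tp <- if (nTrueEdge) 100 * sum(tv != 0 & pv == tv) / nTrueEdge else 0
  fdr <- if (nPredEdge) 100 * sum(pv != 0 & tv == 0) / nPredEdge else 0
  fpr <- if (sum(tv == 0)) 100 * sum(pv != 0 & tv == 0) / sum(tv == 0) else 0
  list(tp_pct = tp, fp_pct_fdr = fdr, fp_pct_fpr = fpr, counts = counts)
}

#' Sweep reconstruction accuracy over an (experiments x alpha) grid
#'
#' Runs the prior -> balance -> SVM -> score pipeline at every grid point on
#' one network and one expression pool; smaller experiment counts reuse the
#' pool by column subsampling, so all grid points share the same underlying
#' randomness. Each point evaluates on the cells its own prior left unknown.
#'
#' @param net the ground-truth conditioned [RegulatoryNetwork-class].
#' @param exprPool an [ExpressionDataset-class] with at least \code{max(ns)}
#'   columns.
#' @param alphas,ns swept prior fractions and experiment counts (non-empty).
#' @param orientation prior orientation, \code{"rows"} or \code{"columns"}.
#' @param seed master seed; per-grid-point sub-seeds are derived from it.
#' @param config an [svmConfig()].
#' @param errorType,errorRate when \code{errorRate > 0}, every grid point's
#'   prior is corrupted with [injectErrors()] of this type and rate before
#'   learning (scoring still uses the clean truth).
#' @return an [EvalSurface-class].
#' @export
sweepSurface <- function(net, exprPool, alphas, ns,
                         orientation = c("rows", "columns"), seed = NULL,
                         config = svmConfig(), errorType = "I",
                         errorRate = 0) {
  stopifnot(is(net, "RegulatoryNetwork"), is(exprPool, "ExpressionDataset"))
  orientation <- match.arg(orientation)
  if (!length(alphas) || !length(ns)) stop("alphas and ns must be non-empty")
  nPool <- ncol(exprPool)
  if (max(ns) > nPool) stop("expression pool has fewer columns than max(ns)")
  pts <- expand.grid(n = ns, alpha = alphas)
  seeds <- deriveSeeds(if (is.null(seed)) 1L else seed, 2L * nrow(pts))
  rows <- vector("list", nrow(pts))
  for (r in seq_len(nrow(pts))) {
    n <- pts$n[r]; alpha <- pts$alpha[r]
    cols <- if (n == nPool) seq_len(nPool)
            else withSeed(seeds[[2 * r - 1]], sampleVec(seq_len(nPool), n))
    expr <- exprPool[, cols]
    prior <- makePrior(net, alpha, orientation, seed = seeds[[2 * r]])
    if (errorRate > 0)
      prior <- injectErrors(prior, errorType, errorRate, seed = seeds[[2 * r]])
    cfg <- config
    cfg$seed <- seeds[[2 * r]]
    res <- learnNetwork(expr, prior, cfg)
    sc <- scorePrediction(res$predicted, net, !prior@knownMask)
    rows[[r]] <- data.frame(n = n, alpha = alpha, tp_pct = sc$tp_pct,
                            fp_pct_fdr = sc$fp_pct_fdr,
                            fp_pct_fpr = sc$fp_pct_fpr)
  }
  new("EvalSurface", grid = do.call(rbind, rows),
      ns = as.numeric(sort(unique(ns))),
      alphas = as.numeric(sort(unique(alphas))), orientation = orientation)
}

#' Volume under an evaluation surface
#'
#' Bilinear (trapezoidal) integration of a surface metric over the
#' (experiments x alpha) grid with both axes rescaled to [0, 1], so the VUS of
#' a constant surface equals the constant and values are comparable across
#' grids. Degenerate axes (a single value) reduce to the 1-D trapezoid or to
#' the single cell's value.
#'
#' @param surface an [EvalSurface-class].
#' @param metric which grid column to integrate.
#' @return the VUS (same units as the metric, 0-100 for percentages).
#' @export
volumeUnderSurface <- function(surface,
                               metric = c("tp_pct", "fp_pct_fdr", "fp_pct_fpr")) {
  stopifnot(is(surface, "EvalSurface"))
  metric <- match.arg(metric)
  ns <- surface@ns; alphas <- surface@alphas
  g <- surface@grid
  Z <- matrix(NA_real_, length(ns), length(alphas))
  for (r in seq_len(nrow(g)))
    Z[match(g$n[r], ns), match(g$alpha[r], alphas)] <- g[[metric]][r]
  if (anyNA(Z)) stop("incomplete grid: missing cells for ", metric)
  normAxis <- function(x) if (length(x) > 1) (x - min(x)) / (max(x) - min(x)) else 0
  u <- normAxis(ns); v <- normAxis(alphas)
  if (length(u) == 1 && length(v) == 1) return(Z[1, 1])
  lineInt <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  if (length(u) == 1) return(lineInt(v, Z[1, ]))
  if (length(v) == 1) return(lineInt(u, Z[, 1]))
  vus <- 0
  for (a in seq_len(length(u) - 1))
    for (b in seq_len(length(v) - 1))
      vus <- vus + (u[a + 1] - u[a]) * (v[b + 1] - v[b]) *
        mean(Z[a:(a + 1), b:(b + 1)])
  vus
}

#' Bootstrap the VUS over network resamples
#'
#' Per cycle, a uniform fraction of the network's genes is retained (dropped
#' TFs disappear both as rows and as regulator columns, so the resample is a
#' coherent subnetwork), expression is re-simulated with fresh starts and
#' noise, the full sweep is rerun and its VUS recorded. The spread of the
#' returned values measures the stability of the reconstruction benchmark.
#'
#' @param net the conditioned ground-truth [RegulatoryNetwork-class].
#' @param simConfig a [simulationConfig()] used to regenerate the expression
#'   pool each cycle (its \code{nExperiments} must cover \code{max(ns)}).
#' @param alphas,ns,orientation,config as in [sweepSurface()].
#' @param nCycles bootstrap cycles.
#' @param resampleFraction fraction of genes retained per cycle.
#' @param seed master seed.
#' @param metric surface metric to integrate.
#' @return numeric vector of VUS values, one per cycle.
#' @export
bootstrapVus <- function(net, simConfig, alphas, ns,
                         orientation = c("rows", "columns"),
                         nCycles = 10L, resampleFraction = 0.9, seed = NULL,
                         config = svmConfig(), metric = "tp_pct") {
  stopifnot(is(net, "RegulatoryNetwork"))
  orientation <- match.arg(orientation)
  if (nCycles < 1L) stop("nCycles must be >= 1")
  if (resampleFraction <= 0 || resampleFraction > 1)
    stop("resampleFraction must be in (0, 1]")
  seeds <- deriveSeeds(if (is.null(seed)) 1L else seed, 3L * nCycles)
  out <- numeric(nCycles)
  for (cyc in seq_len(nCycles)) {
    keep <- withSeed(seeds[[3 * cyc - 2]], {
      nG <- nTF(net) + nTA(net)
      sort(sampleVec(seq_len(nG), max(1L, floor(resampleFraction * nG))))
    })
    tfKeep <- keep[keep <= nTF(net)]
    taKeep <- keep[keep > nTF(net)] - nTF(net)
    if (!length(tfKeep)) stop("resample retained no TFs; increase resampleFraction")
    sub <- new("RegulatoryNetwork",
               A = net@A[tfKeep, tfKeep, drop = FALSE],
               B = net@B[taKeep, tfKeep, drop = FALSE],
               geneNames = net@geneNames[c(tfKeep, nTF(net) + taKeep)],
               config = net@config, spectralState = net@spectralState,
               liftedPairs = net@liftedPairs)
    sc <- simConfig
    sc$seed <- seeds[[3 * cyc - 1]]
    pool <- simulateMultistart(sub, sc)
    surf <- sweepSurface(sub, pool, alphas, ns, orientation,
                         seed = seeds[[3 * cyc]], config = config)
    out[cyc] <- volumeUnderSurface(surf, metric)
  }
  out
}
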
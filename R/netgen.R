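#' Configuration for random network generation
#'
#' Collects the parameters of the random-network generator: network size,
#' per-gene bounds on the number of regulators (in-degree), the coefficient
#' distribution, and the power-law exponent governing TF out-degrees.
#'
#' @param nTF number of transcription factors (columns of \eqn{N}); >= 1.
#' @param nTA number of regulated-only target genes; >= 0.
#' @param kMin,kMax per-gene bounds on the number of regulators;
#'   \code{1 <= kMin <= kMax <= nTF}. The defaults (1 and 4, mean 2.5) match
#'   the edge density of curated bacterial regulons (~2.5 regulators per
#'   gene).
#' @param coefficientMode \code{"gaussian"}: nonzero weights drawn from
#'   Normal(\code{beta}, 1); \code{"signed_unit"}: fair-coin \eqn{\pm 1}.
#' @param beta mean of the Gaussian coefficient distribution. The default 0
#'   gives balanced activation/repression.
#' @param outExponent target power-law exponent of the TF out-degree tail;
#'   mapped to the preferential-attachment initial attractiveness
#'   \code{a = m (outExponent - 2)} (Price's relation, \code{m} = mean
#'   in-degree), floored at 1 so the process cannot condense onto one TF.
#' @param allowSelfLoops whether a TF may regulate itself (auto-regulation).
#' @param seed RNG seed; identical configurations regenerate identical networks.
#' @return a named list of class \code{"networkConfig"}.
#' @examples
#' cfg <- networkConfig(nTF = 10, nTA = 50, seed = 1)
#' net <- generateNetwork(cfg)
#' @export
networkConfig <- function(nTF, nTA = 0L, kMin = 1L, kMax = 4L,
                          coefficientMode = c("gaussian", "signed_unit"),
                          beta = 0, outExponent = 2,
                          allowSelfLoops = TRUE, seed = NULL) {
  coefficientMode <- match.arg(coefficientMode)
  nTF <- as.integer(nTF); nTA <- as.integer(nTA)
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (nTF < 1L) stop("nTF must be >= 1")
  if (nTA < 0L) stop("nTA must be >= 0")
  if (kMin < 1L || kMin > kMax) stop("need 1 <= kMin <= kMax")
  if (kMax > nTF) stop("kMax cannot exceed the number of TFs")
  if (outExponent <= 0) stop("outExponent must be positive")
  structure(list(nTF = nTF, nTA = nTA, kMin = kMin, kMax = kMax,
                 coefficientMode = coefficientMode, beta = beta,
                 outExponent = outExponent, allowSelfLoops = allowSelfLoops,
                 seed = seed),
            class = "networkConfig")
}

#' Generate a random sparse signed regulatory network
#'
#' Builds the signed weight matrix \eqn{N = [A; B]} cell-wise: each gene
#' receives an in-degree drawn uniformly from \code{[kMin, kMax]}, and its
#' regulators are sampled without replacement by preferential attachment
#' (probability proportional to the TF's current out-degree plus an initial
#' attractiveness set by \code{outExponent} through Price's relation). This
#' yields heavy-tailed, scale-free-like out-degree distributions with
#' realistic hub sizes — the largest hubs regulate a sizable fraction of the
#' genome, never essentially all of it — while keeping every in-degree within
#' its bounds.
#'
#' @param config a [networkConfig()].
#' @return a [RegulatoryNetwork-class] with \code{spectralState = "raw"}.
#' @examples
#' net <- generateNetwork(networkConfig(nTF = 20, nTA = 100, seed = 3))
#' networkStats(net)$n_edges
#' @export
generateNetwork <- function(config) {
  stopifnot(inherits(config, "networkConfig"))
  nG <- config$nTF + config$nTA
  # infeasibility is an error, never silently relaxed
  if (!config$allowSelfLoops && config$nTF >= 1L && config$kMax > config$nTF - 1L &&
      config$nTF > 1L)
    stop("kMax exceeds the number of candidate regulators when self-loops are disallowed")
  if (!config$allowSelfLoops && config$nTF == 1L)
    stop("a 1-TF network without self-loops has no feasible regulator")
  withSeed(config$seed, {
    kIn <- if (config$kMin == config$kMax) rep(config$kMin, nG)
           else sample(seq.int(config$kMin, config$kMax), nG, replace = TRUE)
    # Preferential attachment over regulator choice (Price's model): each
    # gene picks its regulators with probability proportional to the TF's
    # current out-degree plus an initial attractiveness a. The realized
    # out-degree tail follows a power law of exponent ~ 2 + a/m (m = mean
    # in-degree), so a is derived from the requested exponent; genes are
    # processed in random order so early rows carry no systematic advantage.
    m <- mean(kIn)
    a <- max(m * (config$outExponent - 2), 1)
    outDeg <- numeric(config$nTF)
    N <- matrix(0, nG, config$nTF)
    for (i in sample(seq_len(nG))) {
      cand <- seq_len(config$nTF)
      if (!config$allowSelfLoops && i <= config$nTF) cand <- cand[cand != i]
      w <- outDeg[cand] + a
      regs <- sampleVec(cand, kIn[i], prob = w)
      outDeg[regs] <- outDeg[regs] + 1
      weights <- switch(config$coefficientMode,
        gaussian    = rnorm(length(regs), mean = config$beta, sd = 1),
        signed_unit = sample(c(-1, 1), length(regs), replace = TRUE))
      # a Gaussian draw of exactly 0 would erase the edge; resample (measure-zero)
      while (any(weights == 0))
        weights[weights == 0] <- rnorm(sum(weights == 0), config$beta, 1)
      N[i, regs] <- weights
    }
    geneNames <- c(sprintf("TF%d", seq_len(config$nTF)),
                   if (config$nTA > 0) sprintf("TA%d", seq_len(config$nTA)))
    new("RegulatoryNetwork",
        A = N[seq_len(config$nTF), , drop = FALSE],
        B = N[config$nTF + seq_len(config$nTA), , drop = FALSE],
        geneNames = geneNames, config = unclass(config),
        spectralState = "raw", liftedPairs = 0L)
  })
}

#' Degree statistics of a network
#'
#' Edge count, sparsity (fraction of nonzero cells of \eqn{N}), in- and
#' out-degree vectors, and the least-squares slope of log frequency versus log
#' degree for the out-degree distribution (degrees >= 1 only); a clearly
#' negative slope is the signature of the heavy-tailed, scale-free-like
#' out-degree behaviour the generator is constrained to produce.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return a list with elements \code{n_edges}, \code{sparsity},
#'   \code{in_degrees}, \code{out_degrees}, \code{out_degree_loglog_slope}.
#' @export
networkStats <- function(net) {
  stopifnot(is(net, "RegulatoryNetwork"))
  N <- rbind(net@A, net@B)
  nz <- N != 0
  outDeg <- colSums(nz)
  inDeg <- rowSums(nz)
  pos <- outDeg[outDeg >= 1]
  slope <- NA_real_
  if (length(unique(pos)) >= 2) {
    tab <- table(pos)
    slope <- unname(stats::coef(lm(log(as.numeric(tab)) ~ log(as.numeric(names(tab)))))[2])
  }
  list(n_edges = sum(nz), sparsity = mean(nz),
       in_degrees = as.integer(inDeg), out_degrees = as.integer(outDeg),
       out_degree_loglog_slope = slope)
}
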
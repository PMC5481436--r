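# Spectral conditioning of the linear expression dynamics.
#
# The per-step map of log-TF-expression is V(t+1) = (I + A) V(t), so
# convergence/oscillation is governed by the spectrum of the iteration matrix
# M = I + A. All conditioning here (radius standardization, unit-circle
# placement) therefore acts on M: all eigenvalues inside the unit disk gives
# decay, one on the circle gives stability, extra conjugate pairs on the
# circle give sustained oscillation.

iterationMatrix <- function(net) diag(nrow(net@A)) + net@A

#' Standardize the spectral radius of the iteration matrix to 1
#'
#' Rescales \eqn{M = I + A} by \eqn{1/\rho(M)} (dense eigendecomposition), so
#' the conditioned dynamics are stable instead of exploding or vanishing:
#' \eqn{A \leftarrow M/\rho(M) - I}, and \eqn{B} is rescaled by the same scalar
#' to preserve the relative TF-on-target influence. The off-diagonal sparsity
#' pattern of \eqn{A} is unchanged (the rescaling introduces diagonal terms).
#'
#' @param net a raw [RegulatoryNetwork-class].
#' @return the network with \code{spectralState = "normalized"} and
#'   \eqn{\rho(I + A) = 1} up to floating point.
#' @export
normalizeSpectralRadius <- function(net) {
  stopifnot(is(net, "RegulatoryNetwork"))
  if (net@spectralState != "raw")
    stop("network is already spectrally conditioned")
  M <- iterationMatrix(net)
  rho <- max(Mod(eigen(M, only.values = TRUE)$values))
  if (rho == 0) stop("iteration matrix has spectral radius 0")
  net@A <- M / rho - diag(nrow(M))
  net@B <- net@B / rho
  net@spectralState <- "normalized"
  net
}

#' Lift conjugate eigenvalue pairs onto the unit circle
#'
#' Selects the \code{p} strictly complex conjugate eigenvalue pairs of the
#' normalized iteration matrix that are closest to the unit circle (largest
#' modulus < 1) and moves each vertically — the real part is kept, the
#' imaginary part of \eqn{a + bi} is set to \eqn{\pm\sqrt{1 - a^2}} — until it
#' sits on the circle. The matrix is rebuilt from the modified
#' eigendecomposition; since shifts are applied conjugate-symmetrically the
#' rebuilt matrix is real up to numerical residue, which is discarded (and its
#' magnitude recorded). The perturbation \eqn{E_p} = lifted minus normalized
#' iteration matrix is dense but of very low magnitude, giving the conditioned
#' network many new weak connections — the price of genome-wide oscillation.
#'
#' Pairs with \eqn{|a| \ge 1} cannot reach the circle vertically and are
#' skipped in closest-first order.
#'
#' @param net a normalized [RegulatoryNetwork-class].
#' @param p number of conjugate pairs to lift, \code{0 <= p < 10}.
#' @param tolerance modulus tolerance for counting eigenvalues "on the circle".
#' @return a list with elements \code{network} (state \code{"lifted"}) and
#'   \code{conditioning} (a [SpectralConditioning-class]).
#' @examples
#' net <- normalizeSpectralRadius(generateNetwork(networkConfig(30, 60, seed = 2)))
#' lifted <- liftEigenvalues(net, p = 1)
#' lifted$conditioning
#' @export
liftEigenvalues <- function(net, p, tolerance = 1e-6) {
  stopifnot(is(net, "RegulatoryNetwork"))
  if (net@spectralState != "normalized")
    stop("lift requires a normalized network (run normalizeSpectralRadius first)")
  p <- as.integer(p)
  if (p < 0L || p >= 10L) stop("p must satisfy 0 <= p < 10")
  M <- iterationMatrix(net)
  eg <- eigen(M)
  vals <- eg$values
  preCount <- sum(abs(Mod(vals) - 1) < tolerance)
  if (p == 0L) {
    net@spectralState <- "lifted"
    net@liftedPairs <- 0L
    cond <- new("SpectralConditioning", p = 0L, liftedBefore = complex(0),
                liftedAfter = complex(0), perturbation = matrix(0, nrow(M), ncol(M)),
                unitCircleCount = as.integer(preCount), tolerance = tolerance,
                maxImagResidue = 0)
    return(list(network = net, conditioning = cond))
  }
  # candidate pairs: strictly complex, inside the circle, vertically liftable
  idx <- which(Im(vals) > tolerance & Mod(vals) < 1 - tolerance &
                 abs(Re(vals)) < 1 - tolerance)
  idx <- idx[order(Mod(vals[idx]), decreasing = TRUE)]
  if (length(idx) < p)
    stop("fewer than p liftable complex conjugate pairs; re-seed the network generation")
  sel <- idx[seq_len(p)]
  before <- after <- complex(0)
  # E_p is built from the spectral projectors of the selected pairs only:
  # shifting a simple eigenvalue lambda (right eigenvector v, left w) by
  # i*delta perturbs M by i*delta * v w^T / (w^T v); adding the conjugate
  # pair's term makes the total exactly real and leaves every other
  # eigenvalue untouched. The rest of the spectrum may be defective (sparse
  # networks usually carry a highly multiple eigenvalue) without harm.
  n <- nrow(M)
  DeltaC <- matrix(0 + 0i, n, n)
  for (k in sel) {
    lam <- vals[k]
    a <- Re(lam); b <- Im(lam)
    v <- eg$vectors[, k]
    sv <- svd(t(M) - lam * diag(n))
    if (sv$d[n] > 1e-7 * sv$d[1])
      stop("selected eigenvalue is not numerically simple; re-seed the network")
    if (n > 1 && sv$d[n - 1] < 1e-7 * sv$d[1])
      stop("selected eigenvalue is defective within tolerance; re-seed the network")
    w <- sv$v[, n]  # left eigenvector: t(M) w = lam w up to conjugation scaling
    denom <- sum(w * v)
    if (Mod(denom) < 1e-10)
      stop("left/right eigenvectors nearly orthogonal (defective pair); re-seed")
    delta <- sqrt(1 - a^2) - b
    DeltaC <- DeltaC + (1i * delta / denom) * (v %*% t(w))
    before <- c(before, lam, Conj(lam))
    after <- c(after, complex(real = a, imaginary = sqrt(1 - a^2)),
               complex(real = a, imaginary = -sqrt(1 - a^2)))
  }
  DeltaC <- DeltaC + Conj(DeltaC)
  resid <- max(abs(Im(DeltaC)))
  if (resid > 1e-6 || !is.finite(resid))
    stop("perturbation failed to come out real; re-seed the network")
  Ep <- Re(DeltaC)
  Mnew <- M + Ep
  net@A <- Mnew - diag(nrow(Mnew))
  net@spectralState <- "lifted"
  net@liftedPairs <- p
  postCount <- sum(abs(Mod(eigen(Mnew, only.values = TRUE)$values) - 1) < tolerance)
  cond <- new("SpectralConditioning", p = p, liftedBefore = before,
              liftedAfter = after, perturbation = Ep,
              unitCircleCount = as.integer(postCount), tolerance = tolerance,
              maxImagResidue = resid)
  list(network = net, conditioning = cond)
}

#' Compare network coefficients before and after lifting
#'
#' Pairs every cell of \eqn{N} before and after spectral conditioning,
#' identifies the "new" connections (zero before, nonzero after), and
#' summarizes the magnitude gap between the injected weak connections and the
#' original coefficients: \code{gap_ratio} = median |new nonzero| / median
#' |original nonzero| (0 when there are no new connections).
#'
#' @param before,after two [RegulatoryNetwork-class] objects of identical
#'   shape, typically the normalized network and its lifted version.
#' @return list with \code{pairs} (data.frame \code{before}, \code{after} per
#'   cell), \code{new_cells} (data.frame \code{row}, \code{col}),
#'   \code{gap_ratio}.
#' @export
coefficientShiftReport <- function(before, after) {
  stopifnot(is(before, "RegulatoryNetwork"), is(after, "RegulatoryNetwork"))
  Nb <- rbind(before@A, before@B)
  Na <- rbind(after@A, after@B)
  if (!identical(dim(Nb), dim(Na))) stop("networks have different shapes")
  newMask <- Nb == 0 & Na != 0
  origNz <- abs(Nb[Nb != 0])
  gap <- if (any(newMask) && length(origNz))
    median(abs(Na[newMask])) / median(origNz) else 0
  idx <- which(newMask, arr.ind = TRUE)
  list(pairs = data.frame(before = as.vector(Nb), after = as.vector(Na)),
       new_cells = data.frame(row = idx[, 1], col = idx[, 2]),
       gap_ratio = gap)
}

#' Couple conditioned network modules through their hub TFs
#'
#' Combines spectrally conditioned modules into one network: \eqn{A} becomes
#' block-diagonal, \eqn{B} block-diagonal over the module TF columns, and for
#' each consecutive module pair one edge is added in each direction between the
#' modules' hub TFs (hub = TF of maximal out-degree in \eqn{N}, ties broken by
#' lowest index). Link weights are drawn from the source module's coefficient
#' distribution and scaled by \code{linkScale}; weak coupling preserves each
#' module's conditioned spectrum, so modules keep their distinct stable or
#' oscillatory behaviour.
#'
#' @param modules list of conditioned [RegulatoryNetwork-class] objects.
#' @param linkScale positive multiplier applied to inter-module hub weights.
#' @param seed RNG seed for the link-weight draws.
#' @return a combined [RegulatoryNetwork-class] (gene names prefixed
#'   \code{M<k>_}), \code{spectralState = "lifted"}.
#' @export
assembleModular <- function(modules, linkScale = 0.1, seed = NULL) {
  if (!length(modules)) stop("empty module list")
  ok <- vapply(modules, function(m) is(m, "RegulatoryNetwork"), logical(1))
  stopifnot(all(ok))
  if (any(vapply(modules, nTF, integer(1)) == 0L)) stop("module with zero TFs")
  if (any(vapply(modules, spectralState, character(1)) == "raw"))
    stop("modules must be spectrally conditioned before assembly")
  nTFs <- vapply(modules, nTF, integer(1))
  nTAs <- vapply(modules, nTA, integer(1))
  tfOff <- cumsum(c(0L, nTFs))
  taOff <- cumsum(c(0L, nTAs))
  totTF <- sum(nTFs); totTA <- sum(nTAs)
  A <- matrix(0, totTF, totTF)
  B <- matrix(0, totTA, totTF)
  hubs <- integer(length(modules))
  for (m in seq_along(modules)) {
    mod <- modules[[m]]
    rTF <- tfOff[m] + seq_len(nTFs[m])
    A[rTF, rTF] <- mod@A
    if (nTAs[m] > 0)
      B[taOff[m] + seq_len(nTAs[m]), rTF] <- mod@B
    outDeg <- colSums(rbind(mod@A, mod@B) != 0)
    hubs[m] <- tfOff[m] + which.max(outDeg)  # which.max breaks ties low
  }
  drawWeight <- function(mod) {
    cfg <- mod@config
    w <- if (identical(cfg$coefficientMode, "signed_unit"))
      sample(c(-1, 1), 1) else rnorm(1, mean = cfg$beta %||% 0, sd = 1)
    while (w == 0) w <- rnorm(1, cfg$beta %||% 0, 1)
    w
  }
  withSeed(seed, {
    if (length(modules) > 1) {
      for (m in seq_len(length(modules) - 1)) {
        # hub of module m regulates hub of module m+1, and vice versa
        A[hubs[m + 1], hubs[m]] <- drawWeight(modules[[m]]) * linkScale
        A[hubs[m], hubs[m + 1]] <- drawWeight(modules[[m + 1]]) * linkScale
      }
    }
    geneNames <- c(
      unlist(lapply(seq_along(modules), function(m)
        sprintf("M%d_%s", m, modules[[m]]@geneNames[seq_len(nTFs[m])]))),
      unlist(lapply(seq_along(modules), function(m)
        if (nTAs[m] > 0)
          sprintf("M%d_%s", m, modules[[m]]@geneNames[nTFs[m] + seq_len(nTAs[m])])
        else character(0))))
    new("RegulatoryNetwork", A = A, B = B, geneNames = geneNames,
        config = list(modules = lapply(modules, slot, "config"),
                      linkScale = linkScale, seed = seed),
        spectralState = "lifted",
        liftedPairs = sum(vapply(modules, slot, integer(1), "liftedPairs")))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
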
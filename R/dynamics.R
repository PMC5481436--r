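# Expression simulation from a conditioned network.
#
# Log-expression evolves linearly: V(t+1) - V(t) = A V(t) for TFs and
# W(t+1) - W(t) = B V(t) for targets (synchronous update: both increments use
# V(t)). Observed expression is exp(latent) + Gaussian measurement noise.

#' Configuration for expression simulation
#'
#' @param mode \code{"multistart"}: many independent random initializations
#'   observed at one iteration step (one column per start); \code{"dynamic"}:
#'   a single trajectory observed at successive steps \code{E_1..E_steps}.
#' @param nExperiments number of columns to produce (multistart mode only).
#' @param steps iteration count at which multistart observations are taken, or
#'   the trajectory length in dynamic mode.
#' @param mu,sigma mean and standard deviation of the initial log-expression
#'   (starts are i.i.d. Normal(\code{mu}, \code{sigma}^2), so expression is
#'   log-normal).
#' @param noiseSd standard deviation of the additive measurement noise on the
#'   observation (exp) scale; noise may make observations negative and is
#'   recorded as-is. No noise is applied at step 0.
#' @param seed RNG seed.
#' @return a named list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(mode = c("multistart", "dynamic"),
                             nExperiments = 1000L, steps = 1L,
                             mu = 0, sigma = 1, noiseSd = 0.1, seed = NULL) {
  mode <- match.arg(mode)
  steps <- as.integer(steps)
  nExperiments <- as.integer(nExperiments)
  if (steps < 0L) stop("steps must be >= 0")
  if (sigma <= 0) stop("sigma must be positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (mode == "multistart" && nExperiments < 1L) stop("nExperiments must be >= 1")
  structure(list(mode = mode, nExperiments = nExperiments, steps = steps,
                 mu = mu, sigma = sigma, noiseSd = noiseSd, seed = seed),
            class = "simulationConfig")
}

#' Matrix power by dyadic (square-and-multiply) decomposition
#'
#' Computes \eqn{M^n} with at most \eqn{\lceil \log_2 n \rceil} squarings plus
#' one multiplication per set bit of \eqn{n}, instead of \eqn{n - 1} naive
#' products.
#'
#' @param M a square numeric matrix.
#' @param n a non-negative integer.
#' @return the matrix power \eqn{M^n} (\eqn{M^0 = I}).
#' @examples
#' M <- matrix(rnorm(9), 3)
#' max(abs(matrixPowerDyadic(M, 3) - M %*% M %*% M))
#' @export
matrixPowerDyadic <- function(M, n) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be a square matrix")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  R <- diag(nrow(M))
  P <- M
  while (n > 0L) {
    if (bitwAnd(n, 1L)) R <- R %*% P
    n <- bitwShiftR(n, 1L)
    if (n > 0L) P <- P %*% P
  }
  R
}

.checkConditioned <- function(net) {
  if (net@spectralState == "raw")
    stop("network is unconditioned; run normalizeSpectralRadius() (and optionally ",
         "liftEigenvalues()) before simulating, otherwise expression explodes or vanishes")
}

.newExpressionDataset <- function(latent, obs, geneNames, labels, config) {
  dimnames(latent) <- dimnames(obs) <- list(geneNames, labels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(observations = obs, latentLogs = latent),
    metadata = list(config = unclass(config)))
  new("ExpressionDataset", se)
}

#' Simulate multistart expression data
#'
#' Draws \code{nExperiments} independent initial log-expression vectors
#' \eqn{V(0), W(0) \sim N(\mu, \sigma^2)} and records each system at iteration
#' \code{steps}: \eqn{V(t) = M^t V(0)} with \eqn{M = I + A} (computed by
#' [matrixPowerDyadic()]) and \eqn{W(t) = W(0) + B \sum_{s<t} V(s)}. The
#' observation is \eqn{\exp(V, W) + \varepsilon} (no noise at step 0).
#'
#' @param net a conditioned [RegulatoryNetwork-class].
#' @param config a [simulationConfig()] with \code{mode = "multistart"}.
#' @return an [ExpressionDataset-class], genes x experiments, columns
#'   labelled \code{S1..Sn}.
#' @export
simulateMultistart <- function(net, config) {
  stopifnot(is(net, "RegulatoryNetwork"), inherits(config, "simulationConfig"))
  if (config$mode != "multistart") stop("config mode must be 'multistart'")
  .checkConditioned(net)
  ntf <- nTF(net); nta <- nTA(net); n <- config$nExperiments
  M <- diag(ntf) + net@A
  t <- config$steps
  Mt <- matrixPowerDyadic(M, t)
  # S = sum_{s=0}^{t-1} M^s, so W(t) = W(0) + B S V(0)
  S <- matrix(0, ntf, ntf)
  P <- diag(ntf)
  for (s in seq_len(t)) { S <- S + P; P <- P %*% M }
  withSeed(config$seed, {
    V0 <- matrix(rnorm(ntf * n, config$mu, config$sigma), ntf, n)
    W0 <- if (nta > 0) matrix(rnorm(nta * n, config$mu, config$sigma), nta, n)
          else matrix(0, 0, n)
    Vt <- Mt %*% V0
    Wt <- if (nta > 0) W0 + net@B %*% (S %*% V0) else W0
    latent <- rbind(Vt, Wt)
    obs <- exp(latent)
    if (config$noiseSd > 0 && t > 0)
      obs <- obs + matrix(rnorm(length(obs), 0, config$noiseSd),
                          nrow(obs), ncol(obs))
    .newExpressionDataset(latent, obs, net@geneNames,
                          sprintf("S%d", seq_len(n)), config)
  })
}

#' Simulate a dynamic expression trajectory
#'
#' One random initialization iterated \code{steps} times; columns are the
#' observations \eqn{X(1) \ldots X(steps)} of the single trajectory, with
#' measurement noise drawn independently per observation. The latent assay
#' carries the noise-free log-scale trajectory.
#'
#' @inheritParams simulateMultistart
#' @param config a [simulationConfig()] with \code{mode = "dynamic"};
#'   \code{steps} must be >= 1.
#' @return an [ExpressionDataset-class], genes x steps, columns \code{E1..Et}.
#' @export
simulateDynamic <- function(net, config) {
  stopifnot(is(net, "RegulatoryNetwork"), inherits(config, "simulationConfig"))
  if (config$mode != "dynamic") stop("config mode must be 'dynamic'")
  if (config$steps < 1L) stop("dynamic mode needs steps >= 1")
  .checkConditioned(net)
  ntf <- nTF(net); nta <- nTA(net)
  withSeed(config$seed, {
    V <- rnorm(ntf, config$mu, config$sigma)
    W <- if (nta > 0) rnorm(nta, config$mu, config$sigma) else numeric(0)
    latent <- matrix(0, ntf + nta, config$steps)
    for (s in seq_len(config$steps)) {
      Vnew <- V + net@A %*% V
      Wnew <- if (nta > 0) W + net@B %*% V else W
      V <- drop(Vnew); W <- drop(Wnew)
      latent[, s] <- c(V, W)
    }
    obs <- exp(latent)
    if (config$noiseSd > 0)
      obs <- obs + matrix(rnorm(length(obs), 0, config$noiseSd),
                          nrow(obs), ncol(obs))
    .newExpressionDataset(latent, obs, net@geneNames,
                          sprintf("E%d", seq_len(config$steps)), config)
  })
}
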
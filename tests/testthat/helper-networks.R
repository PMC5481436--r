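# Shared fixtures, built in code.

# A hand-made network object with given A and B matrices.
handNet <- function(A, B = matrix(0, 0, ncol(A)), state = "raw",
                    config = list()) {
  new("RegulatoryNetwork", A = A, B = B,
      geneNames = c(sprintf("TF%d", seq_len(nrow(A))),
                    if (nrow(B)) sprintf("TA%d", seq_len(nrow(B)))),
      config = config, spectralState = state, liftedPairs = 0L)
}

# A small conditioned network plus matching expression pool, reused by the
# learner and evaluation tests.
smallStudy <- function(nTF = 15, nTA = 60, nExp = 400, seed = 42,
                       mode = "signed_unit", p = 0, noiseSd = 0.1) {
  net <- normalizeSpectralRadius(generateNetwork(
    networkConfig(nTF, nTA, coefficientMode = mode, seed = seed)))
  if (p > 0) net <- liftEigenvalues(net, p)$network
  expr <- simulateMultistart(net, simulationConfig(
    "multistart", nExperiments = nExp, steps = 1, noiseSd = noiseSd,
    seed = seed + 1))
  list(net = net, expr = expr)
}

# First generation seed (from `from`) whose normalized iteration matrix has
# exactly `count` eigenvalues on the unit circle.
findSeedWithUnitCount <- function(nTF, nTA, count = 1, from = 1,
                                  mode = "gaussian", tries = 40) {
  for (s in seq(from, from + tries - 1)) {
    net <- normalizeSpectralRadius(generateNetwork(
      networkConfig(nTF, nTA, coefficientMode = mode, seed = s)))
    ev <- eigen(diag(nTF) + net@A, only.values = TRUE)$values
    if (sum(abs(Mod(ev) - 1) < 1e-6) == count) return(list(seed = s, net = net))
  }
  stop("no seed with the requested unit-circle count in range")
}
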
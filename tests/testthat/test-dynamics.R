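test_that("dyadic matrix power matches naive repeated multiplication", {
  M <- matrix(rnorm(36), 6)
  expect_equal(matrixPowerDyadic(M, 0), diag(6))
  expect_equal(matrixPowerDyadic(M, 1), M)
  naive <- function(M, n) Reduce(`%*%`, rep(list(M), n), accumulate = FALSE)
  expect_equal(matrixPowerDyadic(M, 11), naive(M, 11), tolerance = 1e-10)
  set.seed(1)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    A <- matrix(rnorm(k * k, sd = 0.5), k)
    n <- sample(2:32, 1)
    expect_equal(matrixPowerDyadic(A, n), naive(A, n), tolerance = 1e-10)
  }
  expect_error(matrixPowerDyadic(matrix(0, 2, 3), 2), "square")
  expect_error(matrixPowerDyadic(M, -1), "non-negative")
})

test_that("decoupled genes never move: columns equal their own exp'd starts", {
  net <- handNet(matrix(0, 2, 2), matrix(0, 1, 2), state = "normalized")
  cfg0 <- simulationConfig("multistart", nExperiments = 5, steps = 0,
                           noiseSd = 0, seed = 4)
  cfg5 <- simulationConfig("multistart", nExperiments = 5, steps = 5,
                           noiseSd = 0, seed = 4)
  expect_equal(latentLogs(simulateMultistart(net, cfg5)),
               latentLogs(simulateMultistart(net, cfg0)))
})

test_that("one multistart step follows the evolution equations exactly", {
  a <- 0.7
  net <- handNet(rbind(c(0, a), c(0, 0)), matrix(c(0.3, -0.2), 1, 2),
                 state = "normalized")
  cfg0 <- simulationConfig("multistart", nExperiments = 3, steps = 0,
                           noiseSd = 0, seed = 9)
  cfg1 <- simulationConfig("multistart", nExperiments = 3, steps = 1,
                           noiseSd = 0, seed = 9)
  start <- latentLogs(simulateMultistart(net, cfg0))
  one <- latentLogs(simulateMultistart(net, cfg1))
  # V(1) = V(0) + A V(0); W(1) = W(0) + B V(0)
  expect_equal(one[1, ], start[1, ] + a * start[2, ], tolerance = 1e-12)
  expect_equal(one[2, ], start[2, ], tolerance = 1e-12)
  expect_equal(one[3, ], start[3, ] + 0.3 * start[1, ] - 0.2 * start[2, ],
               tolerance = 1e-12)
})

test_that("multistart equals the matching column of a dynamic run (dual path)", {
  study <- smallStudy(nTF = 10, nTA = 20, nExp = 1)
  net <- study$net
  dyn <- simulateDynamic(net, simulationConfig("dynamic", steps = 8,
                                               noiseSd = 0, seed = 77))
  for (t in c(1, 4, 8)) {
    ms <- simulateMultistart(net, simulationConfig("multistart",
                                                   nExperiments = 1, steps = t,
                                                   noiseSd = 0, seed = 77))
    expect_equal(drop(latentLogs(ms)), latentLogs(dyn)[, t], tolerance = 1e-8)
  }
})

test_that("observations are exactly exp(latent) when noise is off", {
  study <- smallStudy(nTF = 8, nTA = 12, nExp = 20, noiseSd = 0)
  expect_identical(observations(study$expr), exp(latentLogs(study$expr)))
  # and no noise is ever applied at step 0, even with noiseSd > 0
  net <- study$net
  e0 <- simulateMultistart(net, simulationConfig("multistart",
                                                 nExperiments = 4, steps = 0,
                                                 noiseSd = 0.5, seed = 3))
  expect_identical(observations(e0), exp(latentLogs(e0)))
})

test_that("simulation is reproducible and refuses unconditioned networks", {
  raw <- generateNetwork(networkConfig(6, 10, seed = 2))
  cfg <- simulationConfig("multistart", nExperiments = 3, steps = 1, seed = 5)
  expect_error(simulateMultistart(raw, cfg), "unconditioned")
  expect_error(simulateDynamic(raw, simulationConfig("dynamic", steps = 3,
                                                     seed = 5)),
               "unconditioned")
  net <- normalizeSpectralRadius(raw)
  expect_identical(observations(simulateMultistart(net, cfg)),
                   observations(simulateMultistart(net, cfg)))
  dcfg <- simulationConfig("dynamic", steps = 6, seed = 8)
  expect_identical(observations(simulateDynamic(net, dcfg)),
                   observations(simulateDynamic(net, dcfg)))
})

test_that("unnormalized dynamics explode or vanish, conditioned ones stay bounded", {
  blown <- vapply(1:20, function(s) {
    raw <- generateNetwork(networkConfig(50, 0, seed = s))
    M <- diag(50) + raw@A
    set.seed(s)
    V <- rnorm(50)
    for (t in 1:100) V <- drop(M %*% V)
    nrm <- sqrt(sum(V^2))
    nrm > 1e6 || nrm < 1e-6 || !is.finite(nrm)
  }, logical(1))
  expect_gte(sum(blown), 18L)
})
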
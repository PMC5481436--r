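test_that("normalization drives the iteration-matrix spectral radius to 1", {
  for (s in 1:3) {
    net <- normalizeSpectralRadius(generateNetwork(
      networkConfig(40, 120, seed = s)))
    rho <- max(Mod(eigen(diag(40) + net@A, only.values = TRUE)$values))
    expect_lt(abs(rho - 1), 1e-8)
    expect_identical(spectralState(net), "normalized")
  }
})

test_that("normalization leaves identity dynamics untouched and rescales diagonally", {
  zero <- handNet(matrix(0, 3, 3), matrix(0, 2, 3))
  nz <- normalizeSpectralRadius(zero)
  expect_equal(nz@A, matrix(0, 3, 3))
  expect_equal(nz@B, matrix(0, 2, 3))

  # A = I gives M = 2I; rescaling a diagonal matrix is closed-form: A' = 0
  ident <- handNet(diag(3))
  ni <- normalizeSpectralRadius(ident)
  expect_equal(ni@A, matrix(0, 3, 3), tolerance = 1e-12)
})

test_that("normalization preserves the off-diagonal sparsity pattern and rescales B", {
  net <- generateNetwork(networkConfig(20, 50, seed = 5))
  nn <- normalizeSpectralRadius(net)
  off <- !diag(TRUE, 20)
  expect_identical(net@A[off] != 0, nn@A[off] != 0)
  rho <- max(Mod(eigen(diag(20) + net@A, only.values = TRUE)$values))
  expect_equal(nn@B, net@B / rho, tolerance = 1e-12)
  expect_error(normalizeSpectralRadius(nn), "already")
})

test_that("a known complex pair is lifted vertically onto the unit circle", {
  # block form with eigenvalues {0.9, 0.3, 0.5 +/- 0.6i}, densified by an
  # orthogonal change of basis; the pair must move to 0.5 +/- sqrt(0.75)i
  blocks <- rbind(c(0.9, 0, 0, 0),
                  c(0, 0.3, 0, 0),
                  c(0, 0, 0.5, -0.6),
                  c(0, 0, 0.6, 0.5))
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  M <- Q %*% blocks %*% t(Q)
  net <- handNet(M - diag(4), state = "normalized")
  lf <- liftEigenvalues(net, 1)
  ev <- eigen(diag(4) + lf$network@A, only.values = TRUE)$values
  mods <- sort(Mod(ev), decreasing = TRUE)
  expect_equal(mods[1:2], c(1, 1), tolerance = 1e-9)
  expect_equal(mods[3:4], c(0.9, 0.3), tolerance = 1e-9)
  shifted <- lf$conditioning@liftedAfter
  expect_equal(sort(Re(shifted)), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sort(abs(Im(shifted))), rep(sqrt(0.75), 2), tolerance = 1e-9)
  # |0.5 + 0.8660i| = 1 by construction
  expect_equal(Mod(shifted), c(1, 1), tolerance = 1e-12)
  expect_identical(lf$conditioning@unitCircleCount, 2L)
})

test_that("p = 0 lift is a no-op with a zero perturbation", {
  net <- normalizeSpectralRadius(generateNetwork(networkConfig(15, 30, seed = 2)))
  lf <- liftEigenvalues(net, 0)
  expect_equal(lf$network@A, net@A)
  expect_equal(lf$conditioning@perturbation, matrix(0, 15, 15))
  expect_identical(spectralState(lf$network), "lifted")
})

test_that("lift bookkeeping: unit-circle count grows by 2p and E_p is real", {
  for (s in c(1, 4, 9, 14, 23)) {
    net <- normalizeSpectralRadius(generateNetwork(
      networkConfig(30, 90, seed = s)))
    pre <- sum(abs(Mod(eigen(diag(30) + net@A, only.values = TRUE)$values) - 1) < 1e-6)
    p <- 2L
    lf <- liftEigenvalues(net, p)
    expect_identical(lf$conditioning@unitCircleCount, as.integer(pre + 2 * p))
    expect_lt(lf$conditioning@maxImagResidue, 1e-8)
    expect_true(is.numeric(lf$conditioning@perturbation))
    # the perturbation is exactly the difference of iteration matrices
    expect_equal(lf$conditioning@perturbation, lf$network@A - net@A,
                 tolerance = 1e-12)
  }
})

test_that("lift rejects invalid inputs", {
  raw <- generateNetwork(networkConfig(10, 0, seed = 1))
  expect_error(liftEigenvalues(raw, 1), "normalized")
  nn <- normalizeSpectralRadius(raw)
  expect_error(liftEigenvalues(nn, 10), "p must")
  # a diagonal (all-real-spectrum) matrix has no complex pairs to lift
  di <- normalizeSpectralRadius(handNet(diag(c(0.2, 0.4, 0.6)) - diag(3)))
  expect_error(liftEigenvalues(di, 1), "fewer than p")
})

test_that("coefficient shift report isolates new weak connections", {
  net <- normalizeSpectralRadius(generateNetwork(networkConfig(20, 60, seed = 3)))
  same <- coefficientShiftReport(net, net)
  expect_identical(nrow(same$new_cells), 0L)
  expect_identical(same$gap_ratio, 0)

  # hand-built: one 0.001 entry injected over originals of magnitude ~1
  A0 <- rbind(c(0, 1.2, 0), c(-0.9, 0, 0), c(0, 1.1, 0))
  A1 <- A0; A1[1, 3] <- 0.001
  before <- handNet(A0, state = "normalized")
  after <- handNet(A1, state = "lifted")
  rep <- coefficientShiftReport(before, after)
  expect_identical(nrow(rep$new_cells), 1L)
  expect_equal(rep$gap_ratio, 0.001 / median(c(1.2, 0.9, 1.1)), tolerance = 1e-12)
  expect_identical(nrow(rep$pairs), 9L)
})

test_that("lifting injects connections well below the original coefficient scale", {
  net <- normalizeSpectralRadius(generateNetwork(networkConfig(30, 100, seed = 6)))
  lf <- liftEigenvalues(net, 1)
  rep <- coefficientShiftReport(net, lf$network)
  expect_gt(nrow(rep$new_cells), 0L)
  expect_lt(rep$gap_ratio, 0.1)
})

test_that("modular assembly couples consecutive modules through their hubs", {
  mods <- lapply(c(31, 32), function(s)
    liftEigenvalues(normalizeSpectralRadius(generateNetwork(
      networkConfig(10, 20, seed = s))), if (s == 32) 1 else 0)$network)
  edgesBefore <- vapply(mods, function(m) sum(rbind(m@A, m@B) != 0), numeric(1))
  comb <- assembleModular(mods, linkScale = 0.1, seed = 7)
  expect_identical(nTF(comb), 20L)
  expect_identical(nTA(comb), 40L)
  expect_identical(sum(rbind(comb@A, comb@B) != 0), as.integer(sum(edgesBefore) + 2))
  # the two extra cells sit at the hub positions
  hub <- function(m) which.max(colSums(rbind(m@A, m@B) != 0))
  h1 <- hub(mods[[1]]); h2 <- 10 + hub(mods[[2]])
  expect_true(comb@A[h2, h1] != 0 && comb@A[h1, h2] != 0)
  expect_true(startsWith(comb@geneNames[1], "M1_"))

  single <- assembleModular(mods[1], seed = 1)
  expect_equal(single@A, mods[[1]]@A)
  expect_true(all(startsWith(single@geneNames, "M1_")))

  four <- assembleModular(rep(mods[1], 4), seed = 2)
  expect_identical(sum(rbind(four@A, four@B) != 0),
                   as.integer(4 * edgesBefore[1] + 6))
  expect_error(assembleModular(list()), "empty")
})
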
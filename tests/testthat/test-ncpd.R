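test_that("reconstruct matches the outer-product definition", {
  ## single cell: a = e1, b = e2, c = 1, lambda = 3
  m <- CPModel(A = cbind(c(3, 0)), B = cbind(c(0, 1)), C = cbind(1))
  r <- reconstruct(m)
  expect_equal(r[1, 2, 1], 3)
  expect_equal(sum(r != 0), 1L)

  ## random 3-component model on 4 x 4 x 3 against the loop oracle
  set.seed(3)
  A <- matrix(runif(12), 4); B <- matrix(runif(12), 4)
  C <- matrix(runif(9), 3)
  m3 <- CPModel(A, B, C)
  expect_equal(unname(reconstruct(m3)), loopReconstruct(A, B, C),
               tolerance = 1e-12)
})

test_that("a sparse-support component reconstructs exactly its O-D block", {
  geo <- c("SanFrancisco", "SantaClara", "Alameda", "SanMateo", "Marin")
  a <- c(2, 1.5, 0, 0, 0)
  b <- c(0, 0, 1, 0.8, 0.5)
  cc <- c(1, 2, 1.5)
  m <- CPModel(cbind(a), cbind(b), cbind(cc), geo = geo,
               periods = c("2000", "2001", "2002"))
  r <- reconstruct(m)
  support <- r[c("SanFrancisco", "SantaClara"),
               c("Alameda", "SanMateo", "Marin"), ]
  expect_equal(sum(r), sum(support))           # nothing outside the block
  ## each year's slab is the same rank-one matrix scaled by c
  expect_equal(r[, , 2], 2 * r[, , 1], tolerance = 1e-12)
  expect_equal(r[, , 3], 1.5 * r[, , 1], tolerance = 1e-12)
})

test_that("maskedObjective ignores the diagonal and matches the loop oracle", {
  set.seed(4)
  A <- matrix(runif(6), 3); B <- matrix(runif(6), 3); C <- matrix(runif(4), 2)
  truthV <- loopReconstruct(A, B, C)
  v <- truthV
  di <- cbind(rep(1:3, 2), rep(1:3, 2), rep(1:2, each = 3))
  v[di] <- 999                                  # arbitrary diagonal junk
  x <- FlowTensor(v)
  m <- CPModel(A, B, C)
  expect_equal(maskedObjective(x, m), 0, tolerance = 1e-18)

  ## a vanishing-scale model leaves the full masked energy
  tiny <- CPModel(A * 1e-30, B, C)
  expect_equal(maskedObjective(x, tiny), sum(flowMask(x) * v^2),
               tolerance = 1e-10)

  ## random model vs. brute force
  set.seed(5)
  A2 <- matrix(runif(6), 3); B2 <- matrix(runif(6), 3); C2 <- matrix(runif(4), 2)
  m2 <- CPModel(A2, B2, C2)
  expect_equal(maskedObjective(x, m2),
               loopMaskedObjective(v, flowMask(x),
                                   originFactors(m2), destFactors(m2),
                                   temporalFactors(m2), systemScales(m2)),
               tolerance = 1e-10)
})

test_that("CPModel normalization: scales, idempotence, ordering, drops", {
  m <- CPModel(A = cbind(c(3, 4, 0)), B = cbind(c(0, 0, 1)),
               C = cbind(c(2, 0)))
  expect_equal(unname(systemScales(m)), 10)          # 5 * 1 * 2
  expect_equal(unname(originFactors(m)[, 1]), c(0.6, 0.8, 0))

  ## idempotence on an already-normalized model
  m2 <- CPModel(sweep(originFactors(m), 2, systemScales(m), "*"),
                destFactors(m), temporalFactors(m))
  expect_equal(unname(systemScales(m2)), 10, tolerance = 1e-12)
  expect_equal(originFactors(m2), originFactors(m), tolerance = 1e-14)

  ## components re-sorted by lambda
  A <- cbind(c(2, 0), c(0, 7)); B <- cbind(c(1, 0), c(0, 1))
  C <- cbind(c(1, 0), c(0, 1))
  ms <- CPModel(A, B, C)
  expect_equal(unname(systemScales(ms)), c(7, 2))
  expect_equal(unname(originFactors(ms)[, 1]), c(0, 1))

  ## all-zero component dropped with a warning
  expect_warning(
    md <- CPModel(cbind(c(1, 0), 0), cbind(c(0, 1), 0), cbind(1, 1)),
    "zero")
  expect_equal(nComponents(md), 1L)

  ## normalization preserves the reconstruction
  set.seed(6)
  Ar <- matrix(runif(8), 4); Br <- matrix(runif(8), 4); Cr <- matrix(runif(6), 3)
  expect_equal(unname(reconstruct(CPModel(Ar, Br, Cr))),
               loopReconstruct(Ar, Br, Cr), tolerance = 1e-12)
})

test_that("reconstruct is invariant to scale transfer between modes", {
  set.seed(8)
  A <- matrix(runif(8), 4); B <- matrix(runif(8), 4); C <- matrix(runif(6), 3)
  base <- reconstruct(CPModel(A, B, C))
  moved <- reconstruct(CPModel(A * 2.5, B, C / 2.5))
  expect_equal(moved, base, tolerance = 1e-12)
})

test_that("fitNCPD recovers a noiseless rank-1 system near-perfectly", {
  sim <- generatePlanted(plantedSpec(I = 10, K = 6, nSystems = 1,
                                     supportSize = 3, noise = "none",
                                     seed = 9))
  fit <- fitNCPD(sim$tensor, rank = 1, restarts = 3, seed = 1)
  expect_gte(factorMatchScore(fit, sim$truth), 0.999)
  expect_true(isTRUE(fit@converged))
})

test_that("fitNCPD recovers well-separated noiseless planted systems", {
  sim <- generatePlanted(smallSpec(seed = 21))
  fit <- fitNCPD(sim$tensor, rank = 2, restarts = 5, seed = 1)
  expect_gte(factorMatchScore(fit, sim$truth), 0.99)
  relres <- sqrt(maskedObjective(sim$tensor, fit)) /
    sqrt(sum(flowMask(sim$tensor) * flowValues(sim$tensor)^2))
  expect_lte(relres, 1e-6)
})

test_that("the solver attains the grid-search optimum on tiny instances", {
  set.seed(12)
  for (K in c(1L, 2L)) {
    v <- array(sample(1:9, 4 * K, replace = TRUE), c(2, 2, K))
    x <- FlowTensor(v)
    fit <- fitNCPD(x, rank = 1, restarts = 10, seed = 1,
                   tol = 1e-14, maxIter = 5000)
    oracle <- gridRank1Objective(v, flowMask(x))
    expect_equal(maskedObjective(x, fit), oracle, tolerance = 1e-8)
  }
})

test_that("fit refuses empty and degenerate inputs", {
  x <- FlowTensor(array(0, c(3, 3, 2)))
  expect_error(fitNCPD(x, rank = 1), "nothing to fit")
  v <- array(1, c(2, 2, 2))
  expect_warning(fitNCPD(FlowTensor(v), rank = 3, restarts = 1,
                         maxIter = 5),
                 "exceeds")
  expect_error(fitNCPD(FlowTensor(v), rank = 0), "positive")
})

test_that("objective trace is non-increasing for every restart and tensor", {
  for (s in 1:3) {
    sim <- generatePlanted(smallSpec(noise = "poisson", seed = 30 + s))
    X <- flowValues(sim$tensor); W <- flowMask(sim$tensor)
    res <- migtensor:::withSeed(s, migtensor:::.ncpdSingle(X, W, 2L, 200L, 1e-8))
    expectMonotoneTrace(res$trace)
  }
})

test_that("masked-out cells are completely neutral to the fit", {
  sim <- generatePlanted(smallSpec(seed = 41))
  fit1 <- fitNCPD(sim$tensor, rank = 2, restarts = 2, seed = 7)

  v <- flowValues(sim$tensor)
  I <- dim(v)[1]; K <- dim(v)[3]
  di <- cbind(rep(seq_len(I), K), rep(seq_len(I), K), rep(seq_len(K), each = I))
  v[di] <- v[di] * 1e6 + 123.456               # arbitrary perturbation
  pert <- FlowTensor(v, geo = geoLabels(sim$tensor),
                     periods = periodLabels(sim$tensor))
  fit2 <- fitNCPD(pert, rank = 2, restarts = 2, seed = 7)

  expect_identical(originFactors(fit1), originFactors(fit2))
  expect_identical(destFactors(fit1), destFactors(fit2))
  expect_identical(temporalFactors(fit1), temporalFactors(fit2))
  expect_identical(objectiveTrace(fit1), objectiveTrace(fit2))
})

test_that("fitNCPD is deterministic given seed and options", {
  sim <- generatePlanted(smallSpec(seed = 55))
  f1 <- fitNCPD(sim$tensor, rank = 2, restarts = 3, seed = 2)
  f2 <- fitNCPD(sim$tensor, rank = 2, restarts = 3, seed = 2)
  expect_identical(originFactors(f1), originFactors(f2))
  expect_identical(objectiveTrace(f1), objectiveTrace(f2))
})

test_that("rankScan residuals are small at the true rank and non-increasing", {
  sim <- generatePlanted(plantedSpec(I = 8, K = 4, nSystems = 1,
                                     supportSize = 3, noise = "none",
                                     seed = 13))
  scan1 <- rankScan(sim$tensor, 1L, restarts = 3, seed = 1)
  expect_lte(scan1$relResidual, 1e-6)

  sim2 <- generatePlanted(smallSpec(noise = "poisson", seed = 14))
  scan <- rankScan(sim2$tensor, 1:4, restarts = 3, seed = 1)
  expect_true(all(scan$relResidual >= 0 & scan$relResidual <= 1))
  expect_true(all(diff(scan$relResidual) <= 1e-6))
  expect_error(rankScan(sim2$tensor, c(2, 2)), "increasing")
})

test_that("congruence scores: identity is 1, disjoint supports are ~0", {
  sim <- generatePlanted(smallSpec(seed = 61))
  fit <- fitNCPD(sim$tensor, rank = 2, restarts = 2, seed = 1)
  expect_equal(unname(congruenceScores(fit, fit)), c(1, 1),
               tolerance = 1e-12)

  ## components supported on disjoint geographies score ~0
  m1 <- CPModel(cbind(c(1, 0, 0, 0)), cbind(c(0, 1, 0, 0)), cbind(c(1, 0)))
  m2 <- CPModel(cbind(c(0, 0, 1, 0)), cbind(c(0, 0, 0, 1)), cbind(c(0, 1)))
  expect_equal(unname(congruenceScores(m1, m2)), 0)
})
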
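# Stochastic simulation of the expansion/suspension protocol.

test_that("clone expansion doubles deterministically and obeys no-switch limits", {
  m0 <- SwitchingModel(0, 0)
  st <- expandClone(m0, G = 1, founder = "resistant", nClones = 5, seed = 1)
  expect_equal(st$n_resistant, rep(2, 5))
  expect_equal(st$n_sensitive, rep(0, 5))
  st8 <- expandClone(m0, G = 8, founder = "sensitive", nClones = 3, seed = 1)
  expect_equal(st8$n_sensitive + st8$n_resistant, rep(256, 3))
  expect_equal(st8$n_resistant, rep(0, 3))
  expect_error(expandClone(m0, G = 31), "overflow")
  expect_error(expandClone(SwitchingModel(0, 0), G = 2,
                           founder = "equilibrium", nClones = 1),
               "undefined")
})

test_that("expansion matches the lineage-state recursion in expectation", {
  m <- SwitchingModel(0.3, 0.095)
  # symmetric chain equilibrates in one step
  msym <- SwitchingModel(0.5, 0.5)
  st <- expandClone(msym, G = 2, founder = "sensitive", nClones = 4000,
                    seed = 2)
  frac <- sum(st$n_resistant) / sum(st$n_resistant + st$n_sensitive)
  expect_equal(frac, 0.5, tolerance = 0.02)
  # G = 3 from a sensitive founder: m3 = 0.5913
  st3 <- expandClone(m, G = 3, founder = "sensitive", nClones = 20000,
                     seed = 3)
  frac3 <- sum(st3$n_resistant) / (8 * 20000)
  expect_equal(frac3, oracleResistantProb(0.3, 0.095, 3, 0),
               tolerance = 0.01)
})

test_that("per-cell and aggregate expansion engines agree in distribution", {
  m <- SwitchingModel(0.25, 0.1)
  rejections <- 0
  for (s in 1:20) {
    a <- expandClone(m, G = 4, founder = "sensitive", nClones = 400,
                     mode = "aggregate", seed = s)$n_resistant
    b <- expandClone(m, G = 4, founder = "sensitive", nClones = 400,
                     mode = "percell", seed = s + 1000)$n_resistant
    p <- suppressWarnings(ks.test(a, b)$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("suspension assay has the survival-law expectation", {
  m <- defaultModel(Td = 100)
  # pure resistant clone: expected survival e^(gamma T) = 1.181
  res <- suspensionAssay(m, nS = 0, nR = 50000, T = 24, seed = 4)
  expect_equal(res$survival_fraction, exp(log(2) / 100 * 24),
               tolerance = 0.02)
  # pure sensitive clone: zero survivors under the default death mode
  res0 <- suspensionAssay(m, nS = 1000, nR = 0, seed = 5)
  expect_equal(res0$survival_fraction, 0)
  # the worked mixture: 190,000 R + 60,000 S at Td = 100 gives ~0.9
  mix <- suspensionAssay(m, nS = 60000, nR = 190000, seed = 6)
  expect_equal(mix$survival_fraction, 0.76 * exp(log(2) / 100 * 24),
               tolerance = 0.01)
  expect_equal(mix$survival_fraction, 0.9, tolerance = 0.02)
  # exponential sensitive-death mode keeps some sensitive survivors
  me <- SwitchingModel(0.3, 0.095, TdSusp = Inf,
                       sensitiveDeath = "exponential", deathRate = 0.05)
  re <- suspensionAssay(me, nS = 100000, nR = 0, T = 24, seed = 7)
  expect_equal(re$survival_fraction, exp(-0.05 * 24), tolerance = 0.05)
  expect_error(suspensionAssay(m, 0, 0), "at least one cell")
})

test_that("fluctuation experiment is reproducible and conserves the survival law", {
  m <- defaultModel(Td = 100)
  p <- smallProtocol(G = 10, N0 = 500, nClones = 200)
  r1 <- fluctuationExperiment(m, p, seed = 42)
  r2 <- fluctuationExperiment(m, p, seed = 42)
  expect_identical(r1@survival, r2@survival)
  expect_identical(r1@founders, r2@founders)
  r3 <- fluctuationExperiment(m, p, seed = 43)
  expect_false(identical(r1@survival, r3@survival))
  # mean survival ~ f_eq e^(gamma T)
  expect_equal(mean(r1@survival),
               equilibriumFraction(m) * exp(log(2) / 100 * 24),
               tolerance = 0.03)
  # homogeneous no-switching resistant clones, deterministic assay: CV = 0
  m0 <- SwitchingModel(0, 0, TdSusp = 100)
  r0 <- fluctuationExperiment(m0, smallProtocol(G = 6, N0 = 50, nClones = 20),
                              founder = "resistant", seed = 1,
                              stochasticAssay = FALSE)
  expect_equal(cv(r0@survival), 0)
  # exact sampling mode refuses clones smaller than the plating number
  tiny <- AssayProtocol(expansionGenerations = 3, cellsPlated = 100,
                        nClones = 5)
  expect_error(fluctuationExperiment(m, tiny, seed = 1,
                                     sampling = "hypergeometric"),
               "binomial")
  rbin <- fluctuationExperiment(m, tiny, seed = 1, sampling = "binomial")
  expect_length(rbin@survival, 5)
})

test_that("founder-state influence on survival decays as (1-kOn-kOff)^G", {
  m <- defaultModel(Td = 100)  # lambda ~ 0.60
  lambda <- 1 - m@kOn - m@kOff
  boost <- exp(log(2) / 100 * 24)
  # empirical founder effect (mean survival difference R- vs S-founded
  # clones) matches the lineage-recursion prediction lambda^G e^(gamma T)
  for (G in c(2, 4)) {
    r <- fluctuationExperiment(m, smallProtocol(G = G, N0 = 2^G,
                                                nClones = 4000),
                               seed = 9, plated = "whole",
                               stochasticAssay = FALSE)
    isR <- r@founders == "R"
    diffHat <- mean(r@survival[isR]) - mean(r@survival[!isR])
    expect_equal(diffHat, lambda^G * boost, tolerance = 0.12)
  }
  # Pearson correlation with survival also decays with expansion depth
  cors <- vapply(c(2, 6, 12), function(G) {
    r <- fluctuationExperiment(m, smallProtocol(G = G, N0 = 2^G %/% 2,
                                                nClones = 3000), seed = 9)
    abs(cor(as.numeric(r@founders == "R"), r@survival))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
  # at the study depth (G = 20) the founder effect is analytically < 1e-4
  expect_lt(expectedResistantFraction(m, 20, 1) -
              expectedResistantFraction(m, 20, 0), 1e-4)
})

test_that("predicted CV shrinks with plated cell number and is seed-stable", {
  m <- defaultModel(Td = 100)
  cvs <- vapply(c(2500, 25000, 250000), function(N0) {
    p <- AssayProtocol(cellsPlated = N0, nClones = 60)
    predictedCV(m, p, nReps = 60, seed = 17)[["cv"]]
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
  p1 <- predictedCV(m, AssayProtocol(), nReps = 20, seed = 5)
  p2 <- predictedCV(m, AssayProtocol(), nReps = 20, seed = 5)
  expect_identical(p1, p2)
})

test_that("Monte Carlo CV agrees with exhaustive enumeration on a small instance", {
  kOn <- 0.3; kOff <- 0.095; G <- 3; N0 <- 6; Td <- 100
  exact <- oracleSurvivalCV(kOn, kOff, G, N0, Td)
  m <- SwitchingModel(kOn, kOff, TdSusp = Td)
  p <- AssayProtocol(expansionGenerations = G, cellsPlated = N0,
                     nClones = 400)
  mc <- predictedCV(m, p, nReps = 200, seed = 21, stochasticAssay = FALSE)
  expect_lt(abs(mc[["cv"]] - exact), 3 * mc[["mc_error"]] + 0.002)
})
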
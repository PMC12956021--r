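# Closed-form relations among doubling time, growth rate, survival and
# resistant fraction.

test_that("growth rate from doubling time", {
  expect_equal(growthRateFromDoubling(100), log(2) / 100, tolerance = 1e-12)
  expect_equal(growthRateFromDoubling(100), 0.006931, tolerance = 1e-4)
  expect_equal(growthRateFromDoubling(38), 0.018240, tolerance = 1e-4)
  expect_identical(growthRateFromDoubling(Inf), 0)
  expect_error(growthRateFromDoubling(0), "positive")
  expect_error(growthRateFromDoubling(-5), "positive")
})

test_that("resistant fraction from mean survival reproduces the worked value", {
  expect_equal(round(resistantFractionFromSurvival(0.9, 24, 100), 2), 0.76)
  expect_equal(resistantFractionFromSurvival(0.9, 24, Inf), 0.9)
  # high-precision evaluation of 0.9 * 2^(-24/38)
  expect_equal(resistantFractionFromSurvival(0.9, 24, 38),
               0.9 * 2^(-24 / 38), tolerance = 1e-12)
  expect_equal(resistantFractionFromSurvival(0.9, 24, 38), 0.5809,
               tolerance = 1e-4)
  expect_error(resistantFractionFromSurvival(0, 24, 100), "S must be")
  # infeasible: survival exceeds what pure resistant growth allows
  expect_error(resistantFractionFromSurvival(1.5, 24, 200), "infeasible")
  expect_warning(resistantFractionFromSurvival(1.5, 24, 200, strict = FALSE),
                 "infeasible")
})

test_that("survival balance round-trips across parameter space", {
  set.seed(11)
  for (i in 1:50) {
    f <- runif(1, 1e-6, 1)
    Td <- runif(1, 10, 1e4)
    gamma <- log(2) / Td
    S <- f * exp(gamma * 24)
    expect_equal(resistantFractionFromSurvival(S, 24, Td, strict = FALSE),
                 f, tolerance = 1e-12)
  }
})

test_that("resistant fraction is monotone in Td and in survival", {
  Tds <- c(38, 50, 75, 100, 150, 200, 1000)
  fs <- resistantFractionFromSurvival(0.9, 24, Tds)
  expect_true(all(diff(fs) > 0))
  Ss <- seq(0.2, 1.1, by = 0.1)
  fs2 <- vapply(Ss, resistantFractionFromSurvival, numeric(1),
                T = 24, Td = 100)
  expect_true(all(diff(fs2) > 0))
})

test_that("memory/equilibrium to rates map and its inverse compose to identity", {
  k <- ratesFromMemoryEquilibrium(10.5, 0.76)
  expect_equal(unname(k), c(0.3016, 0.09524), tolerance = 1e-4)
  back <- memoryEquilibriumFromRates(k[["kOn"]], k[["kOff"]])
  expect_equal(back[["M"]], 10.5, tolerance = 1e-12)
  expect_equal(back[["fEq"]], 0.76, tolerance = 1e-12)
  # symmetry at f_eq = 0.5, and pure decay at f_eq = 0
  k5 <- ratesFromMemoryEquilibrium(7, 0.5)
  expect_equal(k5[["kOn"]], k5[["kOff"]])
  k0 <- ratesFromMemoryEquilibrium(10.5, 0)
  expect_equal(unname(k0), c(0, 1 / 10.5))
  expect_error(ratesFromMemoryEquilibrium(10.5, 1), "sensitive reservoir")
  expect_error(ratesFromMemoryEquilibrium(0, 0.5), "M must be")
})

test_that("effective growth rate matches its definition and handles edges", {
  expect_equal(effectiveGrowthRate(250000, 0.9 * 250000, 24),
               log(0.9) / 24, tolerance = 1e-12)
  expect_equal(signif(effectiveGrowthRate(1, 0.9, 24), 1), -0.004)
  expect_identical(effectiveGrowthRate(100, 100, 24), 0)
  expect_equal(effectiveGrowthRate(1000, 2000, 45), log(2) / 45,
               tolerance = 1e-12)
  expect_identical(effectiveGrowthRate(100, 0, 24), -Inf)
  expect_error(effectiveGrowthRate(0, 10, 24), "N0")
  expect_error(effectiveGrowthRate(10, -1, 24), "Nt")
  # exact inversion of exponential growth
  set.seed(3)
  for (i in 1:20) {
    g <- runif(1, -0.05, 0.05)
    expect_equal(effectiveGrowthRate(1e5, 1e5 * exp(g * 24), 24), g,
                 tolerance = 1e-12)
  }
})

test_that("anoikis classification uses the >= 100% viability rule", {
  expect_equal(as.character(classifyAnoikis(0.361)), "sensitive")
  expect_equal(as.character(classifyAnoikis(1.252)), "resistant")
  expect_equal(as.character(classifyAnoikis(1.0)), "resistant")
  expect_equal(as.character(classifyAnoikis(c(0.5, 1.5))),
               c("sensitive", "resistant"))
  expect_error(classifyAnoikis(-0.1), ">= 0")
})

test_that("switching model accessors and validity", {
  m <- switchingModelFromMemory(10.5, 0.76, TdSusp = 100)
  expect_equal(equilibriumFraction(m), 0.76, tolerance = 1e-12)
  expect_equal(memoryGenerations(m), 10.5, tolerance = 1e-12)
  expect_error(SwitchingModel(-0.1, 0.5), "probability")
  expect_error(SwitchingModel(0.1, 0.5, TdSusp = -1), "positive")
  # expected resistant fraction follows the lineage recursion
  m2 <- SwitchingModel(0.3, 0.095)
  expect_equal(expectedResistantFraction(m2, 3, 0),
               oracleResistantProb(0.3, 0.095, 3, 0), tolerance = 1e-12)
  expect_equal(expectedResistantFraction(m2, 3, 0), 0.5913,
               tolerance = 1e-4)
})
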
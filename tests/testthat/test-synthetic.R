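# Synthetic-data generators: determinism, calibration, and the
# discriminating property between the two-state and continuum models.

test_that("presets load with their documented parameters", {
  expect_true(all(c("ov90-clones", "parental") %in% listPresets()))
  pr <- continuumPreset("ov90-clones")
  expect_s4_class(pr, "ContinuumParams")
  expect_equal(pr@muG, -0.004)
  expect_equal(pr@sigmaG, 0.012)
  expect_equal(pr@rho, 0)
  expect_equal(pr@nClones, 60)
  par <- continuumPreset("parental")
  expect_equal(par$noise_cv, 0.11)
  expect_equal(par$n_replicates, 11)
  expect_error(continuumPreset("nope"), "unknown preset")
})

test_that("continuum tables are deterministic given the seed", {
  pr <- continuumPreset("ov90-clones")
  t1 <- generateContinuumTable(pr, seed = 5)
  t2 <- generateContinuumTable(pr, seed = 5)
  expect_identical(records(t1), records(t2))
  t3 <- generateContinuumTable(pr, seed = 6)
  expect_false(identical(records(t1), records(t3)))
  # zero heterogeneity and zero noise collapse to a constant table
  flat <- ContinuumParams(sigmaG = 0, measCV = 0, nClones = 10)
  tf <- generateContinuumTable(flat, seed = 1)
  expect_equal(cv(survivalFractions(tf, "P1")), 0)
})

test_that("ov90 preset reproduces the observed clone-cohort moments at large n", {
  pr <- continuumPreset("ov90-clones")
  tab <- generateContinuumTable(pr, seed = 31, nClones = 50000)
  s1 <- survivalFractions(tab, "P1")
  # survival CV close to its closed-form design value and to the observed
  # 0.25-0.3 band
  expect_equal(cv(s1), continuumTrueCV(pr), tolerance = 0.02)
  expect_equal(cv(s1), 0.283, tolerance = 0.05)
  # growth-rate cohort: mean -0.004 /h, SD ~0.012 (CV ~300%), ~2/3
  # negative, a few 45-h doublers per 60 clones
  gs <- growthRateSummary(tab)
  expect_lt(abs(gs$mean - (-0.004)), 2e-4)
  expect_lt(abs(gs$sd - 0.012), 4e-4)
  expect_equal(gs$cv, 3, tolerance = 0.15)
  expect_gt(gs$frac_negative, 0.55)
  expect_lt(gs$frac_negative, 0.72)
  doubPer60 <- gs$n_doubling / gs$n * 60
  expect_gt(doubPer60, 1)
  expect_lt(doubPer60, 8)
  # the lognormal link puts the mean survival slightly above the observed
  # ~0.9 when the growth-rate moments are matched (documented limitation)
  expect_equal(mean(s1), exp(pr@muG * 24 + ((pr@sigmaG * 24)^2 +
                                              log(1 + pr@measCV^2)) / 2),
               tolerance = 0.01)
})

test_that("growth-rate cohort shape holds at the study size across seeds", {
  pr <- continuumPreset("ov90-clones")
  stats <- t(vapply(1:20, function(s) {
    gs <- growthRateSummary(generateContinuumTable(pr, seed = 300 + s))
    c(fneg = gs$frac_negative, ndoub = gs$n_doubling)
  }, numeric(2)))
  expect_gt(mean(stats[, "fneg"]), 0.55)
  expect_lt(mean(stats[, "fneg"]), 0.72)
  expect_true(median(stats[, "ndoub"]) >= 1 && median(stats[, "ndoub"]) <= 8)
})

test_that("parental replicates carry only population-level noise", {
  x <- generateParentalReplicates(10000, noiseCV = 0.11, seed = 2)
  expect_equal(cv(x), 0.11, tolerance = 0.01)
  expect_equal(mean(x), 0.9, tolerance = 0.01)
  expect_equal(generateParentalReplicates(5, noiseCV = 0, seed = 1),
               rep(0.9, 5))
  # n = 11 sampling spread of the CV is on the order of the reported
  # +/- 0.04 interval half-width
  cvs <- vapply(1:500, function(s)
    cv(generateParentalReplicates(11, seed = 600 + s)), numeric(1))
  expect_equal(mean(cvs), 0.11, tolerance = 0.015)
  expect_gt(sd(cvs), 0.01)
  expect_lt(sd(cvs), 0.05)
})

test_that("two-state tables use the common schema and near-zero fluctuation", {
  m <- defaultModel(Td = 100)
  tab <- generateTwoStateTable(m, AssayProtocol(nClones = 60), seed = 8)
  rec <- records(tab)
  expect_named(rec, c("clone_id", "passage", "n_plated", "n_live",
                      "survival_fraction"))
  expect_equal(nrow(rec), 60)
  expect_equal(unique(rec$passage), "P1")
  expect_lt(cv(rec$survival_fraction), 0.01)
  # no-switching homogeneous resistant population: CV 0 without assay noise
  m0 <- SwitchingModel(0, 0, TdSusp = 100)
  t0 <- generateTwoStateTable(m0, smallProtocol(G = 8, N0 = 128, nClones = 10),
                              seed = 1, founder = "resistant",
                              stochasticAssay = FALSE)
  expect_equal(cv(records(t0)$survival_fraction), 0)
  # multi-passage tables keep all clones at each passage
  t3 <- generateTwoStateTable(m, AssayProtocol(expansionGenerations = 12,
                                               cellsPlated = 2000,
                                               nClones = 15),
                              seed = 3, passages = c("P1", "P3", "P6"))
  expect_equal(sort(unique(records(t3)$passage)), c("P1", "P3", "P6"))
  expect_equal(sum(records(t3)$passage == "P6"), 15)
})

test_that("two-state and continuum generators are separated by their CV", {
  m <- defaultModel(Td = 100)
  pr <- continuumPreset("ov90-clones")
  twoState <- vapply(1:20, function(s) {
    cv(records(generateTwoStateTable(m, AssayProtocol(), seed = s))$
         survival_fraction)
  }, numeric(1))
  cont <- vapply(1:20, function(s) {
    cv(survivalFractions(generateContinuumTable(pr, seed = s), "P1"))
  }, numeric(1))
  expect_true(all(twoState < 0.01))
  expect_gt(mean(cont), 0.25)
  expect_lt(mean(cont), 0.31)
  expect_true(all(cont > 3 * max(twoState)))
})

test_that("memoryless continuum passages show no inter-passage correlation", {
  pr <- continuumPreset("ov90-clones")  # rho = 0
  ps <- vapply(1:200, function(s) {
    tab <- generateContinuumTable(pr, seed = 1000 + s)
    passageCorrelation(survivalFractions(tab, "P1"),
                       survivalFractions(tab, "P3"))[["p"]]
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  # with rho = 1 the latent propensity is frozen and passages correlate
  frozen <- ContinuumParams(rho = 1, nClones = 60)
  pf <- vapply(1:20, function(s) {
    tab <- generateContinuumTable(frozen, seed = 2000 + s)
    passageCorrelation(survivalFractions(tab, "P1"),
                       survivalFractions(tab, "P3"))[["p"]]
  }, numeric(1))
  expect_gte(mean(pf < 0.05), 0.9)
})
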
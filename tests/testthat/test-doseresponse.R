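test_that("dose-response assembly computes fractions with Wilson intervals", {
  tab <- data.frame(calcium = c(10, 100), nDocked = c(50, 50),
                    nFused = c(30, 0))
  cv <- assembleDoseResponse(tab)
  ff <- fractionFused(cv)
  expect_equal(ff$fraction, c(0.6, 0))
  expect_lt(ff$ciHigh[2], 0.5)    # CI for 0/50 excludes one half
  # per-granule input with a scoring window
  gr <- data.frame(calcium = rep(c(10, 100), each = 4),
                   fused = c(TRUE, TRUE, FALSE, FALSE,
                             TRUE, TRUE, TRUE, FALSE),
                   onsetS = c(1, 30, NA, NA, 1, 2, 3, NA))
  cv2 <- assembleDoseResponse(gr, windowS = 10)
  expect_equal(fractionFused(cv2)$nFused, c(1, 3))
  expect_error(assembleDoseResponse(data.frame(calcium = 1, nDocked = 0,
                                               nFused = 0)), "zero docked")
})

test_that("noiseless single-component data is recovered exactly and matches a grid-search oracle", {
  C <- defaultCalciumLadder()
  p <- 0.65 * C^2 / (C^2 + 10^2)
  cv <- new("DoseResponseCurve", calcium = C, nDocked = rep(1000, 8),
            nFused = round(p * 1000), fraction = p, ciLow = p, ciHigh = p)
  fit <- fitDoseResponse(cv, 1)
  expect_equal(kHalf(fit), 10, tolerance = 1e-7)
  expect_equal(hillCoefficients(fit), 2, tolerance = 1e-7)
  expect_equal(fit@fMax, 0.65, tolerance = 1e-7)
  # brute-force K grid (0.5 uM) with h fixed at truth agrees
  kOracle <- hillGridOracle(C, p, rep(1, 8), h = 2)
  expect_lt(abs(kOracle - kHalf(fit)), 0.5)
})

test_that("noiseless two-component data recovers both K values in ascending order", {
  C <- c(2, 5, 9, 13, 18, 24, 32, 45, 90, 300)
  p <- 0.6 * (0.5 * C^5 / (C^5 + 10^5) + 0.5 * C^5 / (C^5 + 48^5))
  cv <- new("DoseResponseCurve", calcium = C, nDocked = rep(2000, 10),
            nFused = round(p * 2000), fraction = p, ciLow = p, ciHigh = p)
  fit <- fitDoseResponse(cv, 2)
  expect_equal(kHalf(fit), c(10, 48), tolerance = 1e-4)
  expect_false(is.unsorted(kHalf(fit)))
  expect_equal(componentWeights(fit), c(0.5, 0.5), tolerance = 1e-4)
})

test_that("fitted curves vanish at zero calcium and increase monotonically", {
  sim <- simulateFusionOutcomes(makeScenario("untreated"), nGranules = 300,
                                seed = 2)
  fit <- fitDoseResponse(assembleDoseResponse(sim$outcomes), 2)
  Cg <- seq(0, 400, by = 1)
  Fg <- fit@fMax * (fit@weights[1] * Cg^fit@hill[1] /
                      (Cg^fit@hill[1] + fit@kHalf[1]^fit@hill[1]) +
                    fit@weights[2] * Cg^fit@hill[2] /
                      (Cg^fit@hill[2] + fit@kHalf[2]^fit@hill[2]))
  expect_equal(Fg[1], 0)
  expect_true(all(diff(Fg) >= -1e-12))
})

test_that("model selection applies the AICc, weight and K-ratio gates", {
  C <- defaultCalciumLadder()
  p <- 0.6 * C^5 / (C^5 + 12^5)
  cv <- new("DoseResponseCurve", calcium = C, nDocked = rep(300, 8),
            nFused = round(p * 300), fraction = round(p * 300) / 300,
            ciLow = p, ciHigh = p)
  f1 <- fitDoseResponse(cv, 1)
  f2 <- fitDoseResponse(cv, 2)
  sel <- selectDoseModel(f1, f2)
  # identical-K (monophasic) truth must fall back to one component
  expect_equal(sel$nComponents, 1L)
})

test_that("scenario comparison flags the lost affinity component", {
  un <- simulateFusionOutcomes(makeScenario("untreated"), nGranules = 400,
                               seed = 3)
  ffa <- simulateFusionOutcomes(makeScenario("ffa"), nGranules = 400,
                                seed = 3)
  fits <- list(
    untreated = selectDoseModel(
      fitDoseResponse(assembleDoseResponse(un$outcomes), 1),
      fitDoseResponse(assembleDoseResponse(un$outcomes), 2))$chosen,
    ffa = selectDoseModel(
      fitDoseResponse(assembleDoseResponse(ffa$outcomes), 1),
      fitDoseResponse(assembleDoseResponse(ffa$outcomes), 2))$chosen)
  rep <- compareScenarios(fits, reference = "untreated")
  expect_equal(rep$shift[rep$scenario == "untreated"], "reference")
  expect_equal(rep$shift[rep$scenario == "ffa"],
               "low-affinity component lost")
  expect_error(compareScenarios(fits, reference = "missing"),
               "missing reference")
})

test_that("K_1/2 estimator is nearly unbiased at 300 granules per level", {
  ks <- vapply(1:25, function(s) {
    sim <- simulateFusionOutcomes(makeScenario("syt9_only"),
                                  nGranules = 300, seed = s)
    kHalf(fitDoseResponse(assembleDoseResponse(sim$outcomes), 1))
  }, numeric(1))
  expect_lt(abs(mean(ks) - 48) / 48, 0.05)
})
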
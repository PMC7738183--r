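test_that("the correlation model has the right limits and amplitudes", {
  # decorrelation: G -> 1 at long lags
  g <- fcsModel(c(1e3, 1e5), occupancy = 2, tauD = 1e-3, omegaR = 1,
                omegaZ = 5, tB = 0.2, tauB = 1e-4)
  expect_equal(g, c(1, 1), tolerance = 1e-4)
  # amplitude identity: G(0) - 1 = 1/N without photophysics
  g0 <- fcsModel(1e-9, occupancy = 4, tauD = 1e-3, omegaR = 1, omegaZ = 5)
  expect_equal(g0 - 1, 1 / 4, tolerance = 1e-5)
  # X(tauD) = 1/2 in the flat-focus limit
  gd <- fcsModel(1e-3, occupancy = 1, tauD = 1e-3, omegaR = 1,
                 omegaZ = 1e6)
  expect_equal(gd - 1, 1 / 2, tolerance = 1e-5)
  # diffusion-only curves decrease strictly to 1
  tau <- defaultTauGrid()
  gg <- fcsModel(tau, occupancy = 0.5, tauD = 4e-3, omegaR = 1, omegaZ = 5)
  expect_true(all(diff(gg) < 0))
  expect_true(all(gg > 1))
  expect_error(fcsModel(1, 1, 1, 1, omegaR = 1, omegaZ = 5, tB = 1),
               "< 1")
})

test_that("Vogel viscosity and Stokes-Einstein reproduce their printed values", {
  expect_equal(vogelViscosity(298.15), 0.891, tolerance = 5e-4)
  expect_equal(vogelViscosity(310.15), 0.694, tolerance = 1e-3)
  # agreement with an independent arithmetic path to 10 digits
  a <- -3.72; b <- 578.919; cc <- -137.546
  for (T in c(280, 295.15, 298.15, 310.15, 318)) {
    eta2 <- exp((a * (cc + T) + b) / (cc + T))
    expect_equal(vogelViscosity(T), eta2, tolerance = 1e-10)
  }
  # monotone decreasing over the supported range
  Ts <- seq(278, 320, by = 0.5)
  expect_true(all(diff(vogelViscosity(Ts)) < 0))
  expect_error(vogelViscosity(100), "outside")

  expect_equal(stokesEinstein(4.5e-10, 298.15) * 1e9, 0.545,
               tolerance = 1e-3)
  expect_equal(stokesEinstein(2.53e-12, 298.15) * 1e9, 97,
               tolerance = 0.01)
  # independent path: R_h = (k/(6 pi eta)) * (T/D)
  kB <- 1.380649e-23
  for (T in c(295.15, 298.15)) {
    rh2 <- (kB / (6 * pi * vogelViscosity(T) * 1e-3)) * T / 2.5e-12
    expect_equal(stokesEinstein(2.5e-12, T), rh2, tolerance = 1e-10)
  }
  expect_equal(stokesEinstein(2 * 4.5e-10, 298.15),
               stokesEinstein(4.5e-10, 298.15) / 2)
  expect_error(stokesEinstein(-1, 298.15), "> 0")
})

test_that("forward simulation matches the closed-form diffusion quantities", {
  # D from rh via viscosity at temperature
  expect_equal(diffusionFromRh(97e-9, 298.15), 2.53e-12,
               tolerance = 2e-3)
  # tauD = omegaR^2 / (4 D)
  curves <- simulateFcs(D = 2.53e-12, omegaR = 0.2e-6, noise = 0,
                        noiseFloor = 0, tB = 0, nRuns = 1, seed = 1)
  truth <- attr(curves, "truth")
  expect_equal(truth$tauD, (0.2e-6)^2 / (4 * 2.53e-12), tolerance = 1e-9)
  expect_equal(truth$tauD, 3.95e-3, tolerance = 0.01)
  # noiseless blink-free curve decreases strictly to 1
  g <- fcsG(curves[[1]])
  expect_true(all(diff(g) < 0))
  expect_equal(tail(g, 1), 1, tolerance = 1e-3)
  expect_error(simulateFcs(structure = 0.5), "> 1")
  expect_error(simulateFcs(tB = 1), "\\[0, 1\\)")
})

test_that("noiseless curves are fitted to high precision (exact model class)", {
  curves <- simulateFcs(rh = 97.5e-9, temperature = 295.15, noise = 0,
                        noiseFloor = 0, nRuns = 1, seed = 1)
  truth <- attr(curves, "truth")
  fit <- fitFcsCurve(curves[[1]], "blink")
  expect_equal(tauD(fit), truth$tauD, tolerance = 1e-7)
  expect_equal(fit@occupancy, truth$nMean, tolerance = 1e-7)
  expect_equal(fit@tB, truth$tB, tolerance = 1e-6)
  expect_equal(fit@tauB, truth$tauB, tolerance = 1e-6)
  expect_equal(diffusionCoefficient(fit), truth$D, tolerance = 1e-7)
})

test_that("1%-noise curves recover D within 5% and flag the triplet correctly", {
  ok <- vapply(1:10, function(s) {
    curves <- simulateFcs(rh = 97.5e-9, nRuns = 20, seed = s)
    truth <- attr(curves, "truth")
    fit <- fitFcsCurve(averageFcsCurves(curves), "blink")
    abs(diffusionCoefficient(fit) - truth$D) / truth$D < 0.05
  }, logical(1))
  expect_true(all(ok))
  # model selection across seeds
  blinkOnly <- vapply(1:10, function(s) {
    avg <- averageFcsCurves(simulateFcs(rh = 97.5e-9, tT = 0, nRuns = 20,
                                        seed = 100 + s))
    selectFcsModel(fitFcsCurve(avg, "blink"),
                   fitFcsCurve(avg, "blink_triplet"))@model
  }, character(1))
  withTrip <- vapply(1:10, function(s) {
    avg <- averageFcsCurves(simulateFcs(rh = 97.5e-9, tT = 0.25,
                                        tauT = 5e-6, nRuns = 20,
                                        seed = 200 + s))
    selectFcsModel(fitFcsCurve(avg, "blink"),
                   fitFcsCurve(avg, "blink_triplet"))@model
  }, character(1))
  expect_gte(mean(c(blinkOnly == "blink",
                    withTrip == "blink_triplet")), 0.9)
})

test_that("confocal calibration recovers the focus radius", {
  cal <- simulateFcs(D = 4.5e-10, temperature = 298.15, nMean = 2,
                     tB = 0.1, tauB = 5e-5, nRuns = 20, seed = 3)
  cc <- calibrateFocus(averageFcsCurves(cal), dRef = 4.5e-10)
  expect_lt(abs(cc$omegaR - 2e-7) / 2e-7, 0.02)
  # closed form: tauD = 40 us at D = 4.5e-10 gives omegaR = 0.268 um
  expect_equal(sqrt(4 * 4.5e-10 * 4e-5), 2.683e-7, tolerance = 1e-3)
  # doubling the reference D scales omegaR by sqrt(2)
  cc2 <- calibrateFocus(averageFcsCurves(cal), dRef = 9e-10)
  expect_equal(cc2$omegaR / cc$omegaR, sqrt(2), tolerance = 1e-9)
})

test_that("per-run radii agree across temperatures after viscosity correction", {
  temps <- c(292.15, 295.15, 299.15)
  fits <- lapply(seq_along(temps), function(i) {
    curves <- simulateFcs(rh = 97.5e-9, temperature = temps[i],
                          nRuns = 20, seed = 40 + i)
    fitFcsCurve(averageFcsCurves(curves), "blink")
  })
  res <- aggregateRh(fits, temps)
  rhNm <- perRunRh(res) * 1e9
  expect_true(all(abs(rhNm - 97.5) / 97.5 < 0.05))
  expect_equal(meanRh(res) * 1e9, 97.5, tolerance = 0.05 * 97.5)
  expect_equal(diameterNm(res), 195, tolerance = 0.05 * 195)
  # identical runs give zero SD
  same <- aggregateRh(fits[c(1, 1, 1)], rep(temps[1], 3))
  expect_equal(same@sdRh, 0)
  expect_error(aggregateRh(fits[1:2], temps[1:2]), "at least 3")
})

test_that("FCS CSV round trip preserves curves", {
  curves <- simulateFcs(nRuns = 2, seed = 5)
  f <- tempfile(fileext = ".csv")
  writeFcsCurves(curves, f)
  back <- readFcsCurves(f)
  expect_equal(length(back), 2)
  expect_equal(fcsG(back[[1]]), fcsG(curves[[1]]), tolerance = 1e-12)
  expect_equal(runTemperature(back[[2]]), runTemperature(curves[[2]]))
  unlink(f)
})
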
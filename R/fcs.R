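# FCS autocorrelation models, fitting, confocal-volume calibration, and the
# viscosity-corrected Stokes-Einstein conversion to hydrodynamic radius.

#' FCS autocorrelation model with blinking and optional triplet dynamics
#'
#' Evaluates
#' \deqn{G(\tau) = 1 + \frac{\sum_i f_i n_i^2 X_i(\tau)}{(\sum_i f_i n_i)^2}
#'   \, B(\tau) \, [T(\tau)]}
#' with the 3D diffusion factor
#' \eqn{X_i = (1+\tau/\tau_{d,i})^{-1} (1+(\tau/\tau_{d,i})
#' (\omega_r/\omega_z)^2)^{-1/2}}, blinking factor
#' \eqn{B = 1 + T_b e^{-\tau/\tau_b}/(1-T_b)} and triplet factor
#' \eqn{T = 1 + T_t e^{-\tau/\tau_t}/(1-T_t)}. Occupancies \code{f} are mean
#' particle numbers in the focus, so the single-species amplitude
#' G(0) - 1 is 1/N.
#'
#' @param tau lag times, s
#' @param occupancy mean particle number per diffusing component
#' @param brightness molecular brightness per component
#' @param tauD diffusion time per component, s
#' @param omegaR,omegaZ lateral and axial focus radii (same units; only the
#'   ratio enters)
#' @param tB,tauB blinking fraction (in [0, 1)) and relaxation time, s
#' @param tT,tauT triplet fraction (in [0, 1)) and relaxation time, s
#' @param model "blink" (default) or "blink_triplet"
#' @return G(tau), same length as tau.
#' @export
fcsModel <- function(tau, occupancy, brightness = 1, tauD, omegaR, omegaZ,
                     tB = 0, tauB = 1e-4, tT = 0, tauT = 1e-5,
                     model = c("blink", "blink_triplet")) {
  model <- match.arg(model)
  if (tB >= 1 || tT >= 1) stop("tB and tT must be < 1")
  if (tB < 0 || tT < 0) stop("tB and tT must be >= 0")
  if (omegaZ <= omegaR) stop("omegaZ must exceed omegaR (structure > 1)")
  k <- length(occupancy)
  brightness <- rep_len(brightness, k)
  stopifnot(length(tauD) == k)
  num <- 0
  for (i in seq_len(k)) {
    x <- tau / tauD[i]
    Xi <- 1 / (1 + x) / sqrt(1 + x * (omegaR / omegaZ)^2)
    num <- num + occupancy[i] * brightness[i]^2 * Xi
  }
  amp <- num / sum(occupancy * brightness)^2
  B <- 1 + tB * exp(-tau / tauB) / (1 - tB)
  G <- 1 + amp * B
  if (model == "blink_triplet")
    G <- 1 + amp * B * (1 + tT * exp(-tau / tauT) / (1 - tT))
  G
}

#' Average FCS curves collected on the same lag grid
#'
#' @param curves list of \linkS4class{FcsCurve} on identical tau grids
#' @return An \linkS4class{FcsCurve} with the mean correlation and mean
#'   temperature.
#' @export
averageFcsCurves <- function(curves) {
  stopifnot(length(curves) >= 1)
  tau <- fcsTau(curves[[1]])
  for (cv in curves)
    if (!isTRUE(all.equal(fcsTau(cv), tau)))
      stop("curves must share one lag grid")
  g <- rowMeans(vapply(curves, fcsG, numeric(length(tau))))
  new("FcsCurve", tau = tau, g = g,
      temperature = mean(vapply(curves, runTemperature, numeric(1))),
      duration = sum(vapply(curves, function(cv) cv@duration, numeric(1))))
}

.fcsAicc <- function(rss, nObs, nPar) {
  k <- nPar + 1  # + residual variance
  nObs * log(rss / nObs) + 2 * k + 2 * k * (k + 1) / max(nObs - k - 1, 0.5)
}

#' Fit an FCS curve with the blinking (and optionally triplet) model
#'
#' Least-squares fit of \code{\link{fcsModel}} with a fixed structure
#' parameter omegaZ/omegaR taken from the confocal calibration. Fitted
#' parameters: occupancy, diffusion time(s), blinking fraction and time,
#' plus triplet fraction and time for \code{model = "blink_triplet"}
#' (triplet initialised faster than blinking). Brightness is fixed at 1 (it
#' cancels in single-component fits). Multi-start over diffusion-time and
#' blinking initialisations.
#'
#' @param curve an \linkS4class{FcsCurve}
#' @param model "blink" or "blink_triplet"
#' @param calibration list with \code{omegaR} (m) and \code{structure}
#'   (omegaZ/omegaR), e.g. from \code{\link{calibrateFocus}}
#' @param nComponents diffusing components (1--3; default 1)
#' @return An \linkS4class{FcsFit}; its \code{D} slot is
#'   omegaR^2/(4 tauD) of the slowest component, m^2/s.
#' @export
fitFcsCurve <- function(curve, model = c("blink", "blink_triplet"),
                        calibration = list(omegaR = 2e-7, structure = 5),
                        nComponents = 1) {
  model <- match.arg(model)
  stopifnot(is(curve, "FcsCurve"), nComponents %in% 1:3)
  tau <- curve@tau; g <- curve@g
  if (length(tau) < 8 + 2 * nComponents)
    stop("curve shorter than the parameter count")
  s <- calibration$structure
  omegaR <- calibration$omegaR
  amp0 <- max(g[1] - 1, 1e-3)
  n0 <- 1 / amp0
  half <- 1 + amp0 / 2
  tauD0 <- tau[which.min(abs(g - half))]
  triplet <- model == "blink_triplet"
  obj <- function(par) {
    k <- nComponents
    occ <- exp(par[seq_len(k)])
    td <- exp(par[k + seq_len(k)])
    tb <- plogis(par[2 * k + 1]); taub <- exp(par[2 * k + 2])
    tt <- if (triplet) plogis(par[2 * k + 3]) else 0
    taut <- if (triplet) exp(par[2 * k + 4]) else 1e-5
    fcsModel(tau, occ, 1, td, omegaR, s * omegaR, tb, taub, tt, taut,
             model = model)
  }
  best <- NULL
  for (fD in c(1, 0.3, 3)) for (tb0 in c(0.2, 0.05)) {
    k <- nComponents
    tds <- tauD0 * fD * if (k == 1) 1 else 10^(seq(-1, 1, length.out = k))
    start <- c(rep(log(n0 / k), k), log(tds), qlogis(tb0), log(1e-4))
    if (triplet) start <- c(start, qlogis(0.1), log(5e-6))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(p) g - obj(p),
        control = nls.lm.control(maxiter = 400, ftol = 1e-15,
                                 ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("FCS fit did not converge from any start")
  par <- best$par
  k <- nComponents
  occ <- exp(par[seq_len(k)])
  td <- exp(par[k + seq_len(k)])
  o <- order(td)
  occ <- occ[o]; td <- td[o]
  tb <- plogis(par[2 * k + 1]); taub <- exp(par[2 * k + 2])
  tt <- if (triplet) plogis(par[2 * k + 3]) else 0
  taut <- if (triplet) exp(par[2 * k + 4]) else 0
  rss <- best$deviance
  nPar <- length(par)
  new("FcsFit", model = model, occupancy = unname(occ),
      brightness = rep(1, k), tauD = unname(td), omegaR = omegaR,
      omegaZ = s * omegaR, tB = unname(tb), tauB = unname(taub),
      tT = unname(tt), tauT = unname(taut),
      D = unname(omegaR^2 / (4 * max(td))), rss = rss,
      aicc = .fcsAicc(rss, length(tau), nPar), converged = TRUE)
}

#' Choose between blink-only and blink+triplet FCS fits
#'
#' The triplet model is kept only when it improves AICc by at least
#' \code{deltaAicc}; ties go to the simpler blink-only model.
#'
#' @param fitBlink,fitTriplet fits of the same averaged curve
#' @param deltaAicc required AICc improvement (default 2)
#' @return The chosen \linkS4class{FcsFit}.
#' @export
selectFcsModel <- function(fitBlink, fitTriplet, deltaAicc = 2) {
  stopifnot(is(fitBlink, "FcsFit"), is(fitTriplet, "FcsFit"))
  if (aicc(fitTriplet) <= aicc(fitBlink) - deltaAicc) fitTriplet else fitBlink
}

#' Calibrate the confocal volume with a reference dye
#'
#' Fits a single-component model with a free structure parameter to a
#' reference-dye curve (Rhodamine B by default) and converts the fitted
#' diffusion time to the lateral focus radius,
#' omegaR = sqrt(4 dRef tauD).
#'
#' The reference diffusion coefficient defaults to 4.50e-10 m^2/s at
#' 25 C, the established Rhodamine B value; see the methods vignette for
#' the unit discussion.
#'
#' @param curve reference-dye \linkS4class{FcsCurve}
#' @param dRef reference diffusion coefficient, m^2/s
#' @param temperature calibration temperature, K (recorded only)
#' @return List with omegaR (m), omegaZ (m), structure, tauD (s) and the
#'   underlying \linkS4class{FcsFit}.
#' @export
calibrateFocus <- function(curve, dRef = 4.5e-10, temperature = 298.15) {
  stopifnot(is(curve, "FcsCurve"), dRef > 0)
  tau <- curve@tau; g <- curve@g
  amp0 <- max(g[1] - 1, 1e-3)
  tauD0 <- tau[which.min(abs(g - (1 + amp0 / 2)))]
  obj <- function(par) {
    occ <- exp(par[1]); td <- exp(par[2]); s <- 1 + exp(par[3])
    tb <- plogis(par[4]); taub <- exp(par[5])
    fcsModel(tau, occ, 1, td, 1, s, tb, taub, model = "blink")
  }
  best <- NULL
  for (fD in c(1, 0.3, 3)) {
    start <- c(log(1 / amp0), log(tauD0 * fD), log(4), qlogis(0.1),
               log(max(tauD0 / 50, 2e-6)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(p) g - obj(p),
        control = nls.lm.control(maxiter = 400, ftol = 1e-15,
                                 ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("calibration fit failed")
  par <- best$par
  tauDFit <- exp(par[2]); s <- 1 + exp(par[3])
  omegaR <- sqrt(4 * dRef * tauDFit)
  fitObj <- new("FcsFit", model = "blink", occupancy = exp(par[1]),
    brightness = 1, tauD = unname(tauDFit), omegaR = unname(omegaR),
    omegaZ = unname(s * omegaR), tB = unname(plogis(par[4])),
    tauB = unname(exp(par[5])), tT = 0, tauT = 0, D = dRef,
    rss = best$deviance,
    aicc = .fcsAicc(best$deviance, length(tau), 5), converged = TRUE)
  list(omegaR = unname(omegaR), omegaZ = unname(s * omegaR),
       structure = unname(s), tauD = unname(tauDFit),
       temperature = temperature, fit = fitObj)
}

#' Water viscosity from the Vogel equation
#'
#' eta(T) = exp(a + b / (c + T)) with the water parameterisation
#' a = -3.72, b = 578.919 K, c = -137.546 K and T in Kelvin. Returns
#' viscosity in mPa s (= cP); eta(298.15 K) = 0.891 mPa s.
#'
#' @param temperature K (supported range about 278--320 K)
#' @param a,b,c Vogel parameters
#' @return Viscosity, mPa s.
#' @export
vogelViscosity <- function(temperature, a = -3.72, b = 578.919,
                           c = -137.546) {
  if (any(c + temperature <= 0))
    stop("temperature outside the validity of the Vogel parameterisation")
  exp(a + b / (c + temperature))
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' R_h = k T / (6 pi eta(T) D), with eta from \code{\link{vogelViscosity}}.
#'
#' @param D diffusion coefficient, m^2/s
#' @param temperature K
#' @return Hydrodynamic radius, m.
#' @export
stokesEinstein <- function(D, temperature) {
  if (any(D <= 0)) stop("D must be > 0")
  .kB * temperature / (6 * pi * vogelViscosity(temperature) * 1e-3 * D)
}

#' Diffusion coefficient of a particle of given hydrodynamic radius
#'
#' Inverse of \code{\link{stokesEinstein}}: D = k T / (6 pi eta(T) R_h).
#'
#' @param rh hydrodynamic radius, m
#' @param temperature K
#' @return D, m^2/s.
#' @export
diffusionFromRh <- function(rh, temperature) {
  if (any(rh <= 0)) stop("rh must be > 0")
  .kB * temperature / (6 * pi * vogelViscosity(temperature) * 1e-3 * rh)
}

#' Aggregate per-run FCS fits into a hydrodynamic radius
#'
#' Converts each run's diffusion coefficient to a hydrodynamic radius at
#' that run's own temperature (accounting for run-to-run viscosity
#' differences), then averages across runs.
#'
#' @param fits list of \linkS4class{FcsFit}, one per run
#' @param temperatures per-run temperatures, K
#' @return An \linkS4class{RhResult}.
#' @export
aggregateRh <- function(fits, temperatures) {
  if (length(fits) < 3) stop("at least 3 runs are required")
  stopifnot(length(fits) == length(temperatures))
  rh <- vapply(seq_along(fits), function(i)
    stokesEinstein(diffusionCoefficient(fits[[i]]), temperatures[i]),
    numeric(1))
  new("RhResult", perRunRh = rh, temperatures = temperatures,
      meanRh = mean(rh), sdRh = sd(rh), kBoltzmann = .kB)
}

#' Read FCS curves from CSV
#'
#' Expects columns tau_s, g, temperature_K, run_id.
#'
#' @param path CSV file
#' @return Named list of \linkS4class{FcsCurve}, one per run_id.
#' @export
readFcsCurves <- function(path) {
  d <- read.csv(path)
  need <- c("tau_s", "g", "temperature_K", "run_id")
  if (!all(need %in% names(d)))
    stop("missing column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  lapply(split(d, d$run_id), function(r)
    new("FcsCurve", tau = r$tau_s, g = r$g,
        temperature = r$temperature_K[1], duration = 30))
}

#' Write FCS curves to CSV (inverse of \code{readFcsCurves})
#'
#' @param curves named list of \linkS4class{FcsCurve}
#' @param path output CSV
#' @return Invisibly, \code{path}.
#' @export
writeFcsCurves <- function(curves, path) {
  ids <- if (is.null(names(curves))) seq_along(curves) else names(curves)
  d <- do.call(rbind, lapply(seq_along(curves), function(i)
    data.frame(tau_s = fcsTau(curves[[i]]), g = fcsG(curves[[i]]),
               temperature_K = runTemperature(curves[[i]]),
               run_id = ids[i])))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Full FCS sizing pipeline over runs
#'
#' For each run (a list of curves from one collection), averages the
#' curves, fits the blinking model (and, when \code{model = "auto"}, also
#' the blink+triplet model, keeping the AICc winner), and converts to a
#' per-run hydrodynamic radius at the run temperature.
#'
#' @param runs list of runs; each run is a list of \linkS4class{FcsCurve}
#' @param calibration confocal calibration (see \code{\link{fitFcsCurve}})
#' @param model "blink", "blink_triplet", or "auto"
#' @return List with \code{rh} (an \linkS4class{RhResult}), per-run
#'   \code{fits}, and the models chosen.
#' @export
fcsSizing <- function(runs, calibration = list(omegaR = 2e-7, structure = 5),
                      model = c("auto", "blink", "blink_triplet")) {
  model <- match.arg(model)
  fits <- vector("list", length(runs))
  temps <- numeric(length(runs))
  for (i in seq_along(runs)) {
    avg <- averageFcsCurves(runs[[i]])
    temps[i] <- runTemperature(avg)
    fits[[i]] <- if (model == "auto") {
      selectFcsModel(fitFcsCurve(avg, "blink", calibration),
                     fitFcsCurve(avg, "blink_triplet", calibration))
    } else fitFcsCurve(avg, model, calibration)
  }
  list(rh = aggregateRh(fits, temps), fits = fits,
       models = vapply(fits, function(f) f@model, character(1)))
}
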
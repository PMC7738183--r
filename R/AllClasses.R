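#' Parameters of one granule population
#'
#' Generative parameters for a single granule population (one synaptotagmin
#' isoform). Fusion probability at calcium concentration C follows
#' maxFuseProb * C^h / (C^h + kHalf^h). Content release follows the two-step
#' model: exponential loss at \code{poreRate} after fusion onset, an
#' instantaneous intensity step of \code{collapseGain} times the remaining
#' intensity when the granule collapses, then exponential decay at
#' \code{postRate}.
#'
#' @slot label population label, "syt7" or "syt9"
#' @slot weight mixture fraction in a scenario, in [0, 1]
#' @slot kHalf calcium half-activation, uM
#' @slot hill Hill cooperativity (dimensionless)
#' @slot maxFuseProb asymptotic fusion probability in [0, 1]
#' @slot delayMean mean fusion delay after calcium arrival, s
#' @slot poreRate pre-collapse content-loss rate, 1/s
#' @slot collapseGain fractional intensity jump at collapse (sets the
#'   delta-I_C scale)
#' @slot postRate post-collapse decay rate, 1/s
#' @slot diamMean,diamSd diameter distribution, nm
#' @slot brightness mean spot amplitude at docking, photons/frame
#' @export
setClass("PopulationParams",
  representation(label = "character", weight = "numeric", kHalf = "numeric",
    hill = "numeric", maxFuseProb = "numeric", delayMean = "numeric",
    poreRate = "numeric", collapseGain = "numeric", postRate = "numeric",
    diamMean = "numeric", diamSd = "numeric", brightness = "numeric"))

setValidity("PopulationParams", function(object) {
  msg <- character()
  if (!object@label %in% c("syt7", "syt9"))
    msg <- c(msg, "label must be 'syt7' or 'syt9'")
  if (object@weight < 0 || object@weight > 1)
    msg <- c(msg, "weight must be in [0, 1]")
  if (object@kHalf <= 0) msg <- c(msg, "kHalf must be > 0")
  if (object@maxFuseProb < 0 || object@maxFuseProb > 1)
    msg <- c(msg, "maxFuseProb must be in [0, 1]")
  if (object@diamSd <= 0) msg <- c(msg, "diamSd must be > 0")
  if (object@hill <= 0) msg <- c(msg, "hill must be > 0")
  if (object@poreRate <= 0 || object@postRate <= 0)
    msg <- c(msg, "poreRate and postRate must be > 0")
  if (object@collapseGain < 0) msg <- c(msg, "collapseGain must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Scenario configuration
#'
#' A named treatment/depletion scenario with its granule populations and a
#' seed. The six scenario names map onto the study conditions: "untreated"
#' and "cytokine_doc2b" carry both populations; "ffa" (palmitate) and
#' "syt7_only" carry only the syt7 population; "cytokine" and "syt9_only"
#' only the syt9 population.
#'
#' @slot name scenario name
#' @slot populations list of \linkS4class{PopulationParams}
#' @slot seed integer seed attached to the scenario
#' @export
setClass("ScenarioConfig",
  representation(name = "character", populations = "list", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  labs <- vapply(object@populations, function(p) p@label, character(1))
  w <- vapply(object@populations, function(p) p@weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "population weights must sum to 1")
  need <- switch(object@name,
    untreated = , cytokine_doc2b = c("syt7", "syt9"),
    ffa = , syt7_only = "syt7",
    cytokine = , syt9_only = "syt9",
    NULL)
  if (!is.null(need) && !identical(sort(labs), sort(need)))
    msg <- c(msg, sprintf("scenario '%s' must contain population(s): %s",
                          object@name, paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Single-granule intensity trace
#'
#' Background-subtracted photometry of one granule: the summed counts of a
#' 5x5 pixel region of interest around the detected centre, per frame.
#'
#' @slot values counts per frame
#' @slot frameInterval s between frames
#' @slot roiCenter (x, y) pixel centre (0-based, x = column)
#' @slot roiHalfWidth half-width of the square ROI in px (2 for 5x5)
#' @export
setClass("IntensityTrace",
  representation(values = "numeric", frameInterval = "numeric",
    roiCenter = "numeric", roiHalfWidth = "integer"))

setValidity("IntensityTrace", function(object) {
  msg <- character()
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' Granule detections on a maximum-intensity projection
#'
#' @slot centers data.frame with columns x, y (sub-pixel, 0-based) and peak
#' @slot threshold intensity threshold used (background median + k * MAD)
#' @slot minSep minimum spot separation in px used for merging
#' @export
setClass("DetectionResult",
  representation(centers = "data.frame", threshold = "numeric",
    minSep = "numeric"))

#' Calcium dose-response curve
#'
#' Fraction of docked granules that fused within the scoring window, per
#' calcium level, with Wilson binomial confidence intervals.
#'
#' @slot calcium calcium concentrations, uM
#' @slot nDocked,nFused counts per level
#' @slot fraction nFused/nDocked
#' @slot ciLow,ciHigh Wilson 95\% interval
#' @export
setClass("DoseResponseCurve",
  representation(calcium = "numeric", nDocked = "numeric", nFused = "numeric",
    fraction = "numeric", ciLow = "numeric", ciHigh = "numeric"))

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  n <- length(object@calcium)
  if (any(lengths(list(object@nDocked, object@nFused, object@fraction)) != n))
    msg <- c(msg, "all slots must have the same length")
  if (any(object@nFused > object@nDocked))
    msg <- c(msg, "nFused must be <= nDocked")
  if (any(object@fraction < 0 | object@fraction > 1))
    msg <- c(msg, "fraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Hill (mixture) fit of a dose-response curve
#'
#' One- or two-component Hill decomposition
#' F(C) = fMax * sum_j w_j C^h_j / (C^h_j + K_j^h_j), sum w_j = 1.
#' Components are ordered by ascending K. The AICc slot is computed from the
#' binomial log-likelihood of the fused counts with the total number of
#' granules as the effective sample size.
#'
#' @slot nComponents 1 or 2
#' @slot fMax overall maximum fusion probability
#' @slot weights component amplitudes (sum to 1)
#' @slot kHalf half-activation K_1/2 per component, uM, ascending
#' @slot hill Hill coefficient per component
#' @slot se asymptotic standard errors (named list)
#' @slot rss weighted residual sum of squares
#' @slot logLik binomial log-likelihood
#' @slot aicc corrected AIC
#' @slot fitted fitted fractions at the data calcium levels
#' @slot calcium the calcium levels fitted
#' @slot converged logical
#' @export
setClass("HillFit",
  representation(nComponents = "integer", fMax = "numeric",
    weights = "numeric", kHalf = "numeric", hill = "numeric", se = "list",
    rss = "numeric", logLik = "numeric", aicc = "numeric",
    fitted = "numeric", calcium = "numeric", converged = "logical"))

setValidity("HillFit", function(object) {
  msg <- character()
  if (is.unsorted(object@kHalf)) msg <- c(msg, "kHalf must be ascending")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FCS autocorrelation curve
#'
#' @slot tau lag times, s, strictly increasing
#' @slot g correlation values G(tau)
#' @slot temperature sample temperature during the run, K
#' @slot duration acquisition duration, s
#' @export
setClass("FcsCurve",
  representation(tau = "numeric", g = "numeric", temperature = "numeric",
    duration = "numeric"))

setValidity("FcsCurve", function(object) {
  msg <- character()
  if (length(object@tau) != length(object@g))
    msg <- c(msg, "tau and g must have the same length")
  if (any(object@tau <= 0) || is.unsorted(object@tau, strictly = TRUE))
    msg <- c(msg, "tau must be positive and strictly increasing")
  if (any(!is.finite(object@g))) msg <- c(msg, "g must be finite")
  if (length(msg)) msg else TRUE
})

#' Fit of an FCS autocorrelation curve
#'
#' Parameters of the three-dimensional diffusion model with blinking (and
#' optionally triplet) corrections. For a single diffusing species the
#' occupancy f is the mean number of particles in the focus, so the
#' amplitude G(0) - 1 equals 1/f.
#'
#' @slot model "blink" or "blink_triplet"
#' @slot occupancy mean particle number per component
#' @slot brightness molecular brightness per component (fixed at 1 for
#'   single-component fits, where it cancels)
#' @slot tauD diffusion time per component, s
#' @slot omegaR,omegaZ lateral and axial focus radii, m
#' @slot tB,tauB blinking fraction and relaxation time
#' @slot tT,tauT triplet fraction and relaxation time
#' @slot D diffusion coefficient omegaR^2/(4 tauD) of the slowest
#'   component, m^2/s
#' @slot rss residual sum of squares
#' @slot aicc corrected AIC (Gaussian)
#' @slot converged logical
#' @export
setClass("FcsFit",
  representation(model = "character", occupancy = "numeric",
    brightness = "numeric", tauD = "numeric", omegaR = "numeric",
    omegaZ = "numeric", tB = "numeric", tauB = "numeric", tT = "numeric",
    tauT = "numeric", D = "numeric", rss = "numeric", aicc = "numeric",
    converged = "logical"))

setValidity("FcsFit", function(object) {
  msg <- character()
  if (object@tB < 0 || object@tB >= 1) msg <- c(msg, "tB must be in [0, 1)")
  if (object@tT < 0 || object@tT >= 1) msg <- c(msg, "tT must be in [0, 1)")
  if (object@omegaZ <= object@omegaR)
    msg <- c(msg, "omegaZ must exceed omegaR")
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture fit of a diameter sample
#'
#' @slot k number of components
#' @slot means,sds,weights component parameters, ordered by ascending mean
#' @slot logLik final log-likelihood
#' @slot logLikTrace per-iteration log-likelihood of the best restart
#' @slot posterior n x k responsibility matrix
#' @slot separable TRUE when the fitted components are resolvable (mean
#'   separation of at least one pooled SD and both weights >= 0.1)
#' @slot converged logical
#' @export
setClass("DiameterMixtureFit",
  representation(k = "integer", means = "numeric", sds = "numeric",
    weights = "numeric", logLik = "numeric", logLikTrace = "numeric",
    posterior = "matrix", separable = "logical", converged = "logical"))

#' Hydrodynamic radius aggregated over FCS runs
#'
#' Each run's diffusion coefficient is converted to a hydrodynamic radius at
#' that run's own temperature (Vogel viscosity + Stokes-Einstein), then
#' averaged.
#'
#' @slot perRunRh hydrodynamic radius per run, m
#' @slot temperatures per-run temperatures, K
#' @slot meanRh,sdRh summary over runs, m
#' @slot kBoltzmann Boltzmann constant used, J/K
#' @export
setClass("RhResult",
  representation(perRunRh = "numeric", temperatures = "numeric",
    meanRh = "numeric", sdRh = "numeric", kBoltzmann = "numeric"))
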
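# Forward generator for FCS autocorrelation runs.

#' Default logarithmic lag grid for simulated FCS curves
#' @param from,to lag range, s
#' @param length number of lags
#' @return Strictly increasing numeric vector of lag times.
#' @export
defaultTauGrid <- function(from = 2e-7, to = 5, length = 150) {
  10^seq(log10(from), log10(to), length.out = length)
}

#' Simulate a set of FCS correlation runs
#'
#' Curves are generated from the forward model of \code{\link{fcsModel}}.
#' The particle's diffusion coefficient is either given directly or derived
#' from a hydrodynamic radius via the Stokes-Einstein relation with
#' Vogel-equation viscosity at the run temperature. Noise is i.i.d.
#' Gaussian with standard deviation \code{noise * (G(tau) - 1) +
#' noiseFloor} (real FCS noise is lag-correlated; this stationary model is
#' sufficient for parameter-recovery testing).
#'
#' @param rh hydrodynamic radius, m (ignored when \code{D} is given)
#' @param D diffusion coefficient, m^2/s, optional
#' @param temperature run temperature, K
#' @param omegaR lateral focus radius, m
#' @param structure omegaZ/omegaR (> 1)
#' @param nMean mean particle number in the focus
#' @param tB,tauB blinking fraction and relaxation time, s
#' @param tT,tauT triplet fraction and relaxation time, s
#' @param tauGrid lag grid, s (strictly increasing, positive)
#' @param noise relative noise amplitude on (G - 1)
#' @param noiseFloor additive noise floor
#' @param nRuns number of 30 s curves to generate
#' @param seed integer seed
#' @return List of \linkS4class{FcsCurve} with attribute \code{truth}
#'   (list: D, rh, tauD, and the photophysics parameters).
#' @export
simulateFcs <- function(rh = 97.5e-9, D = NULL, temperature = 295.15,
                        omegaR = 2e-7, structure = 5, nMean = 0.5,
                        tB = 0.3, tauB = 2e-4, tT = 0, tauT = 5e-6,
                        tauGrid = defaultTauGrid(), noise = 0.01,
                        noiseFloor = 1e-5, nRuns = 20, seed = 1L) {
  if (structure <= 1) stop("structure parameter must be > 1")
  if (tB < 0 || tB >= 1 || tT < 0 || tT >= 1)
    stop("tB and tT must be in [0, 1)")
  if (any(tauGrid <= 0) || is.unsorted(tauGrid, strictly = TRUE))
    stop("tauGrid must be positive and strictly increasing")
  if (is.null(D)) D <- diffusionFromRh(rh, temperature)
  tauDiff <- omegaR^2 / (4 * D)
  model <- if (tT > 0) "blink_triplet" else "blink"
  gClean <- fcsModel(tauGrid, nMean, 1, tauDiff, omegaR,
                     structure * omegaR, tB, tauB, tT, tauT, model = model)
  withr::local_seed(seed)
  curves <- lapply(seq_len(nRuns), function(i) {
    g <- gClean + rnorm(length(tauGrid), 0,
                        noise * (gClean - 1) + noiseFloor)
    new("FcsCurve", tau = tauGrid, g = g, temperature = temperature,
        duration = 30)
  })
  attr(curves, "truth") <- list(D = D, rh = stokesEinstein(D, temperature),
    tauD = tauDiff, nMean = nMean, tB = tB, tauB = tauB, tT = tT,
    tauT = tauT, temperature = temperature)
  curves
}
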
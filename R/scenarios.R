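# Scenario construction and the tabular generators that depend only on the
# scenario (fusion outcomes, diameters, depletion blots, secretion).

.popDefaults <- function(label, kHalf, weight) {
  shared <- list(hill = 5, maxFuseProb = 0.6, delayMean = 2, brightness = 300)
  kin <- switch(label,
    syt7 = list(poreRate = 0.4, collapseGain = 0.3, postRate = 1.0,
                diamMean = 175, diamSd = 40),
    syt9 = list(poreRate = 2.0, collapseGain = 0.8, postRate = 4.0,
                diamMean = 215, diamSd = 50),
    stop("unknown population label: ", label))
  do.call(new, c(list("PopulationParams", label = label, weight = weight,
                      kHalf = kHalf), shared, kin))
}

.scenarioTable <- list(
  untreated      = list(syt7 = 12, syt9 = 41),
  ffa            = list(syt7 = 12),
  cytokine       = list(syt9 = 41),
  cytokine_doc2b = list(syt7 = 12, syt9 = 41),
  syt7_only      = list(syt7 = 10),
  syt9_only      = list(syt9 = 48))

#' Scenario names known to the generators
#' @return Character vector of the six scenario names.
#' @export
scenarioNames <- function() names(.scenarioTable)

#' Build a scenario configuration
#'
#' Constructs the generative configuration for one of the six study
#' scenarios. Treatment scenarios (untreated, ffa, cytokine, cytokine_doc2b)
#' use the calcium half-activations fitted for whole dose-response curves
#' (12 and 41 uM); immunodepletion scenarios (syt7_only, syt9_only) use the
#' values fitted for depleted granules (10 and 48 uM). Two-population
#' scenarios mix syt7 and syt9 granules 50/50.
#'
#' @param name one of \code{scenarioNames()}
#' @param seed integer seed stored with the scenario
#' @param overrides named list of \linkS4class{PopulationParams} field
#'   overrides. A top-level field name (e.g. \code{kHalf}) applies to every
#'   population; a population label (\code{syt7}/\code{syt9}) may map to a
#'   nested list applying only to that population. Unknown names are an
#'   error.
#' @return A \linkS4class{ScenarioConfig}.
#' @examples
#' makeScenario("syt7_only")
#' makeScenario("ffa", overrides = list(kHalf = 20))
#' @export
makeScenario <- function(name, seed = 1L, overrides = list()) {
  if (!name %in% names(.scenarioTable))
    stop("unknown scenario name: '", name, "'; expected one of ",
         paste(names(.scenarioTable), collapse = ", "))
  ks <- .scenarioTable[[name]]
  w <- 1 / length(ks)
  pops <- lapply(names(ks), function(lab) .popDefaults(lab, ks[[lab]], w))
  names(pops) <- names(ks)
  popFields <- setdiff(slotNames("PopulationParams"), "label")
  for (nm in names(overrides)) {
    if (nm %in% popFields) {
      for (i in seq_along(pops)) slot(pops[[i]], nm) <- overrides[[nm]]
    } else if (nm %in% names(pops)) {
      sub <- overrides[[nm]]
      bad <- setdiff(names(sub), popFields)
      if (length(bad)) stop("unknown population field(s): ",
                            paste(bad, collapse = ", "))
      for (f in names(sub)) slot(pops[[nm]], f) <- sub[[f]]
    } else {
      stop("unknown override '", nm, "': not a population field or label")
    }
  }
  pops <- lapply(pops, function(p) { validObject(p); p })
  cfg <- new("ScenarioConfig", name = name, populations = unname(pops),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Expected fraction fused at a calcium concentration
#'
#' Closed-form mixture of the population Hill terms:
#' sum_j w_j maxP_j C^h_j / (C^h_j + K_j^h_j).
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param calcium concentration(s), uM
#' @return Expected fraction fused, same length as \code{calcium}.
#' @export
expectedFractionFused <- function(config, calcium) {
  stopifnot(is(config, "ScenarioConfig"), all(calcium >= 0))
  out <- 0
  for (p in config@populations)
    out <- out + p@weight * p@maxFuseProb *
      calcium^p@hill / (calcium^p@hill + p@kHalf^p@hill)
  out
}

#' Simulate fusion outcomes over a calcium ladder
#'
#' Each granule is assigned to a population by the scenario weights, then
#' fuses with probability maxFuseProb * C^h / (C^h + K^h). Fused granules
#' receive an exponential onset delay after calcium arrival.
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param calciumLevels calcium concentrations, uM (all > 0)
#' @param nGranules docked granules per level
#' @param seed integer seed
#' @return List with \code{outcomes} (calcium, nDocked, nFused) and
#'   \code{truth} (one row per granule: calcium, population, fused, onsetS).
#' @export
simulateFusionOutcomes <- function(config,
                                   calciumLevels = defaultCalciumLadder(),
                                   nGranules = 300, seed = config@seed) {
  stopifnot(is(config, "ScenarioConfig"))
  if (any(calciumLevels <= 0)) stop("calciumLevels must be > 0")
  if (nGranules < 1) stop("nGranules must be >= 1")
  withr::local_seed(seed)
  w <- vapply(config@populations, function(p) p@weight, numeric(1))
  truth <- do.call(rbind, lapply(calciumLevels, function(C) {
    popIdx <- sample.int(length(w), nGranules, replace = TRUE, prob = w)
    pFuse <- vapply(popIdx, function(i) {
      p <- config@populations[[i]]
      p@maxFuseProb * C^p@hill / (C^p@hill + p@kHalf^p@hill)
    }, numeric(1))
    fused <- runif(nGranules) < pFuse
    onset <- ifelse(fused,
      rexp(nGranules, rate = 1 / vapply(popIdx, function(i)
        config@populations[[i]]@delayMean, numeric(1))), NA_real_)
    data.frame(calcium = C,
      population = vapply(popIdx, function(i)
        config@populations[[i]]@label, character(1)),
      fused = fused, onsetS = onset)
  }))
  outcomes <- do.call(rbind, lapply(split(truth, truth$calcium), function(d)
    data.frame(calcium = d$calcium[1], nDocked = nrow(d),
               nFused = sum(d$fused))))
  outcomes <- outcomes[order(outcomes$calcium), ]
  rownames(outcomes) <- NULL
  list(outcomes = outcomes, truth = truth)
}

#' Sample granule diameters from a scenario
#'
#' Draws from the scenario's Gaussian mixture of population diameters,
#' truncated at zero (negative draws are resampled).
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param n number of diameters
#' @param seed integer seed
#' @return Numeric vector of diameters, nm.
#' @export
sampleDiameters <- function(config, n, seed = config@seed) {
  stopifnot(is(config, "ScenarioConfig"), n >= 1)
  withr::local_seed(seed)
  w <- vapply(config@populations, function(p) p@weight, numeric(1))
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  mu <- vapply(config@populations, function(p) p@diamMean, numeric(1))[idx]
  s <- vapply(config@populations, function(p) p@diamSd, numeric(1))[idx]
  d <- rnorm(n, mu, s)
  while (any(bad <- d <= 0)) d[bad] <- rnorm(sum(bad), mu[bad], s[bad])
  d
}

#' Closed-form mean and SD of a scenario's diameter mixture
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @return List with \code{mean} and \code{sd} of the (untruncated) mixture.
#' @export
diameterMixtureMoments <- function(config) {
  w <- vapply(config@populations, function(p) p@weight, numeric(1))
  mu <- vapply(config@populations, function(p) p@diamMean, numeric(1))
  s <- vapply(config@populations, function(p) p@diamSd, numeric(1))
  m <- sum(w * mu)
  v <- sum(w * (s^2 + mu^2)) - m^2
  list(mean = m, sd = sqrt(v))
}

#' Simulate an immunodepletion western blot
#'
#' For each protein, the supernatant after depleting one granule type
#' retains the signal carried by the other type:
#' dep7 = control * fractionSyt9, dep9 = control * fractionSyt7, plus
#' optional Gaussian noise (clamped at zero).
#'
#' @param trueFractionSyt7 named numeric vector: per-protein fraction of the
#'   total associated with syt7 granules (each in [0, 1]; the syt9 fraction
#'   is the complement)
#' @param control control band intensity (recycled per protein)
#' @param noiseSd Gaussian noise SD on band intensities
#' @param seed integer seed
#' @return data.frame with protein, control, dep7, dep9 and the true
#'   fractions.
#' @export
simulateDepletionBlot <- function(trueFractionSyt7, control = 10,
                                  noiseSd = 0, seed = 1L) {
  if (any(trueFractionSyt7 < 0 | trueFractionSyt7 > 1))
    stop("fractions must be in [0, 1]")
  withr::local_seed(seed)
  nP <- length(trueFractionSyt7)
  control <- rep_len(control, nP)
  f7 <- as.numeric(trueFractionSyt7)
  dep7 <- control * (1 - f7) + rnorm(nP, 0, noiseSd)
  dep9 <- control * f7 + rnorm(nP, 0, noiseSd)
  data.frame(protein = if (is.null(names(trueFractionSyt7)))
               paste0("protein", seq_len(nP)) else names(trueFractionSyt7),
             control = control, dep7 = pmax(dep7, 0), dep9 = pmax(dep9, 0),
             trueFractionSyt7 = f7, row.names = NULL)
}

#' Simulate a KCl-stimulated secretion measurement
#'
#' KCl depolarisation is mapped to an effective free-calcium surrogate
#' (25 mM -> 30 uM, 90 mM -> 100 uM); the secreted signal is proportional to
#' the scenario's expected fraction fused at that calcium plus a small
#' baseline leak, scaled by the scenario's releasable pool (single-population
#' scenarios retain half of the untreated pool), with log-normal replicate
#' noise. Lysate signal and protein
#' mass are included so the normalisation steps can be exercised.
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param stimulus KCl concentration, 25 or 90 mM (0 gives the unstimulated
#'   baseline leak)
#' @param nReps replicates
#' @param cv coefficient of variation of replicate noise
#' @param seed integer seed
#' @return data.frame with scenario, stimulus, secreted, lysate, protein.
#' @export
simulateSecretion <- function(config, stimulus, nReps = 3, cv = 0.1,
                              seed = config@seed) {
  stopifnot(is(config, "ScenarioConfig"))
  if (!stimulus %in% c(0, 25, 90))
    stop("stimulus must be 0, 25 or 90 mM KCl")
  withr::local_seed(seed + as.integer(stimulus))
  caEff <- if (stimulus == 0) 0 else .kclCalciumMap[[as.character(stimulus)]]
  leak <- 0.02
  scale <- 100
  # treatments/depletions remove a subpopulation: a single-population
  # scenario retains half of the untreated releasable pool
  poolFraction <- length(config@populations) / 2
  mu <- scale * poolFraction * (leak + expectedFractionFused(config, caEff))
  sdl <- sqrt(log(1 + cv^2))
  secreted <- mu * exp(rnorm(nReps, -sdl^2 / 2, sdl))
  lysate <- 1000 * exp(rnorm(nReps, -sdl^2 / 2, sdl))
  protein <- pmax(rnorm(nReps, 1, 0.05), 0.5)
  data.frame(scenario = config@name, stimulus = stimulus,
             rep = seq_len(nReps), secreted = secreted, lysate = lysate,
             protein = protein)
}
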
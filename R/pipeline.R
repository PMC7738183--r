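# Orchestration: run configuration validation and end-to-end scenario runs.

#' Default run configuration
#'
#' @param scenario scenario name
#' @param seed integer seed
#' @return Nested named list with every stage parameter documented in the
#'   methods vignette; serialises losslessly to YAML.
#' @export
defaultRunConfig <- function(scenario = "untreated", seed = 1L) {
  list(
    scenario = scenario,
    seed = as.integer(seed),
    stages = list(doseresponse = TRUE, sizing = TRUE, fcs = TRUE,
                  lipids = TRUE, depletion = TRUE, secretion = TRUE,
                  tirf = FALSE),
    doseresponse = list(calciumLevels = defaultCalciumLadder(),
                        nGranules = 300),
    sizing = list(nDiameters = 2000, mixtureK = 2),
    fcs = list(nRuns = 3, curvesPerRun = 20, noise = 0.01,
               omegaR = 2e-7, structure = 5, temperature = 295.15),
    lipids = list(nReps = 4, cv = 0.15),
    depletion = list(noiseSd = 0.3),
    tirf = list(nGranules = 24, shape = c(96, 96), nFrames = 160,
                calcium = 100, psfSigma = 1.2, background = 100))
}

.checkConfig <- function(cfg) {
  errs <- character()
  ref <- defaultRunConfig()
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  for (nm in intersect(names(cfg), names(ref))) {
    if (is.list(ref[[nm]]) && !is.null(cfg[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), names(ref[[nm]]))
      if (length(bad))
        errs <- c(errs, paste0("unknown key(s) under '", nm, "': ",
                               paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$scenario) && !cfg$scenario %in% scenarioNames())
    errs <- c(errs, paste0("unknown scenario '", cfg$scenario, "'"))
  num <- function(path, val, test, msg)
    if (!is.null(val) && !test(val)) paste0(path, " ", msg) else NULL
  errs <- c(errs,
    num("seed", cfg$seed, function(x) is.numeric(x) && x == round(x),
        "must be an integer"),
    num("doseresponse$nGranules", cfg$doseresponse$nGranules,
        function(x) is.numeric(x) && x >= 1, "must be >= 1"),
    num("doseresponse$calciumLevels", cfg$doseresponse$calciumLevels,
        function(x) is.numeric(x) && all(x > 0), "must be > 0"),
    num("sizing$nDiameters", cfg$sizing$nDiameters,
        function(x) is.numeric(x) && x >= 2, "must be >= 2"),
    num("fcs$noise", cfg$fcs$noise,
        function(x) is.numeric(x) && x >= 0, "must be >= 0"),
    num("lipids$cv", cfg$lipids$cv,
        function(x) is.numeric(x) && x > 0, "must be > 0"))
  errs
}

#' Validate and normalise a run configuration
#'
#' Reads a YAML file (or takes a list), reports all unknown keys, type
#' errors and constraint violations together, and fills unset fields from
#' \code{\link{defaultRunConfig}}.
#'
#' @param config path to a YAML file, or a named list
#' @return The normalised configuration list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  errs <- .checkConfig(config)
  if (length(errs))
    stop("invalid run configuration:\n  ", paste(errs, collapse = "\n  "))
  out <- modifyList(defaultRunConfig(
    scenario = if (is.null(config$scenario)) "untreated" else config$scenario,
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed)),
    config)
  out$seed <- as.integer(out$seed)
  out
}

.configHash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline for one scenario
#'
#' Simulates every enabled input with the scenario's generative defaults
#' and runs the corresponding analysis stage: dose-response assembly plus
#' mono/biphasic Hill decomposition; diameter sampling with mixture
#' analysis; FCS generation, fitting and hydrodynamic sizing; lipidomics
#' normalisation and volcano; depletion fractions; secretion
#' normalisations; optionally the TIRF image pipeline (stack simulation,
#' detection, trace extraction, release fitting, mode classification).
#'
#' @param config a configuration from \code{\link{validateRunConfig}} /
#'   \code{\link{defaultRunConfig}}, or a scenario name
#' @param outDir optional output directory; when given, stage tables are
#'   written as CSV and the report as JSON
#' @return A run report (list, class "gfRunReport"): per-stage summary
#'   metrics, package version and config hash. Identical config and seed
#'   give an identical report.
#' @export
runScenarioPipeline <- function(config = "untreated", outDir = NULL) {
  if (is.character(config)) config <- defaultRunConfig(scenario = config)
  config <- validateRunConfig(config)
  scen <- makeScenario(config$scenario, seed = config$seed)
  report <- list(scenario = config$scenario, seed = config$seed,
                 version = as.character(packageVersion("granuleFusion")),
                 configHash = .configHash(config))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(d, name) {
    if (!is.null(outDir))
      write.csv(d, file.path(outDir, paste0(name, ".csv")),
                row.names = FALSE)
  }
  if (isTRUE(config$stages$doseresponse)) {
    sim <- simulateFusionOutcomes(scen, config$doseresponse$calciumLevels,
                                  config$doseresponse$nGranules,
                                  seed = config$seed)
    curve <- assembleDoseResponse(sim$outcomes)
    sel <- selectDoseModel(fitDoseResponse(curve, 1),
                           fitDoseResponse(curve, 2))
    emit(sim$outcomes, "dose_response")
    report$doseresponse <- list(
      nComponents = sel$nComponents,
      kHalf = sel$chosen@kHalf, weights = sel$chosen@weights,
      fMax = sel$chosen@fMax, evidence = sel$evidence)
  }
  if (isTRUE(config$stages$sizing)) {
    d <- sampleDiameters(scen, config$sizing$nDiameters, seed = config$seed)
    sm <- summarizeDiameters(d)
    mix <- fitDiameterMixture(d, k = config$sizing$mixtureK,
                              seed = config$seed)
    emit(data.frame(diameter_nm = d), "diameters")
    report$sizing <- list(mean = sm$mean, sd = sm$sd, n = sm$n,
      mixtureMeans = mixtureMeans(mix), mixtureWeights = componentWeights(mix),
      separable = isSeparable(mix))
  }
  if (isTRUE(config$stages$fcs)) {
    mom <- diameterMixtureMoments(scen)
    rhTrue <- mom$mean / 2 * 1e-9
    runs <- lapply(seq_len(config$fcs$nRuns), function(i)
      simulateFcs(rh = rhTrue,
                  temperature = config$fcs$temperature + (i - 2),
                  omegaR = config$fcs$omegaR,
                  structure = config$fcs$structure,
                  noise = config$fcs$noise,
                  nRuns = config$fcs$curvesPerRun,
                  seed = config$seed + i))
    siz <- fcsSizing(runs, calibration = list(omegaR = config$fcs$omegaR,
                                              structure = config$fcs$structure))
    report$fcs <- list(diameterNm = diameterNm(siz$rh),
                       rhNm = meanRh(siz$rh) * 1e9,
                       sdNm = siz$rh@sdRh * 1e9, models = siz$models)
  }
  if (isTRUE(config$stages$lipids)) {
    se <- normalizeLipids(simulateLipidTable(nReps = config$lipids$nReps,
                                             cv = config$lipids$cv,
                                             seed = config$seed))
    volc <- lipidVolcano(se)
    emit(volc, "lipid_volcano")
    report$lipids <- list(
      nSignificant = sum(volc$significant),
      significantSpecies = volc$species[volc$significant],
      sm421Fold = 2^(-volc$log2Ratio[volc$species == "SM 42:1"]))
  }
  if (isTRUE(config$stages$depletion)) {
    blot <- simulateDepletionBlot(
      c(syt7 = 0.8, VAMP4 = 0.7, syt9 = 0.15, PC2 = 0.4),
      noiseSd = config$depletion$noiseSd, seed = config$seed)
    fr <- depletionFractions(blot$control, blot$dep7, blot$dep9,
                             protein = blot$protein)
    emit(fr, "depletion_fractions")
    report$depletion <- fr[c("protein", "fractionSyt7", "fractionSyt9")]
  }
  if (isTRUE(config$stages$secretion)) {
    meas <- rbind(simulateSecretion(scen, 25, seed = config$seed),
                  simulateSecretion(scen, 90, seed = config$seed))
    ref <- rbind(
      simulateSecretion(makeScenario("untreated", seed = config$seed), 25,
                        seed = config$seed),
      simulateSecretion(makeScenario("untreated", seed = config$seed), 90,
                        seed = config$seed))
    all <- if (config$scenario == "untreated") meas else rbind(meas, ref)
    rel <- relativeSecretion(all)
    emit(rel, "secretion")
    agg <- tapply(rel$relative[rel$scenario == config$scenario],
                  rel$stimulus[rel$scenario == config$scenario], mean)
    report$secretion <- list(relative25 = unname(agg[["25"]]),
                             relative90 = unname(agg[["90"]]))
  }
  if (isTRUE(config$stages$tirf)) {
    tp <- config$tirf
    sim <- simulateStack(scen, calcium = tp$calcium, shape = tp$shape,
                         nGranules = tp$nGranules, psfSigma = tp$psfSigma,
                         background = tp$background, nFrames = tp$nFrames,
                         seed = config$seed)
    filt <- preprocessStack(sim$stack, 5)
    det <- detectGranules(filt)
    traces <- extractTraces(sim$stack, det,
                            frameInterval = sim$frameInterval)
    events <- do.call(rbind, lapply(traces, function(tr) {
      seg <- segmentEvent(tr)
      if (is.null(seg)) NULL else fitRelease(tr, seg)
    }))
    if (!is.null(events) && nrow(events) >= 20)
      events <- classifyModes(events)$events
    emit(events, "tirf_events")
    report$tirf <- list(nDetected = nrow(detectedCenters(det)),
                        nEvents = if (is.null(events)) 0L else nrow(events),
                        modes = if (!is.null(events)) table(events$mode))
  }
  if (!is.null(outDir)) {
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(report) <- "gfRunReport"
  report
}

#' @export
print.gfRunReport <- function(x, ...) {
  cat("granuleFusion run report -- scenario '", x$scenario, "' (seed ",
      x$seed, ", v", x$version, ")\n", sep = "")
  if (!is.null(x$doseresponse))
    cat(sprintf("  dose-response: %d component(s), K_1/2 = %s uM\n",
                x$doseresponse$nComponents,
                paste(sprintf("%.1f", x$doseresponse$kHalf), collapse = "/")))
  if (!is.null(x$sizing))
    cat(sprintf("  sizing: %.0f +/- %.0f nm (n=%d)\n", x$sizing$mean,
                x$sizing$sd, x$sizing$n))
  if (!is.null(x$fcs))
    cat(sprintf("  FCS: hydrodynamic diameter %.0f nm\n", x$fcs$diameterNm))
  if (!is.null(x$lipids))
    cat(sprintf("  lipids: %d significant species (%s)\n",
                x$lipids$nSignificant,
                paste(x$lipids$significantSpecies, collapse = ", ")))
  if (!is.null(x$secretion))
    cat(sprintf("  secretion: rel. 25 mM %.2f, 90 mM %.2f\n",
                x$secretion$relative25, x$secretion$relative90))
  invisible(x)
}
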
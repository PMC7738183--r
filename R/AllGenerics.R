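#' @name accessors
#' @title Accessors for granuleFusion S4 classes
#' @param object an S4 object from this package
#' @description Small accessor generics; slot access in user code is
#'   discouraged.
NULL

#' @rdname accessors
#' @export
setGeneric("scenarioName", function(object) standardGeneric("scenarioName"))
#' @rdname accessors
#' @export
setMethod("scenarioName", "ScenarioConfig", function(object) object@name)

#' @rdname accessors
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))
#' @rdname accessors
#' @export
setMethod("populations", "ScenarioConfig", function(object) {
  setNames(object@populations,
           vapply(object@populations, function(p) p@label, character(1)))
})

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "IntensityTrace", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "IntensityTrace",
          function(object) object@frameInterval)

#' @rdname accessors
#' @export
setGeneric("detectedCenters", function(object) standardGeneric("detectedCenters"))
#' @rdname accessors
#' @export
setMethod("detectedCenters", "DetectionResult", function(object) object@centers)

#' @rdname accessors
#' @export
setGeneric("fractionFused", function(object) standardGeneric("fractionFused"))
#' @rdname accessors
#' @export
setMethod("fractionFused", "DoseResponseCurve", function(object) {
  data.frame(calcium = object@calcium, nDocked = object@nDocked,
             nFused = object@nFused, fraction = object@fraction,
             ciLow = object@ciLow, ciHigh = object@ciHigh)
})

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setMethod("nComponents", "HillFit", function(object) object@nComponents)

#' @rdname accessors
#' @export
setGeneric("kHalf", function(object) standardGeneric("kHalf"))
#' @rdname accessors
#' @export
setMethod("kHalf", "HillFit", function(object) object@kHalf)
#' @rdname accessors
#' @export
setMethod("kHalf", "PopulationParams", function(object) object@kHalf)

#' @rdname accessors
#' @export
setGeneric("componentWeights", function(object) standardGeneric("componentWeights"))
#' @rdname accessors
#' @export
setMethod("componentWeights", "HillFit", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("componentWeights", "DiameterMixtureFit",
          function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("hillCoefficients", function(object) standardGeneric("hillCoefficients"))
#' @rdname accessors
#' @export
setMethod("hillCoefficients", "HillFit", function(object) object@hill)

#' @rdname accessors
#' @export
setGeneric("aicc", function(object) standardGeneric("aicc"))
#' @rdname accessors
#' @export
setMethod("aicc", "HillFit", function(object) object@aicc)
#' @rdname accessors
#' @export
setMethod("aicc", "FcsFit", function(object) object@aicc)

#' @rdname accessors
#' @export
setGeneric("tauD", function(object) standardGeneric("tauD"))
#' @rdname accessors
#' @export
setMethod("tauD", "FcsFit", function(object) object@tauD)

#' @rdname accessors
#' @export
setGeneric("diffusionCoefficient",
           function(object) standardGeneric("diffusionCoefficient"))
#' @rdname accessors
#' @export
setMethod("diffusionCoefficient", "FcsFit", function(object) object@D)

#' @rdname accessors
#' @export
setGeneric("mixtureMeans", function(object) standardGeneric("mixtureMeans"))
#' @rdname accessors
#' @export
setMethod("mixtureMeans", "DiameterMixtureFit", function(object) object@means)

#' @rdname accessors
#' @export
setGeneric("mixtureSds", function(object) standardGeneric("mixtureSds"))
#' @rdname accessors
#' @export
setMethod("mixtureSds", "DiameterMixtureFit", function(object) object@sds)

#' @rdname accessors
#' @export
setGeneric("isSeparable", function(object) standardGeneric("isSeparable"))
#' @rdname accessors
#' @export
setMethod("isSeparable", "DiameterMixtureFit",
          function(object) object@separable)

#' @rdname accessors
#' @export
setGeneric("meanRh", function(object) standardGeneric("meanRh"))
#' @rdname accessors
#' @export
setMethod("meanRh", "RhResult", function(object) object@meanRh)

#' @rdname accessors
#' @export
setGeneric("perRunRh", function(object) standardGeneric("perRunRh"))
#' @rdname accessors
#' @export
setMethod("perRunRh", "RhResult", function(object) object@perRunRh)

#' @rdname accessors
#' @export
setGeneric("diameterNm", function(object) standardGeneric("diameterNm"))
#' @rdname accessors
#' @export
setMethod("diameterNm", "RhResult",
          function(object) 2 * object@meanRh * 1e9)

#' @rdname accessors
#' @export
setGeneric("fcsTau", function(object) standardGeneric("fcsTau"))
#' @rdname accessors
#' @export
setMethod("fcsTau", "FcsCurve", function(object) object@tau)

#' @rdname accessors
#' @export
setGeneric("fcsG", function(object) standardGeneric("fcsG"))
#' @rdname accessors
#' @export
setMethod("fcsG", "FcsCurve", function(object) object@g)

#' @rdname accessors
#' @export
setGeneric("runTemperature", function(object) standardGeneric("runTemperature"))
#' @rdname accessors
#' @export
setMethod("runTemperature", "FcsCurve", function(object) object@temperature)

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig '", object@name, "' (seed ", object@seed, ")\n",
      sep = "")
  for (p in object@populations)
    cat(sprintf("  %s: w=%.2f K_1/2=%g uM h=%g maxP=%.2f diam=%g+/-%g nm\n",
                p@label, p@weight, p@kHalf, p@hill, p@maxFuseProb,
                p@diamMean, p@diamSd))
})

setMethod("show", "DoseResponseCurve", function(object) {
  cat("DoseResponseCurve with", length(object@calcium), "calcium levels\n")
  print(fractionFused(object), row.names = FALSE, digits = 3)
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: %d component(s), fMax=%.3f, AICc=%.1f%s\n",
              object@nComponents, object@fMax, object@aicc,
              if (object@converged) "" else " (not converged)"))
  for (j in seq_len(object@nComponents))
    cat(sprintf("  component %d: w=%.2f K_1/2=%.1f uM h=%.2f\n",
                j, object@weights[j], object@kHalf[j], object@hill[j]))
})

setMethod("show", "FcsFit", function(object) {
  cat(sprintf(
    "FcsFit (%s): N=%.3g tauD=%.3g s D=%.3g m^2/s Tb=%.2f taub=%.2g s",
    object@model, sum(object@occupancy), max(object@tauD), object@D,
    object@tB, object@tauB))
  if (object@model == "blink_triplet")
    cat(sprintf(" Tt=%.2f taut=%.2g s", object@tT, object@tauT))
  cat("\n")
})

setMethod("show", "FcsCurve", function(object) {
  cat(sprintf("FcsCurve: %d lags %.2g..%.2g s, T=%.2f K\n",
              length(object@tau), min(object@tau), max(object@tau),
              object@temperature))
})

setMethod("show", "DiameterMixtureFit", function(object) {
  cat(sprintf("DiameterMixtureFit: k=%d, logLik=%.1f%s\n", object@k,
              object@logLik,
              if (object@separable) "" else " (components not separable)"))
  for (j in seq_len(object@k))
    cat(sprintf("  component %d: mean=%.1f sd=%.1f weight=%.2f\n",
                j, object@means[j], object@sds[j], object@weights[j]))
})

setMethod("show", "RhResult", function(object) {
  cat(sprintf("RhResult: R_h = %.1f +/- %.1f nm over %d runs (diameter %.0f nm)\n",
              object@meanRh * 1e9, object@sdRh * 1e9,
              length(object@perRunRh), 2 * object@meanRh * 1e9))
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d spots (threshold %.1f, minSep %g px)\n",
              nrow(object@centers), object@threshold, object@minSep))
})
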
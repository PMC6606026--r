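#' @name accessors
#' @title Accessors for cohesinCensus S4 classes
#' @description Getter functions for the slots of [AcfRecord-class],
#'   [AcfFit-class], [FrapCurve-class], [FrapFit-class],
#'   [PopulationFractions-class], [EquilibriumParams-class] and
#'   [EquilibriumState-class]. Slots should be read through these, not `@`.
#' @param object an object of the documented class.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setMethod("nParticles", "AcfFit", function(object) object@nParticles)

#' @rdname accessors
#' @export
setGeneric("acfLags", function(object) standardGeneric("acfLags"))
#' @rdname accessors
#' @export
setMethod("acfLags", "AcfRecord", function(object) object@lags)

#' @rdname accessors
#' @export
setGeneric("acfValues", function(object) standardGeneric("acfValues"))
#' @rdname accessors
#' @export
setMethod("acfValues", "AcfRecord", function(object) object@acf)

#' @rdname accessors
#' @export
setGeneric("meanIntensity", function(object) standardGeneric("meanIntensity"))
#' @rdname accessors
#' @export
setMethod("meanIntensity", "AcfRecord", function(object) object@meanIntensity)

#' @rdname accessors
#' @export
setGeneric("cpm", function(object) standardGeneric("cpm"))
#' @rdname accessors
#' @export
setMethod("cpm", "AcfFit", function(object) object@cpm)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "AcfFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("isConverged", "FrapFit", function(object) object@converged)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "AcfFit", function(object) object@rSquared)

#' @rdname accessors
#' @export
setGeneric("chisqPerPoint", function(object) standardGeneric("chisqPerPoint"))
#' @rdname accessors
#' @export
setMethod("chisqPerPoint", "AcfFit", function(object) object@chisqPerPoint)

#' @rdname accessors
#' @export
setGeneric("effectiveVolume", function(object) standardGeneric("effectiveVolume"))
#' @rdname accessors
#' @export
setMethod("effectiveVolume", "ConfocalCalibration",
          function(object) object@effectiveVolume)

#' @rdname accessors
#' @export
setGeneric("kOff1", function(object) standardGeneric("kOff1"))
#' @rdname accessors
#' @export
setMethod("kOff1", "FrapFit", function(object) object@kOff1)

#' @rdname accessors
#' @export
setGeneric("kOff2", function(object) standardGeneric("kOff2"))
#' @rdname accessors
#' @export
setMethod("kOff2", "FrapFit", function(object) object@kOff2)

#' @rdname accessors
#' @export
setGeneric("fastAmplitude", function(object) standardGeneric("fastAmplitude"))
#' @rdname accessors
#' @export
setMethod("fastAmplitude", "FrapFit", function(object) object@a)

#' @rdname accessors
#' @export
setGeneric("residenceDynamic", function(object) standardGeneric("residenceDynamic"))
#' @rdname accessors
#' @export
setMethod("residenceDynamic", "FrapFit", function(object) object@residenceDynamic)

#' @rdname accessors
#' @export
setGeneric("residenceStable", function(object) standardGeneric("residenceStable"))
#' @rdname accessors
#' @export
setMethod("residenceStable", "FrapFit", function(object) object@residenceStable)

#' @rdname accessors
#' @export
setGeneric("modelType", function(object) standardGeneric("modelType"))
#' @rdname accessors
#' @export
setMethod("modelType", "FrapFit", function(object) object@model)

#' @rdname accessors
#' @export
setGeneric("solubleFrac", function(object) standardGeneric("solubleFrac"))
#' @rdname accessors
#' @export
setMethod("solubleFrac", "PopulationFractions", function(object) object@soluble)

#' @rdname accessors
#' @export
setGeneric("dynamicFrac", function(object) standardGeneric("dynamicFrac"))
#' @rdname accessors
#' @export
setMethod("dynamicFrac", "PopulationFractions", function(object) object@dynamic)

#' @rdname accessors
#' @export
setGeneric("stableFrac", function(object) standardGeneric("stableFrac"))
#' @rdname accessors
#' @export
setMethod("stableFrac", "PopulationFractions", function(object) object@stable)

#' @rdname accessors
#' @export
setGeneric("boundIntercept", function(object) standardGeneric("boundIntercept"))
#' @rdname accessors
#' @export
setMethod("boundIntercept", "EquilibriumParams", function(object) object@intercept)

#' @rdname accessors
#' @export
setGeneric("boundSlope", function(object) standardGeneric("boundSlope"))
#' @rdname accessors
#' @export
setMethod("boundSlope", "EquilibriumParams", function(object) object@slope)

#' @rdname accessors
#' @export
setGeneric("rateOn", function(object) standardGeneric("rateOn"))
#' @rdname accessors
#' @export
setMethod("rateOn", "EquilibriumParams", function(object) object@kOn)

#' @rdname accessors
#' @export
setGeneric("rateOff", function(object) standardGeneric("rateOff"))
#' @rdname accessors
#' @export
setMethod("rateOff", "EquilibriumParams", function(object) object@kOff)

#' @rdname accessors
#' @export
setGeneric("copiesTotal", function(object) standardGeneric("copiesTotal"))
#' @rdname accessors
#' @export
setMethod("copiesTotal", "EquilibriumState", function(object) object@cT)

#' @rdname accessors
#' @export
setGeneric("copiesUnbound", function(object) standardGeneric("copiesUnbound"))
#' @rdname accessors
#' @export
setMethod("copiesUnbound", "EquilibriumState", function(object) object@U)

#' @rdname accessors
#' @export
setGeneric("copiesDynamic", function(object) standardGeneric("copiesDynamic"))
#' @rdname accessors
#' @export
setMethod("copiesDynamic", "EquilibriumState", function(object) object@D)

#' @rdname accessors
#' @export
setGeneric("copiesStable", function(object) standardGeneric("copiesStable"))
#' @rdname accessors
#' @export
setMethod("copiesStable", "EquilibriumState", function(object) object@S)

#' @rdname accessors
#' @export
setGeneric("boundFrac", function(object) standardGeneric("boundFrac"))
#' @rdname accessors
#' @export
setMethod("boundFrac", "EquilibriumState", function(object) object@bT)

setMethod("show", "AcfRecord", function(object) {
  cat("AcfRecord:", object@cellId, sprintf("(%s, %s)\n",
      object@condition, object@compartment))
  cat(sprintf("  %d lags in [%.4g, %.4g] ms; G(min lag) = %.4g\n",
      length(object@lags), min(object@lags), max(object@lags),
      object@acf[1]))
  if (!is.na(object@meanIntensity))
    cat(sprintf("  mean intensity %.3g kHz over %.3g s\n",
        object@meanIntensity, object@duration))
})

setMethod("show", "AcfFit", function(object) {
  if (!object@converged) {
    cat("AcfFit: NOT CONVERGED\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "AcfFit: N = %.4g, tau1 = %.4g ms, tau2 = %.4g ms, frac1 = %.3f\n",
    object@nParticles, object@tau1, object@tau2, object@frac1))
  cat(sprintf("  kappa = %.3g, offset = %.3g, R2 = %.4f, chi2/N = %.4g",
      object@structureParam, object@offset, object@rSquared,
      object@chisqPerPoint))
  if (!is.na(object@cpm)) cat(sprintf(", CPM = %.3g kHz", object@cpm))
  cat("\n")
})

setMethod("show", "FrapCurve", function(object) {
  cat("FrapCurve:", object@cellId, sprintf("(%s), %d frames over %.3g min\n",
      object@condition, length(object@times), max(object@times)))
})

setMethod("show", "FrapFit", function(object) {
  if (!object@converged) {
    cat("FrapFit: NOT CONVERGED\n")
    return(invisible(NULL))
  }
  if (object@model == "single") {
    cat(sprintf("FrapFit (single): kOff1 = %.4g/min, residence %.3g min\n",
        object@kOff1, object@residenceDynamic))
  } else {
    cat(sprintf(
      "FrapFit (double): a = %.3f, kOff1 = %.4g/min (%.3g min), kOff2 = %.4g/min (%.3g hr)%s\n",
      object@a, object@kOff1, object@residenceDynamic, object@kOff2,
      object@residenceStable, if (object@boundary) " [boundary]" else ""))
  }
  cat(sprintf("  RSS = %.4g, AICc = %.4g over %d points\n", object@rss,
      object@aicc, object@nPoints))
})

setMethod("show", "PopulationFractions", function(object) {
  cat(sprintf(
    "PopulationFractions: soluble %.3f, dynamic %.3f, stable %.3f\n",
    object@soluble, object@dynamic, object@stable))
})

setMethod("show", "EquilibriumParams", function(object) {
  cat(sprintf("EquilibriumParams: bT(s) = %.3f + %.3f s", object@intercept,
      object@slope))
  if (!is.na(object@kOff))
    cat(sprintf("  (kOn = %.4g, kOff = %.4g per min)", object@kOn,
        object@kOff))
  cat("\n")
})

setMethod("show", "EquilibriumState", function(object) {
  cat(sprintf(
    "EquilibriumState: cT = %.6g; U = %.6g (%.3f), D = %.6g (%.3f), S = %.6g (%.3f); bT = %.3f\n",
    object@cT, object@U, object@u, object@D, object@d, object@S, object@s,
    object@bT))
})
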
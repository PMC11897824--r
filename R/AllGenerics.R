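#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; slot access in user
#' code should go through these.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))
#' @rdname accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))
#' @rdname accessors
#' @export
setGeneric("specMeta", function(x) standardGeneric("specMeta"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("sto2", function(x) standardGeneric("sto2"))
#' @rdname accessors
#' @export
setGeneric("qualityFlags", function(x) standardGeneric("qualityFlags"))
#' @rdname accessors
#' @export
setGeneric("rbfi", function(x) standardGeneric("rbfi"))
#' @rdname accessors
#' @export
setGeneric("epsHbO2", function(x) standardGeneric("epsHbO2"))
#' @rdname accessors
#' @export
setGeneric("epsHb", function(x) standardGeneric("epsHb"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)
#' @rdname accessors
#' @export
setMethod("wavelengths", "ExtinctionTable", function(x) x@wavelength)
#' @rdname accessors
#' @export
setMethod("specValues", "Spectrum", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("spectrumKind", "Spectrum", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("specMeta", "Spectrum", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("sampleTimes", "StO2Series", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("sampleTimes", "RBFiSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("sto2", "StO2Series", function(x) x@sto2)
#' @rdname accessors
#' @export
setMethod("sto2", "HbFit", function(x) x@sto2)
#' @rdname accessors
#' @export
setMethod("sto2", "PumpStepdownResult", function(x) x@sto2)
#' @rdname accessors
#' @export
setMethod("qualityFlags", "StO2Series", function(x) x@flags)
#' @rdname accessors
#' @export
setMethod("rbfi", "RBFiSeries", function(x) x@rbfi)
#' @rdname accessors
#' @export
setMethod("epsHbO2", "ExtinctionTable", function(x) x@epsHbO2)
#' @rdname accessors
#' @export
setMethod("epsHb", "ExtinctionTable", function(x) x@epsHb)

#' @rdname accessors
#' @export
setGeneric("fittedAmplitudes", function(x) standardGeneric("fittedAmplitudes"))
#' @rdname accessors
#' @export
setMethod("fittedAmplitudes", "HbFit",
          function(x) c(aHbO2 = x@aHbO2, aHb = x@aHb))
#' @rdname accessors
#' @export
setGeneric("backgroundCoefs", function(x) standardGeneric("backgroundCoefs"))
#' @rdname accessors
#' @export
setMethod("backgroundCoefs", "HbFit", function(x) x@background)
#' @rdname accessors
#' @export
setGeneric("flowLevels", function(x) standardGeneric("flowLevels"))
#' @rdname accessors
#' @export
setMethod("flowLevels", "PumpStepdownResult", function(x) x@flows)
#' @rdname accessors
#' @export
setGeneric("largestDropInterval",
           function(x) standardGeneric("largestDropInterval"))
#' @rdname accessors
#' @export
setMethod("largestDropInterval", "PumpStepdownResult",
          function(x) x@largestDropInterval)
#' @rdname accessors
#' @export
setGeneric("plateauOnset", function(x) standardGeneric("plateauOnset"))
#' @rdname accessors
#' @export
setMethod("plateauOnset", "PumpStepdownResult", function(x) x@plateauOnset)
#' @rdname accessors
#' @export
setGeneric("eventKind", function(x) standardGeneric("eventKind"))
#' @rdname accessors
#' @export
setMethod("eventKind", "EventWindow", function(x) x@kind)
#' @rdname accessors
#' @export
setGeneric("eventBounds", function(x) standardGeneric("eventBounds"))
#' @rdname accessors
#' @export
setMethod("eventBounds", "EventWindow",
          function(x) c(start = x@start, end = x@end))
#' @rdname accessors
#' @export
setGeneric("trueSto2", function(x) standardGeneric("trueSto2"))
#' @rdname accessors
#' @export
setMethod("trueSto2", "ScenarioTruth", function(x) x@trueSto2)
#' @rdname accessors
#' @export
setGeneric("scenarioSpectra", function(x) standardGeneric("scenarioSpectra"))
#' @rdname accessors
#' @export
setMethod("scenarioSpectra", "ScenarioTruth", function(x) x@spectra)
#' @rdname accessors
#' @export
setGeneric("referenceSpectrum",
           function(x) standardGeneric("referenceSpectrum"))
#' @rdname accessors
#' @export
setMethod("referenceSpectrum", "ScenarioTruth", function(x) x@reference)
#' @rdname accessors
#' @export
setGeneric("scenarioConfig", function(x) standardGeneric("scenarioConfig"))
#' @rdname accessors
#' @export
setMethod("scenarioConfig", "ScenarioTruth", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("rbfi", "ScenarioTruth", function(x) x@rbfi)
#' @rdname accessors
#' @export
setMethod("sampleTimes", "ScenarioTruth", function(x) x@times)
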
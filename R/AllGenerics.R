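## Accessors and show methods.

#' @describeIn EcgRecord-class sample vector in mV.
#' @param object an object of the documented class.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @describeIn EcgRecord-class sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @describeIn EcgRecord-class record duration in seconds.
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @describeIn EcgRecord-class annotation interval table.
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' @describeIn EcgSegment-class two-level quality label.
#' @export
setGeneric("qualityLabel", function(object) standardGeneric("qualityLabel"))

#' @describeIn EcgSegment-class rhythm label of a clean window.
#' @export
setGeneric("rhythmLabel", function(object) standardGeneric("rhythmLabel"))

#' @export
setMethod("samples", "EcgRecord", function(object) object@samples)
#' @export
setMethod("samples", "EcgSegment", function(object) object@samples)
#' @export
setMethod("samplingRate", "EcgRecord", function(object) object@fs)
#' @export
setMethod("samplingRate", "EcgSegment", function(object) object@fs)
#' @export
setMethod("duration", "EcgRecord",
          function(object) length(object@samples) / object@fs)
#' @export
setMethod("duration", "EcgSegment",
          function(object) length(object@samples) / object@fs)
#' @export
setMethod("annotations", "EcgRecord", function(object) object@annotations)
#' @export
setMethod("qualityLabel", "EcgSegment", function(object) object@qualityLabel)
#' @export
setMethod("rhythmLabel", "EcgSegment", function(object) object@rhythmLabel)

setMethod("show", "EcgRecord", function(object) {
  cat(sprintf("EcgRecord '%s': %.1f s at %g Hz (%s), %d annotation(s)\n",
              object@recordId, duration(object), object@fs, object@sourceDb,
              nrow(object@annotations)))
})

setMethod("show", "EcgSegment", function(object) {
  cat(sprintf("EcgSegment %s[%d]: %.1f s at %g Hz, %s/%s\n",
              object@recordId, object@index, duration(object), object@fs,
              object@qualityLabel, object@rhythmLabel))
})

setMethod("show", "CwtMatrix", function(object) {
  f <- range(object@pseudoFrequencies)
  cat(sprintf("CwtMatrix: %d scales x %d samples, %.2f-%.1f Hz\n",
              nrow(object@coefficients), ncol(object@coefficients),
              f[1], f[2]))
})

setMethod("show", "ScalogramImage", function(object) {
  cat(sprintf("ScalogramImage: %dx%dx%d (%s), source magnitude %dx%d\n",
              dim(object@rgb)[1], dim(object@rgb)[2], dim(object@rgb)[3],
              object@colormap, nrow(object@magnitude), ncol(object@magnitude)))
})

setMethod("show", "SqiVector", function(object) {
  cat(sprintf("SqiVector: bSQI=%.3f pSQI=%.3f kSQI=%.3f basSQI=%.3f\n",
              object@bsqi, object@psqi, object@ksqi, object@bassqi))
})

setMethod("show", "QualityModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("QualityModel: AlexNet architecture, %d layer entries, %s parameters\n",
              length(object@spec), format(np, big.mark = ",")))
})

setMethod("show", "SqiSvmModel", function(object) {
  cat(sprintf("SqiSvmModel: %s kernel SVM, C=%g, gamma=%g\n",
              object@config$kernel, object@config$C, object@config$gamma))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d learning-testing runs\n",
              nrow(object@perRun)))
  print(round(object@aggregates, 2))
})

#' @describeIn ValidationReport-class per-run metric table.
#' @param object a `ValidationReport`.
#' @export
setGeneric("perRunMetrics", function(object) standardGeneric("perRunMetrics"))
#' @export
setMethod("perRunMetrics", "ValidationReport", function(object) object@perRun)

#' @describeIn ValidationReport-class mean/std/max/min aggregate table.
#' @export
setGeneric("aggregates", function(object) standardGeneric("aggregates"))
#' @export
setMethod("aggregates", "ValidationReport", function(object) object@aggregates)

#' @describeIn SqiVector-class the four indices as a named numeric vector.
#' @export
setGeneric("asFeatureVector", function(object) standardGeneric("asFeatureVector"))
#' @export
setMethod("asFeatureVector", "SqiVector", function(object) {
  c(bsqi = object@bsqi, psqi = object@psqi,
    ksqi = object@ksqi, bassqi = object@bassqi)
})
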
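## Central S4 containers. Enumerated labels are kept as plain character
## vectors validated against the constants below, mirroring how the
## annotation vocabularies are fixed in the source databases.

#' @rdname EcgRecord-class
#' @export
RHYTHMS <- c("NSR", "AF", "OR", "NONE")

#' @rdname EcgRecord-class
#' @export
QUALITIES <- c("CLEAN", "NOISY")

#' @rdname EcgRecord-class
#' @export
SOURCE_DBS <- c("PC2017", "THDB", "PDB", "SYNTH", "OTHER")

## quality labels carried by segments (record annotations use CLEAN/NOISY)
#' @rdname EcgSegment-class
#' @export
SEGMENT_QUALITIES <- c("HIGH", "LOW")

emptyAnnotations <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             rhythm = character(0), quality = character(0),
             stringsAsFactors = FALSE)
}

#' Single-lead ECG recording
#'
#' An `EcgRecord` holds one raw single-lead recording: the sample vector in
#' millivolt, its sampling rate, the database it came from, and a table of
#' expert annotation intervals (`start_s`, `end_s`, `rhythm`, `quality`).
#' A whole-record annotation is represented as one interval spanning the
#' full duration.  The `meta` list carries generator provenance such as
#' ground-truth R-peak times for synthetic records.
#'
#' @slot recordId opaque record identifier.
#' @slot samples numeric vector of samples (mV).
#' @slot fs sampling rate in Hz.
#' @slot sourceDb one of `SOURCE_DBS`.
#' @slot annotations data.frame of annotation intervals.
#' @slot meta free-form provenance list.
#' @aliases RHYTHMS QUALITIES SOURCE_DBS
#' @export
setClass("EcgRecord",
  representation(recordId = "character", samples = "numeric", fs = "numeric",
                 sourceDb = "character", annotations = "data.frame",
                 meta = "list"),
  prototype(recordId = "rec", samples = numeric(0), fs = 1,
            sourceDb = "OTHER", annotations = emptyAnnotations(),
            meta = list()))

setValidity("EcgRecord", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) < 1)
    msg <- c(msg, "samples must contain at least one value")
  if (!object@sourceDb %in% SOURCE_DBS)
    msg <- c(msg, sprintf("sourceDb must be one of %s",
                          paste(SOURCE_DBS, collapse = ", ")))
  ann <- object@annotations
  req <- c("start_s", "end_s", "rhythm", "quality")
  if (!all(req %in% names(ann))) {
    msg <- c(msg, "annotations must have columns start_s, end_s, rhythm, quality")
  } else if (nrow(ann) > 0) {
    dur <- length(object@samples) / object@fs
    if (any(ann$start_s >= ann$end_s))
      msg <- c(msg, "annotation intervals must have start_s < end_s")
    if (any(ann$start_s < -1e-9) || any(ann$end_s > dur + 1e-9))
      msg <- c(msg, "annotation intervals must lie within [0, duration]")
    if (!all(ann$rhythm %in% RHYTHMS))
      msg <- c(msg, "annotation rhythms must be NSR/AF/OR/NONE")
    if (!all(ann$quality %in% QUALITIES))
      msg <- c(msg, "annotation qualities must be CLEAN/NOISY")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled 5-s ECG segment
#'
#' A fixed-duration window cut from an [EcgRecord-class], carrying the
#' two-level quality label (`HIGH`/`LOW`) and, for clean windows, the rhythm
#' during the window (`NSR`/`AF`/`OR`; `NONE` for noisy windows).
#'
#' @slot recordId id of the parent record.
#' @slot index 0-based window index within the record.
#' @slot samples numeric vector of exactly `round(window * fs)` samples.
#' @slot fs sampling rate in Hz.
#' @slot qualityLabel `"HIGH"` or `"LOW"`.
#' @slot rhythmLabel `"NSR"`, `"AF"`, `"OR"` or `"NONE"`.
#' @aliases SEGMENT_QUALITIES
#' @export
setClass("EcgSegment",
  representation(recordId = "character", index = "integer",
                 samples = "numeric", fs = "numeric",
                 qualityLabel = "character", rhythmLabel = "character"),
  prototype(recordId = "rec", index = 0L, samples = numeric(0), fs = 1,
            qualityLabel = "HIGH", rhythmLabel = "NSR"))

setValidity("EcgSegment", function(object) {
  msg <- character(0)
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (!object@qualityLabel %in% SEGMENT_QUALITIES)
    msg <- c(msg, "qualityLabel must be HIGH or LOW")
  if (!object@rhythmLabel %in% RHYTHMS)
    msg <- c(msg, "rhythmLabel must be NSR/AF/OR/NONE")
  highRhythm <- object@rhythmLabel %in% c("NSR", "AF", "OR")
  if (object@qualityLabel == "HIGH" && !highRhythm)
    msg <- c(msg, "HIGH segments must carry a clean rhythm label")
  if (object@qualityLabel == "LOW" && object@rhythmLabel != "NONE")
    msg <- c(msg, "LOW segments must carry rhythm NONE")
  if (length(msg)) msg else TRUE
})

#' Continuous wavelet transform of a segment
#'
#' Complex Morlet CWT coefficients on a logarithmic scale grid, one row per
#' scale (smallest scale, i.e. highest pseudo-frequency, first) and one
#' column per signal sample.
#'
#' @slot coefficients complex matrix, scales by time.
#' @slot scales scale values a in seconds, strictly increasing.
#' @slot pseudoFrequencies per-scale equivalent frequency in Hz.
#' @slot fs sampling rate of the analysed segment.
#' @export
setClass("CwtMatrix",
  representation(coefficients = "matrix", scales = "numeric",
                 pseudoFrequencies = "numeric", fs = "numeric"))

setValidity("CwtMatrix", function(object) {
  msg <- character(0)
  if (nrow(object@coefficients) != length(object@scales))
    msg <- c(msg, "one coefficient row per scale required")
  if (length(object@scales) && any(diff(object@scales) <= 0))
    msg <- c(msg, "scales must be strictly increasing")
  if (length(object@scales) && any(object@scales <= 0))
    msg <- c(msg, "scales must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Rendered scalogram image
#'
#' The magnitude of a [CwtMatrix-class] min-max normalised per segment,
#' quantised to a 128-colour jet palette and resized to the fixed
#' 227 x 227 x 3 classifier input geometry.  `index` retains the integer
#' colour index (0..127) of every output pixel; low pseudo-frequencies sit
#' on the bottom image rows.
#'
#' @slot magnitude non-negative CWT magnitude before resizing.
#' @slot rgb 227 x 227 x 3 array in [0, 1].
#' @slot index 227 x 227 integer matrix of colour indices.
#' @slot colormap colormap identifier, `"JET128"`.
#' @export
setClass("ScalogramImage",
  representation(magnitude = "matrix", rgb = "array", index = "matrix",
                 colormap = "character"),
  prototype(colormap = "JET128"))

setValidity("ScalogramImage", function(object) {
  msg <- character(0)
  if (!identical(dim(object@rgb), c(227L, 227L, 3L)))
    msg <- c(msg, "rgb must be exactly 227 x 227 x 3")
  if (any(object@magnitude < 0)) msg <- c(msg, "magnitude must be non-negative")
  if (any(object@rgb < 0 | object@rgb > 1))
    msg <- c(msg, "rgb values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Clifford-style signal quality indices for one segment
#'
#' @slot bsqi fraction of R peaks on which two independent detectors agree.
#' @slot psqi relative spectral power in the QRS band.
#' @slot ksqi kurtosis of the segment (non-excess; Gaussian gives 3).
#' @slot bassqi one minus the relative power in the baseline band.
#' @export
setClass("SqiVector",
  representation(bsqi = "numeric", psqi = "numeric", ksqi = "numeric",
                 bassqi = "numeric"))

setValidity("SqiVector", function(object) {
  msg <- character(0)
  inUnit <- function(v) is.na(v) || (v >= 0 && v <= 1)
  if (!inUnit(object@bsqi)) msg <- c(msg, "bsqi must lie in [0,1]")
  if (!inUnit(object@psqi)) msg <- c(msg, "psqi must lie in [0,1]")
  if (!inUnit(object@bassqi)) msg <- c(msg, "bassqi must lie in [0,1]")
  if (!is.na(object@ksqi) && object@ksqi < 0)
    msg <- c(msg, "ksqi must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Two-class ECG quality network
#'
#' Parameter store plus architecture description for the
#' AlexNet-architecture classifier.  `classOrder` fixes the meaning of the
#' two softmax outputs as `c("HIGH", "LOW")`.
#'
#' @slot spec layer-by-layer architecture description (see [alexNetSpec()]).
#' @slot params named list of weight matrices and bias vectors.
#' @slot classOrder output class order.
#' @slot lossTrace per-epoch mean training loss of the last fine-tuning.
#' @export
setClass("QualityModel",
  representation(spec = "list", params = "list", classOrder = "character",
                 lossTrace = "numeric"),
  prototype(classOrder = c("HIGH", "LOW"), lossTrace = numeric(0)))

#' Fitted SQI + SVM baseline
#'
#' @slot svm fitted [e1071::svm] object (radial kernel).
#' @slot center,scale training-set feature standardisation statistics.
#' @slot config list recording kernel, C and gamma.
#' @export
setClass("SqiSvmModel",
  representation(svm = "ANY", center = "numeric", scale = "numeric",
                 config = "list"))

#' Multi-run validation report
#'
#' @slot perRun data.frame with one row per learning-testing run (columns
#'   `Se`, `Sp`, `Acc`, `RNSR`, `RAF`, `ROR`, plus bookkeeping columns).
#' @slot aggregates data.frame with rows `mean`, `std`, `maximum`, `minimum`.
#' @export
setClass("ValidationReport",
  representation(perRun = "data.frame", aggregates = "data.frame"))

setValidity("ValidationReport", function(object) {
  agg <- object@aggregates
  if (nrow(agg) == 4 && all(c("mean", "maximum", "minimum") %in% rownames(agg))) {
    for (j in seq_len(ncol(agg))) {
      v <- agg[, j]
      if (all(is.finite(v[c("mean", "maximum", "minimum")]))) {
        if (v["minimum"] > v["mean"] + 1e-9 || v["mean"] > v["maximum"] + 1e-9)
          return("aggregate min <= mean <= max violated")
      }
    }
  }
  TRUE
})
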
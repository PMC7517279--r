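## Glue between the classifiers and the validation protocol, plus the
## scaled-down end-to-end synthetic benchmark used for desk-scale
## evaluation.

#' CNN classifier backend for the validation protocol
#'
#' Each holdout run re-trains the network from the supplied starting model
#' (the pretrained/initialised state), never from a previous run's
#' weights.
#'
#' @param images named list of [ScalogramImage-class], keyed by
#'   `segment_id`.
#' @param baseModel starting [QualityModel-class].
#' @param cfg a [trainConfig()].
#' @return classifier backend usable with [runHoldout()].
#' @export
makeCnnClassifier <- function(images, baseModel = buildModel(seed = 1L),
                              cfg = fastTrainConfig()) {
  ## with a frozen base the activations below the trained head are
  ## identical in every run, so they are extracted once for all images
  cache <- NULL
  if (cfg$freeze %in% c("features", "conv")) {
    cache <- extractFrozenFeatures(baseModel, images, freeze = cfg$freeze)
    rownames(cache) <- names(images)
  }
  list(
    fit = function(trainDf) {
      finetune(baseModel, images[trainDf$segment_id], trainDf$quality, cfg,
               features = if (is.null(cache)) NULL
                          else cache[trainDf$segment_id, , drop = FALSE])
    },
    predict = function(fitted, testDf) {
      if (is.null(cache)) {
        predictQuality(fitted, images[testDf$segment_id])$label
      } else {
        predictQuality(fitted, features = cache[testDf$segment_id, ,
                                                drop = FALSE],
                       freeze = cfg$freeze)$label
      }
    })
}

#' SQI + SVM classifier backend for the validation protocol
#'
#' @param features feature data.frame from [sqiFeatures()] with a
#'   `segment_id` column.
#' @param C,gamma SVM hyperparameters.
#' @return classifier backend usable with [runHoldout()].
#' @export
makeSqiClassifier <- function(features, C = 25, gamma = 1) {
  rownames(features) <- features$segment_id
  list(
    fit = function(trainDf) {
      f <- features[trainDf$segment_id, , drop = FALSE]
      fitBaseline(f, trainDf$quality, C = C, gamma = gamma)
    },
    predict = function(fitted, testDf) {
      classifyBaseline(fitted, features[testDf$segment_id, , drop = FALSE])
    })
}

segmentsToManifest <- function(segments, sourceDb = "SYNTH") {
  do.call(rbind, lapply(segments, function(seg) {
    data.frame(segment_id = sprintf("%s_%03d", seg@recordId, seg@index),
               source_db = sourceDb, quality = seg@qualityLabel,
               rhythm = seg@rhythmLabel, stringsAsFactors = FALSE)
  }))
}

#' Scaled-down end-to-end synthetic benchmark
#'
#' Generates a balanced synthetic two-class record set, cuts it into 5-s
#' segments, renders scalogram images and computes SQI features, then runs
#' one balanced validation cycle (stratified 80/20 holdout, `kRuns`
#' times) for both the CNN and the SQI+SVM baseline on identical splits.
#'
#' @param nPerClass records per quality class.
#' @param fs sampling rate in Hz.
#' @param seed single integer controlling generation, splits, dropout and
#'   head initialisation.
#' @param kRuns holdout repetitions.
#' @param cnnCfg CNN training configuration (default: the fast frozen-base
#'   preset).
#' @param verbose print progress.
#' @return list with `cnn` and `baseline` [ValidationReport-class]
#'   objects, the segment `manifest`, and the rendered `images`.
#' @export
runSyntheticBenchmark <- function(nPerClass = 300, fs = 300, seed = 1L,
                                  kRuns = 5, cnnCfg = fastTrainConfig(seed = seed),
                                  verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("generating ", 2 * nPerClass, " synthetic records")
  bench <- generateBenchmark(nPerClass, fs = fs, seed = seed)
  segments <- unlist(lapply(bench$records, segmentRecord), recursive = FALSE)
  manifest <- segmentsToManifest(segments)
  names(segments) <- manifest$segment_id

  say("rendering ", length(segments), " scalogram images")
  cfg <- cwtConfig()
  images <- lapply(segments, segmentToImage, cfg = cfg)
  say("computing SQI features")
  features <- sqiFeatures(segments)

  plan <- cyclePlan("COMBINED", 1L, "take-all", seed = seed)
  cycle <- buildCycles(manifest, plan)[[1]]

  say("running CNN holdout")
  cnnRuns <- runHoldout(cycle, makeCnnClassifier(images,
                                                 baseModel = buildModel(seed = seed),
                                                 cfg = cnnCfg),
                        kRuns = kRuns, seed = seed)
  say("running SQI+SVM holdout")
  svmRuns <- runHoldout(cycle, makeSqiClassifier(features),
                        kRuns = kRuns, seed = seed)

  list(cnn = aggregateReports(cnnRuns), baseline = aggregateReports(svmRuns),
       manifest = manifest, images = images, features = features)
}
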
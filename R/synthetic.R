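## Synthetic single-lead ECG generator.  Clean beats are a sum-of-Gaussians
## PQRST template placed at irregular R times; AF replaces the P wave by a
## slowly modulated ~6 Hz fibrillatory oscillation and draws highly variable
## RR intervals; the four noise families mimic what wearable recorders pick
## up: baseline wander, 50 Hz powerline, high-frequency EMG, and sparse
## high-amplitude motion transients.

## (amplitude mV, centre s relative to R, width s) of each wave
PQRST_WAVES <- list(
  P = c(a = 0.15,  mu = -0.20,  s = 0.025),
  Q = c(a = -0.10, mu = -0.030, s = 0.010),
  R = c(a = 1.00,  mu = 0.000,  s = 0.012),
  S = c(a = -0.15, mu = 0.030,  s = 0.010),
  T = c(a = 0.30,  mu = 0.25,   s = 0.050))

NOISE_TYPES <- c("baseline_wander", "powerline", "emg", "motion_artifact")

#' Configuration for the synthetic ECG generator
#'
#' @param fs sampling rate in Hz; the three emulated databases use 300, 500
#'   and 250 Hz.
#' @param durationS record duration in seconds (>= 5).
#' @param rhythm `"NSR"`, `"AF"` or `"OR"`.
#' @param heartRateBpm mean heart rate in beats per minute.
#' @param rrCv coefficient of variation of the RR intervals; defaults to
#'   0.02 for NSR/OR and 0.24 for AF.
#' @param seed integer RNG seed.
#' @return a `SynthConfig` list.
#' @export
synthConfig <- function(fs = 300, durationS = 5, rhythm = "NSR",
                        heartRateBpm = 72, rrCv = NULL, seed = 1L) {
  stopifnot(fs %in% c(250, 300, 500) || fs > 0, durationS >= 5,
            heartRateBpm >= 30, heartRateBpm <= 220)
  rhythm <- match.arg(rhythm, c("NSR", "AF", "OR"))
  if (is.null(rrCv)) rrCv <- if (rhythm == "AF") 0.24 else 0.02
  if (rhythm == "AF" && rrCv < 0.15)
    stop("AF requires irregular RR intervals (rrCv >= 0.15)")
  if (rhythm != "AF" && rrCv > 0.03)
    stop("NSR/OR require near-regular RR intervals (rrCv <= 0.03)")
  structure(list(fs = fs, durationS = durationS, rhythm = rhythm,
                 heartRateBpm = heartRateBpm, rrCv = rrCv,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

## draw R-peak times covering [0, durationS] with mean RR and given CV
drawRPeakTimes <- function(durationS, hrBpm, cv) {
  rrMean <- 60 / hrBpm
  times <- -stats::runif(1, 0, rrMean)   # random phase of the beat train
  peaks <- numeric(0)
  while (times < durationS + rrMean) {
    peaks <- c(peaks, times)
    rr <- if (cv > 0) rrMean * exp(stats::rnorm(1, 0, cv)) else rrMean
    times <- times + max(rr, 0.25)
  }
  peaks
}

beatTrain <- function(t, rpeaks, waves, widthScale = 1) {
  x <- numeric(length(t))
  for (r in rpeaks) {
    for (w in waves) {
      s <- w[["s"]] * widthScale
      ctr <- r + w[["mu"]] * widthScale
      idx <- which(t >= ctr - 5 * s & t <= ctr + 5 * s)
      if (length(idx))
        x[idx] <- x[idx] + w[["a"]] * exp(-(t[idx] - ctr)^2 / (2 * s^2))
    }
  }
  x
}

#' Generate a clean synthetic single-lead ECG record
#'
#' Produces a quasi-periodic sum-of-Gaussians PQRST train.  For AF the P
#' wave is removed, RR intervals are drawn with high variability and a
#' slowly amplitude/frequency-modulated ~6 Hz fibrillatory wave is added;
#' for "other rhythm" every third beat is a wide, large, P-less ectopic
#' beat with an inverted T wave.  Ground-truth R-peak times (those falling
#' inside the record) are returned in `meta$rpeaks`.
#'
#' @param cfg a [synthConfig()].
#' @param recordId record identifier.
#' @return an [EcgRecord-class] annotated CLEAN with the configured rhythm.
#' @export
generateClean <- function(cfg, recordId = sprintf("synth-%s-%d", cfg$rhythm, cfg$seed)) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$durationS * fs)
  t <- (seq_len(n) - 1) / fs
  rpeaks <- drawRPeakTimes(cfg$durationS, cfg$heartRateBpm, cfg$rrCv)

  if (cfg$rhythm == "NSR") {
    x <- beatTrain(t, rpeaks, PQRST_WAVES)
  } else if (cfg$rhythm == "AF") {
    waves <- PQRST_WAVES[c("Q", "R", "S", "T")]   # absent P wave
    x <- beatTrain(t, rpeaks, waves)
    fMod <- 6 + 0.5 * sin(2 * pi * 0.11 * t + stats::runif(1, 0, 2 * pi))
    aMod <- 0.08 * (1 + 0.4 * sin(2 * pi * 0.07 * t + stats::runif(1, 0, 2 * pi)))
    x <- x + aMod * sin(2 * pi * cumsum(fMod) / fs + stats::runif(1, 0, 2 * pi))
  } else {  # OR: trigeminy-like ectopic interleaving
    normal <- rpeaks[seq_along(rpeaks) %% 3 != 0]
    ectopic <- rpeaks[seq_along(rpeaks) %% 3 == 0]
    x <- beatTrain(t, normal, PQRST_WAVES)
    ectWaves <- list(R = c(a = 1.3, mu = 0, s = 0.03),
                     T = c(a = -0.35, mu = 0.3, s = 0.06))
    x <- x + beatTrain(t, ectopic, ectWaves, widthScale = 1.4)
  }

  inside <- rpeaks[rpeaks >= 0 & rpeaks <= cfg$durationS - 1 / fs]
  ann <- data.frame(start_s = 0, end_s = n / fs, rhythm = cfg$rhythm,
                    quality = "CLEAN", stringsAsFactors = FALSE)
  new("EcgRecord", recordId = recordId, samples = x, fs = fs,
      sourceDb = "SYNTH", annotations = ann,
      meta = list(rpeaks = inside, config = cfg))
}

## raw (unscaled) realisations of the four wearable-device noise families
rawNoise <- function(type, t, fs) {
  n <- length(t)
  switch(type,
    baseline_wander = {
      w <- numeric(n)
      for (i in 1:3) {
        f <- stats::runif(1, 0.05, 0.5)
        w <- w + stats::runif(1, 0.5, 1) * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
      w
    },
    powerline = sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)),
    emg = {
      w <- stats::rnorm(n)
      bf <- signal::butter(4, min(20 / (fs / 2), 0.9), type = "high")
      signal::filtfilt(bf, w)
    },
    motion_artifact = {
      w <- numeric(n)
      for (i in seq_len(sample(3:6, 1))) {
        ctr <- stats::runif(1, 0, max(t))
        width <- stats::runif(1, 0.1, 0.4)
        w <- w + sample(c(-1, 1), 1) * stats::runif(1, 2, 5) *
          exp(-(t - ctr)^2 / (2 * width^2))
      }
      w
    },
    stop("unknown noise type: ", type))
}

#' Corrupt a clean record with one noise family at a target SNR
#'
#' The noise realisation is rescaled so the realised
#' \eqn{10 \log_{10}(P_{signal}/P_{noise})} over the whole record equals the
#' requested SNR.  The returned record is annotated NOISY over its full
#' duration; `meta$noise` keeps the added component so the realised SNR can
#' be recomputed.
#'
#' @param rec a clean [EcgRecord-class].
#' @param noiseType one of `"baseline_wander"`, `"powerline"`, `"emg"`,
#'   `"motion_artifact"`.
#' @param snrDb target signal-to-noise ratio in dB (finite).
#' @param seed integer RNG seed for the noise realisation.
#' @return a NOISY-annotated [EcgRecord-class].
#' @export
addNoise <- function(rec, noiseType, snrDb, seed = 1L) {
  stopifnot(is(rec, "EcgRecord"), is.finite(snrDb))
  if (!noiseType %in% NOISE_TYPES)
    stop("unknown noise type: ", noiseType)
  if (any(rec@annotations$quality == "NOISY"))
    stop("addNoise expects a clean record")
  set.seed(as.integer(seed))
  x <- rec@samples
  t <- (seq_along(x) - 1) / rec@fs
  w <- rawNoise(noiseType, t, rec@fs)
  pSig <- mean(x^2)
  pW <- mean(w^2)
  if (pW <= 0 || pSig <= 0) stop("degenerate signal or noise power")
  w <- w * sqrt(pSig / (pW * 10^(snrDb / 10)))
  ann <- data.frame(start_s = 0, end_s = length(x) / rec@fs,
                    rhythm = "NONE", quality = "NOISY",
                    stringsAsFactors = FALSE)
  new("EcgRecord", recordId = paste0(rec@recordId, "-", noiseType),
      samples = x + w, fs = rec@fs, sourceDb = rec@sourceDb,
      annotations = ann,
      meta = c(rec@meta, list(noise = w, noise_type = noiseType,
                              snr_db = snrDb)))
}

#' Generate a balanced two-class synthetic benchmark
#'
#' Builds `nPerClass` high-quality records (split between NSR and AF, plus
#' OR if requested) and `nPerClass` low-quality records obtained by
#' corrupting independent clean records with the four noise families in
#' rotation at SNRs drawn from `snrRangeDb`.  Heart rates are drawn
#' uniformly from 55-100 bpm.  When `dir` is given, every record is written
#' as a single-column CSV and a `manifest.csv` referencing them is written
#' alongside, so the records can be re-read through [readRecord()].
#'
#' @param nPerClass records per quality class (>= 1).
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed; the whole benchmark is a deterministic
#'   function of it.
#' @param durationS record duration in seconds.
#' @param includeOr also include "other rhythm" records in the clean class.
#' @param snrRangeDb SNR range (dB) for the noisy class; the default keeps
#'   all noisy records at or below 0 dB.
#' @param dir optional output directory for CSV records and manifest.
#' @return list with `records` (named list of [EcgRecord-class]) and
#'   `manifest` (data.frame: record_id, path, format, fs, quality, rhythm,
#'   noise_type, snr_db).
#' @export
generateBenchmark <- function(nPerClass, fs = 300, seed = 1L, durationS = 5,
                              includeOr = FALSE, snrRangeDb = c(-6, 0),
                              dir = NULL) {
  stopifnot(nPerClass >= 1, snrRangeDb[1] <= snrRangeDb[2])
  set.seed(as.integer(seed))
  rhythms <- if (includeOr) c("NSR", "AF", "OR") else c("NSR", "AF")
  highRhythm <- rep(rhythms, length.out = nPerClass)
  ## per-record seeds are drawn once up front so record content is a
  ## deterministic function of the benchmark seed
  seeds <- sample.int(.Machine$integer.max, 3 * nPerClass)
  hrs <- stats::runif(2 * nPerClass, 55, 100)
  snrs <- stats::runif(nPerClass, snrRangeDb[1], snrRangeDb[2])
  lowNoise <- rep(NOISE_TYPES, length.out = nPerClass)
  lowRhythm <- rep(rhythms, length.out = nPerClass)

  records <- list()
  rows <- list()
  for (i in seq_len(nPerClass)) {
    cfg <- synthConfig(fs = fs, durationS = durationS,
                       rhythm = highRhythm[i], heartRateBpm = hrs[i],
                       seed = seeds[i])
    id <- sprintf("high-%04d", i)
    records[[id]] <- generateClean(cfg, recordId = id)
    rows[[id]] <- data.frame(record_id = id, path = NA_character_,
                             format = "csv", fs = fs, quality = "HIGH",
                             rhythm = highRhythm[i],
                             noise_type = NA_character_, snr_db = NA_real_,
                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(nPerClass)) {
    cfg <- synthConfig(fs = fs, durationS = durationS,
                       rhythm = lowRhythm[i], heartRateBpm = hrs[nPerClass + i],
                       seed = seeds[nPerClass + i])
    clean <- generateClean(cfg, recordId = sprintf("lowbase-%04d", i))
    id <- sprintf("low-%04d", i)
    noisy <- addNoise(clean, lowNoise[i], snrs[i],
                      seed = seeds[2 * nPerClass + i])
    noisy@recordId <- id
    records[[id]] <- noisy
    rows[[id]] <- data.frame(record_id = id, path = NA_character_,
                             format = "csv", fs = fs, quality = "LOW",
                             rhythm = "NONE", noise_type = lowNoise[i],
                             snr_db = snrs[i], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(records)) {
      p <- file.path(dir, paste0(id, ".csv"))
      ## single column, no header
      writeLines(formatC(records[[id]]@samples, format = "g", digits = 15), p)
      manifest$path[manifest$record_id == id] <- p
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(records = records, manifest = manifest)
}
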
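## Clifford-style signal quality indices and the Gaussian-kernel SVM
## baseline that combines them.  The two QRS detectors follow the classic
## Pan-Tompkins and Hamilton-Tompkins recipes (bandpass, derivative,
## rectify/square, moving-window integration, adaptive threshold with a
## refractory period); the agreement between them (bSQI), together with
## QRS-band relative power (pSQI), kurtosis (kSQI) and baseline relative
## power (basSQI), feeds the SVM.

extractSamples <- function(segment, fs) {
  if (is(segment, "EcgSegment") || is(segment, "EcgRecord"))
    list(x = samples(segment), fs = samplingRate(segment))
  else {
    if (is.null(fs)) stop("fs is required for a bare numeric signal")
    list(x = as.numeric(segment), fs = fs)
  }
}

qrsDetect <- function(x, fs, band, order, rectify, integS, refracS, thrFrac) {
  n <- length(x)
  if (n < fs || stats::sd(x) == 0) return(numeric(0))
  bf <- signal::butter(order, pmin(band / (fs / 2), 0.99), type = "pass")
  xf <- signal::filtfilt(bf, x)
  d <- c(diff(xf), 0)
  e <- if (rectify) abs(d) else d^2
  win <- max(1L, round(integS * fs))
  integ <- stats::filter(e, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  if (max(integ) <= 0) return(numeric(0))

  thr <- thrFrac * stats::quantile(integ, 0.98)
  refrac <- round(refracS * fs)
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (integ[i] > thr && integ[i] >= integ[i - 1] && integ[i] >= integ[i + 1]) {
      if (length(peaks) == 0 || i - peaks[length(peaks)] > refrac) {
        peaks <- c(peaks, i)
      } else if (integ[i] > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
      }
    }
    i <- i + 1L
  }
  if (length(peaks) == 0) return(numeric(0))
  ## refine each candidate to the local extremum of the bandpassed signal
  half <- round(0.10 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1, p - half); hi <- min(n, p + half)
    lo + which.max(abs(xf[lo:hi])) - 1L
  }, numeric(1))
  sort(unique(refined - 1)) / fs
}

#' R-peak detection, Pan-Tompkins style
#'
#' Bandpass 5-15 Hz, differentiate, square, integrate over 150 ms, then
#' adaptive-threshold peak picking with a 250 ms refractory period.
#'
#' @param segment an [EcgSegment-class], [EcgRecord-class] or numeric
#'   vector.
#' @param fs sampling rate, required for a bare vector.
#' @return strictly increasing R-peak times in seconds (possibly empty).
#' @export
detectRPeaksPT <- function(segment, fs = NULL) {
  s <- extractSamples(segment, fs)
  qrsDetect(s$x, s$fs, band = c(5, 15), order = 3, rectify = FALSE,
            integS = 0.150, refracS = 0.250, thrFrac = 0.3)
}

#' R-peak detection, Hamilton-Tompkins style
#'
#' Bandpass 8-16 Hz, differentiate, rectify, integrate over 80 ms, then
#' adaptive-threshold peak picking with a 200 ms refractory period.
#'
#' @inheritParams detectRPeaksPT
#' @return strictly increasing R-peak times in seconds (possibly empty).
#' @export
detectRPeaksHT <- function(segment, fs = NULL) {
  s <- extractSamples(segment, fs)
  qrsDetect(s$x, s$fs, band = c(8, 16), order = 3, rectify = TRUE,
            integS = 0.080, refracS = 0.200, thrFrac = 0.35)
}

#' Inter-detector R-peak agreement (bSQI)
#'
#' Greedy one-to-one nearest-neighbour matching of the two peak trains
#' within `tolS`; the index is the matched count over the size of the
#' union after matching.  Two empty trains give 0.
#'
#' @param peaksA,peaksB sorted peak times in seconds.
#' @param tolS matching tolerance in seconds (default 150 ms, within the
#'   physiological refractory period).
#' @return agreement fraction in [0, 1].
#' @export
bsqi <- function(peaksA, peaksB, tolS = 0.150) {
  nA <- length(peaksA); nB <- length(peaksB)
  if (nA + nB == 0) return(0)
  ## one-to-one greedy matching by ascending time difference; symmetric in
  ## the two trains
  d <- abs(outer(peaksA, peaksB, "-"))
  cand <- which(d <= tolS, arr.ind = TRUE)
  matched <- 0L
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    usedA <- logical(nA); usedB <- logical(nB)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!usedA[i] && !usedB[j]) {
        usedA[i] <- TRUE; usedB[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  matched / (nA + nB - matched)
}

bandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half][f[half] > lo & f[half] <= hi])
}

#' QRS-band relative spectral power (pSQI)
#'
#' Periodogram power in 5-15 Hz over power in 5-45 Hz.
#'
#' @inheritParams detectRPeaksPT
#' @return fraction in [0, 1]; 0 (with a warning) when the 5-45 Hz band
#'   carries no power.
#' @export
psqi <- function(segment, fs = NULL) {
  s <- extractSamples(segment, fs)
  denom <- bandPower(s$x, s$fs, 5, 45)
  if (denom <= 0) {
    warning("zero power in 5-45 Hz band; pSQI set to 0")
    return(0)
  }
  min(bandPower(s$x, s$fs, 5, 15) / denom, 1)
}

#' Baseline relative spectral power (basSQI)
#'
#' One minus the periodogram power in 0-1 Hz over power in 0-40 Hz
#' (DC excluded), so a baseline-dominated segment scores near 0.
#'
#' @inheritParams detectRPeaksPT
#' @return fraction in [0, 1]; 0 (with a warning) when the 0-40 Hz band
#'   carries no power.
#' @export
bassqi <- function(segment, fs = NULL) {
  s <- extractSamples(segment, fs)
  denom <- bandPower(s$x, s$fs, 0, 40)
  if (denom <= 0) {
    warning("zero power in 0-40 Hz band; basSQI set to 0")
    return(0)
  }
  max(1 - bandPower(s$x, s$fs, 0, 1) / denom, 0)
}

#' Kurtosis of the segment (kSQI)
#'
#' Fourth standardised central moment, non-excess convention (Gaussian
#' noise scores about 3).
#'
#' @inheritParams detectRPeaksPT
#' @return kurtosis; `NaN` with a warning for a zero-variance segment.
#' @export
ksqi <- function(segment, fs = NULL) {
  s <- extractSamples(segment, fs)
  x <- s$x - mean(s$x)
  m2 <- mean(x^2)
  if (m2 == 0) {
    warning("zero-variance segment; kSQI undefined")
    return(NaN)
  }
  mean(x^4) / m2^2
}

#' Compute the four quality indices for one segment
#'
#' @inheritParams detectRPeaksPT
#' @return a [SqiVector-class].
#' @export
sqiVector <- function(segment, fs = NULL) {
  s <- extractSamples(segment, fs)
  new("SqiVector",
      bsqi = bsqi(detectRPeaksPT(s$x, s$fs), detectRPeaksHT(s$x, s$fs)),
      psqi = suppressWarnings(psqi(s$x, s$fs)),
      ksqi = {
        k <- suppressWarnings(ksqi(s$x, s$fs))
        if (is.nan(k)) 0 else k
      },
      bassqi = suppressWarnings(bassqi(s$x, s$fs)))
}

#' Feature table for a set of segments
#'
#' @param segments list of [EcgSegment-class].
#' @return data.frame with columns `segment_id`, `bsqi`, `psqi`, `ksqi`,
#'   `bassqi`, `label`.
#' @export
sqiFeatures <- function(segments) {
  rows <- lapply(segments, function(seg) {
    v <- asFeatureVector(sqiVector(seg))
    data.frame(segment_id = sprintf("%s_%03d", seg@recordId, seg@index),
               bsqi = v[["bsqi"]], psqi = v[["psqi"]], ksqi = v[["ksqi"]],
               bassqi = v[["bassqi"]], label = seg@qualityLabel,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the SQI + SVM baseline classifier
#'
#' Features are z-scored by training-set statistics and fed to a
#' Gaussian-kernel SVM with `C = 25` and `gamma = 1`.
#'
#' @param features data.frame with columns `bsqi`, `psqi`, `ksqi`,
#'   `bassqi`.
#' @param labels `HIGH`/`LOW` labels, one per row.
#' @param C SVM cost parameter.
#' @param gamma RBF kernel width.
#' @return a [SqiSvmModel-class].
#' @export
fitBaseline <- function(features, labels, C = 25, gamma = 1) {
  cols <- c("bsqi", "psqi", "ksqi", "bassqi")
  stopifnot(all(cols %in% names(features)), C > 0, gamma > 0)
  labels <- factor(labels, levels = c("HIGH", "LOW"))
  if (length(unique(labels[!is.na(labels)])) < 2)
    stop("both classes must be present in the training set")
  X <- as.matrix(features[, cols])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- e1071::svm(Xs, labels, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  new("SqiSvmModel", svm = fit, center = ctr, scale = scl,
      config = list(kernel = "radial", C = C, gamma = gamma))
}

#' Classify segments with a fitted SQI + SVM baseline
#'
#' @param model a [SqiSvmModel-class].
#' @param features feature data.frame as in [fitBaseline()].
#' @return character vector of `HIGH`/`LOW` labels.
#' @export
classifyBaseline <- function(model, features) {
  stopifnot(is(model, "SqiSvmModel"))
  cols <- c("bsqi", "psqi", "ksqi", "bassqi")
  Xs <- scale(as.matrix(features[, cols]), center = model@center,
              scale = model@scale)
  as.character(predict(model@svm, Xs))
}
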
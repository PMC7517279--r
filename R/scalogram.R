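## Morlet continuous wavelet transform and scalogram rendering.
##
## The transform evaluates, on a logarithmic scale grid with a fixed number
## of voices per octave,
##
##   W(a, b) = a^{-1/2} * sum_n x[n] conj(psi((t_n - b) / a)) * dt
##
## with the analytic Morlet mother wavelet
##   psi(u) = pi^{-1/4} exp(i w0 u) exp(-u^2 / 2),  w0 = 6 by default,
## i.e. a complex exponential under a Gaussian window.  The sum is the
## Riemann discretisation of the CWT integral over the segment's support
## (samples outside the window contribute nothing: no padding).  Per scale
## it is a correlation of the signal with the scaled wavelet and is
## evaluated exactly by zero-padded FFT convolution.

#' CWT configuration
#'
#' The scale grid is derived from the sampling rate and segment length at
#' transform time: the smallest scale puts the wavelet centre frequency at
#' the Nyquist frequency, the largest is bounded by the requirement that
#' the wavelet's energy spread in time (`boundSigma` Gaussian standard
#' deviations each side) fits inside the analysed window, and scales are
#' spaced geometrically with `voicesPerOctave` scales per factor of two.
#'
#' @param wavelet mother wavelet; only `"morlet"`.
#' @param voicesPerOctave scales per octave (default 48).
#' @param omega0 Morlet centre frequency in rad/s at unit scale (default 6,
#'   the conventional admissible choice balancing time and frequency
#'   spread).
#' @param nSigma Gaussian half-support, in standard deviations, at which
#'   the sampled wavelet is truncated (accuracy of the transform).
#' @param boundSigma Gaussian half-widths, in standard deviations, that
#'   must fit inside the analysed window at the largest scale.  The
#'   default \eqn{\sqrt 2} is the conventional filter-bank energy-spread
#'   rule; on a 5-s window it reaches down to about 0.5 Hz, keeping
#'   baseline wander and motion transients visible in the scalogram.
#' @return a `CwtConfig` list.
#' @export
cwtConfig <- function(wavelet = "morlet", voicesPerOctave = 48, omega0 = 6,
                      nSigma = 5, boundSigma = sqrt(2)) {
  wavelet <- match.arg(wavelet)
  stopifnot(voicesPerOctave >= 1, omega0 > 0, nSigma > 0, boundSigma > 0)
  structure(list(wavelet = wavelet, voicesPerOctave = voicesPerOctave,
                 omega0 = omega0, nSigma = nSigma, boundSigma = boundSigma),
            class = "CwtConfig")
}

cwtScales <- function(cfg, fs, n) {
  aMin <- cfg$omega0 / (2 * pi * (fs / 2))     # centre freq at Nyquist
  aMax <- (n / fs) / (2 * cfg$boundSigma)      # energy spread fits window
  if (aMax <= aMin) stop("segment too short for the configured scale rule")
  nOct <- log2(aMax / aMin)
  k <- 0:floor(nOct * cfg$voicesPerOctave)
  aMin * 2^(k / cfg$voicesPerOctave)
}

## correlation of x with every scaled wavelet by zero-padded FFT
## convolution, batched over scales at a common padded length; equals the
## truncated-support quadrature of the CWT integral.  The convolution
## kernel at lag k is conj(psi(-k dt / a)), so that circular convolution
## reproduces the correlation sum_n x[n] conj(psi((n - j) dt / a)).
cwtAllScales <- function(x, fs, scales, omega0, nSigma) {
  n <- length(x)
  Mmax <- ceiling(nSigma * max(scales) * fs)
  L <- stats::nextn(n + 2 * Mmax, 2)
  K <- matrix(0i, L, length(scales))
  for (i in seq_along(scales)) {
    M <- ceiling(nSigma * scales[i] * fs)
    u <- ((-M):M) / (fs * scales[i])
    h <- pi^(-0.25) * exp(1i * omega0 * u) * exp(-u^2 / 2)
    K[1:(M + 1), i] <- h[(M + 1):(2 * M + 1)]
    K[(L - M + 1):L, i] <- h[1:M]
  }
  HF <- stats::mvfft(K)
  xf <- stats::fft(c(x, rep(0, L - n)))
  Y <- stats::mvfft(HF * xf, inverse = TRUE) / L
  t(Y[1:n, , drop = FALSE]) / (sqrt(scales) * fs)
}

#' Continuous wavelet transform of an ECG segment
#'
#' @param segment an [EcgSegment-class], [EcgRecord-class] or numeric
#'   vector.
#' @param cfg a [cwtConfig()].
#' @param fs sampling rate, required when `segment` is a bare vector.
#' @return a [CwtMatrix-class] with one row per scale (highest
#'   pseudo-frequency first) and one column per sample.
#' @export
ecgCwt <- function(segment, cfg = cwtConfig(), fs = NULL) {
  if (is(segment, "EcgSegment") || is(segment, "EcgRecord")) {
    x <- samples(segment); fs <- samplingRate(segment)
  } else {
    x <- as.numeric(segment)
    if (is.null(fs)) stop("fs is required for a bare numeric signal")
  }
  if (length(x) == 0) stop("empty segment")
  if (anyNA(x) || any(!is.finite(x))) stop("segment contains NA/NaN/Inf samples")
  scales <- cwtScales(cfg, fs, length(x))
  coef <- cwtAllScales(x, fs, scales, cfg$omega0, cfg$nSigma)
  new("CwtMatrix", coefficients = coef, scales = scales,
      pseudoFrequencies = cfg$omega0 / (2 * pi * scales), fs = fs)
}

#' Jet colormap lookup table
#'
#' The classic blue-cyan-yellow-red palette, reproducing the MATLAB
#' construction for `n` colours.
#'
#' @param n number of colours (default 128).
#' @return an `n` x 3 matrix of RGB values in [0, 1].
#' @export
jetColormap <- function(n = 128) {
  m <- n
  nn <- ceiling(m / 4)
  u <- c(seq_len(nn) / nn, rep(1, nn - 1), seq(nn, 1) / nn)
  g <- ceiling(nn / 2) - as.integer(m %% 4 == 1) + seq_along(u)
  r <- g + nn
  b <- g - nn
  J <- matrix(0, m, 3)
  rIn <- r >= 1 & r <= m; gIn <- g >= 1 & g <= m; bIn <- b >= 1 & b <= m
  J[r[rIn], 1] <- u[rIn]
  J[g[gIn], 2] <- u[gIn]
  J[b[bIn], 3] <- u[bIn]
  J
}

#' Render a CWT matrix as a fixed-size jet scalogram image
#'
#' The coefficient magnitude is min-max normalised per segment to [0, 1],
#' bilinearly resized to the 227 x 227 classifier geometry (low
#' pseudo-frequencies at the bottom rows), then quantised to 128 jet
#' colours, so the colour index is a monotone non-decreasing function of
#' the normalised magnitude.  An all-zero magnitude yields a uniform image
#' at colour index 0.
#'
#' @param mat a [CwtMatrix-class].
#' @param size output height/width in pixels.
#' @param nColors number of palette colours.
#' @param keepMagnitude retain the full pre-resize magnitude matrix in the
#'   returned object.  Setting this to `FALSE` stores an empty placeholder
#'   instead, which keeps large image collections (hundreds of segments)
#'   within a desktop memory budget.
#' @return a [ScalogramImage-class].
#' @export
renderScalogram <- function(mat, size = 227L, nColors = 128L,
                            keepMagnitude = TRUE) {
  stopifnot(is(mat, "CwtMatrix"), nrow(mat@coefficients) > 0)
  mag <- Mod(mat@coefficients)
  rng <- range(mag)
  norm <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(mag), ncol(mag))
  ## rows are ordered smallest scale (highest frequency) first, which is
  ## the top image row; EBImage's first dimension indexes x, so transpose
  res <- EBImage::resize(EBImage::Image(t(norm)), w = size, h = size,
                         filter = "bilinear")
  normR <- t(EBImage::imageData(res))            # size x size, row = y
  normR <- pmin(pmax(normR, 0), 1)
  idx <- matrix(as.integer(pmin(floor(normR * nColors), nColors - 1)),
                size, size)
  lut <- jetColormap(nColors)
  rgbArr <- array(lut[idx + 1L, ], dim = c(size, size, 3L))
  new("ScalogramImage",
      magnitude = if (keepMagnitude) mag else matrix(numeric(0), 0, 0),
      rgb = rgbArr, index = idx, colormap = sprintf("JET%d", nColors))
}

#' Turn a 5-s ECG segment into its scalogram image
#'
#' Composition of [ecgCwt()] and [renderScalogram()]; deterministic for a
#' fixed configuration.
#'
#' The full magnitude matrix is not retained on this composed path (see
#' `keepMagnitude` in [renderScalogram()]); use [ecgCwt()] plus
#' [renderScalogram()] to keep it.
#'
#' @inheritParams ecgCwt
#' @return a [ScalogramImage-class].
#' @export
segmentToImage <- function(segment, cfg = cwtConfig(), fs = NULL) {
  renderScalogram(ecgCwt(segment, cfg, fs = fs), keepMagnitude = FALSE)
}

#' Write a scalogram image as PNG
#'
#' @param img a [ScalogramImage-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeScalogramPng <- function(img, path) {
  stopifnot(is(img, "ScalogramImage"))
  png::writePNG(img@rgb, path)
  invisible(path)
}

#' Convert labeled segments into an image directory with a label CSV
#'
#' @param segments list of [EcgSegment-class].
#' @param dir output directory.
#' @param cfg a [cwtConfig()].
#' @return data.frame mapping image files to labels (also written as
#'   `labels.csv` in `dir`).
#' @export
scalogramBatch <- function(segments, dir, cfg = cwtConfig()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(segments, function(seg) {
    f <- sprintf("%s_%03d.png", seg@recordId, seg@index)
    writeScalogramPng(segmentToImage(seg, cfg), file.path(dir, f))
    data.frame(image = f, record_id = seg@recordId, index = seg@index,
               quality = seg@qualityLabel, rhythm = seg@rhythmLabel,
               stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, rows)
  rownames(labels) <- NULL
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  labels
}
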
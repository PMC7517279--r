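## Reading single-lead ECG recordings from PhysioNet-style storage (WFDB
## header + signal pairs, per-record MAT files) and plain single-column
## CSV, plus windowing into labeled 5-s segments.
##
## The WFDB reader supports the common format-16 (little-endian int16)
## signal encoding and applies the header's gain/baseline calibration; the
## MAT reader supports MATLAB Level 4 files and uncompressed Level 5 files
## holding a single numeric matrix, which covers the per-record files of
## the PhysioNet/CinC 2017 training set style of distribution.

parseWfdbHeader <- function(heaPath) {
  lines <- readLines(heaPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  recName <- sub("/.*", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sigs <- lapply(lines[1 + seq_len(nsig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    gainTok <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gainTok)))
    baseline <- if (grepl("\\(", gainTok))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainTok)) else NA_real_
    adcZero <- if (length(tok) >= 5) as.numeric(tok[5]) else 0
    list(file = tok[1], format = sub("x.*", "", tok[2]),
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = if (is.na(baseline)) adcZero else baseline)
  })
  list(record = recName, nsig = nsig, fs = fs, nsamp = nsamp, signals = sigs)
}

readWfdbRecord <- function(path, channel = 1, channelGiven = TRUE) {
  heaPath <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(heaPath)) stop("WFDB header not found: ", heaPath)
  hdr <- parseWfdbHeader(heaPath)
  if (hdr$nsig > 1 && !channelGiven)
    stop("multi-channel record: select a channel explicitly")
  if (channel > hdr$nsig) stop("channel out of range")
  sig <- hdr$signals[[channel]]
  sigPath <- file.path(dirname(heaPath), sig$file)
  if (!file.exists(sigPath)) stop("WFDB signal file not found: ", sigPath)

  if (grepl("\\.mat$", sig$file)) {
    raw <- readMatArray(sigPath)$data
    adc <- if (is.matrix(raw)) raw[channel, ] else as.numeric(raw)
  } else {
    if (!identical(sig$format, "16"))
      stop("unsupported WFDB signal format '", sig$format, "' (only 16)")
    sz <- file.info(sigPath)$size
    all16 <- readBin(sigPath, "integer", n = sz / 2, size = 2,
                     endian = "little", signed = TRUE)
    ## interleaved frames across signals
    adc <- all16[seq(channel, length(all16), by = hdr$nsig)]
  }
  if (!is.na(hdr$nsamp) && length(adc) > hdr$nsamp) adc <- adc[seq_len(hdr$nsamp)]
  mv <- (as.numeric(adc) - sig$baseline) / sig$gain
  list(samples = mv, fs = hdr$fs, recordId = hdr$record)
}

## Minimal MATLAB MAT-file reader: Level 4, and uncompressed Level 5 with a
## single numeric (double/int16/int32/single/uint8/uint16) matrix element.
readMatArray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head4 <- readBin(con, "raw", n = 4)
  magic <- as.integer(head4)
  v4type <- magic[1] + 256 * magic[2] + 65536 * magic[3] + 16777216 * magic[4]
  if (v4type < 10000 && magic[4] == 0) {   # Level 4: MOPT type code
    mrows <- readBin(con, "integer", 1, 4, endian = "little")
    ncols <- readBin(con, "integer", 1, 4, endian = "little")
    imagf <- readBin(con, "integer", 1, 4, endian = "little")
    namlen <- readBin(con, "integer", 1, 4, endian = "little")
    nm <- rawToChar(readBin(con, "raw", namlen)[seq_len(namlen - 1)])
    p <- v4type %% 100 %/% 10   # element storage type
    vals <- switch(as.character(p),
      "0" = readBin(con, "double", mrows * ncols, 8, endian = "little"),
      "1" = readBin(con, "double", mrows * ncols, 4, endian = "little"),
      "3" = readBin(con, "integer", mrows * ncols, 2, endian = "little",
                    signed = TRUE),
      "4" = readBin(con, "integer", mrows * ncols, 2, endian = "little",
                    signed = FALSE),
      stop("unsupported MAT v4 element type ", p))
    return(list(name = nm, data = matrix(as.numeric(vals), mrows, ncols)))
  }
  ## Level 5: 128-byte header, then tagged data elements
  seek(con, 124)
  endTag <- readBin(con, "raw", 4)
  endian <- if (rawToChar(endTag[3:4]) == "IM") "little" else "big"
  readTag <- function() {
    b <- readBin(con, "raw", 4)
    if (length(b) < 4) return(NULL)
    t <- readBin(b, "integer", 1, 4, endian = endian)
    if (t > 65535) {   # small data element: type/size packed in one word
      list(type = t %% 65536, bytes = t %/% 65536, small = TRUE)
    } else {
      list(type = t, bytes = readBin(con, "integer", 1, 4, endian = endian),
           small = FALSE)
    }
  }
  readElementData <- function(type, bytes) {
    switch(as.character(type),
      "1" = readBin(con, "integer", bytes, 1, signed = TRUE, endian = endian),
      "2" = readBin(con, "integer", bytes, 1, signed = FALSE, endian = endian),
      "3" = readBin(con, "integer", bytes / 2, 2, signed = TRUE, endian = endian),
      "4" = readBin(con, "integer", bytes / 2, 2, signed = FALSE, endian = endian),
      "5" = readBin(con, "integer", bytes / 4, 4, endian = endian),
      "6" = readBin(con, "double", bytes / 4, 4, endian = endian),
      "7" = readBin(con, "double", bytes / 4, 4, endian = endian),
      "9" = readBin(con, "double", bytes / 8, 8, endian = endian),
      stop("unsupported MAT v5 data type ", type))
  }
  repeat {
    tag <- readTag()
    if (is.null(tag)) stop("no numeric matrix element found in ", path)
    if (tag$type == 15)
      stop("compressed MAT v5 files are not supported; save uncompressed")
    if (tag$type != 14) {           # skip non-matrix element (pad to 8)
      skip <- tag$bytes + (8 - tag$bytes %% 8) %% 8
      seek(con, skip, origin = "current")
      next
    }
    ## miMATRIX: array flags, dimensions, name, real part
    ft <- readTag(); flags <- readBin(con, "integer", 2, 4, endian = endian)
    dt <- readTag()
    dims <- readBin(con, "integer", dt$bytes / 4, 4, endian = endian)
    if (!dt$small) seek(con, (8 - dt$bytes %% 8) %% 8, origin = "current")
    nt <- readTag()
    nmRaw <- readBin(con, "raw", nt$bytes)
    nm <- rawToChar(nmRaw)
    pad <- if (nt$small) (4 - nt$bytes %% 4) %% 4 else (8 - nt$bytes %% 8) %% 8
    seek(con, pad, origin = "current")
    vt <- readTag()
    vals <- readElementData(vt$type, vt$bytes)
    return(list(name = nm, data = matrix(as.numeric(vals), dims[1], dims[2])))
  }
}

#' Read a single-lead ECG recording
#'
#' Reads one recording from WFDB (header + signal pair, format 16 or a
#' MAT-stored signal referenced by the header), a per-record MAT file, or a
#' single-column headerless CSV.  For WFDB the samples are calibrated to mV
#' using the header gain and baseline; for MAT and CSV an explicit `gain`
#' (ADC units per mV) may be supplied.
#'
#' @param path file path (for WFDB either the `.hea` file or the record
#'   base name).
#' @param format `"wfdb"`, `"mat"`, `"csv"`, or `"auto"` (by extension).
#' @param fs sampling rate in Hz; required for CSV and MAT, ignored for
#'   WFDB (taken from the header).
#' @param channel channel to extract from a multi-channel file.
#' @param gain optional ADC-units-per-mV calibration for MAT/CSV input.
#' @param recordId identifier; defaults to the file base name.
#' @param sourceDb one of `SOURCE_DBS`.
#' @param annotations optional annotation data.frame (`start_s`, `end_s`,
#'   `rhythm`, `quality`); a whole-record label can be supplied via
#'   `rhythm=`/`quality=` columns of a manifest instead, see
#'   [readManifest()].
#' @return an [EcgRecord-class].
#' @export
readRecord <- function(path, format = c("auto", "wfdb", "mat", "csv"),
                       fs = NULL, channel = 1, gain = NULL,
                       recordId = NULL, sourceDb = "OTHER",
                       annotations = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path)) "wfdb"
      else if (grepl("\\.mat$", path)) "mat"
      else if (grepl("\\.csv$", path)) "csv"
      else if (file.exists(paste0(path, ".hea"))) "wfdb"
      else stop("cannot infer format of ", path)
  }
  if (format != "wfdb" && !file.exists(path)) stop("file not found: ", path)

  if (format == "wfdb") {
    r <- readWfdbRecord(path, channel = channel,
                        channelGiven = !missing(channel))
    x <- r$samples; fs <- r$fs
    if (is.null(recordId)) recordId <- r$recordId
  } else if (format == "mat") {
    m <- readMatArray(path)
    if (is.null(fs)) stop("fs is required for MAT input")
    if (nrow(m$data) > 1 && ncol(m$data) > 1 && missing(channel))
      stop("multi-channel MAT record: select a channel explicitly")
    x <- if (nrow(m$data) == 1 || ncol(m$data) == 1) as.numeric(m$data)
         else m$data[channel, ]
    if (!is.null(gain)) x <- x / gain
  } else {
    if (is.null(fs)) stop("fs is required for CSV input")
    x <- tryCatch(scan(path, what = numeric(), quiet = TRUE, sep = "\n"),
                  error = function(e) stop("unreadable CSV: ", path))
    if (!is.null(gain)) x <- x / gain
  }
  if (is.null(recordId))
    recordId <- sub("\\.[a-zA-Z0-9]+$", "", basename(path))
  if (is.null(annotations)) annotations <- emptyAnnotations()
  new("EcgRecord", recordId = recordId, samples = as.numeric(x), fs = fs,
      sourceDb = sourceDb, annotations = annotations, meta = list())
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `record_id`, `path`, `format`, `fs`
#' and whole-record label columns `quality` (`HIGH`/`LOW`) and `rhythm`.
#'
#' @param path manifest CSV path.
#' @return a data.frame.
#' @export
readManifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("record_id", "path", "format", "fs", "quality", "rhythm")
  missingCols <- setdiff(req, names(m))
  if (length(missingCols))
    stop("manifest lacks columns: ", paste(missingCols, collapse = ", "))
  m
}

#' Load the records referenced by a manifest
#'
#' Whole-record manifest labels are converted to a single spanning
#' annotation interval (`HIGH` rows become CLEAN with the stated rhythm,
#' `LOW` rows NOISY/NONE).
#'
#' @param manifest a data.frame as returned by [readManifest()].
#' @param sourceDb source database tag applied to all records.
#' @return named list of [EcgRecord-class] objects.
#' @export
loadManifestRecords <- function(manifest, sourceDb = "OTHER") {
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rec <- readRecord(row$path, format = row$format, fs = row$fs,
                      recordId = row$record_id, sourceDb = sourceDb)
    q <- if (identical(row$quality, "LOW")) "NOISY" else "CLEAN"
    rh <- if (q == "NOISY") "NONE" else row$rhythm
    rec@annotations <- data.frame(start_s = 0, end_s = duration(rec),
                                  rhythm = rh, quality = q,
                                  stringsAsFactors = FALSE)
    validObject(rec)
    rec
  })
  names(recs) <- manifest$record_id
  recs
}

#' Assign quality and rhythm labels to one window of a record
#'
#' Any overlap with a NOISY annotation contaminates the window (it becomes
#' `LOW`/`NONE`); otherwise the window is `HIGH` and takes the rhythm of
#' the clean annotation with the largest overlap, ties broken toward AF.
#'
#' @param rec an annotated [EcgRecord-class].
#' @param startS,endS window bounds in seconds, `[startS, endS)`.
#' @return list with `quality` (`HIGH`/`LOW`) and `rhythm`.
#' @export
assignLabels <- function(rec, startS, endS) {
  stopifnot(is(rec, "EcgRecord"), startS < endS)
  ann <- rec@annotations
  if (nrow(ann) == 0) stop("record has no annotations")
  ov <- pmin(ann$end_s, endS) - pmax(ann$start_s, startS)
  keep <- ov > 1e-9
  if (!any(keep)) stop(sprintf("window [%g, %g) overlaps no annotation",
                               startS, endS))
  ann <- ann[keep, , drop = FALSE]; ov <- ov[keep]
  if (any(ann$quality == "NOISY"))
    return(list(quality = "LOW", rhythm = "NONE"))
  byRhythm <- tapply(ov, factor(ann$rhythm, levels = c("AF", "NSR", "OR")),
                     sum)
  byRhythm[is.na(byRhythm)] <- 0
  ## which.max on the AF-first ordering breaks exact ties toward AF
  list(quality = "HIGH", rhythm = names(byRhythm)[which.max(byRhythm)])
}

#' Cut a record into consecutive labeled windows
#'
#' Non-overlapping windows are taken from t = 0; a trailing remainder
#' shorter than one window is discarded.  Each window inherits its labels
#' through [assignLabels()].
#'
#' @param rec an annotated [EcgRecord-class].
#' @param windowS window length in seconds (default 5).
#' @return list of [EcgSegment-class]; empty if the record is shorter than
#'   one window.
#' @export
segmentRecord <- function(rec, windowS = 5) {
  stopifnot(is(rec, "EcgRecord"), windowS > 0)
  nWin <- round(windowS * rec@fs)
  nSeg <- floor(length(rec@samples) / nWin)
  if (nSeg == 0) return(list())
  lapply(seq_len(nSeg) - 1L, function(i) {
    idx <- (i * nWin + 1):((i + 1) * nWin)
    lab <- assignLabels(rec, i * nWin / rec@fs, (i + 1) * nWin / rec@fs)
    new("EcgSegment", recordId = rec@recordId, index = i,
        samples = rec@samples[idx], fs = rec@fs,
        qualityLabel = lab$quality, rhythmLabel = lab$rhythm)
  })
}
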
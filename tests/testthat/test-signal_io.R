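test_that("CSV records round-trip with the stated duration arithmetic", {
  p <- tempfile(fileext = ".csv")
  writeLines(formatC(sin(1:1500), format = "g", digits = 15), p)
  rec <- readRecord(p, format = "csv", fs = 300)
  expect_s4_class(rec, "EcgRecord")
  expect_equal(duration(rec), 5.0)
  expect_equal(samples(rec), sin(1:1500), tolerance = 1e-12)
  expect_error(readRecord(p, format = "csv"), "fs is required")
  expect_error(readRecord(tempfile(fileext = ".csv"), format = "csv",
                          fs = 300), "not found")
})

test_that("WFDB format-16 records are read with header calibration", {
  ## fixture bytes are laid out by hand, independently of the reader:
  ## 300 Hz, 9000 samples, gain 1000 ADU/mV, baseline 0, int16 LE
  dir <- withr::local_tempdir()
  adc <- as.integer(round(1000 * sin(2 * pi * 7 * (0:8999) / 300)))
  writeLines(c("rec01 1 300 9000", "rec01.dat 16 1000(0)/mV 16 0 0 0 0 ECG"),
             file.path(dir, "rec01.hea"))
  writeBin(adc, file.path(dir, "rec01.dat"), size = 2, endian = "little")
  rec <- readRecord(file.path(dir, "rec01.hea"), format = "wfdb")
  expect_equal(duration(rec), 30)          # 9000 samples at 300 Hz
  expect_equal(samplingRate(rec), 300)
  expect_equal(samples(rec), adc / 1000, tolerance = 1e-9)

  ## two interleaved channels: explicit selection required
  adc2 <- as.integer(rbind(adc[1:100], rev(adc[1:100]))) # frame-interleaved
  writeLines(c("rec02 2 300 100",
               "rec02.dat 16 1000(0)/mV 16 0 0 0 0 ECG1",
               "rec02.dat 16 1000(0)/mV 16 0 0 0 0 ECG2"),
             file.path(dir, "rec02.hea"))
  writeBin(adc2, file.path(dir, "rec02.dat"), size = 2, endian = "little")
  expect_error(readRecord(file.path(dir, "rec02.hea"), format = "wfdb"),
               "channel")
  r2 <- readRecord(file.path(dir, "rec02.hea"), format = "wfdb", channel = 2)
  expect_equal(r2@samples, rev(adc[1:100]) / 1000, tolerance = 1e-9)
})

test_that("MAT v4 and v5 files written by an independent writer are read", {
  dir <- withr::local_tempdir()
  vals <- round(sin(1:900), 6)

  ## Level 4 layout, written byte by byte from the format definition
  p4 <- file.path(dir, "v4.mat")
  con <- file(p4, "wb")
  writeBin(0L, con, size = 4, endian = "little")       # MOPT = 0000: LE double
  writeBin(1L, con, size = 4, endian = "little")       # mrows
  writeBin(900L, con, size = 4, endian = "little")     # ncols
  writeBin(0L, con, size = 4, endian = "little")       # imagf
  writeBin(4L, con, size = 4, endian = "little")       # name length
  writeBin(c(charToRaw("val"), as.raw(0)), con)
  writeBin(vals, con, size = 8, endian = "little")
  close(con)
  m4 <- readRecord(p4, format = "mat", fs = 300)
  expect_equal(duration(m4), 3)
  expect_equal(samples(m4), vals, tolerance = 1e-12)

  ## Level 5 layout: 128-byte header + one miMATRIX of doubles
  p5 <- file.path(dir, "v5.mat")
  con <- file(p5, "wb")
  desc <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, test fixture"))
  writeBin(desc, con)
  writeBin(raw(8), con)                                 # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                  # version 0x0100
  writeBin(charToRaw("IM"), con)                        # little-endian tag
  nData <- 7200L                                        # 8 * 900
  writeBin(c(14L, 48L + nData), con, size = 4, endian = "little")
  writeBin(c(6L, 8L), con, size = 4, endian = "little") # UINT32 array flags
  writeBin(c(6L, 0L), con, size = 4, endian = "little") # mxDOUBLE_CLASS
  writeBin(c(5L, 8L), con, size = 4, endian = "little") # INT32 dims
  writeBin(c(1L, 900L), con, size = 4, endian = "little")
  writeBin(1L + 4L * 65536L, con, size = 4, endian = "little") # small INT8 name
  writeBin(c(charToRaw("val"), as.raw(0)), con)
  writeBin(c(9L, nData), con, size = 4L, endian = "little")  # miDOUBLE
  writeBin(vals, con, size = 8, endian = "little")
  close(con)
  m5 <- readRecord(p5, format = "mat", fs = 300, recordId = "v5")
  expect_equal(samples(m5), vals, tolerance = 1e-12)
  expect_equal(duration(m5), 3)
})

test_that("segmentation discards the trailing remainder and inherits labels", {
  fs <- 300
  rec9 <- new("EcgRecord", recordId = "r9", samples = rnorm(9 * fs), fs = fs,
              sourceDb = "PC2017",
              annotations = wholeRecordAnnotation(9 * fs, fs, "AF", "CLEAN"),
              meta = list())
  segs <- segmentRecord(rec9)
  expect_length(segs, 1)                  # trailing 4 s discarded
  expect_equal(qualityLabel(segs[[1]]), "HIGH")
  expect_equal(rhythmLabel(segs[[1]]), "AF")

  rec60 <- new("EcgRecord", recordId = "r60", samples = rnorm(60 * fs),
               fs = fs, sourceDb = "PC2017",
               annotations = wholeRecordAnnotation(60 * fs, fs, "NONE",
                                                   "NOISY"),
               meta = list())
  segs60 <- segmentRecord(rec60)
  expect_length(segs60, 12)
  expect_true(all(vapply(segs60, qualityLabel, "") == "LOW"))
  expect_true(all(vapply(segs60, rhythmLabel, "") == "NONE"))

  recShort <- new("EcgRecord", recordId = "rs", samples = rnorm(4.9 * fs),
                  fs = fs, sourceDb = "OTHER",
                  annotations = wholeRecordAnnotation(4.9 * fs, fs, "NSR",
                                                      "CLEAN"),
                  meta = list())
  expect_length(segmentRecord(recShort), 0)
})

test_that("any noisy overlap contaminates a window; clean rhythm by majority", {
  rec <- toyTwoIntervalRecord(fs = 100)    # 0-6 s NSR clean, 6-10 s noisy
  expect_equal(assignLabels(rec, 0, 5), list(quality = "HIGH", rhythm = "NSR"))
  ## window half clean, half noisy -> LOW/NONE
  expect_equal(assignLabels(rec, 4, 9), list(quality = "LOW", rhythm = "NONE"))
  expect_error(assignLabels(rec, 11, 12), "bounds|overlaps no annotation")

  ## majority rule with tie toward AF
  ann <- data.frame(start_s = c(0, 2, 4.5), end_s = c(2, 4.5, 10),
                    rhythm = c("AF", "NSR", "AF"),
                    quality = "CLEAN", stringsAsFactors = FALSE)
  recM <- new("EcgRecord", recordId = "maj", samples = rnorm(1000), fs = 100,
              sourceDb = "OTHER", annotations = ann, meta = list())
  expect_equal(assignLabels(recM, 0, 5)$rhythm, "AF")    # 2.5 s AF vs 2.5 NSR
  expect_equal(assignLabels(recM, 1.5, 4.4)$rhythm, "NSR")
})

test_that("segment count and sample conservation hold for arbitrary records", {
  fs <- 250
  for (durS in c(5, 7.3, 12.49, 25, 60)) {
    n <- round(durS * fs)
    rec <- new("EcgRecord", recordId = "p", samples = rnorm(n), fs = fs,
               sourceDb = "OTHER",
               annotations = wholeRecordAnnotation(n, fs, "NSR", "CLEAN"),
               meta = list())
    segs <- segmentRecord(rec)
    expect_length(segs, floor(durS / 5))
    if (length(segs)) {
      recon <- unlist(lapply(segs, samples))
      expect_identical(recon, rec@samples[seq_along(recon)])
      labs <- vapply(segs, rhythmLabel, "")
      expect_true(all(labs %in% RHYTHMS))
      quals <- vapply(segs, qualityLabel, "")
      expect_true(all(quals %in% SEGMENT_QUALITIES))
    }
  }
})

test_that("manifest round trip feeds records back through the CSV reader", {
  dir <- withr::local_tempdir()
  bench <- generateBenchmark(3, fs = 250, seed = 77, dir = dir)
  m <- readManifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 6)
  recs <- loadManifestRecords(m, sourceDb = "SYNTH")
  expect_length(recs, 6)
  orig <- bench$records[[m$record_id[1]]]
  expect_equal(samples(recs[[m$record_id[1]]]), samples(orig),
               tolerance = 1e-9)
  expect_equal(annotations(recs[[1]])$quality,
               ifelse(m$quality[1] == "HIGH", "CLEAN", "NOISY"))
})
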
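# Shared fixtures.  Everything is generated in code; expensive objects are
# memoised in this environment so several test files can reuse them within
# one session.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

## a record with known annotation structure: 0-6 s clean NSR, 6-10 s noisy
toyTwoIntervalRecord <- function(fs = 100) {
  n <- 10 * fs
  ann <- data.frame(start_s = c(0, 6), end_s = c(6, 10),
                    rhythm = c("NSR", "NONE"),
                    quality = c("CLEAN", "NOISY"),
                    stringsAsFactors = FALSE)
  new("EcgRecord", recordId = "toy2", samples = sin(2 * pi * 1.2 * (1:n) / fs),
      fs = fs, sourceDb = "OTHER", annotations = ann, meta = list())
}

wholeRecordAnnotation <- function(nSamples, fs, rhythm, quality) {
  data.frame(start_s = 0, end_s = nSamples / fs, rhythm = rhythm,
             quality = quality, stringsAsFactors = FALSE)
}

## deterministic 5-s zero segment
zeroSegment <- function(fs = 300) {
  new("EcgSegment", recordId = "zero", index = 0L,
      samples = rep(0, 5 * fs), fs = fs, qualityLabel = "LOW",
      rhythmLabel = "NONE")
}

cleanNsrSegment <- function(fs = 300, seed = 21) {
  rec <- generateClean(synthConfig(fs = fs, durationS = 5, rhythm = "NSR",
                                   heartRateBpm = 66, seed = seed))
  segmentRecord(rec)[[1]]
}

## uniform-colour 227x227x3 images for separability checks
uniformImage <- function(level) array(level, dim = c(227L, 227L, 3L))

## metadata-only segment manifest with the requested per-stratum counts
syntheticSegmentManifest <- function(counts) {
  ## counts: data.frame(source_db, quality, rhythm, n)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ],
         data.frame(segment_id = sprintf("%s-%s-%s-%05d", source_db, quality,
                                         rhythm, seq_len(n)),
                    source_db = source_db, quality = quality, rhythm = rhythm,
                    stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

## the scaled-down end-to-end benchmark (shared by the acceptance tests)
benchmarkRun <- function(key = "bench1", seed = 101) {
  memo(key, runSyntheticBenchmark(nPerClass = 300, fs = 300, seed = seed,
                                  kRuns = 5))
}
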
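## Class-rebalanced multi-cycle validation.  Strongly imbalanced datasets
## are handled by repeated cycles: each cycle keeps (or samples) the
## low-quality class and draws a rhythm-stratified random subset of equal
## size from the high-quality class, then a stratified 80/20 holdout is
## trained and tested five times.  Metrics are Se/Sp/Acc plus the
## per-rhythm retention rates RNSR/RAF/ROR, aggregated as
## mean/std/max/min across all runs.

#' Sampling plan for one validation scope
#'
#' @param scope `"PC2017"`, `"THDB"`, `"PDB"` or `"COMBINED"`.
#' @param nCycles number of validation cycles.
#' @param lowQualityRule `"take-all"` or a positive integer: how the
#'   low-quality subset of each cycle is formed.
#' @param highQualityStrata named integer vector, rhythm -> per-cycle
#'   count, for the high-quality subset (ignored when `perDbQuota` is
#'   given with its own stratification).
#' @param perDbQuota named integer vector, database -> per-class count per
#'   cycle (COMBINED scope only).
#' @param seed RNG seed for the cycle draws.
#' @return a `CyclePlan` list.
#' @export
cyclePlan <- function(scope, nCycles, lowQualityRule = "take-all",
                      highQualityStrata = NULL, perDbQuota = NULL,
                      seed = 1L) {
  scope <- match.arg(scope, c("PC2017", "THDB", "PDB", "COMBINED"))
  stopifnot(nCycles >= 1)
  if (!identical(lowQualityRule, "take-all"))
    stopifnot(is.numeric(lowQualityRule), lowQualityRule >= 1)
  structure(list(scope = scope, nCycles = as.integer(nCycles),
                 lowQualityRule = lowQualityRule,
                 highQualityStrata = highQualityStrata,
                 perDbQuota = perDbQuota, seed = as.integer(seed)),
            class = "CyclePlan")
}

#' The four canonical validation plans
#'
#' Cycle geometry used throughout: 40 cycles on PC2017 keeping all
#' low-quality segments and drawing 468 NSR + 340 AF + 330 OR high-quality
#' segments per cycle; 19 cycles on PDB at 1200 low and 600 NSR + 600 AF
#' high; a single cycle on the already-balanced THDB; and 40 combined
#' cycles drawing 1000/500/1000 segments per class from
#' PC2017/THDB/PDB with near-equal rhythm composition inside each
#' database's high-quality quota.  With five holdout runs per cycle this
#' totals 500 learning-testing iterations.
#'
#' @param seed base RNG seed (each scope uses `seed + offset`).
#' @return named list of [cyclePlan()] objects.
#' @export
canonicalPlans <- function(seed = 1L) {
  list(
    pc2017 = cyclePlan("PC2017", 40L, "take-all",
                       highQualityStrata = c(NSR = 468L, AF = 340L, OR = 330L),
                       seed = seed),
    thdb = cyclePlan("THDB", 1L, "take-all", seed = seed + 1L),
    pdb = cyclePlan("PDB", 19L, 1200,
                    highQualityStrata = c(NSR = 600L, AF = 600L),
                    seed = seed + 2L),
    combined = cyclePlan("COMBINED", 40L, "take-all",
                         perDbQuota = c(PC2017 = 1000L, THDB = 500L,
                                        PDB = 1000L),
                         seed = seed + 3L))
}

sampleStratum <- function(ids, nWanted, what) {
  if (length(ids) < nWanted)
    stop(sprintf("stratum '%s' has %d segments but %d are required",
                 what, length(ids), nWanted))
  if (length(ids) == nWanted) ids else sample(ids, nWanted)
}

drawHighSubset <- function(manifest, plan) {
  high <- manifest[manifest$quality == "HIGH", , drop = FALSE]
  if (!is.null(plan$perDbQuota)) {
    out <- character(0)
    for (db in names(plan$perDbQuota)) {
      sub <- high[high$source_db == db, , drop = FALSE]
      rhythms <- sort(unique(sub$rhythm))
      if (!length(rhythms))
        stop(sprintf("stratum '%s/HIGH' has 0 segments but %d are required",
                     db, plan$perDbQuota[[db]]))
      quota <- plan$perDbQuota[[db]]
      base <- quota %/% length(rhythms)
      counts <- rep(base, length(rhythms))
      counts[seq_len(quota - base * length(rhythms))] <-
        counts[seq_len(quota - base * length(rhythms))] + 1
      for (k in seq_along(rhythms)) {
        ids <- sub$segment_id[sub$rhythm == rhythms[k]]
        out <- c(out, sampleStratum(ids, counts[k],
                                    paste0(db, "/", rhythms[k])))
      }
    }
    out
  } else if (!is.null(plan$highQualityStrata)) {
    out <- character(0)
    for (rh in names(plan$highQualityStrata)) {
      ids <- high$segment_id[high$rhythm == rh]
      out <- c(out, sampleStratum(ids, plan$highQualityStrata[[rh]], rh))
    }
    out
  } else {
    high$segment_id
  }
}

drawLowSubset <- function(manifest, plan) {
  low <- manifest[manifest$quality == "LOW", , drop = FALSE]
  if (identical(plan$lowQualityRule, "take-all")) {
    if (!is.null(plan$perDbQuota)) {
      out <- character(0)
      for (db in names(plan$perDbQuota)) {
        ids <- low$segment_id[low$source_db == db]
        out <- c(out, sampleStratum(ids, plan$perDbQuota[[db]],
                                    paste0(db, "/LOW")))
      }
      out
    } else {
      low$segment_id
    }
  } else {
    sampleStratum(low$segment_id, plan$lowQualityRule, "LOW")
  }
}

#' Draw the per-cycle sample sets of a validation plan
#'
#' Sampling is without replacement within a cycle; cycles are independent
#' seeded draws (overlap across cycles is allowed).
#'
#' @param manifest segment manifest data.frame with columns `segment_id`,
#'   `source_db`, `quality`, `rhythm`.
#' @param plan a [cyclePlan()].
#' @return list of per-cycle data.frames (rows of `manifest`).
#' @export
buildCycles <- function(manifest, plan) {
  req <- c("segment_id", "source_db", "quality", "rhythm")
  stopifnot(all(req %in% names(manifest)), inherits(plan, "CyclePlan"))
  scoped <- if (plan$scope == "COMBINED") manifest
            else manifest[manifest$source_db == plan$scope, , drop = FALSE]
  set.seed(plan$seed)
  lapply(seq_len(plan$nCycles), function(cyc) {
    ids <- c(drawHighSubset(scoped, plan), drawLowSubset(scoped, plan))
    out <- scoped[match(ids, scoped$segment_id), , drop = FALSE]
    out$cycle <- cyc
    rownames(out) <- NULL
    out
  })
}

## per-stratum test counts for a stratified split: nearest-integer
## rounding, then the largest stratum absorbs the remainder so the global
## test fraction is exact
stratifiedTestIndex <- function(strata, testFrac) {
  n <- length(strata)
  nTest <- round(n * testFrac)
  tab <- table(strata)
  want <- round(as.numeric(tab) * testFrac)
  want <- pmin(pmax(want, ifelse(as.numeric(tab) > 1, 1, 0)), as.numeric(tab))
  diffN <- nTest - sum(want)
  if (diffN != 0) {
    biggest <- which.max(as.numeric(tab))
    want[biggest] <- min(max(want[biggest] + diffN, 0), as.numeric(tab)[biggest])
  }
  idx <- integer(0)
  for (k in seq_along(tab)) {
    members <- which(strata == names(tab)[k])
    if (want[k] > 0) idx <- c(idx, sample(members, want[k]))
  }
  sort(idx)
}

#' Confusion counts of one learning-testing run
#'
#' `TP` counts correctly identified high-quality segments and `TN`
#' correctly classified low-quality ones.
#'
#' @param truth true `HIGH`/`LOW` labels.
#' @param predicted predicted labels.
#' @return named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(truth, predicted) {
  c(TP = sum(truth == "HIGH" & predicted == "HIGH"),
    TN = sum(truth == "LOW" & predicted == "LOW"),
    FP = sum(truth == "LOW" & predicted == "HIGH"),
    FN = sum(truth == "HIGH" & predicted == "LOW"))
}

#' Confusion-derived performance metrics
#'
#' Se = 100 TP/(TP+FN), Sp = 100 TN/(TN+FP),
#' Acc = 100 (TP+TN)/(TP+TN+FP+FN); RNSR/RAF/ROR are the percentages of
#' clean NSR/AF/OR test segments retained as high-quality.  A metric with
#' a zero denominator is reported as `NA`, never silently as 0.
#'
#' @param counts output of [confusionCounts()].
#' @param rhythmCounts optional named list/vector pairs: for each rhythm,
#'   `c(correct, total)`; alternatively pass `truthRhythm` and `predicted`.
#' @param truthRhythm rhythm labels of the test segments (used with
#'   `truth`/`predicted` based rate computation).
#' @param truth,predicted labels used to derive per-rhythm rates when
#'   `rhythmCounts` is not given.
#' @return named numeric vector `Se`, `Sp`, `Acc`, `RNSR`, `RAF`, `ROR`
#'   (percent).
#' @export
computeMetrics <- function(counts, rhythmCounts = NULL, truthRhythm = NULL,
                           truth = NULL, predicted = NULL) {
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  se <- rate(counts[["TP"]], counts[["TP"]] + counts[["FN"]])
  sp <- rate(counts[["TN"]], counts[["TN"]] + counts[["FP"]])
  acc <- rate(counts[["TP"]] + counts[["TN"]], sum(counts))
  rr <- c(RNSR = NA_real_, RAF = NA_real_, ROR = NA_real_)
  if (is.null(rhythmCounts) && !is.null(truthRhythm)) {
    rhythmCounts <- list()
    for (rh in c("NSR", "AF", "OR")) {
      sel <- truth == "HIGH" & truthRhythm == rh
      rhythmCounts[[rh]] <- c(sum(sel & predicted == "HIGH"), sum(sel))
    }
  }
  if (!is.null(rhythmCounts)) {
    for (rh in names(rhythmCounts)) {
      key <- paste0("R", rh)
      if (key %in% names(rr))
        rr[key] <- rate(rhythmCounts[[rh]][1], rhythmCounts[[rh]][2])
    }
  }
  c(Se = se, Sp = sp, Acc = acc, rr)
}

#' Run the stratified 80/20 holdout of one cycle several times
#'
#' Each run draws a fresh stratified split (stratified jointly on quality
#' and rhythm), trains the classifier from its starting point on the 80%
#' learning part, predicts the held-out 20%, and scores the prediction.
#'
#' @param cycleSamples one element of [buildCycles()] output.
#' @param classifier list with functions `fit(trainDf)` returning a fitted
#'   object and `predict(fitted, testDf)` returning `HIGH`/`LOW` labels.
#' @param kRuns number of holdout repetitions (default 5).
#' @param testFrac held-out fraction (default 0.2).
#' @param seed RNG seed.
#' @return data.frame with one row per run: confusion counts and metrics.
#' @export
runHoldout <- function(cycleSamples, classifier, kRuns = 5, testFrac = 0.2,
                       seed = 1L) {
  stopifnot(is.function(classifier$fit), is.function(classifier$predict))
  if (length(unique(cycleSamples$quality)) < 2)
    stop("both quality classes must be present in the cycle")
  set.seed(as.integer(seed))
  strata <- paste(cycleSamples$quality, cycleSamples$rhythm, sep = "/")
  ## all splits are drawn up front so that classifiers that reseed the RNG
  ## during fitting cannot influence later splits, and two classifiers run
  ## with the same seed see identical splits
  splits <- lapply(seq_len(kRuns), function(run)
    stratifiedTestIndex(strata, testFrac))
  rows <- lapply(seq_len(kRuns), function(run) {
    testIdx <- splits[[run]]
    trainDf <- cycleSamples[-testIdx, , drop = FALSE]
    testDf <- cycleSamples[testIdx, , drop = FALSE]
    if (length(unique(trainDf$quality)) < 2 ||
        length(unique(testDf$quality)) < 2)
      stop("a quality class is absent from a stratified split")
    fitted <- classifier$fit(trainDf)
    pred <- classifier$predict(fitted, testDf)
    cc <- confusionCounts(testDf$quality, pred)
    met <- computeMetrics(cc, truthRhythm = testDf$rhythm,
                          truth = testDf$quality, predicted = pred)
    data.frame(run = run, t(as.matrix(cc)) , t(as.matrix(met)),
               n_test = nrow(testDf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-run metrics into a validation report
#'
#' @param perRun data.frame of per-run metric rows (e.g. rbind of
#'   [runHoldout()] outputs across cycles).
#' @return a [ValidationReport-class] with mean, sample standard deviation
#'   (n-1), maximum and minimum per metric; with a single run the std row
#'   is reported as 0.
#' @export
aggregateReports <- function(perRun) {
  metrics <- intersect(c("Se", "Sp", "Acc", "RNSR", "RAF", "ROR"),
                       names(perRun))
  agg <- sapply(metrics, function(m) {
    v <- perRun[[m]]
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA, std = NA, maximum = NA, minimum = NA))
    c(mean = mean(v), std = if (length(v) > 1) stats::sd(v) else 0,
      maximum = max(v), minimum = min(v))
  })
  new("ValidationReport", perRun = perRun,
      aggregates = as.data.frame(agg))
}

#' Table-layout export of a validation report
#'
#' Writes the mean/std/max/min rows for Se, Sp, Acc, RNSR, RAF, ROR in the
#' conventional results-table layout.
#'
#' @param report a [ValidationReport-class].
#' @param path optional CSV output path.
#' @return the formatted data.frame, invisibly when `path` is given.
#' @export
reportTable <- function(report, path = NULL) {
  agg <- aggregates(report)
  out <- data.frame(Value = c("Mean", "Std", "Maximum", "Minimum"),
                    round(t(t(agg)), 2)[c("mean", "std", "maximum",
                                          "minimum"), , drop = FALSE])
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Total learning-testing iterations of a set of plans
#'
#' @param plans list of [cyclePlan()] objects.
#' @param kRuns holdout repetitions per cycle.
#' @return total number of learning-testing iterations.
#' @export
totalIterations <- function(plans, kRuns = 5) {
  sum(vapply(plans, function(p) p$nCycles, numeric(1))) * kRuns
}
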
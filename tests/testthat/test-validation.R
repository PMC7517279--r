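## a metadata-only manifest large enough for every canonical plan
fullProtocolManifest <- function() {
  syntheticSegmentManifest(data.frame(
    source_db = c("PC2017", "PC2017", "PC2017", "PC2017",
                  "THDB", "THDB", "PDB", "PDB", "PDB"),
    quality = c("HIGH", "HIGH", "HIGH", "LOW",
                "HIGH", "LOW", "HIGH", "HIGH", "LOW"),
    rhythm = c("NSR", "AF", "OR", "NONE",
               "NSR", "NONE", "NSR", "AF", "NONE"),
    n = c(1500, 900, 800, 1168,
          700, 650, 900, 900, 1500),
    stringsAsFactors = FALSE))
}

test_that("cycle construction honours strata exactly and is seed-stable", {
  manifest <- fullProtocolManifest()
  plans <- canonicalPlans(seed = 9)
  cycles <- buildCycles(manifest, plans$pc2017)
  expect_length(cycles, 40)
  for (cyc in cycles[c(1, 17, 40)]) {
    expect_equal(sum(cyc$quality == "HIGH" & cyc$rhythm == "NSR"), 468)
    expect_equal(sum(cyc$quality == "HIGH" & cyc$rhythm == "AF"), 340)
    expect_equal(sum(cyc$quality == "HIGH" & cyc$rhythm == "OR"), 330)
    expect_equal(sum(cyc$quality == "LOW"), 1168)        # take-all
    expect_equal(anyDuplicated(cyc$segment_id), 0)       # no replacement
  }
  expect_identical(buildCycles(manifest, plans$pc2017)[[1]]$segment_id,
                   cycles[[1]]$segment_id)

  ## exhaustion case: a manifest with exactly the requested counts is
  ## used in full in every cycle
  tight <- syntheticSegmentManifest(data.frame(
    source_db = "PDB", quality = c("HIGH", "HIGH", "LOW"),
    rhythm = c("NSR", "AF", "NONE"), n = c(600, 600, 1200),
    stringsAsFactors = FALSE))
  tcyc <- buildCycles(tight, canonicalPlans()$pdb)
  expect_length(tcyc, 19)
  expect_setequal(tcyc[[5]]$segment_id, tight$segment_id)
})

test_that("a stratum shortfall is reported by name", {
  small <- syntheticSegmentManifest(data.frame(
    source_db = "PC2017", quality = c("HIGH", "HIGH", "HIGH", "LOW"),
    rhythm = c("NSR", "AF", "OR", "NONE"), n = c(468, 100, 330, 50),
    stringsAsFactors = FALSE))
  expect_error(buildCycles(small, canonicalPlans()$pc2017),
               "'AF' has 100 .* 340")
})

test_that("combined-scope cycles meet per-database quotas for both classes", {
  manifest <- fullProtocolManifest()
  cyc <- buildCycles(manifest, canonicalPlans(seed = 3)$combined)[[1]]
  for (db in c("PC2017", "THDB", "PDB")) {
    quota <- c(PC2017 = 1000, THDB = 500, PDB = 1000)[[db]]
    expect_equal(sum(cyc$source_db == db & cyc$quality == "HIGH"), quota)
    expect_equal(sum(cyc$source_db == db & cyc$quality == "LOW"), quota)
    ## rhythm composition inside each database's high quota is near-equal
    tab <- table(cyc$rhythm[cyc$source_db == db & cyc$quality == "HIGH"])
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("the four scopes with five holdout runs give 500 iterations", {
  plans <- canonicalPlans()
  expect_equal(vapply(plans, function(p) p$nCycles, numeric(1)),
               c(pc2017 = 40, thdb = 1, pdb = 19, combined = 40))
  expect_equal(totalIterations(plans, kRuns = 5), 500)
})

test_that("stratified 80/20 splits have exact arithmetic and conservation", {
  manifest <- syntheticSegmentManifest(data.frame(
    source_db = "SYNTH", quality = c("HIGH", "LOW"),
    rhythm = c("NSR", "NONE"), n = c(50, 50), stringsAsFactors = FALSE))
  alwaysHigh <- list(fit = function(df) NULL,
                     predict = function(m, df) rep("HIGH", nrow(df)))
  runs <- runHoldout(manifest, alwaysHigh, kRuns = 5, seed = 4)
  expect_equal(nrow(runs), 5)
  expect_equal(runs$n_test, rep(20, 5))                 # 20% of 100
  expect_equal(runs$TP + runs$FN, rep(10, 5))           # 10 HIGH per test
  expect_equal(runs$TN + runs$FP, rep(10, 5))           # 10 LOW per test
  ## the degenerate classifier: perfect on HIGH, zero on LOW
  expect_equal(runs$Se, rep(100, 5))
  expect_equal(runs$Sp, rep(0, 5))
  expect_equal(runs$Acc, rep(50, 5))
  expect_error(
    runHoldout(manifest[manifest$quality == "HIGH", ], alwaysHigh),
    "both quality classes")
})

test_that("metrics match a brute-force per-sample tally on random tables", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(20:200, 1)
    truth <- sample(c("HIGH", "LOW"), n, replace = TRUE)
    rhythm <- ifelse(truth == "HIGH",
                     sample(c("NSR", "AF", "OR"), n, replace = TRUE), "NONE")
    pred <- sample(c("HIGH", "LOW"), n, replace = TRUE)
    cc <- confusionCounts(truth, pred)
    expect_equal(sum(cc), n)
    met <- computeMetrics(cc, truthRhythm = rhythm, truth = truth,
                          predicted = pred)
    ## brute-force tally, written independently of the implementation
    nH <- sum(truth == "HIGH"); nL <- n - nH
    if (nH > 0)
      expect_equal(met[["Se"]],
                   100 * sum(pred == "HIGH" & truth == "HIGH") / nH)
    if (nL > 0)
      expect_equal(met[["Sp"]],
                   100 * sum(pred == "LOW" & truth == "LOW") / nL)
    expect_equal(met[["Acc"]], 100 * mean(pred == truth))
    ## Acc is the prevalence-weighted mean of Se and Sp
    if (nH > 0 && nL > 0)
      expect_equal(met[["Acc"]],
                   (nH * met[["Se"]] + nL * met[["Sp"]]) / n)
    for (rh in c("NSR", "AF", "OR")) {
      sel <- truth == "HIGH" & rhythm == rh
      expected <- if (sum(sel) > 0)
        100 * sum(sel & pred == "HIGH") / sum(sel) else NA_real_
      expect_equal(met[[paste0("R", rh)]], expected)
    }
  }
  ## direct substitution example
  met <- computeMetrics(c(TP = 8, TN = 9, FP = 1, FN = 2))
  expect_equal(met[["Se"]], 80)
  expect_equal(met[["Sp"]], 90)
  expect_equal(met[["Acc"]], 85)
  ## zero denominator never silently becomes 0
  expect_true(is.na(computeMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0))[["Se"]]))
})

test_that("aggregation reports mean/std/max/min and matches recomputation", {
  perRun <- data.frame(Se = c(80, 90), Sp = c(70, 74), Acc = c(75, 82),
                       RNSR = c(85, 95), RAF = c(80, 90), ROR = c(NA, NA))
  rep1 <- aggregateReports(perRun)
  agg <- aggregates(rep1)
  expect_equal(agg["mean", "Se"], 85)
  expect_equal(agg["maximum", "Se"], 90)
  expect_equal(agg["minimum", "Se"], 80)
  expect_equal(agg["std", "Se"], sd(c(80, 90)))          # sample std, n-1
  ## single run: std reported as 0
  single <- aggregateReports(perRun[1, ])
  expect_equal(aggregates(single)["std", "Acc"], 0)
  ## brute-force recomputation across random tables
  set.seed(77)
  pr <- data.frame(Se = runif(12, 50, 100), Sp = runif(12, 50, 100),
                   Acc = runif(12, 50, 100))
  agg2 <- aggregates(aggregateReports(pr))
  for (m in c("Se", "Sp", "Acc")) {
    expect_equal(agg2["mean", m], mean(pr[[m]]))
    expect_equal(agg2["std", m], sd(pr[[m]]))
    expect_equal(agg2["maximum", m], max(pr[[m]]))
    expect_equal(agg2["minimum", m], min(pr[[m]]))
  }
  tab <- reportTable(rep1)
  expect_equal(tab$Value, c("Mean", "Std", "Maximum", "Minimum"))
  expect_true(all(c("Se", "Sp", "Acc") %in% names(tab)))
})
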
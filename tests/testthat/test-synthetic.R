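test_that("target pre-mRNA generation is seeded and honors GC content", {
  s1 <- simulateTargetPremrna(7063, seed = 3)
  s2 <- simulateTargetPremrna(7063, seed = 3)
  expect_equal(length(s1), 7063L)
  expect_identical(as.character(s1), as.character(s2))

  at_only <- simulateTargetPremrna(500, gcFraction = 0, seed = 4)
  expect_false(grepl("[GC]", as.character(at_only)))

  gc <- Biostrings::letterFrequency(simulateTargetPremrna(20000, 0.45, 5),
                                    "GC", as.prob = TRUE)
  expect_equal(unname(gc), 0.45, tolerance = 0.02)
})

test_that("tiled ASOs are reverse complements of target windows", {
  config <- generatorConfig()
  target <- simulateTargetPremrna(3000, seed = 11)
  panel <- tileAsos(target, 40, config, seed = 12)
  tchar <- as.character(target)
  for (i in seq_len(40)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(asoBases(panel)[[i]])))
    expect_identical(
      substr(tchar, panel@annot$target_start[[i]],
             panel@annot$target_end[[i]]), rc)
  }
  lens <- nchar(unname(asoBases(panel)))
  expect_true(all(lens >= 14 & lens <= 20))
  fv <- featureTable(panel)
  expect_true(all(fv$n_lna >= 2 & fv$n_lna <= 9))
  expect_true(all(fv$gap_length >= 1))

  expect_equal(length(tileAsos(target, 1, config, seed = 13)), 1L)
})

test_that("the training panel spreads over the configured disjoint regions", {
  config <- generatorConfig()
  target <- simulateTargetPremrna(config$targetLength, seed = 14)
  panel <- tileAsos(target, 330, config, seed = 15)
  regions <- panel@annot$region
  expect_equal(length(unique(regions)), 313L)
  # regions are disjoint: windows in different regions never overlap
  byRegion <- split(seq_len(330), regions)
  starts <- panel@annot$target_start; ends <- panel@annot$target_end
  for (r in sample(313, 30)) {
    others <- setdiff(seq_len(330), byRegion[[r]])
    for (i in byRegion[[r]])
      expect_true(all(ends[others] < starts[[i]] |
                        starts[others] > ends[[i]]))
  }
})

test_that("calcium score generation is exact at zero noise and unbiased", {
  study <- makeStudyPanels(30, 5, seed = 16)
  truth <- study$config$trueCoefficients
  mu <- calculateScore(truth, study$train)
  expect_gt(min(mu), 0)
  expect_equal(unname(simulateCalciumScores(study$train, truth, noiseSd = 0,
                                            seed = 17)), unname(mu))
  # law of large numbers on one ASO
  one <- study$train[1]
  reps <- vapply(1:1000, function(r)
    simulateCalciumScores(one, truth, noiseSd = 25, seed = 3000 + r),
    numeric(1))
  expect_lt(abs(mean(reps) - mu[[1]]), 3 * 25 / sqrt(1000))
  # determinism
  expect_identical(simulateCalciumScores(study$train, truth, seed = 18),
                   simulateCalciumScores(study$train, truth, seed = 18))
  # capping applies on request
  capped <- simulateCalciumScores(study$train, truth, noiseSd = 60,
                                  seed = 19, cap = 200)
  expect_lte(max(capped), 200)
})

test_that("simulated tolerability decreases with calcium score", {
  config <- generatorConfig()
  study <- makeStudyPanels(30, 148, seed = 21)
  mu <- calculateScore(config$trueCoefficients, study$test)
  tol <- simulateTolerability(mu, config, seed = 22)
  expect_length(tol$group_mean, 148)
  expect_true(all(tol$group_mean >= 0 & tol$group_mean <= 20))
  st <- spearmanTest(mu, tol$group_mean)
  expect_lt(st$rho, 0)

  # per-mouse category decomposition: five categories in [0,4] summing to
  # the per-mouse total; 4-6 mice per group
  cats <- as.matrix(tol$mice[, c("cat1", "cat2", "cat3", "cat4", "cat5")])
  expect_true(all(cats >= 0 & cats <= 4))
  expect_equal(unname(rowSums(cats)), tol$mice$total)
  miceCounts <- table(tol$mice$id)
  expect_true(all(miceCounts >= 4 & miceCounts <= 6))

  # link floor: a huge calcium score with zero noise gives tolerability 0
  quiet <- generatorConfig(tolNoiseSd = 0)
  expect_equal(unname(simulateTolerability(c(a = 500), quiet,
                                           seed = 23)$group_mean), 0)
})

test_that("simulated FLIPR traces have Poisson-rate spikes and fixed seeds", {
  flat <- simulateFliprTrace(spikeRate = 0, noiseSd = 0, seed = 31)
  expect_true(all(flat@samples == flat@samples[[1]]))

  counts <- vapply(1:40, function(r) {
    tr <- simulateFliprTrace(spikeRate = 0.03, amplitude = 100,
                             noiseSd = 0, seed = 400 + r)
    countPeaks(tr, window = 180, referenceAmp = 100)
  }, integer(1))
  # expected 0.03 * 180 = 5.4 peaks; sd of the mean ~ sqrt(5.4/40) = 0.37
  expect_lt(abs(mean(counts) - 5.4), 1.2)

  t1 <- simulateFliprTrace(seed = 99)
  t2 <- simulateFliprTrace(seed = 99)
  expect_identical(t1@samples, t2@samples)
})

test_that("simulated transcriptomes are reproducible with unique ids", {
  tx <- simulateTranscriptome(50, seed = 41)
  expect_equal(length(tx), 50L)
  expect_false(anyDuplicated(names(tx)) > 0)
  tx2 <- simulateTranscriptome(50, seed = 41)
  expect_identical(as.character(tx), as.character(tx2))

  # planted reverse complement is found by the screen
  probe <- parseGapmer("TTaccattaccaTT", id = "probe")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTACCATTACCATT")))
  planted <- c(as.character(tx),
               planted = paste0("ACGT", rc, "ACGT"))
  res <- offtargetScreen(probe, Biostrings::DNAStringSet(planted), 0)
  expect_true(res$perfect_match)
})

test_that("a materialized study directory is complete and parseable", {
  dir <- withr::local_tempdir()
  cfg <- generatorConfig(trainSize = 60L, testSize = 25L,
                         validationSize = 8L, targetLength = 2000L,
                         nRegions = 40L)
  paths <- simulateStudy(dir, cfg, seed = 5)
  for (p in paths) expect_true(file.exists(p))

  train <- readPanel(paths$train)
  expect_length(train, 60)
  expect_false(is.null(calciumScores(train)))
  test <- readPanel(paths$test)
  expect_length(test, 25)
  expect_false(is.null(tolerabilityScores(test)))
  mice <- read.delim(paths$test_mice)
  expect_true(all(rowSums(mice[, c("cat1", "cat2", "cat3", "cat4",
                                   "cat5")]) == mice$total))
  txome <- Biostrings::readDNAStringSet(paths$transcriptome)
  expect_equal(length(txome), 50L)
  traces <- readTraces(paths$traces)
  expect_equal(length(traces), 8L)
})

test_that("calculated scores outperform noisy measured scores on test panels", {
  # the in-vivo labels are driven by each sequence's underlying effect, so
  # a model fitted on a large noisy training screen de-noises the assay and
  # classifies tolerability better than the raw measurement
  config <- generatorConfig()
  study <- makeStudyPanels(1645, 148, seed = 51)
  truth <- config$trueCoefficients

  caTrain <- simulateCalciumScores(study$train, truth,
                                   config$calciumNoiseSd, seed = 52)
  model <- fitScoreModel(featureTable(study$train), caTrain)

  muTest <- calculateScore(truth, study$test)
  caTest <- simulateCalciumScores(study$test, truth,
                                  config$calciumNoiseSd, seed = 53)
  tol <- simulateTolerability(muTest, config, seed = 54)
  labels <- binaryLabel(tol$group_mean)
  expect_true(all(levels(labels) %in% c("acceptable", "toxic")))
  expect_gt(sum(labels == "toxic"), 10)
  expect_gt(sum(labels == "acceptable"), 10)

  calc <- calculateScore(model, study$test)
  aucCalc <- rocCurve(calc, labels)$auc
  aucMeasured <- rocCurve(caTest, labels)$auc
  expect_gt(aucCalc, aucMeasured)
  expect_gt(aucCalc, 0.8)
})
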
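test_that("CA19-9 coding follows the 37 U/mL clinical convention", {
  expect_identical(encodeCa199(c(50, 10, NA, 37, 37.0001)),
                   c(1L, 0L, 0L, 0L, 1L))
  expect_error(encodeCa199(c(5, -1)), "negative")
  expect_error(encodeCa199(10, threshold = 0))
})

test_that("OR and AND combinations behave as documented", {
  sc <- c(a = 0.3, b = 0.9, c = 0.1)
  expect_equal(combineOr(sc, c(a = 1, b = 0, c = 0)),
               c(a = 1.3, b = 0.9, c = 0.1))
  expect_equal(combineAnd(sc, c(a = 0, b = 1, c = 1)),
               c(a = 0, b = 0.9, c = 0.1))
  # all-zero codes leave the OR ranking (and AUROC) unchanged
  lab <- c("PDAC", "PDAC", "CTR")
  expect_equal(auroc(rocEvaluate(combineOr(sc, c(a = 0, b = 0, c = 0)), lab)),
               auroc(rocEvaluate(sc, lab)))
  # all-one codes leave AND identical to the microbiome-only scores
  expect_identical(combineAnd(sc, c(a = 1, b = 1, c = 1)), sc)
  # an uninformative constant code never changes the OR AUROC
  expect_equal(auroc(rocEvaluate(combineOr(sc, c(a = 1, b = 1, c = 1)), lab)),
               auroc(rocEvaluate(sc, lab)))
  expect_error(combineOr(sc, c(1, 0)), "same samples")
  expect_error(combineOr(sc, c(a = 1, b = NA, c = 0)), "0/1")
  expect_error(combineOr(sc, c(x = 1, y = 0, z = 0)), "identifiers")
})

test_that("fusing complementary signals improves discrimination in simulation", {
  set.seed(55)
  n <- 300
  lab <- rep(c("PDAC", "CTR"), each = n / 2)
  micro <- plogis(ifelse(lab == "PDAC", rnorm(n / 2, 0.8), rnorm(n / 2, -0.8)))
  names(micro) <- sprintf("s%03d", seq_len(n))
  code <- simulateCa199(lab, seed = 9)$code
  names(code) <- names(micro)
  aM <- auroc(rocEvaluate(micro, lab))
  expect_gte(auroc(rocEvaluate(combineOr(micro, code), lab)), aM)
  # a perfect code makes the AND combination at least as good
  perfect <- setNames(as.integer(lab == "PDAC"), names(micro))
  expect_gte(auroc(rocEvaluate(combineAnd(micro, perfect), lab)), aM)
})

test_that("threshold calibration hits the target FPR by order statistics", {
  # 10 distinct scores: exactly one exceeds the threshold
  s10 <- (1:10) / 10
  cal <- calibrateThreshold(s10, targetSpecificity = 0.90)
  expect_equal(sum(s10 > cal@threshold), 1L)
  expect_equal(cal@achievedFprTrain, 0.10)
  # 50 controls at 90% target: 5 flagged
  set.seed(8)
  s50 <- runif(50)
  cal50 <- calibrateThreshold(s50)
  expect_equal(sum(s50 > cal50@threshold), 5L)
  expect_equal(cal50@achievedFprTrain, 0.10)
  # all controls at zero: smallest t with FPR 0 is 0
  cal0 <- calibrateThreshold(rep(0, 20))
  expect_equal(cal0@threshold, 0)
  expect_equal(cal0@achievedFprTrain, 0)
  # monotonicity: raising the target never lowers the threshold
  t1 <- calibrateThreshold(s50, targetSpecificity = 0.80)@threshold
  t2 <- calibrateThreshold(s50, targetSpecificity = 0.90)@threshold
  t3 <- calibrateThreshold(s50, targetSpecificity = 0.98)@threshold
  expect_true(t1 <= t2 && t2 <= t3)
  expect_error(calibrateThreshold(runif(5)), "at least 10")
  expect_warning(calibrateThreshold(runif(12), targetSpecificity = 0.99),
                 "granularity")
})

test_that("evaluating the calibration scores reproduces the achieved FPR", {
  set.seed(19)
  scores <- c(runif(40, 0.4, 1), runif(60, 0, 0.6))
  names(scores) <- sprintf("s%03d", 1:100)
  status <- rep(c("PDAC", "CTR"), c(40, 60))
  cal <- calibrateThreshold(scores[status == "CTR"])
  ev <- evaluateScores(scores, status, cal, cohortLabel = "train")
  expect_equal(ev$rate[ev$status == "CTR"], cal@achievedFprTrain)
  expect_equal(ev$n[ev$status == "PDAC"], 40L)
  expect_true(all(ev$n_flagged <= ev$n))
})

test_that("external evaluation is frozen: order-invariant and reproducible", {
  spec <- smallSpec(nSpecies = 50L, nCases = 20L, nControls = 20L, seed = 95L)
  co <- generateCohort(spec)
  f <- filterModelFeatures(filterTaxa(co))
  labels <- sampleData(co)$group
  ens <- trainEnsemble(f, labels, nRepeats = 2, nFolds = 5, seed = 14)
  cal <- calibrateThreshold(cvScores(ens)[labels == "CTR"])
  ext <- generateExternalPanel(spec, data.frame(
    label = "OD", diseaseType = "other_disease", n = 25, batchSeed = 3))[[1]]
  ev1 <- evaluateExternal(ens, cal, ext)
  ev2 <- evaluateExternal(ens, cal, ext)
  expect_identical(ev1, ev2)
  # shuffled sample order: identical per-sample scores
  shuf <- ext[, sample(ncol(ext))]
  s1 <- attr(ev1, "scores")
  s2 <- scoreSamples(ens, shuf)
  expect_identical(s2[names(s1)], s1)
  # extra features are ignored
  extra <- rbind(abundances(ext),
                 novel = runif(ncol(ext), 0, 1e-3))
  expect_identical(scoreSamples(ens, extra), s1)
  # pooled non-PDAC row appears when statuses are mixed
  evMix <- evaluateScores(setNames(runif(30), paste0("x", 1:30)),
                          rep(c("PDAC", "CTR", "CP"), 10),
                          cal, cohortLabel = "mix")
  expect_true("nonPDAC" %in% evMix$status)
  nonRow <- evMix[evMix$status == "nonPDAC", ]
  expect_equal(nonRow$n, 20L)
})

test_that("covariate diagnostics recover planted associations and nulls", {
  set.seed(23)
  n <- 80
  md <- data.frame(age = sample(40:85, n, TRUE),
                   sex = sample(c("F", "M"), n, TRUE),
                   depth = round(runif(n, 1e6, 5e7)))
  # score equal to age: Spearman rho = 1
  d1 <- scoreCovariateDiagnostics(as.numeric(md$age), md)
  expect_equal(d1$estimate[d1$covariate == "age"], 1)
  # independent score: no strong association
  d2 <- scoreCovariateDiagnostics(runif(n), md)
  expect_lt(abs(d2$estimate[d2$covariate == "age"]), 0.35)
  # small worked table matches Pearson-on-ranks
  sc <- c(0.1, 0.9, 0.4, 0.8, 0.2, 0.6)
  age <- c(41, 78, 55, 70, 44, 61)
  d3 <- scoreCovariateDiagnostics(sc, data.frame(age = age))
  expect_equal(d3$estimate[d3$covariate == "age"],
               cor(rank(sc), rank(age)))
  # constant covariate reported as NA
  d4 <- scoreCovariateDiagnostics(sc, data.frame(age = rep(50, 6),
                                                 sex = rep("F", 6)))
  expect_true(all(is.na(d4$estimate)))
})
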
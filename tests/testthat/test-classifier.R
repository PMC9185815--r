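test_that("cross-validation schemes partition, stratify and reproduce", {
  labels <- rep(c("PDAC", "CTR"), each = 50)
  sch <- makeCvScheme(labels, nRepeats = 10, nFolds = 10, seed = 4)
  # every fold size 10; each sample tested exactly once per repeat
  for (r in 1:10) expect_true(all(table(sch@assignment[, r]) == 10))
  # stratification: per-fold class ratio within +-1 of global
  for (r in 1:10) for (k in 1:10) {
    inFold <- labels[sch@assignment[, r] == k]
    expect_lte(abs(sum(inFold == "PDAC") - 5), 1)
  }
  expect_identical(makeCvScheme(labels, nRepeats = 10, nFolds = 10, seed = 4),
                   sch)
  # uneven 40/60 split still balances within +-1
  lab2 <- rep(c("PDAC", "CTR"), times = c(40, 60))
  sch2 <- makeCvScheme(lab2, nFolds = 10, seed = 9)
  for (r in 1:10) for (k in 1:10)
    expect_lte(abs(sum(lab2[sch2@assignment[, r] == k] == "PDAC") - 4), 1)
  expect_error(makeCvScheme(rep(c("PDAC", "CTR"), times = c(7, 93)),
                            nFolds = 10), "smallest class")
})

test_that("enrichment filter keeps exactly the features with AUROC >= 0.5", {
  set.seed(12)
  m <- matrix(rnorm(30 * 24), nrow = 30,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:24)))
  lab <- rep(c("PDAC", "CTR"), each = 12)
  keep <- enrichmentFilter(m, lab)
  oracle <- rownames(m)[vapply(seq_len(nrow(m)), function(j)
    naiveAuroc(m[j, ], lab == "PDAC") >= 0.5, NA)]
  expect_identical(keep, oracle)
  # boundary: an anti-associated feature is excluded, an enriched one kept
  m2 <- rbind(anti = c(rep(0, 12), rep(1, 12)), pro = c(rep(1, 12), rep(0, 12)))
  colnames(m2) <- colnames(m)
  expect_identical(enrichmentFilter(m2, lab), "pro")
})

test_that("the ensemble recovers a strong synthetic signal with robust features", {
  spec <- smallSpec(nSpecies = 80L, nCases = 30L, nControls = 30L, seed = 61L)
  co <- generateCohort(spec)
  f <- filterModelFeatures(filterTaxa(co))
  labels <- sampleData(co)$group
  ens <- trainEnsemble(f, labels, nRepeats = 3, nFolds = 5, seed = 2)
  expect_s4_class(ens, "TrainedEnsemble")
  expect_length(foldModels(ens), 15L)
  expect_true(all(cvScores(ens) >= 0 & cvScores(ens) <= 1))
  expect_gt(auroc(rocEvaluate(cvScores(ens), labels)), 0.8)
  # determinism
  ens2 <- trainEnsemble(f, labels, nRepeats = 3, nFolds = 5, seed = 2)
  expect_identical(cvScores(ens2), cvScores(ens))
  # cv scores invariant to sample order (same scheme applied by sample id)
  expect_identical(sort(names(cvScores(ens))), sort(sampleIds(f)))
})

test_that("a single perfectly separating feature reaches robustness 1", {
  set.seed(77)
  p <- 10; n <- 40
  m <- matrix(runif(p * n, 1e-4, 1e-3), nrow = p,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n)))
  lab <- rep(c("PDAC", "CTR"), each = n / 2)
  m[1, lab == "PDAC"] <- runif(n / 2, 1e-2, 2e-2)  # clean separation
  ens <- trainEnsemble(m, lab, nRepeats = 2, nFolds = 5, seed = 3)
  expect_equal(unname(robustness(ens)["f01"]), 1)
  expect_gt(auroc(rocEvaluate(cvScores(ens), lab)), 0.95)
})

test_that("null-label ensembles score near chance", {
  spec <- smallSpec(nSpecies = 60L, nCases = 25L, nControls = 25L,
                    effectEnriched = 1 + 1e-9, effectDepleted = 1 - 1e-9,
                    seed = 71L)
  co <- generateCohort(spec)
  f <- filterModelFeatures(filterTaxa(co))
  labels <- sampleData(co)$group
  ens <- trainEnsemble(f, labels, nRepeats = 3, nFolds = 5, seed = 5)
  a <- auroc(rocEvaluate(cvScores(ens), labels))
  expect_gt(a, 0.3)
  expect_lt(a, 0.7)
})

test_that("model-2 fold models obey the enrichment constraint on every fold", {
  spec <- smallSpec(nSpecies = 50L, nCases = 20L, nControls = 20L, seed = 81L)
  co <- generateCohort(spec)
  f <- filterModelFeatures(filterTaxa(co))
  labels <- sampleData(co)$group
  m <- abundances(f)
  ens <- trainEnsemble(f, labels, variant = "enrichment_constrained",
                       nRepeats = 2, nFolds = 5, seed = 6)
  for (fm in foldModels(ens)) {
    if (fm$degenerate) next
    expect_true(all(names(fm$coef) %in% fm$features))
    # recompute the training-fold AUROC of every selected feature
    trainIdx <- setdiff(seq_len(ncol(m)), fm$testIdx)
    np <- new("NormalizationParams", featureIds = rownames(m),
              pseudocount = 1e-5, centre = fm$centre, scale = fm$scale)
    Ztr <- applyFrozen(np, m[, trainIdx])
    for (feat in names(fm$coef))
      expect_gte(singleFeatureAUROC(Ztr[feat, ], labels[trainIdx]), 0.5)
  }
})

test_that("an empty enrichment subset degenerates to the constant predictor 0.5", {
  # on a raw (uncentred) matrix an all-anti-associated fold is possible
  set.seed(99)
  m <- matrix(runif(8 * 30, 1e-4, 1e-3), nrow = 8,
              dimnames = list(sprintf("f%02d", 1:8), sprintf("s%02d", 1:30)))
  lab <- rep(c("PDAC", "CTR"), each = 15)
  m[, lab == "CTR"] <- m[, lab == "CTR"] + 5e-3
  expect_length(enrichmentFilter(m, lab), 0L)
  # NOTE: after within-sample clr the per-sample feature differences sum to
  # zero, so a fold where EVERY feature is depleted cannot generically arise;
  # the degenerate branch is defensive. Exercise its scoring path directly.
  np <- new("NormalizationParams", featureIds = rownames(m),
            pseudocount = 1e-5,
            centre = rep(0, 8), scale = rep(1, 8))
  sch <- makeCvScheme(lab, nRepeats = 1, nFolds = 5, seed = 1)
  fmDegen <- list(repeatIdx = 1L, fold = 1L,
                  coef = setNames(numeric(0), character(0)), intercept = 0,
                  cost = NA_real_, features = character(), degenerate = TRUE,
                  centre = rep(0, 8), scale = rep(1, 8), testIdx = 1:6)
  ens <- new("TrainedEnsemble", foldModels = list(fmDegen), normParams = np,
             robustness = setNames(rep(0, 8), rownames(m)),
             cvScores = setNames(rep(0.5, 30), colnames(m)),
             variant = "enrichment_constrained", scheme = sch,
             caseLabel = "PDAC", controlLabel = "CTR")
  expect_true(all(scoreSamples(ens, m) == 0.5))
})

test_that("fold fitting never touches test-fold samples (tamper test)", {
  spec <- smallSpec(nSpecies = 30L, nCases = 15L, nControls = 15L, seed = 91L)
  co <- generateCohort(spec)
  m <- abundances(filterModelFeatures(filterTaxa(co)))
  labels <- sampleData(co)$group
  sch <- makeCvScheme(labels, nRepeats = 2, nFolds = 5, seed = 10)
  base <- trainEnsemble(m, labels, scheme = sch,
                        variant = "enrichment_constrained", seed = 10)
  folds <- expand.grid(r = 1:2, k = 1:5)
  set.seed(123)
  for (i in sample(nrow(folds), 6)) {
    r <- folds$r[i]; k <- folds$k[i]
    testIdx <- which(sch@assignment[, r] == k)
    tampered <- m
    victim <- testIdx[1]
    tampered[, victim] <- rev(tampered[, victim]) * 3 + 1e-3  # gross perturbation
    tamperedRun <- trainEnsemble(tampered, labels, scheme = sch,
                                 variant = "enrichment_constrained", seed = 10)
    fmIdx <- (r - 1) * 5 + k
    fb <- foldModels(base)[[fmIdx]]
    ft <- foldModels(tamperedRun)[[fmIdx]]
    # the tampered sample is in this fold's TEST set: fitted normalization,
    # enrichment subset and coefficients must be unchanged
    expect_identical(ft$centre, fb$centre)
    expect_identical(ft$scale, fb$scale)
    expect_identical(ft$features, fb$features)
    expect_identical(ft$coef, fb$coef)
    expect_identical(ft$cost, fb$cost)
  }
})

test_that("ROC evaluation matches pair counting, bootstrap CI and the trivial cases", {
  expect_equal(auroc(rocEvaluate(c(1, 1, 0, 0), c("PDAC", "PDAC", "CTR", "CTR"))), 1)
  flat <- rocEvaluate(rep(0.4, 6), rep(c("PDAC", "CTR"), 3))
  expect_equal(auroc(flat), 0.5)
  expect_equal(nrow(flat@points), 2L)
  # 6-point toy set: AUROC equals the pair-counting oracle
  sc <- c(0.9, 0.62, 0.58, 0.6, 0.3, 0.1)
  lab <- c("PDAC", "PDAC", "PDAC", "CTR", "CTR", "CTR")
  rc <- rocEvaluate(sc, lab)
  expect_equal(auroc(rc), naiveAuroc(sc, lab == "PDAC"))
  expect_true(all(diff(rc@points$fpr) >= 0))
  expect_true(all(diff(rc@points$tpr) >= 0))
  expect_true(rc@ciLow <= auroc(rc) && auroc(rc) <= rc@ciHigh)
  # DeLong CI close to a bootstrap CI on a larger sample
  set.seed(2024)
  n <- 60
  lab2 <- rep(c("PDAC", "CTR"), each = n / 2)
  sc2 <- ifelse(lab2 == "PDAC", rnorm(n / 2, 1), rnorm(n / 2, 0))
  rc2 <- rocEvaluate(sc2, lab2)
  boots <- replicate(800, {
    idx1 <- sample(which(lab2 == "PDAC"), replace = TRUE)
    idx0 <- sample(which(lab2 == "CTR"), replace = TRUE)
    naiveAuroc(c(sc2[idx1], sc2[idx0]),
               rep(c(TRUE, FALSE), c(length(idx1), length(idx0))))
  })
  bci <- quantile(boots, c(0.025, 0.975))
  expect_lt(abs(rc2@ciLow - bci[[1]]), 0.03)
  expect_lt(abs(rc2@ciHigh - bci[[2]]), 0.03)
  expect_error(rocEvaluate(1:4, rep("PDAC", 4)), "two levels")
})

test_that("ensemble JSON artifacts reapply exactly", {
  spec <- smallSpec(nSpecies = 40L, nCases = 15L, nControls = 15L, seed = 93L)
  co <- generateCohort(spec)
  f <- filterModelFeatures(filterTaxa(co))
  labels <- sampleData(co)$group
  ens <- trainEnsemble(f, labels, nRepeats = 2, nFolds = 5, seed = 12)
  tf <- withr::local_tempfile(fileext = ".json")
  writeEnsembleJSON(ens, tf)
  back <- readEnsembleJSON(tf)
  expect_identical(variant(back), variant(ens))
  expect_equal(cvScores(back), cvScores(ens))
  expect_equal(robustness(back), robustness(ens))
  ext <- generateExternalPanel(spec, data.frame(
    label = "HC", diseaseType = "healthy", n = 12, batchSeed = 5))[[1]]
  expect_equal(scoreSamples(back, ext), scoreSamples(ens, ext), tolerance = 1e-12)
})
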
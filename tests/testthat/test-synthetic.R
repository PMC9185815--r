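test_that("generated cohorts are closed, labelled and deterministic", {
  spec <- smallSpec(seed = 11L)
  co <- generateCohort(spec)
  m <- abundances(co)
  expect_equal(unname(colSums(m)), rep(1, ncol(m)), tolerance = 1e-12)
  expect_true(all(m >= 0))
  md <- sampleData(co)
  expect_setequal(unique(md$group), c("PDAC", "CTR"))
  expect_equal(sum(md$group == "PDAC"), 20L)
  expect_true(all(is.na(md$stage[md$group == "CTR"])))
  expect_true(all(md$stage[md$group == "PDAC"] %in% c("I", "II", "III", "IV")))
  # byte-identical regeneration under the same seed
  co2 <- generateCohort(smallSpec(seed = 11L))
  expect_identical(abundances(co2), m)
  expect_identical(sampleData(co2), md)
  # a different seed changes the draw
  expect_false(identical(abundances(generateCohort(smallSpec(seed = 12L))), m))
})

test_that("generator matches an independent Monte-Carlo oracle of the sampling formula", {
  spec <- smallSpec(nSpecies = 40L, nCases = 400L, nControls = 400L,
                    sparsity = 0.1, seed = 21L)
  co <- generateCohort(spec)
  md <- sampleData(co)
  m <- abundances(co)
  isCase <- md$group == "PDAC"
  # oracle: re-simulate the generative equations independently (plain R,
  # own RNG stream), then compare group mean relative abundances
  oracle <- local({
    set.seed(987654)
    nrep <- 2000L
    mu <- spec@baselineLogMean; s <- spec@baselineLogSd
    simGroup <- function(case) {
      acc <- matrix(0, nrow = spec@nSpecies, ncol = nrep)
      for (i in seq_len(nrep)) {
        x <- 10^(mu + s * rnorm(spec@nSpecies))
        x[runif(spec@nSpecies) < spec@sparsity] <- 0
        if (case) {
          x[spec@enrichedSet] <- x[spec@enrichedSet] * spec@effectEnriched
          x[spec@depletedSet] <- x[spec@depletedSet] * spec@effectDepleted
        }
        acc[, i] <- x / sum(x)
      }
      rowMeans(acc)
    }
    list(case = simGroup(TRUE), ctrl = simGroup(FALSE))
  })
  expect_equal(unname(rowMeans(m[, isCase])), oracle$case, tolerance = 0.25)
  expect_equal(unname(rowMeans(m[, !isCase])), oracle$ctrl, tolerance = 0.25)
  expect_gt(cor(rowMeans(m[, isCase]), oracle$case), 0.9)
  # every enriched species higher in cases, both in the draw and the oracle
  enr <- spec@enrichedSet
  expect_true(all(rowMeans(m[enr, isCase]) > rowMeans(m[enr, !isCase])))
  expect_true(all(oracle$case[enr] > oracle$ctrl[enr]))
})

test_that("with all effects at 1 the groups are exchangeable", {
  spec <- smallSpec(nSpecies = 200L, nCases = 40L, nControls = 40L,
                    effectEnriched = 1 + 1e-12, effectDepleted = 1 - 1e-12,
                    sparsity = 0, seed = 31L)
  co <- generateCohort(spec)
  labels <- sampleData(co)$group
  scr <- wilcoxonScreen(co, labels)
  ks <- suppressWarnings(ks.test(scr$p_raw, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(scr$p_adj < 0.05), 0.05)
})

test_that("empirical generalised fold change recovers the enriched effect", {
  spec <- smallSpec(nSpecies = 200L, nCases = 4000L, nControls = 4000L,
                    sparsity = 0, seed = 41L)
  co <- generateCohort(spec)
  md <- sampleData(co)
  m <- abundances(co)
  isCase <- md$group == "PDAC"
  target <- log10(spec@effectEnriched)
  gfcs <- vapply(spec@enrichedSet, function(j)
    generalizedFoldChange(m[j, isCase], m[j, !isCase]), 0)
  expect_true(all(gfcs > 0))
  expect_true(all(abs(gfcs - target) < 0.2 * target))
})

test_that("external panel applies the documented effect structure", {
  spec <- smallSpec(seed = 51L)
  defs <- data.frame(label = c("OD1", "HC1", "PD1"),
                     diseaseType = c("other_disease", "healthy", "pdac_like"),
                     n = c(10, 10, 10), batchSeed = c(1, 2, 3))
  panel <- generateExternalPanel(spec, defs)
  expect_named(panel, c("OD1", "HC1", "PD1"))
  tOD <- S4Vectors::metadata(panel$OD1)$truth
  expect_false(tOD$enrichedEffectApplied)
  expect_true(tOD$depletedEffectApplied)
  expect_length(tOD$enrichedSet, 0L)
  tHC <- S4Vectors::metadata(panel$HC1)$truth
  expect_false(tHC$depletedEffectApplied)
  tPD <- S4Vectors::metadata(panel$PD1)$truth
  expect_true(tPD$enrichedEffectApplied && tPD$depletedEffectApplied)
  expect_true(all(startsWith(sampleData(panel$OD1)$group, "OTHER:")))
  expect_true(all(sampleData(panel$HC1)$group == "CTR"))
  # regeneration with the same defs is identical
  panel2 <- generateExternalPanel(spec, defs)
  expect_identical(lapply(panel2, abundances), lapply(panel, abundances))
  # with batchLogSd = 0 a healthy cohort is exchangeable with training controls
  spec0 <- smallSpec(nSpecies = 150L, nCases = 30L, nControls = 30L,
                     batchLogSd = 0, sparsity = 0, seed = 52L)
  co <- generateCohort(spec0)
  hc <- generateExternalPanel(spec0, data.frame(
    label = "HC", diseaseType = "healthy", n = 30, batchSeed = 9))[[1]]
  ctr <- abundances(co)[, sampleData(co)$group == "CTR"]
  comb <- cbind(ctr, abundances(hc))
  scr <- wilcoxonScreen(comb, rep(c("a", "b"), each = 30), caseLabel = "a")
  expect_gt(suppressWarnings(ks.test(scr$p_raw, "punif"))$p.value, 0.01)
})

test_that("invalid generator specifications are rejected", {
  expect_error(smallSpec(enrichedSet = 1:5, depletedSet = 3:8), "disjoint")
  expect_error(smallSpec(effectEnriched = 0.9), "effectEnriched")
  expect_error(smallSpec(effectDepleted = 1.5), "effectDepleted")
  expect_error(smallSpec(sparsity = 1.2), "probabilities")
  expect_error(syntheticSpec(nSpecies = 10, nCases = 5, nControls = 5,
                             enrichedSet = 1:8, depletedSet = 9:12),
               "outside 1..nSpecies")
  expect_error(generateExternalPanel(smallSpec(), list()), "at least one")
})

test_that("simulated CA19-9 honours its operating characteristics", {
  # perfect marker equals the case indicator
  lab <- rep(c("PDAC", "CTR"), each = 50)
  perfect <- simulateCa199(lab, sensitivity = 1, specificity = 1, seed = 1)
  expect_identical(perfect$code, as.integer(lab == "PDAC"))
  # defaults: empirical rates near 0.80 / 0.75 within binomial error (n=5000)
  cases <- simulateCa199(rep("PDAC", 5000), seed = 1)
  ctrls <- simulateCa199(rep("CTR", 5000), seed = 2)
  expect_lt(abs(mean(cases$code) - 0.80), 0.02)
  expect_lt(abs((1 - mean(ctrls$code)) - 0.75), 0.02)
  # levels are consistent with the code at the 37 U/mL convention
  expect_identical(encodeCa199(cases$level), cases$code)
  # missingness codes to 0
  mis <- simulateCa199(rep("PDAC", 2000), missingFrac = 0.3, seed = 3)
  expect_true(all(mis$code[is.na(mis$level)] == 0L))
  expect_lt(abs(mean(is.na(mis$level)) - 0.3), 0.03)
})
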
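#' Specify a synthetic case-control metagenomic cohort
#'
#' Builds a [SyntheticSpec-class] describing the generative model used by
#' [generateCohort()] and [generateExternalPanel()]: species abundances are
#' log10-normal with per-species baselines, Bernoulli structural zeros,
#' multiplicative case effects on an enriched and a depleted marker set, and
#' per-sample compositional closure to sum 1. Per-species baselines are drawn
#' reproducibly from `seed` unless supplied.
#'
#' Defaults describe a filtered stool species profile: 200 species with
#' baseline log10 relative abundances uniform on \[-4, -2\] (before closure),
#' 0.7 log10 units of between-subject variation (the typical scale for
#' prevalent stool species), 10% structural zeros (species passing an
#' abundance-prevalence screen are mostly prevalent; the zeros exercise the
#' pseudocount path without dominating between-group variation), 15 species
#' enriched 4-fold and 12 depleted to 0.25-fold in cases, 60 cases vs 60
#' controls, and a binary CA19-9 marker with sensitivity 0.80 and
#' specificity 0.75.
#'
#' @param nSpecies,nCases,nControls cohort dimensions.
#' @param baselineLogMean,baselineLogSd per-species baseline parameters on the
#'   log10 relative-abundance scale; scalars are recycled, `NULL` baselines
#'   are drawn from U(-4, -2) under `seed`.
#' @param sparsity probability of a structural zero per species x sample.
#' @param enrichedSet,depletedSet disjoint species indices carrying the case
#'   effects.
#' @param effectEnriched fold change > 1 applied to enriched species in cases.
#' @param effectDepleted fold change in (0,1) applied to depleted species in
#'   cases (and in "other disease" external cohorts).
#' @param batchLogSd sd of the per-cohort per-species log10 batch shift used
#'   by [generateExternalPanel()].
#' @param ca199Sensitivity,ca199Specificity,ca199Missing operating
#'   characteristics of the simulated binary CA19-9 marker.
#' @param stageProbs tumour-stage probabilities over I-IV for cases.
#' @param ageCaseShift additive shift (years) of case ages, 0 by default
#'   (cases and controls age-matched); a nonzero value reproduces the
#'   age-association diagnostic of external validation.
#' @param seed integer master seed; all sub-streams derive from it.
#'
#' @return A validated [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(nSpecies = 50, nCases = 20, nControls = 20, seed = 7)
#' spec
#' @export
syntheticSpec <- function(nSpecies = 200L, nCases = 60L, nControls = 60L,
                          baselineLogMean = NULL, baselineLogSd = 0.7,
                          sparsity = 0.1,
                          enrichedSet = seq_len(min(15L, nSpecies)),
                          depletedSet = seq_len(min(12L, max(0L, nSpecies - 15L))) + 15L,
                          effectEnriched = 4, effectDepleted = 0.25,
                          batchLogSd = 0.2,
                          ca199Sensitivity = 0.80, ca199Specificity = 0.75,
                          ca199Missing = 0,
                          stageProbs = c(I = 0.20, II = 0.24, III = 0.28, IV = 0.28),
                          ageCaseShift = 0, seed = 42L) {
  nSpecies <- as.integer(nSpecies)
  if (is.null(baselineLogMean))
    baselineLogMean <- .withSeed(.deriveSeed(seed, 101L),
                                 runif(nSpecies, min = -4, max = -2))
  baselineLogMean <- rep_len(baselineLogMean, nSpecies)
  baselineLogSd <- rep_len(baselineLogSd, nSpecies)
  new("SyntheticSpec",
      nSpecies = nSpecies, nCases = as.integer(nCases),
      nControls = as.integer(nControls),
      baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
      sparsity = sparsity,
      enrichedSet = as.integer(enrichedSet), depletedSet = as.integer(depletedSet),
      effectEnriched = effectEnriched, effectDepleted = effectDepleted,
      batchLogSd = batchLogSd,
      ca199Sensitivity = ca199Sensitivity, ca199Specificity = ca199Specificity,
      ca199Missing = ca199Missing,
      stageProbs = stageProbs / sum(stageProbs),
      ageCaseShift = ageCaseShift, seed = as.integer(seed))
}

# Core sampler: abundance for species j in sample i is zero with probability
# `sparsity`, else 10^(mu_j + batch_j + sd_j * z), multiplied by the case
# effects where applicable, then closed to sum 1 per sample.
.sampleProfiles <- function(spec, n, isCase, applyEnriched, applyDepleted,
                            batchShift, seed, idPrefix) {
  p <- spec@nSpecies
  m <- .withSeed(seed, {
    z <- matrix(rnorm(p * n), nrow = p)
    keep <- matrix(runif(p * n) >= spec@sparsity, nrow = p)
    x <- 10^(spec@baselineLogMean + batchShift + spec@baselineLogSd * z)
    x * keep
  })
  eff <- rep(1, p)
  if (applyEnriched) eff[spec@enrichedSet] <- spec@effectEnriched
  if (applyDepleted) eff[spec@depletedSet] <- spec@effectDepleted
  m[, isCase] <- m[, isCase, drop = FALSE] * eff
  cs <- colSums(m)
  if (any(cs == 0))
    stop("generated an all-zero sample; lower sparsity or increase nSpecies")
  m <- sweep(m, 2L, cs, "/")
  dimnames(m) <- list(sprintf("sp_%04d", seq_len(p)),
                      sprintf("%s_%04d", idPrefix, seq_len(n)))
  m
}

.sampleMetadata <- function(spec, sampleIds, group, cohortLabel, seed) {
  n <- length(sampleIds)
  isCase <- group == "PDAC"
  .withSeed(seed, {
    stage <- rep(NA_character_, n)
    stage[isCase] <- sample(names(spec@stageProbs), sum(isCase),
                            replace = TRUE, prob = spec@stageProbs)
    age <- round(rnorm(n, mean = 64, sd = 11) + spec@ageCaseShift * isCase)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    depth <- round(rlnorm(n, meanlog = log(3e7), sdlog = 0.35))
    data.frame(sample_id = sampleIds, group = group, stage = stage,
               age = age, sex = sex, cohort = cohortLabel,
               depth = depth, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic case-control cohort
#'
#' Draws a cohort under `spec`: `nCases` PDAC samples carrying both marker-set
#' effects and `nControls` unaffected controls, with stage, age, sex,
#' sequencing depth and a simulated binary CA19-9 marker in the sample
#' metadata. Deterministic given `spec@seed`.
#'
#' @param spec a [SyntheticSpec-class] from [syntheticSpec()].
#' @param cohortLabel character scalar naming the cohort (sample-id prefix).
#' @return A [MicrobiomeProfile-class] whose columns sum to 1, with metadata in
#'   `sampleData(x)` and the generative truth (marker sets, effects, batch
#'   shift) in `metadata(x)$truth`.
#' @examples
#' cohort <- generateCohort(syntheticSpec(nSpecies = 60, nCases = 15,
#'                                        nControls = 15, seed = 3))
#' cohort
#' table(sampleData(cohort)$group)
#' @export
generateCohort <- function(spec, cohortLabel = "ES") {
  validObject(spec)
  n <- spec@nCases + spec@nControls
  isCase <- c(rep(TRUE, spec@nCases), rep(FALSE, spec@nControls))
  m <- .sampleProfiles(spec, n, isCase, applyEnriched = TRUE,
                       applyDepleted = TRUE, batchShift = rep(0, spec@nSpecies),
                       seed = .deriveSeed(spec@seed, 1L), idPrefix = cohortLabel)
  group <- ifelse(isCase, "PDAC", "CTR")
  md <- .sampleMetadata(spec, colnames(m), group, cohortLabel,
                        seed = .deriveSeed(spec@seed, 2L))
  ca <- simulateCa199(group, sensitivity = spec@ca199Sensitivity,
                      specificity = spec@ca199Specificity,
                      missingFrac = spec@ca199Missing,
                      seed = .deriveSeed(spec@seed, 3L))
  md$ca199_level <- ca$level
  md$ca199_code <- ca$code
  truth <- list(enrichedSet = rownames(m)[spec@enrichedSet],
                depletedSet = rownames(m)[spec@depletedSet],
                effectEnriched = spec@effectEnriched,
                effectDepleted = spec@effectDepleted,
                batchLogSd = 0, seed = spec@seed)
  MicrobiomeProfile(m, sampleData = md, truth = truth)
}

#' Generate a panel of external validation cohorts
#'
#' Each external cohort receives an independent per-species batch shift
#' (normal on the log10 scale with sd `spec@batchLogSd`). `"pdac_like"`
#' cohorts carry both marker-set effects, `"other_disease"` cohorts carry
#' ONLY the depleted-set effect (generic dysbiosis without the PDAC-specific
#' enrichment), and `"healthy"` cohorts carry neither.
#'
#' @param spec a [SyntheticSpec-class].
#' @param cohortDefs data.frame (or list of lists) with columns/fields
#'   `label`, `diseaseType` (`"pdac_like"`, `"other_disease"` or `"healthy"`),
#'   `n`, and `batchSeed`.
#' @return Named list of [MicrobiomeProfile-class] cohorts.
#' @examples
#' spec <- syntheticSpec(nSpecies = 60, nCases = 15, nControls = 15, seed = 3)
#' defs <- data.frame(label = c("CD", "HC"),
#'                    diseaseType = c("other_disease", "healthy"),
#'                    n = c(20, 20), batchSeed = c(11, 12))
#' panel <- generateExternalPanel(spec, defs)
#' names(panel)
#' @export
generateExternalPanel <- function(spec, cohortDefs) {
  validObject(spec)
  if (is.data.frame(cohortDefs))
    cohortDefs <- lapply(seq_len(nrow(cohortDefs)),
                         function(i) as.list(cohortDefs[i, ]))
  if (length(cohortDefs) == 0L)
    stop("cohortDefs must define at least one cohort")
  out <- lapply(cohortDefs, function(def) {
    type <- match.arg(def$diseaseType, c("pdac_like", "other_disease", "healthy"))
    n <- as.integer(def$n)
    shift <- if (spec@batchLogSd > 0)
      .withSeed(.deriveSeed(def$batchSeed, 7L),
                rnorm(spec@nSpecies, sd = spec@batchLogSd))
    else rep(0, spec@nSpecies)
    isCase <- rep(type != "healthy", n)
    m <- .sampleProfiles(spec, n, isCase,
                         applyEnriched = type == "pdac_like",
                         applyDepleted = type != "healthy",
                         batchShift = shift,
                         seed = .deriveSeed(def$batchSeed, 8L),
                         idPrefix = def$label)
    group <- switch(type,
                    pdac_like = rep("PDAC", n),
                    other_disease = rep(paste0("OTHER:", def$label), n),
                    healthy = rep("CTR", n))
    md <- .sampleMetadata(spec, colnames(m),
                          ifelse(group == "PDAC", "PDAC", "CTR"),
                          def$label, seed = .deriveSeed(def$batchSeed, 9L))
    md$group <- group
    truth <- list(diseaseType = type,
                  enrichedEffectApplied = type == "pdac_like",
                  depletedEffectApplied = type != "healthy",
                  enrichedSet = if (type == "pdac_like")
                    rownames(m)[spec@enrichedSet] else character(),
                  depletedSet = if (type != "healthy")
                    rownames(m)[spec@depletedSet] else character(),
                  batchLogSd = spec@batchLogSd, batchSeed = def$batchSeed)
    MicrobiomeProfile(m, sampleData = md, truth = truth)
  })
  names(out) <- vapply(cohortDefs, function(d) as.character(d$label), "")
  out
}

#' Simulate the coded CA19-9 serum marker
#'
#' Flags each case positive with probability `sensitivity` and each
#' non-case positive with probability `1 - specificity`, independently.
#' A fraction `missingFrac` of samples gets a missing serum level; the coded
#' marker treats "not available" as 0 (negative), matching the clinical
#' coding convention of [encodeCa199()].
#'
#' @param labels character/factor group labels; `caseLabel` marks cases.
#' @param sensitivity,specificity marker operating characteristics
#'   (defaults 0.80 and 0.75).
#' @param missingFrac fraction of samples with no serum measurement.
#' @param seed integer seed.
#' @param caseLabel the positive-class label (default `"PDAC"`).
#' @return data.frame with `sample` index, simulated serum `level` (U/mL,
#'   `NA` when unavailable) and the binary `code` (1 positive, 0 negative or
#'   not available).
#' @examples
#' sim <- simulateCa199(rep(c("PDAC", "CTR"), each = 500), seed = 1)
#' mean(sim$code[1:500])        # close to the 0.80 sensitivity
#' 1 - mean(sim$code[501:1000]) # close to the 0.75 specificity
#' @export
simulateCa199 <- function(labels, sensitivity = 0.80, specificity = 0.75,
                          missingFrac = 0, seed = 1L, caseLabel = "PDAC") {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            missingFrac >= 0, missingFrac <= 1)
  labels <- as.character(labels)
  isCase <- labels == caseLabel
  n <- length(labels)
  .withSeed(seed, {
    pPos <- ifelse(isCase, sensitivity, 1 - specificity)
    positive <- runif(n) < pPos
    # serum level drawn consistent with the binary call around the 37 U/mL cut
    level <- ifelse(positive, exp(runif(n, log(38), log(1200))),
                    runif(n, 0.5, 37))
    missing <- runif(n) < missingFrac
    level[missing] <- NA_real_
    code <- as.integer(positive & !missing)
    data.frame(sample = seq_len(n), level = level, code = code)
  })
}
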
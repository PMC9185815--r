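#' @import methods
#' @importFrom stats sd quantile rnorm runif rlnorm plogis wilcox.test
#'   p.adjust cor.test na.omit setNames median predict coef
#' @importFrom utils head write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.checkAbundanceAssay <- function(object, assayName, integerValued = FALSE) {
  msg <- character()
  if (!(assayName %in% assayNames(object)))
    msg <- c(msg, sprintf("assay '%s' is required", assayName))
  else {
    m <- assay(object, assayName)
    if (!is.numeric(m)) msg <- c(msg, sprintf("assay '%s' must be numeric", assayName))
    else {
      if (anyNA(m)) msg <- c(msg, "missing values are not allowed")
      else if (any(m < 0)) msg <- c(msg, "negative values are not allowed")
      else if (integerValued && any(m != round(m)))
        msg <- c(msg, "counts must be integer-valued")
    }
  }
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "feature and sample identifiers (dimnames) are required")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicated feature identifiers")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicated sample identifiers")
  }
  msg
}

#' Container for relative-abundance profile tables
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' features x samples relative-abundance matrix in the `"abundance"` assay,
#' per-sample metadata in `colData`, and (for generated cohorts) the
#' ground-truth generative parameters in `metadata(x)$truth`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [MicrobiomeProfile()], [MicrobiomeCounts-class]
#' @export
setClass("MicrobiomeProfile", contains = "SummarizedExperiment")

setValidity("MicrobiomeProfile", function(object) {
  msg <- .checkAbundanceAssay(object, "abundance")
  if (length(msg)) msg else TRUE
})

#' Container for read-count tables
#'
#' As [MicrobiomeProfile-class] but carrying integer read counts in the
#' `"counts"` assay (for example 16S amplicon taxon tables), the input
#' expected by [qcCountTable()] and [hillDiversity()].
#'
#' @export
setClass("MicrobiomeCounts", contains = "SummarizedExperiment")

setValidity("MicrobiomeCounts", function(object) {
  msg <- .checkAbundanceAssay(object, "counts", integerValued = TRUE)
  if (length(msg)) msg else TRUE
})

#' Frozen normalization parameters
#'
#' Records everything needed to reproduce the training-set normalization on
#' new data bit for bit: the model's feature universe, the pseudocount, and
#' the per-feature centre (training mean of clr values) and scale (training
#' sd, n-1 denominator).
#'
#' @slot featureIds character, the ordered model feature universe.
#' @slot pseudocount numeric(1), added before log10 (default 1e-5).
#' @slot centre,scale numeric, per-feature standardization parameters.
#' @export
setClass("NormalizationParams",
  representation(featureIds = "character", pseudocount = "numeric",
                 centre = "numeric", scale = "numeric"))

setValidity("NormalizationParams", function(object) {
  p <- length(object@featureIds)
  msg <- character()
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single positive number")
  if (length(object@centre) != p || length(object@scale) != p)
    msg <- c(msg, "centre and scale must match featureIds in length")
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "featureIds must be unique")
  if (length(object@scale) && any(object@scale <= 0))
    msg <- c(msg, "scale must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Repeated cross-validation scheme
#'
#' Fold assignment for an `nRepeats` x `nFolds` repeated cross-validation:
#' `assignment[i, r]` is the test-fold index of sample `i` in repeat `r`.
#'
#' @export
setClass("CVScheme",
  representation(sampleIds = "character", nRepeats = "integer",
                 nFolds = "integer", assignment = "matrix",
                 stratified = "logical", seed = "integer"))

setValidity("CVScheme", function(object) {
  msg <- character()
  a <- object@assignment
  if (nrow(a) != length(object@sampleIds) || ncol(a) != object@nRepeats)
    msg <- c(msg, "assignment must be n_samples x n_repeats")
  else if (!all(a %in% seq_len(object@nFolds)))
    msg <- c(msg, "fold indices out of range")
  if (length(msg)) msg else TRUE
})

#' Trained repeated-CV LASSO ensemble
#'
#' Holds the per-fold L1-regularised logistic regression models (one per
#' repeat x fold), the full-training-set frozen normalization used for
#' transfer to external data, per-feature robustness (fraction of fold models
#' with a nonzero coefficient), and the mean cross-validated test-fold
#' prediction score per training sample.
#'
#' @slot foldModels list of per-fold model records (coefficients, intercept,
#'   selected cost, fold-level normalization, enrichment subset).
#' @slot normParams [NormalizationParams-class] fitted on all training samples,
#'   used for frozen transfer.
#' @slot robustness named numeric in `[0,1]`.
#' @slot cvScores named numeric in `[0,1]`, mean over repeats of held-out
#'   predicted probabilities.
#' @slot variant `"unconstrained"` (model-1) or `"enrichment_constrained"`
#'   (model-2).
#' @export
setClass("TrainedEnsemble",
  representation(foldModels = "list", normParams = "NormalizationParams",
                 robustness = "numeric", cvScores = "numeric",
                 variant = "character", scheme = "CVScheme",
                 caseLabel = "character", controlLabel = "character"))

setValidity("TrainedEnsemble", function(object) {
  msg <- character()
  if (!object@variant %in% c("unconstrained", "enrichment_constrained"))
    msg <- c(msg, "unknown variant")
  if (length(object@cvScores) &&
      (min(object@cvScores) < 0 || max(object@cvScores) > 1))
    msg <- c(msg, "cvScores must lie in [0,1]")
  if (length(object@robustness) &&
      (min(object@robustness) < 0 || max(object@robustness) > 1))
    msg <- c(msg, "robustness must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Empirical ROC curve with AUROC and DeLong 95% CI
#'
#' @slot points data.frame with columns `threshold`, `fpr`, `tpr`.
#' @slot auroc numeric(1); @slot ciLow,ciHigh DeLong 95% confidence bounds.
#' @export
setClass("RocCurve",
  representation(points = "data.frame", auroc = "numeric",
                 ciLow = "numeric", ciHigh = "numeric"))

#' Decision threshold calibrated to a target specificity
#'
#' @slot threshold numeric(1), smallest score value such that the fraction of
#'   training control scores strictly above it does not exceed
#'   `1 - targetSpecificity`.
#' @slot targetSpecificity numeric(1), default 0.90.
#' @slot achievedFprTrain numeric(1), realized false-positive rate on the
#'   training controls.
#' @export
setClass("ThresholdCalibration",
  representation(threshold = "numeric", targetSpecificity = "numeric",
                 achievedFprTrain = "numeric", nControls = "integer"))

setValidity("ThresholdCalibration", function(object) {
  slack <- if (object@nControls > 0) 1 / object@nControls else 0
  if (object@achievedFprTrain > 1 - object@targetSpecificity + slack + 1e-12)
    "achieved FPR exceeds the target beyond the discreteness allowance"
  else TRUE
})

#' Single-factor PERMANOVA result
#'
#' @slot R2 fraction of distance-matrix sum of squares explained by the
#'   grouping. For semi-metric dissimilarities such as Bray-Curtis the
#'   between-group sum of squares can come out marginally negative under the
#'   null (negative eigenvalues of the Gower-centred matrix), so small
#'   negative values are admitted, as in the standard adonis implementation.
#' @slot F pseudo-F statistic; @slot p permutation p-value.
#' @export
setClass("PermanovaResult",
  representation(R2 = "numeric", F = "numeric", p = "numeric",
                 nPerm = "integer", strata = "character"))

setValidity("PermanovaResult", function(object) {
  msg <- character()
  if (object@R2 < -1 || object@R2 > 1) msg <- c(msg, "R2 must lie in [-1,1]")
  if (object@p < 1 / (object@nPerm + 1) - 1e-12 || object@p > 1)
    msg <- c(msg, "p outside attainable range")
  if (length(msg)) msg else TRUE
})

#' Parameterization of the synthetic cohort generator
#'
#' Full specification of the generative model: per-species log10-normal
#' baselines with Bernoulli structural zeros, a PDAC-enriched and a
#' non-specifically depleted marker set acting multiplicatively in cases,
#' per-cohort per-species log-normal batch shifts, a binary CA19-9 simulator,
#' and stage/confounder metadata. Construct with [syntheticSpec()].
#'
#' @export
setClass("SyntheticSpec",
  representation(nSpecies = "integer", nCases = "integer", nControls = "integer",
                 baselineLogMean = "numeric", baselineLogSd = "numeric",
                 sparsity = "numeric", enrichedSet = "integer",
                 depletedSet = "integer", effectEnriched = "numeric",
                 effectDepleted = "numeric", batchLogSd = "numeric",
                 ca199Sensitivity = "numeric", ca199Specificity = "numeric",
                 ca199Missing = "numeric", stageProbs = "numeric",
                 ageCaseShift = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  probs <- c(sparsity = object@sparsity,
             ca199Sensitivity = object@ca199Sensitivity,
             ca199Specificity = object@ca199Specificity,
             ca199Missing = object@ca199Missing)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    msg <- c(msg, paste("probabilities outside [0,1]:",
                        paste(names(probs)[bad], collapse = ", ")))
  if (length(intersect(object@enrichedSet, object@depletedSet)))
    msg <- c(msg, "enrichedSet and depletedSet must be disjoint")
  if (!(object@effectEnriched > 1))
    msg <- c(msg, "effectEnriched must be > 1")
  if (!(object@effectDepleted > 0 && object@effectDepleted < 1))
    msg <- c(msg, "effectDepleted must lie in (0,1)")
  marked <- union(object@enrichedSet, object@depletedSet)
  if (length(marked) && (min(marked) < 1L || max(marked) > object@nSpecies))
    msg <- c(msg, "marker indices outside 1..nSpecies")
  if (object@nSpecies < length(marked))
    msg <- c(msg, "nSpecies smaller than the marker sets")
  if (length(object@baselineLogMean) != object@nSpecies ||
      length(object@baselineLogSd) != object@nSpecies)
    msg <- c(msg, "baselineLogMean/baselineLogSd must have length nSpecies")
  if (length(object@baselineLogSd) && any(object@baselineLogSd <= 0))
    msg <- c(msg, "baselineLogSd must be positive")
  if (abs(sum(object@stageProbs) - 1) > 1e-8 || any(object@stageProbs < 0))
    msg <- c(msg, "stageProbs must be non-negative and sum to 1")
  if (object@batchLogSd < 0) msg <- c(msg, "batchLogSd must be >= 0")
  if (length(msg)) msg else TRUE
})
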
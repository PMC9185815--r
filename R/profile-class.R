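#' Construct a MicrobiomeProfile or MicrobiomeCounts
#'
#' @param abundance numeric features x samples matrix of relative abundances
#'   (non-negative; rows and columns must be named).
#' @param sampleData optional data.frame / DataFrame of per-sample metadata,
#'   with rownames (or a `sample_id` column) matching `colnames(abundance)`.
#' @param truth optional list of generative ground truth, stored in
#'   `metadata(x)$truth`.
#'
#' @return A [MicrobiomeProfile-class] (or [MicrobiomeCounts-class]) object.
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.1, 0.9), nrow = 2,
#'             dimnames = list(c("spA", "spB"), c("s1", "s2")))
#' MicrobiomeProfile(m)
#' @export
MicrobiomeProfile <- function(abundance, sampleData = NULL, truth = NULL) {
  cd <- .sampleDataFrame(sampleData, colnames(abundance))
  se <- SummarizedExperiment(assays = list(abundance = abundance), colData = cd)
  if (!is.null(truth)) metadata(se)$truth <- truth
  new("MicrobiomeProfile", se)
}

#' @rdname MicrobiomeProfile
#' @param counts integer features x samples matrix of read counts.
#' @export
MicrobiomeCounts <- function(counts, sampleData = NULL) {
  storage.mode(counts) <- if (max(abs(counts)) < .Machine$integer.max)
    "integer" else "double"
  cd <- .sampleDataFrame(sampleData, colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  new("MicrobiomeCounts", se)
}

.sampleDataFrame <- function(sampleData, sampleIds) {
  if (is.null(sampleData))
    return(DataFrame(row.names = sampleIds))
  sd <- as.data.frame(sampleData)
  if (!is.null(sd$sample_id)) rownames(sd) <- sd$sample_id
  if (!setequal(rownames(sd), sampleIds))
    stop("sampleData rows do not match the table's sample identifiers")
  DataFrame(sd[sampleIds, , drop = FALSE])
}

#' @rdname MicrobiomeProfile
#' @param x a MicrobiomeProfile or MicrobiomeCounts.
#' @param ... unused.
#' @export
setMethod("abundances", "MicrobiomeProfile", function(x, ...) assay(x, "abundance"))

#' @rdname MicrobiomeProfile
#' @export
setMethod("abundances", "MicrobiomeCounts", function(x, ...) assay(x, "counts"))

#' @rdname MicrobiomeProfile
#' @export
setMethod("sampleData", "SummarizedExperiment",
          function(x, ...) as.data.frame(colData(x)))

#' @rdname MicrobiomeProfile
#' @export
setMethod("featureIds", "SummarizedExperiment", function(x, ...) rownames(x))

#' @rdname MicrobiomeProfile
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x, ...) colnames(x))

setMethod("show", "MicrobiomeProfile", function(object) {
  cat(sprintf("MicrobiomeProfile: %s x %s\n",
              .fmtCount(nrow(object), "feature"),
              .fmtCount(ncol(object), "sample")))
  if (ncol(colData(object)))
    cat("  sampleData:", paste(colnames(colData(object)), collapse = ", "), "\n")
  if (!is.null(metadata(object)$truth))
    cat("  carries generative ground truth in metadata(x)$truth\n")
})

setMethod("show", "MicrobiomeCounts", function(object) {
  cat(sprintf("MicrobiomeCounts: %s x %s, median depth %.0f reads\n",
              .fmtCount(nrow(object), "taxon"),
              .fmtCount(ncol(object), "sample"),
              stats::median(colSums(assay(object, "counts")))))
})

setMethod("show", "NormalizationParams", function(object) {
  cat(sprintf(paste0("NormalizationParams: %s, pseudocount %.3g ",
                     "(log10 + clr + frozen centre/scale)\n"),
              .fmtCount(length(object@featureIds), "feature"),
              object@pseudocount))
})

setMethod("show", "CVScheme", function(object) {
  cat(sprintf("CVScheme: %d x %d-fold CV over %s%s, seed %d\n",
              object@nRepeats, object@nFolds,
              .fmtCount(length(object@sampleIds), "sample"),
              if (object@stratified) " (stratified)" else "", object@seed))
})

setMethod("show", "TrainedEnsemble", function(object) {
  cat(sprintf("TrainedEnsemble (%s): %s over %s\n", object@variant,
              .fmtCount(length(object@foldModels), "fold model"),
              .fmtCount(length(object@cvScores), "sample")))
  cat(sprintf("  features with robustness > 0.5: %d\n",
              sum(object@robustness > 0.5)))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: AUROC %.3f (95%% CI %.3f-%.3f), %d points\n",
              object@auroc, object@ciLow, object@ciHigh, nrow(object@points)))
})

setMethod("show", "ThresholdCalibration", function(object) {
  cat(sprintf(paste0("ThresholdCalibration: threshold %.4f at target ",
                     "specificity %.2f (achieved training FPR %.3f, n=%d)\n"),
              object@threshold, object@targetSpecificity,
              object@achievedFprTrain, object@nControls))
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA: R2 = %.4f, F = %.3f, p = %.4g (%d permutations%s)\n",
              object@R2, object@F, object@p, object@nPerm,
              if (nzchar(object@strata)) paste0(", strata: ", object@strata) else ""))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d species, %d cases + %d controls; ",
                     "%d enriched x%.2g, %d depleted x%.2g; sparsity %.2f; ",
                     "batch log-sd %.2f; seed %d\n"),
              object@nSpecies, object@nCases, object@nControls,
              length(object@enrichedSet), object@effectEnriched,
              length(object@depletedSet), object@effectDepleted,
              object@sparsity, object@batchLogSd, object@seed))
})

#' @rdname TrainedEnsemble
#' @param object a TrainedEnsemble.
#' @export
setMethod("cvScores", "TrainedEnsemble", function(object) object@cvScores)

#' @rdname TrainedEnsemble
#' @export
setMethod("robustness", "TrainedEnsemble", function(object) object@robustness)

#' @rdname TrainedEnsemble
#' @export
setMethod("foldModels", "TrainedEnsemble", function(object) object@foldModels)

#' @rdname TrainedEnsemble
#' @export
setMethod("normParams", "TrainedEnsemble", function(object) object@normParams)

#' @rdname TrainedEnsemble
#' @export
setMethod("variant", "TrainedEnsemble", function(object) object@variant)

#' @rdname RocCurve
#' @param object a RocCurve.
#' @export
setMethod("auroc", "RocCurve", function(object) object@auroc)
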
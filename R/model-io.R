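#' Serialize / restore a trained ensemble as a single JSON artifact
#'
#' The artifact carries everything needed for exact reapplication on new
#' cohorts: the variant, the frozen normalization parameters (feature list,
#' pseudocount, centre, scale), every fold model as a sparse coefficient map
#' with intercept and selected cost (plus its fold-level normalization for
#' auditability), per-feature robustness, per-sample cross-validation
#' scores, and the CV scheme seed.
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param path output JSON path.
#' @return [writeEnsembleJSON()] returns `path` invisibly;
#'   [readEnsembleJSON()] returns the restored [TrainedEnsemble-class]
#'   (scores from the restored object are identical to the original's).
#' @export
writeEnsembleJSON <- function(ensemble, path) {
  fm <- lapply(ensemble@foldModels, function(f) list(
    repeatIdx = f$repeatIdx, fold = f$fold,
    coef = as.list(f$coef), intercept = f$intercept, cost = f$cost,
    features = f$features, degenerate = isTRUE(f$degenerate),
    centre = f$centre, scale = f$scale, testIdx = f$testIdx))
  obj <- list(
    format = "pdacscreen-ensemble-1",
    variant = ensemble@variant,
    caseLabel = ensemble@caseLabel, controlLabel = ensemble@controlLabel,
    normParams = list(featureIds = ensemble@normParams@featureIds,
                      pseudocount = ensemble@normParams@pseudocount,
                      centre = ensemble@normParams@centre,
                      scale = ensemble@normParams@scale),
    foldModels = fm,
    robustness = as.list(ensemble@robustness),
    cvScores = as.list(ensemble@cvScores),
    scheme = list(sampleIds = ensemble@scheme@sampleIds,
                  nRepeats = ensemble@scheme@nRepeats,
                  nFolds = ensemble@scheme@nFolds,
                  stratified = ensemble@scheme@stratified,
                  seed = ensemble@scheme@seed,
                  assignment = ensemble@scheme@assignment))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeEnsembleJSON
#' @export
readEnsembleJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "pdacscreen-ensemble-1"))
    stop("not a pdacscreen ensemble artifact: ", path)
  np <- new("NormalizationParams",
            featureIds = obj$normParams$featureIds,
            pseudocount = obj$normParams$pseudocount,
            centre = obj$normParams$centre, scale = obj$normParams$scale)
  fm <- lapply(obj$foldModels, function(f) list(
    repeatIdx = f$repeatIdx, fold = f$fold,
    coef = unlist(f$coef) %||% setNames(numeric(0), character(0)),
    intercept = f$intercept, cost = f$cost %||% NA_real_,
    features = as.character(unlist(f$features)),
    degenerate = isTRUE(f$degenerate),
    centre = unlist(f$centre), scale = unlist(f$scale),
    testIdx = as.integer(unlist(f$testIdx))))
  scheme <- new("CVScheme",
                sampleIds = obj$scheme$sampleIds,
                nRepeats = as.integer(obj$scheme$nRepeats),
                nFolds = as.integer(obj$scheme$nFolds),
                assignment = matrix(as.integer(obj$scheme$assignment),
                                    nrow = length(obj$scheme$sampleIds)),
                stratified = isTRUE(obj$scheme$stratified),
                seed = as.integer(obj$scheme$seed))
  new("TrainedEnsemble",
      foldModels = fm, normParams = np,
      robustness = unlist(obj$robustness),
      cvScores = unlist(obj$cvScores),
      variant = obj$variant, scheme = scheme,
      caseLabel = obj$caseLabel, controlLabel = obj$controlLabel)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
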
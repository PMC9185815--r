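#' @rdname MicrobiomeProfile
#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @rdname MicrobiomeProfile
#' @export
setGeneric("sampleData", function(x, ...) standardGeneric("sampleData"))

#' @rdname MicrobiomeProfile
#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @rdname MicrobiomeProfile
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname filterTaxa
#' @export
setGeneric("filterTaxa", function(x, ...) standardGeneric("filterTaxa"))

#' @rdname filterModelFeatures
#' @export
setGeneric("filterModelFeatures",
           function(x, ...) standardGeneric("filterModelFeatures"))

#' @rdname qcCountTable
#' @export
setGeneric("qcCountTable", function(x, ...) standardGeneric("qcCountTable"))

#' @rdname fitNormalization
#' @export
setGeneric("fitNormalization",
           function(x, ...) standardGeneric("fitNormalization"))

#' @rdname applyFrozen
#' @export
setGeneric("applyFrozen",
           function(params, x, ...) standardGeneric("applyFrozen"))

#' @rdname brayCurtis
#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))

#' @rdname hillDiversity
#' @export
setGeneric("hillDiversity", function(x, ...) standardGeneric("hillDiversity"))

#' @rdname wilcoxonScreen
#' @export
setGeneric("wilcoxonScreen",
           function(x, labels, ...) standardGeneric("wilcoxonScreen"))

#' @rdname trainEnsemble
#' @export
setGeneric("trainEnsemble",
           function(x, labels, ...) standardGeneric("trainEnsemble"))

#' @rdname scoreSamples
#' @export
setGeneric("scoreSamples",
           function(ensemble, x, ...) standardGeneric("scoreSamples"))

#' @rdname TrainedEnsemble
#' @export
setGeneric("cvScores", function(object) standardGeneric("cvScores"))

#' @rdname TrainedEnsemble
#' @export
setGeneric("robustness", function(object) standardGeneric("robustness"))

#' @rdname TrainedEnsemble
#' @export
setGeneric("foldModels", function(object) standardGeneric("foldModels"))

#' @rdname TrainedEnsemble
#' @export
setGeneric("normParams", function(object) standardGeneric("normParams"))

#' @rdname TrainedEnsemble
#' @export
setGeneric("variant", function(object) standardGeneric("variant"))

#' @rdname RocCurve
#' @export
setGeneric("auroc", function(object) standardGeneric("auroc"))
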
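#' Prevalence-abundance filtering of taxonomic profiles
#'
#' Retains feature `j` iff it is observed at relative abundance
#' `>= minAbund` in at least a fraction `minPrevFrac` of samples (both
#' comparisons inclusive). The defaults (`1e-5` in `>= 2%` of samples) are
#' the standard species-profile screen; functional profiles use the same
#' call with `minPrevFrac = 0.15`. The sample set and all retained values are
#' unchanged, so the operation is idempotent.
#'
#' @param x a [MicrobiomeProfile-class] or features x samples matrix.
#' @param minAbund abundance floor (inclusive).
#' @param minPrevFrac minimum fraction of samples at or above the floor
#'   (inclusive).
#' @return The filtered object, same class as the input. An empty result
#'   raises a warning, not an error.
#' @examples
#' m <- matrix(c(1e-6, 1e-3, 1e-6, 2e-3), nrow = 2,
#'             dimnames = list(c("rare", "common"), c("s1", "s2")))
#' featureIds(filterTaxa(MicrobiomeProfile(m)))
#' @export
setMethod("filterTaxa", "ANY", function(x, minAbund = 1e-5, minPrevFrac = 0.02) {
  stopifnot(minAbund >= 0, minPrevFrac >= 0, minPrevFrac <= 1)
  m <- .asAbundance(x)
  prev <- rowMeans(m >= minAbund)
  keep <- prev >= minPrevFrac
  if (!any(keep))
    warning("no features pass the prevalence-abundance filter")
  .rewrap(x, m[keep, , drop = FALSE])
})

#' Abundance screen for model features
#'
#' Retains feature `j` iff its maximum relative abundance across samples is
#' `>= abundCutoff` (default 0.001), the screen applied before model
#' training. Prevalence screening is assumed to have happened upstream via
#' [filterTaxa()]. A `cutoff` of 0 is the identity.
#'
#' @param x a [MicrobiomeProfile-class] or matrix.
#' @param abundCutoff minimum max-abundance (inclusive).
#' @param statistic `"max"` (default) or `"mean"`: which per-feature summary
#'   the cutoff applies to.
#' @return The filtered object, same class as the input.
#' @export
setMethod("filterModelFeatures", "ANY",
          function(x, abundCutoff = 0.001, statistic = c("max", "mean")) {
  stopifnot(abundCutoff >= 0)
  statistic <- match.arg(statistic)
  m <- .asAbundance(x)
  s <- if (statistic == "max") apply(m, 1L, max) else rowMeans(m)
  keep <- s >= abundCutoff
  if (!any(keep))
    warning("no features pass the model-feature abundance screen")
  .rewrap(x, m[keep, , drop = FALSE])
})

#' Quality-control filtering of count tables
#'
#' Drops samples with fewer than `minReads` total reads, then taxa present
#' (count > 0) in fewer than `minTaxonSamples` of the remaining samples —
#' the standard noise filter for 16S count tables (defaults: 500 reads,
#' 5 samples).
#'
#' @param x a [MicrobiomeCounts-class] or integer matrix.
#' @param minReads minimum per-sample read total (samples with fewer are
#'   dropped; exactly `minReads` is kept).
#' @param minTaxonSamples minimum number of samples a taxon must occur in
#'   (exactly `minTaxonSamples` is kept).
#' @return The filtered object, same class as the input.
#' @export
setMethod("qcCountTable", "ANY", function(x, minReads = 500, minTaxonSamples = 5) {
  m <- .asAbundance(x)
  keepSamples <- colSums(m) >= minReads
  if (!any(keepSamples))
    stop("all samples fall below the ", minReads, "-read threshold")
  m <- m[, keepSamples, drop = FALSE]
  keepTaxa <- rowSums(m > 0) >= minTaxonSamples
  .rewrap(x, m[keepTaxa, , drop = FALSE])
})
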
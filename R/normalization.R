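#' Fit the log10 + clr + standardization normalization
#'
#' For each sample `i` over the supplied (already model-feature-filtered)
#' feature set: `L_ij = log10(x_ij + pseudocount)`; the centred log-ratio
#' value `clr_ij = L_ij - mean_j(L_ij)` (centring within the sample across
#' the model's features); then per-feature z-standardization
#' `z_ij = (clr_ij - centre_j)/scale_j` with `centre_j` and `scale_j` the
#' across-sample mean and sd (n-1 denominator) of `clr_.j`. The fitted
#' centre/scale, feature list and pseudocount are frozen in the returned
#' [NormalizationParams-class] so that [applyFrozen()] reproduces the exact
#' transform on new cohorts.
#'
#' A constant feature (zero sd across training samples) gets scale 1 with a
#' warning: it contributes a constant and cannot break frozen transfer.
#'
#' Whether the clr centring runs over the full profile or only the model
#' features is controlled by which table is passed in: centring always uses
#' the features of `x`.
#'
#' @param x a [MicrobiomeProfile-class] or features x samples matrix.
#' @param pseudocount positive value added before log10 (default 1e-5).
#' @return list with `normalized` (features x samples matrix of standardized
#'   clr scores, per-feature mean 0 / sd 1 across training samples) and
#'   `params` (a [NormalizationParams-class]).
#' @examples
#' m <- matrix(runif(40, 1e-4, 1e-2), nrow = 4,
#'             dimnames = list(paste0("sp", 1:4), paste0("s", 1:10)))
#' fit <- fitNormalization(m)
#' round(rowMeans(fit$normalized), 12)  # all zero
#' @seealso [applyFrozen()]
#' @export
setMethod("fitNormalization", "ANY", function(x, pseudocount = 1e-5) {
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  m <- .asAbundance(x)
  clr <- .clrMatrix(m, pseudocount)
  centre <- rowMeans(clr)
  scale <- apply(clr, 1L, sd)
  if (any(degenerate <- !is.finite(scale) | scale == 0)) {
    warning(sum(degenerate), " constant feature(s); scale set to 1")
    scale[degenerate] <- 1
  }
  params <- new("NormalizationParams", featureIds = rownames(m),
                pseudocount = pseudocount,
                centre = unname(centre), scale = unname(scale))
  list(normalized = applyFrozen(params, m), params = params)
})

.clrMatrix <- function(m, pseudocount) {
  L <- log10(m + pseudocount)
  sweep(L, 2L, colMeans(L), "-")
}

#' Apply a frozen normalization to a (possibly external) profile table
#'
#' Selects exactly `params@featureIds` from `x` — features absent from the
#' new table are imputed as zero abundance (so they become
#' `log10(pseudocount)` before centring), extra features are ignored — and
#' applies the identical log10 / clr / centre-scale transform with the FROZEN
#' training parameters. Nothing is refitted, so scoring an external cohort is
#' deterministic and invariant to its sample order and to extra features.
#'
#' @param params a [NormalizationParams-class] from [fitNormalization()].
#' @param x a [MicrobiomeProfile-class] or matrix.
#' @return features x samples matrix of standardized clr scores with rows
#'   `params@featureIds`.
#' @export
setMethod("applyFrozen", c("NormalizationParams", "ANY"), function(params, x) {
  m <- .asAbundance(x)
  missing <- setdiff(params@featureIds, rownames(m))
  if (length(missing)) {
    warning(length(missing), " model feature(s) absent from the table; ",
            "imputed as zero abundance")
    zero <- matrix(0, nrow = length(missing), ncol = ncol(m),
                   dimnames = list(missing, colnames(m)))
    m <- rbind(m, zero)
  }
  m <- m[params@featureIds, , drop = FALSE]
  clr <- .clrMatrix(m, params@pseudocount)
  (clr - params@centre) / params@scale
})
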
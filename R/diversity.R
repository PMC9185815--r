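#' Hill numbers of a relative-abundance vector
#'
#' Effective number of taxa of order `q`: `q = 0` richness (count of taxa
#' with nonzero abundance), `q = 1` exponential of Shannon entropy,
#' `q = 2` inverse Simpson index. Hill numbers are non-increasing in `q`.
#'
#' @param p numeric vector of counts or proportions (normalised internally).
#' @param q Hill order, one of 0, 1, 2.
#' @return numeric(1), the effective number of taxa.
#' @examples
#' hillNumbers(rep(1, 10), q = 0)         # 10
#' hillNumbers(c(0.75, 0.25), q = 2)      # 1 / (0.75^2 + 0.25^2) = 1.6
#' @export
hillNumbers <- function(p, q) {
  stopifnot(q %in% c(0, 1, 2), all(p >= 0))
  tot <- sum(p)
  if (tot == 0) return(0)
  p <- p[p > 0] / tot
  switch(as.character(q),
         "0" = length(p),
         "1" = exp(-sum(p * log(p))),
         "2" = 1 / sum(p^2))
}

#' Rarefied Hill-number alpha diversity
#'
#' For each sample and order `q`, subsamples `depth` reads without
#' replacement, computes the Hill number, and averages over `nIter`
#' rarefaction iterations. Samples with fewer than `depth` reads are skipped
#' with a warning. Evenness ratios (`q1/q0`, `q2/q0`) are attached per
#' sample.
#'
#' @param x a [MicrobiomeCounts-class] or integer matrix (taxa x samples).
#' @param q Hill orders to compute (subset of `c(0, 1, 2)`).
#' @param depth rarefaction depth in reads; default the minimum sample depth.
#' @param nIter number of rarefaction iterations (default 100).
#' @param seed integer seed for the subsampling stream.
#' @return tidy data.frame with columns `sample_id`, `q`, `value`,
#'   `rarefaction_depth`, `n_iterations`, plus `evenness_q1_q0` and
#'   `evenness_q2_q0` repeated per sample.
#' @export
setMethod("hillDiversity", "ANY",
          function(x, q = c(0, 1, 2), depth = NULL, nIter = 100, seed = 1L) {
  m <- .asAbundance(x)
  stopifnot(all(q %in% c(0, 1, 2)))
  depths <- colSums(m)
  if (is.null(depth)) depth <- min(depths)
  if (depth <= 0) stop("rarefaction depth must be positive")
  keep <- depths >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below the rarefaction depth skipped")
    m <- m[, keep, drop = FALSE]
  }
  acc <- array(0, dim = c(length(q), ncol(m)))
  .withSeed(seed, {
    for (it in seq_len(nIter)) {
      # rrarefy heuristically warns when no singleton counts are present;
      # the input here is validated integer counts
      rar <- .muffling("observed counts", t(vegan::rrarefy(t(m), depth)))
      for (qi in seq_along(q))
        acc[qi, ] <- acc[qi, ] + apply(rar, 2L, hillNumbers, q = q[qi])
    }
  })
  acc <- acc / nIter
  res <- data.frame(
    sample_id = rep(colnames(m), each = length(q)),
    q = rep(q, times = ncol(m)),
    value = as.vector(acc),
    rarefaction_depth = depth,
    n_iterations = nIter)
  if (all(c(0, 1) %in% q))
    res$evenness_q1_q0 <- rep(acc[match(1, q), ] / acc[match(0, q), ],
                              each = length(q))
  if (all(c(0, 2) %in% q))
    res$evenness_q2_q0 <- rep(acc[match(2, q), ] / acc[match(0, q), ],
                              each = length(q))
  res
})

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i,k) = sum_j |x_ij - x_kj| / sum_j (x_ij + x_kj)`, computed on raw or
#' square-root transformed values. Bounded in `[0, 1]`, symmetric, zero on
#' the diagonal; it is not a metric (no triangle inequality). A pair of
#' all-zero samples gets distance 0 with a warning.
#'
#' @param x a [MicrobiomeProfile-class], [MicrobiomeCounts-class] or matrix.
#' @param sqrtTransform apply an elementwise square root first.
#' @return a `dist` object over samples.
#' @examples
#' m <- matrix(c(2, 1, 1, 1), nrow = 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' brayCurtis(m)  # 0.2
#' @export
setMethod("brayCurtis", "ANY", function(x, sqrtTransform = FALSE) {
  m <- .asAbundance(x)
  if (sqrtTransform) m <- sqrt(m)
  d <- suppressWarnings(vegan::vegdist(t(m), method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s); their distance is defined as 0")
    d[is.na(d)] <- 0
  }
  d
})

#' Single-factor PERMANOVA with optional strata-restricted permutations
#'
#' Partitions the squared-distance sum of squares by group labels:
#' `SS_total = sum_{i<k} d_ik^2 / n`, `SS_within = sum_g sum_{i<k in g}
#' d_ik^2 / n_g`, `F = (SS_between/(g-1)) / (SS_within/(n-g))`,
#' `R2 = SS_between / SS_total` (the Gower-centred partition, identical to
#' the one-factor `adonis2` model). The permutation p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + nPerm)`; when `strata` is given, labels
#' are permuted only within strata, leaving each stratum's label multiset
#' invariant.
#'
#' @param d a `dist` or square symmetric matrix of dissimilarities.
#' @param grouping factor-like group labels (>= 2 levels).
#' @param strata optional factor partitioning the samples; permutations are
#'   restricted within its levels.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param permutations optional matrix of pre-specified label orderings (one
#'   permutation per row, indices into the samples), e.g. an exhaustive
#'   enumeration; overrides `nPerm`/`seed`.
#' @return a [PermanovaResult-class].
#' @export
permanovaTest <- function(d, grouping, strata = NULL, nPerm = 999, seed = 1L,
                          permutations = NULL) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  grouping <- as.factor(grouping)
  if (length(grouping) != n)
    stop("grouping length does not match the distance matrix")
  if (nlevels(droplevels(grouping)) < 2L)
    stop("grouping must have at least two levels")
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    if (length(strata) != n) stop("strata length does not match the samples")
  }
  g <- nlevels(droplevels(grouping))
  ssTotal <- sum(D2[upper.tri(D2)]) / n
  fstat <- function(gr) {
    ssW <- 0
    for (lv in levels(gr)) {
      idx <- which(gr == lv)
      ng <- length(idx)
      if (ng > 1L)
        ssW <- ssW + sum(D2[idx, idx][upper.tri(diag(ng))]) / ng
    }
    ssB <- ssTotal - ssW
    (ssB / (g - 1)) / (ssW / (n - g))
  }
  fObs <- fstat(grouping)
  ssWithin <- 0
  for (lv in levels(grouping)) {
    idx <- which(grouping == lv)
    if (length(idx) > 1L)
      ssWithin <- ssWithin +
        sum(D2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
  }
  r2 <- (ssTotal - ssWithin) / ssTotal
  if (is.null(permutations)) {
    perms <- .withSeed(seed, {
      t(vapply(seq_len(nPerm), function(b) .permuteWithinStrata(n, strata),
               integer(n)))
    })
  } else {
    perms <- permutations
    nPerm <- nrow(perms)
  }
  fPerm <- apply(perms, 1L, function(ord) fstat(grouping[ord]))
  p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + nPerm)
  new("PermanovaResult", R2 = r2, F = fObs, p = p, nPerm = as.integer(nPerm),
      strata = if (is.null(strata)) "" else "yes")
}

.permuteWithinStrata <- function(n, strata) {
  ord <- seq_len(n)
  if (is.null(strata)) return(sample.int(n))
  for (lv in levels(strata)) {
    idx <- which(strata == lv)
    ord[idx] <- idx[sample.int(length(idx))]
  }
  ord
}
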
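# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a user seed and an offset,
# kept strictly inside the 32-bit integer range.
.deriveSeed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 1000003) * 1009 + as.numeric(offset) * 7919
  as.integer(s %% 2147483587) + 1L
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Extract the features x samples numeric matrix from a matrix,
# MicrobiomeProfile or MicrobiomeCounts.
.asAbundance <- function(x) {
  if (is(x, "MicrobiomeProfile")) return(assay(x, "abundance"))
  if (is(x, "MicrobiomeCounts")) return(assay(x, "counts"))
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("matrix input must carry feature (row) and sample (column) names")
    return(x)
  }
  stop("expected a numeric matrix, MicrobiomeProfile or MicrobiomeCounts")
}

# Rebuild an object of the same container class as `template` with a new
# assay matrix, subsetting colData to the retained samples.
.rewrap <- function(template, m) {
  if (is.matrix(template)) return(m)
  if (is(template, "MicrobiomeCounts"))
    return(new("MicrobiomeCounts", SummarizedExperiment(
      assays = list(counts = m),
      colData = colData(template)[colnames(m), , drop = FALSE],
      metadata = metadata(template))))
  new("MicrobiomeProfile", SummarizedExperiment(
    assays = list(abundance = m),
    colData = colData(template)[colnames(m), , drop = FALSE],
    metadata = metadata(template)))
}

# Rank-based AUROC (tie-corrected Mann-Whitney), positives = `pos` logical.
.aurocRank <- function(values, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUROC")
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds, so per-fold class counts differ by at most 1.
.stratifiedFolds <- function(y, nFolds, seed) {
  fold <- integer(length(y))
  .withSeed(seed, {
    for (lv in unique(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

# Coerce labels to a case/control logical given the positive-class label.
.asCaseIndicator <- function(labels, caseLabel) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("labels must have exactly two levels, got: ",
         paste(lev, collapse = ", "))
  if (!caseLabel %in% lev)
    stop(sprintf("case label '%s' not present in labels", caseLabel))
  labels == caseLabel
}

.fmtCount <- function(n, noun) sprintf("%d %s%s", n, noun, if (n == 1) "" else "s")

# Muffle a specific, expected dependency warning while letting others through.
.muffling <- function(pattern, expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl(pattern, conditionMessage(w))) invokeRestart("muffleWarning")
  })
}
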
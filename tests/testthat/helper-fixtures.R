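# Small fixtures shared across test files; everything generated in code.

smallSpec <- function(seed = 7L, ...) {
  args <- list(nSpecies = 60L, nCases = 20L, nControls = 20L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(syntheticSpec, args)
}

randomProfile <- function(p = 20, n = 10, seed = 1) {
  m <- pdacscreen:::.withSeed(seed,
    matrix(runif(p * n, 0, 1e-2), nrow = p,
           dimnames = list(sprintf("f%02d", seq_len(p)),
                           sprintf("s%02d", seq_len(n)))))
  m
}

randomCounts <- function(p = 15, n = 8, lambda = 40, seed = 1) {
  m <- pdacscreen:::.withSeed(seed,
    matrix(rpois(p * n, lambda), nrow = p,
           dimnames = list(sprintf("t%02d", seq_len(p)),
                           sprintf("s%02d", seq_len(n)))))
  m
}

# Independent naive Bray-Curtis for oracle comparisons.
naiveBray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Independent pair-counting AUROC oracle.
naiveAuroc <- function(values, pos) {
  cs <- values[pos]
  ct <- values[!pos]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Independent naive PERMANOVA pieces on a distance matrix.
naivePermanovaF <- function(D, g) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  gl <- unique(g)
  ssT <- 0
  for (i in seq_len(n - 1)) for (k in (i + 1):n) ssT <- ssT + D2[i, k]
  ssT <- ssT / n
  ssW <- 0
  for (lv in gl) {
    idx <- which(g == lv)
    if (length(idx) > 1)
      for (a in seq_along(idx)[-length(idx)])
        for (b in (a + 1):length(idx))
          ssW <- ssW + D2[idx[a], idx[b]] / length(idx)
  }
  ssB <- ssT - ssW
  list(F = (ssB / (length(gl) - 1)) / (ssW / (n - length(gl))),
       R2 = ssB / ssT)
}
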
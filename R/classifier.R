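#' Build a repeated, stratified cross-validation scheme
#'
#' Per repeat, a fresh random partition of the samples into `nFolds` test
#' folds; with `stratified = TRUE` (the default) each class is dealt
#' round-robin so per-fold class counts differ by at most one sample from
#' the global ratio. Deterministic given `seed`.
#'
#' @param labels per-sample group labels (define the strata).
#' @param nRepeats,nFolds scheme dimensions (defaults 10 x 10).
#' @param stratified stratify folds by class.
#' @param seed integer seed.
#' @return a [CVScheme-class].
#' @export
makeCvScheme <- function(labels, nRepeats = 10, nFolds = 10,
                         stratified = TRUE, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(names(labels))) names(labels) <- sprintf("sample_%04d", seq_len(n))
  if (nFolds > n) stop("more folds than samples")
  if (stratified) {
    minClass <- min(table(labels))
    if (minClass < nFolds)
      stop(sprintf(paste0("stratified %d-fold CV impossible: smallest class ",
                          "has only %d samples"), nFolds, minClass))
  }
  assignment <- vapply(seq_len(nRepeats), function(r) {
    if (stratified)
      .stratifiedFolds(labels, nFolds, .deriveSeed(seed, 1000L + r))
    else
      .withSeed(.deriveSeed(seed, 1000L + r),
                sample(rep_len(seq_len(nFolds), n)))
  }, integer(n))
  new("CVScheme", sampleIds = names(labels), nRepeats = as.integer(nRepeats),
      nFolds = as.integer(nFolds), assignment = assignment,
      stratified = stratified, seed = as.integer(seed))
}

#' Enrichment-constrained feature subset for one training fold
#'
#' Returns the features whose training-fold single-feature AUROC (cases as
#' positives) is at least 0.5 — i.e. drops every feature whose direction of
#' association points away from disease, so the resulting model can only use
#' disease-enriched signals. Applied inside each cross-validation training
#' fold by the `"enrichment_constrained"` variant of [trainEnsemble()].
#'
#' @param trainMatrix features x samples matrix (normalized training fold).
#' @param trainLabels two-level labels for the training samples.
#' @param caseLabel the positive-class label.
#' @return character vector of retained feature ids (possibly empty; an
#'   empty set makes the fold emit the constant predictor 0.5).
#' @export
enrichmentFilter <- function(trainMatrix, trainLabels, caseLabel = "PDAC") {
  isCase <- .asCaseIndicator(trainLabels, caseLabel)
  aur <- apply(trainMatrix, 1L, .aurocRank, pos = isCase)
  rownames(trainMatrix)[aur >= 0.5]
}

# Select the L1 cost from `lambdaGrid` by stratified 5-fold CV on the
# training samples, maximizing the AUROC of the pooled held-out predictions;
# ties break towards the larger (sparser) cost.
.selectLambda <- function(Ztr, yTr, lambdaGrid, seed) {
  foldid <- .stratifiedFolds(yTr, 5L, seed)
  preds <- matrix(NA_real_, nrow = length(yTr), ncol = length(lambdaGrid))
  for (k in seq_len(5L)) {
    tr <- foldid != k
    fit <- .muffling("fewer than 8",
      glmnet::glmnet(x = t(Ztr[, tr, drop = FALSE]),
                     y = factor(yTr[tr], levels = c(FALSE, TRUE)),
                     family = "binomial", alpha = 1,
                     lambda = lambdaGrid, standardize = FALSE))
    preds[!tr, ] <- stats::predict(fit, newx = t(Ztr[, !tr, drop = FALSE]),
                                   s = lambdaGrid, type = "response")
  }
  aucs <- apply(preds, 2L, .aurocRank, pos = yTr)
  lambdaGrid[which.max(aucs)]  # grid is decreasing: first max is sparsest
}

#' Train a repeated cross-validated LASSO ensemble
#'
#' The headline multivariable workflow. Per test fold of a 10x10 repeated CV
#' scheme: the normalization (log10 + clr + standardization) is fitted on the
#' training folds only; under the `"enrichment_constrained"` variant the
#' feature set is additionally restricted by [enrichmentFilter()] on the
#' normalized training fold; the L1 cost is selected from `lambdaGrid` by
#' inner stratified 5-fold AUROC; an L1-regularised logistic regression is
#' fitted and the held-out fold's predicted probabilities are recorded.
#' Per-sample cross-validation scores are the arithmetic mean of the held-out
#' predictions over repeats; per-feature robustness is the fraction of fold
#' models with a nonzero coefficient. A full-training-set normalization is
#' also fitted and frozen into the ensemble for transfer to external cohorts.
#'
#' A fold whose enrichment filter leaves no features (all features
#' anti-associated in that training fold) yields the constant predictor 0.5
#' and an all-zero coefficient vector, preserving the ensemble shape.
#'
#' @param x a [MicrobiomeProfile-class] or features x samples matrix,
#'   already model-feature-filtered ([filterModelFeatures()]).
#' @param labels two-level group labels aligned with the samples.
#' @param scheme a [CVScheme-class]; built from `nRepeats`/`nFolds`/`seed`
#'   when `NULL`.
#' @param variant `"unconstrained"` (model-1) or `"enrichment_constrained"`
#'   (model-2).
#' @param lambdaGrid fixed log-spaced grid of L1 costs (default 10 values
#'   from 1 down to 1e-3).
#' @param nRepeats,nFolds,seed used when `scheme` is `NULL`; `seed` also
#'   drives the inner-CV streams.
#' @param pseudocount pseudocount of the normalization.
#' @param caseLabel the positive-class label (default `"PDAC"`).
#' @return a [TrainedEnsemble-class].
#' @seealso [scoreSamples()], [rocEvaluate()], [evaluateExternal()]
#' @export
setMethod("trainEnsemble", "ANY",
          function(x, labels, scheme = NULL,
                   variant = c("unconstrained", "enrichment_constrained"),
                   lambdaGrid = 10^seq(0, -3, length.out = 10),
                   nRepeats = 10, nFolds = 10, seed = 1L,
                   pseudocount = 1e-5, caseLabel = "PDAC") {
  variant <- match.arg(variant)
  m <- .asAbundance(x)
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    stop("labels must align with the samples")
  names(labels) <- colnames(m)
  isCase <- .asCaseIndicator(labels, caseLabel)
  controlLabel <- setdiff(unique(labels), caseLabel)
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  if (is.null(scheme))
    scheme <- makeCvScheme(labels, nRepeats = nRepeats, nFolds = nFolds,
                           stratified = TRUE, seed = seed)
  if (!identical(scheme@sampleIds, colnames(m)))
    scheme@sampleIds <- colnames(m)  # scheme built from bare labels
  n <- ncol(m)
  predMat <- matrix(NA_real_, nrow = n, ncol = scheme@nRepeats,
                    dimnames = list(colnames(m), NULL))
  foldModelList <- vector("list", scheme@nRepeats * scheme@nFolds)
  nzCount <- setNames(numeric(nrow(m)), rownames(m))
  idx <- 0L
  for (r in seq_len(scheme@nRepeats)) {
    for (k in seq_len(scheme@nFolds)) {
      idx <- idx + 1L
      testIdx <- which(scheme@assignment[, r] == k)
      trainIdx <- setdiff(seq_len(n), testIdx)
      fit <- suppressWarnings(
        fitNormalization(m[, trainIdx, drop = FALSE], pseudocount = pseudocount))
      Ztr <- fit$normalized
      feats <- if (variant == "enrichment_constrained")
        enrichmentFilter(Ztr, labels[trainIdx], caseLabel = caseLabel)
      else rownames(m)
      innerSeed <- .deriveSeed(scheme@seed, 5000L + r * 100L + k)
      if (length(feats) == 0L) {
        predMat[testIdx, r] <- 0.5
        foldModelList[[idx]] <- list(
          repeatIdx = r, fold = k, coef = setNames(numeric(0), character(0)),
          intercept = 0, cost = NA_real_, features = character(),
          degenerate = TRUE, centre = fit$params@centre,
          scale = fit$params@scale, testIdx = testIdx)
        next
      }
      Zsub <- Ztr[feats, , drop = FALSE]
      if (length(feats) == 1L)  # glmnet needs >= 2 columns
        Zsub <- rbind(Zsub, `.dummy` = 0)
      lam <- .selectLambda(Zsub, isCase[trainIdx], lambdaGrid, innerSeed)
      gfit <- .muffling("fewer than 8",
        glmnet::glmnet(x = t(Zsub),
                       y = factor(isCase[trainIdx], levels = c(FALSE, TRUE)),
                       family = "binomial", alpha = 1,
                       lambda = lambdaGrid, standardize = FALSE))
      Zte <- applyFrozen(fit$params, m[, testIdx, drop = FALSE])[
        rownames(Zsub)[rownames(Zsub) %in% rownames(m)], , drop = FALSE]
      if (length(feats) == 1L) Zte <- rbind(Zte, `.dummy` = 0)
      predMat[testIdx, r] <- as.numeric(
        stats::predict(gfit, newx = t(Zte), s = lam, type = "response"))
      cf <- stats::coef(gfit, s = lam)
      w <- setNames(as.numeric(cf)[-1], rownames(cf)[-1])
      w <- w[names(w) != ".dummy"]
      nz <- w[w != 0]
      nzCount[names(nz)] <- nzCount[names(nz)] + 1
      foldModelList[[idx]] <- list(
        repeatIdx = r, fold = k, coef = nz, intercept = as.numeric(cf)[1],
        cost = lam, features = feats, degenerate = FALSE,
        centre = fit$params@centre, scale = fit$params@scale,
        testIdx = testIdx)
    }
  }
  fullFit <- suppressWarnings(fitNormalization(m, pseudocount = pseudocount))
  new("TrainedEnsemble",
      foldModels = foldModelList, normParams = fullFit$params,
      robustness = nzCount / length(foldModelList),
      cvScores = rowMeans(predMat), variant = variant, scheme = scheme,
      caseLabel = caseLabel, controlLabel = controlLabel)
})

#' Score new samples with a trained ensemble
#'
#' Applies the ensemble's frozen full-training-set normalization
#' ([applyFrozen()]) and returns, per sample, the arithmetic mean of the
#' predicted probabilities over all fold models (degenerate folds contribute
#' their constant 0.5). Purely deterministic: invariant to sample order and
#' to extra features in `x`.
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param x a [MicrobiomeProfile-class] or matrix for the new cohort.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
setMethod("scoreSamples", c("TrainedEnsemble", "ANY"), function(ensemble, x) {
  Z <- applyFrozen(ensemble@normParams, x)
  p <- ensemble@normParams@featureIds
  M <- length(ensemble@foldModels)
  C <- matrix(0, nrow = length(p), ncol = M, dimnames = list(p, NULL))
  b <- numeric(M)
  degen <- logical(M)
  for (i in seq_len(M)) {
    fm <- ensemble@foldModels[[i]]
    degen[i] <- isTRUE(fm$degenerate)
    if (!degen[i]) {
      C[names(fm$coef), i] <- fm$coef
      b[i] <- fm$intercept
    }
  }
  eta <- t(Z) %*% C
  probs <- plogis(sweep(eta, 2L, b, "+"))
  probs[, degen] <- 0.5
  rowMeans(probs)
})

#' Empirical ROC curve, AUROC and DeLong 95% CI
#'
#' Computes the empirical ROC over all unique score thresholds, the AUROC by
#' the trapezoid rule (equal to the tie-corrected Mann-Whitney statistic),
#' and a 95% confidence interval by the DeLong variance method.
#'
#' @param scores numeric prediction scores (larger = more case-like).
#' @param labels two-level labels; `caseLabel` marks the positives.
#' @param caseLabel the positive-class label (default `"PDAC"`).
#' @return a [RocCurve-class].
#' @export
rocEvaluate <- function(scores, labels, caseLabel = "PDAC") {
  isCase <- .asCaseIndicator(labels, caseLabel)
  if (length(unique(scores)) == 1L) {
    pts <- data.frame(threshold = c(Inf, -Inf), fpr = c(0, 1), tpr = c(0, 1))
    return(new("RocCurve", points = pts, auroc = 0.5, ciLow = 0.5, ciHigh = 0.5))
  }
  r <- pROC::roc(response = isCase, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- tryCatch(
    .muffling("AUC == 1", as.numeric(pROC::ci.auc(r, method = "delong"))),
    error = function(e) rep(as.numeric(pROC::auc(r)), 3))
  pts <- data.frame(threshold = r$thresholds,
                    fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  new("RocCurve", points = pts, auroc = as.numeric(pROC::auc(r)),
      ciLow = ci[1], ciHigh = ci[3])
}
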
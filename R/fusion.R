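#' Encode CA19-9 serum levels as a binary marker
#'
#' Clinical coding: a level strictly above the threshold (37 U/mL by
#' default) is positive (1); a level at or below it, or a missing
#' measurement, is negative (0). Negative concentrations are a data error.
#'
#' @param level numeric serum concentrations in U/mL; `NA` = not available.
#' @param threshold positivity cut-off, default 37 U/mL (strict `>`).
#' @return integer vector of 0/1 codes.
#' @examples
#' encodeCa199(c(50, 10, NA, 37))  # 1 0 0 0
#' @export
encodeCa199 <- function(level, threshold = 37) {
  stopifnot(threshold > 0)
  if (any(level < 0, na.rm = TRUE))
    stop("negative CA19-9 level(s): ",
         paste(head(level[!is.na(level) & level < 0]), collapse = ", "))
  as.integer(!is.na(level) & level > threshold)
}

#' Combine classifier scores with the coded CA19-9 marker
#'
#' The OR combination adds the binary code to the mean cross-validated
#' prediction score (`score + code`, range `[0, 2]`; no clipping — ROC
#' evaluation is rank-based, and any positive marker lifts a sample above
#' every marker-negative one). The AND combination multiplies
#' (`score * code`), so only samples positive on both readouts keep a
#' nonzero score.
#'
#' @param scores named numeric classifier scores.
#' @param codes 0/1 integer codes, named or aligned with `scores`; names, if
#'   present on both, are matched.
#' @return numeric vector of combined scores, same names as `scores`.
#' @export
combineOr <- function(scores, codes) {
  codes <- .alignCodes(scores, codes)
  scores + codes
}

#' @rdname combineOr
#' @export
combineAnd <- function(scores, codes) {
  codes <- .alignCodes(scores, codes)
  scores * codes
}

.alignCodes <- function(scores, codes) {
  if (length(codes) != length(scores))
    stop("scores and codes must cover the same samples")
  if (!is.null(names(scores)) && !is.null(names(codes))) {
    if (!setequal(names(scores), names(codes)))
      stop("sample identifiers of scores and codes do not match")
    codes <- codes[names(scores)]
  }
  if (anyNA(codes) || !all(codes %in% c(0, 1)))
    stop("codes must be 0/1 with no missing values (code 'not available' as 0)")
  as.numeric(codes)
}

#' Calibrate the decision threshold to a target specificity
#'
#' Returns the smallest observed score value `t` such that the fraction of
#' training control scores strictly above `t` does not exceed
#' `1 - targetSpecificity` (default: a 10% false-positive rate among
#' training controls). The achieved FPR can undershoot the target because
#' score distributions are discrete; it never exceeds it.
#'
#' @param controlScores numeric scores of the training controls (>= 10).
#' @param targetSpecificity target specificity in (0, 1), default 0.90.
#' @return a [ThresholdCalibration-class].
#' @examples
#' calib <- calibrateThreshold(seq(0.01, 0.50, length.out = 50))
#' calib  # 5 of 50 controls exceed the threshold: achieved FPR 0.10
#' @export
calibrateThreshold <- function(controlScores, targetSpecificity = 0.90) {
  stopifnot(targetSpecificity > 0, targetSpecificity < 1)
  n <- length(controlScores)
  if (n < 10L)
    stop("at least 10 control scores are required for calibration")
  if (n * (1 - targetSpecificity) < 1 - 1e-9)
    warning("fewer controls than the target FPR granularity requires; ",
            "the achieved FPR will be 0")
  cand <- sort(unique(controlScores))
  fprs <- vapply(cand, function(t) mean(controlScores > t), 0)
  # small tolerance so e.g. a 10% empirical rate meets a 0.90 target exactly
  t <- cand[which(fprs <= 1 - targetSpecificity + 1e-12)[1]]
  new("ThresholdCalibration", threshold = t,
      targetSpecificity = targetSpecificity,
      achievedFprTrain = mean(controlScores > t), nControls = as.integer(n))
}

#' Tabulate flagging rates of scores against a calibrated threshold
#'
#' Flags samples with score strictly above the calibrated threshold and
#' reports, per status group, the number and rate of flagged samples — the
#' false-positive rate for non-PDAC groups, the recall for PDAC groups. A
#' pooled `"nonPDAC"` row aggregates every non-PDAC sample of the cohort.
#'
#' @param scores named numeric scores.
#' @param status per-sample status labels aligned with `scores`.
#' @param calib a [ThresholdCalibration-class].
#' @param cohortLabel cohort name recorded in the output.
#' @return data.frame with columns `cohort`, `status`, `n`, `n_flagged`,
#'   `rate`.
#' @export
evaluateScores <- function(scores, status, calib, cohortLabel = "cohort") {
  stopifnot(length(scores) == length(status))
  flagged <- scores > calib@threshold
  groups <- split(flagged, as.character(status))
  res <- data.frame(
    cohort = cohortLabel,
    status = names(groups),
    n = vapply(groups, length, 0L),
    n_flagged = vapply(groups, sum, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  nonPdac <- as.character(status) != "PDAC"
  if (any(nonPdac) && length(unique(status[nonPdac])) > 1L)
    res <- rbind(res, data.frame(
      cohort = cohortLabel, status = "nonPDAC",
      n = sum(nonPdac), n_flagged = sum(flagged[nonPdac])))
  res$rate <- res$n_flagged / res$n
  res
}

#' Evaluate a frozen ensemble on an external cohort
#'
#' Scores each external sample with [scoreSamples()] (frozen normalization,
#' mean probability over all fold models), flags samples above the
#' calibrated threshold, and tabulates per status group via
#' [evaluateScores()]. Only frozen parameters are used: rescoring the cohort,
#' or scoring it in shuffled sample order, reproduces the same result.
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param calib a [ThresholdCalibration-class].
#' @param x the external cohort: a [MicrobiomeProfile-class] (status taken
#'   from `sampleData(x)$group` unless `status` is given) or a matrix.
#' @param status optional per-sample status labels.
#' @param cohortLabel cohort name recorded in the output (defaults to the
#'   cohort's own label when available).
#' @return data.frame as [evaluateScores()], with the per-sample scores
#'   attached as `attr(res, "scores")`.
#' @export
evaluateExternal <- function(ensemble, calib, x, status = NULL,
                             cohortLabel = NULL) {
  if (is.null(status)) {
    if (!is(x, "SummarizedExperiment") || !"group" %in% colnames(colData(x)))
      stop("no status labels: supply `status` or a cohort with a 'group' column")
    status <- sampleData(x)$group
  }
  if (is.null(cohortLabel))
    cohortLabel <- if (is(x, "SummarizedExperiment") &&
                       "cohort" %in% colnames(colData(x)))
      as.character(sampleData(x)$cohort[1]) else "external"
  scores <- scoreSamples(ensemble, x)
  res <- evaluateScores(scores, status, calib, cohortLabel = cohortLabel)
  attr(res, "scores") <- scores
  res
}

#' Association diagnostics of prediction scores with covariates
#'
#' Spearman rank correlation (with p-value) of the scores against age and
#' sequencing depth, and a two-group Wilcoxon rank test against sex — the
#' routine checks for demographic and technical drivers of external
#' prediction scores. A constant covariate yields `NA`.
#'
#' @param scores numeric prediction scores.
#' @param metadata data.frame with columns `age`, `sex`, `depth` (missing
#'   columns are skipped).
#' @return data.frame with columns `covariate`, `method`, `estimate`
#'   (Spearman rho, or the difference of mean score between sexes), `p`.
#' @export
scoreCovariateDiagnostics <- function(scores, metadata) {
  rows <- list()
  for (cv in c("age", "depth")) {
    if (!cv %in% colnames(metadata)) next
    v <- metadata[[cv]]
    if (length(unique(na.omit(v))) < 2L) {
      rows[[cv]] <- data.frame(covariate = cv, method = "spearman",
                               estimate = NA_real_, p = NA_real_)
    } else {
      ct <- suppressWarnings(cor.test(scores, v, method = "spearman",
                                      exact = FALSE))
      rows[[cv]] <- data.frame(covariate = cv, method = "spearman",
                               estimate = unname(ct$estimate), p = ct$p.value)
    }
  }
  if ("sex" %in% colnames(metadata)) {
    s <- as.factor(metadata$sex)
    if (nlevels(droplevels(s)) == 2L) {
      lv <- levels(droplevels(s))
      wt <- suppressWarnings(wilcox.test(scores[s == lv[1]], scores[s == lv[2]]))
      rows$sex <- data.frame(covariate = "sex", method = "wilcoxon",
                             estimate = mean(scores[s == lv[1]]) -
                               mean(scores[s == lv[2]]),
                             p = wt$p.value)
    } else {
      rows$sex <- data.frame(covariate = "sex", method = "wilcoxon",
                             estimate = NA_real_, p = NA_real_)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
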
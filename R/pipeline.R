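#' Run the end-to-end workflow and write the artifact bundle
#'
#' Orchestrates the two headline workflows on a synthetic cohort:
#' simulate -> filter -> univariate screen -> diversity -> train (model-1
#' and/or model-2) -> CA19-9 fusion -> threshold calibration -> external
#' specificity panel. Writes, under `config$outputDir`: the raw and filtered
#' profile TSVs, the metadata TSV, a truth JSON sidecar, per-variant model
#' JSON artifacts, ROC point TSVs, the univariate TSV, a tidy alpha-diversity
#' TSV, the external-evaluation TSV, and a run manifest (config echo,
#' package version, seed, config hash). Every output file carries the run's
#' seed and config hash in a leading `#` comment. Re-running with an
#' identical config reproduces all numeric outputs exactly.
#'
#' @param config a named list; recognised entries (all optional):
#'   `outputDir` (default `tempfile("pdacscreen_run")`), `seed` (default 42),
#'   `spec` (a [SyntheticSpec-class]; default `syntheticSpec(seed = seed)`),
#'   `variants` (default both model variants), `nRepeats`, `nFolds`
#'   (default 10, 10), `targetSpecificity` (default 0.90), `abundCutoff`
#'   (default 0.001), `minAbund`/`minPrevFrac` (defaults 1e-5, 0.02),
#'   `pseudocount` (default 1e-5), `externalPanel` (cohort definition
#'   data.frame as in [generateExternalPanel()]; default a 4-cohort
#'   other-disease panel plus one healthy cohort), `diversityDepth`
#'   (rarefaction depth for the diversity stage, default 5000 reads after
#'   scaling profiles to counts), `diversityIter` (default 25).
#' @return (invisibly) a list with the cohort, trained ensembles,
#'   calibrations, evaluation tables and the manifest.
#' @export
runPipeline <- function(config = list()) {
  cfg <- config
  cfg$seed <- cfg$seed %||% 42L
  cfg$outputDir <- cfg$outputDir %||% tempfile("pdacscreen_run")
  cfg$variants <- cfg$variants %||% c("unconstrained", "enrichment_constrained")
  cfg$nRepeats <- cfg$nRepeats %||% 10L
  cfg$nFolds <- cfg$nFolds %||% 10L
  cfg$targetSpecificity <- cfg$targetSpecificity %||% 0.90
  cfg$abundCutoff <- cfg$abundCutoff %||% 0.001
  cfg$minAbund <- cfg$minAbund %||% 1e-5
  cfg$minPrevFrac <- cfg$minPrevFrac %||% 0.02
  cfg$pseudocount <- cfg$pseudocount %||% 1e-5
  cfg$diversityDepth <- cfg$diversityDepth %||% 5000
  cfg$diversityIter <- cfg$diversityIter %||% 25
  spec <- cfg$spec %||% syntheticSpec(seed = cfg$seed)
  cfg$spec <- NULL  # echoed separately below
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outputDir, f)

  # config hash: md5 of the canonical config + generator spec echo
  # (output location excluded so the hash identifies the analysis, not paths)
  hashCfg <- cfg[setdiff(names(cfg), "outputDir")]
  echo <- c(hashCfg[order(names(hashCfg))],
            list(spec = list(nSpecies = spec@nSpecies, nCases = spec@nCases,
                             nControls = spec@nControls, sparsity = spec@sparsity,
                             effectEnriched = spec@effectEnriched,
                             effectDepleted = spec@effectDepleted,
                             batchLogSd = spec@batchLogSd, seed = spec@seed)))
  jsonlite::write_json(echo, out("config.json"), auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(out("config.json")))
  stamp <- c(sprintf("seed: %d", cfg$seed), sprintf("config_hash: %s", hash))

  cohort <- generateCohort(spec)
  writeProfileTSV(cohort, out("profile_raw.tsv"), comments = stamp)
  writeSampleMetadata(sampleData(cohort), out("metadata.tsv"), comments = stamp)
  jsonlite::write_json(metadata(cohort)$truth, out("truth.json"),
                       auto_unbox = TRUE, digits = NA)

  filtered <- filterTaxa(cohort, minAbund = cfg$minAbund,
                         minPrevFrac = cfg$minPrevFrac)
  modelTable <- filterModelFeatures(filtered, abundCutoff = cfg$abundCutoff)
  writeProfileTSV(modelTable, out("profile_filtered.tsv"), comments = stamp)

  labels <- sampleData(cohort)$group
  uni <- wilcoxonScreen(filtered, labels, pseudocount = cfg$pseudocount)
  .writeTidyTSV(uni, out("univariate.tsv"), stamp)

  counts <- round(abundances(cohort) * 10 * cfg$diversityDepth)
  alpha <- hillDiversity(counts, depth = cfg$diversityDepth,
                         nIter = cfg$diversityIter,
                         seed = .deriveSeed(cfg$seed, 11L))
  .writeTidyTSV(alpha, out("alpha_diversity.tsv"), stamp)

  ensembles <- list()
  calibs <- list()
  evals <- list()
  rocs <- list()
  panelDefs <- cfg$externalPanel %||% data.frame(
    label = c("CD", "UC", "LD", "T2D", "HC"),
    diseaseType = c(rep("other_disease", 4), "healthy"),
    n = 50,
    batchSeed = .deriveSeed(cfg$seed, 21L:25L))
  panel <- generateExternalPanel(spec, panelDefs)
  for (v in cfg$variants) {
    ens <- trainEnsemble(modelTable, labels, variant = v,
                         nRepeats = cfg$nRepeats, nFolds = cfg$nFolds,
                         seed = .deriveSeed(cfg$seed, 31L),
                         pseudocount = cfg$pseudocount)
    tag <- if (v == "unconstrained") "model1" else "model2"
    writeEnsembleJSON(ens, out(paste0(tag, ".json")))
    roc <- rocEvaluate(cvScores(ens), labels)
    .writeTidyTSV(roc@points, out(paste0(tag, "_roc.tsv")),
                  c(stamp, sprintf("auroc: %.6f (95%% CI %.6f-%.6f)",
                                   roc@auroc, roc@ciLow, roc@ciHigh)))
    calib <- calibrateThreshold(cvScores(ens)[labels != "PDAC"],
                                targetSpecificity = cfg$targetSpecificity)
    ev <- do.call(rbind, lapply(panel, function(co)
      evaluateExternal(ens, calib, co)))
    ev$model_variant <- v
    ensembles[[tag]] <- ens
    calibs[[tag]] <- calib
    evals[[tag]] <- ev
    rocs[[tag]] <- roc
  }
  evalTable <- do.call(rbind, c(evals, list(make.row.names = FALSE)))
  .writeTidyTSV(evalTable, out("external_eval.tsv"), stamp)

  manifest <- list(package = "pdacscreen",
                   version = as.character(packageVersion("pdacscreen")),
                   seed = cfg$seed, config_hash = hash,
                   config = echo,
                   outputs = list.files(cfg$outputDir))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, modelTable = modelTable,
                 ensembles = ensembles, calibrations = calibs,
                 rocCurves = rocs, externalEval = evalTable,
                 univariate = uni, alphaDiversity = alpha,
                 manifest = manifest, outputDir = cfg$outputDir))
}

.writeTidyTSV <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
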
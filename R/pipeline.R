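#' Assemble a pipeline run configuration
#'
#' A run configuration is a plain named list; this helper fills defaults
#' and validates it. Either `countsPath`/`clinicalPath` point to input
#' files, or `simulate = TRUE` generates a synthetic cohort from the spec
#' fields. All randomness flows from the single `seed`.
#'
#' @param countsPath,clinicalPath input files (gene x sample TSV/CSV and
#'   clinical CSV), or NULL to simulate.
#' @param simulate generate a synthetic cohort (default: TRUE when no
#'   counts path is given).
#' @param nPatients,subtypeProportions,expressionSeparation passed to
#'   [cohortSpec()] when simulating.
#' @param seed integer seed for the whole run.
#' @param outDir output directory (created if absent).
#' @param tilsCutoff,immuneCutoff dichotomisation cutoffs.
#' @param standardize passed to [normalizePanel()].
#' @return validated config list of class `"lumityper_config"`.
#' @export
runConfig <- function(countsPath = NULL, clinicalPath = NULL,
                      simulate = is.null(countsPath), nPatients = 87L,
                      subtypeProportions = c(LumA = 0.71, LumB = 0.20,
                                             HER2E = 0.02, Basal = 0.07),
                      expressionSeparation = 2, seed = 1L,
                      outDir = tempfile("lumityper_run_"),
                      tilsCutoff = 13.5, immuneCutoff = 45.5,
                      standardize = FALSE) {
  cfg <- list(countsPath = countsPath, clinicalPath = clinicalPath,
              simulate = simulate, nPatients = as.integer(nPatients),
              subtypeProportions = subtypeProportions,
              expressionSeparation = expressionSeparation,
              seed = as.integer(seed), outDir = outDir,
              tilsCutoff = tilsCutoff, immuneCutoff = immuneCutoff,
              standardize = standardize)
  for (p in c("countsPath", "clinicalPath"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(p, " does not exist: ", cfg[[p]])
  if (!cfg$simulate && is.null(cfg$countsPath) && is.null(cfg$clinicalPath))
    stop("nothing to do: no inputs and simulate = FALSE")
  class(cfg) <- "lumityper_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match the arguments of [runConfig()].
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$subtypeProportions))
    cfg$subtypeProportions <- unlist(cfg$subtypeProportions)
  do.call(runConfig, cfg)
}

#' Run the full pipeline
#'
#' Orchestrates the stages in methods order: cohort acquisition (file or
#' simulation), sample QC, normalisation, molecular scoring (subtype,
#' ROR-P, RS, immune score), IHC surrogate calls, and downstream
#' statistics (risk-class cross-tab with Cohen's kappa, subtype
#' concordance, Kaplan-Meier/log-rank by risk class, Cox factor menu).
#' Writes per-stage CSVs and a machine-readable `summary.json` to the
#' output directory; identical config + seed gives identical outputs.
#'
#' When only a clinical table is available (no expression), the molecular
#' stages are skipped and the surrogate + survival stages still run.
#'
#' @param config a config list from [runConfig()]/[readRunConfig()].
#' @return invisibly, a list with the per-stage objects and the summary.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "lumityper_config"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)
  out <- list(config = config)

  clinical <- NULL
  pe <- NULL
  if (config$simulate) {
    spec <- cohortSpec(nPatients = config$nPatients,
                       subtypeProportions = config$subtypeProportions,
                       expressionSeparation = config$expressionSeparation,
                       seed = config$seed)
    coh <- generateCohort(spec)
    pe <- coh$panel
    clinical <- coh$clinical
    out$truth <- coh$truth
  } else {
    if (!is.null(config$countsPath)) pe <- readCounts(config$countsPath)
    if (!is.null(config$clinicalPath))
      clinical <- readClinicalCSV(config$clinicalPath)
  }
  summary$n <- if (!is.null(clinical)) nrow(clinical) else ncol(pe)

  scores <- NULL
  if (!is.null(pe)) {
    pe <- qcFilterSamples(pe)
    writeQCReport(pe, file.path(config$outDir, "qc_report.csv"))
    if (!is.null(clinical))
      clinical <- clinical[clinical$id %in% colnames(pe), , drop = FALSE]
    pe <- normalizePanel(pe, standardize = config$standardize)
    labels <- SummarizedExperiment::colData(pe)$true_subtype
    if (is.null(labels))
      stop("stage scoring: no subtype training labels available for ",
           "this cohort; supply a simulated cohort or labelled colData")
    model <- trainCentroids(pe, labels, onSmall = "pool")
    scores <- scoreCohort(pe, model, immuneCutoff = config$immuneCutoff)
    utils::write.csv(as.data.frame(scores),
                     file.path(config$outDir, "score_set.csv"))
    summary$qc_excluded <- sum(qcReport(pe)$excluded)
    summary$subtype_counts <- as.list(table(
      factor(scores$subtype, levels = .SUBTYPES)))
    summary$ror_class_counts <- as.list(table(scores$ror_class))
    summary$rs_class_counts <- as.list(table(scores$rs_class))
    out$panel <- pe
    out$model <- model
    out$scores <- scores
  }

  surrogate <- NULL
  if (!is.null(clinical)) {
    surrogate <- surrogateCalls(clinical, tilsCutoff = config$tilsCutoff)
    utils::write.csv(surrogate,
                     file.path(config$outDir, "surrogate_calls.csv"),
                     row.names = FALSE)
    summary$modified_ihc_counts <- as.list(table(surrogate$modified))
    out$surrogate <- surrogate
  }

  if (!is.null(scores) && !is.null(surrogate)) {
    risk_k <- cohensKappa(as.character(scores$ror_class),
                          as.character(scores$rs_class),
                          levels = c("low", "medium", "high"))
    sub_k <- cohensKappa(as.character(scores$subtype), surrogate$modified,
                         levels = c(.SUBTYPES))
    summary$risk_class_kappa <- unname(risk_k$kappa)
    summary$subtype_concordance <- unname(sub_k$observed_agreement)
    summary$subtype_kappa <- unname(sub_k$kappa)
    utils::write.csv(as.data.frame(sub_k$crosstab),
                     file.path(config$outDir, "subtype_crosstab.csv"),
                     row.names = FALSE)
    out$agreement <- list(risk = risk_k, subtype = sub_k)
  }

  if (!is.null(clinical) && all(c("dfs_months", "dfs_event") %in%
                                names(clinical))) {
    grp <- if (!is.null(scores)) as.character(scores$ror_class) else
      surrogate$modified
    km <- kmLogrank(clinical$dfs_months, clinical$dfs_event, grp)
    summary$dfs_logrank_p <- km$p
    covars <- data.frame(
      age_gt50 = clinical$age_years > 50,
      size_gt1cm = clinical$tumor_size_cm > 1,
      grade3 = clinical$grade == 3,
      ki67_high = clinical$ki67_pct > 30,
      basal_marker = surrogate$basal_marker_any,
      tils_high = surrogate$tils_level == "high",
      stringsAsFactors = FALSE)
    if (!is.null(scores)) covars$immune_strong <-
      scores$immune_group == "istrong"
    cox <- coxAnalysis(covars, clinical$dfs_months, clinical$dfs_event,
                       univariate = names(covars))
    utils::write.csv(cox$univariate,
                     file.path(config$outDir, "cox_dfs_univariate.csv"),
                     row.names = FALSE)
    if (!is.null(cox$multivariate))
      utils::write.csv(cox$multivariate,
                       file.path(config$outDir, "cox_dfs_multivariate.csv"),
                       row.names = FALSE)
    km_df <- do.call(rbind, Map(function(g, d)
      cbind(group = g, d), names(km$curves), km$curves))
    utils::write.csv(km_df, file.path(config$outDir, "km_dfs.csv"),
                     row.names = FALSE)
    out$km <- km
    out$cox <- cox
  }

  summary_path <- file.path(config$outDir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  out$summary <- summary
  invisible(out)
}
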
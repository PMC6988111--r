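#' @include AllClasses.R effect_size.R
NULL

# Deterministic per-stage sub-seed from the master seed (kept < 2^31).
.stageSeed <- function(seed, stage) {
  as.integer((as.double(seed) * 131 +
              sum(utf8ToInt(stage)) * 2654435) %% 2147483629)
}

#' Run the whole proteotype-variation pipeline
#'
#' Orchestrates every stage on one cohort: simulation (when \code{config}
#' is given) or user-supplied datasets, conditional preprocessing, module
#' recovery (AUC), the complex co-abundance landscape (with >= 2 datasets),
#' stoichiometry decomposition and component calls, covariate differential
#' analysis, and ridge effect sizes. All stage outputs are written as TSV
#' under \code{outDir} together with a MANIFEST of completed stages; any
#' stage failure leaves the earlier outputs and records the failure in the
#' MANIFEST before re-throwing. Stage seeds are derived deterministically
#' from the master seed, so a re-run with identical inputs reproduces
#' identical outputs.
#'
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{cohortConfig}} to simulate from, or
#'   \code{NULL} when \code{datasets} are supplied.
#' @param datasets,complexes,pathways,interactions,metadata inputs used when
#'   \code{config} is \code{NULL}.
#' @param seed master seed.
#' @param nPermLandscape,nPermPathway,nPermEffect permutation budgets for
#'   the landscape null, pathway pre-filter and effect-size FDR.
#' @param nIterMwu,nSampleMwu subsampled Mann-Whitney budget.
#' @param minMembers,trim,qThreshold shared stage parameters.
#' @return invisibly, a list with each stage's in-memory result.
#' @export
runPipeline <- function(outDir, config = NULL, datasets = NULL,
                        complexes = NULL, pathways = NULL,
                        interactions = NULL, metadata = NULL, seed = 1L,
                        nPermLandscape = 100L, nPermPathway = 100L,
                        nPermEffect = 0L, nIterMwu = 100L,
                        nSampleMwu = 1000L, minMembers = 5L, trim = 0.25,
                        qThreshold = 0.01) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(outDir, "MANIFEST")
  cat("stage\tstatus\tseconds\n", file = manifest)
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      cat(name, "failed", round(proc.time()[["elapsed"]] - t0, 1),
          sep = "\t", file = manifest, append = TRUE)
      cat("\n", file = manifest, append = TRUE)
      stop("stage \"", name, "\" failed: ", conditionMessage(e),
           call. = FALSE)
    })
    cat(name, "ok", round(proc.time()[["elapsed"]] - t0, 1), sep = "\t",
        file = manifest, append = TRUE)
    cat("\n", file = manifest, append = TRUE)
    res
  }
  writeTab <- function(d, name)
    utils::write.table(d, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")

  if (!is.null(config)) {
    sim <- stage("simulate", generateCohort(config))
    datasets <- sim$datasets
    complexes <- sim$complexes
    pathways <- sim$pathways
    interactions <- sim$interactions
    metadata <- sim$metadata
    writeTab(sim$groundTruth$complexes, "ground_truth_complexes.tsv")
    writeTab(sim$groundTruth$subunits, "ground_truth_subunits.tsv")
    results$groundTruth <- sim$groundTruth
  }
  stopifnot(!is.null(datasets), !is.null(complexes))

  datasets <- stage("preprocess", lapply(datasets, function(d) {
    pp <- preprocessDataset(d, seed = .stageSeed(seed, "preprocess"))
    pp$dataset
  }))
  for (d in datasets)
    writeAbundanceMatrix(d, file.path(outDir, paste0(datasetId(d), ".tsv")))

  sources <- list(complex = complexes)
  if (!is.null(pathways)) sources$pathway <- pathways
  if (!is.null(interactions)) sources$interaction <- interactions
  rec <- stage("recover",
               recoveryMatrix(datasets, sources,
                              seed = .stageSeed(seed, "recover"),
                              nIterMwu = nIterMwu,
                              nSampleMwu = nSampleMwu))
  writeTab(rec$records, "recovery_auc.tsv")
  results$recovery <- rec

  perDs <- stage("landscape_rank", lapply(datasets, function(d)
    complexMedianCoabundance(d, complexes, minMembers)))
  results$perDatasetCoabundance <- perDs
  writeTab(do.call(rbind, perDs), "complex_coabundance.tsv")
  if (length(datasets) >= 2L) {
    land <- stage("landscape", aggregateLandscape(perDs))
    writeTab(land, "landscape.tsv")
    results$landscape <- land
    cons <- stage("landscape_consistency",
                  landscapeConsistency(datasets, complexes,
                                       nPerm = nPermLandscape,
                                       seed = .stageSeed(seed, "landscape"),
                                       minMembers = minMembers))
    writeTab(data.frame(mean_rho = cons$meanRho, p = cons$p),
             "landscape_consistency.tsv")
    results$consistency <- cons
  }

  profiles <- stage("stoichiometry", lapply(datasets, function(d)
    subunitVarianceZ(complexNormalize(d, complexes, trim = trim,
                                      minMembers = minMembers))))
  results$profiles <- profiles
  for (p in profiles)
    writeTab(cbind(dataset_id = datasetId(p), zTable(p)),
             paste0("zscores_", datasetId(p), ".tsv"))
  if (length(profiles) >= 2L) {
    calls <- stage("components", crossDatasetComponentTest(profiles))
    writeTab(calls, "component_calls.tsv")
    results$componentCalls <- calls
  }

  hasCovariates <- !is.null(metadata) &&
    all(c("sex", "diet") %in% names(metadata)) &&
    length(unique(stats::na.omit(metadata$sex[metadata$sex !=
                                              "unknown"]))) >= 2L &&
    length(unique(stats::na.omit(metadata$diet[metadata$diet !=
                                               "unknown"]))) >= 2L
  if (hasCovariates) {
    d1 <- datasets[[1L]]
    med <- complexMedianAbundance(d1, complexes, minSubunits = minMembers)
    diff <- stage("covariates", rbind(
      differentialModuleAbundance(med, metadata, "sex", qThreshold),
      differentialModuleAbundance(med, metadata, "diet", qThreshold)))
    writeTab(diff, "differential_abundance.tsv")
    results$differentialAbundance <- diff
    mod <- stage("moderated",
                 fitModeratedContrasts(profiles[[1L]], metadata,
                                       qThreshold = qThreshold))
    writeTab(mod, "stoichiometry_contrasts.tsv")
    results$moderatedContrasts <- mod
    verd <- stage("verdict", combineComplexVerdict(mod))
    writeTab(verd, "complex_verdicts.tsv")
    results$verdicts <- verd
    eff <- stage("effect_size",
                 effectSizeTable(d1, complexes, metadata,
                                 pathways = pathways, nPerm = nPermEffect,
                                 nPermPathway = nPermPathway,
                                 trim = trim, minMembers = minMembers,
                                 seed = .stageSeed(seed, "effect")))
    writeTab(eff$records, "effect_sizes.tsv")
    writeTab(eff$summary, "effect_size_summary.tsv")
    results$effectSizes <- eff
  } else {
    cat("covariates", "skipped: metadata lacks two-level sex/diet", "0",
        sep = "\t", file = manifest, append = TRUE)
    cat("\n", file = manifest, append = TRUE)
  }
  invisible(results)
}

#' Plot a module-recovery ROC curve
#'
#' Minimal base-graphics ROC plot for a \code{\link{covariationRecord}}.
#'
#' @param record a record with attribute \code{"rocPoints"}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the ROC points.
#' @export
plotRoc <- function(record, ...) {
  pts <- attr(record, "rocPoints")
  if (is.null(pts)) stop("record carries no ROC points")
  plot(pts$fpr, pts$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("%s / %s (AUC = %.3f)", record$dataset_id,
                      record$category, record$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(pts)
}
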
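#' Run the full diagnosis pipeline
#'
#' Orchestrates the four stages on a synthetic study (or one loaded with
#' [readStudyCsv()]): preprocessing, phase division with a common threshold
#' and modal phase count, reference-phase-driven basis assignment and feature
#' extraction fused with offline data, and contrastive-cluster PCA against
#' the background cluster plus a one-tailed Welch t-test of the cluster
#' productivities.  A second run with identical inputs and seed produces an
#' identical report.  When `outDir` is given every intermediate artifact is
#' persisted (clean study CSVs, segmentation JSON, basis-spec YAML, feature
#' CSV, contrast JSON) so each stage can be re-run and audited independently.
#'
#' @param config a [SyntheticConfig-class], used when `study` is `NULL`.
#' @param labels cluster labels per batch for synthetic generation.
#' @param study optional pre-built list of [BatchRecord-class] (overrides
#'   `config`).
#' @param seed master seed for generation.
#' @param meta variable metadata for preprocessing.
#' @param params a [KnnParams-class].
#' @param spec a [BasisSpec-class], or `"auto"` to derive one from the
#'   reference phases.
#' @param backgroundCluster label of the background (e.g. low-productivity)
#'   cluster.
#' @param alpha numeric contrastive parameter, or `"auto"` for silhouette
#'   selection via [selectAlpha()].
#' @param scaling feature scaling for the contrast step.
#' @param discardMissingThreshold passed to [preprocessStudy()].
#' @param outDir optional directory for intermediate artifacts.
#' @return a [RunReport-class].
#' @export
runPipeline <- function(config = syntheticConfig(), labels = NULL,
                        study = NULL, seed = config@seed,
                        meta = NULL, params = knnParams(),
                        spec = "auto", backgroundCluster = "low",
                        alpha = "auto", scaling = "zscore",
                        discardMissingThreshold = 0.3, outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  if (is.null(study)) {
    if (is.null(labels))
      labels <- rep(names(config@productivity),
                    length.out = config@nBatches)
    study <- stage("simulate", generateStudy(config, labels, seed))
  }
  if (is.null(meta))
    meta <- tryCatch(defaultVariableMeta(config),
                     error = function(e) variableMeta(rownames(study[[1]]@inline)))

  pre <- stage("preprocess",
               preprocessStudy(study, meta, discardMissingThreshold))
  clean <- pre$study

  segres <- stage("phases", segmentStudy(clean, params))
  keep <- vapply(clean, batchId, "") %in% names(segres$segmentations)
  clean <- clean[keep]

  if (identical(spec, "auto"))
    spec <- stage("features", assignBasisSpec(clean, segres$segmentations))
  inlineSE <- stage("features",
                    buildFeatureMatrix(clean, segres$segmentations, spec))
  extended <- stage("features", fuseOffline(inlineSE, clean))

  if (identical(alpha, "auto"))
    alpha <- stage("contrast",
                   selectAlpha(extended, backgroundCluster,
                               scaling = scaling))$alpha
  contrast <- stage("contrast",
                    ccpcaContributions(extended, backgroundCluster,
                                       alpha = alpha, scaling = scaling))
  cl <- SummarizedExperiment::colData(extended)$cluster
  prods <- SummarizedExperiment::colData(extended)$productivity
  ptest <- stage("contrast",
                 compareProductivity(prods[cl != backgroundCluster],
                                     prods[cl == backgroundCluster]))

  dims <- c(batches = ncol(extended),
            inline = nrow(inlineSE),
            offline = nrow(extended) - nrow(inlineSE),
            extended = nrow(extended))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeStudyCsv(clean, file.path(outDir, "clean"))
    for (id in names(segres$segmentations))
      writeSegmentationJson(segres$segmentations[[id]],
                            file.path(outDir, paste0("segmentation_", id, ".json")))
    writeBasisSpecYaml(spec, file.path(outDir, "basis_spec.yaml"))
    writeFeatureCsv(extended, file.path(outDir, "features.csv"))
    writeContrastJson(contrast, file.path(outDir, "contrast.json"))
  }

  new("RunReport", filterReport = pre$report,
      phaseCounts = segres$phaseCounts, delta = segres$delta,
      basisSpec = spec, featureDims = dims, contrast = contrast,
      productivityTest = ptest, seed = as.numeric(seed),
      params = list(knn = params, background = backgroundCluster,
                    alpha = alpha, scaling = scaling,
                    discard_missing_threshold = discardMissingThreshold,
                    rejected_batches = segres$rejected))
}
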
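#' @rdname BatchRecord-class
#' @param object,x a package object.
#' @export
setGeneric("batchId", function(x) standardGeneric("batchId"))

#' @rdname BatchRecord-class
#' @export
setGeneric("inlineData", function(x) standardGeneric("inlineData"))

#' @rdname BatchRecord-class
#' @export
setGeneric("inlineTimes", function(x) standardGeneric("inlineTimes"))

#' @rdname BatchRecord-class
#' @export
setGeneric("offlineData", function(x) standardGeneric("offlineData"))

#' @rdname BatchRecord-class
#' @export
setGeneric("productivity", function(x) standardGeneric("productivity"))

#' @rdname BatchRecord-class
#' @export
setGeneric("clusterLabel", function(x) standardGeneric("clusterLabel"))

#' Compute or extract a moving-window kNN set-distance profile
#'
#' For a [BatchRecord-class] the profile is computed (see the details in
#' [knnSetDistance()]); for a [PhaseSegmentation-class] the stored profile is
#' returned.
#'
#' @param x a `BatchRecord` or `PhaseSegmentation`.
#' @param ... for `BatchRecord`, `params`, a [KnnParams-class].
#' @return numeric vector with one distance per inline sample.
#' @export
setGeneric("distanceProfile", function(x, ...) standardGeneric("distanceProfile"))

#' @rdname PhaseSegmentation-class
#' @export
setGeneric("stablePhases", function(x) standardGeneric("stablePhases"))

#' @rdname PhaseSegmentation-class
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @rdname PhaseSegmentation-class
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname BasisSpec-class
#' @export
setGeneric("basisEntries", function(x) standardGeneric("basisEntries"))

#' Total number of inline coefficient features implied by a basis spec
#'
#' The inline feature-matrix width is the sum of the basis counts over all
#' (variable, phase) entries; with a shared spec across batches this is the
#' number of columns of the inline coefficient block for any batch count.
#'
#' @param x a [BasisSpec-class].
#' @return integer feature count.
#' @export
setGeneric("nInlineFeatures", function(x) standardGeneric("nInlineFeatures"))

#' @rdname ContrastResult-class
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname ContrastResult-class
#' @export
setGeneric("featureRanking", function(x) standardGeneric("featureRanking"))

#' @rdname ContrastResult-class
#' @export
setGeneric("contrastLoadings", function(x) standardGeneric("contrastLoadings"))

# ---- accessors ----

#' @rdname BatchRecord-class
#' @export
setMethod("batchId", "BatchRecord", function(x) x@batchId)

#' @rdname BatchRecord-class
#' @export
setMethod("inlineData", "BatchRecord", function(x) x@inline)

#' @rdname BatchRecord-class
#' @export
setMethod("inlineTimes", "BatchRecord", function(x) x@inlineTimes)

#' @rdname BatchRecord-class
#' @export
setMethod("offlineData", "BatchRecord", function(x) x@offline)

#' @rdname BatchRecord-class
#' @export
setMethod("productivity", "BatchRecord", function(x) x@productivity)

#' @rdname BatchRecord-class
#' @export
setMethod("clusterLabel", "BatchRecord", function(x) x@clusterLabel)

#' @rdname PhaseSegmentation-class
#' @export
setMethod("distanceProfile", "PhaseSegmentation", function(x, ...) x@distanceProfile)

#' @rdname PhaseSegmentation-class
#' @export
setMethod("stablePhases", "PhaseSegmentation", function(x) x@stablePhases)

#' @rdname PhaseSegmentation-class
#' @export
setMethod("transitions", "PhaseSegmentation", function(x) x@transitions)

#' @rdname PhaseSegmentation-class
#' @export
setMethod("nPhases", "PhaseSegmentation", function(x) nrow(x@stablePhases))

#' @rdname BasisSpec-class
#' @export
setMethod("basisEntries", "BasisSpec", function(x) x@entries)

#' @rdname nInlineFeatures
#' @export
setMethod("nInlineFeatures", "BasisSpec", function(x) as.integer(sum(x@entries$n_basis)))

#' @rdname ContrastResult-class
#' @export
setMethod("contributions", "ContrastResult", function(x) x@contributions)

#' @rdname ContrastResult-class
#' @export
setMethod("featureRanking", "ContrastResult", function(x) x@ranking)

#' @rdname ContrastResult-class
#' @export
setMethod("contrastLoadings", "ContrastResult", function(x) x@loadings)

# ---- show methods ----

setMethod("show", "BatchRecord", function(object) {
  cat(sprintf("BatchRecord '%s': %d inline variables x %d samples, %d offline variables x %d days\n",
              object@batchId, nrow(object@inline), ncol(object@inline),
              nrow(object@offline), ncol(object@offline)))
  cat(sprintf("  productivity %.3f, cluster %s, %d missing inline values\n",
              object@productivity, object@clusterLabel,
              sum(is.na(object@inline))))
})

setMethod("show", "KnnParams", function(object) {
  cat(sprintf("KnnParams: L=%d, k=%d, delta=%s, minPhaseLength=%d, standardize=%s\n",
              as.integer(object@L), as.integer(object@k),
              if (is.na(object@delta)) "auto" else format(object@delta),
              as.integer(object@minPhaseLength), object@standardize))
})

setMethod("show", "PhaseSegmentation", function(object) {
  cat(sprintf("PhaseSegmentation: %d stable phases, %d transitions, delta=%.4g\n",
              nrow(object@stablePhases), nrow(object@transitions), object@delta))
  if (nrow(object@stablePhases))
    cat("  stable lengths:",
        paste(object@stablePhases[, 2] - object@stablePhases[, 1], collapse = ", "), "\n")
})

setMethod("show", "BasisSpec", function(object) {
  e <- object@entries
  cat(sprintf("BasisSpec: %d entries over %d variables x %d phases, %d coefficients total\n",
              nrow(e), length(unique(e$variable)), length(unique(e$phase)),
              sum(e$n_basis)))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d batches discarded, %d variables discarded, %d kept\n",
              nrow(object@batchesDiscarded), nrow(object@variablesDiscarded),
              length(object@variablesKept)))
})

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("ContrastResult: alpha=%.4g, %d features, background=%s\n",
              object@alpha, length(object@contributions), object@background))
  cat("Top contributions:\n")
  print(utils::head(object@ranking, 5))
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport\n")
  cat(sprintf("  batches analysed: %d (discarded: %d)\n",
              object@featureDims[["batches"]],
              nrow(object@filterReport@batchesDiscarded)))
  cat(sprintf("  phases per batch: %s; delta=%.4g\n",
              paste(unique(object@phaseCounts), collapse = "/"), object@delta))
  cat(sprintf("  features: %d inline + %d offline = %d\n",
              object@featureDims[["inline"]], object@featureDims[["offline"]],
              object@featureDims[["extended"]]))
  pt <- object@productivityTest
  cat(sprintf("  productivity: target %.3f vs background %.3f, one-tailed p=%.3g\n",
              pt$mean_target, pt$mean_background, pt$p_value))
  cat("  top contrast features:\n")
  print(utils::head(object@contrast@ranking, 5))
})
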
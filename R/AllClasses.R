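#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib batchlens, .registration = TRUE
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Configuration for the synthetic fed-batch data generator
#'
#' Describes a simulated fed-batch cell-culture study: run length, inline
#' sampling interval, the inline and offline variable sets with their
#' trajectory families and noise levels, feed events (medium additions that
#' produce a volume step plus a short high-variance disturbance on the other
#' sensors), cluster-level effects, per-cluster productivity distributions,
#' and optional data-quality defects.  Use [syntheticConfig()] to construct
#' one with defaults mirroring a typical 12-day, 9-inline-variable,
#' 7-offline-variable monoclonal-antibody culture.
#'
#' @slot nBatches number of batches to generate.
#' @slot nDays run length in days.
#' @slot sampleIntervalS inline sampling interval in seconds.
#' @slot inlineVariables data.frame with columns `name`, `family`
#'   (`smooth`, `step`, `ramp`, `quadratic`, `volume`), `level`, `amplitude`,
#'   `noise_sd`, `disturbance`, `valid_low`, `valid_high`.
#' @slot offlineVariables data.frame with columns `name`, `family`
#'   (`logistic`, `decline`, `ramp`, `flat`, `hump`), `start`, `end`,
#'   `noise_sd`.
#' @slot feedTimes day offsets of the medium feed events.
#' @slot feedVolumeStep volume step per feed event (L).
#' @slot feedDisturbanceMin duration of the post-feed sensor disturbance
#'   (minutes).
#' @slot feedNoiseMult noise-sd multiplier during the disturbance.
#' @slot clusterEffects named list: cluster label -> list of effects, each a
#'   list with `kind` (`"inline"` or `"offline"`), `variable`, `days`
#'   (length-2 day window), `shift` (additive mean shift).
#' @slot productivity named list: cluster label -> c(mean, sd) of the
#'   dimensionless scaled productivity.
#' @slot lengthJitter fractional jitter of the inline batch length, so that
#'   batches have unequal numbers of samples.
#' @slot missingFraction fraction of inline samples lost to simulated
#'   network outages (contiguous runs, all variables at once).
#' @slot spikeCount number of single-point out-of-range sensor spikes.
#' @slot seed default master seed.
#' @export
setClass("SyntheticConfig",
  representation(
    nBatches = "numeric", nDays = "numeric", sampleIntervalS = "numeric",
    inlineVariables = "data.frame", offlineVariables = "data.frame",
    feedTimes = "numeric", feedVolumeStep = "numeric",
    feedDisturbanceMin = "numeric", feedNoiseMult = "numeric",
    clusterEffects = "list", productivity = "list",
    lengthJitter = "numeric", missingFraction = "numeric",
    spikeCount = "numeric", seed = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  ft <- object@feedTimes
  if (length(ft) && (any(diff(ft) <= 0) || any(ft <= 0) || any(ft >= object@nDays)))
    msg <- c(msg, "feedTimes must be strictly increasing within (0, nDays)")
  if (object@missingFraction < 0 || object@missingFraction >= 1)
    msg <- c(msg, "missingFraction must be in [0, 1)")
  if (object@spikeCount < 0) msg <- c(msg, "spikeCount must be >= 0")
  if (any(object@inlineVariables$noise_sd < 0) ||
      any(object@offlineVariables$noise_sd < 0))
    msg <- c(msg, "noise sds must be >= 0")
  if (!all(names(object@clusterEffects) %in% names(object@productivity)))
    msg <- c(msg, "every clusterEffects label needs a productivity entry")
  if (length(msg)) msg else TRUE
})

#' A single fed-batch culture batch
#'
#' Holds one batch's inline sensor matrix (variables x time points), the
#' offline assay matrix (variables x days), its scaled productivity, an
#' optional cluster label and free-form metadata (the synthetic generator
#' records ground truth such as feed times and injected defect positions
#' there).  Batches may have different numbers of inline samples; the inline
#' matrix may contain `NA` sentinels before preprocessing.
#'
#' @slot batchId character identifier.
#' @slot inline numeric matrix, variables in rows, time points in columns.
#' @slot inlineTimes strictly increasing sample times in seconds.
#' @slot offline numeric matrix, variables in rows, days in columns.
#' @slot productivity positive scaled productivity.
#' @slot clusterLabel cluster label or `NA`.
#' @slot metadata list of extra information.
#' @export
setClass("BatchRecord",
  representation(
    batchId = "character", inline = "matrix", inlineTimes = "numeric",
    offline = "matrix", productivity = "numeric", clusterLabel = "character",
    metadata = "list"
  )
)

setValidity("BatchRecord", function(object) {
  msg <- character()
  if (ncol(object@inline) != length(object@inlineTimes))
    msg <- c(msg, "inline columns must match inlineTimes length")
  if (length(object@inlineTimes) > 1 && any(diff(object@inlineTimes) <= 0))
    msg <- c(msg, "inlineTimes must be strictly increasing")
  if (is.null(rownames(object@inline)))
    msg <- c(msg, "inline must have variable rownames")
  if (nrow(object@offline) > 0 && is.null(rownames(object@offline)))
    msg <- c(msg, "offline must have variable rownames")
  if (length(object@productivity) != 1 || object@productivity <= 0)
    msg <- c(msg, "productivity must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Parameters of the moving-window kNN set distance
#'
#' @slot L window half-length in samples: the window for sample t spans
#'   `[t - L, t + L]`, clipped at the batch boundaries.
#' @slot k number of nearest neighbours averaged in the set distance.
#' @slot delta transition threshold on the distance profile (`NA` = choose
#'   automatically from pooled profiles, see [chooseDelta()]).
#' @slot minPhaseLength stable runs shorter than this many samples are merged
#'   into the adjacent transition.
#' @slot minTransitionLength transitional runs shorter than this many samples
#'   are reclassified as stable: a genuine operating transition (a feed
#'   event) elevates the distance for its whole duration, while an isolated
#'   sensor-noise outlier elevates only its own sample.
#' @slot standardize z-score each variable (batch-level statistics) before
#'   computing Euclidean distances, so that the mixed-unit variable set
#'   (pH, degrees C, L/min, L) contributes comparably.
#' @export
setClass("KnnParams",
  representation(L = "numeric", k = "numeric", delta = "numeric",
                 minPhaseLength = "numeric", minTransitionLength = "numeric",
                 standardize = "logical")
)

setValidity("KnnParams", function(object) {
  msg <- character()
  if (object@k > 2 * object@L)
    msg <- c(msg, "k must be <= 2*L so neighbours exist inside the window")
  if (object@k < 1 || object@L < 1) msg <- c(msg, "L and k must be >= 1")
  if (!is.na(object@delta) && object@delta <= 0)
    msg <- c(msg, "delta must be > 0")
  if (object@minPhaseLength < 1) msg <- c(msg, "minPhaseLength must be >= 1")
  if (object@minTransitionLength < 1)
    msg <- c(msg, "minTransitionLength must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Phase segmentation of one batch
#'
#' Result of thresholding a batch's kNN set-distance profile: maximal runs of
#' samples with distance above the threshold are transition intervals, the
#' remaining runs are stable phases.  Intervals are half-open `[start, end)`
#' in 1-based sample indices.
#'
#' @slot distanceProfile the d(x_t) profile, one value per sample.
#' @slot stablePhases integer matrix with columns `start`, `end`.
#' @slot transitions integer matrix with columns `start`, `end`.
#' @slot params the [KnnParams-class] used.
#' @slot delta the threshold actually applied.
#' @export
setClass("PhaseSegmentation",
  representation(distanceProfile = "numeric", stablePhases = "matrix",
                 transitions = "matrix", params = "KnnParams",
                 delta = "numeric")
)

setValidity("PhaseSegmentation", function(object) {
  iv <- rbind(object@stablePhases, object@transitions)
  if (nrow(iv)) {
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[, 2] <= iv[, 1])) return("empty or inverted interval")
    if (nrow(iv) > 1 && any(iv[-1, 1] != iv[-nrow(iv), 2]))
      return("intervals must tile the index range without gaps or overlap")
  }
  TRUE
})

#' Basis specification for functional feature extraction
#'
#' One entry per (variable, phase): the basis family (`bspline_degree3` or
#' `polynomial`) and the number of basis functions M.  The same entry is
#' applied to that variable/phase in every batch, which is what makes the
#' extracted coefficients comparable across batches of unequal length.
#' For `polynomial`, M basis functions mean highest degree M - 1; for
#' `bspline_degree3`, M >= 4.
#'
#' @slot entries data.frame with columns `variable`, `phase`, `family`,
#'   `n_basis`.
#' @export
setClass("BasisSpec", representation(entries = "data.frame"))

setValidity("BasisSpec", function(object) {
  e <- object@entries
  need <- c("variable", "phase", "family", "n_basis")
  if (!all(need %in% names(e))) return("entries must have variable, phase, family, n_basis")
  if (!all(e$family %in% c("bspline_degree3", "polynomial")))
    return("family must be bspline_degree3 or polynomial")
  if (any(e$n_basis < 1)) return("n_basis must be >= 1")
  if (any(e$family == "bspline_degree3" & e$n_basis < 4))
    return("bspline_degree3 requires n_basis >= 4")
  if (anyDuplicated(e[, c("variable", "phase")]))
    return("duplicate (variable, phase) entry")
  TRUE
})

#' Report of the preprocessing filters
#'
#' @slot batchesDiscarded data.frame with columns `batch_id`,
#'   `missing_fraction` for batches removed by the missing-data rule.
#' @slot variablesDiscarded data.frame with columns `name`, `reason`
#'   (`missing`, `not_linked`, `low_inner_variance`, `low_inter_variance`).
#' @slot variablesKept character vector of surviving inline variables.
#' @slot innerVariances named numeric, median inner-batch variance per
#'   variable on standardized units.
#' @slot interVariances named numeric, inter-batch variance of per-batch
#'   means (standardized units); `NA` where the inner-batch rule already kept
#'   the variable.
#' @export
setClass("FilterReport",
  representation(batchesDiscarded = "data.frame",
                 variablesDiscarded = "data.frame",
                 variablesKept = "character",
                 innerVariances = "numeric", interVariances = "numeric")
)

#' Reference-phase selection report
#'
#' For every phase, the indicator H combining relative phase length and
#' relative trajectory roughness for each batch, and the batch chosen as the
#' reference (the H maximiser) whose curve drives basis-type and
#' basis-count selection.
#'
#' @slot indicators data.frame with columns `phase`, `batch_id`, `H`,
#'   `length`.
#' @slot reference named character vector, phase -> reference batch id.
#' @slot excludedVariables variables excluded from the roughness sum because
#'   their roughness is zero in every batch.
#' @export
setClass("ReferenceReport",
  representation(indicators = "data.frame", reference = "character",
                 excludedVariables = "character")
)

#' Result of a contrastive-cluster PCA
#'
#' @slot alpha contrastive parameter used.
#' @slot eigenvalues spectrum of `C_E - alpha * C_R`, descending.
#' @slot loadings signed first contrastive PC loading vector (unit norm).
#' @slot contributions absolute loadings, one per feature.
#' @slot ranking data.frame of features sorted by decreasing contribution,
#'   carrying the feature metadata columns.
#' @slot background label or description of the background row set.
#' @slot flaggedConstant features whose column was constant under z-score
#'   scaling (scale fixed to 1).
#' @export
setClass("ContrastResult",
  representation(alpha = "numeric", eigenvalues = "numeric",
                 loadings = "numeric", contributions = "numeric",
                 ranking = "data.frame", background = "character",
                 flaggedConstant = "character")
)

setValidity("ContrastResult", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-8)
    msg <- c(msg, "loadings must have unit norm")
  if (any(object@contributions < 0) || !any(object@contributions > 0))
    msg <- c(msg, "contributions must be >= 0 with at least one > 0")
  if (length(msg)) msg else TRUE
})

#' Report of a full pipeline run
#'
#' @slot filterReport the preprocessing [FilterReport-class].
#' @slot phaseCounts named integer, stable-phase count per batch.
#' @slot delta the distance threshold used for segmentation.
#' @slot basisSpec the [BasisSpec-class] used.
#' @slot featureDims named integer: inline, offline and extended feature
#'   counts plus batch count.
#' @slot contrast the [ContrastResult-class].
#' @slot productivityTest list with `mean_target`, `mean_background`,
#'   `p_value` from the one-tailed Welch t-test.
#' @slot seed master seed of the run.
#' @slot params echo of the run parameters.
#' @export
setClass("RunReport",
  representation(filterReport = "FilterReport", phaseCounts = "integer",
                 delta = "numeric", basisSpec = "BasisSpec",
                 featureDims = "integer", contrast = "ContrastResult",
                 productivityTest = "list", seed = "numeric", params = "list")
)
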
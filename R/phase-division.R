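#' Construct moving-window kNN parameters
#'
#' Defaults follow common plant practice for 10 s historian data: a window
#' half-length of 1200 samples (200 min) and k = 300 neighbours (50 min of
#' samples).  For coarser resampled data scale both with the sampling
#' interval or pass values directly.
#'
#' @param L window half-length in samples.
#' @param k neighbour count (`k <= 2L`).
#' @param delta transition threshold; `NA` to choose automatically.
#' @param minPhaseLength minimal stable-phase length in samples.
#' @param minTransitionLength transitional runs shorter than this are
#'   reclassified as stable (isolated noise outliers are not transitions).
#' @param standardize z-score variables before distances (recommended for
#'   mixed-unit data).
#' @return a [KnnParams-class].
#' @export
knnParams <- function(L = 1200, k = 300, delta = NA_real_,
                      minPhaseLength = 60, minTransitionLength = 3,
                      standardize = TRUE) {
  new("KnnParams", L = L, k = k, delta = as.numeric(delta),
      minPhaseLength = minPhaseLength,
      minTransitionLength = minTransitionLength, standardize = standardize)
}

scaleColumns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Moving-window kNN set distance at one sample
#'
#' The mean of the squared Euclidean distances from sample `t` to its `k`
#' nearest neighbours within the window `[t - L, t + L]` (clipped at the
#' series boundaries), excluding the sample itself.  Samples inside a stable
#' operating phase have many close neighbours and a small distance; samples
#' in a short, highly dynamic transition (e.g. during a feed event) are far
#' from everything in their window and score high.  Ties between equidistant
#' neighbours are broken by lower time index; the distance value is
#' unaffected.
#'
#' @param X numeric matrix, samples in rows, variables in columns.
#' @param t sample index (1-based).
#' @param params a [KnnParams-class]; if `params@standardize`, distances are
#'   computed on per-variable z-scored columns (statistics over all of `X`).
#' @return nonnegative scalar.
#' @examples
#' X <- matrix(c(0, 0, 0, 10, 0, 0, 0), ncol = 1)
#' knnSetDistance(X, 4, knnParams(L = 2, k = 2, standardize = FALSE))  # 100
#' @export
knnSetDistance <- function(X, t, params) {
  stopifnot(is(params, "KnnParams"))
  validObject(params)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  if (t < 1 || t > nrow(X)) stop("t out of range")
  if (params@standardize) X <- scaleColumns(X)
  .knn_point_cpp(X, as.integer(t), as.integer(params@L), as.integer(params@k))
}

#' @rdname distanceProfile
#' @export
setMethod("distanceProfile", "BatchRecord", function(x, ...) {
  args <- list(...)
  params <- if (length(args)) args[[1]] else knnParams()
  stopifnot(is(params, "KnnParams"))
  X <- t(x@inline)
  if (anyNA(X)) stop("batch must be preprocessed (no missing values)")
  if (nrow(X) < 2 * params@L + 1)
    stop("batch of length ", nrow(X), " is shorter than 2L+1 = ",
         2 * params@L + 1)
  if (params@standardize) X <- scaleColumns(X)
  .knn_profile_cpp(X, as.integer(params@L), as.integer(params@k))
})

#' Choose the transition threshold from pooled distance profiles
#'
#' The default rule (`method = "median"`) sets the threshold to a multiple of
#' the pooled profile median.  The stable bulk of a kNN set-distance profile
#' is tightly concentrated (each value averages k squared distances), while
#' feed transitions exceed the stable level by well over the default
#' multiplier, so a median multiple separates the two regimes without flagging
#' any stable samples.  `method = "quantile"` instead returns the plain
#' pooled q-quantile (linear-interpolation type 7), useful when transitions
#' are known to occupy more than `1 - q` of the samples.
#'
#' @param profiles list of numeric distance profiles (or one vector).
#' @param q quantile for `method = "quantile"`.
#' @param method `"median"` or `"quantile"`.
#' @param multiplier median multiplier for `method = "median"`.
#' @return list with `delta`, `method`, `pooled` summary quantiles, and
#'   `histogram` (a [graphics::hist()] object, not plotted) for inspection.
#' @export
chooseDelta <- function(profiles, q = 0.95, method = c("median", "quantile"),
                        multiplier = 10) {
  method <- match.arg(method)
  if (q <= 0 || q >= 1) stop("q must be inside (0, 1)")
  pooled <- unlist(profiles)
  if (!length(pooled)) stop("profiles must be nonempty")
  delta <- switch(method,
    median = multiplier * stats::median(pooled),
    quantile = unname(stats::quantile(pooled, q, type = 7))
  )
  list(delta = delta, method = method,
       pooled = stats::quantile(pooled, c(0, 0.25, 0.5, 0.75, 0.95, 1)),
       histogram = graphics::hist(pooled, plot = FALSE))
}

#' Segment a distance profile into stable phases and transitions
#'
#' Samples with distance above `delta` are transitional; maximal transitional
#' runs become transition intervals and the remaining maximal runs stable
#' phases.  Transitional runs shorter than `minTransitionLength` are first
#' reclassified as stable (an isolated distance spike is a noise outlier, not
#' an operating transition), then stable runs shorter than `minPhaseLength`
#' are merged into the adjacent transition (repeatedly, until stable).  When
#' no transition touches a boundary, the number of stable phases is the
#' number of transitions plus one.
#'
#' @param profile numeric distance profile.
#' @param params a [KnnParams-class]; its `delta` is used unless overridden.
#' @param delta optional threshold override.
#' @return a [PhaseSegmentation-class] with half-open 1-based `[start, end)`
#'   intervals.
#' @export
segmentPhases <- function(profile, params, delta = params@delta) {
  stopifnot(is(params, "KnnParams"))
  if (is.na(delta)) stop("delta must be set (see chooseDelta)")
  flag <- profile > delta
  if (all(flag)) stop("all samples transitional; raise delta")
  if (params@minTransitionLength > 1) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths < params@minTransitionLength))
      flag[starts[i]:ends[i]] <- FALSE
  }
  repeat {
    r <- rle(flag)
    short <- !r$values & r$lengths < params@minPhaseLength
    # boundary stable runs are kept only if a transition exists beside them
    if (!any(short)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(short)) flag[starts[i]:ends[i]] <- TRUE
    if (all(flag)) stop("all samples transitional after merging; raise delta")
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  stable <- cbind(start = as.integer(starts[!r$values]),
                  end = as.integer(ends[!r$values]) + 1L)
  trans <- cbind(start = as.integer(starts[r$values]),
                 end = as.integer(ends[r$values]) + 1L)
  new("PhaseSegmentation", distanceProfile = profile,
      stablePhases = stable, transitions = trans, params = params,
      delta = delta)
}

#' Segment every batch of a study with a common threshold
#'
#' Computes the distance profile of each batch, chooses a global threshold
#' (unless `params@delta` is set), segments each batch, and forces a common
#' phase count: the modal stable-phase count across batches is taken as the
#' study's phase count and batches that disagree are set aside with a report
#' rather than silently kept.
#'
#' @param study list of preprocessed [BatchRecord-class].
#' @param params a [KnnParams-class].
#' @param deltaMethod,deltaQ,deltaMultiplier passed to [chooseDelta()] when
#'   `params@delta` is `NA`.
#' @return list with `segmentations` (named by batch id, conforming batches
#'   only), `delta`, `phaseCount` (modal), `phaseCounts` (all batches), and
#'   `rejected` (ids of nonconforming batches).
#' @export
segmentStudy <- function(study, params = knnParams(),
                         deltaMethod = "median", deltaQ = 0.95,
                         deltaMultiplier = 10) {
  profiles <- lapply(study, distanceProfile, params)
  delta <- if (is.na(params@delta))
    chooseDelta(profiles, q = deltaQ, method = deltaMethod,
                multiplier = deltaMultiplier)$delta
  else params@delta
  segs <- lapply(profiles, segmentPhases, params = params, delta = delta)
  names(segs) <- vapply(study, batchId, "")
  counts <- vapply(segs, nPhases, 0L)
  tab <- table(counts)
  modal <- as.integer(names(tab)[which.max(tab)])
  rejected <- names(segs)[counts != modal]
  list(segmentations = segs[counts == modal], delta = delta,
       phaseCount = modal, phaseCounts = counts, rejected = rejected)
}
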
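#' Construct an inline variable metadata table
#'
#' Engineering metadata used by the variable filter: measurement/setting/
#' status/accessory category, whether the sensor is directly linked to the
#' bioreactor (as opposed to, e.g., CIP skids or pipeline temperatures), and
#' an optional physically valid range for spike repair.
#'
#' @param name variable names.
#' @param category one of `measurement`, `setting`, `status`, `accessory`
#'   (recycled).
#' @param linked logical, directly linked to the bioreactor (recycled).
#' @param validLow,validHigh optional valid range bounds (recycled; `NA` for
#'   none).
#' @return data.frame with one row per variable.
#' @export
variableMeta <- function(name, category = "measurement", linked = TRUE,
                         validLow = NA_real_, validHigh = NA_real_) {
  out <- data.frame(name = name, category = category, linked = linked,
                    valid_low = validLow, valid_high = validHigh,
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$valid_low) & !is.na(out$valid_high) &
    out$valid_low >= out$valid_high
  if (any(bad)) stop("valid_low must be < valid_high")
  if (!all(out$category %in% c("measurement", "setting", "status", "accessory")))
    stop("unknown category")
  out
}

#' Variable metadata matching a synthetic configuration
#'
#' @param config a [SyntheticConfig-class].
#' @return data.frame as from [variableMeta()].
#' @export
defaultVariableMeta <- function(config = syntheticConfig()) {
  iv <- config@inlineVariables
  variableMeta(iv$name, validLow = iv$valid_low, validHigh = iv$valid_high)
}

#' Fraction of missing values in a series
#'
#' @param series numeric vector with `NA` marking missing samples.
#' @return fraction in [0, 1].
#' @export
missingFraction <- function(series) {
  if (!length(series)) stop("empty series")
  mean(is.na(series))
}

# Maximal runs of NA in a logical index space: matrix (start, end) inclusive.
naRuns <- function(isna) {
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Impute missing values by neighbouring means
#'
#' Each maximal run of missing values is replaced by the mean of the nearest
#' valid point before and after the run (network outages produce contiguous
#' runs, inside which pointwise neighbour means are undefined).  A run
#' touching either boundary is filled with the single nearest valid value.
#' Non-missing entries are never altered.
#'
#' @param series numeric vector with `NA` marking missing samples.
#' @param maxGap runs longer than this raise an error (default unlimited).
#' @return the series with no missing values.
#' @examples
#' imputeMissing(c(1, NA, 3))      # 1 2 3
#' imputeMissing(c(2, NA, NA, 6))  # 2 4 4 6
#' @export
imputeMissing <- function(series, maxGap = Inf) {
  if (!length(series)) stop("empty series")
  if (all(is.na(series))) stop("all-missing series cannot be imputed")
  runs <- naRuns(is.na(series))
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    if (b - a + 1 > maxGap)
      stop("missing run of length ", b - a + 1, " exceeds maxGap = ", maxGap)
    left <- if (a > 1) series[a - 1] else NA_real_
    right <- if (b < length(series)) series[b + 1] else NA_real_
    fill <- mean(c(left, right), na.rm = TRUE)
    series[a:b] <- fill
  }
  series
}

#' Repair out-of-range spikes
#'
#' Every point falling outside the valid range is replaced by the mean of its
#' nearest in-range neighbours on each side (the single nearest one at a
#' boundary); consecutive out-of-range points are repaired as one run.
#' In-range points are unchanged.  If more than half of the points are out of
#' range the series has a problem that spike repair should not paper over,
#' and an error is raised.
#'
#' @param series numeric vector (no `NA`).
#' @param validRange numeric length-2 `c(low, high)`.
#' @return list with `series` (repaired) and `nRepaired`.
#' @examples
#' repairSpikes(c(7.0, 0.0, 7.2), c(4, 9))$series  # 7.0 7.1 7.2
#' @export
repairSpikes <- function(series, validRange) {
  stopifnot(length(validRange) == 2, validRange[1] < validRange[2])
  out <- series < validRange[1] | series > validRange[2]
  out[is.na(out)] <- FALSE
  nRepaired <- sum(out)
  if (nRepaired > 0.5 * sum(!is.na(series)))
    stop("more than 50% of points out of range; not a spike problem")
  if (nRepaired) {
    tmp <- series
    tmp[out] <- NA_real_
    series <- imputeMissing(tmp)
    series[is.na(tmp) & !out] <- NA_real_  # preserve genuine missing
  }
  list(series = series, nRepaired = nRepaired)
}

#' Filter low-information inline variables
#'
#' Three sub-steps: (a) variables not directly linked to the bioreactor, or of
#' category `status`/`accessory`, are dropped; (b) inner-batch filtering: per
#' batch, the variance of the variable on standardized units (pooled z-score
#' across all batches) is computed; if the median inner-batch variance
#' exceeds `innerVarThreshold` the variable is kept; (c) otherwise the
#' variance across batches of the per-batch means (inter-batch variance) must
#' exceed `interVarThreshold` for the variable to survive.  Step (c) retains
#' variables that are flat within each batch but differ between batches.
#'
#' @param study list of [BatchRecord-class].
#' @param meta data.frame from [variableMeta()].
#' @param innerVarThreshold,interVarThreshold variance thresholds on
#'   unit-variance-scaled data.
#' @return a [FilterReport-class].
#' @export
filterVariables <- function(study, meta, innerVarThreshold = 1e-6,
                            interVarThreshold = 1e-6) {
  stopifnot(length(study) >= 1, innerVarThreshold >= 0, interVarThreshold >= 0)
  vars <- rownames(study[[1]]@inline)
  for (b in study)
    if (!identical(rownames(b@inline), vars))
      stop("all batches must share the same variable set")

  discarded <- data.frame(name = character(), reason = character(),
                          stringsAsFactors = FALSE)
  m <- meta[match(vars, meta$name), ]
  drop <- !m$linked | m$category %in% c("status", "accessory")
  drop[is.na(drop)] <- FALSE
  if (any(drop))
    discarded <- rbind(discarded, data.frame(name = vars[drop],
                                             reason = "not_linked"))
  keepCand <- vars[!drop]

  innerVar <- interVar <- stats::setNames(rep(NA_real_, length(keepCand)), keepCand)
  kept <- character()
  for (v in keepCand) {
    pooled <- unlist(lapply(study, function(b) b@inline[v, ]))
    mu <- mean(pooled, na.rm = TRUE)
    sdv <- stats::sd(pooled, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    perBatch <- lapply(study, function(b) (b@inline[v, ] - mu) / sdv)
    innerVar[v] <- stats::median(vapply(perBatch, stats::var, 0, na.rm = TRUE))
    if (is.finite(innerVar[v]) && innerVar[v] > innerVarThreshold) {
      kept <- c(kept, v)
      next
    }
    if (length(study) < 2)
      stop("inter-batch filtering for '", v, "' requires more than one batch")
    means <- vapply(perBatch, mean, 0, na.rm = TRUE)
    interVar[v] <- stats::var(means)
    if (interVar[v] > interVarThreshold) {
      kept <- c(kept, v)
    } else {
      discarded <- rbind(discarded,
                         data.frame(name = v, reason = "low_inter_variance"))
    }
  }
  new("FilterReport",
      batchesDiscarded = data.frame(batch_id = character(),
                                    missing_fraction = numeric()),
      variablesDiscarded = discarded, variablesKept = kept,
      innerVariances = innerVar, interVariances = interVar)
}

#' Preprocess a study: missing data, spikes, variable filtering
#'
#' The full inline data-quality procedure.  First, variables whose pooled
#' missing fraction across all batches exceeds `discardMissingThreshold` are
#' dropped (reason `missing`).  Second, any batch in which some remaining
#' variable exceeds the threshold is discarded whole.  Third, remaining
#' missing runs are imputed by neighbouring means and out-of-range spikes are
#' repaired using the valid ranges in `meta`.  Finally low-information
#' variables are filtered via [filterVariables()].  The output study contains
#' no missing and no out-of-range inline values.
#'
#' @param study list of [BatchRecord-class].
#' @param meta data.frame from [variableMeta()].
#' @param discardMissingThreshold per-variable missing fraction above which a
#'   batch (or, pooled, a variable) is discarded; 0.3 by default.
#' @param innerVarThreshold,interVarThreshold passed to [filterVariables()].
#' @return list with `study` (clean) and `report` ([FilterReport-class]).
#' @export
preprocessStudy <- function(study, meta = defaultVariableMeta(),
                            discardMissingThreshold = 0.3,
                            innerVarThreshold = 1e-6,
                            interVarThreshold = 1e-6) {
  stopifnot(length(study) >= 1)
  vars <- rownames(study[[1]]@inline)

  pooledMiss <- vapply(vars, function(v)
    missingFraction(unlist(lapply(study, function(b) b@inline[v, ]))), 0)
  dropVars <- vars[pooledMiss > discardMissingThreshold]

  batchMiss <- vapply(study, function(b) {
    keep <- setdiff(vars, dropVars)
    max(vapply(keep, function(v) missingFraction(b@inline[v, ]), 0))
  }, 0)
  dropBatch <- batchMiss > discardMissingThreshold
  if (all(dropBatch)) stop("all batches discarded by the missing-data rule")

  discardedBatches <- data.frame(
    batch_id = vapply(study[dropBatch], batchId, ""),
    missing_fraction = batchMiss[dropBatch])
  study <- study[!dropBatch]

  study <- lapply(study, function(b) {
    inline <- b@inline[setdiff(vars, dropVars), , drop = FALSE]
    for (v in rownames(inline)) {
      x <- inline[v, ]
      if (anyNA(x)) x <- imputeMissing(x)
      mrow <- meta[meta$name == v, ]
      if (nrow(mrow) == 1 && !is.na(mrow$valid_low) && !is.na(mrow$valid_high))
        x <- repairSpikes(x, c(mrow$valid_low, mrow$valid_high))$series
      inline[v, ] <- x
    }
    b@inline <- inline
    b
  })

  rep <- filterVariables(study, meta, innerVarThreshold, interVarThreshold)
  if (length(dropVars))
    rep@variablesDiscarded <- rbind(
      data.frame(name = dropVars, reason = "missing"), rep@variablesDiscarded)
  rep@batchesDiscarded <- discardedBatches

  study <- lapply(study, function(b) {
    b@inline <- b@inline[rep@variablesKept, , drop = FALSE]
    b
  })
  list(study = study, report = rep)
}
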
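#' Default inline variable descriptors
#'
#' Mirrors the nine measurement variables of a typical fed-batch mAb culture:
#' two pH probes, two dissolved-oxygen probes, temperature, three gas flows
#' and the broth volume.  `family` controls the simulated trajectory shape,
#' `level`/`amplitude` its location and excursion, `noise_sd` the sensor
#' noise, `disturbance` the amplitude of the transient excursion after each
#' medium feed, and `valid_low`/`valid_high` the physically plausible range
#' used for spike injection and repair.
#'
#' @return data.frame of inline variable descriptors.
#' @export
defaultInlineVariables <- function() {
  data.frame(
    name = c("pH1", "pH2", "DO1", "DO2", "temperature",
             "air_sparger", "air_overlay", "o2_sparger", "volume"),
    family = c("smooth", "smooth", "step", "step", "step",
               "step", "step", "quadratic", "volume"),
    level = c(7.05, 7.02, 40, 40, 36.8, 2, 1, 0.5, 1000),
    amplitude = c(-0.2, -0.18, 0, 0, 0, 0, 0, 1.2, 5),
    noise_sd = c(0.01, 0.01, 1, 1, 0.05, 0.05, 0.02, 0.05, 0.5),
    disturbance = c(0.15, 0.15, 10, 10, 0.3, 0.5, 0.2, 0.3, 0),
    valid_low = c(4, 4, 0, 0, 30, 0, 0, 0, 0),
    valid_high = c(9, 9, 150, 150, 40, 10, 10, 10, 3000),
    stringsAsFactors = FALSE
  )
}

#' Default offline variable descriptors
#'
#' Mirrors the seven daily offline assays of a fed-batch culture: viable cell
#' density (1e6/mL), viability (%), mean cell diameter (um), agglomeration
#' ratio (%), offline pH, glucose and lactate concentrations (g/L).  `family`
#' selects the daily mean trajectory, interpolating from `start` (day 1) to
#' `end` (last day).
#'
#' @return data.frame of offline variable descriptors.
#' @export
defaultOfflineVariables <- function() {
  data.frame(
    name = c("VCD", "viability", "cell_diameter", "agglomeration",
             "pH_offline", "glucose", "lactate"),
    family = c("logistic", "decline", "ramp", "ramp", "flat", "decline", "hump"),
    start = c(2, 98, 14, 2, 7.0, 6, 1),
    end = c(25, 86, 17, 5, 6.9, 2.5, 2),
    noise_sd = c(0.8, 1, 0.2, 0.4, 0.03, 0.4, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Default cluster-level effects
#'
#' The "high" productivity cluster is shifted on exactly two feature groups,
#' mimicking a root cause localised in late culture: broth volume during the
#' final phase (days 8-12) is 20 L lower, and cell viability on days 10-12 is
#' 5 percentage points lower.  Every other variable is identically
#' distributed across clusters, so a correct contrastive analysis must rank
#' exactly these feature groups on top.
#'
#' @return named list of per-cluster effect lists.
#' @export
defaultClusterEffects <- function() {
  list(
    high = list(
      list(kind = "inline", variable = "volume", days = c(8, 12), shift = -20),
      list(kind = "offline", variable = "viability", days = c(10, 12), shift = -5)
    ),
    low = list()
  )
}

#' Construct a synthetic-study configuration
#'
#' @param nBatches number of batches.
#' @param nDays run length in days.
#' @param sampleIntervalS inline sampling interval in seconds (10 s emulates
#'   a plant historian; coarser values such as 60 s or 300 s are convenient
#'   for desk-scale analysis).
#' @param inlineVariables,offlineVariables variable descriptor tables, see
#'   [defaultInlineVariables()] and [defaultOfflineVariables()].
#' @param feedTimes day offsets of the medium feed events.
#' @param feedVolumeStep volume step per feed (L).
#' @param feedDisturbanceMin duration of the post-feed transient (minutes).
#' @param feedNoiseMult sensor-noise multiplier during the transient.
#' @param clusterEffects see [defaultClusterEffects()].
#' @param productivity named list label -> c(mean, sd).
#' @param lengthJitter fractional batch-length jitter.
#' @param missingFraction,spikeCount data-quality defects injected by
#'   [generateStudy()] via [injectQualityIssues()].
#' @param seed default master seed.
#' @return a [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(nBatches = 4, sampleIntervalS = 300)
#' b <- generateBatch(cfg, "high", seed = 1)
#' b
#' @export
syntheticConfig <- function(nBatches = 26, nDays = 12, sampleIntervalS = 10,
                            inlineVariables = defaultInlineVariables(),
                            offlineVariables = defaultOfflineVariables(),
                            feedTimes = c(2, 4, 6, 8),
                            feedVolumeStep = 40, feedDisturbanceMin = 30,
                            feedNoiseMult = 5,
                            clusterEffects = defaultClusterEffects(),
                            productivity = list(high = c(1.05, 0.01),
                                                low = c(0.961, 0.01)),
                            lengthJitter = 0.02, missingFraction = 0,
                            spikeCount = 0, seed = 1) {
  new("SyntheticConfig", nBatches = nBatches, nDays = nDays,
      sampleIntervalS = sampleIntervalS, inlineVariables = inlineVariables,
      offlineVariables = offlineVariables, feedTimes = feedTimes,
      feedVolumeStep = feedVolumeStep, feedDisturbanceMin = feedDisturbanceMin,
      feedNoiseMult = feedNoiseMult, clusterEffects = clusterEffects,
      productivity = productivity, lengthJitter = lengthJitter,
      missingFraction = missingFraction, spikeCount = spikeCount, seed = seed)
}

# Deterministic per-batch seed from (master seed, batch index); keeps seeds
# independent of generation order and below 2^31.
deriveSeed <- function(masterSeed, index) {
  as.integer((as.numeric(masterSeed) * 48271 + index * 16807) %% 2147483647)
}

offlineCurve <- function(family, start, end, day, nDays) {
  s <- (day - 1) / max(nDays - 1, 1)
  switch(family,
    logistic = start + (end - start) / (1 + exp(-8 * (s - 0.4))),
    decline = start + (end - start) * s^2,
    ramp = start + (end - start) * s,
    flat = start + (end - start) * s,
    hump = start + (end - start) * s + 3 * sin(pi * s) * exp(-2 * (s - 0.5)^2),
    stop("unknown offline family: ", family)
  )
}

#' Generate one synthetic batch
#'
#' Builds a [BatchRecord-class] with deterministic pseudo-random content:
#' smooth-curve variables follow a noisy smooth trajectory, step variables are
#' piecewise constant, the quadratic variable rises as the square of elapsed
#' time, and the volume is piecewise linear with one upward step per feed
#' event.  Each feed additionally triggers a short half-sine excursion plus
#' inflated noise on the variables with a nonzero `disturbance`, providing
#' the ground-truth transition periods for phase division.  Cluster effects
#' shift per-(variable, day-window) means for the given label.  The truth
#' (feed sample indices, transition windows, per-phase windows) is stored in
#' the record metadata.
#'
#' @param config a [SyntheticConfig-class].
#' @param clusterLabel label with entries in `config@clusterEffects`.
#' @param seed integer seed; identical (config, label, seed) give identical
#'   batches.
#' @param batchId identifier, default derived from the seed.
#' @return a [BatchRecord-class].
#' @export
generateBatch <- function(config, clusterLabel, seed, batchId = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (!clusterLabel %in% names(config@clusterEffects))
    stop("unknown cluster label '", clusterLabel, "'; known labels: ",
         paste(names(config@clusterEffects), collapse = ", "))
  set.seed(seed)
  iv <- config@inlineVariables
  dt <- config@sampleIntervalS
  nNominal <- floor(config@nDays * 86400 / dt)
  jit <- if (config@lengthJitter > 0)
    stats::runif(1, -config@lengthJitter, config@lengthJitter) else 0
  n <- max(2, floor(nNominal * (1 + jit)))
  times <- (seq_len(n) - 1) * dt
  day <- times / 86400
  s <- times / (config@nDays * 86400)

  feedSec <- config@feedTimes * 86400
  durSec <- config@feedDisturbanceMin * 60
  inline <- matrix(0, nrow(iv), n, dimnames = list(iv$name, NULL))
  for (r in seq_len(nrow(iv))) {
    base <- switch(iv$family[r],
      smooth = iv$level[r] + iv$amplitude[r] * (s + 0.25 * sin(2 * pi * s)),
      step = rep(iv$level[r], n),
      ramp = iv$level[r] + iv$amplitude[r] * s,
      quadratic = iv$level[r] + iv$amplitude[r] * s^2,
      volume = iv$level[r] + iv$amplitude[r] * day +
        config@feedVolumeStep * vapply(day, function(d) sum(config@feedTimes <= d), 0),
      stop("unknown inline family: ", iv$family[r])
    )
    x <- base + stats::rnorm(n, 0, iv$noise_sd[r])
    for (f in feedSec) {
      idx <- which(times >= f & times < f + durSec)
      if (!length(idx)) next
      pulse <- sin(pi * (times[idx] - f) / durSec)
      x[idx] <- x[idx] + iv$disturbance[r] * pulse +
        stats::rnorm(length(idx), 0, iv$noise_sd[r] * (config@feedNoiseMult - 1))
    }
    inline[r, ] <- x
  }

  ov <- config@offlineVariables
  days <- seq_len(config@nDays)
  offline <- matrix(0, nrow(ov), config@nDays,
                    dimnames = list(ov$name, paste0("day", days)))
  for (r in seq_len(nrow(ov)))
    offline[r, ] <- offlineCurve(ov$family[r], ov$start[r], ov$end[r],
                                 days, config@nDays) +
      stats::rnorm(config@nDays, 0, ov$noise_sd[r])

  for (eff in config@clusterEffects[[clusterLabel]]) {
    if (eff$kind == "inline") {
      # a window reaching nDays covers the whole (possibly jittered) run tail
      hi <- if (eff$days[2] >= config@nDays) Inf else eff$days[2]
      idx <- which(day >= eff$days[1] & day < hi)
      inline[eff$variable, idx] <- inline[eff$variable, idx] + eff$shift
    } else {
      idx <- which(days >= eff$days[1] & days <= eff$days[2])
      offline[eff$variable, idx] <- offline[eff$variable, idx] + eff$shift
    }
  }

  pr <- config@productivity[[clusterLabel]]
  prod <- stats::rnorm(1, pr[1], pr[2])
  if (prod <= 0) prod <- pr[1]

  transIdx <- lapply(feedSec, function(f) which(times >= f & times < f + durSec))
  bounds <- c(0, feedSec, Inf)
  phaseIdx <- lapply(seq_len(length(bounds) - 1), function(p)
    range(which(times >= bounds[p] & times < bounds[p + 1])))

  new("BatchRecord",
      batchId = if (is.null(batchId)) sprintf("batch_s%d", seed) else batchId,
      inline = inline, inlineTimes = times, offline = offline,
      productivity = prod, clusterLabel = clusterLabel,
      metadata = list(seed = seed, sample_interval_s = dt,
                      feed_times_days = config@feedTimes,
                      feed_sample_index = vapply(feedSec, function(f)
                        which.max(times >= f), 0L),
                      transition_index = transIdx,
                      phase_sample_range = phaseIdx))
}

#' Generate a synthetic study
#'
#' Generates one [BatchRecord-class] per label with per-batch seeds derived
#' deterministically from the master seed, then injects the configured
#' data-quality defects.  Batch lengths are jittered by
#' `config@lengthJitter` so the uneven-batch-length problem is exercised.
#'
#' @param config a [SyntheticConfig-class].
#' @param labels character vector of length `config@nBatches` of cluster
#'   labels.
#' @param seed master seed.
#' @return list of [BatchRecord-class] objects.
#' @examples
#' cfg <- syntheticConfig(nBatches = 3, sampleIntervalS = 600)
#' study <- generateStudy(cfg, c("high", "low", "low"), seed = 7)
#' vapply(study, batchId, "")
#' @export
generateStudy <- function(config, labels, seed = config@seed) {
  stopifnot(is(config, "SyntheticConfig"))
  if (length(labels) != config@nBatches)
    stop("labels must have length nBatches = ", config@nBatches)
  lapply(seq_along(labels), function(i) {
    b <- generateBatch(config, labels[i], seed = deriveSeed(seed, i),
                       batchId = sprintf("batch_%02d", i))
    if (config@missingFraction > 0 || config@spikeCount > 0)
      b <- injectQualityIssues(b, config@missingFraction, config@spikeCount,
                               seed = deriveSeed(seed, i + config@nBatches),
                               config = config)
    b
  })
}

#' Inject data-quality defects into a batch
#'
#' Missing data emulate network outages: contiguous runs of samples (default
#' run length 10 min) are set to `NA` across all inline variables until the
#' requested fraction of samples is reached.  Spikes emulate sensor failures:
#' single points are pushed outside the variable's declared valid range.
#' Positions of both defect types are recorded in the batch metadata
#' (`missing_index`, `spikes`) so tests can compare repairs against truth.
#'
#' @param batch a [BatchRecord-class].
#' @param missingFraction fraction in [0, 1) of inline samples to blank.
#' @param spikeCount number of single-point spikes.
#' @param seed integer seed.
#' @param runLengthS outage run length in seconds.
#' @param config optional [SyntheticConfig-class] supplying valid ranges;
#'   defaults to [defaultInlineVariables()] ranges matched by name.
#' @return the modified [BatchRecord-class].
#' @export
injectQualityIssues <- function(batch, missingFraction, spikeCount, seed,
                                runLengthS = 600, config = NULL) {
  stopifnot(is(batch, "BatchRecord"))
  if (missingFraction < 0 || missingFraction >= 1)
    stop("missingFraction must be in [0, 1)")
  if (missingFraction == 0 && spikeCount == 0) return(batch)
  set.seed(seed)
  inline <- batch@inline
  n <- ncol(inline)
  dt <- batch@metadata$sample_interval_s
  if (is.null(dt)) dt <- stats::median(diff(batch@inlineTimes))

  missIdx <- integer()
  if (missingFraction > 0) {
    target <- round(missingFraction * n)
    runLen <- max(1L, round(runLengthS / dt))
    guard <- 0
    while (length(missIdx) < target && guard < 10 * n) {
      start <- sample.int(n, 1)
      run <- start:min(n, start + runLen - 1)
      missIdx <- unique(c(missIdx, run))
      guard <- guard + 1
    }
    missIdx <- sort(missIdx[seq_len(min(length(missIdx), target))])
    inline[, missIdx] <- NA_real_
  }

  spikes <- NULL
  if (spikeCount > 0) {
    ranges <- if (is.null(config)) defaultInlineVariables() else config@inlineVariables
    ranges <- ranges[match(rownames(inline), ranges$name), ]
    ok <- which(!is.na(ranges$valid_low))
    avail <- setdiff(seq_len(n), missIdx)
    pos <- sample(avail, spikeCount)
    var <- sample(rep(ok, length.out = max(spikeCount, length(ok))), spikeCount)
    spikes <- data.frame(variable = rownames(inline)[var], index = pos,
                         original = inline[cbind(var, pos)])
    span <- ranges$valid_high[var] - ranges$valid_low[var]
    inline[cbind(var, pos)] <- ranges$valid_high[var] + 0.5 * span
  }

  batch@inline <- inline
  batch@metadata$missing_index <- missIdx
  batch@metadata$spikes <- spikes
  batch
}

#' Sampling-point bookkeeping for inline data
#'
#' Number of inline sampling points collected by `nVariables` sensors over
#' `nDays` days at a fixed interval: `nVariables * nDays * 86400 / intervalS`.
#'
#' @param nVariables number of inline variables.
#' @param nDays number of days.
#' @param intervalS sampling interval in seconds.
#' @return numeric count.
#' @examples
#' inlineSamplingPoints(71, 1, 10)   # one day of a 71-sensor historian
#' @export
inlineSamplingPoints <- function(nVariables, nDays, intervalS) {
  stopifnot(nVariables >= 1, nDays > 0, intervalS > 0)
  nVariables * nDays * 86400 / intervalS
}
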
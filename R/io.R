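#' Write a study to long-format CSV files
#'
#' Three files: `inline.csv` (`batch_id, timestamp_s, variable, value`),
#' `offline.csv` (`batch_id, day, variable, value`) and `outcomes.csv`
#' (`batch_id, productivity, cluster`).  Timestamps are seconds from batch
#' start; missing inline values are written as empty fields.
#'
#' @param study list of [BatchRecord-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeStudyCsv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inline <- do.call(rbind, lapply(study, function(b) {
    data.frame(batch_id = batchId(b),
               timestamp_s = rep(b@inlineTimes, each = nrow(b@inline)),
               variable = rep(rownames(b@inline), ncol(b@inline)),
               value = as.vector(b@inline))
  }))
  offline <- do.call(rbind, lapply(study, function(b) {
    data.frame(batch_id = batchId(b),
               day = rep(seq_len(ncol(b@offline)), each = nrow(b@offline)),
               variable = rep(rownames(b@offline), ncol(b@offline)),
               value = as.vector(b@offline))
  }))
  outcomes <- data.frame(batch_id = vapply(study, batchId, ""),
                         productivity = vapply(study, productivity, 0),
                         cluster = vapply(study, clusterLabel, ""))
  paths <- file.path(dir, c("inline.csv", "offline.csv", "outcomes.csv"))
  utils::write.csv(inline, paths[1], row.names = FALSE, na = "")
  utils::write.csv(offline, paths[2], row.names = FALSE, na = "")
  utils::write.csv(outcomes, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a study from long-format CSV files
#'
#' Inverse of [writeStudyCsv()].
#'
#' @param dir directory containing `inline.csv`, `offline.csv`,
#'   `outcomes.csv`.
#' @return list of [BatchRecord-class].
#' @export
readStudyCsv <- function(dir) {
  inline <- utils::read.csv(file.path(dir, "inline.csv"))
  offline <- utils::read.csv(file.path(dir, "offline.csv"))
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"))
  lapply(seq_len(nrow(outcomes)), function(i) {
    id <- outcomes$batch_id[i]
    di <- inline[inline$batch_id == id, ]
    vars <- unique(di$variable)
    times <- sort(unique(di$timestamp_s))
    m <- matrix(NA_real_, length(vars), length(times),
                dimnames = list(vars, NULL))
    m[cbind(match(di$variable, vars), match(di$timestamp_s, times))] <- di$value
    doff <- offline[offline$batch_id == id, ]
    ovars <- unique(doff$variable)
    days <- sort(unique(doff$day))
    mo <- matrix(NA_real_, length(ovars), length(days),
                 dimnames = list(ovars, paste0("day", days)))
    mo[cbind(match(doff$variable, ovars), match(doff$day, days))] <- doff$value
    new("BatchRecord", batchId = id, inline = m, inlineTimes = times,
        offline = mo, productivity = outcomes$productivity[i],
        clusterLabel = as.character(outcomes$cluster[i]), metadata = list())
  })
}

#' Serialize a phase segmentation to JSON
#'
#' Intervals are written 0-based half-open; the distance profile is included
#' optionally.
#'
#' @param seg a [PhaseSegmentation-class].
#' @param path output file.
#' @param profile include the distance profile.
#' @return invisibly, `path`.
#' @export
writeSegmentationJson <- function(seg, path, profile = FALSE) {
  toIv <- function(m) lapply(seq_len(nrow(m)), function(i)
    list(start = unname(m[i, 1]) - 1L, end = unname(m[i, 2]) - 1L))
  x <- list(delta = seg@delta,
            stable_phases = toIv(seg@stablePhases),
            transitions = toIv(seg@transitions),
            params = list(L = seg@params@L, k = seg@params@k,
                          min_phase_length = seg@params@minPhaseLength,
                          standardize = seg@params@standardize))
  if (profile) x$distance_profile <- seg@distanceProfile
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a basis spec as YAML
#'
#' The YAML layout mirrors a variable-by-phase table:
#' `variable -> phase -> {family, n_basis}`.
#'
#' @param spec a [BasisSpec-class].
#' @param path file path.
#' @return `writeBasisSpecYaml` invisibly returns `path`;
#'   `readBasisSpecYaml` returns a [BasisSpec-class].
#' @export
writeBasisSpecYaml <- function(spec, path) {
  e <- spec@entries
  out <- lapply(split(e, e$variable), function(dv) {
    dv <- dv[order(dv$phase), ]
    stats::setNames(lapply(seq_len(nrow(dv)), function(i)
      list(family = dv$family[i], n_basis = dv$n_basis[i])),
      paste0("phase", dv$phase))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeBasisSpecYaml
#' @export
readBasisSpecYaml <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- list()
  for (v in names(y)) for (p in names(y[[v]]))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, phase = as.integer(sub("phase", "", p)),
      family = y[[v]][[p]]$family, n_basis = y[[v]][[p]]$n_basis)
  basisSpec(do.call(rbind, rows))
}

#' Write a feature matrix with its column metadata
#'
#' The assay is written as CSV (features in rows, batches in columns) with a
#' JSON sidecar holding the feature metadata and batch outcomes.
#'
#' @param se `SummarizedExperiment` from the feature-extraction step.
#' @param path CSV path; the sidecar gets extension `.meta.json`.
#' @return invisibly, the two paths.
#' @export
writeFeatureCsv <- function(se, path) {
  m <- SummarizedExperiment::assay(se)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  side <- sub("\\.csv$", ".meta.json", path)
  jsonlite::write_json(
    list(features = as.data.frame(SummarizedExperiment::rowData(se)),
         batches = as.data.frame(SummarizedExperiment::colData(se))),
    side, digits = NA)
  invisible(c(path, side))
}

#' Serialize a contrast result to JSON
#'
#' @param res a [ContrastResult-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeContrastJson <- function(res, path) {
  jsonlite::write_json(
    list(alpha = res@alpha, eigenvalues = res@eigenvalues,
         loadings = res@loadings, ranking = res@ranking,
         background = res@background,
         flagged_constant = res@flaggedConstant),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
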
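#' Trajectory roughness: mean absolute second difference
#'
#' `mean over t of |x[t+2] - 2 x[t+1] + x[t]|`.  Affine sequences score zero;
#' a quadratic sampled at integers scores its constant second difference.
#' Used, together with phase length, to pick the reference batch per phase:
#' the basis system chosen on a long, rough exemplar is flexible enough for
#' every other batch.
#'
#' @param values numeric vector of length >= 3.
#' @return nonnegative scalar.
#' @export
roughness <- function(values) {
  if (length(values) < 3) stop("roughness needs at least 3 points")
  mean(abs(diff(values, differences = 2)))
}

#' Reference-phase indicator H
#'
#' For one phase across batches, combines relative phase length and relative
#' roughness per variable:
#' `H_i = (L_i / max(L) + sum_m D[i,m] / max_i(D[i,m])) / (M + 1)`
#' where `D[i,m]` is the roughness of variable m in batch i and M counts the
#' variables included in the sum.  Variables with zero roughness in every
#' batch are excluded (their maximum would divide by zero) and M counts only
#' included variables.  H lies in (0, 1]; the maximising batch is the
#' reference for the phase.
#'
#' @param lengths numeric per-batch phase lengths.
#' @param roughnesses matrix, batches x variables, of [roughness()] values.
#' @return list with `H` (per batch), `included` (variable columns used).
#' @export
phaseIndicator <- function(lengths, roughnesses) {
  roughnesses <- as.matrix(roughnesses)
  stopifnot(length(lengths) == nrow(roughnesses))
  if (max(lengths) <= 0) stop("phase lengths must be positive")
  dmax <- apply(roughnesses, 2, max)
  included <- which(dmax > 0)
  M <- length(included)
  ratio <- if (M) rowSums(sweep(roughnesses[, included, drop = FALSE], 2,
                                dmax[included], "/")) else rep(0, length(lengths))
  H <- (lengths / max(lengths) + ratio) / (M + 1)
  list(H = H, included = included)
}

#' Select the reference batch for every phase
#'
#' @param study list of preprocessed [BatchRecord-class].
#' @param segmentations named list of [PhaseSegmentation-class] (one per
#'   batch, common phase count).
#' @return a [ReferenceReport-class].  Ties are broken by longer phase, then
#'   lower batch id.
#' @export
referencePhases <- function(study, segmentations) {
  ids <- vapply(study, batchId, "")
  study <- study[ids %in% names(segmentations)]
  ids <- ids[ids %in% names(segmentations)]
  P <- nPhases(segmentations[[1]])
  vars <- rownames(study[[1]]@inline)
  indicators <- NULL
  reference <- character(P)
  excluded <- character()
  for (p in seq_len(P)) {
    lengths <- numeric(length(study))
    rough <- matrix(0, length(study), length(vars),
                    dimnames = list(ids, vars))
    for (i in seq_along(study)) {
      iv <- stablePhases(segmentations[[ids[i]]])[p, ]
      idx <- iv[1]:(iv[2] - 1)
      lengths[i] <- length(idx)
      for (v in vars) rough[i, v] <- roughness(study[[i]]@inline[v, idx])
    }
    pi <- phaseIndicator(lengths, rough)
    excluded <- union(excluded, vars[setdiff(seq_along(vars), pi$included)])
    ord <- order(-pi$H, -lengths, ids)
    reference[p] <- ids[ord[1]]
    indicators <- rbind(indicators,
                        data.frame(phase = p, batch_id = ids, H = pi$H,
                                   length = lengths))
  }
  names(reference) <- as.character(seq_len(P))
  new("ReferenceReport", indicators = indicators, reference = reference,
      excludedVariables = excluded)
}

bsplineDesignMatrix <- function(t01, M) {
  stopifnot(M >= 4)
  nint <- M - 4
  interior <- if (nint > 0) seq(0, 1, length.out = nint + 2)[2:(nint + 1)] else numeric()
  knots <- c(rep(0, 4), interior, rep(1, 4))
  splines::splineDesign(knots, t01, ord = 4)
}

basisDesignMatrix <- function(t01, family, M) {
  switch(family,
    polynomial = outer(t01, seq_len(M) - 1, "^"),
    bspline_degree3 = bsplineDesignMatrix(t01, M),
    stop("unknown basis family: ", family)
  )
}

rescale01 <- function(times) {
  r <- range(times)
  if (r[2] == r[1]) stop("degenerate time range")
  (times - r[1]) / (r[2] - r[1])
}

#' Least-squares basis fit of one phase curve
#'
#' Fits `values ~ sum_m c_m phi_m(t)` by ordinary least squares on times
#' rescaled to [0, 1].  The polynomial basis is `1, t, ..., t^(M-1)`; the
#' B-spline basis is the degree-3 system with uniformly spaced knots (M
#' functions, interior knots `M - 4`).  Rescaling makes the basis common
#' across batches whose phases have different absolute lengths.
#'
#' @param times sample times (any scale; rescaled internally).
#' @param values sample values (same length, `length >= M + 2`).
#' @param family `"polynomial"` or `"bspline_degree3"`.
#' @param M number of basis functions.
#' @return list with `coefficients` (length M), `mse` (mean squared
#'   residual), `fitted`.
#' @examples
#' fitBasis(1:10, 2 + 3 * (1:10), "polynomial", 2)$mse  # 0: exact line
#' @export
fitBasis <- function(times, values, family, M) {
  stopifnot(length(times) == length(values))
  if (length(values) < M + 2)
    stop("need at least M + 2 = ", M + 2, " samples, got ", length(values))
  B <- basisDesignMatrix(rescale01(times), family, M)
  qrB <- qr(B)
  if (qrB$rank < M)
    stop("rank-deficient design (duplicate times?): rank ", qrB$rank,
         " < M = ", M)
  coef <- qr.coef(qrB, values)
  fitted <- drop(B %*% coef)
  list(coefficients = unname(coef), mse = mean((values - fitted)^2),
       fitted = fitted)
}

#' Choose the B-spline basis count by the MSE knee rule
#'
#' Fits every candidate count and returns the smallest candidate after which
#' the MSE curve never again drops sharply: the knee is the first candidate
#' such that every subsequent single-step relative improvement of the
#' best-so-far MSE stays below `relTol`.  The best-so-far (running minimum)
#' MSE is used because with uniform interior knots the raw MSE is not
#' monotone in the basis count (knot alignment effects), and the look-ahead
#' keeps an early plateau from masking a later sharp drop.  If no candidate
#' qualifies the largest is returned, and a single candidate is returned
#' as-is; both cases are flagged in `warnings`.
#'
#' @param times,values the curve, as in [fitBasis()].
#' @param family basis family.
#' @param candidates increasing candidate counts.
#' @param relTol relative-improvement threshold.
#' @return list with `nBasis`, `table` (candidate, mse), `warnings`.
#' @export
selectNBasis <- function(times, values, family = "bspline_degree3",
                         candidates = 4:40, relTol = 0.05) {
  if (is.unsorted(candidates, strictly = TRUE))
    stop("candidates must be increasing")
  warnings <- character()
  feasible <- candidates[candidates + 2 <= length(values)]
  if (!length(feasible)) stop("no candidate fits the curve length")
  if (length(feasible) < length(candidates))
    warnings <- c(warnings, "candidates exceeding curve length dropped")
  mses <- vapply(feasible, function(M)
    fitBasis(times, values, family, M)$mse, 0)
  tab <- data.frame(n_basis = feasible, mse = mses)
  if (length(feasible) == 1) {
    warnings <- c(warnings, "single candidate returned as-is")
    return(list(nBasis = feasible, table = tab, warnings = warnings))
  }
  best <- cummin(mses)
  negligible <- .Machine$double.eps * (mean(values^2) + 1)  # numerically-zero fit
  relImp <- ifelse(utils::head(best, -1) <= negligible, 0,
                   -diff(best) / utils::head(best, -1))
  sharpLater <- rev(cummax(rev(relImp >= relTol)))  # any sharp drop at >= i
  pick <- NA_integer_
  for (i in seq_len(length(feasible) - 1))
    if (!sharpLater[i]) { pick <- feasible[i]; break }
  if (is.na(pick)) {
    if (relImp[length(relImp)] < relTol) pick <- feasible[length(feasible)]
    else {
      pick <- feasible[length(feasible)]
      warnings <- c(warnings, "MSE still improving at the largest candidate")
    }
  }
  list(nBasis = pick, table = tab, warnings = warnings)
}

#' Assign a basis family and count per (variable, phase)
#'
#' Applies a nested least-squares heuristic to each reference curve: if a
#' straight line improves on the horizontal mean line by less than `relTol`
#' (relative MSE), the curve is step-like and gets the degree-0 polynomial
#' (M = 1); else if the quadratic improves on the line by less than `relTol`,
#' the degree-1 polynomial (M = 2); else if the best B-spline improves on the
#' quadratic by less than `relTol`, the quadratic polynomial (M = 3);
#' otherwise the degree-3 B-spline with the MSE-knee count from
#' [selectNBasis()].  The returned spec is user-overridable before feature
#' extraction.
#'
#' @param study,segmentations as in [referencePhases()].
#' @param reference a [ReferenceReport-class]; computed if missing.
#' @param candidates,relTol passed to [selectNBasis()].
#' @return a [BasisSpec-class].
#' @export
assignBasisSpec <- function(study, segmentations,
                            reference = referencePhases(study, segmentations),
                            candidates = 4:40, relTol = 0.05) {
  ids <- vapply(study, batchId, "")
  P <- nPhases(segmentations[[1]])
  vars <- rownames(study[[1]]@inline)
  rows <- list()
  for (p in seq_len(P)) {
    refBatch <- study[[match(reference@reference[[as.character(p)]], ids)]]
    iv <- stablePhases(segmentations[[batchId(refBatch)]])[p, ]
    idx <- iv[1]:(iv[2] - 1)
    tt <- refBatch@inlineTimes[idx]
    for (v in vars) {
      y <- refBatch@inline[v, idx]
      mse <- vapply(1:3, function(M) fitBasis(tt, y, "polynomial", M)$mse, 0)
      relImp <- function(a, b) if (a <= .Machine$double.eps^2) 0 else (a - b) / a
      if (relImp(mse[1], mse[2]) < relTol) {
        fam <- "polynomial"; M <- 1L
      } else if (relImp(mse[2], mse[3]) < relTol) {
        fam <- "polynomial"; M <- 2L
      } else {
        sel <- selectNBasis(tt, y, "bspline_degree3", candidates, relTol)
        if (relImp(mse[3], min(sel$table$mse)) < relTol) {
          fam <- "polynomial"; M <- 3L
        } else {
          fam <- "bspline_degree3"; M <- as.integer(sel$nBasis)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(variable = v, phase = p,
                                             family = fam, n_basis = M)
    }
  }
  basisSpec(do.call(rbind, rows))
}

#' Construct a basis spec from a table
#'
#' @param entries data.frame with columns `variable`, `phase`, `family`,
#'   `n_basis`.
#' @return a [BasisSpec-class].
#' @export
basisSpec <- function(entries) {
  entries$phase <- as.integer(entries$phase)
  entries$n_basis <- as.integer(entries$n_basis)
  rownames(entries) <- NULL
  new("BasisSpec", entries = entries)
}

#' Build the inline coefficient feature matrix
#'
#' For every batch and every (phase, variable) entry of the spec, fits the
#' stable-phase curve by least squares and collects the coefficients.
#' Column order is phase-major, then variable (spec order), then coefficient
#' index, identical for all batches.  The result is a
#' [SummarizedExperiment::SummarizedExperiment] with features in rows
#' (rowData: `kind`, `variable`, `phase`, `coeff`) and batches in columns
#' (colData: `batch_id`, `productivity`, `cluster`).
#'
#' @param study list of preprocessed [BatchRecord-class].
#' @param segmentations named list of [PhaseSegmentation-class].
#' @param spec a [BasisSpec-class] covering every (variable, phase).
#' @return a `SummarizedExperiment`.
#' @export
buildFeatureMatrix <- function(study, segmentations, spec) {
  stopifnot(is(spec, "BasisSpec"))
  validObject(spec)
  ids <- vapply(study, batchId, "")
  study <- study[ids %in% names(segmentations)]
  ids <- ids[ids %in% names(segmentations)]
  P <- nPhases(segmentations[[1]])
  e <- spec@entries
  vars <- rownames(study[[1]]@inline)
  for (p in seq_len(P)) for (v in vars)
    if (!any(e$variable == v & e$phase == p))
      stop("spec missing entry for variable '", v, "', phase ", p)

  meta <- NULL
  for (p in seq_len(P)) {
    ep <- e[e$phase == p & e$variable %in% vars, ]
    ep <- ep[match(vars, ep$variable), ]
    for (r in seq_len(nrow(ep)))
      meta <- rbind(meta, data.frame(kind = "inline_coeff",
                                     variable = ep$variable[r], phase = p,
                                     coeff = seq_len(ep$n_basis[r]),
                                     family = ep$family[r]))
  }
  Fn <- nrow(meta)
  mat <- matrix(NA_real_, Fn, length(study),
                dimnames = list(NULL, ids))
  for (i in seq_along(study)) {
    b <- study[[i]]
    col <- numeric(0)
    for (p in seq_len(P)) {
      iv <- stablePhases(segmentations[[ids[i]]])[p, ]
      idx <- iv[1]:(iv[2] - 1)
      tt <- b@inlineTimes[idx]
      for (v in vars) {
        er <- e[e$variable == v & e$phase == p, ]
        if (length(idx) < er$n_basis + 2)
          stop("phase ", p, " of batch '", ids[i], "' too short (",
               length(idx), " samples) for variable '", v, "' with M = ",
               er$n_basis)
        fit <- fitBasis(tt, b@inline[v, idx], er$family, er$n_basis)
        col <- c(col, fit$coefficients)
      }
    }
    mat[, i] <- col
  }
  rownames(meta) <- NULL
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(meta),
    colData = S4Vectors::DataFrame(
      batch_id = ids,
      productivity = vapply(study, productivity, 0),
      cluster = vapply(study, clusterLabel, ""),
      row.names = ids))
}

#' Fuse batch-wise unfolded offline data with inline features
#'
#' The offline matrix of each batch is unfolded variable-major then day into
#' one row of `S_v * D` values and appended below the inline coefficient
#' block.  Offline values must be complete.
#'
#' @param inlineFeatures `SummarizedExperiment` from [buildFeatureMatrix()].
#' @param study the same study (source of the offline tables).
#' @return an extended `SummarizedExperiment`.
#' @export
fuseOffline <- function(inlineFeatures, study) {
  ids <- colnames(inlineFeatures)
  study <- study[match(ids, vapply(study, batchId, ""))]
  off1 <- study[[1]]@offline
  vars <- rownames(off1); D <- ncol(off1)
  if (D == 0) return(inlineFeatures)
  for (b in study) {
    if (!identical(dim(b@offline), dim(off1)))
      stop("offline tables must share variables and day count")
    if (anyNA(b@offline))
      stop("missing offline value in batch '", batchId(b), "'")
  }
  block <- vapply(study, function(b) as.vector(t(b@offline)),
                  numeric(length(vars) * D))
  meta <- data.frame(kind = "offline",
                     variable = rep(vars, each = D),
                     phase = rep(seq_len(D), length(vars)),
                     coeff = rep(seq_len(D), length(vars)),
                     family = "offline")
  mat <- rbind(SummarizedExperiment::assay(inlineFeatures), block)
  rd <- rbind(as.data.frame(SummarizedExperiment::rowData(inlineFeatures)), meta)
  rownames(rd) <- NULL
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = unname(mat)),
    rowData = S4Vectors::DataFrame(rd),
    colData = SummarizedExperiment::colData(inlineFeatures))
}
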
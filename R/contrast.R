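#' Sample covariance of a feature matrix
#'
#' Column-centered sample covariance with divisor n - 1.
#'
#' @param X numeric matrix, rows = observations, columns = features.
#' @return symmetric covariance matrix.
#' @export
covarianceMatrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("covariance needs at least 2 rows")
  stats::cov(X)
}

#' First contrastive principal component
#'
#' The unit eigenvector of `C_target - alpha * C_background` with the largest
#' eigenvalue: the direction maximising target variance penalised by `alpha`
#' times background variance.  With `alpha = 0` this is the classical first
#' PC of the target.  The sign is fixed so that the largest-magnitude loading
#' is positive, making results deterministic across linear-algebra backends.
#'
#' @param Ctarget,Cbackground symmetric matrices of equal dimension.
#' @param alpha contrastive parameter, >= 0.
#' @param tol symmetry tolerance.
#' @return list with `v` (unit loading vector) and `values` (full descending
#'   spectrum).
#' @export
cpcaDirection <- function(Ctarget, Cbackground, alpha, tol = 1e-8) {
  stopifnot(alpha >= 0, all(dim(Ctarget) == dim(Cbackground)))
  sym <- function(M) max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
  if (!sym(Ctarget) || !sym(Cbackground))
    stop("covariance inputs must be symmetric")
  M <- Ctarget - alpha * Cbackground
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- ee$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(v = v, values = ee$values)
}

scaleFeatures <- function(E, scaling) {
  flagged <- character()
  if (scaling == "zscore") {
    mu <- colMeans(E)
    sdv <- apply(E, 2, stats::sd)
    const <- !is.finite(sdv) | sdv == 0
    if (any(const)) {
      flagged <- colnames(E)[const]
      if (is.null(flagged)) flagged <- as.character(which(const))
      sdv[const] <- 1
    }
    E <- sweep(sweep(E, 2, mu), 2, sdv, "/")
  }
  list(E = E, flagged = flagged)
}

#' Contrastive-cluster PCA feature contributions
#'
#' Ranks features by their contribution to what separates the target cluster
#' from the background.  The entire feature matrix (target plus background
#' rows) is `E`; the background cluster rows are `R`; the first eigenvector
#' `v*` of `C_E - alpha * C_R` is computed after (by default) z-scoring the
#' columns of `E` (the extended matrix mixes spline coefficients, liters and
#' percentages; background rows inherit `E`'s column scaling).  Contributions
#' are `|v*|`; signed loadings are retained for direction interpretation.
#'
#' @param features `SummarizedExperiment` from [fuseOffline()] /
#'   [buildFeatureMatrix()], or a plain matrix batches x features.
#' @param background for a `SummarizedExperiment`, a cluster label present in
#'   `colData(features)$cluster`, or a logical/integer row selector; for a
#'   matrix, a row selector.  Must be a nonempty strict subset of the rows.
#' @param alpha contrastive parameter.
#' @param scaling `"zscore"` or `"none"`.
#' @return a [ContrastResult-class].
#' @export
ccpcaContributions <- function(features, background, alpha = 1,
                               scaling = c("zscore", "none")) {
  scaling <- match.arg(scaling)
  if (is(features, "SummarizedExperiment")) {
    E <- t(SummarizedExperiment::assay(features))
    meta <- as.data.frame(SummarizedExperiment::rowData(features))
    if (is.character(background) && length(background) == 1) {
      bgLabel <- background
      background <- SummarizedExperiment::colData(features)$cluster == background
    } else bgLabel <- "custom"
  } else {
    E <- as.matrix(features)
    meta <- data.frame(feature = seq_len(ncol(E)))
    bgLabel <- "custom"
  }
  if (is.logical(background)) background <- which(background)
  if (!length(background) || length(background) >= nrow(E))
    stop("background must be a nonempty strict subset of the rows")

  sc <- scaleFeatures(E, scaling)
  CE <- covarianceMatrix(sc$E)
  CR <- covarianceMatrix(sc$E[background, , drop = FALSE])
  dir <- cpcaDirection(CE, CR, alpha)
  contrib <- abs(dir$v)
  ranking <- cbind(meta, loading = dir$v, contribution = contrib)
  ranking <- ranking[order(-contrib), ]
  rownames(ranking) <- NULL
  new("ContrastResult", alpha = alpha, eigenvalues = dir$values,
      loadings = dir$v, contributions = contrib, ranking = ranking,
      background = bgLabel, flaggedConstant = sc$flagged)
}

# Mean silhouette width for a 2-group labelling of rows of P (Euclidean).
meanSilhouette <- function(P, groupA) {
  n <- nrow(P)
  d <- as.matrix(stats::dist(P))
  g <- rep(2L, n); g[groupA] <- 1L
  s <- vapply(seq_len(n), function(i) {
    own <- which(g == g[i] & seq_len(n) != i)
    oth <- which(g != g[i])
    if (!length(own)) return(0)
    a <- mean(d[i, own]); b <- mean(d[i, oth])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Select the contrastive parameter by cluster separation
#'
#' Scores each candidate alpha by the two-cluster mean silhouette of the rows
#' projected onto the top-2 contrastive components and returns the maximiser
#' (smallest alpha on ties).  Candidates whose projection is degenerate
#' (zero variance) are skipped with a record.
#'
#' @param features,background,scaling as in [ccpcaContributions()].
#' @param candidates nonnegative grid including 0.
#' @return list with `alpha`, `table` (alpha, silhouette), `skipped`.
#' @export
selectAlpha <- function(features, background,
                        candidates = c(0, 10^(-2:3)),
                        scaling = c("zscore", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(all(candidates >= 0))
  if (is(features, "SummarizedExperiment")) {
    E <- t(SummarizedExperiment::assay(features))
    if (is.character(background) && length(background) == 1)
      background <- which(
        SummarizedExperiment::colData(features)$cluster == background)
  } else E <- as.matrix(features)
  if (is.logical(background)) background <- which(background)
  sc <- scaleFeatures(E, scaling)
  CE <- covarianceMatrix(sc$E)
  CR <- covarianceMatrix(sc$E[background, , drop = FALSE])
  target <- setdiff(seq_len(nrow(E)), background)
  scores <- rep(NA_real_, length(candidates))
  skipped <- numeric()
  for (i in seq_along(candidates)) {
    ee <- eigen(CE - candidates[i] * CR, symmetric = TRUE)
    P <- sc$E %*% ee$vectors[, 1:2, drop = FALSE]
    if (all(apply(P, 2, stats::var) < 1e-12)) {
      skipped <- c(skipped, candidates[i]); next
    }
    scores[i] <- meanSilhouette(P, target)
  }
  if (all(is.na(scores))) stop("all candidate alphas degenerate")
  best <- which(scores == max(scores, na.rm = TRUE))[1]
  list(alpha = candidates[best],
       table = data.frame(alpha = candidates, silhouette = scores),
       skipped = skipped)
}

#' One-tailed Welch t-test of cluster productivities
#'
#' Tests mean(target) > mean(background).  If both groups have zero variance
#' the test statistic is undefined; by convention p = 0.5 when the means are
#' equal, 0 when the target mean is larger and 1 otherwise, flagged in the
#' result.
#'
#' @param target,background numeric vectors of per-batch productivities
#'   (length >= 2 each).
#' @return list with `mean_target`, `mean_background`, `p_value`,
#'   `degenerate` flag.
#' @export
compareProductivity <- function(target, background) {
  stopifnot(length(target) >= 2, length(background) >= 2)
  mt <- mean(target); mb <- mean(background)
  if (stats::var(target) == 0 && stats::var(background) == 0) {
    p <- if (mt == mb) 0.5 else if (mt > mb) 0 else 1
    return(list(mean_target = mt, mean_background = mb, p_value = p,
                degenerate = TRUE))
  }
  p <- stats::t.test(target, background, alternative = "greater",
                     var.equal = FALSE)$p.value
  list(mean_target = mt, mean_background = mb, p_value = p,
       degenerate = FALSE)
}
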
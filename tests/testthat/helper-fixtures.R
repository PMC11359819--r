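# Desk-scale study conditions used across tests.
#
# The generator's scientific defaults (12 days, feeds on days 2/4/6/8, the
# 9 + 7 variable set, cluster effects on volume phase 5 and viability days
# 10-12) are kept; only the sampling interval is coarsened so that tests run
# in seconds.  Window parameters are scaled with the interval to preserve
# the 200-min window / 50-min neighbour set of the 10-s defaults.

coarseConfig <- function(intervalS = 300, ...) {
  syntheticConfig(sampleIntervalS = intervalS, ...)
}

# KnnParams equivalent to L = 1200, k = 300 at 10 s, for interval `intervalS`
coarseKnnParams <- function(intervalS = 300, ...) {
  f <- intervalS / 10
  knnParams(L = max(4, round(1200 / f)), k = max(2, round(300 / f)),
            minPhaseLength = max(2, round(60 / f * 10)), ...)
}

# Brute-force oracle for the moving-window kNN set distance: full stable
# sort inside the clipped window, mean of the k smallest squared distances.
bruteKnnDistance <- function(X, t, L, k, standardize = FALSE) {
  X <- as.matrix(X)
  if (standardize) {
    sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, colMeans(X)), 2, sdv, "/")
  }
  idx <- max(1, t - L):min(nrow(X), t + L)
  idx <- setdiff(idx, t)
  d2 <- colSums((t(X[idx, , drop = FALSE]) - X[t, ])^2)
  mean(sort(d2, method = "radix")[seq_len(k)])
}

# Independent maximizer of the quadratic form v'Mv on the unit sphere:
# random search followed by a Nelder-Mead polish of the Rayleigh quotient.
randomSearchMax <- function(M, nVectors = 1e5) {
  p <- nrow(M)
  V <- matrix(rnorm(p * nVectors), p)
  V <- V / rep(sqrt(colSums(V^2)), each = p)
  q <- colSums(V * (M %*% V))
  v0 <- V[, which.max(q)]
  opt <- optim(v0, function(v) -sum(v * (M %*% v)) / sum(v^2),
               control = list(maxit = 2000, reltol = 1e-14))
  max(max(q), -opt$value)
}

# Tiny two-cluster feature matrix with one shifted column
shiftedMatrix <- function(n1 = 6, n2 = 20, p = 20, shiftCol = 3, shift = 5,
                          seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  X[seq_len(n1), shiftCol] <- X[seq_len(n1), shiftCol] + shift
  list(X = X, target = seq_len(n1), background = n1 + seq_len(n2))
}
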
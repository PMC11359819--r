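test_that("covariance matches hand computation and a double-loop oracle", {
  expect_equal(covarianceMatrix(rbind(c(1, 2), c(1, 2))),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(covarianceMatrix(rbind(c(0, 0), c(2, 0))),
               rbind(c(2, 0), c(0, 0)), ignore_attr = TRUE)
  set.seed(13)
  X <- matrix(rnorm(15), 5, 3)
  C <- covarianceMatrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    oracle[i, j] <- sum(Xc[, i] * Xc[, j]) / (nrow(X) - 1)
  expect_equal(C, oracle, ignore_attr = TRUE)
  expect_lt(max(abs(C - t(C))), 1e-12)
  expect_error(covarianceMatrix(matrix(1:3, 1)), "2 rows")
})

test_that("contrastive direction reduces to PCA and solves the toy case", {
  set.seed(14)
  X <- matrix(rnorm(80), 20, 4)
  C <- covarianceMatrix(X)
  d <- cpcaDirection(C, diag(0, 4), alpha = 0)
  pc1 <- prcomp(X)$rotation[, 1]
  if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
  expect_equal(d$v, unname(pc1), tolerance = 1e-10)

  d2 <- cpcaDirection(diag(c(1, 2)), diag(c(0, 3)), alpha = 1)
  expect_equal(d2$v, c(1, 0))
  expect_equal(d2$values, c(1, -1))

  expect_error(cpcaDirection(matrix(c(1, 2, 0, 1), 2), diag(2), 1), "symmetric")
})

test_that("the first contrastive PC is an exact eigenvector and a maximiser", {
  set.seed(15)
  for (r in 1:10) {
    A <- crossprod(matrix(rnorm(16), 4))
    B <- crossprod(matrix(rnorm(16), 4))
    alpha <- runif(1, 0, 2)
    d <- cpcaDirection(A, B, alpha)
    M <- A - alpha * B
    expect_lt(max(abs(M %*% d$v - d$values[1] * d$v)), 1e-8)
    # random-search oracle for max of the quadratic form on the unit sphere
    best <- randomSearchMax(M)
    scale <- max(1, abs(d$values[1]))
    expect_lt(abs(d$values[1] - best) / scale, 1e-3)
  }
})

test_that("ccPCA recovers an injected single-feature shift", {
  hits <- 0
  for (s in 1:100) {
    sm <- shiftedMatrix(p = 10, seed = s)
    res <- ccpcaContributions(sm$X, sm$background, alpha = 1)
    if (which.max(contributions(res)) == 3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("null contrast singles out no feature systematically", {
  # when target and background are identically distributed, the top
  # contribution must wander over the features from seed to seed
  # (exchangeability) instead of settling on any one of them
  topFeature <- integer(50)
  for (s in 1:50) {
    set.seed(2000 + s)
    X <- matrix(rnorm(40 * 10), 40, 10)
    res <- ccpcaContributions(X, 11:40, alpha = 1)
    topFeature[s] <- which.max(contributions(res))
  }
  # under exchangeability each of the 10 features is top with prob 1/10;
  # 15/50 would be a > 4-sigma excess
  expect_lte(max(table(topFeature)), 15)
  expect_gte(length(unique(topFeature)), 5)
})

test_that("alpha = 0 reduces contributions to PCA loadings", {
  sm <- shiftedMatrix(seed = 3)
  res <- ccpcaContributions(sm$X, sm$background, alpha = 0, scaling = "none")
  pc1 <- prcomp(sm$X)$rotation[, 1]
  expect_equal(contributions(res), unname(abs(pc1)), tolerance = 1e-10)
})

test_that("contributions are invariant to row order and track column permutation", {
  sm <- shiftedMatrix(seed = 4)
  res <- ccpcaContributions(sm$X, sm$background, alpha = 1)
  set.seed(18)
  perm <- sample(nrow(sm$X))
  res2 <- ccpcaContributions(sm$X[perm, ], which(perm %in% sm$background),
                             alpha = 1)
  expect_equal(contributions(res2), contributions(res), tolerance = 1e-8)
  cperm <- c(5, 3, 1, 2, 4, 6:20)
  res3 <- ccpcaContributions(sm$X[, cperm], sm$background, alpha = 1)
  expect_equal(contributions(res3), contributions(res)[cperm], tolerance = 1e-8)
})

test_that("constant columns are flagged, not dropped", {
  sm <- shiftedMatrix(seed = 5)
  X <- cbind(sm$X, 7)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  res <- ccpcaContributions(X, sm$background, alpha = 1)
  expect_identical(res@flaggedConstant, "f21")
  expect_length(contributions(res), 21L)
})

test_that("background must be a nonempty strict subset", {
  sm <- shiftedMatrix(seed = 6)
  expect_error(ccpcaContributions(sm$X, integer(), alpha = 1), "subset")
  expect_error(ccpcaContributions(sm$X, seq_len(nrow(sm$X)), alpha = 1),
               "subset")
})

test_that("alpha selection prefers contrast when a nuisance direction dominates", {
  # clusters differ along feature 1 (small shift); both share a dominant
  # high-variance nuisance along feature 2, which classical PCA picks up
  set.seed(16)
  n1 <- 10; n2 <- 20
  X <- cbind(c(rnorm(n1, 2, 0.3), rnorm(n2, 0, 0.3)),
             rnorm(n1 + n2, 0, 20),
             matrix(rnorm((n1 + n2) * 3, 0, 0.3), n1 + n2, 3))
  sel <- selectAlpha(X, background = n1 + seq_len(n2), scaling = "none")
  expect_gt(sel$alpha, 0)
  tab <- sel$table
  expect_gt(tab$silhouette[tab$alpha == sel$alpha],
            tab$silhouette[tab$alpha == 0])
  expect_true(sel$alpha %in% c(0, 10^(-2:3)))
})

test_that("one-tailed productivity comparison mirrors the cluster contrast", {
  set.seed(17)
  hi <- 1.05 + rnorm(6, 0, 0.005)
  lo <- 0.961 + rnorm(20, 0, 0.005)
  cmp <- compareProductivity(hi, lo)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$mean_target, cmp$mean_background)
  # identical groups: t = 0, p = 0.5
  x <- c(1, 1.1, 0.9, 1.05)
  expect_equal(compareProductivity(x, x)$p_value, 0.5)
  # swapping groups maps p to 1 - p
  cmp2 <- compareProductivity(lo, hi)
  expect_equal(cmp2$p_value, 1 - cmp$p_value, tolerance = 1e-12)
  # zero variance in both groups
  expect_equal(compareProductivity(c(1, 1), c(1, 1))$p_value, 0.5)
  expect_true(compareProductivity(c(1, 1), c(1, 1))$degenerate)
  expect_equal(compareProductivity(c(2, 2), c(1, 1))$p_value, 0)
})
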
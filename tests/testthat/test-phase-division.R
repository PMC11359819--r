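test_that("kNN set distance matches hand-computable cases", {
  p <- knnParams(L = 2, k = 2, minPhaseLength = 1, minTransitionLength = 1,
                 standardize = FALSE)
  expect_equal(knnSetDistance(matrix(rep(5, 9), ncol = 1), 5, p), 0)
  X <- matrix(c(0, 0, 0, 10, 0, 0, 0), ncol = 1)
  expect_equal(knnSetDistance(X, 4, p), 100)  # (10^2 + 10^2) / 2
  expect_error(knnSetDistance(X, 1, knnParams(L = 2, k = 4, standardize = FALSE)),
               "candidate")
})

test_that("kNN set distance equals the exhaustive-sort oracle", {
  set.seed(42)
  for (r in 1:30) {
    n <- sample(10:50, 1)
    J <- sample(1:4, 1)
    X <- matrix(rnorm(n * J), n, J)
    if (r %% 3 == 0) X[sample(length(X), 5)] <- X[sample(length(X), 5)]  # ties
    L <- sample(3:25, 1)
    k <- sample(seq_len(min(2 * L, n - 1, 8)), 1)
    p <- knnParams(L = L, k = k, minPhaseLength = 1, minTransitionLength = 1,
                   standardize = FALSE)
    for (t in sample(n, 5)) {
      lo <- max(1, t - L); hi <- min(n, t + L)
      if (hi - lo < k) next
      expect_equal(knnSetDistance(X, t, p), bruteKnnDistance(X, t, L, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("distance profile flags feed events and little else", {
  cfg <- coarseConfig(300, nBatches = 1, lengthJitter = 0)
  b <- generateBatch(cfg, "low", seed = 31)
  p <- coarseKnnParams(300)
  prof <- distanceProfile(b, p)
  expect_length(prof, length(inlineTimes(b)))
  med <- median(prof)
  for (f in b@metadata$feed_sample_index)
    expect_gt(max(prof[f:(f + 6)]), 5 * med)  # spec'd spike criterion
  expect_error(distanceProfile(b, knnParams(L = 1e5, k = 10)), "2L\\+1")
})

test_that("appending zero columns leaves the unstandardized profile unchanged", {
  set.seed(3)
  X <- matrix(rnorm(600), 200, 3)
  inl <- t(X); rownames(inl) <- c("a", "b", "c")
  b <- new("BatchRecord", batchId = "z", inline = inl,
           inlineTimes = as.numeric(1:200), offline = matrix(numeric(), 0, 0),
           productivity = 1, clusterLabel = "x", metadata = list())
  p <- knnParams(L = 20, k = 5, minPhaseLength = 1, standardize = FALSE)
  prof1 <- distanceProfile(b, p)
  b2 <- b; b2@inline <- rbind(b@inline, zero = 0)
  expect_equal(distanceProfile(b2, p), prof1)
})

test_that("white-noise batches yield flat profiles with no spurious transitions", {
  # the profile's max/median stays within the noise band (the own-sample
  # deviation term gives it a chi-square tail, so ~3.5 is typical at J = 9)
  # and in particular never reaches the auto threshold: segmentation finds
  # a single stable phase
  flat <- 0; onePhase <- 0
  p <- knnParams(L = 100, k = 60, minPhaseLength = 1)
  for (s in 1:50) {
    set.seed(400 + s)
    X <- matrix(rnorm(1200 * 9), 1200, 9)  # the 9-variable setting
    prof <- batchlens:::.knn_profile_cpp(X, 100L, 60L)
    if (max(prof) / median(prof) < 5) flat <- flat + 1
    seg <- segmentPhases(prof, p, chooseDelta(list(prof))$delta)
    if (nPhases(seg) == 1L && nrow(transitions(seg)) == 0L) onePhase <- onePhase + 1
  }
  expect_gte(flat, 48)      # >= 95% of 50 seeds
  expect_gte(onePhase, 48)  # >= 95% of 50 seeds
})

test_that("segmentation thresholds, merges and counts phases", {
  p <- knnParams(L = 5, k = 2, minPhaseLength = 1, minTransitionLength = 1)
  seg <- segmentPhases(rep(1, 100), p, delta = 2)
  expect_identical(nPhases(seg), 1L)
  expect_identical(nrow(transitions(seg)), 0L)

  prof <- rep(1, 100); prof[40:45] <- 10
  seg2 <- segmentPhases(prof, p, delta = 5)
  expect_identical(nPhases(seg2), 2L)
  expect_identical(unname(transitions(seg2)[1, ]), c(40L, 46L))
  expect_error(segmentPhases(rep(10, 50), p, delta = 5), "transitional")

  # short stable islands merge into the surrounding transition
  prof3 <- rep(1, 100); prof3[40:60] <- 10; prof3[50] <- 1
  p3 <- knnParams(L = 5, k = 2, minPhaseLength = 5, minTransitionLength = 1)
  seg3 <- segmentPhases(prof3, p3, delta = 5)
  expect_identical(nPhases(seg3), 2L)

  # isolated spikes are not transitions
  prof4 <- rep(1, 100); prof4[c(20, 70)] <- 10
  p4 <- knnParams(L = 5, k = 2, minPhaseLength = 5, minTransitionLength = 3)
  seg4 <- segmentPhases(prof4, p4, delta = 5)
  expect_identical(nPhases(seg4), 1L)
})

test_that("raising delta never lengthens the transitions", {
  set.seed(7)
  p <- knnParams(L = 5, k = 2, minPhaseLength = 1, minTransitionLength = 1)
  prof <- abs(rnorm(300)) + rep(c(0, 5, 0, 5, 0), each = 60)
  lens <- vapply(seq(0.5, 8, by = 0.5), function(d) {
    seg <- segmentPhases(prof, p, delta = d)
    tr <- transitions(seg)
    sum(tr[, 2] - tr[, 1])
  }, 0)
  expect_true(all(diff(lens) <= 0))
})

test_that("segmentation count is invariant to variable order", {
  cfg <- coarseConfig(300, nBatches = 1, lengthJitter = 0)
  b <- generateBatch(cfg, "low", seed = 33)
  p <- coarseKnnParams(300)
  prof1 <- distanceProfile(b, p)
  b2 <- b; b2@inline <- b@inline[rev(seq_len(nrow(b@inline))), ]
  prof2 <- distanceProfile(b2, p)
  d <- chooseDelta(list(prof1))$delta
  expect_identical(nPhases(segmentPhases(prof1, p, d)),
                   nPhases(segmentPhases(prof2, p, d)))
})

test_that("chooseDelta quantile rule matches the interpolation oracle", {
  expect_equal(chooseDelta(rep(4.2, 50), method = "quantile")$delta, 4.2)
  expect_equal(chooseDelta(list(1:100), q = 0.95, method = "quantile")$delta,
               95.05)
  expect_error(chooseDelta(1:10, q = 1.2), "q must")
  expect_error(chooseDelta(list()), "nonempty")
})

test_that("auto threshold separates feeds from stable samples", {
  # run at the averaging scale of the real window (k = 300 neighbours):
  # with few neighbours the profile's stable bulk is too noisy for a
  # zero-false-positive guarantee
  ok <- 0
  for (s in 1:20) {
    cfg <- coarseConfig(60, nBatches = 1)
    b <- generateBatch(cfg, "low", seed = 500 + s)
    p <- knnParams()
    prof <- distanceProfile(b, p)
    d <- chooseDelta(list(prof))$delta
    trans <- unlist(b@metadata$transition_index)
    margin <- unique(c(trans, trans + rep(-p@L:p@L, each = length(trans))))
    stableIdx <- setdiff(seq_along(prof), margin)
    noFalse <- !any(prof[stableIdx] > d)
    allFeeds <- all(vapply(b@metadata$feed_sample_index, function(f)
      any(prof[f:(f + 29)] > d), TRUE))
    if (noFalse && allFeeds) ok <- ok + 1
  }
  expect_gte(ok, 18)  # >= 90% of seeds
})

test_that("a study segments into five phases with a common threshold", {
  cfg <- coarseConfig(300, nBatches = 4)
  study <- generateStudy(cfg, rep(c("high", "low"), 2), seed = 61)
  pre <- preprocessStudy(study, defaultVariableMeta(cfg))
  res <- segmentStudy(pre$study, coarseKnnParams(300))
  expect_identical(res$phaseCount, 5L)
  expect_length(res$segmentations, 4L)
  expect_identical(res$rejected, character(0))
  # phase-length pattern: four ~2-day phases then one ~4-day phase
  seg <- res$segmentations[[1]]
  lens <- stablePhases(seg)[, 2] - stablePhases(seg)[, 1]
  dayLen <- 86400 / 300
  expect_true(all(abs(lens[1:4] - 2 * dayLen) < 0.15 * 2 * dayLen))
  expect_lt(abs(lens[5] - 4 * dayLen), 0.15 * 4 * dayLen)
})
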
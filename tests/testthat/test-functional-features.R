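test_that("roughness is the mean absolute second difference", {
  expect_equal(roughness(5 + 3 * (1:20)), 0)
  expect_equal(roughness(c(0, 1, 0, 1, 0)), 2)
  expect_equal(roughness((0:10)^2), 2)
  expect_error(roughness(c(1, 2)), "3 points")
})

test_that("phase indicator combines length and roughness ratios", {
  # dominating batch: every ratio is 1 -> H = 1
  r <- phaseIndicator(c(10, 5), rbind(c(2, 3), c(1, 1)))
  expect_equal(r$H[1], 1)
  # two batches, one variable: (L=10, D=0) vs (L=5, D=2)
  r2 <- phaseIndicator(c(10, 5), matrix(c(0, 2), 2, 1))
  expect_equal(r2$H, c(0.5, 0.75))
  # scaling lengths by a common factor leaves H unchanged
  r3 <- phaseIndicator(c(10, 5) * 7, matrix(c(0, 2), 2, 1))
  expect_equal(r3$H, r2$H)
  # zero-roughness variables are excluded from the sum and from M
  r4 <- phaseIndicator(c(10, 5), cbind(c(0, 0), c(0, 2)))
  expect_equal(r4$included, 2L)
  expect_equal(r4$H, c((1 + 0) / 2, (0.5 + 1) / 2))
})

test_that("H stays in (0, 1] across random inputs", {
  set.seed(8)
  for (r in 1:50) {
    n <- sample(2:10, 1)
    H <- phaseIndicator(runif(n, 1, 100),
                        matrix(rexp(n * 3), n, 3))$H
    expect_true(all(H > 0 & H <= 1))
  }
})

test_that("basis fits reduce to closed forms", {
  set.seed(9)
  y <- rnorm(40, 10, 2)
  f1 <- fitBasis(1:40, y, "polynomial", 1)
  expect_equal(f1$coefficients, mean(y), tolerance = 1e-12)
  expect_equal(f1$mse, mean((y - mean(y))^2), tolerance = 1e-12)

  yl <- 2.5 - 1.25 * seq(0, 1, length.out = 30)
  f2 <- fitBasis(seq(0, 1, length.out = 30), yl, "polynomial", 2)
  expect_equal(f2$mse, 0, tolerance = 1e-20)
  expect_equal(f2$coefficients, c(2.5, -1.25), tolerance = 1e-10)

  # round trip: data from a known 8-coefficient spline are recovered
  tt <- seq(0, 1, length.out = 60)
  cf <- c(1, -2, 0.5, 3, -1, 2, 0, 1.5)
  y8 <- drop(batchlens:::bsplineDesignMatrix(tt, 8) %*% cf)
  f3 <- fitBasis(tt, y8, "bspline_degree3", 8)
  expect_equal(f3$coefficients, cf, tolerance = 1e-8)
  expect_lt(f3$mse, 1e-16)

  expect_error(fitBasis(rep(c(0, 1), 4), rnorm(8), "polynomial", 4), "rank")
  expect_error(fitBasis(1:4, rnorm(4), "polynomial", 3), "at least")
})

test_that("least-squares fits are locally optimal in each coefficient", {
  set.seed(10)
  tt <- seq(0, 1, length.out = 50)
  y <- sin(2 * pi * tt) + rnorm(50, 0, 0.1)
  for (spec in list(c("polynomial", 3), c("bspline_degree3", 6))) {
    f <- fitBasis(tt, y, spec[1], as.integer(spec[2]))
    B <- batchlens:::basisDesignMatrix(tt, spec[1], as.integer(spec[2]))
    for (m in seq_along(f$coefficients)) for (eps in c(-1e-3, 1e-3)) {
      cf <- f$coefficients; cf[m] <- cf[m] + eps
      expect_gte(mean((y - drop(B %*% cf))^2), f$mse)
    }
  }
})

test_that("the MSE knee recovers the generating basis count", {
  picks <- vapply(1:20, function(s) {
    set.seed(s)
    tt <- seq(0, 1, length.out = 500)
    cf <- rep(c(2, -2), 12) + rnorm(24, 0, 0.3)
    y <- drop(batchlens:::bsplineDesignMatrix(tt, 24) %*% cf) +
      rnorm(500, 0, 0.02)
    selectNBasis(tt, y, candidates = 4:40)$nBasis
  }, 0)
  expect_gte(mean(picks >= 22 & picks <= 28), 0.9)
})

test_that("knee rule degenerate cases", {
  tt <- seq(0, 1, length.out = 100)
  expect_equal(selectNBasis(tt, 1 + 2 * tt, candidates = 4:12)$nBasis, 4)
  sel <- selectNBasis(tt, sin(8 * tt), candidates = c(6L))
  expect_equal(sel$nBasis, 6)
  expect_match(sel$warnings, "single candidate")
  expect_error(selectNBasis(tt, sin(tt), candidates = c(8, 4)), "increasing")
  # raw MSE table is non-increasing for nested polynomial candidates
  set.seed(11)
  y <- rnorm(80)
  tab <- selectNBasis(1:80, y, family = "polynomial", candidates = 1:6)$table
  expect_true(all(diff(tab$mse) <= 1e-12))
})

studyWithSegs <- function(nBatches = 4, seed = 71, intervalS = 300) {
  cfg <- coarseConfig(intervalS, nBatches = nBatches)
  study <- generateStudy(cfg, rep(c("high", "low"), length.out = nBatches),
                         seed = seed)
  pre <- preprocessStudy(study, defaultVariableMeta(cfg))
  segres <- segmentStudy(pre$study, coarseKnnParams(intervalS))
  list(study = pre$study, segs = segres$segmentations, cfg = cfg)
}

test_that("reference phases maximise H with deterministic tie-breaking", {
  s <- studyWithSegs()
  ref <- referencePhases(s$study, s$segs)
  expect_length(ref@reference, 5L)
  for (p in 1:5) {
    ind <- ref@indicators[ref@indicators$phase == p, ]
    expect_equal(ref@reference[[as.character(p)]],
                 ind$batch_id[which.max(ind$H)])
    expect_true(all(ind$H > 0 & ind$H <= 1))
  }
})

test_that("basis assignment classifies trajectory families sensibly", {
  s <- studyWithSegs()
  spec <- assignBasisSpec(s$study, s$segs)
  e <- basisEntries(spec)
  # step-like setpoints: degree-0 polynomial
  for (v in c("DO1", "temperature", "air_sparger"))
    expect_true(all(e$family[e$variable == v] == "polynomial" &
                    e$n_basis[e$variable == v] == 1), info = v)
  # volume: straight line per phase
  expect_true(all(e$family[e$variable == "volume"] == "polynomial"))
  expect_true(all(e$n_basis[e$variable == "volume"] == 2))
  # smooth curved pH: B-spline with selected count
  expect_true(any(e$family[e$variable == "pH1"] == "bspline_degree3"))
})

test_that("feature matrix dimensions follow the basis bookkeeping", {
  s <- studyWithSegs()
  spec <- readBasisSpecYaml(system.file("extdata", "fedbatch_basis_spec.yaml",
                                        package = "batchlens"))
  expect_identical(nInlineFeatures(spec), 368L)
  # a random small spec: width equals the sum of counts
  set.seed(12)
  vars <- rownames(inlineData(s$study[[1]]))
  e <- expand.grid(variable = vars, phase = 1:5, stringsAsFactors = FALSE)
  e$family <- "polynomial"
  e$n_basis <- sample(1:3, nrow(e), replace = TRUE)
  sp <- basisSpec(e)
  se <- buildFeatureMatrix(s$study, s$segs, sp)
  expect_identical(nrow(se), nInlineFeatures(sp))
  expect_identical(ncol(se), length(s$study))
  expect_false(anyNA(SummarizedExperiment::assay(se)))
  # column metadata bookkeeping: per-(variable, phase) counts match the spec
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  cnt <- aggregate(coeff ~ variable + phase, rd, length)
  m <- merge(cnt, e)
  expect_equal(m$coeff, m$n_basis)
})

test_that("identical batches give identical feature columns", {
  s <- studyWithSegs(nBatches = 2)
  b2 <- s$study[[1]]; b2@batchId <- "clone"
  segs <- s$segs; segs[["clone"]] <- segs[[batchId(s$study[[1]])]]
  spec <- assignBasisSpec(s$study, s$segs)
  se <- buildFeatureMatrix(list(s$study[[1]], b2), segs, spec)
  expect_equal(SummarizedExperiment::assay(se)[, 1],
               SummarizedExperiment::assay(se)[, 2])
})

test_that("coefficients reproduce the fitted curve exactly", {
  s <- studyWithSegs(nBatches = 2)
  spec <- assignBasisSpec(s$study, s$segs)
  se <- buildFeatureMatrix(s$study, s$segs, spec)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  b <- s$study[[1]]
  iv <- stablePhases(s$segs[[batchId(b)]])[2, ]
  idx <- iv[1]:(iv[2] - 1)
  er <- basisEntries(spec)
  er <- er[er$variable == "pH1" & er$phase == 2, ]
  fit <- fitBasis(b@inlineTimes[idx], inlineData(b)["pH1", idx],
                  er$family, er$n_basis)
  stored <- SummarizedExperiment::assay(se)[
    rd$variable == "pH1" & rd$phase == 2 & rd$kind == "inline_coeff", 1]
  expect_equal(unname(stored), fit$coefficients)
  B <- batchlens:::basisDesignMatrix(
    batchlens:::rescale01(b@inlineTimes[idx]), er$family, er$n_basis)
  expect_equal(drop(B %*% stored), fit$fitted)
})

test_that("offline fusion appends a variable-major day block", {
  s <- studyWithSegs(nBatches = 3)
  spec <- assignBasisSpec(s$study, s$segs)
  se <- buildFeatureMatrix(s$study, s$segs, spec)
  ext <- fuseOffline(se, s$study)
  expect_identical(nrow(ext), nrow(se) + 7L * 12L)
  rd <- as.data.frame(SummarizedExperiment::rowData(ext))
  off <- rd[rd$kind == "offline", ]
  expect_identical(off$variable[1:12], rep("VCD", 12))
  expect_identical(off$phase[1:12], 1:12)
  b1 <- s$study[[1]]
  expect_equal(unname(SummarizedExperiment::assay(ext)[nrow(se) + 1:12, 1]),
               unname(offlineData(b1)["VCD", ]))
  # no offline variables: extended equals inline block
  s0 <- lapply(s$study, function(b) { b@offline <- matrix(numeric(), 0, 0); b })
  expect_identical(nrow(fuseOffline(se, s0)), nrow(se))
  # missing offline value is an error
  sbad <- s$study; sbad[[2]]@offline[3, 4] <- NA
  expect_error(fuseOffline(se, sbad), "missing offline")
})

test_that("a phase too short for its basis count names the offender", {
  s <- studyWithSegs(nBatches = 2)
  vars <- rownames(inlineData(s$study[[1]]))
  e <- expand.grid(variable = vars, phase = 1:5, stringsAsFactors = FALSE)
  e$family <- "polynomial"; e$n_basis <- 1
  e$n_basis[e$variable == "pH1" & e$phase == 1] <- 4000
  expect_error(buildFeatureMatrix(s$study, s$segs, basisSpec(e)),
               "too short.*pH1|pH1.*too short")
})
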
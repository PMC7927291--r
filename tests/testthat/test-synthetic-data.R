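test_that("generated scores equal the planted forward model exactly", {
  ds <- tinyDataset(n = 40L, noiseSd = 0.3, scoreNoiseSd = 0, seed = 2L)
  expect_equal(unname(scores(ds)), truthScores(ds), tolerance = 1e-12)
  # with score noise the identity still holds through the recorded residual
  ds2 <- tinyDataset(n = 40L, seed = 3L)
  expect_equal(unname(scores(ds2)), truthScores(ds2), tolerance = 1e-12)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- syntheticConfig(nSubjects = 30L,
                         voxelsPerModality = c(a = 50L, b = 40L),
                         nTrueVoxels = 4L, seed = 9L)
  expect_identical(generateDataset(cfg), generateDataset(cfg))
  ts1 <- generateTimeSeries(nSubjects = 2L, seed = 5L, noiseSd = 1)
  ts2 <- generateTimeSeries(nSubjects = 2L, seed = 5L, noiseSd = 1)
  expect_identical(ts1@series, ts2@series)
  expect_identical(ts1@motion, ts2@motion)
  a1 <- generateAtlas(100L, 10L, 3L, seed = 4L)
  a2 <- generateAtlas(100L, 10L, 3L, seed = 4L)
  expect_identical(a1@voxelNode, a2@voxelNode)
  expect_identical(a1@nodeNetwork, a2@nodeNetwork)
})

test_that("feature matrices have the configured dimensions and scores the configured range", {
  cfg <- syntheticConfig(nSubjects = 25L,
                         voxelsPerModality = c(alff = 80L, gmv = 60L, fa = 70L),
                         nTrueVoxels = c(alff = 6L, gmv = 4L, fa = 8L),
                         seed = 1L)
  ds <- generateDataset(cfg)
  for (m in names(cfg$voxelsPerModality)) {
    expect_identical(dim(featureMatrix(ds, m)),
                     c(25L, cfg$voxelsPerModality[[m]]))
    expect_identical(sum(plantedTruth(ds)@weightMaps[[m]] != 0),
                     cfg$nTrueVoxels[[m]])
  }
  expect_gte(min(scores(ds)), 0)
  expect_lte(max(scores(ds)), 4)
})

test_that("cross-modality signal sharing matches the planted fraction", {
  # oracle: modality signal components recomputed directly from the truth;
  # their correlation is f attenuated by the within-cluster feature noise,
  # f / (1 + noiseSd^2 / nTrue)
  f <- 0.5; tau <- 1; nTrue <- 10L
  ds <- generateDataset(syntheticConfig(
    nSubjects = 200L, voxelsPerModality = c(a = 300L, b = 300L),
    nTrueVoxels = nTrue, sharedSignalFraction = f, noiseSd = tau,
    seed = 31L))
  tr <- plantedTruth(ds)
  compA <- as.numeric(featureMatrix(ds, "a") %*% tr@weightMaps[["a"]])
  compB <- as.numeric(featureMatrix(ds, "b") %*% tr@weightMaps[["b"]])
  expected <- f / (1 + tau^2 / nTrue)
  expect_lt(abs(cor(compA, compB) - expected), 0.12)
  # independence check at f = 0
  ds0 <- generateDataset(syntheticConfig(
    nSubjects = 200L, voxelsPerModality = c(a = 300L, b = 300L),
    nTrueVoxels = nTrue, sharedSignalFraction = 0, noiseSd = tau,
    seed = 32L))
  tr0 <- plantedTruth(ds0)
  c0 <- cor(as.numeric(featureMatrix(ds0, "a") %*% tr0@weightMaps[["a"]]),
            as.numeric(featureMatrix(ds0, "b") %*% tr0@weightMaps[["b"]]))
  expect_lt(abs(c0), 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(voxelsPerModality = c(a = 10L),
                               nTrueVoxels = 20L), "exceeds")
  expect_error(syntheticConfig(voxelsPerModality = c(a = 10L),
                               clusterWidth = 11L), "clusterWidth")
  expect_error(syntheticConfig(sharedSignalFraction = 1.2), "0, 1")
  expect_error(syntheticConfig(noiseSd = -1), "noiseSd")
})

test_that("OLS restricted to the true support recovers the planted weights", {
  # recoverability ceiling at planted R^2 = 0.5 (score noise set by the
  # generator default). Per-voxel attribution requires voxel-specific
  # variance, so the ceiling is checked at feature noise 4 where individual
  # voxels are identifiable; under the default latent-dominated covariance
  # (feature noise 1) support voxels are strongly collinear and only a
  # weaker per-voxel attribution bound holds.
  olsCor <- function(noiseSd, seed) {
    ds <- tinyDataset(n = 200L, voxels = c(a = 300L, b = 300L),
                      nTrue = 10L, noiseSd = noiseSd, seed = seed)
    tr <- plantedTruth(ds)
    Xs <- do.call(cbind, lapply(modalities(ds), function(m)
      featureMatrix(ds, m)[, tr@weightMaps[[m]] != 0, drop = FALSE]))
    wTrue <- unlist(lapply(tr@weightMaps, function(w) w[w != 0]))
    cor(lm.fit(cbind(1, Xs), unname(scores(ds)))$coefficients[-1], wTrue)
  }
  expect_gt(mean(vapply(1:10, function(s) olsCor(4, 700L + s),
                        numeric(1))), 0.9)
  expect_gt(mean(vapply(1:10, function(s) olsCor(1, 700L + s),
                        numeric(1))), 0.5)
})

test_that("time series concentrate energy at the requested frequency bin", {
  # brute-force DFT oracle on a single sinusoid at an exact grid frequency
  ts <- generateTimeSeries(nSubjects = 1L, timepoints = 200L, voxels = 3L,
                           trSeconds = 2,
                           bandComponents = data.frame(freq = 0.05,
                                                       amplitude = 1),
                           noiseSd = 0, seed = 1L)
  x <- ts@series[[1]][, 1]
  nT <- length(x)
  dft <- vapply(0:(nT - 1), function(k)
    abs(sum(x * exp(-2i * pi * k * (0:(nT - 1)) / nT))), numeric(1))
  binHz <- 1 / (nT * 2)
  expect_equal(binHz, 0.0025)
  target <- which.max(dft[2:(nT / 2)]) + 1L
  expect_equal((target - 1) * binHz, 0.05)
  offTarget <- dft[2:(nT / 2)][-(target - 1L)]
  expect_lt(max(offTarget), 1e-8 * dft[target])
})

test_that("empty band components with zero noise give an all-zero series", {
  ts <- generateTimeSeries(nSubjects = 1L, timepoints = 50L, voxels = 4L,
                           noiseSd = 0, seed = 2L)
  expect_true(all(ts@series[[1]] == 0))
})

test_that("super-Nyquist components and short series are rejected", {
  expect_error(generateTimeSeries(bandComponents = data.frame(
    freq = 0.3, amplitude = 1), trSeconds = 2), "Nyquist")
  expect_error(generateTimeSeries(timepoints = 5L), ">= 8")
})

test_that("roster honors per-flag counts and pairwise overlaps", {
  counts <- c(head_motion = 69L, missing_volumes = 4L,
              normalization_failure = 1L, dwi_artifact = 8L)
  ov <- data.frame(flag1 = "dwi_artifact", flag2 = "head_motion", n = 4L)
  ros <- generateRoster(625L, counts, ov, seed = 3L)
  for (f in names(counts)) expect_identical(sum(ros[[f]]), counts[[f]])
  expect_identical(sum(ros$dwi_artifact & ros$head_motion), 4L)
  # set-union oracle: distinct flagged subjects
  flagged <- Reduce(`|`, ros[names(counts)])
  expect_identical(sum(flagged), 78L)

  ros0 <- generateRoster(20L, c(a = 0L, b = 0L), seed = 1L)
  expect_identical(sum(ros0$a | ros0$b), 0L)

  set.seed(11)
  counts2 <- setNames(sample(0:15, 4), c("w", "x", "y", "z"))
  ros2 <- generateRoster(100L, counts2, seed = 5L)
  expect_identical(sum(Reduce(`|`, ros2[names(counts2)])),
                   sum(counts2))
})

test_that("infeasible rosters are rejected", {
  expect_error(generateRoster(10L, c(a = 2L, b = 2L),
    data.frame(flag1 = "a", flag2 = "b", n = 3L)), "infeasible")
  expect_error(generateRoster(5L, c(a = 4L, b = 4L)), "infeasible")
})

test_that("toy atlases partition voxels into non-empty nodes and networks", {
  at <- generateAtlas(100L, 10L, 3L, seed = 2L)
  expect_identical(length(at@voxelNode), 100L)
  expect_identical(sort(unique(at@voxelNode)), 1:10)
  expect_identical(as.integer(sum(table(at@voxelNode))), 100L)
  expect_true(all(1:3 %in% at@nodeNetwork))
  # identity partition
  atI <- generateAtlas(7L, 7L, 2L, seed = 1L)
  expect_identical(at <- atI@voxelNode, 1:7)
  expect_error(generateAtlas(5L, 6L), "impossible")
  expect_error(generateAtlas(5L, 3L, 4L), "impossible")
})
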
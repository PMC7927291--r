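test_that("exclusion bookkeeping counts the union of flagged subjects once", {
  ros <- generateRoster(625L,
    c(head_motion = 69L, missing_volumes = 4L,
      normalization_failure = 1L, dwi_artifact = 8L),
    data.frame(flag1 = "dwi_artifact", flag2 = "head_motion", n = 4L),
    seed = 1L)
  rep <- applyExclusions(ros)
  expect_identical(rep@nIncluded, 547L)
  expect_identical(rep@nOverlap, 4L)
  expect_identical(rep@countsPerReason[["head_motion"]], 69L)

  # no flags: nothing excluded
  ros0 <- generateRoster(50L, c(a = 0L), seed = 1L)
  expect_identical(applyExclusions(ros0)@nIncluded, 50L)

  # random roster vs brute-force set-union recount
  set.seed(8)
  ros2 <- generateRoster(200L, c(p = 17L, q = 9L, r = 3L),
                         data.frame(flag1 = "p", flag2 = "q", n = 5L),
                         seed = 21L)
  rep2 <- applyExclusions(ros2)
  unionIds <- unique(unlist(lapply(c("p", "q", "r"), function(f)
    ros2$subject_id[ros2[[f]]])))
  expect_identical(rep2@nIncluded, 200L - length(unionIds))
  expect_setequal(rep2@excludedIds, unionIds)
})

test_that("exclusion is idempotent and rejects duplicate ids", {
  ros <- generateRoster(100L, c(a = 10L, b = 5L), seed = 2L)
  rep1 <- applyExclusions(ros)
  filtered <- ros[ros$subject_id %in% rep1@includedIds, ]
  rep2 <- applyExclusions(filtered)
  expect_identical(rep2@nIncluded, nrow(filtered))
  expect_identical(length(rep2@excludedIds), 0L)
  dup <- rbind(ros, ros[1, ])
  expect_error(applyExclusions(dup), "duplicate")
})

test_that("Friston-24 expansion follows the [R, R^2, lag, lag^2] layout", {
  z <- matrix(0, 10L, 6L)
  expect_true(all(friston24(z) == 0))
  m <- z[1:3, ]
  m[, 1] <- c(1, 2, 3)
  f <- friston24(m)
  expect_equal(unname(f[, 1]), c(1, 2, 3))
  expect_equal(unname(f[, 7]), c(1, 4, 9))
  expect_equal(unname(f[, 13]), c(0, 1, 2))
  expect_equal(unname(f[, 19]), c(0, 1, 4))
  expect_error(friston24(matrix(0, 5L, 5L)), "6 columns")

  # independent per-element loop oracle
  set.seed(3)
  mo <- matrix(rnorm(60), 10L, 6L)
  f2 <- friston24(mo)
  for (j in 1:6) for (t in 1:10) {
    lagv <- if (t == 1) 0 else mo[t - 1, j]
    expect_identical(unname(f2[t, j]), mo[t, j])
    expect_identical(unname(f2[t, j + 6]), mo[t, j]^2)
    expect_identical(unname(f2[t, j + 12]), lagv)
    expect_identical(unname(f2[t, j + 18]), lagv^2)
  }
})

test_that("framewise displacement matches the finite-difference definition", {
  const <- matrix(5, 20L, 6L)
  expect_true(all(framewiseDisplacement(const) == 0))
  m <- matrix(0, 5L, 6L)
  m[3:5, 1] <- 1  # single 1 mm x-translation step at frame 3
  expect_equal(framewiseDisplacement(m), c(0, 0, 1, 0, 0))

  set.seed(4)
  rw <- apply(matrix(rnorm(30 * 6, sd = 0.05), 30L, 6L), 2L, cumsum)
  fd <- framewiseDisplacement(rw, headRadiusMm = 50)
  oracle <- numeric(30)
  for (t in 2:30)
    oracle[t] <- sum(abs(rw[t, 1:3] - rw[t - 1, 1:3])) +
      50 * sum(abs(rw[t, 4:6] - rw[t - 1, 4:6]))
  expect_equal(fd, oracle, tolerance = 1e-12)
  rw[2, 1] <- NA
  expect_error(framewiseDisplacement(rw), "non-finite")
})

test_that("nuisance design contains the documented columns and spike indicators", {
  set.seed(5)
  nT <- 40L
  motion <- apply(matrix(rnorm(nT * 6, sd = 0.02), nT, 6L), 2L, cumsum)
  tis <- list(csf = rnorm(nT), wm = rnorm(nT), global = rnorm(nT))
  fd <- rep(0.1, nT); fd[c(5, 17, 30)] <- 0.9
  d <- buildNuisanceDesign(motion, tis, includeGsr = TRUE, fd = fd)
  dNoG <- buildNuisanceDesign(motion, tis, includeGsr = FALSE, fd = fd)
  expect_identical(ncol(d) - ncol(dNoG), 1L)  # global signal column
  spikeCols <- grep("^spike", colnames(d))
  expect_identical(length(spikeCols), 3L)
  for (k in seq_along(spikeCols))
    expect_equal(sum(d[, spikeCols[k]]), 1)  # one-hot
  expect_identical(which(rowSums(d[, spikeCols]) > 0), c(5L, 17L, 30L))
  dCalm <- buildNuisanceDesign(motion, tis, fd = rep(0.1, nT))
  expect_identical(length(grep("^spike", colnames(dCalm))), 0L)
  # censoring every frame destroys the rank
  expect_error(
    buildNuisanceDesign(motion, tis, fd = rep(1, nT)), "rank")
})

test_that("nuisance regression returns residuals orthogonal to the design", {
  set.seed(6)
  nT <- 60L
  motion <- apply(matrix(rnorm(nT * 6, sd = 0.02), nT, 6L), 2L, cumsum)
  tis <- list(csf = rnorm(nT), wm = rnorm(nT), global = rnorm(nT))
  d <- buildNuisanceDesign(motion, tis)
  Y <- matrix(rnorm(nT * 8), nT, 8L)
  R <- regressNuisance(Y, d)
  crossTalk <- abs(crossprod(d, R)) /
    outer(sqrt(colSums(d^2)), sqrt(pmax(colSums(R^2), 1e-300)))
  expect_lt(max(crossTalk), 1e-8)
  # a series equal to a design column vanishes
  expect_lt(max(abs(regressNuisance(d[, 3, drop = FALSE], d))), 1e-10)
  # normal-equations oracle
  beta <- solve(crossprod(d), crossprod(d, Y))
  expect_equal(R, Y - d %*% beta, tolerance = 1e-8, ignore_attr = TRUE)
  # already-orthogonal series pass through unchanged
  Yo <- R
  expect_equal(regressNuisance(Yo, d), Yo, tolerance = 1e-8)
  expect_error(regressNuisance(Y, cbind(d, d[, 1])), "singular")
})

test_that("ALFF equals the mean in-band amplitude, checked against a DFT oracle", {
  nT <- 200L; tr <- 2
  tGrid <- (0:(nT - 1)) * tr
  x <- 1.7 * sin(2 * pi * 0.05 * tGrid)
  res <- computeALFF(x, tr)
  # brute-force DFT amplitude oracle
  amp <- vapply(0:(nT - 1), function(k)
    2 * abs(sum(x * exp(-2i * pi * k * (0:(nT - 1)) / nT))) / nT,
    numeric(1))
  freqs <- (0:(nT - 1)) / (nT * tr)
  inBand <- which(freqs >= 0.01 & freqs <= 0.1)
  expect_equal(res$values, mean(amp[inBand]), tolerance = 1e-10)
  # the sinusoid occupies exactly one bin: ALFF = amplitude / nBins
  expect_equal(res$values, 1.7 / res$nBins, tolerance = 1e-10)

  expect_equal(computeALFF(rep(3, nT), tr)$values, 0)          # constant
  expect_equal(computeALFF(3 * x, tr)$values, 3 * res$values,  # homogeneity
               tolerance = 1e-10)
  # out-of-band sinusoid (0.2 Hz, an exact bin) contributes nothing
  y <- sin(2 * pi * 0.2 * tGrid)
  expect_lt(computeALFF(x + y, tr)$values - res$values, 1e-10)
  expect_error(computeALFF(rnorm(20), tr, band = c(0.01, 0.02)), "bins")
  expect_error(computeALFF(x, tr, band = c(0.01, 0.3)), "Nyquist")
})

test_that("mask thresholding is strict by default and validates its input", {
  expect_identical(makeMask(c(0.1, 0.25, 0.2)), c(FALSE, TRUE, FALSE))
  expect_identical(makeMask(c(0.1, 0.25, 0.2), strict = FALSE),
                   c(FALSE, TRUE, TRUE))
  expect_true(all(makeMask(rep(1, 5))))
  set.seed(7)
  pm <- runif(50)
  expect_identical(makeMask(pm, 0.37), pm > 0.37)  # elementwise oracle
  expect_error(makeMask(c(0.5, 1.2)), "\\[0, 1\\]")
})
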
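test_that("fold averaging zero-fills unselected voxels", {
  w1 <- c(1, 0, 0.5)
  wm <- averageFoldWeights(list(w1, w1, w1), "m")
  expect_equal(voxelWeights(wm), w1)
  expect_identical(wm@nFolds, 3L)
  # selected in 1 of 2 folds with weight 1 -> 0.5 under zero-fill
  wm2 <- averageFoldWeights(list(c(1, 0), c(0, 0)))
  expect_equal(voxelWeights(wm2), c(0.5, 0))
  # selected-folds-only variant keeps the conditional mean
  wm3 <- averageFoldWeights(list(c(1, 0), c(0, 0)),
                            selectedFoldsOnly = TRUE)
  expect_equal(voxelWeights(wm3), c(1, 0))
  expect_error(averageFoldWeights(list()), "empty")

  set.seed(40)
  folds <- lapply(1:6, function(i) rnorm(12) * rbinom(12, 1, 0.6))
  avg <- voxelWeights(averageFoldWeights(folds))
  oracle <- numeric(12)
  for (f in folds) oracle <- oracle + f / 6
  expect_equal(avg, oracle, tolerance = 1e-12)
})

test_that("atlas aggregation averages member voxels and conserves mass", {
  at <- new("AtlasLabels", voxelNode = c(1L, 1L, 2L),
            nodeNetwork = c(1L, 1L), nodeNames = c("n1", "n2"),
            networkNames = "net1")
  nodes <- mapToAtlas(c(0.1, 0.3, 5), at)
  expect_equal(unname(nodes), c(0.2, 5))
  # single-voxel nodes are the identity
  atI <- generateAtlas(8L, 8L, 2L, seed = 1L)
  w <- rnorm(8)
  expect_equal(unname(mapToAtlas(w, atI)), w)

  set.seed(41)
  at2 <- generateAtlas(200L, 20L, 4L, seed = 3L)
  w2 <- rnorm(200)
  nw <- mapToAtlas(w2, at2)
  # group-by loop oracle
  for (k in 1:20)
    expect_equal(unname(nw[k]), mean(w2[at2@voxelNode == k]),
                 tolerance = 1e-12)
  # conservation: node means weighted by node size recover the voxel sum
  sizes <- as.numeric(table(at2@voxelNode))
  expect_equal(sum(unname(nw) * sizes), sum(w2), tolerance = 1e-10)
  expect_error(mapToAtlas(rnorm(10), at2), "covers")
})

test_that("network contributions split positive and negative node weights", {
  at <- new("AtlasLabels", voxelNode = 1:3,
            nodeNetwork = c(1L, 1L, 1L),
            nodeNames = c("n1", "n2", "n3"), networkNames = "net1")
  nc <- networkContributions(setNames(c(1, -2, 3), at@nodeNames), at)
  expect_equal(nc$positive_sum, 4)
  expect_equal(nc$negative_sum, -2)
  expect_equal(nc$net_sum, 2)
  nc0 <- networkContributions(setNames(rep(0, 3), at@nodeNames), at)
  expect_equal(nc0$positive_sum, 0)
  expect_equal(nc0$negative_sum, 0)

  set.seed(42)
  at2 <- generateAtlas(60L, 12L, 3L, seed = 4L)
  nw <- setNames(rnorm(12), at2@nodeNames)
  nc2 <- networkContributions(nw, at2)
  for (k in 1:3) {
    members <- nw[at2@nodeNetwork == k]
    expect_equal(nc2$positive_sum[k], sum(members[members > 0]),
                 tolerance = 1e-12)
    expect_equal(nc2$negative_sum[k], sum(members[members < 0]),
                 tolerance = 1e-12)
  }
  expect_true(all(nc2$positive_sum >= 0 & nc2$negative_sum <= 0))
})

test_that("top-region ranking orders by magnitude with index tie-breaks", {
  tp <- topRegions(c(3, -1, 2), k = 2L, sign = "positive")
  expect_identical(tp$index, c(1L, 3L))
  expect_equal(tp$weight, c(3, 2))
  expect_warning(tn <- topRegions(c(3, -1, 2), k = 2L, sign = "negative"),
                 "truncating")
  expect_identical(tn$index, 2L)
  expect_warning(topRegions(rep(-1, 3), k = 5L, sign = "negative"),
                 "truncating")
  # all-negative vector yields an empty positive table
  tpn <- topRegions(c(-1, -2), k = 2L, sign = "positive")
  expect_identical(nrow(tpn), 0L)

  set.seed(43)
  w <- rnorm(100)
  tb <- topRegions(w, k = 10L, sign = "both")
  posOracle <- order(-w, seq_along(w))[1:10]
  negOracle <- order(w, seq_along(w))[1:10]
  expect_identical(tb$index[tb$sign == "positive"], as.integer(posOracle))
  expect_identical(sort(tb$index[tb$sign == "negative"]),
                   sort(as.integer(negOracle)))
  expect_error(topRegions(w, k = 0L), "k must be")
})

test_that("planted weight signs survive fold averaging and atlas mapping", {
  ds <- tinyDataset(n = 200L, voxels = c(a = 300L), nTrue = 10L, seed = 44L)
  res <- suppressWarnings(
    runCV(ds, cvScheme("kfold", k = 5L, repeats = 1L, seed = 2L),
          keepWeights = TRUE))
  wm <- attr(res, "weightMaps")[["a"]]
  truthW <- plantedTruth(ds)@weightMaps[["a"]]
  sup <- which(truthW != 0)
  expect_gt(mean(sign(voxelWeights(wm)[sup]) == sign(truthW[sup])), 0.8)
  # atlas aggregation keeps the cluster signal visible at node level
  at <- generateAtlas(300L, 30L, 4L, seed = 5L)
  nodes <- mapToAtlas(wm, at)
  expect_identical(length(nodes), 30L)
})
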
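test_that("voxel downsampling averages within voxels", {
  # single point survives untouched
  one <- voxelDownsample(pointCloud(cbind(0, 0, 0)), 0.005)
  expect_equal(coords(one), cbind(x = 0, y = 0, z = 0))

  # three points in one 5 mm voxel collapse to their centroid
  m <- rbind(c(0, 0, 0), c(0.001, 0, 0), c(0.004, 0.004, 0.004))
  out <- voxelDownsample(pointCloud(m), 0.005)
  expect_equal(nPoints(out), 1L)
  expect_equal(as.numeric(coords(out)),
               c(0.0016667, 0.0013333, 0.0013333), tolerance = 1e-4)

  # points in distinct voxels stay distinct
  two <- voxelDownsample(pointCloud(rbind(c(0, 0, 0), c(0.006, 0, 0))),
                         0.005)
  expect_equal(nPoints(two), 2L)

  expect_error(voxelDownsample(one, 0), "positive")
})

test_that("voxel output count matches an independent hashing oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    pc <- pointCloud(matrix(runif(3 * 400, -1, 1), ncol = 3))
    vs <- 0.15
    out <- voxelDownsample(pc, vs)
    key <- apply(floor(coords(pc) / vs), 1, paste, collapse = "/")
    expect_equal(nPoints(out), length(unique(key)))
    # no two output points share a voxel
    okey <- apply(floor(coords(out) / vs), 1, paste, collapse = "/")
    expect_false(anyDuplicated(okey) > 0)
  }
})

test_that("statistical outlier removal matches the brute-force oracle", {
  # the spec's collinear example: ten 1 mm-spaced points plus one far away
  cl <- pointCloud(rbind(cbind(seq(0, 0.009, 0.001), 0, 0), c(1, 0, 0)))
  r <- removeStatisticalOutliers(cl, k = 2, alpha = 1)
  expect_equal(which(!r$keep), 11L)
  expect_equal(nPoints(r$inliers), 10L)

  # huge alpha keeps everything
  set.seed(1)
  pc <- pointCloud(matrix(rnorm(3 * 100), ncol = 3))
  expect_true(all(removeStatisticalOutliers(pc, 5, alpha = 10)$keep))

  # precondition: more points than neighbors
  expect_error(removeStatisticalOutliers(
    pointCloud(rbind(c(0, 0, 0), c(1, 1, 1))), k = 2), "at least 3")

  # randomized agreement with the O(N^2) oracle
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(30:80, 1)
    m <- matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
    m[sample(n, 3), ] <- matrix(rnorm(9, sd = 3), ncol = 3)  # outliers
    for (k in c(3, 8)) for (alpha in c(0.075, 0.5, 1.5)) {
      got <- removeStatisticalOutliers(pointCloud(m), k, alpha)$keep
      expect_identical(got, oracleOutlierMask(m, k, alpha))
    }
  }
})

test_that("decreasing alpha never increases the retained count", {
  set.seed(42)
  pc <- pointCloud(matrix(rnorm(3 * 150), ncol = 3))
  alphas <- c(3, 1, 0.5, 0.2, 0.075, 0)
  kept <- vapply(alphas, function(a)
    sum(removeStatisticalOutliers(pc, 10, a)$keep), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("the noise-parameter sweep emits one row per combination", {
  set.seed(3)
  pc <- generateCanopy("cone", 0.3, 1, 600, seed = 3)$cloud
  sw <- sweepNoiseParams(pc, ks = c(8, 16, 24, 32, 40),
                         alphas = seq(0.05, 0.4, length.out = 8))
  expect_equal(nrow(sw), 40L)  # the 5 x 8 selection grid
  expect_named(sw, c("k", "alpha", "height_m", "removed_count"))

  # alpha = 10 rows equal the no-removal baseline
  sw10 <- sweepNoiseParams(pc, ks = c(8, 16), alphas = 10)
  expect_true(all(sw10$removed_count == 0))
  expect_equal(sw10$height_m, rep(canopyHeight(pc), 2))

  # for fixed k, removals are non-increasing in alpha
  swm <- sweepNoiseParams(pc, ks = 16, alphas = c(0.05, 0.2, 0.5, 1))
  expect_true(all(diff(swm$removed_count) <= 0))

  # an oversized k is skipped with a warning, not an error
  expect_warning(swsmall <- sweepNoiseParams(
    pointCloud(matrix(rnorm(30), ncol = 3)), ks = c(3, 50), alphas = 0.5),
    "skipped")
  expect_true(all(is.na(swsmall$height_m[swsmall$k == 50])))
})

test_that("euclidean clustering agrees with a union-find oracle", {
  # two clumps 1 m apart
  set.seed(9)
  clump <- function(ctr) sweep(matrix(rnorm(30, sd = 0.01), ncol = 3), 2,
                               ctr, "+")
  pc <- pointCloud(rbind(clump(c(0, 0, 0)), clump(c(1, 0, 0))))
  lab <- euclideanCluster(pc, 0.05)
  expect_setequal(unique(lab), c(0L, 1L))
  expect_equal(length(unique(lab[1:10])), 1L)

  # a chain with hops exactly at the radius is one cluster
  # (0.0625 is exactly representable, so "exactly at" is unambiguous)
  chain <- pointCloud(cbind(seq(0, 0.625, by = 0.0625), 0, 0))
  expect_equal(unique(euclideanCluster(chain, 0.0625)), 0L)

  # minPoints relabels small clusters to -1
  five <- pointCloud(matrix(rnorm(15, sd = 0.01), ncol = 3))
  expect_true(all(euclideanCluster(five, 0.1, minPoints = 6) == -1L))

  expect_equal(euclideanCluster(emptyPointCloud(), 0.1), integer(0))

  # randomized agreement with the all-pairs oracle
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(3 * 120, 0, 1), ncol = 3)
    for (radius in c(0.08, 0.15)) {
      got <- euclideanCluster(pointCloud(m), radius)
      expect_true(samePartition(got, oracleComponents(m, radius)))
    }
  }

  # label 0 is the largest cluster
  pc2 <- pointCloud(rbind(clump(c(0, 0, 0)), clump(c(1, 0, 0)),
                          clump(c(2, 0, 0))[1:5, ]))
  lab2 <- euclideanCluster(pc2, 0.05)
  expect_gte(sum(lab2 == 0L), sum(lab2 == 1L))
})

test_that("color-marker detection recovers synthetic sphere centers", {
  sc <- generateFieldScene(rows = 2, cols = 2, seed = 21)
  mk <- detectColorMarkers(sc$cloud, "white")
  expect_equal(nrow(markerCenters(mk)), 4L)
  expect_lt(maxMatchDistance(markerCenters(mk),
                             sc$truth$whiteMarkerCenters), 0.01)

  # the z constraint excludes low white objects (e.g. plot stakes)
  low <- pointCloud(matrix(c(0, 0, 0.5), 1, 3),
                    matrix(c(0.95, 0.95, 0.95), 1, 3))
  none <- detectColorMarkers(low, "white", zMin = 1, minPoints = 1)
  expect_equal(nrow(markerCenters(none)), 0L)

  # no near-white points at all
  green <- pointCloud(cbind(0, 0, 2), matrix(c(0.2, 0.6, 0.2), 1, 3))
  expect_equal(nrow(markerCenters(detectColorMarkers(green, "white",
                                                     minPoints = 1))), 0L)

  expect_error(detectColorMarkers(pointCloud(cbind(0, 0, 2)), "white"),
               "color")
})

test_that("block cropping keeps the closed quadrilateral interior", {
  corners <- rbind(c(0, 0, 1.5), c(7.6, 0, 1.5), c(7.6, 7.6, 1.5),
                   c(0, 7.6, 1.5))
  pc <- pointCloud(rbind(c(3, 3, 0.5),      # inside
                         c(8, 3, 0.5),      # outside
                         c(0, 3.8, 0.2),    # exactly on an edge
                         c(7.6, 7.6, 9)))   # on a corner, any z
  kept <- cropBlock(pc, corners)
  expect_equal(nPoints(kept), 3L)
  expect_false(any(coords(kept)[, 1] == 8))

  # all outside -> empty, not an error
  far <- pointCloud(cbind(100, 100, 1))
  expect_equal(nPoints(cropBlock(far, corners)), 0L)

  expect_error(cropBlock(pc, corners[1:3, ]), "4 corner markers")
})
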
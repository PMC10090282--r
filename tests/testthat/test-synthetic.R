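test_that("generated cones satisfy their constructive bounds", {
  cone <- generateCanopy("cone", 0.3, 1.0, 5000, seed = 42)
  m <- coords(cone$cloud)
  expect_gte(min(m[, 3]), 0)
  expect_lte(max(m[, 3]), 1 + 1e-9)
  # every surface point obeys the cone inequality r <= R (1 - z/h)
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  expect_true(all(r <= 0.3 * (1 - m[, 3]) + 1e-9))
  expect_equal(cone$truth$volume, pi * 0.09 / 3)
  expect_equal(cone$truth$surfaceArea,
               pi * 0.3^2 + pi * 0.3 * sqrt(0.3^2 + 1))
  expect_equal(cone$truth$height, 1)
})

test_that("identical seeds reproduce identical clouds", {
  a <- generateCanopy("ellipsoid", 0.2, 0.6, 500, noiseSigma = 0.002,
                      seed = 7)
  b <- generateCanopy("ellipsoid", 0.2, 0.6, 500, noiseSigma = 0.002,
                      seed = 7)
  expect_identical(coords(a$cloud), coords(b$cloud))
  expect_identical(pointColors(a$cloud), pointColors(b$cloud))
  c_ <- generateCanopy("ellipsoid", 0.2, 0.6, 500, noiseSigma = 0.002,
                       seed = 8)
  expect_false(identical(coords(a$cloud), coords(c_$cloud)))

  s1 <- generateFieldScene(rows = 2, cols = 2, seed = 3)
  s2 <- generateFieldScene(rows = 2, cols = 2, seed = 3)
  expect_identical(coords(s1$cloud), coords(s2$cloud))
  expect_identical(s1$labels, s2$labels)
})

test_that("field scenes conserve labels and expose exact truth", {
  sc <- generateFieldScene(rows = 2, cols = 3, seed = 11)
  expect_equal(length(sc$labels), nPoints(sc$cloud))
  tab <- table(sc$labels)
  expect_equal(sum(tab), nPoints(sc$cloud))
  expect_equal(sum(grepl("^canopy_", names(tab))), 6L)
  expect_equal(sum(grepl("^marker_w", names(tab))), 4L)

  # flat ground: all ground-labeled points exactly on the plane
  flat <- generateFieldScene(rows = 1, cols = 2, seed = 12,
                             groundRoughnessSigma = 0)
  gz <- coords(flat$cloud)[flat$labels == "ground", 3]
  expect_true(all(gz == 0))

  # canopies would overlap -> error
  expect_error(generateFieldScene(rows = 1, cols = 2, spacing = 0.3,
                                  seed = 1),
               "overlap")

  # cross-module round trip: marker detection recovers the truth
  mk <- detectColorMarkers(sc$cloud, "white")
  expect_lt(maxMatchDistance(markerCenters(mk),
                             sc$truth$whiteMarkerCenters), 0.01)
})

test_that("simulated views implement pose, dropout and noise exactly", {
  sc <- generateFieldScene(rows = 1, cols = 2, seed = 5)
  n <- nPoints(sc$cloud)

  # identity pose, no dropout, no noise: the view is the scene
  sim0 <- simulateViews(sc$cloud, list(identityTransform()), dropout = 0,
                        sensorNoiseSigma = 0, seed = 1)
  expect_identical(coords(sim0$views[[1]]), coords(sc$cloud))

  # dropout 0.5: exact ceiling count by permutation
  simH <- simulateViews(sc$cloud, list(identityTransform()),
                        dropout = 0.5, sensorNoiseSigma = 0, seed = 2)
  expect_equal(nPoints(simH$views[[1]]), n - floor(0.5 * n))

  # marker truth rides along into each view frame
  pose <- rigidTransform(rotationAboutZ(1), c(2, 0, 0))
  simM <- simulateViews(sc$cloud, list(pose), dropout = 0,
                        sensorNoiseSigma = 0, seed = 3,
                        markerCenters = sc$truth$whiteMarkerCenters)
  expect_equal(simM$markers[[1]],
               applyTransform(sc$truth$whiteMarkerCenters, pose))

  expect_error(simulateViews(sc$cloud, list(pose), dropout = 1), "0, 1")
})

test_that("hull traits of dense volume samples converge to analytic truth", {
  shapes <- list(
    list(shape = "cone", radius = 0.3, height = 1.0),
    list(shape = "cylinder", radius = 0.3, height = 1.0),
    list(shape = "hemisphere", radius = 0.4, height = 0.4),
    list(shape = "ellipsoid", radius = 0.3, height = 0.8))
  for (s in shapes) {
    g <- generateCanopy(s$shape, s$radius, s$height, 20000,
                        fill = "volume", seed = 31)
    mt <- meshTraits(canopyMesh(g$cloud))
    expect_lt(abs(mt$volume - g$truth$volume) / g$truth$volume, 0.05)
  }
})
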
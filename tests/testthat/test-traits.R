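test_that("canopy height averages the top fraction of z values", {
  # 100 evenly spaced z values: top 3 are {0.97, 0.98, 0.99}
  pc <- pointCloud(cbind(0, 0, seq(0, 0.99, by = 0.01)))
  expect_equal(canopyHeight(pc), 0.98)

  expect_equal(canopyHeight(pointCloud(cbind(0, 0, rep(0.5, 10)))), 0)
  expect_equal(canopyHeight(pointCloud(cbind(1, 2, 3))), 0)
  expect_error(canopyHeight(emptyPointCloud()), "empty")
  expect_error(canopyHeight(pc, topFraction = 0), "0, 1")

  # translation invariance and z-scale homogeneity
  set.seed(2)
  m <- cbind(rnorm(200), rnorm(200), runif(200, 0, 2))
  h <- canopyHeight(pointCloud(m))
  shifted <- m; shifted[, 3] <- shifted[, 3] + 5
  expect_equal(canopyHeight(pointCloud(shifted)), h)
  scaled <- m; scaled[, 3] <- scaled[, 3] * 3
  expect_equal(canopyHeight(pointCloud(scaled)), 3 * h)
})

test_that("convex-hull meshing produces watertight, correct solids", {
  cube <- pointCloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  mesh <- canopyMesh(cube)
  expect_equal(nrow(mesh@faces), 12L)
  expect_true(isWatertight(mesh))
  mt <- meshTraits(mesh)
  expect_equal(mt$volume, 1, tolerance = 1e-5)
  expect_equal(mt$surfaceArea, 6, tolerance = 1e-5)

  # points in a unit ball: hull volume bounded by the ball volume
  set.seed(3)
  w <- matrix(rnorm(3 * 10000), ncol = 3)
  w <- w / sqrt(rowSums(w^2)) * runif(10000)^(1 / 3)
  ball <- canopyMesh(pointCloud(w))
  expect_true(isWatertight(ball))
  expect_lt(meshTraits(ball)$volume, 4 * pi / 3)

  expect_error(canopyMesh(pointCloud(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1),
                                           0))), "coplanar")
  expect_error(canopyMesh(pointCloud(cbind(1, 2, 3))), "4 points")
})

test_that("mesh volume and area scale as s^3 and s^2", {
  set.seed(4)
  pc <- generateCanopy("cone", 0.3, 1, 800, seed = 4)$cloud
  m1 <- meshTraits(canopyMesh(pc))
  s <- 2.5
  m2 <- meshTraits(canopyMesh(pointCloud(coords(pc) * s)))
  expect_equal(m2$volume, m1$volume * s^3, tolerance = 1e-5)
  expect_equal(m2$surfaceArea, m1$surfaceArea * s^2, tolerance = 1e-5)
})

test_that("the slice hull is watertight and tighter on waisted shapes", {
  # hourglass: two cones tip to tip; the convex hull bridges the waist
  bottom <- generateCanopy("cone", 0.3, 0.5, 3000, seed = 6)$cloud
  top <- generateCanopy("inverted_cone", 0.3, 0.5, 3000, seed = 5)$cloud
  hour <- bindPointClouds(
    pointCloud(coords(bottom)),
    pointCloud(sweep(coords(top), 2, c(0, 0, 0.5), "+")))
  trueVol <- 2 * pi * 0.3^2 * 0.5 / 3
  vHull <- meshTraits(canopyMesh(hour, "convex_hull"))$volume
  mSlice <- canopyMesh(hour, "slice_hull", sliceThickness = 0.05)
  expect_true(isWatertight(mSlice))
  vSlice <- meshTraits(mSlice)$volume
  expect_lt(abs(vSlice - trueVol), abs(vHull - trueVol))
  expect_lt(vSlice, vHull)
})

test_that("projected outlines contain their points and match known areas", {
  # axis-aligned box -> rectangle
  set.seed(7)
  box <- pointCloud(cbind(runif(2000, 0, 2), runif(2000, 0, 1),
                          runif(2000)))
  rect <- projectOutline(box, "xy")
  ot <- outlineTraits(rect)
  expect_equal(ot$area, 2, tolerance = 0.02)

  # vertical cylinder, xy projection: area within 2% of pi r^2
  cyl <- generateCanopy("cylinder", 0.5, 1, 10000, seed = 8)$cloud
  circ <- outlineTraits(projectOutline(cyl, "xy"))
  expect_equal(circ$area, pi * 0.25, tolerance = 0.02)

  # hull property: every projected point is inside or on the outline
  poly <- projectOutline(box, "xy")
  m <- coords(box)[, 1:2]
  both <- rbind(poly, m)
  expect_equal(abs(canopyprint:::.shoelace(
    both[rev(grDevices::chull(both)), ])),
    abs(canopyprint:::.shoelace(poly)), tolerance = 1e-9)

  expect_error(projectOutline(pointCloud(cbind(1:5, 2 * (1:5), 0)), "xy"),
               "collinear")
})

test_that("outline descriptors hit their closed forms", {
  theta <- seq(0, 2 * pi, length.out = 1001)[-1001]
  gon <- cbind(cos(theta), sin(theta))
  ot <- outlineTraits(gon)
  expect_equal(ot$circularity, 1, tolerance = 1e-3)
  expect_equal(ot$roundness, 1, tolerance = 1e-3)
  expect_equal(ot$solidity, 1, tolerance = 1e-9)
  expect_equal(ot$aspectRatio, 1, tolerance = 1e-3)
  expect_equal(ot$majorAxis, 2, tolerance = 1e-2)

  sq <- outlineTraits(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)
  expect_equal(sq$circularity, pi / 4, tolerance = 1e-12)

  # 2:1 ellipse: aspect 2, roundness = b/a = 0.5
  t2 <- seq(0, 2 * pi, length.out = 2001)[-2001]
  ell <- outlineTraits(cbind(cos(t2), 0.5 * sin(t2)))
  expect_equal(ell$aspectRatio, 2, tolerance = 0.01)
  expect_equal(ell$roundness, 0.5, tolerance = 0.01)

  expect_error(outlineTraits(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
})

test_that("circularity and roundness of regular k-gons increase toward 1", {
  vals <- vapply(c(3, 4, 6, 12, 48, 360), function(k) {
    th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    ot <- outlineTraits(cbind(cos(th), sin(th)))
    c(ot$circularity, ot$roundness)
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
  expect_true(all(vals <= 1 + 1e-9))
})

test_that("solidity is 1 for convex outlines and below 1 for a star", {
  k <- 10
  ang <- seq(0, 2 * pi, length.out = 2 * k + 1)[-(2 * k + 1)]
  r <- rep(c(1, 0.4), k)
  star <- outlineTraits(cbind(r * cos(ang), r * sin(ang)))
  expect_lt(star$solidity, 1)
  hexagon <- outlineTraits(cbind(cos(ang[c(TRUE, FALSE)]),
                                 sin(ang[c(TRUE, FALSE)])))
  expect_equal(hexagon$solidity, 1, tolerance = 1e-9)
})

test_that("Z-score flagging uses the population deviation", {
  vals <- c(1:10, 100)
  flagged <- flagOutlierMeasurements(vals)
  expect_equal(which(flagged), 11L)
  # direct oracle: population sd
  z <- abs(vals - mean(vals)) / sqrt(mean((vals - mean(vals))^2))
  expect_identical(flagged, z > 2.5)

  expect_false(any(flagOutlierMeasurements(rep(3, 5))))
  expect_false(any(flagOutlierMeasurements(c(-1, 1))))
  expect_error(flagOutlierMeasurements(1), "at least 2")
})

test_that("canopyTraits assembles a one-row trait table", {
  cone <- generateCanopy("cone", 0.3, 1, 1500, seed = 9)
  tr <- canopyTraits(cone$cloud, id = "c1")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$id, "c1")
  expect_equal(tr$volume_m3, cone$truth$volume, tolerance = 0.05)
  expect_equal(tr$area_m2, pi * 0.3^2, tolerance = 0.05)
  expect_equal(tr$solidity, 1, tolerance = 1e-6)
})
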
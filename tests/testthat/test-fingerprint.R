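test_that("slicing partitions the z range into 2n + 1 equal sections", {
  pc <- pointCloud(cbind(0, 0, runif(100)))
  expect_length(sliceCanopy(pc, 0), 1L)
  expect_length(sliceCanopy(pc, 1), 3L)
  expect_length(sliceCanopy(pc, 4), 9L)
  expect_equal(nPoints(sliceCanopy(pc, 0)[[1]]), 100L)

  # every point lands in exactly one slice
  sl <- sliceCanopy(pc, 4)
  expect_equal(sum(vapply(sl, nPoints, integer(1))), 100L)

  # uniform z: thirds within 2% at 3e4 points
  set.seed(1)
  big <- pointCloud(cbind(0, 0, runif(30000)))
  counts <- vapply(sliceCanopy(big, 1), nPoints, integer(1))
  expect_true(all(abs(counts / 10000 - 1) < 0.02))

  # boundary points: half-open below, closed top
  flat <- pointCloud(cbind(0, 0, c(0, 1, 2, 3)))
  sl3 <- sliceCanopy(flat, 1)    # breaks at 1 and 2
  expect_equal(vapply(sl3, nPoints, integer(1)), c(1L, 1L, 2L))

  expect_error(sliceCanopy(emptyPointCloud(), 1), "empty")
})

test_that("sub-canopy signatures follow the configured feature order", {
  cfg <- fingerprintConfig(1, c("point_count", "slice_height", "area2d"))
  set.seed(2)
  cube <- pointCloud(matrix(runif(3 * 3000), ncol = 3))
  sig <- subCanopySignature(cube, cfg)
  expect_named(sig, c("point_count", "slice_height", "area2d"))
  expect_equal(unname(sig["point_count"]), 3000)
  expect_equal(unname(sig["area2d"]), 1, tolerance = 0.05)

  # degenerate slices yield flagged zeros, not errors
  zeroSig <- subCanopySignature(emptyPointCloud(), cfg)
  expect_true(all(zeroSig == 0))
  expect_true(all(attr(zeroSig, "degenerate")))

  # a dense unit cube: volume ~ 1, solidity 1
  cfg2 <- fingerprintConfig(0, c("volume", "solidity"))
  sig2 <- subCanopySignature(cube, cfg2)
  expect_equal(unname(sig2["volume"]), 1, tolerance = 0.05)
  expect_equal(unname(sig2["solidity"]), 1, tolerance = 1e-6)
})

test_that("fingerprints are center-normalized, slice-major vectors", {
  cyl <- generateCanopy("cylinder", 0.3, 1, 6000, seed = 3)$cloud
  cfg <- fingerprintConfig(1, c("point_count", "area2d"))
  fp <- computeFingerprint(cyl, cfg, "cyl")
  expect_length(fp@values, 6L)
  m <- fingerprintMatrix(fp)
  expect_equal(m[2, ], c(point_count = 1, area2d = 1))  # center block
  expect_true(all(abs(m - 1) < 0.05))  # cylinder symmetry

  # cone: area profile ~ (2.25, 1, 0.25) bottom to top
  cone <- generateCanopy("cone", 0.3, 1, 20000, seed = 4)$cloud
  fpc <- computeFingerprint(cone, fingerprintConfig(1, "area2d"))
  expect_equal(as.numeric(fingerprintMatrix(fpc)), c(2.25, 1, 0.25),
               tolerance = 0.05)

  # translation invariance (to floating-point precision of the traits)
  t <- rigidTransform(diag(3), c(3.2, -1.1, 0.7))
  fpT <- computeFingerprint(applyTransform(cone, t),
                            fingerprintConfig(1, "area2d"))
  expect_equal(fpT@values, fpc@values, tolerance = 1e-9)
})

test_that("normalized fingerprints are scale- and z-rotation-invariant", {
  cone <- generateCanopy("cone", 0.3, 1, 8000, seed = 5)$cloud
  cfg <- fingerprintConfig(2, c("area2d", "convex_area", "volume",
                                "solidity"))
  fp <- computeFingerprint(cone, cfg)

  scaled <- pointCloud(coords(cone) * 1.7)
  fpS <- computeFingerprint(scaled, cfg)
  expect_lt(max(abs(fpS@values - fp@values) / pmax(abs(fp@values), 1)),
            0.01)

  rot <- applyTransform(cone, rigidTransform(rotationAboutZ(1.1),
                                             c(0, 0, 0)))
  fpR <- computeFingerprint(rot, cfg)
  expect_lt(max(abs(fpR@values - fp@values) / pmax(abs(fp@values), 1)),
            0.01)

  # NOT tilt-invariant: a 30-degree tilt moves the fingerprint measurably
  tilted <- generateCanopy("cone", 0.3, 1, 8000, seed = 5,
                           tiltDeg = 30)$cloud
  fpTilt <- computeFingerprint(tilted, cfg)
  expect_gt(sqrt(sum((fpTilt@values - fp@values)^2)), 0.1)
})

test_that("a degenerate center slice is refused or kept raw", {
  # all mass at the extremes: the center third is empty -> error
  pinch <- pointCloud(cbind(runif(200), runif(200),
                            c(runif(100, 0, 0.1), runif(100, 0.9, 1))))
  expect_error(computeFingerprint(pinch, fingerprintConfig(1, "area2d")),
               "smaller n")

  # center nonzero for point_count but zero for volume -> volume kept raw
  set.seed(6)
  sparseMid <- pointCloud(rbind(
    matrix(runif(300), 100, 3) %*% diag(c(1, 1, 0.33)),
    cbind(0.5, 0.5, c(0.4, 0.5, 0.6)),                 # 3 collinear mid
    matrix(runif(300), 100, 3) %*% diag(c(1, 1, 0.33)) +
      matrix(rep(c(0, 0, 0.67), each = 100), 100)))
  fp <- computeFingerprint(sparseMid,
                           fingerprintConfig(1, c("point_count", "volume")))
  expect_true("volume" %in% fp@rawFeatures)
  expect_false("point_count" %in% fp@rawFeatures)
})

test_that("query returns ascending distances with id tie-breaks", {
  cfg <- fingerprintConfig(1, "area2d")
  mk <- function(profile, id)
    new("Fingerprint", values = profile, config = cfg, canopyId = id,
        rawFeatures = character(0))
  db <- fingerprintDB(list(mk(c(2, 1, 1), "b"), mk(c(2, 1, 1), "a"),
                           mk(c(4, 1, 1), "c")))
  q <- mk(c(2, 1, 1), "query")
  res <- queryNearest(db, q, k = 3)
  expect_equal(res$canopy_id, c("a", "b", "c"))  # tie broken by id
  expect_equal(res$distance[1:2], c(0, 0))

  # k larger than the database size
  expect_equal(nrow(queryNearest(db, q, k = 10)), 3L)

  # config mismatch names both configurations
  q2 <- ideotypeFingerprint("cylindrical", fingerprintConfig(2, "area2d"))
  expect_error(queryNearest(db, q2, 1), "config mismatch")
})

test_that("query agrees with a brute-force distance scan", {
  cfg <- fingerprintConfig(1, "area2d")
  set.seed(7)
  fps <- lapply(1:50, function(i)
    new("Fingerprint", values = c(runif(1), 1, runif(1)), config = cfg,
        canopyId = sprintf("c%02d", i), rawFeatures = character(0)))
  db <- fingerprintDB(fps)
  q <- fps[[17]]
  res <- queryNearest(db, q, k = 50)
  brute <- sort(vapply(fps, function(f)
    sqrt(sum((f@values - q@values)^2)), numeric(1)))
  expect_equal(res$distance, brute, tolerance = 1e-12)
  expect_equal(res$canopy_id[1], "c17")
})

test_that("ideotype fingerprints match their closed-form profiles", {
  cfg <- fingerprintConfig(1, "area2d")
  expect_equal(as.numeric(fingerprintMatrix(
    ideotypeFingerprint("conical", cfg))), c(2.25, 1, 0.25))
  expect_true(all(ideotypeFingerprint("cylindrical",
                                      fingerprintConfig(4))@values == 1))
  conical <- fingerprintMatrix(ideotypeFingerprint("conical", cfg))
  inverted <- fingerprintMatrix(ideotypeFingerprint("inverted_conical",
                                                    cfg))
  expect_equal(inverted[3:1, , drop = FALSE], conical,
               ignore_attr = TRUE)
  expect_error(ideotypeFingerprint("bushy", cfg), "valid names")
})

test_that("conical-ideotype retrieval finds only cones in a mixed DB", {
  cfg <- fingerprintConfig(1, c("area2d", "volume"))
  set.seed(8)
  fps <- list()
  for (i in 1:10) {
    r <- runif(1, 0.2, 0.4); h <- runif(1, 0.6, 1.2)
    fps[[i]] <- computeFingerprint(
      generateCanopy("cone", r, h, 3000, seed = 100 + i)$cloud, cfg,
      sprintf("cone_%02d", i))
    fps[[10 + i]] <- computeFingerprint(
      generateCanopy("inverted_cone", r, h, 3000, seed = 200 + i)$cloud,
      cfg, sprintf("icone_%02d", i))
  }
  db <- fingerprintDB(fps)
  hits <- queryNearest(db, ideotypeFingerprint("conical", cfg), k = 10)
  expect_true(all(startsWith(hits$canopy_id, "cone_")))

  # clustering separates the two families perfectly at k = 2
  cl <- clusterFingerprints(db, 2, seed = 17)
  fam <- startsWith(canopyIds(db), "cone_")
  expect_equal(length(unique(cl$labels[fam])), 1L)
  expect_equal(length(unique(cl$labels[!fam])), 1L)
  expect_false(cl$labels[fam][1] == cl$labels[!fam][1])

  # determinism and trivial k
  cl2 <- clusterFingerprints(db, 2, seed = 17)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$embedding, cl2$embedding)
  expect_equal(length(unique(clusterFingerprints(db, 1, 1)$labels)), 1L)
  expect_error(clusterFingerprints(db, 21, 1), "between 1 and")
  expect_length(cl$explainedVariance, 2L)
})

test_that("fingerprint databases round-trip through CSV + JSON sidecar", {
  cfg <- fingerprintConfig(1, c("area2d", "solidity"),
                           outlineMode = "convex")
  fps <- lapply(1:3, function(i)
    computeFingerprint(generateCanopy("cone", 0.3, 1, 1000,
                                      seed = i)$cloud, cfg,
                       sprintf("p%d", i)))
  db <- fingerprintDB(fps)
  f <- tempfile(fileext = ".csv")
  writeFingerprintDB(db, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- readFingerprintDB(f)
  expect_equal(canopyIds(back), canopyIds(db))
  expect_equal(fingerprintValues(back), fingerprintValues(db),
               tolerance = 1e-12)
  cfg2 <- fingerprintConfigOf(back)
  expect_equal(cfg2@n, cfg@n)
  expect_equal(cfg2@featureSet, cfg@featureSet)
  expect_error(readFingerprintDB("/nonexistent.csv"), "no such")
})
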
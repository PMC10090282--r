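test_that("Procrustes recovers exact transforms and flags degeneracy", {
  set.seed(4)
  src <- matrix(rnorm(12), ncol = 3)

  # src == dst -> identity, rmse 0
  fit0 <- estimateRigidTransform(src, src)
  expect_lt(max(abs(fit0$transform@rotation - diag(3))), 1e-12)
  expect_lt(max(abs(fit0$transform@translation)), 1e-12)
  expect_equal(fit0$rmse, 0)

  # a known rotation + translation on 6 sphere-center-like points
  src6 <- matrix(rnorm(18), ncol = 3)
  t0 <- rigidTransform(rotationAboutZ(30 * pi / 180), c(1, 2, 0.5))
  fit <- estimateRigidTransform(src6, applyTransform(src6, t0))
  expect_lt(max(abs(fit$transform@rotation - t0@rotation)), 1e-9)
  expect_lt(max(abs(fit$transform@translation - t0@translation)), 1e-9)
  expect_lt(fit$rmse, 1e-9)

  # degenerate configurations
  lin <- cbind(1:3, 2 * (1:3), 3 * (1:3))
  expect_error(estimateRigidTransform(lin, lin + 1), "collinear")
  expect_error(estimateRigidTransform(src6[1:2, ], src6[1:2, ]),
               "at least 3")

  # the solution is always a proper rotation, never a reflection
  for (seed in 1:10) {
    set.seed(seed)
    s <- matrix(rnorm(15), ncol = 3)
    d <- applyTransform(s, rigidTransform(
      rotationAboutAxis(rnorm(3), runif(1, 0, pi)), rnorm(3))) +
      matrix(rnorm(15, sd = 0.01), ncol = 3)
    R <- estimateRigidTransform(s, d)$transform@rotation
    expect_gt(det(R), 0.999)
  }
})

test_that("registration is equivariant under a common rotation", {
  set.seed(11)
  src <- matrix(rnorm(18), ncol = 3)
  t0 <- rigidTransform(rotationAboutAxis(c(0, 1, 1), 0.8), c(0.4, -1, 2))
  dst <- applyTransform(src, t0)
  Q <- rotationAboutAxis(c(1, 2, 3), 0.5)
  fitQ <- estimateRigidTransform(src %*% t(Q), dst %*% t(Q))
  expect_lt(max(abs(fitQ$transform@rotation -
                    Q %*% t0@rotation %*% t(Q))), 1e-9)
})

test_that("ICP refines a small perturbation to sub-millimeter rmse", {
  cone <- generateCanopy("cone", 0.3, 1, 4000, seed = 2)$cloud

  # already aligned: stays near identity
  r0 <- icpRefine(cone, cone, maxIterations = 10)
  expect_lt(r0$rmse, 1e-9)
  expect_true(r0$converged)

  # 1 degree + 5 mm off: recovers to < 1 mm on a dense noiseless cloud
  pert <- rigidTransform(rotationAboutZ(pi / 180), c(0.005, 0, 0))
  src <- applyTransform(cone, invertTransform(pert))
  r <- icpRefine(src, cone, maxIterations = 60)
  expect_lt(r$rmse, 0.001)
  expect_true(r$converged)

  # disjoint distant clouds: no correspondence inside the gate
  far <- applyTransform(cone, rigidTransform(diag(3), c(50, 0, 0)))
  expect_warning(rf <- icpRefine(far, cone, maxDistance = 0.05),
                 "gate")
  expect_false(rf$converged)

  expect_error(icpRefine(emptyPointCloud(), cone), "non-empty")
})

test_that("automatic marker matching survives permutation and motion", {
  set.seed(5)
  src <- matrix(runif(21, -2, 2), ncol = 3)
  t0 <- rigidTransform(rotationAboutZ(2.1), c(3, -1, 0.2))
  perm <- sample(7)
  dst <- applyTransform(src, t0)[perm, ]
  j <- matchMarkersByDistance(src, dst)
  expect_equal(j, order(perm))  # src i corresponds to dst j[i]
  expect_equal(dst[j, ], applyTransform(src, t0), tolerance = 1e-12)
  expect_error(matchMarkersByDistance(src[1:2, ], dst[1:2, ]),
               "at least 3")
})

test_that("multi-view registration merges within the 0.01 m marker bound", {
  sc <- generateFieldScene(rows = 2, cols = 2, seed = 5)
  poses <- list(identityTransform(),
                rigidTransform(rotationAboutZ(pi / 2), c(1.5, -0.4, 0.02)),
                rigidTransform(rotationAboutZ(pi), c(0.8, 2.1, -0.01)),
                rigidTransform(rotationAboutZ(-pi / 2), c(-1.1, 0.6, 0.03)))
  sim <- simulateViews(sc$cloud, poses, dropout = 0.2,
                       sensorNoiseSigma = 0.002, seed = 9)
  detAll <- function(v) rbind(
    markerCenters(detectColorMarkers(v, "white")),
    markerCenters(detectColorMarkers(v, "yellow")),
    markerCenters(detectColorMarkers(v, "red")))
  cents <- lapply(sim$views, detAll)
  expect_true(all(vapply(cents, nrow, integer(1)) == 10L))
  mp <- lapply(2:4, function(i) {
    j <- matchMarkersByDistance(cents[[i]], cents[[1]])
    list(src = cents[[i]], dst = cents[[1]][j, ])
  })
  reg <- registerViews(sim$views, mp, voxelSize = 0.005)
  expect_length(reg$perStepRmse, 3L)
  expect_true(all(reg$perStepRmse < 0.01))
  # voxel dedup: merged count cannot exceed the sum of the views
  expect_lte(nPoints(reg$merged), sum(vapply(sim$views, nPoints,
                                             integer(1))))
})

test_that("single-view registration is just the voxel pass", {
  pc <- makeColoredCloud(200)
  reg <- registerViews(list(pc), voxelSize = 0.05)
  expect_length(reg$perStepRmse, 0L)
  expect_equal(nPoints(reg$merged), nPoints(voxelDownsample(pc, 0.05)))
  expect_error(registerViews(list(pc, pc), list()), "markerPairs")
})
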
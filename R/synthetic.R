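#' @include fingerprint.R
NULL

# Parametric canopy solids and field scenes emulating the hill-plot TLS
# study conditions: 0.76 m hill spacing, 0.127 m diameter spherical targets
# at 1.52 m dowel height, white corner markers, a flat ground patch with
# millimeter-scale roughness, and 2 mm sensor noise in simulated views.
# Cones and cylinders are sampled by inverse-CDF in z so the density is
# uniform per surface/volume element: naive uniform-z sampling would bias
# fingerprint slice counts.

.analyticTruth <- function(shape, r, h) {
  switch(shape,
    cone = , inverted_cone = list(
      volume = pi * r^2 * h / 3,
      surfaceArea = pi * r^2 + pi * r * sqrt(r^2 + h^2),
      height = h),
    cylinder = list(
      volume = pi * r^2 * h,
      surfaceArea = 2 * pi * r^2 + 2 * pi * r * h,
      height = h),
    ellipsoid = {
      c_ <- h / 2
      p <- 1.6075  # Knud Thomsen approximation for the surface area
      list(volume = 4 / 3 * pi * r^2 * c_,
           surfaceArea = 4 * pi * ((r^p * r^p + 2 * r^p * c_^p) / 3)^(1 / p),
           height = h)
    },
    hemisphere = list(
      volume = 2 / 3 * pi * r^3,
      surfaceArea = 3 * pi * r^2,
      height = r))
}

.sampleCanopyPoints <- function(shape, r, h, n, fill) {
  u <- stats::runif(n); v <- stats::runif(n)
  theta <- stats::runif(n, 0, 2 * pi)
  if (shape %in% c("cone", "inverted_cone")) {
    if (fill == "surface") {
      # lateral surface: area element ~ (1 - z/h); z/h = 1 - sqrt(u)
      zf <- 1 - sqrt(u)
      rad <- r * (1 - zf)
    } else {
      # volume: density in z ~ (1 - z/h)^2; radial ~ sqrt within the disk
      zf <- 1 - (1 - u)^(1 / 3)
      rad <- r * (1 - zf) * sqrt(v)
    }
    z <- zf * h
    if (shape == "inverted_cone") z <- h - z
  } else if (shape == "cylinder") {
    z <- u * h
    rad <- if (fill == "surface") rep(r, n) else r * sqrt(v)
  } else if (shape == "ellipsoid") {
    c_ <- h / 2
    if (fill == "surface") {
      w <- matrix(stats::rnorm(3 * n), ncol = 3)
      w <- w / sqrt(rowSums(w^2))
      return(cbind(r * w[, 1], r * w[, 2], c_ * w[, 3] + c_))
    }
    w <- matrix(stats::rnorm(3 * n), ncol = 3)
    w <- w / sqrt(rowSums(w^2)) * stats::runif(n)^(1 / 3)
    return(cbind(r * w[, 1], r * w[, 2], c_ * w[, 3] + c_))
  } else if (shape == "hemisphere") {
    cz <- if (fill == "surface") u else {
      w <- matrix(stats::rnorm(3 * n), ncol = 3)
      w <- w / sqrt(rowSums(w^2)) * stats::runif(n)^(1 / 3)
      return(r * cbind(w[, 1], w[, 2], abs(w[, 3])))
    }
    sz <- sqrt(pmax(0, 1 - cz^2))
    return(r * cbind(sz * cos(theta), sz * sin(theta), cz))
  }
  cbind(rad * cos(theta), rad * sin(theta), z)
}

#' Generate a parametric canopy point cloud
#'
#' Samples a canopy-like solid (cone apex-up, inverted cone apex-down,
#' cylinder, ellipsoid, hemisphere) uniformly on its surface or within its
#' volume, optionally tilts it about a horizontal axis through its
#' centroid, and adds isotropic Gaussian noise. Identical seeds give
#' identical clouds. The returned `truth` holds the analytic volume,
#' surface area and height of the untilted, noiseless solid.
#'
#' @param shape one of "cone", "inverted_cone", "cylinder", "ellipsoid",
#'   "hemisphere"
#' @param radius base/equatorial radius in meters (> 0)
#' @param height total height in meters (> 0; ignored for hemisphere,
#'   whose height is its radius)
#' @param nPoints number of points (>= 1)
#' @param fill "surface" (the outer surface that determines the hull) or
#'   "volume"
#' @param noiseSigma isotropic Gaussian noise standard deviation (m)
#' @param tiltDeg tilt about the x axis through the centroid, degrees
#' @param seed integer RNG seed
#' @param color optional RGB triple for all points (default a foliage
#'   green with slight per-point variation); NULL for a colorless cloud
#' @return list with `cloud` (a [PointCloud-class], base centered at the
#'   origin) and `truth` (`volume`, `surfaceArea`, `height`)
#' @examples
#' cone <- generateCanopy("cone", 0.3, 1.0, 2000, seed = 1)
#' cone$truth$volume  # pi * 0.09 / 3
#' @export
generateCanopy <- function(shape = c("cone", "inverted_cone", "cylinder",
                                     "ellipsoid", "hemisphere"),
                           radius, height = radius, nPoints = 2000L,
                           fill = c("surface", "volume"), noiseSigma = 0,
                           tiltDeg = 0, seed = 1L,
                           color = c(0.2, 0.55, 0.2)) {
  shape <- match.arg(shape)
  fill <- match.arg(fill)
  if (radius <= 0 || height <= 0) stop("radius and height must be > 0")
  nPoints <- as.integer(nPoints)
  if (is.na(nPoints) || nPoints < 1L) stop("nPoints must be >= 1")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (shape == "hemisphere") height <- radius
  m <- withSeed(seed, {
    pts <- .sampleCanopyPoints(shape, radius, height, nPoints, fill)
    if (tiltDeg != 0) {
      ctr <- colMeans(pts)
      R <- rotationAboutAxis(c(1, 0, 0), tiltDeg * pi / 180)
      pts <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr, "+")
    }
    if (noiseSigma > 0)
      pts <- pts + matrix(stats::rnorm(3 * nPoints, sd = noiseSigma),
                          ncol = 3)
    pts
  })
  colors <- if (!is.null(color)) {
    jit <- withSeed(seed + 1L,
                    matrix(stats::runif(3 * nPoints, -0.05, 0.05), ncol = 3))
    pmin(pmax(matrix(color, nPoints, 3, byrow = TRUE) + jit, 0), 1)
  }
  list(cloud = pointCloud(m, colors),
       truth = .analyticTruth(shape, radius, height))
}

# points on a sphere surface, colored
.sphereMarker <- function(center, diameter, n, color, seed) {
  withSeed(seed, {
    w <- matrix(stats::rnorm(3 * n), ncol = 3)
    w <- w / sqrt(rowSums(w^2)) * diameter / 2
    jit <- matrix(stats::runif(3 * n, -0.03, 0.03), ncol = 3)
    list(pts = sweep(w, 2, center, "+"),
         col = pmin(pmax(matrix(color, n, 3, byrow = TRUE) + jit, 0), 1))
  })
}

#' Generate a hill-plot field scene
#'
#' Builds a labeled synthetic block: a flat ground patch with Gaussian
#' roughness, canopies on a rows x cols grid at the standard 0.76 m hill
#' spacing, white spherical corner markers (0.127 m diameter, centers at
#' the 1.52 m dowel-top height) at the block's four corners, and a set of
#' colored (yellow/red) in-block spheres at seeded, jittered positions —
#' the jitter keeps the marker layout's pairwise-distance signatures
#' unambiguous for automatic matching. Every point carries a ground-truth
#' label.
#'
#' @param rows,cols grid dimensions (>= 1)
#' @param spacing hill spacing in meters (default 0.76); must exceed the
#'   largest canopy diameter or generation stops with an error
#' @param canopySpecs optional list (length rows*cols, row-major) of lists
#'   with any of `shape`, `radius`, `height`, `nPoints`, `fill`; defaults
#'   to cones of radius 0.25 m and height 0.8 m with 2000 surface points
#' @param groundRoughnessSigma ground z roughness (m), default 0.005
#' @param groundSpacing ground sampling pitch (m), default 0.02
#' @param margin ground margin beyond the outer hills (m); the white
#'   corner markers sit at the corners of this extent
#' @param nColoredMarkers number of in-block colored spheres (>= 0)
#' @param markerHeight z of marker centers (m), default 1.52
#' @param markerDiameter marker sphere diameter (m), default 0.127
#' @param markerPoints points per marker sphere
#' @param includeMarkers logical; set FALSE for a marker-free scene
#'   (ground and canopies only)
#' @param seed integer RNG seed; identical specs + seed give identical
#'   scenes
#' @return list with `cloud` (colored [PointCloud-class]), `labels`
#'   (character vector: "ground", "canopy_<i>", "marker_w<i>",
#'   "marker_c<i>") and `truth` (list: `hillCenters` (rows*cols) x 2,
#'   `canopyHeights`, `whiteMarkerCenters` 4 x 3, `coloredMarkerCenters`,
#'   `groundPlane` a [Plane-class])
#' @export
generateFieldScene <- function(rows = 2L, cols = 2L, spacing = 0.76,
                               canopySpecs = NULL,
                               groundRoughnessSigma = 0.005,
                               groundSpacing = 0.015, margin = 0.5,
                               nColoredMarkers = 6L, markerHeight = 1.52,
                               markerDiameter = 0.127,
                               markerPoints = 200L, includeMarkers = TRUE,
                               seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  nHills <- rows * cols
  defaults <- list(shape = "cone", radius = 0.25, height = 0.8,
                   nPoints = 3000L, fill = "surface")
  specs <- lapply(seq_len(nHills), function(i) {
    s <- if (!is.null(canopySpecs)) utils::modifyList(defaults,
                                                      canopySpecs[[i]])
    else defaults
    s
  })
  maxDiam <- max(vapply(specs, function(s) 2 * s$radius, numeric(1)))
  if (nHills > 1L && spacing <= maxDiam)
    stop(sprintf(
      "hill spacing %.2f m does not exceed the largest canopy diameter %.2f m: canopies would overlap",
      spacing, maxDiam))

  hillX <- rep(seq_len(cols) - 1L, times = rows) * spacing
  hillY <- rep(seq_len(rows) - 1L, each = cols) * spacing
  xr <- c(-margin, (cols - 1L) * spacing + margin)
  yr <- c(-margin, (rows - 1L) * spacing + margin)

  pts <- list(); cols_ <- list(); labs <- list()

  # ground patch
  gx <- seq(xr[1], xr[2], by = groundSpacing)
  gy <- seq(yr[1], yr[2], by = groundSpacing)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  g <- g + withSeed(seed + 1L,
    matrix(stats::runif(2L * nrow(g), -groundSpacing / 3, groundSpacing / 3),
           ncol = 2))
  gz <- if (groundRoughnessSigma > 0)
    withSeed(seed, stats::rnorm(nrow(g), sd = groundRoughnessSigma))
  else rep(0, nrow(g))
  gcol <- withSeed(seed + 2L, {
    base <- matrix(c(0.45, 0.33, 0.2), nrow(g), 3, byrow = TRUE)
    pmin(pmax(base + matrix(stats::runif(3 * nrow(g), -0.05, 0.05),
                            ncol = 3), 0), 1)
  })
  pts[[1]] <- cbind(g, gz); cols_[[1]] <- gcol
  labs[[1]] <- rep("ground", nrow(g))

  # canopies
  for (i in seq_len(nHills)) {
    s <- specs[[i]]
    can <- generateCanopy(s$shape, s$radius, s$height, s$nPoints,
                          fill = s$fill, seed = seed + 10L + i)
    m <- coords(can$cloud)
    m[, 1] <- m[, 1] + hillX[i]; m[, 2] <- m[, 2] + hillY[i]
    pts[[length(pts) + 1L]] <- m
    cols_[[length(cols_) + 1L]] <- pointColors(can$cloud)
    labs[[length(labs) + 1L]] <- rep(paste0("canopy_", i), nrow(m))
  }

  # white corner markers
  corners <- cbind(x = xr[c(1, 2, 2, 1)], y = yr[c(1, 1, 2, 2)],
                   z = markerHeight)
  if (includeMarkers) for (i in 1:4) {
    mk <- .sphereMarker(corners[i, ], markerDiameter, markerPoints,
                        c(0.97, 0.97, 0.97), seed + 100L + i)
    pts[[length(pts) + 1L]] <- mk$pts
    cols_[[length(cols_) + 1L]] <- mk$col
    labs[[length(labs) + 1L]] <- rep(paste0("marker_w", i), markerPoints)
  }

  # colored in-block markers along the block edges, jittered
  coloredCenters <- matrix(numeric(0), ncol = 3)
  if (includeMarkers && nColoredMarkers > 0L) {
    base <- withSeed(seed + 200L, {
      t_ <- seq(0, 1, length.out = nColoredMarkers + 2L)[
        2:(nColoredMarkers + 1L)]
      side <- rep_len(1:2, nColoredMarkers)
      bx <- ifelse(side == 1L, xr[1] + t_ * diff(xr), xr[1] + t_ * diff(xr))
      by <- ifelse(side == 1L, yr[1], yr[2])
      jit <- matrix(stats::runif(2L * nColoredMarkers, -0.15, 0.15),
                    ncol = 2)
      cbind(bx + jit[, 1], by + jit[, 2], markerHeight)
    })
    coloredCenters <- base
    for (i in seq_len(nColoredMarkers)) {
      colr <- if (i %% 2L == 1L) c(0.9, 0.85, 0.1) else c(0.9, 0.12, 0.12)
      mk <- .sphereMarker(base[i, ], markerDiameter, markerPoints,
                          colr, seed + 300L + i)
      pts[[length(pts) + 1L]] <- mk$pts
      cols_[[length(cols_) + 1L]] <- mk$col
      labs[[length(labs) + 1L]] <- rep(paste0("marker_c", i), markerPoints)
    }
  }

  cloud <- pointCloud(do.call(rbind, pts), do.call(rbind, cols_))
  list(cloud = cloud,
       labels = unlist(labs),
       truth = list(
         hillCenters = cbind(x = hillX, y = hillY),
         canopyHeights = vapply(specs, `[[`, numeric(1), "height"),
         whiteMarkerCenters = corners,
         coloredMarkerCenters = coloredCenters,
         groundPlane = new("Plane", a = 0, b = 0, c = 0, fitRmse = 0)))
}

#' Simulate multi-view scans of a scene
#'
#' Each view is the scene expressed in that pose's frame (the pose maps
#' world coordinates into the view frame), with a seeded random fraction
#' `dropout` of points removed (exact count, by permutation) and isotropic
#' Gaussian sensor noise added. The default 2 mm noise matches the
#' instrument's point-spacing scale at a 10 m range. When marker centers
#' are supplied they are transformed into each view's frame and returned
#' for correspondence building.
#'
#' @param scene a [PointCloud-class] in world coordinates
#' @param poses list of [RigidTransform-class] view poses
#' @param dropout proportion of points removed per view, in `[0, 1)`
#' @param sensorNoiseSigma Gaussian noise sd in meters (default 0.002)
#' @param seed integer RNG seed
#' @param markerCenters optional M x 3 matrix of true marker centers in
#'   world coordinates
#' @return list with `views` (list of [PointCloud-class]) and `markers`
#'   (list of transformed M x 3 center matrices, or NULL)
#' @export
simulateViews <- function(scene, poses, dropout = 0,
                          sensorNoiseSigma = 0.002, seed = 1L,
                          markerCenters = NULL) {
  .assertCloud(scene, "scene")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (sensorNoiseSigma < 0) stop("sensorNoiseSigma must be >= 0")
  stopifnot(all(vapply(poses, is, logical(1), "RigidTransform")))
  n <- nPoints(scene)
  views <- vector("list", length(poses))
  markers <- if (!is.null(markerCenters)) vector("list", length(poses))
  for (v in seq_along(poses)) {
    pc <- applyTransform(scene, poses[[v]])
    pc <- withSeed(seed + v, {
      keepN <- n - floor(dropout * n)
      keep <- sample.int(n)[seq_len(keepN)]
      out <- pc[sort(keep)]
      if (sensorNoiseSigma > 0)
        out <- pointCloud(coords(out) +
                            matrix(stats::rnorm(3 * keepN,
                                                sd = sensorNoiseSigma),
                                   ncol = 3),
                          pointColors(out))
      out
    })
    views[[v]] <- pc
    if (!is.null(markerCenters))
      markers[[v]] <- applyTransform(as.matrix(markerCenters), poses[[v]])
  }
  list(views = views, markers = markers)
}
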
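#' @include segment.R
NULL

#' Canopy height from the top fraction of points
#'
#' Height = mean z of the `ceiling(topFraction * N)` highest points minus
#' the minimum z. Averaging the top 3% (the default) instead of taking the
#' single maximum makes the estimate robust to residual high outliers; a
#' single-point cloud has height 0.
#'
#' @param canopy a non-empty [PointCloud-class]
#' @param topFraction proportion in (0, 1] of highest points to average
#' @return height in meters
#' @examples
#' canopyHeight(pointCloud(cbind(0, 0, seq(0, 0.99, by = 0.01))))
#' @export
canopyHeight <- function(canopy, topFraction = 0.03) {
  .assertCloud(canopy, "canopy")
  if (nPoints(canopy) == 0L) stop("cannot measure the height of an empty cloud")
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  z <- coords(canopy)[, 3]
  nTop <- max(1L, ceiling(topFraction * length(z)))
  mean(sort(z, decreasing = TRUE)[seq_len(nTop)]) - min(z)
}

# rank of the centered coordinates; 3 = full 3D spread
.pointRank <- function(m, tol = 1e-9) {
  if (nrow(m) < 2L) return(0L)
  c_ <- sweep(m, 2, colMeans(m))
  d <- svd(c_, nu = 0, nv = 0)$d
  sum(d > tol * max(d[1], 1e-12))
}

#' Bound a canopy in a watertight triangular mesh
#'
#' `convex_hull` computes the 3D convex hull (incremental algorithm,
#' compiled); `slice_hull` is a tightened alternative for z-concave
#' canopies: the cloud is cut into horizontal slabs, each slab's 2D convex
#' outline is computed, and consecutive outlines are lofted into a closed
#' side wall with flat caps — watertight by construction and closer than
#' the convex hull wherever the silhouette narrows and widens with height.
#'
#' @param canopy a [PointCloud-class] with at least 4 non-coplanar points
#' @param method "convex_hull" (default) or "slice_hull"
#' @param sliceThickness slab height in meters for `slice_hull`
#'   (default 0.1)
#' @return a [TriMesh-class], outward-oriented
#' @seealso [meshTraits()]
#' @export
canopyMesh <- function(canopy, method = c("convex_hull", "slice_hull"),
                       sliceThickness = 0.1) {
  .assertCloud(canopy, "canopy")
  method <- match.arg(method)
  m <- coords(canopy)
  if (nrow(m) < 4L)
    stop("meshing needs at least 4 points (got ", nrow(m), ")")
  if (.pointRank(m) < 3L)
    stop("meshing needs non-coplanar points")
  if (method == "convex_hull") .convexHullMesh(m) else
    .sliceHullMesh(m, sliceThickness)
}

.convexHullMesh <- function(m) {
  res <- .convexHull3d(m)
  faces <- res$faces
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(m)); remap[used] <- seq_along(used)
  faces <- matrix(remap[as.integer(faces)], ncol = 3L)
  mesh <- new("TriMesh", vertices = m[used, , drop = FALSE], faces = faces)
  .orientOutward(mesh)
}

# flip all faces if the signed volume is negative
.orientOutward <- function(mesh) {
  if (.signedMeshVolume(mesh@vertices, mesh@faces) < 0)
    mesh@faces <- mesh@faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

.signedMeshVolume <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Loft two convex rings (both CCW seen from +z, lower ring below upper)
# into a closed triangle strip. Advancing the lower ring emits
# (a_i, a_{i+1}, b_j); advancing the upper ring emits (a_i, b_{j+1}, b_j);
# every internal edge is traversed once in each direction, giving a
# consistently outward-oriented watertight wall of na + nb triangles.
.loftRings <- function(lower, upper) {
  ctr <- colMeans(rbind(lower$xy, upper$xy))
  angA <- atan2(lower$xy[, 2] - ctr[2], lower$xy[, 1] - ctr[1])
  angB <- atan2(upper$xy[, 2] - ctr[2], upper$xy[, 1] - ctr[1])
  oa <- order(angA); ob <- order(angB)
  ia <- lower$idx[oa]; sa <- angA[oa]
  ib <- upper$idx[ob]; sb <- angB[ob]
  na <- length(ia); nb <- length(ib)
  faces <- matrix(0L, na + nb, 3L)
  stepsA <- 0L; stepsB <- 0L; fi <- 0L
  cura <- 1L; curb <- 1L
  # unwrapped angle of the vertex an advance would move to
  nextA <- function() sa[((stepsA + 1L) %% na) + 1L] +
    2 * pi * ((stepsA + 1L) %/% na)
  nextB <- function() sb[((stepsB + 1L) %% nb) + 1L] +
    2 * pi * ((stepsB + 1L) %/% nb)
  while (stepsA < na || stepsB < nb) {
    advanceA <- if (stepsA >= na) FALSE
      else if (stepsB >= nb) TRUE
      else nextA() <= nextB()
    fi <- fi + 1L
    if (advanceA) {
      nxt <- (cura %% na) + 1L
      faces[fi, ] <- c(ia[cura], ia[nxt], ib[curb])
      cura <- nxt; stepsA <- stepsA + 1L
    } else {
      nxt <- (curb %% nb) + 1L
      faces[fi, ] <- c(ia[cura], ib[nxt], ib[curb])
      curb <- nxt; stepsB <- stepsB + 1L
    }
  }
  faces
}

.sliceHullMesh <- function(m, sliceThickness) {
  zr <- range(m[, 3])
  nSlab <- max(1L, ceiling((zr[2] - zr[1]) / sliceThickness))
  cuts <- seq(zr[1], zr[2], length.out = nSlab + 1L)
  slab <- pmin(pmax(findInterval(m[, 3], cuts, rightmost.closed = TRUE),
                    1L), nSlab)
  # merge slabs upward until each has a non-degenerate 2D hull
  groups <- list(); cur <- integer(0)
  for (s in seq_len(nSlab)) {
    cur <- c(cur, which(slab == s))
    ok <- length(cur) >= 3L &&
      .pointRank(cbind(m[cur, 1:2], 0)) >= 2L
    if (ok) { groups[[length(groups) + 1L]] <- cur; cur <- integer(0) }
  }
  if (length(cur)) {
    if (length(groups)) groups[[length(groups)]] <-
        c(groups[[length(groups)]], cur)
    else stop("slice_hull: cloud collapses to a line in plan view")
  }
  if (length(groups) < 1L) stop("slice_hull: no usable slab")
  # one CCW convex ring per slab boundary: ring k sits at the slab's
  # z-extremes; use each slab's hull at both its bottom and top so the
  # solid is a stack of prisms over the slab silhouettes
  verts <- NULL; rings <- vector("list", 2L * length(groups))
  addRing <- function(xy, z, verts) {
    h <- grDevices::chull(xy)            # clockwise
    h <- rev(h)                          # CCW
    ring <- list(xy = xy[h, , drop = FALSE],
                 idx = nrow(verts) + seq_along(h))
    list(ring = ring, verts = rbind(verts, cbind(ring$xy, z)))
  }
  verts <- matrix(numeric(0), ncol = 3L)
  for (g in seq_along(groups)) {
    pts <- m[groups[[g]], , drop = FALSE]
    zlo <- min(pts[, 3]); zhi <- max(pts[, 3])
    r1 <- addRing(pts[, 1:2, drop = FALSE], zlo, verts)
    verts <- r1$verts
    r2 <- addRing(pts[, 1:2, drop = FALSE], zhi, verts)
    verts <- r2$verts
    rings[[2L * g - 1L]] <- r1$ring
    rings[[2L * g]] <- r2$ring
  }
  faces <- list()
  for (k in seq_len(length(rings) - 1L))
    faces[[k]] <- .loftRings(rings[[k]], rings[[k + 1L]])
  # caps: bottom ring fanned downward, top ring fanned upward
  capFan <- function(ring, verts, up) {
    ctr <- c(colMeans(ring$xy), verts[ring$idx[1], 3])
    ci <- nrow(verts) + 1L
    n <- length(ring$idx)
    f <- matrix(0L, n, 3L)
    for (i in seq_len(n)) {
      j <- (i %% n) + 1L
      f[i, ] <- if (up) c(ci, ring$idx[i], ring$idx[j])
                else c(ci, ring$idx[j], ring$idx[i])
    }
    list(faces = f, verts = rbind(verts, ctr))
  }
  bot <- capFan(rings[[1L]], verts, up = FALSE)
  verts <- bot$verts
  top <- capFan(rings[[length(rings)]], verts, up = TRUE)
  verts <- top$verts
  F <- do.call(rbind, c(faces, list(bot$faces, top$faces)))
  mesh <- new("TriMesh", vertices = verts, faces = F)
  .orientOutward(mesh)
}

#' Check mesh watertightness
#'
#' TRUE when every directed edge of the face set is matched by exactly one
#' reverse directed edge — i.e. the mesh is a closed, consistently oriented
#' 2-manifold.
#'
#' @param mesh a [TriMesh-class]
#' @return logical
#' @export
isWatertight <- function(mesh) {
  stopifnot(is(mesh, "TriMesh"))
  F <- mesh@faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  !anyDuplicated(fwd) && all(fwd %in% paste(e[, 2], e[, 1]))
}

#' Volume and surface area of a watertight mesh
#'
#' Volume by signed tetrahedron summation (divergence theorem); surface
#' area as the sum of triangle areas. Scales as expected under similarity:
#' volume by s^3, area by s^2.
#'
#' @param mesh a watertight [TriMesh-class]
#' @return list with `volume` (m^3) and `surfaceArea` (m^2)
#' @export
meshTraits <- function(mesh) {
  stopifnot(is(mesh, "TriMesh"))
  if (!isWatertight(mesh))
    stop("mesh is not watertight; volume is undefined")
  V <- mesh@vertices; F <- mesh@faces
  vol <- abs(.signedMeshVolume(V, F))
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  list(volume = vol, surfaceArea = sum(sqrt(cx^2 + cy^2 + cz^2)) / 2)
}

#' Flag outlier measurements by Z-score
#'
#' A value is flagged when `|value - mean| / sd > zThreshold`, with the
#' population standard deviation (divisor N). When all values are equal
#' (sd = 0) nothing is flagged. The default threshold 2.5 is the working
#' cut for ground-truth quality screening.
#'
#' @param values numeric vector with at least 2 entries
#' @param zThreshold positive Z-score cut (default 2.5)
#' @return logical mask, TRUE = flagged outlier
#' @examples
#' flagOutlierMeasurements(c(1:10, 100))
#' @export
flagOutlierMeasurements <- function(values, zThreshold = 2.5) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("outlier flagging needs at least 2 values")
  mu <- mean(values)
  sdPop <- sqrt(mean((values - mu)^2))
  if (sdPop == 0) return(rep(FALSE, length(values)))
  abs(values - mu) / sdPop > zThreshold
}

#' All traits of one canopy in one row
#'
#' Convenience wrapper running [canopyHeight()], [canopyMesh()] +
#' [meshTraits()] and [projectOutline()] + [outlineTraits()] on a canopy
#' cloud. Degenerate canopies (< 4 points or coplanar) report 0 volume and
#' surface area; degenerate projections report NA outline traits.
#'
#' @param canopy a [PointCloud-class]
#' @param meshMethod passed to [canopyMesh()]
#' @param outlineMode passed to [projectOutline()]
#' @param outlineAlpha passed to [projectOutline()]
#' @param id optional identifier stored in the row
#' @return one-row data.frame: id, height_m, volume_m3, surface_area_m2,
#'   area_m2, perimeter_m, major_axis_m, minor_axis_m, aspect_ratio,
#'   roundness, circularity, convex_area_m2, solidity
#' @export
canopyTraits <- function(canopy, meshMethod = "convex_hull",
                         outlineMode = "convex", outlineAlpha = 0.05,
                         id = "canopy") {
  .assertCloud(canopy, "canopy")
  h <- canopyHeight(canopy)
  mt <- tryCatch(meshTraits(canopyMesh(canopy, meshMethod)),
                 error = function(e) list(volume = 0, surfaceArea = 0))
  ot <- tryCatch(
    outlineTraits(projectOutline(canopy, "xy", outlineMode, outlineAlpha)),
    error = function(e) NULL)
  data.frame(
    id = id, height_m = h, volume_m3 = mt$volume,
    surface_area_m2 = mt$surfaceArea,
    area_m2 = if (is.null(ot)) NA_real_ else ot$area,
    perimeter_m = if (is.null(ot)) NA_real_ else ot$perimeter,
    major_axis_m = if (is.null(ot)) NA_real_ else ot$majorAxis,
    minor_axis_m = if (is.null(ot)) NA_real_ else ot$minorAxis,
    aspect_ratio = if (is.null(ot)) NA_real_ else ot$aspectRatio,
    roundness = if (is.null(ot)) NA_real_ else ot$roundness,
    circularity = if (is.null(ot)) NA_real_ else ot$circularity,
    convex_area_m2 = if (is.null(ot)) NA_real_ else ot$convexArea,
    solidity = if (is.null(ot)) NA_real_ else ot$solidity,
    stringsAsFactors = FALSE)
}
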
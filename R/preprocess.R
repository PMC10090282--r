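#' @include pointcloud.R
NULL

#' Homogenize point density on a regular voxel grid
#'
#' Replaces all points inside each occupied voxel with their arithmetic
#' mean (colors averaged the same way), so the output has exactly one point
#' per occupied voxel. The voxel index is `floor(coordinate / voxelSize)`
#' per axis on the raw coordinates; a point exactly on a boundary belongs
#' to the higher-index voxel. TLS scans have strongly distance-dependent
#' density; a 5 mm grid is the default working resolution.
#'
#' @param pc a [PointCloud-class]
#' @param voxelSize voxel edge length in meters (> 0); default 0.005
#' @return a [PointCloud-class] with one point per occupied voxel, ordered
#'   by voxel index (x, then y, then z)
#' @examples
#' pc <- pointCloud(matrix(runif(300), ncol = 3))
#' nPoints(voxelDownsample(pc, 0.05))
#' @export
voxelDownsample <- function(pc, voxelSize = 0.005) {
  .assertCloud(pc)
  if (!is.numeric(voxelSize) || length(voxelSize) != 1L || voxelSize <= 0)
    stop("voxelSize must be a single positive number (meters)")
  n <- nPoints(pc)
  if (n == 0L) return(pc)
  m <- coords(pc)
  cols <- list(ix = floor(m[, 1] / voxelSize),
               iy = floor(m[, 2] / voxelSize),
               iz = floor(m[, 3] / voxelSize),
               x = m[, 1], y = m[, 2], z = m[, 3])
  if (hasColors(pc)) {
    cc <- pointColors(pc)
    cols$r <- cc[, 1]; cols$g <- cc[, 2]; cols$b <- cc[, 3]
  }
  dt <- data.table::as.data.table(cols)
  agg <- dt[, lapply(.SD, mean), by = c("ix", "iy", "iz")]
  data.table::setorder(agg, ix, iy, iz)
  pointCloud(as.matrix(agg[, c("x", "y", "z")]),
             if (hasColors(pc)) as.matrix(agg[, c("r", "g", "b")]))
}

# mean distance from each point to its k nearest neighbors (self excluded)
.meanKnnDistance <- function(m, k) {
  nn <- RANN::nn2(m, k = k + 1L)
  rowMeans(nn$nn.dists[, -1L, drop = FALSE])
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `k` nearest neighbors (the
#' query point itself excluded), then discards points whose mean distance
#' exceeds `mu + alpha * sigma`, where `mu` and `sigma` are the mean and
#' standard deviation of those per-point averages over the whole cloud.
#' Smaller `alpha` removes points more aggressively. The threshold is
#' recomputed for every input cloud. Defaults `k = 24`, `alpha = 0.075`
#' are the working values selected by the height-stability sweep (see
#' [sweepNoiseParams()]).
#'
#' @param pc a [PointCloud-class] with more than `k` points
#' @param k number of nearest neighbors (>= 1)
#' @param alpha non-negative standard-deviation ratio
#' @return list with `inliers` (a [PointCloud-class]) and `keep` (logical
#'   mask aligned to the input point order)
#' @export
removeStatisticalOutliers <- function(pc, k = 24L, alpha = 0.075) {
  .assertCloud(pc)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (!is.numeric(alpha) || alpha < 0) stop("alpha must be >= 0")
  n <- nPoints(pc)
  if (n <= k)
    stop(sprintf(
      "statistical outlier removal needs more than k points (N = %d, k = %d; at least %d required)",
      n, k, k + 1L))
  avg <- .meanKnnDistance(coords(pc), k)
  thr <- mean(avg) + alpha * stats::sd(avg)
  keep <- avg <= thr
  list(inliers = pc[keep], keep = keep)
}

#' Sweep denoising parameters and monitor a trait
#'
#' Runs [removeStatisticalOutliers()] over the (k, alpha) grid and records
#' the canopy height of the denoised cloud and the number of removed
#' points for each combination. This reproduces the parameter-selection
#' protocol: the working `k` is the one past which further increases have a
#' negligible effect on the monitored height.
#'
#' @param pc a [PointCloud-class]
#' @param ks integer vector of neighbor counts (e.g. `c(8, 16, 24, 32, 40)`)
#' @param alphas numeric vector of standard-deviation ratios
#' @param trait monitored trait; only "height" is defined
#' @return data.frame with columns `k`, `alpha`, `height_m`,
#'   `removed_count`, one row per combination (ordered k-major). Cells whose
#'   precondition fails (N <= k) are NA with a warning.
#' @export
sweepNoiseParams <- function(pc, ks = c(8L, 16L, 24L, 32L, 40L),
                             alphas, trait = c("height")) {
  .assertCloud(pc)
  trait <- match.arg(trait)
  if (!length(ks) || !length(alphas))
    stop("ks and alphas must be non-empty")
  ks <- as.integer(ks)
  n <- nPoints(pc)
  out <- expand.grid(alpha = as.numeric(alphas), k = ks)[, c("k", "alpha")]
  out$height_m <- NA_real_
  out$removed_count <- NA_integer_
  m <- coords(pc)
  for (k in unique(ks)) {
    rows <- which(out$k == k)
    if (n <= k) {
      warning(sprintf("k = %d skipped: cloud has only %d points", k, n))
      next
    }
    avg <- .meanKnnDistance(m, k)
    mu <- mean(avg); sg <- stats::sd(avg)
    for (i in rows) {
      keep <- avg <= mu + out$alpha[i] * sg
      out$removed_count[i] <- sum(!keep)
      out$height_m[i] <- if (any(keep)) canopyHeight(pc[keep]) else NA_real_
    }
  }
  rownames(out) <- NULL
  out
}

#' Euclidean (fixed-radius) connected-component clustering
#'
#' Two points share a label iff they are connected by a chain of hops each
#' no longer than `radius`. Clusters smaller than `minPoints` are relabeled
#' -1 (unclustered). Labels are 0-based and ordered by descending cluster
#' size, ties broken by the smallest member index.
#'
#' @param pc a [PointCloud-class]
#' @param radius connection radius in meters (> 0)
#' @param minPoints minimum cluster size (>= 1)
#' @return integer vector of labels, one per point (-1 = unclustered)
#' @export
euclideanCluster <- function(pc, radius, minPoints = 1L) {
  .assertCloud(pc)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  minPoints <- as.integer(minPoints)
  if (is.na(minPoints) || minPoints < 1L) stop("minPoints must be >= 1")
  n <- nPoints(pc)
  if (n == 0L) return(integer(0))
  root <- .radiusComponents(coords(pc), radius)
  sizes <- tabulate(root + 1L, nbins = n)
  comps <- which(sizes > 0L) - 1L
  keep <- comps[sizes[comps + 1L] >= minPoints]
  # order: descending size, ties by smallest member index (== root index,
  # since the union-find root is the minimum member)
  keep <- keep[order(-sizes[keep + 1L], keep)]
  lab <- rep(-1L, n)
  for (i in seq_along(keep)) lab[root == keep[i]] <- i - 1L
  lab
}

# color predicates for painted reference targets; thresholds separate the
# painted spheres from foliage and soil
.colorPredicate <- function(colors, colorClass,
                            white = 0.85, strong = 0.75, weak = 0.4) {
  r <- colors[, 1]; g <- colors[, 2]; b <- colors[, 3]
  switch(colorClass,
         white = r >= white & g >= white & b >= white,
         yellow = r >= strong & g >= strong & b <= weak,
         red = r >= strong & g <= weak & b <= weak)
}

#' Detect spherical color reference markers
#'
#' Selects points whose normalized RGB matches the requested color class
#' (white: all channels >= 0.85; yellow: R,G >= 0.75 and B <= 0.4; red:
#' R >= 0.75 and G,B <= 0.4) and whose z exceeds `zMin` — the height
#' constraint excludes white objects near the ground such as plot stake
#' identifiers — then labels the survivors with [euclideanCluster()] and
#' returns each cluster's centroid as a marker center, sorted by x then y.
#'
#' @param pc a [PointCloud-class] with colors
#' @param colorClass "white", "yellow" or "red"
#' @param zMin minimum marker z in meters (default 1, below the 1.52 m
#'   dowel-top height of field targets)
#' @param clusterRadius clustering radius in meters
#' @param minPoints minimum points per marker cluster
#' @param thresholds optional named list overriding the color thresholds
#'   (`white`, `strong`, `weak`)
#' @return a [MarkerSet-class]
#' @export
detectColorMarkers <- function(pc, colorClass = c("white", "yellow", "red"),
                               zMin = 1.0, clusterRadius = 0.05,
                               minPoints = 10L, thresholds = list()) {
  .assertCloud(pc)
  colorClass <- match.arg(colorClass)
  if (!hasColors(pc))
    stop("marker detection needs per-point colors; supply a colored cloud")
  thr <- utils::modifyList(list(white = 0.85, strong = 0.75, weak = 0.4),
                           thresholds)
  sel <- .colorPredicate(pointColors(pc), colorClass,
                         thr$white, thr$strong, thr$weak) &
         coords(pc)[, 3] > zMin
  sub <- pc[which(sel)]
  if (nPoints(sub) == 0L)
    return(new("MarkerSet", centers = matrix(numeric(0), ncol = 3),
               colorClass = colorClass, clusterSizes = integer(0)))
  lab <- euclideanCluster(sub, clusterRadius, minPoints)
  ids <- sort(unique(lab[lab >= 0L]))
  centers <- t(vapply(ids, function(l)
    colMeans(coords(sub)[lab == l, , drop = FALSE]), numeric(3)))
  sizes <- vapply(ids, function(l) sum(lab == l), integer(1))
  if (length(ids)) {
    o <- order(centers[, 1], centers[, 2])
    centers <- centers[o, , drop = FALSE]
    sizes <- sizes[o]
  } else centers <- matrix(numeric(0), ncol = 3)
  new("MarkerSet", centers = centers, colorClass = colorClass,
      clusterSizes = as.integer(sizes))
}

#' Crop a field block using its four corner markers
#'
#' Keeps the points whose (x, y) lie inside (or on the boundary of) the
#' quadrilateral spanned by the four corner-marker positions; z is
#' unrestricted. Vertices are ordered counter-clockwise internally, so any
#' corner ordering is accepted.
#'
#' @param pc a [PointCloud-class]
#' @param cornerMarkers a [MarkerSet-class] with exactly 4 centers, or a
#'   4 x 2 (or 4 x 3) matrix of corner positions
#' @return the cropped [PointCloud-class]
#' @export
cropBlock <- function(pc, cornerMarkers) {
  .assertCloud(pc)
  corners <- if (is(cornerMarkers, "MarkerSet"))
    markerCenters(cornerMarkers) else as.matrix(cornerMarkers)
  if (nrow(corners) != 4L)
    stop("block cropping needs exactly 4 corner markers (got ",
         nrow(corners), ")")
  xy <- corners[, 1:2, drop = FALSE]
  ctr <- colMeans(xy)
  o <- order(atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1]))
  xy <- xy[o, , drop = FALSE]
  if (nPoints(pc) == 0L) return(pc)
  p <- coords(pc)
  inside <- rep(TRUE, nPoints(pc))
  for (i in 1:4) {
    a <- xy[i, ]; b <- xy[if (i == 4L) 1L else i + 1L, ]
    # CCW ordering: inside points have non-negative cross product
    cr <- (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
    inside <- inside & cr >= -1e-12
  }
  pc[inside]
}
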
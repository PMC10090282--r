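#' @include preprocess.R
NULL

#' Least-squares plane fit z = a x + b y + c
#'
#' @param pc a [PointCloud-class] with at least 3 points whose (x, y) are
#'   not collinear
#' @return a [Plane-class] with the fitted coefficients and the RMS
#'   residual
#' @examples
#' pc <- pointCloud(cbind(runif(50), runif(50), 0.02 * runif(50)))
#' fitPlane(pc)
#' @export
fitPlane <- function(pc) {
  .assertCloud(pc)
  m <- coords(pc)
  if (nrow(m) < 3L) stop("plane fitting needs at least 3 points")
  X <- cbind(m[, 1], m[, 2], 1)
  qr_ <- qr(X)
  if (qr_$rank < 3L)
    stop("degenerate (x, y) configuration: points are collinear in plan view")
  beta <- qr.coef(qr_, m[, 3])
  res <- m[, 3] - X %*% beta
  new("Plane", a = unname(beta[1]), b = unname(beta[2]),
      c = unname(beta[3]), fitRmse = sqrt(mean(res^2)))
}

#' Extract the faithful-ground band around a plot center
#'
#' Returns the points whose (x, y) lie in the square annulus around
#' `center`: strictly outside the inner square of half-side
#' `innerHalfLength`, inside (or on) the square of half-side
#' `innerHalfLength + bandWidth`. These are the visible ground points
#' between neighboring plots, used to fit the per-plot ground plane.
#' Defaults implement a 0.1 m inner square side with a 0.1 m wide band.
#'
#' @param pc a [PointCloud-class]
#' @param center numeric (x, y) plot center in meters
#' @param innerHalfLength half side length of the excluded inner square (m)
#' @param bandWidth width of the band outside the inner square (m)
#' @return a [PointCloud-class]; empty with a warning when no points fall
#'   in the band (callers fall back to the block-level plane)
#' @export
extractGroundBand <- function(pc, center, innerHalfLength = 0.05,
                              bandWidth = 0.1) {
  .assertCloud(pc)
  if (innerHalfLength <= 0 || bandWidth <= 0)
    stop("band parameters must be positive")
  if (length(center) < 2L) stop("center must be (x, y)")
  m <- coords(pc)
  d <- pmax(abs(m[, 1] - center[1]), abs(m[, 2] - center[2]))
  sel <- d > innerHalfLength & d <= innerHalfLength + bandWidth
  out <- pc[sel]
  if (nPoints(out) == 0L)
    warning(sprintf("empty ground band around (%.2f, %.2f)",
                    center[1], center[2]))
  out
}

# Trimmed ground-plane fit: drop points whose residual exceeds 2.5 x the
# fit RMSE and refit (two rounds). Protects the "faithful ground" plane
# from canopy stragglers that reach into the square band at its diagonals.
.fitTrimmedPlane <- function(band) {
  plane <- fitPlane(band)
  for (round in 1:2) {
    if (plane@fitRmse == 0) break
    m <- coords(band)
    res <- abs(m[, 3] - planeHeight(plane, m[, 1], m[, 2]))
    keep <- res <= 2.5 * plane@fitRmse
    if (all(keep) || sum(keep) < 3L) break
    trimmed <- band[keep]
    refit <- try(fitPlane(trimmed), silent = TRUE)
    if (inherits(refit, "try-error")) break
    band <- trimmed
    plane <- refit
  }
  plane
}

#' Segment a registered block into per-plot canopies
#'
#' The ground-removal pipeline: (1) fit a block-level plane to the whole
#' cloud — least squares balances canopy and ground mass, so the plane
#' passes through the middle of each plot; (2) keep the points above it
#' (the canopy tops); (3) label the tops with [euclideanCluster()];
#' (4) take each cluster's mean (x, y) as the plot's approximate center;
#' (5) extract the square ground band around each center; (6) fit the
#' per-plot ground plane to the band (block plane fallback when the band
#' is empty); (7) assign every block point to its nearest plot center in
#' (x, y) and keep, per plot, the assigned points strictly above that
#' plot's ground plane as the canopy. Segments are sorted by center
#' (x, then y).
#'
#' Two refinements keep the plane fit faithful when the band geometry
#' overlaps foliage or the ground is rough: only band points within
#' `groundTolerance` of the band's lowest z enter the plane fit (overhanging
#' canopy points in the band are not ground), and the canopy keeps the
#' points exceeding the plane by a clearance of 3 x the plane's fit RMSE,
#' so surface roughness does not leak ground points into the canopy (the
#' clearance is 0 for an exactly planar ground).
#'
#' @param block registered, denoised [PointCloud-class] containing ground
#'   and canopies
#' @param clusterRadius canopy-top clustering radius in meters
#' @param minCanopyPoints minimum top-cluster size; suppresses weed-scale
#'   clusters (default 50)
#' @param innerHalfLength,bandWidth ground-band geometry, see
#'   [extractGroundBand()]
#' @param groundTolerance band points higher than the band minimum z by
#'   more than this are excluded from the ground-plane fit (m)
#' @param minTopHeight a top cluster counts as a canopy only if it rises
#'   at least this far above the block plane (m); suppresses phantom
#'   "canopies" assembled from surface-roughness residuals on sparse or
#'   canopy-free blocks
#' @return list of [PlotSegment-class] objects (possibly empty, with a
#'   warning, when no canopy top is found)
#' @export
segmentPlots <- function(block, clusterRadius = 0.08,
                         minCanopyPoints = 50L,
                         innerHalfLength = 0.05, bandWidth = 0.1,
                         groundTolerance = 0.05, minTopHeight = 0.05) {
  .assertCloud(block, "block")
  if (nPoints(block) < 3L) {
    warning("block too small to segment")
    return(list())
  }
  blockPlane <- fitPlane(block)
  m <- coords(block)
  above <- m[, 3] > planeHeight(blockPlane, m[, 1], m[, 2])
  tops <- block[above]
  if (nPoints(tops) == 0L) {
    warning("no points above the block-level plane; nothing to segment")
    return(list())
  }
  lab <- euclideanCluster(tops, clusterRadius, minCanopyPoints)
  ids <- sort(unique(lab[lab >= 0L]))
  if (length(ids)) {
    tm <- coords(tops)
    rise <- tm[, 3] - planeHeight(blockPlane, tm[, 1], tm[, 2])
    ids <- ids[vapply(ids, function(l) max(rise[lab == l]), numeric(1)) >=
                 minTopHeight]
  }
  if (!length(ids)) {
    warning("no canopy-top cluster of at least ", minCanopyPoints,
            " points rising ", minTopHeight, " m above the block plane")
    return(list())
  }
  centers <- t(vapply(ids, function(l)
    colMeans(coords(tops)[lab == l, 1:2, drop = FALSE]), numeric(2)))
  # nearest-center assignment of every block point, in (x, y)
  nearest <- RANN::nn2(centers, m[, 1:2, drop = FALSE], k = 1L)$nn.idx[, 1]
  segs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ctr <- centers[i, ]
    band <- suppressWarnings(
      extractGroundBand(block, ctr, innerHalfLength, bandWidth))
    if (nPoints(band) > 0L) {
      bz <- coords(band)[, 3]
      band <- band[bz <= min(bz) + groundTolerance]
    }
    fallback <- FALSE
    plane <- if (nPoints(band) >= 3L &&
                 !inherits(try(fitPlane(band), silent = TRUE), "try-error"))
      .fitTrimmedPlane(band)
    else {
      warning(sprintf(
        "plot at (%.2f, %.2f): empty or degenerate ground band, falling back to the block plane",
        ctr[1], ctr[2]))
      fallback <- TRUE
      blockPlane
    }
    mine <- which(nearest == i)
    zi <- m[mine, 3]
    # the clearance tracks measured ground roughness; a block-plane
    # fallback has canopy-inflated residuals, so no clearance is added
    clearance <- if (fallback) 0 else 3 * plane@fitRmse
    keep <- mine[zi > planeHeight(plane, m[mine, 1], m[mine, 2]) +
                   clearance]
    canopy <- block[keep]
    if (nPoints(canopy) == 0L) {
      warning(sprintf("plot at (%.2f, %.2f): empty canopy, dropped",
                      ctr[1], ctr[2]))
      next
    }
    xy <- coords(canopy)
    ctr2 <- c(pmin(pmax(ctr[1], min(xy[, 1])), max(xy[, 1])),
              pmin(pmax(ctr[2], min(xy[, 2])), max(xy[, 2])))
    segs[[i]] <- new("PlotSegment", canopy = canopy,
                     center = as.numeric(ctr2), groundPlane = plane,
                     groundPoints = band, usedFallback = fallback)
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  ctrs <- t(vapply(segs, slot, numeric(2), "center"))
  segs[order(ctrs[, 1], ctrs[, 2])]
}
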
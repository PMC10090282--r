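#' @include AllGenerics.R
NULL

#' Construct a PointCloud
#'
#' @param coords numeric N x 3 matrix-like of x/y/z coordinates in meters
#'   (z up, opposite gravity). Rows containing non-finite values are
#'   dropped with a message (their colors too).
#' @param colors optional N x 3 matrix-like of RGB values. Values in
#'   0--255 integer convention are rescaled to `[0, 1]` automatically.
#' @return a [PointCloud-class]
#' @examples
#' pc <- pointCloud(cbind(runif(10), runif(10), runif(10)))
#' nPoints(pc)
#' @export
pointCloud <- function(coords, colors = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 3L)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (ncol(colors) != 3L) stop("colors must have 3 columns (r, g, b)")
    storage.mode(colors) <- "double"
    if (nrow(colors) != nrow(coords))
      stop("colors must have one row per point")
    if (length(colors) && max(colors, na.rm = TRUE) > 1 + 1e-9)
      colors <- colors / 255
    colors <- pmin(pmax(colors, 0), 1)
  }
  bad <- !is.finite(coords[, 1]) | !is.finite(coords[, 2]) |
         !is.finite(coords[, 3])
  if (any(bad)) {
    message(sum(bad), " non-finite point(s) dropped")
    coords <- coords[!bad, , drop = FALSE]
    if (!is.null(colors)) colors <- colors[!bad, , drop = FALSE]
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (!is.null(colors)) dimnames(colors) <- list(NULL, c("r", "g", "b"))
  new("PointCloud", coords = coords, colors = colors)
}

#' @describeIn pointCloud an empty cloud (N = 0), with or without a color
#'   channel
#' @param withColors logical; allocate an empty color matrix?
#' @export
emptyPointCloud <- function(withColors = FALSE) {
  pointCloud(matrix(numeric(0), ncol = 3L),
             colors = if (withColors) matrix(numeric(0), ncol = 3L))
}

#' @rdname nPoints
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

#' @rdname coords
setMethod("coords", "PointCloud", function(x) x@coords)

#' @rdname pointColors
setMethod("pointColors", "PointCloud", function(x) x@colors)

#' @rdname hasColors
setMethod("hasColors", "PointCloud", function(x) !is.null(x@colors))

#' Subset a PointCloud by point index
#' @param x a [PointCloud-class]
#' @param i numeric or logical index over points
#' @param j,...,drop ignored
#' @return a [PointCloud-class] with the selected points (colors kept in step)
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  new("PointCloud",
      coords = x@coords[i, , drop = FALSE],
      colors = if (is.null(x@colors)) NULL else x@colors[i, , drop = FALSE])
})

setMethod("show", "PointCloud", function(object) {
  n <- nPoints(object)
  cat(sprintf("PointCloud with %d point%s%s\n", n, if (n == 1) "" else "s",
              if (hasColors(object)) " (RGB)" else ""))
  if (n > 0) {
    bb <- apply(object@coords, 2, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f] m\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(NULL)
})

#' Concatenate point clouds
#'
#' Colors are kept only when every input carries them.
#'
#' @param ... [PointCloud-class] objects
#' @return a single [PointCloud-class]
#' @export
bindPointClouds <- function(...) {
  pcs <- list(...)
  if (length(pcs) == 1L && is.list(pcs[[1]]) && !is(pcs[[1]], "PointCloud"))
    pcs <- pcs[[1]]
  stopifnot(all(vapply(pcs, is, logical(1), "PointCloud")))
  coords <- do.call(rbind, lapply(pcs, coords))
  cols <- NULL
  if (length(pcs) && all(vapply(pcs, hasColors, logical(1))))
    cols <- do.call(rbind, lapply(pcs, pointColors))
  pointCloud(if (is.null(coords)) matrix(numeric(0), ncol = 3) else coords,
             cols)
}

# ---- rigid transforms -----------------------------------------------------

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1)
#' @param translation numeric length-3 translation in meters
#' @return a [RigidTransform-class]
#' @examples
#' t <- rigidTransform(rotationAboutZ(pi / 6), c(1, 2, 0.5))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.matrix(rotation),
      translation = as.numeric(translation))
}

#' @describeIn rigidTransform the identity motion
#' @export
identityTransform <- function() rigidTransform()

#' @describeIn rigidTransform rotation matrix about the z axis
#' @param angle rotation angle in radians (counter-clockwise seen from +z)
#' @export
rotationAboutZ <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' @describeIn rigidTransform rotation matrix about an arbitrary unit axis
#' @param axis numeric length-3 rotation axis (normalized internally)
#' @export
rotationAboutAxis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Compose rigid transforms
#'
#' `composeTransforms(t2, t1)` is the motion "apply `t1` first, then `t2`":
#' rotation `R2 R1`, translation `R2 t1 + t2`.
#'
#' @param t2,t1 [RigidTransform-class] objects
#' @return a [RigidTransform-class]
#' @export
composeTransforms <- function(t2, t1) {
  rigidTransform(t2@rotation %*% t1@rotation,
                 as.numeric(t2@rotation %*% t1@translation) + t2@translation)
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class]
#' @return the inverse motion
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

#' @rdname applyTransform
setMethod("applyTransform", signature("matrix", "RigidTransform"),
  function(x, transform) {
    if (nrow(x) == 0L) return(x)
    out <- x %*% t(transform@rotation)
    out[, 1] <- out[, 1] + transform@translation[1]
    out[, 2] <- out[, 2] + transform@translation[2]
    out[, 3] <- out[, 3] + transform@translation[3]
    dimnames(out) <- dimnames(x)
    out
  })

#' @rdname applyTransform
setMethod("applyTransform", signature("PointCloud", "RigidTransform"),
  function(x, transform) {
    new("PointCloud",
        coords = applyTransform(x@coords, transform),
        colors = x@colors)
  })

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf(
    "RigidTransform: rotation %.3f deg, translation (%.4f, %.4f, %.4f) m\n",
    ang * 180 / pi, object@translation[1], object@translation[2],
    object@translation[3]))
  invisible(NULL)
})

#' @rdname planeHeight
setMethod("planeHeight", "Plane", function(plane, x, y) {
  plane@a * x + plane@b * y + plane@c
})

setMethod("show", "Plane", function(object) {
  cat(sprintf("Plane: z = %.4f x + %.4f y + %.4f (fit rmse %.4g m)\n",
              object@a, object@b, object@c, object@fitRmse))
  invisible(NULL)
})

#' @rdname markerCenters
setMethod("markerCenters", "MarkerSet", function(x) x@centers)

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet: %d %s marker%s\n", nrow(object@centers),
              object@colorClass,
              if (nrow(object@centers) == 1) "" else "s"))
  invisible(NULL)
})

setMethod("show", "PlotSegment", function(object) {
  cat(sprintf(
    "PlotSegment at (%.3f, %.3f): %d canopy points%s\n",
    object@center[1], object@center[2], nPoints(object@canopy),
    if (object@usedFallback) " [block-plane fallback]" else ""))
  invisible(NULL)
})

# ---- internal helpers -----------------------------------------------------

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.assertCloud <- function(pc, what = "pc") {
  if (!is(pc, "PointCloud"))
    stop(sprintf("'%s' must be a PointCloud", what))
  invisible(pc)
}
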
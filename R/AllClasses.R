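#' @include canopyprint-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' PointCloud: 3D points in meters, z up
#'
#' The universal currency of the pipeline: an N x 3 coordinate matrix in
#' meters (x, y horizontal; z vertical, opposite gravity) with optional
#' per-point RGB colors normalized to `[0, 1]`. Coordinates must be finite;
#' N = 0 is a valid, empty cloud.
#'
#' @slot coords numeric matrix, N x 3, columns x/y/z in meters.
#' @slot colors numeric matrix N x 3 with values in `[0, 1]`, or NULL.
#' @seealso [pointCloud()], [readPointCloud()], [applyTransform()]
#' @export
setClass("PointCloud",
  representation(coords = "matrix", colors = "matrixOrNULL"),
  prototype(coords = matrix(numeric(0), ncol = 3L), colors = NULL)
)

setValidity("PointCloud", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have 3 columns (x, y, z)")
  else if (length(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "coords must be finite (no NA/NaN/Inf)")
  if (!is.null(object@colors)) {
    if (ncol(object@colors) != 3L)
      msg <- c(msg, "colors must have 3 columns (r, g, b)")
    else if (nrow(object@colors) != nrow(object@coords))
      msg <- c(msg, "colors must have one row per point")
    else if (length(object@colors) &&
             (!all(is.finite(object@colors)) ||
              min(object@colors) < 0 || max(object@colors) > 1))
      msg <- c(msg, "colors must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' RigidTransform: rotation plus translation
#'
#' A proper rigid-body motion: `p -> R p + t` with `R` a 3 x 3 rotation
#' matrix (orthonormal, determinant +1) and `t` a translation in meters.
#'
#' @slot rotation 3 x 3 rotation matrix.
#' @slot translation numeric length-3 translation (m).
#' @seealso [rigidTransform()], [composeTransforms()], [invertTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0))
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  if (!all(is.finite(R)) || !all(is.finite(object@translation)))
    return("transform entries must be finite")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation is not orthonormal within 1e-9")
  if (det(R) < 0) return("rotation must be proper (det +1), not a reflection")
  TRUE
})

#' TriMesh: watertight triangular surface mesh
#'
#' A closed, consistently outward-oriented triangle mesh. Validity requires
#' watertightness: every directed edge is matched by exactly one reverse
#' directed edge, so each undirected edge borders exactly two faces.
#'
#' @slot vertices numeric matrix V x 3 (m).
#' @slot faces integer matrix F x 3 of 1-based vertex indices, CCW from
#'   outside.
#' @seealso [canopyMesh()], [meshTraits()]
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix")
)

setValidity("TriMesh", function(object) {
  V <- object@vertices
  F <- object@faces
  if (ncol(V) != 3L) return("vertices must be V x 3")
  if (ncol(F) != 3L) return("faces must be F x 3")
  if (nrow(F) < 4L) return("a closed mesh needs at least 4 faces")
  idx <- as.integer(F)
  if (any(idx < 1L) || any(idx > nrow(V)))
    return("face indices out of vertex range")
  # watertight: each directed edge appears once, reverse appears once
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  rev <- paste(e[, 2], e[, 1])
  if (anyDuplicated(fwd))
    return("mesh is not a manifold: duplicated directed edge")
  if (!all(fwd %in% rev))
    return("mesh is not watertight: unmatched boundary edge")
  TRUE
})

#' Plane: z = a x + b y + c
#'
#' A non-vertical plane used for ground modeling, stored as the coefficients
#' of `z = a*x + b*y + c` together with the RMS residual of the fit.
#'
#' @slot a,b,c numeric plane coefficients.
#' @slot fitRmse numeric RMS of fit residuals (m); 0 for exact planes.
#' @seealso [fitPlane()], [planeHeight()]
#' @export
setClass("Plane",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 fitRmse = "numeric"),
  prototype(a = 0, b = 0, c = 0, fitRmse = 0)
)

setValidity("Plane", function(object) {
  v <- c(object@a, object@b, object@c, object@fitRmse)
  if (length(v) != 4L || !all(is.finite(v)))
    return("plane coefficients must be finite scalars")
  TRUE
})

#' MarkerSet: detected reference-marker centers
#'
#' Cluster centroids of color-classified reference targets (painted
#' Styrofoam spheres on dowels, or white corner markers), sorted by x then y.
#'
#' @slot centers numeric matrix M x 3 of marker centers (m).
#' @slot colorClass character, one of "white", "yellow", "red".
#' @slot clusterSizes integer vector of supporting point counts.
#' @seealso [detectColorMarkers()], [cropBlock()]
#' @export
setClass("MarkerSet",
  representation(centers = "matrix", colorClass = "character",
                 clusterSizes = "integer")
)

setValidity("MarkerSet", function(object) {
  if (ncol(object@centers) != 3L) return("centers must be M x 3")
  if (nrow(object@centers) != length(object@clusterSizes))
    return("one cluster size per center required")
  if (length(object@colorClass) != 1L ||
      !object@colorClass %in% c("white", "yellow", "red"))
    return("colorClass must be one of white/yellow/red")
  TRUE
})

#' PlotSegment: one plot's canopy and ground model
#'
#' The product of plot segmentation: the canopy cloud of one hill plot, its
#' approximate center (mean x/y of the detected canopy top), the per-plot
#' ground plane, and the ground-band points the plane was fitted to. When
#' the ground band around a plot is empty the block-level plane is used and
#' `usedFallback` is set.
#'
#' @slot canopy PointCloud of canopy points (strictly above the ground plane).
#' @slot center numeric length-2 (x, y) plot center (m).
#' @slot groundPlane Plane fitted to the plot's ground band.
#' @slot groundPoints PointCloud of the band points used for the fit.
#' @slot usedFallback logical; TRUE when the block plane replaced an empty band.
#' @seealso [segmentPlots()]
#' @export
setClass("PlotSegment",
  representation(canopy = "PointCloud", center = "numeric",
                 groundPlane = "Plane", groundPoints = "PointCloud",
                 usedFallback = "logical")
)

setValidity("PlotSegment", function(object) {
  if (length(object@center) != 2L) return("center must be (x, y)")
  if (nPoints(object@canopy) > 0) {
    xy <- coords(object@canopy)
    z0 <- planeHeight(object@groundPlane, xy[, 1], xy[, 2])
    if (any(xy[, 3] <= z0))
      return("canopy points must lie strictly above the ground plane")
    if (object@center[1] < min(xy[, 1]) - 1e-9 ||
        object@center[1] > max(xy[, 1]) + 1e-9 ||
        object@center[2] < min(xy[, 2]) - 1e-9 ||
        object@center[2] > max(xy[, 2]) + 1e-9)
      return("center must lie within the canopy's (x, y) bounding box")
  }
  TRUE
})

.FINGERPRINT_FEATURES <- c("slice_height", "point_count", "volume",
                           "surface_area", "area2d", "aspect_ratio",
                           "roundness", "circularity", "convex_area",
                           "solidity")

#' FingerprintConfig: slicing and feature layout
#'
#' Defines how fingerprints are built: the number of slices (2n + 1, always
#' odd, center index n), the ordered feature set computed per slice, and the
#' 2D outline mode used for projected features.
#'
#' @slot n integer >= 0; the canopy is cut into 2n + 1 equal-height slices.
#' @slot featureSet ordered character vector drawn from
#'   `slice_height, point_count, volume, surface_area, area2d, aspect_ratio,
#'   roundness, circularity, convex_area, solidity`.
#' @slot outlineMode "convex" or "alpha".
#' @slot outlineAlpha numeric alpha radius in meters (alpha mode only).
#' @seealso [fingerprintConfig()], [computeFingerprint()]
#' @export
setClass("FingerprintConfig",
  representation(n = "integer", featureSet = "character",
                 outlineMode = "character", outlineAlpha = "numeric")
)

setValidity("FingerprintConfig", function(object) {
  if (length(object@n) != 1L || is.na(object@n) || object@n < 0L)
    return("n must be a single non-negative integer")
  if (!length(object@featureSet))
    return("featureSet must not be empty")
  bad <- setdiff(object@featureSet, .FINGERPRINT_FEATURES)
  if (length(bad))
    return(paste0("unknown features: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(object@featureSet))
    return("featureSet entries must be unique")
  if (!object@outlineMode %in% c("convex", "alpha"))
    return("outlineMode must be 'convex' or 'alpha'")
  TRUE
})

#' Fingerprint: a canopy's multi-scale shape vector
#'
#' The ordered vector of sub-canopy features for 2n + 1 slices, laid out
#' slice-major bottom to top, each slice's features divided elementwise by
#' the center slice's. The center block is identically 1 by construction.
#' Feature columns whose center value is 0 while another slice is nonzero
#' are kept raw (unnormalized) and listed in `rawFeatures`.
#'
#' @slot values numeric vector of length (2n + 1) * |featureSet|.
#' @slot config FingerprintConfig.
#' @slot canopyId character identifier.
#' @slot rawFeatures character; features left unnormalized (degenerate center).
#' @seealso [computeFingerprint()], [queryNearest()]
#' @export
setClass("Fingerprint",
  representation(values = "numeric", config = "FingerprintConfig",
                 canopyId = "character", rawFeatures = "character")
)

setValidity("Fingerprint", function(object) {
  nExp <- (2L * object@config@n + 1L) * length(object@config@featureSet)
  if (length(object@values) != nExp)
    return(sprintf("values must have length (2n+1)*|features| = %d", nExp))
  if (!all(is.finite(object@values)))
    return("fingerprint values must be finite")
  if (length(object@canopyId) != 1L)
    return("canopyId must be a single string")
  TRUE
})

#' FingerprintDB: a searchable collection of fingerprints
#'
#' Fingerprints stored row-wise under a single shared configuration so
#' Euclidean distances are dimension-compatible.
#'
#' @slot values numeric matrix, one row per canopy, rownames = canopy ids.
#' @slot config shared FingerprintConfig.
#' @seealso [fingerprintDB()], [queryNearest()], [clusterFingerprints()]
#' @export
setClass("FingerprintDB",
  representation(values = "matrix", config = "FingerprintConfig")
)

setValidity("FingerprintDB", function(object) {
  nExp <- (2L * object@config@n + 1L) * length(object@config@featureSet)
  if (nrow(object@values) > 0 && ncol(object@values) != nExp)
    return("fingerprint matrix width does not match the config")
  if (nrow(object@values) > 0 && is.null(rownames(object@values)))
    return("fingerprint rows must be named by canopy id")
  if (anyDuplicated(rownames(object@values)))
    return("canopy ids must be unique")
  TRUE
})
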
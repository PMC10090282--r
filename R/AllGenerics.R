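#' @include AllClasses.R
NULL

#' Number of points in a cloud
#' @param x a [PointCloud-class]
#' @return integer point count
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Coordinate matrix of a cloud
#' @param x a [PointCloud-class]
#' @return N x 3 numeric matrix (m)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Per-point colors of a cloud
#' @param x a [PointCloud-class]
#' @return N x 3 matrix in `[0, 1]`, or NULL when absent
#' @export
setGeneric("pointColors", function(x) standardGeneric("pointColors"))

#' Does a cloud carry colors?
#' @param x a [PointCloud-class]
#' @return logical
#' @export
setGeneric("hasColors", function(x) standardGeneric("hasColors"))

#' Apply a rigid transform
#'
#' Maps every point `p` to `R p + t`; colors are untouched. Works on
#' [PointCloud-class] objects and bare N x 3 matrices.
#'
#' @param x a [PointCloud-class] or N x 3 matrix
#' @param transform a [RigidTransform-class]
#' @return object of the same kind as `x`
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))

#' Evaluate a ground plane at (x, y)
#' @param plane a [Plane-class]
#' @param x,y numeric vectors of horizontal coordinates (m)
#' @return numeric vector of plane heights z = a x + b y + c
#' @export
setGeneric("planeHeight", function(plane, x, y) standardGeneric("planeHeight"))

#' Marker centers of a MarkerSet
#' @param x a [MarkerSet-class]
#' @return M x 3 matrix of centers
#' @export
setGeneric("markerCenters", function(x) standardGeneric("markerCenters"))

#' Canopy ids stored in a fingerprint database
#' @param x a [FingerprintDB-class]
#' @return character vector
#' @export
setGeneric("canopyIds", function(x) standardGeneric("canopyIds"))

#' Fingerprint value matrix of a database
#' @param x a [FingerprintDB-class]
#' @return numeric matrix, one row per canopy
#' @export
setGeneric("fingerprintValues",
           function(x) standardGeneric("fingerprintValues"))

#' Shared fingerprint configuration
#' @param x a [FingerprintDB-class] or [Fingerprint-class]
#' @return a [FingerprintConfig-class]
#' @export
setGeneric("fingerprintConfigOf",
           function(x) standardGeneric("fingerprintConfigOf"))
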
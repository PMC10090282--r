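#' @include outline.R
NULL

#' Construct a FingerprintConfig
#'
#' @param n non-negative integer; the canopy is sliced into 2n + 1
#'   equal-height sections. `n = 1` gives 3 sub-canopies, `n = 4` gives 9.
#' @param featureSet ordered character vector of per-slice features; the
#'   default follows the labeled sub-canopy features (projected 2D area,
#'   aspect ratio, circularity, roundness, convex area, solidity, and 3D
#'   volume)
#' @param outlineMode "convex" (default) or "alpha"
#' @param outlineAlpha alpha radius in meters for concave outlines
#' @return a [FingerprintConfig-class]
#' @export
fingerprintConfig <- function(n = 4L,
                              featureSet = c("area2d", "aspect_ratio",
                                             "circularity", "roundness",
                                             "convex_area", "solidity",
                                             "volume"),
                              outlineMode = c("convex", "alpha"),
                              outlineAlpha = 0.05) {
  outlineMode <- match.arg(outlineMode)
  new("FingerprintConfig", n = as.integer(n), featureSet = featureSet,
      outlineMode = outlineMode, outlineAlpha = as.numeric(outlineAlpha))
}

#' Number of slices of a config
#' @param config a [FingerprintConfig-class]
#' @return integer, 2n + 1
#' @export
sliceCount <- function(config) 2L * config@n + 1L

setMethod("show", "FingerprintConfig", function(object) {
  cat(sprintf("FingerprintConfig: n = %d (%d slices), %d features (%s), %s outline\n",
              object@n, sliceCount(object), length(object@featureSet),
              paste(object@featureSet, collapse = ", "),
              object@outlineMode))
  invisible(NULL)
})

.configCompatible <- function(a, b) {
  a@n == b@n && identical(a@featureSet, b@featureSet) &&
    a@outlineMode == b@outlineMode
}

#' Slice a canopy into 2n + 1 equal-height sub-canopies
#'
#' The z range `[min z, max z]` is partitioned into 2n + 1 equal-height
#' intervals, half-open `[low, high)` except the top one, which is closed,
#' so every point lands in exactly one slice. Empty slices are allowed
#' (and yield degenerate, all-zero signatures downstream).
#'
#' @param canopy a non-empty [PointCloud-class]
#' @param n non-negative integer
#' @return list of 2n + 1 [PointCloud-class] objects, bottom to top
#' @examples
#' length(sliceCanopy(pointCloud(cbind(0, 0, runif(100))), n = 4))
#' @export
sliceCanopy <- function(canopy, n) {
  .assertCloud(canopy, "canopy")
  if (nPoints(canopy) == 0L) stop("cannot slice an empty canopy")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  k <- 2L * n + 1L
  z <- coords(canopy)[, 3]
  z0 <- min(z); z1 <- max(z)
  if (z1 == z0) {
    idx <- rep(n + 1L, length(z))  # zero-extent canopy: all in center slice
  } else {
    h <- (z1 - z0) / k
    idx <- pmin(floor((z - z0) / h) + 1L, k)
  }
  lapply(seq_len(k), function(s) canopy[idx == s])
}

.signatureFeature <- function(slice, feature, config) {
  n <- nPoints(slice)
  need3d <- feature %in% c("volume", "surface_area")
  need2d <- feature %in% c("area2d", "aspect_ratio", "roundness",
                           "circularity", "convex_area", "solidity")
  if (feature == "point_count") return(as.numeric(n))
  if (n == 0L) return(0)
  if (feature == "slice_height")
    return(diff(range(coords(slice)[, 3])))
  if (need3d) {
    mt <- tryCatch(meshTraits(canopyMesh(slice, "convex_hull")),
                   error = function(e) NULL)
    if (is.null(mt)) return(0)
    return(if (feature == "volume") mt$volume else mt$surfaceArea)
  }
  if (need2d) {
    ot <- tryCatch(
      outlineTraits(projectOutline(slice, "xy", config@outlineMode,
                                   config@outlineAlpha)),
      error = function(e) NULL)
    if (is.null(ot)) return(0)
    return(switch(feature,
                  area2d = ot$area, aspect_ratio = ot$aspectRatio,
                  roundness = ot$roundness, circularity = ot$circularity,
                  convex_area = ot$convexArea, solidity = ot$solidity))
  }
  stop("unknown feature '", feature, "'")
}

#' Signature of one sub-canopy slice
#'
#' Computes the configured features on a single slice: 3D features via the
#' slice's convex hull, 2D features via its projected xy outline. Slices
#' with too few points for a feature (< 4 non-coplanar for 3D, < 3
#' non-collinear for 2D) yield 0 for that feature; the `degenerate`
#' attribute flags which entries were zeroed.
#'
#' @param slice a [PointCloud-class] (possibly empty)
#' @param config a [FingerprintConfig-class]
#' @return named numeric vector in `config@featureSet` order, with a
#'   logical `degenerate` attribute
#' @export
subCanopySignature <- function(slice, config) {
  .assertCloud(slice, "slice")
  stopifnot(is(config, "FingerprintConfig"))
  v <- vapply(config@featureSet, .signatureFeature, numeric(1),
              slice = slice, config = config)
  names(v) <- config@featureSet
  deg <- v == 0 & config@featureSet != "point_count"
  deg[config@featureSet == "point_count"] <- nPoints(slice) == 0L
  attr(v, "degenerate") <- deg
  v
}

#' Compute a canopy fingerprint
#'
#' Slices the canopy into 2n + 1 equal-height sub-canopies, computes each
#' slice's signature, divides every signature elementwise by the center
#' slice's, and flattens the result slice-major (bottom slice first). The
#' center block is identically 1. A feature whose center-slice value is 0
#' while another slice is nonzero cannot be normalized; that feature column
#' is kept raw and recorded in the fingerprint's `rawFeatures` (silent
#' division is never performed). If every center-slice feature is 0 the
#' canopy cannot be fingerprinted at this `n`.
#'
#' @param canopy a non-empty [PointCloud-class]
#' @param config a [FingerprintConfig-class]
#' @param canopyId identifier stored in the fingerprint
#' @return a [Fingerprint-class]
#' @export
computeFingerprint <- function(canopy, config = fingerprintConfig(),
                               canopyId = "canopy") {
  .assertCloud(canopy, "canopy")
  stopifnot(is(config, "FingerprintConfig"))
  slices <- sliceCanopy(canopy, config@n)
  nf <- length(config@featureSet)
  sig <- vapply(slices, function(s)
    as.numeric(subCanopySignature(s, config)), numeric(nf))
  sig <- if (nf == 1L) matrix(sig, ncol = 1L) else t(sig)
  colnames(sig) <- config@featureSet
  center <- sig[config@n + 1L, ]
  if (all(center == 0))
    stop("the center slice is fully degenerate (all features 0); ",
         "use a smaller n")
  rawFeatures <- character(0)
  norm <- sig
  for (j in seq_along(center)) {
    if (center[j] != 0) norm[, j] <- sig[, j] / center[j]
    else if (any(sig[, j] != 0))
      rawFeatures <- c(rawFeatures, config@featureSet[j])
    # center 0 and all 0: column stays 0
  }
  new("Fingerprint", values = as.numeric(t(norm)), config = config,
      canopyId = as.character(canopyId), rawFeatures = rawFeatures)
}

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint '%s': %d slices x %d features = %d values\n",
              object@canopyId, sliceCount(object@config),
              length(object@config@featureSet), length(object@values)))
  if (length(object@rawFeatures))
    cat("  unnormalized (degenerate center) features:",
        paste(object@rawFeatures, collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname fingerprintConfigOf
setMethod("fingerprintConfigOf", "Fingerprint", function(x) x@config)

#' Fingerprint values as a slice x feature matrix
#' @param fp a [Fingerprint-class]
#' @return numeric matrix, rows = slices bottom to top
#' @export
fingerprintMatrix <- function(fp) {
  stopifnot(is(fp, "Fingerprint"))
  matrix(fp@values, nrow = sliceCount(fp@config), byrow = TRUE,
         dimnames = list(NULL, fp@config@featureSet))
}

# ---- database -------------------------------------------------------------

#' Build a fingerprint database
#'
#' @param fingerprints list of [Fingerprint-class] objects sharing one
#'   configuration; their `canopyId`s become the database keys
#' @return a [FingerprintDB-class]
#' @export
fingerprintDB <- function(fingerprints) {
  stopifnot(length(fingerprints) > 0,
            all(vapply(fingerprints, is, logical(1), "Fingerprint")))
  cfg <- fingerprints[[1]]@config
  for (fp in fingerprints)
    if (!.configCompatible(cfg, fp@config))
      stop("all fingerprints in a database must share one configuration")
  vals <- do.call(rbind, lapply(fingerprints, slot, "values"))
  rownames(vals) <- vapply(fingerprints, slot, character(1), "canopyId")
  new("FingerprintDB", values = vals, config = cfg)
}

#' @rdname canopyIds
setMethod("canopyIds", "FingerprintDB", function(x) rownames(x@values))

#' @rdname fingerprintValues
setMethod("fingerprintValues", "FingerprintDB", function(x) x@values)

#' @rdname fingerprintConfigOf
setMethod("fingerprintConfigOf", "FingerprintDB", function(x) x@config)

setMethod("show", "FingerprintDB", function(object) {
  cat(sprintf("FingerprintDB: %d canopies, %d values each (n = %d, %s outline)\n",
              nrow(object@values), ncol(object@values), object@config@n,
              object@config@outlineMode))
  invisible(NULL)
})

setMethod("length", "FingerprintDB", function(x) nrow(x@values))

#' Write / read a fingerprint database
#'
#' The CSV holds one row per canopy (`canopy_id`, then the values in the
#' declared slice-major layout); a JSON sidecar (`<path>.json`) records the
#' configuration (n, feature order, outline mode and alpha) so stored
#' fingerprints are never compared across incompatible configs.
#'
#' @param db a [FingerprintDB-class]
#' @param path CSV destination
#' @return `writeFingerprintDB`: invisibly, `path`;
#'   `readFingerprintDB`: a [FingerprintDB-class]
#' @export
writeFingerprintDB <- function(db, path) {
  stopifnot(is(db, "FingerprintDB"))
  d <- data.frame(canopy_id = canopyIds(db), db@values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  colnames(d) <- c("canopy_id", sprintf("v%03d", seq_len(ncol(db@values))))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  cfg <- db@config
  jsonlite::write_json(
    list(n = cfg@n, feature_set = cfg@featureSet,
         outline_mode = cfg@outlineMode, outline_alpha = cfg@outlineAlpha),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFingerprintDB
#' @export
readFingerprintDB <- function(path) {
  if (!file.exists(path)) stop("no such fingerprint database: '", path, "'")
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing config sidecar '", side, "'")
  cfgj <- jsonlite::read_json(side, simplifyVector = TRUE)
  cfg <- fingerprintConfig(n = cfgj$n, featureSet = cfgj$feature_set,
                           outlineMode = cfgj$outline_mode,
                           outlineAlpha = cfgj$outline_alpha)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  rownames(vals) <- as.character(d$canopy_id)
  colnames(vals) <- NULL
  new("FingerprintDB", values = vals, config = cfg)
}

# ---- query / ideotype / clustering ---------------------------------------

#' Query the database for the nearest fingerprints
#'
#' Ranks database entries by Euclidean distance between full fingerprint
#' vectors, optionally weighted per entry. Ties are broken by canopy id
#' (lexicographic).
#'
#' @param db a [FingerprintDB-class]
#' @param query a [Fingerprint-class] with a compatible configuration
#' @param k number of matches to return (capped at the database size)
#' @param weights optional non-negative weight per vector entry (default
#'   all ones)
#' @return data.frame with columns `canopy_id` and `distance`, ascending
#' @export
queryNearest <- function(db, query, k = 5L, weights = NULL) {
  stopifnot(is(db, "FingerprintDB"), is(query, "Fingerprint"))
  if (!.configCompatible(db@config, query@config))
    stop(sprintf(
      "config mismatch: database has n = %d, features (%s), %s outline; query has n = %d, features (%s), %s outline",
      db@config@n, paste(db@config@featureSet, collapse = ", "),
      db@config@outlineMode,
      query@config@n, paste(query@config@featureSet, collapse = ", "),
      query@config@outlineMode))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  w <- if (is.null(weights)) rep(1, ncol(db@values)) else as.numeric(weights)
  if (length(w) != ncol(db@values)) stop("weights length mismatch")
  diff <- sweep(db@values, 2, query@values)
  d <- sqrt(as.numeric(diff^2 %*% w))
  o <- order(d, canopyIds(db))
  o <- o[seq_len(min(k, length(o)))]
  data.frame(canopy_id = canopyIds(db)[o], distance = d[o],
             stringsAsFactors = FALSE)
}

# analytic per-slice profiles for a cone of base radius r and height h cut
# into k equal slices, apex up; slice i = 1..k, bottom to top
.coneSliceProfile <- function(feature, k, r = 0.3, h = 1.0) {
  # radius shrinks linearly: lower radius R_i, upper radius R_{i+1}
  Rlo <- r * (1 - (seq_len(k) - 1) / k)
  Rhi <- r * (1 - seq_len(k) / k)
  hs <- h / k
  switch(feature,
    slice_height = rep(1, k),
    aspect_ratio = , roundness = , circularity = , solidity = rep(1, k),
    area2d = , convex_area = Rlo^2,
    point_count = , volume = Rlo^2 + Rlo * Rhi + Rhi^2,
    surface_area = {
      slant <- sqrt((Rlo - Rhi)^2 + hs^2)
      pi * (Rlo^2 + Rhi^2) + pi * (Rlo + Rhi) * slant
    },
    stop("unknown feature '", feature, "'"))
}

#' Fingerprint of an idealized canopy shape
#'
#' Builds the fingerprint a perfectly shaped canopy would have, for use as
#' a query against a database: `cylindrical` canopies have identical slices
#' (all-ones fingerprint); `conical` (apex up) profiles follow the closed
#' forms of a cone's equal-height frusta — projected areas scale with the
#' squared slice base radius, volumes with the frustum formula — computed
#' for a canonical 0.3 m base radius, 1 m tall cone where a shape ratio is
#' needed; `inverted_conical` reverses the slice order. An explicit
#' slice x feature profile matrix is accepted and center-normalized as-is.
#'
#' @param shape "cylindrical", "conical", "inverted_conical", or a numeric
#'   (2n + 1) x |featureSet| matrix of raw per-slice feature values
#' @param config a [FingerprintConfig-class]
#' @return a [Fingerprint-class] with `canopyId` set to the shape name
#' @export
ideotypeFingerprint <- function(shape, config = fingerprintConfig()) {
  stopifnot(is(config, "FingerprintConfig"))
  k <- sliceCount(config)
  nf <- length(config@featureSet)
  if (is.character(shape)) {
    valid <- c("cylindrical", "conical", "inverted_conical")
    if (!shape %in% valid)
      stop("unknown ideotype shape '", shape, "'; valid names: ",
           paste(valid, collapse = ", "))
    prof <- switch(shape,
      cylindrical = matrix(1, k, nf),
      conical = vapply(config@featureSet, .coneSliceProfile, numeric(k),
                       k = k),
      inverted_conical = {
        p <- vapply(config@featureSet, .coneSliceProfile, numeric(k), k = k)
        p[rev(seq_len(k)), , drop = FALSE]
      })
    id <- shape
  } else {
    prof <- as.matrix(shape)
    if (!all(dim(prof) == c(k, nf)))
      stop("explicit profile must be (2n+1) x |featureSet| = ",
           k, " x ", nf)
    id <- "custom"
  }
  center <- prof[config@n + 1L, ]
  if (any(center == 0)) stop("ideotype center slice has a zero feature")
  norm <- sweep(prof, 2, center, "/")
  new("Fingerprint", values = as.numeric(t(norm)), config = config,
      canopyId = id, rawFeatures = character(0))
}

#' Cluster a fingerprint database and embed it for display
#'
#' Seeded k-means on the raw fingerprint vectors, plus a PCA of the same
#' vectors whose first two principal-component scores serve as a 2D
#' embedding for visualization (the clustering itself runs on the full
#' vectors, not the PCA scores). Deterministic for a fixed seed.
#'
#' @param db a [FingerprintDB-class]
#' @param kClusters number of clusters, 1 <= k <= |db|
#' @param seed integer RNG seed for the k-means initialization
#' @return list with `labels` (named integer vector, 1..k), `embedding`
#'   (|db| x 2 matrix of PC scores), `explainedVariance` (proportions for
#'   PC1 and PC2)
#' @export
clusterFingerprints <- function(db, kClusters, seed = 1L) {
  stopifnot(is(db, "FingerprintDB"))
  kClusters <- as.integer(kClusters)
  n <- length(db)
  if (is.na(kClusters) || kClusters < 1L || kClusters > n)
    stop("kClusters must be between 1 and the database size (", n, ")")
  X <- db@values
  km <- withSeed(seed,
    stats::kmeans(X, centers = kClusters, nstart = 10L, iter.max = 100L))
  labels <- km$cluster
  names(labels) <- canopyIds(db)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(2L, ncol(pc$x))
  emb <- matrix(0, n, 2L, dimnames = list(canopyIds(db), c("PC1", "PC2")))
  emb[, seq_len(nc)] <- pc$x[, seq_len(nc)]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ev2 <- c(ev, 0, 0)[1:2]
  list(labels = labels, embedding = emb, explainedVariance = ev2)
}
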
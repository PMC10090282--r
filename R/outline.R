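#' @include traits.R
NULL

#' Project a canopy and extract its 2D outline
#'
#' Flattens the cloud onto the requested coordinate plane and returns the
#' closed outline of the projected points as an ordered polygon
#' (counter-clockwise, first vertex not repeated). `convex` mode uses the
#' convex hull, so every projected point is inside or on the outline.
#' `alpha` mode builds a concave outline from the Delaunay triangulation:
#' triangles with circumradius larger than `alpha` are discarded and the
#' boundary of the largest remaining region is traced; if the boundary
#' does not close into a single simple loop the convex hull is returned
#' with a warning.
#'
#' @param canopy a [PointCloud-class] with at least 3 points whose
#'   projections are not collinear
#' @param plane "xy" (default, the top view), "xz" or "yz"
#' @param mode "convex" or "alpha"
#' @param alpha alpha radius in meters for concave outlines
#' @return numeric V x 2 matrix of polygon vertices, CCW
#' @seealso [outlineTraits()]
#' @export
projectOutline <- function(canopy, plane = c("xy", "xz", "yz"),
                           mode = c("convex", "alpha"), alpha = 0.05) {
  .assertCloud(canopy, "canopy")
  plane <- match.arg(plane)
  mode <- match.arg(mode)
  m <- coords(canopy)
  if (nrow(m) < 3L) stop("outline extraction needs at least 3 points")
  p <- switch(plane, xy = m[, 1:2], xz = m[, c(1, 3)], yz = m[, 2:3])
  p <- unique(p)
  if (nrow(p) < 3L || .pointRank(cbind(p, 0)) < 2L)
    stop("projected points are collinear; no outline exists")
  if (mode == "convex") return(.convexOutline(p))
  out <- tryCatch(.alphaOutline(p, alpha), error = function(e) NULL)
  if (is.null(out)) {
    warning("alpha outline did not close into a single loop; ",
            "falling back to the convex hull")
    out <- .convexOutline(p)
  }
  out
}

.convexOutline <- function(p) {
  h <- grDevices::chull(p)   # clockwise
  poly <- p[rev(h), , drop = FALSE]
  dimnames(poly) <- list(NULL, c("u", "v"))
  poly
}

.circumradius <- function(a, b, c_) {
  la <- sqrt(sum((b - c_)^2)); lb <- sqrt(sum((a - c_)^2))
  lc <- sqrt(sum((a - b)^2))
  area2 <- abs((b[1] - a[1]) * (c_[2] - a[2]) -
               (c_[1] - a[1]) * (b[2] - a[2]))
  if (area2 < 1e-15) return(Inf)
  la * lb * lc / (2 * area2)
}

# 2D alpha shape outline via Delaunay triangle filtering
.alphaOutline <- function(p, alpha) {
  dxy <- suppressMessages(deldir::deldir(p[, 1], p[, 2]))
  tl <- deldir::triang.list(dxy)
  keep <- vapply(tl, function(tr) {
    a <- c(tr$x[1], tr$y[1]); b <- c(tr$x[2], tr$y[2])
    c_ <- c(tr$x[3], tr$y[3])
    .circumradius(a, b, c_) <= alpha
  }, logical(1))
  tl <- tl[keep]
  if (!length(tl)) stop("alpha too small: no triangle kept")
  tri <- t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
  # connected triangle components via shared edges; keep the largest
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edges <- rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
                 cbind(tri[, 3], tri[, 1]))
  triOf <- rep(seq_len(nrow(tri)), 3L)
  byEdge <- split(triOf, ekey(edges[, 1], edges[, 2]))
  parent <- seq_len(nrow(tri))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ts in byEdge) if (length(ts) == 2L) {
    a <- find(ts[1]); b <- find(ts[2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nrow(tri)), find, integer(1))
  main <- as.integer(names(which.max(table(root))))
  tri <- tri[root == main, , drop = FALSE]
  # boundary edges: used by exactly one kept triangle
  edges <- rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
                 cbind(tri[, 3], tri[, 1]))
  keys <- ekey(edges[, 1], edges[, 2])
  bnd <- edges[keys %in% names(which(table(keys) == 1L)), , drop = FALSE]
  if (nrow(bnd) < 3L) stop("degenerate alpha boundary")
  # chain the boundary into one loop
  nxt <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  if (any(lengths(nxt) != 2L)) stop("boundary is not a simple loop")
  start <- bnd[1, 1]
  loop <- c(start, bnd[1, 2])
  while (TRUE) {
    cands <- nxt[[as.character(loop[length(loop)])]]
    nxtV <- cands[cands != loop[length(loop) - 1L]][1]
    if (nxtV == start) break
    loop <- c(loop, nxtV)
    if (length(loop) > nrow(bnd) + 1L) stop("boundary tracing failed")
  }
  if (length(loop) != nrow(bnd)) stop("boundary has multiple loops")
  poly <- p[loop, , drop = FALSE]
  if (.shoelace(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ,
                                        drop = FALSE]
  dimnames(poly) <- list(NULL, c("u", "v"))
  poly
}

# signed polygon area, positive for CCW
.shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' 2D shape descriptors of a closed outline
#'
#' Given a simple closed polygon (CCW or CW, first vertex not repeated),
#' computes: area (shoelace), perimeter, the best-fit ellipse from the
#' second-order central moments of the polygon *region* (so vertex density
#' does not bias the axes; `majorAxis`/`minorAxis` are FULL axis lengths),
#' and the dimensionless descriptors
#' \deqn{aspect = major / minor}
#' \deqn{roundness = 4 A / (\pi \cdot major^2)}
#' \deqn{circularity = 4 \pi A / P^2}
#' \deqn{solidity = A / A_{convex}}
#' For a circle all three dimensionless descriptors equal 1; circularity
#' may exceed 1 by a discretization epsilon for near-regular polygons.
#'
#' @param polygon numeric V x 2 matrix of vertices, or the result of
#'   [projectOutline()]
#' @return list with `area`, `perimeter`, `majorAxis`, `minorAxis`,
#'   `aspectRatio`, `roundness`, `circularity`, `convexArea`, `solidity`
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 1001)[-1001]
#' circ <- cbind(cos(theta), sin(theta))
#' outlineTraits(circ)$circularity
#' @export
outlineTraits <- function(polygon) {
  poly <- as.matrix(polygon)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("polygon must be a V x 2 matrix with V >= 3")
  A <- .shoelace(poly)
  if (A < 0) { poly <- poly[rev(seq_len(nrow(poly))), ]; A <- -A }
  if (A <= 0) stop("polygon has zero area")
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  perim <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  cx <- sum((x + x2) * cross) / (6 * A)
  cy <- sum((y + y2) * cross) / (6 * A)
  # raw second moments of the region, then centralized
  Ix <- sum((y^2 + y * y2 + y2^2) * cross) / 12        # integral of y^2 dA
  Iy <- sum((x^2 + x * x2 + x2^2) * cross) / 12        # integral of x^2 dA
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cross) / 24
  mxx <- Iy / A - cx^2
  myy <- Ix / A - cy^2
  mxy <- Ixy / A - cx * cy
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  # ellipse with matching region moments: variance along an axis = (a/2)^2/... :
  # for semi-axes (a, b), normalized moments are a^2/4 and b^2/4
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  hull <- poly[rev(grDevices::chull(poly)), , drop = FALSE]
  convexArea <- abs(.shoelace(hull))
  list(area = A, perimeter = perim, majorAxis = major, minorAxis = minor,
       aspectRatio = if (minor > 0) major / minor else Inf,
       roundness = 4 * A / (pi * major^2),
       circularity = 4 * pi * A / perim^2,
       convexArea = convexArea,
       solidity = A / convexArea)
}
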
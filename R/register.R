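#' @include pointcloud.R
NULL

#' Least-squares rigid transform between paired points
#'
#' Solves orthogonal Procrustes without scaling (Kabsch/Umeyama): finds the
#' rotation `R` and translation `t` minimizing
#' `sum ||R src_i + t - dst_i||^2` via SVD of the cross-covariance matrix,
#' with the determinant correction that suppresses reflections. Exact to
#' machine precision on noiseless correspondences.
#'
#' @param src,dst M x 3 matrices of paired points (row i of `src`
#'   corresponds to row i of `dst`); M >= 3 and the `src` points must not
#'   be collinear
#' @return list with `transform` (a [RigidTransform-class]) and `rmse`
#'   (root-mean-square residual in meters after applying it)
#' @examples
#' src <- matrix(rnorm(18), ncol = 3)
#' t0 <- rigidTransform(rotationAboutZ(0.5), c(1, 2, 0.5))
#' fit <- estimateRigidTransform(src, applyTransform(src, t0))
#' fit$rmse
#' @export
estimateRigidTransform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 3L || ncol(dst) != 3L)
    stop("src and dst must be M x 3 matrices with matching rows")
  m <- nrow(src)
  if (m < 3L)
    stop("transform estimation needs at least 3 correspondences (got ",
         m, ")")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  sv <- svd(crossprod(A, B))      # H = A^T B;  R = V diag(1,1,d) U^T
  scale2 <- sum(A^2) / m
  if (sv$d[2] < 1e-9 * max(sv$d[1], sqrt(scale2), 1e-12))
    stop("degenerate correspondence geometry: source points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cd - R %*% cs)
  t <- rigidTransform(R, tr)
  res <- applyTransform(src, t) - dst
  list(transform = t, rmse = sqrt(mean(rowSums(res^2))))
}

#' Iterative closest point refinement
#'
#' Point-to-point ICP from an initial guess: alternates nearest-neighbor
#' correspondence assignment (gated at `maxDistance`) with the closed-form
#' Kabsch update, accepting an iteration only if it lowers the gated RMSE,
#' and stopping when the improvement falls below `tolerance` or the
#' iteration cap is reached. The returned transform maps the `src` frame
#' into the `dst` frame.
#'
#' @param src,dst non-empty [PointCloud-class] objects with expected overlap
#' @param init initial [RigidTransform-class] (default identity)
#' @param maxIterations iteration cap
#' @param tolerance minimum RMSE improvement in meters to continue
#' @param maxDistance correspondence distance gate in meters (default 0.05)
#' @return list with `transform`, `rmse` (m) and `converged` (FALSE when no
#'   correspondences fall inside the gate, with a warning)
#' @export
icpRefine <- function(src, dst, init = identityTransform(),
                      maxIterations = 50L, tolerance = 1e-7,
                      maxDistance = 0.05) {
  .assertCloud(src, "src"); .assertCloud(dst, "dst")
  if (nPoints(src) == 0L || nPoints(dst) == 0L)
    stop("ICP needs two non-empty clouds")
  sm <- coords(src); dm <- coords(dst)
  cur <- init
  best <- Inf
  converged <- FALSE
  for (it in seq_len(maxIterations)) {
    p <- applyTransform(sm, cur)
    nn <- RANN::nn2(dm, p, k = 1L)
    gate <- nn$nn.dists[, 1] <= maxDistance
    if (sum(gate) < 3L) {
      warning("ICP: fewer than 3 correspondences within the ",
              maxDistance, " m gate; not converged")
      return(list(transform = cur, rmse = if (is.finite(best)) best else NA_real_,
                  converged = FALSE))
    }
    rmse <- sqrt(mean(nn$nn.dists[gate, 1]^2))
    if (rmse > best + 1e-15) break       # re-matching made things worse
    improved <- best - rmse
    best <- rmse
    if (improved < tolerance && it > 1L) { converged <- TRUE; break }
    step <- estimateRigidTransform(p[gate, , drop = FALSE],
                                   dm[nn$nn.idx[gate, 1], , drop = FALSE])
    cur <- composeTransforms(step$transform, cur)
    if (it == maxIterations) converged <- TRUE
  }
  list(transform = cur, rmse = best, converged = converged)
}

#' Match markers between two views by distance signatures
#'
#' Pairs marker centers detected in two views of the same scene without an
#' initial alignment, using each marker's sorted vector of distances to its
#' fellow markers — a rigid-motion invariant. Greedy minimal-cost
#' assignment; requires at least 3 markers per view and a layout whose
#' signatures are unambiguous.
#'
#' @param src,dst M x 3 matrices of marker centers (same physical targets,
#'   any order, expressed in each view's own frame)
#' @return integer vector `j` such that `src[i, ]` corresponds to
#'   `dst[j[i], ]`
#' @export
matchMarkersByDistance <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  m <- nrow(src)
  if (m != nrow(dst)) stop("marker counts differ between views")
  if (m < 3L) stop("marker matching needs at least 3 markers per view")
  sig <- function(x) {
    d <- as.matrix(stats::dist(x))
    t(apply(d, 1, sort))[, -1, drop = FALSE]
  }
  ss <- sig(src); sd_ <- sig(dst)
  cost <- outer(seq_len(m), seq_len(m),
                Vectorize(function(i, j) sqrt(sum((ss[i, ] - sd_[j, ])^2))))
  match <- integer(m)
  usedI <- logical(m); usedJ <- logical(m)
  for (step in seq_len(m)) {
    c2 <- cost
    c2[usedI, ] <- Inf; c2[, usedJ] <- Inf
    k <- arrayInd(which.min(c2), dim(c2))
    match[k[1]] <- k[2]
    usedI[k[1]] <- TRUE; usedJ[k[2]] <- TRUE
  }
  match
}

#' Register multiple views into the first view's frame and merge
#'
#' Chain registration: each non-reference view is aligned to view 1 from
#' its marker correspondence (closed-form rigid fit, optionally followed by
#' ICP against view 1's cloud), so |views| - 1 registrations merge the
#' perspectives into one cloud. The concatenated cloud is then voxel
#' downsampled to collapse duplicate points and restore uniform density.
#'
#' @param views list of [PointCloud-class] objects; the first is the
#'   reference frame
#' @param markerPairs list of length |views| - 1; element i links view
#'   i + 1 to the reference as a list with matrices `src` (centers in view
#'   i + 1's frame) and `dst` (the same physical centers in view 1's frame)
#' @param voxelSize deduplication voxel in meters (default 0.005)
#' @param useIcp logical; refine each marker-based alignment with
#'   [icpRefine()] against the reference cloud
#' @param icpMaxDistance ICP correspondence gate in meters
#' @return list with `merged` (a [PointCloud-class]) and `perStepRmse`
#'   (marker RMSE of each of the |views| - 1 registrations, meters)
#' @export
registerViews <- function(views, markerPairs = list(), voxelSize = 0.005,
                          useIcp = FALSE, icpMaxDistance = 0.05) {
  if (!length(views)) stop("at least one view is required")
  lapply(views, .assertCloud, what = "views[[i]]")
  nv <- length(views)
  if (nv > 1L && length(markerPairs) != nv - 1L)
    stop("markerPairs must link each of the ", nv - 1L,
         " non-reference views to view 1 (got ", length(markerPairs), ")")
  aligned <- views[1]
  rmse <- numeric(0)
  for (i in seq_len(nv - 1L)) {
    mp <- markerPairs[[i]]
    if (is.null(mp$src) || is.null(mp$dst))
      stop("missing marker correspondence for view ", i + 1L)
    fit <- estimateRigidTransform(mp$src, mp$dst)
    t <- fit$transform
    if (useIcp) {
      ref <- icpRefine(views[[i + 1L]], views[[1L]], init = t,
                       maxDistance = icpMaxDistance)
      t <- ref$transform
      fit$rmse <- sqrt(mean(rowSums(
        (applyTransform(as.matrix(mp$src), t) - as.matrix(mp$dst))^2)))
    }
    aligned[[i + 1L]] <- applyTransform(views[[i + 1L]], t)
    rmse <- c(rmse, fit$rmse)
  }
  merged <- voxelDownsample(bindPointClouds(aligned), voxelSize)
  list(merged = merged, perStepRmse = rmse)
}
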
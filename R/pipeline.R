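#' @include synthetic.R
NULL

.PIPELINE_KEYS <- c("version", "voxel_size", "k", "alpha", "cluster_radius",
                    "min_canopy_points", "band_inner_half_length",
                    "band_width", "mesh_method", "fingerprint_n",
                    "fingerprint_features", "outline_mode", "outline_alpha",
                    "seed")

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run with the standard working
#' defaults: 5 mm voxel, statistical outlier removal at k = 24 and
#' alpha = 0.075, 0.08 m canopy-top clustering radius, the 0.1 m ground
#' band, convex-hull meshing, and the default fingerprint layout (n = 4,
#' seven features, convex outlines).
#'
#' @param voxel_size homogenization voxel (m)
#' @param k,alpha statistical outlier removal parameters
#' @param cluster_radius canopy-top clustering radius (m)
#' @param min_canopy_points minimum top-cluster size
#' @param band_inner_half_length,band_width ground-band geometry (m)
#' @param mesh_method "convex_hull" or "slice_hull"
#' @param fingerprint_n slicing parameter n
#' @param fingerprint_features per-slice feature set
#' @param outline_mode "convex" or "alpha"
#' @param outline_alpha alpha radius (m)
#' @param seed integer seed for any stochastic step
#' @return a named list of class `PipelineConfig`
#' @seealso [runPipeline()], [readPipelineConfig()]
#' @export
pipelineConfig <- function(voxel_size = 0.005, k = 24L, alpha = 0.075,
                           cluster_radius = 0.08, min_canopy_points = 50L,
                           band_inner_half_length = 0.05, band_width = 0.1,
                           mesh_method = "convex_hull",
                           fingerprint_n = 4L,
                           fingerprint_features = c("area2d",
                             "aspect_ratio", "circularity", "roundness",
                             "convex_area", "solidity", "volume"),
                           outline_mode = "convex", outline_alpha = 0.05,
                           seed = 1L) {
  cfg <- list(version = 1L, voxel_size = voxel_size, k = as.integer(k),
              alpha = alpha, cluster_radius = cluster_radius,
              min_canopy_points = as.integer(min_canopy_points),
              band_inner_half_length = band_inner_half_length,
              band_width = band_width, mesh_method = mesh_method,
              fingerprint_n = as.integer(fingerprint_n),
              fingerprint_features = fingerprint_features,
              outline_mode = outline_mode, outline_alpha = outline_alpha,
              seed = as.integer(seed))
  stopifnot(cfg$voxel_size > 0, cfg$k >= 1, cfg$alpha >= 0,
            cfg$cluster_radius > 0,
            cfg$mesh_method %in% c("convex_hull", "slice_hull"),
            cfg$outline_mode %in% c("convex", "alpha"))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The file carries a `version` schema key; unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path YAML file
#' @return `readPipelineConfig`: a `PipelineConfig`;
#'   `writePipelineConfig`: invisibly, `path`
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: '", path, "'")
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), .PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  y$version <- NULL
  do.call(pipelineConfig, y)
}

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig`
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full canopy-fingerprint pipeline
#'
#' Orchestrates the end-to-end processing of one block:
#' voxel homogenization, statistical outlier removal, multi-view
#' registration (when several views are supplied), corner-marker block
#' cropping (when the scene carries colors and four white corner markers
#' are found), plot segmentation with per-plot ground removal, trait
#' extraction, and fingerprint generation. Every stage logs its parameters
#' and point counts via `message()`. Deterministic for a fixed config.
#'
#' @param input a [PointCloud-class], a path readable by
#'   [readPointCloud()], or a list of either (multiple views)
#' @param markerPairs optional marker correspondences for multi-view
#'   input, as in [registerViews()]
#' @param config a `PipelineConfig`
#' @param cropToMarkers logical; detect white corner markers and crop the
#'   block before segmentation (skipped with a message if exactly 4 are
#'   not found)
#' @param outDir optional output directory; when given, writes
#'   `fingerprints.csv` (+ `.json` sidecar), `traits.csv`, one
#'   `plot_<i>.pcd` per segment and `run_log.txt`
#' @return list with `db` (a [FingerprintDB-class]), `traits`
#'   (data.frame, one row per plot), `segments` (list of
#'   [PlotSegment-class]), `log` (character vector of stage messages)
#' @export
runPipeline <- function(input, markerPairs = list(),
                        config = pipelineConfig(), cropToMarkers = FALSE,
                        outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  logLines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  asCloud <- function(x) if (is(x, "PointCloud")) x else readPointCloud(x)
  views <- if (is.list(input) && !is(input, "PointCloud"))
    lapply(input, asCloud) else list(asCloud(input))
  if (any(vapply(views, nPoints, integer(1)) == 0L))
    stop("stage voxelize: empty input cloud")

  say("stage voxelize: %d view(s), voxel %.3f m", length(views),
      config$voxel_size)
  views <- lapply(views, voxelDownsample, voxelSize = config$voxel_size)
  say("stage voxelize: %s points", paste(vapply(views, nPoints,
                                                integer(1)),
                                         collapse = " + "))

  block <- if (length(views) > 1L) {
    say("stage register: %d registrations", length(views) - 1L)
    reg <- registerViews(views, markerPairs, voxelSize = config$voxel_size)
    say("stage register: marker rmse %s m",
        paste(sprintf("%.4f", reg$perStepRmse), collapse = ", "))
    reg$merged
  } else views[[1L]]

  say("stage denoise: k = %d, alpha = %.3f on %d points", config$k,
      config$alpha, nPoints(block))
  block <- removeStatisticalOutliers(block, config$k, config$alpha)$inliers
  say("stage denoise: %d points kept", nPoints(block))

  if (cropToMarkers) {
    if (!hasColors(block)) {
      say("stage crop: skipped (no colors)")
    } else {
      mk <- detectColorMarkers(block, "white")
      if (nrow(markerCenters(mk)) == 4L) {
        block <- cropBlock(block, mk)
        say("stage crop: 4 corner markers, %d points kept", nPoints(block))
      } else say("stage crop: skipped (%d white markers found, need 4)",
                 nrow(markerCenters(mk)))
    }
  }

  # reference targets must not enter plot segmentation: spheres sit above
  # the block plane and would be labeled as canopy tops
  if (hasColors(block)) {
    cc <- pointColors(block)
    isMarker <- .colorPredicate(cc, "white") |
      .colorPredicate(cc, "yellow") | .colorPredicate(cc, "red")
    if (any(isMarker)) {
      block <- block[!isMarker]
      say("stage segment: %d marker-colored points removed",
          sum(isMarker))
    }
  }

  say("stage segment: radius %.3f m, min %d points", config$cluster_radius,
      config$min_canopy_points)
  segs <- segmentPlots(block, config$cluster_radius,
                       config$min_canopy_points,
                       config$band_inner_half_length, config$band_width)
  say("stage segment: %d plot(s)", length(segs))
  if (!length(segs)) stop("stage segment: no plots found")

  fpConfig <- fingerprintConfig(config$fingerprint_n,
                                config$fingerprint_features,
                                config$outline_mode, config$outline_alpha)
  traits <- list(); fps <- list()
  for (i in seq_along(segs)) {
    id <- sprintf("plot_%03d", i)
    canopy <- segs[[i]]@canopy
    traits[[i]] <- canopyTraits(canopy, config$mesh_method,
                                config$outline_mode, config$outline_alpha,
                                id = id)
    traits[[i]]$center_x <- segs[[i]]@center[1]
    traits[[i]]$center_y <- segs[[i]]@center[2]
    traits[[i]]$n_points <- nPoints(canopy)
    fps[[i]] <- computeFingerprint(canopy, fpConfig, canopyId = id)
  }
  traits <- do.call(rbind, traits)
  db <- fingerprintDB(fps)
  say("stage fingerprint: %d fingerprints of length %d", length(db),
      ncol(fingerprintValues(db)))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFingerprintDB(db, file.path(outDir, "fingerprints.csv"))
    utils::write.csv(traits, file.path(outDir, "traits.csv"),
                     row.names = FALSE)
    for (i in seq_along(segs))
      writePointCloud(segs[[i]]@canopy,
                      file.path(outDir, sprintf("plot_%03d.pcd", i)))
    writeLines(logLines, file.path(outDir, "run_log.txt"))
    say("outputs written to %s", outDir)
  }
  list(db = db, traits = traits, segments = segs, log = logLines)
}
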
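#' @include pointcloud.R
NULL

# Readers/writers for the three formats the pipeline touches. One internal
# convention: meters, z up, colors as floats in [0, 1]. PCD packed-rgb
# (float32 whose bit pattern is 0x00RRGGBB) and 0-255 integer dialects are
# normalized at ingestion; conversions live here, at the boundary.

.formatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pcd = "pcd", ply = "ply", csv = "csv", xyz = "csv", txt = "csv",
    stop("cannot infer point-cloud format from extension '.", ext,
         "'; pass format = 'pcd', 'ply' or 'csv'"))
}

# float32 bit pattern <-> packed 0x00RRGGBB, vectorized
.unpackRgbFloat <- function(v) {
  raw4 <- writeBin(as.numeric(v), raw(), size = 4L, endian = "little")
  u <- readBin(raw4, "integer", n = length(v), size = 4L, endian = "little")
  cbind(r = bitwAnd(bitwShiftR(u, 16L), 255L),
        g = bitwAnd(bitwShiftR(u, 8L), 255L),
        b = bitwAnd(u, 255L)) / 255
}

.packRgbFloat <- function(colors) {
  u <- as.integer(round(colors[, 1] * 255)) * 65536L +
       as.integer(round(colors[, 2] * 255)) * 256L +
       as.integer(round(colors[, 3] * 255))
  raw4 <- writeBin(u, raw(), size = 4L, endian = "little")
  readBin(raw4, "numeric", n = length(u), size = 4L, endian = "little")
}

#' Read a point cloud from PCD, PLY or CSV
#'
#' Supports PCD v0.7 (ASCII and binary, `FIELDS x y z [rgb]`, packed-float
#' or unsigned-int rgb), PLY (ASCII and binary little-endian vertex
#' elements with float/double coordinates and uchar or float colors), and
#' CSV/XYZ tables with columns `x,y,z[,r,g,b]` and an optional header line
#' (auto-detected by a non-numeric first row). Colors in 0--255 convention
#' are rescaled to `[0, 1]`; rows with non-finite coordinates are dropped
#' with a message.
#'
#' @param path file to read
#' @param format "auto" (by extension), "pcd", "ply" or "csv"
#' @return a [PointCloud-class]
#' @seealso [writePointCloud()]
#' @export
readPointCloud <- function(path, format = c("auto", "pcd", "ply", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file '",
                               path, "'")
  if (format == "auto") format <- .formatFromPath(path)
  switch(format,
         pcd = .readPcd(path),
         ply = .readPly(path),
         csv = .readXyzCsv(path))
}

.readPcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("malformed PCD header in '", path,
                            "': no DATA line")
    if (startsWith(line, "#")) next
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    key <- toupper(tok[1])
    hdr[[key]] <- tok[-1]
    if (key == "DATA") break
  }
  for (req in c("FIELDS", "POINTS", "DATA"))
    if (is.null(hdr[[req]]))
      stop("malformed PCD header in '", path, "': missing ", req, " line")
  fields <- tolower(hdr$FIELDS)
  n <- suppressWarnings(as.integer(hdr$POINTS[1]))
  if (is.na(n)) stop("malformed PCD header in '", path,
                     "': unparseable POINTS line 'POINTS ",
                     paste(hdr$POINTS, collapse = " "), "'")
  mode <- tolower(hdr$DATA[1])
  ix <- match(c("x", "y", "z"), fields)
  if (anyNA(ix)) stop("malformed PCD header in '", path,
                      "': FIELDS must include x y z (got '",
                      paste(fields, collapse = " "), "')")
  irgb <- match("rgb", fields)
  types <- if (!is.null(hdr$TYPE)) toupper(hdr$TYPE) else
    rep("F", length(fields))
  sizes <- if (!is.null(hdr$SIZE)) as.integer(hdr$SIZE) else
    rep(4L, length(fields))

  if (!mode %in% c("ascii", "binary"))
    stop("malformed PCD header in '", path, "': DATA '", mode,
         "' not supported (ascii/binary only)")
  if (n == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = length(fields))
  } else if (mode == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < n) stop("truncated PCD data in '", path, "'")
    m <- matrix(as.numeric(unlist(strsplit(trimws(txt[seq_len(n)]),
                                           "\\s+"))),
                nrow = n, byrow = TRUE)
    if (ncol(m) != length(fields))
      stop("malformed PCD data in '", path, "': row width ", ncol(m),
           " does not match FIELDS count ", length(fields))
  } else if (mode == "binary") {
    if (!all(sizes == 4L))
      stop("only 4-byte PCD binary fields are supported ('", path, "')")
    stride <- 4L * length(fields)
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride) stop("truncated PCD data in '", path, "'")
    m <- matrix(NA_real_, n, length(fields))
    for (j in seq_along(fields)) {
      sel <- rep((seq_len(n) - 1L) * stride, each = 4L) +
             (j - 1L) * 4L + seq_len(4L)
      m[, j] <- if (types[j] == "U")
        readBin(raw[sel], "integer", n = n, size = 4L, endian = "little")
      else
        readBin(raw[sel], "numeric", n = n, size = 4L, endian = "little")
    }
  } else stop("malformed PCD header in '", path, "': DATA '", mode,
              "' not supported (ascii/binary only)")

  colors <- NULL
  if (!is.na(irgb)) {
    colors <- if (types[irgb] == "U")
      .unpackRgbFloat(readBin(writeBin(as.integer(m[, irgb]), raw(),
                                       size = 4L, endian = "little"),
                              "numeric", n = n, size = 4L,
                              endian = "little"))
    else .unpackRgbFloat(m[, irgb])
  }
  pointCloud(m[, ix, drop = FALSE], colors)
}

.readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(trimws(first), "ply"))
    stop("malformed PLY header in '", path, "': first line is '", first, "'")
  fmt <- NULL; n <- NA_integer_
  props <- character(0); ptypes <- character(0)
  inVertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("malformed PLY header in '", path,
                            "': no end_header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      inVertex <- tok[2] == "vertex"
      if (inVertex) n <- as.integer(tok[3])
      else if (!is.na(n) && as.integer(tok[3]) > 0)
        stop("PLY files with non-vertex elements are not supported ('",
             path, "')")
    } else if (tok[1] == "property" && inVertex) {
      if (tok[2] == "list")
        stop("malformed PLY header in '", path,
             "': list property in vertex element")
      props <- c(props, tok[3]); ptypes <- c(ptypes, tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.na(n)) stop("malformed PLY header in '", path,
                     "': no vertex element")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("PLY format '", fmt, "' not supported ('", path, "')")
  sizeOf <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
              short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
              int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
              float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (!all(ptypes %in% names(sizeOf)))
    stop("malformed PLY header in '", path, "': unknown property type")

  if (n == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = length(props))
  } else if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < n) stop("truncated PLY data in '", path, "'")
    m <- matrix(as.numeric(unlist(strsplit(trimws(txt[seq_len(n)]),
                                           "\\s+"))),
                nrow = n, byrow = TRUE)
  } else {
    sz <- sizeOf[ptypes]
    stride <- sum(sz)
    offs <- cumsum(c(0L, sz[-length(sz)]))
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride) stop("truncated PLY data in '", path, "'")
    m <- matrix(NA_real_, n, length(props))
    for (j in seq_along(props)) {
      sel <- rep((seq_len(n) - 1L) * stride, each = sz[j]) + offs[j] +
             seq_len(sz[j])
      bytes <- raw[sel]
      m[, j] <- switch(ptypes[j],
        float = , float32 = readBin(bytes, "numeric", n = n, size = 4L,
                                    endian = "little"),
        double = , float64 = readBin(bytes, "numeric", n = n, size = 8L,
                                     endian = "little"),
        uchar = , uint8 = as.integer(bytes),
        char = , int8 = readBin(bytes, "integer", n = n, size = 1L,
                                endian = "little"),
        readBin(bytes, "integer", n = n, size = sz[j], endian = "little",
                signed = !startsWith(ptypes[j], "u")))
    }
  }
  ix <- match(c("x", "y", "z"), props)
  if (anyNA(ix)) stop("malformed PLY header in '", path,
                      "': vertex element lacks x/y/z properties")
  ic <- match(c("red", "green", "blue"), props)
  colors <- if (!anyNA(ic)) m[, ic, drop = FALSE]
  pointCloud(m[, ix, drop = FALSE], colors)
}

.readXyzCsv <- function(path) {
  firstLine <- readLines(path, n = 1L, warn = FALSE)
  if (!length(firstLine)) return(emptyPointCloud())
  firstTok <- strsplit(firstLine, ",")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(firstTok))))
  d <- utils::read.csv(path, header = hasHeader)
  if (!hasHeader)
    names(d) <- c("x", "y", "z", "r", "g", "b")[seq_len(ncol(d))]
  names(d) <- tolower(names(d))
  if (!all(c("x", "y", "z") %in% names(d)))
    stop("malformed CSV in '", path, "': need columns x, y, z")
  colors <- if (all(c("r", "g", "b") %in% names(d)))
    as.matrix(d[, c("r", "g", "b")])
  pointCloud(as.matrix(d[, c("x", "y", "z")]), colors)
}

#' Write a point cloud to PCD, PLY or CSV
#'
#' PCD and PLY can be written as ASCII (default, 6 decimal places, i.e.
#' micrometer-exact round trips) or binary little-endian float32. Color
#' fields are written only when the cloud carries colors; PCD colors use the
#' packed-float rgb dialect, PLY uses uchar red/green/blue, CSV writes
#' `r,g,b` columns in `[0, 1]`.
#'
#' @param pc a [PointCloud-class]
#' @param path destination file
#' @param format "auto" (by extension), "pcd", "ply" or "csv"
#' @param binary logical; write binary PCD/PLY instead of ASCII
#' @return invisibly, `path`
#' @seealso [readPointCloud()]
#' @export
writePointCloud <- function(pc, path,
                            format = c("auto", "pcd", "ply", "csv"),
                            binary = FALSE) {
  .assertCloud(pc)
  format <- match.arg(format)
  if (format == "auto") format <- .formatFromPath(path)
  ok <- tryCatch({
    switch(format,
           pcd = .writePcd(pc, path, binary),
           ply = .writePly(pc, path, binary),
           csv = .writeXyzCsv(pc, path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write point cloud to '", path, "': ",
         conditionMessage(ok))
  invisible(path)
}

.writePcd <- function(pc, path, binary) {
  n <- nPoints(pc)
  withRgb <- hasColors(pc)
  fields <- if (withRgb) "x y z rgb" else "x y z"
  nf <- if (withRgb) 4L else 3L
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", fields),
           paste("SIZE", paste(rep(4L, nf), collapse = " ")),
           paste("TYPE", paste(rep("F", nf), collapse = " ")),
           paste("COUNT", paste(rep(1L, nf), collapse = " ")),
           paste("WIDTH", n),
           "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", n),
           paste("DATA", if (binary) "binary" else "ascii"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  m <- coords(pc)
  if (withRgb) m <- cbind(m, .packRgbFloat(pointColors(pc)))
  if (n == 0L) return(invisible(NULL))
  if (binary) {
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  } else {
    body <- apply(m, 1L, function(r)
      paste(c(sprintf("%.6f", r[1:3]),
              if (withRgb) sprintf("%.8e", r[4])), collapse = " "))
    writeLines(body, con)
  }
  invisible(NULL)
}

.writePly <- function(pc, path, binary) {
  n <- nPoints(pc)
  withRgb <- hasColors(pc)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           if (withRgb) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0L) return(invisible(NULL))
  m <- coords(pc)
  cols <- if (withRgb) round(pointColors(pc) * 255)
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(m[i, ]), con, size = 4L, endian = "little")
      if (withRgb) writeBin(as.raw(cols[i, ]), con)
    }
  } else {
    body <- vapply(seq_len(n), function(i)
      paste(c(sprintf("%.6f", m[i, ]),
              if (withRgb) sprintf("%d", as.integer(cols[i, ]))),
            collapse = " "), character(1))
    writeLines(body, con)
  }
  invisible(NULL)
}

.writeXyzCsv <- function(pc, path) {
  m <- coords(pc)
  d <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
  if (hasColors(pc)) {
    cc <- pointColors(pc)
    d$r <- cc[, 1]; d$g <- cc[, 2]; d$b <- cc[, 3]
  }
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
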
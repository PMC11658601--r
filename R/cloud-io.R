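#' Read and write point clouds
#'
#' Three interchange formats are supported:
#' * `ply` — ASCII PLY with vertex properties x/y/z, optional uchar
#'   red/green/blue and optional uchar label (0 = ground, 1 = canopy
#'   for labels; colors are stored as 0-255 and rescaled to \[0, 1\]).
#'   Coordinates are written with 17 significant digits so a write/read
#'   round trip reproduces them exactly.
#' * `xyz` — whitespace-separated table `x y z [r g b] [label]`.
#' * `las` — LAS 1.2, point data format 2 (xyz + RGB + classification),
#'   scale 0.001 m. Class labels map to the standard ASPRS codes:
#'   ground = 2, canopy = 4 (medium vegetation), unlabeled = 1.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"xyz"`, `"las"`; default guessed from
#'   the file extension.
#' @param cloud a [point_cloud()].
#' @return `read_point_cloud` returns a [point_cloud()];
#'   `write_point_cloud` returns `path` invisibly.
#' @export
read_point_cloud <- function(path, format = NULL) {
  format <- cloud_format(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         ply = read_ply(path),
         xyz = read_xyz(path),
         las = read_las(path))
}

#' @rdname read_point_cloud
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- cloud_format(path, format)
  switch(format,
         ply = write_ply(cloud, path),
         xyz = write_xyz(cloud, path),
         las = write_las(cloud, path))
  invisible(path)
}

cloud_format <- function(path, format) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("ply", "xyz", "las"))
    stop("unsupported point-cloud format: ", format, call. = FALSE)
  format
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_ply <- function(cloud, path) {
  n <- n_points(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z"),
             con)
  if (!is.null(cloud$colors))
    writeLines(c("property uchar red", "property uchar green", "property uchar blue"), con)
  if (!is.null(cloud$labels))
    writeLines("property uchar label", con)
  writeLines("end_header", con)
  parts <- list(fmt_num(cloud$points[, 1]), fmt_num(cloud$points[, 2]),
                fmt_num(cloud$points[, 3]))
  if (!is.null(cloud$colors)) {
    rgb <- round(cloud$colors * 255)
    parts <- c(parts, list(rgb[, 1], rgb[, 2], rgb[, 3]))
  }
  if (!is.null(cloud$labels)) parts <- c(parts, list(cloud$labels))
  writeLines(do.call(paste, parts), con)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("malformed PLY: missing 'ply' magic at line 1", call. = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("malformed PLY: no end_header", call. = FALSE)
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)[1]))
  if (is.na(nv)) stop("malformed PLY: no vertex element", call. = FALSE)
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  body <- lines[end + seq_len(nv)]
  fields <- utils::read.table(text = body, col.names = props)
  pts <- as.matrix(fields[, c("x", "y", "z")])
  cols <- if (all(c("red", "green", "blue") %in% props))
    as.matrix(fields[, c("red", "green", "blue")]) / 255
  labs <- if ("label" %in% props) fields$label
  point_cloud(pts, cols, labs)
}

write_xyz <- function(cloud, path) {
  parts <- list(fmt_num(cloud$points[, 1]), fmt_num(cloud$points[, 2]),
                fmt_num(cloud$points[, 3]))
  if (!is.null(cloud$colors))
    parts <- c(parts, list(fmt_num(cloud$colors[, 1]), fmt_num(cloud$colors[, 2]),
                           fmt_num(cloud$colors[, 3])))
  if (!is.null(cloud$labels)) parts <- c(parts, list(cloud$labels))
  writeLines(do.call(paste, parts), path)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (length(unique(nf)) > 1)
    stop(sprintf("malformed XYZ: inconsistent field count at line %d",
                 which(nf != nf[1])[1]), call. = FALSE)
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop(sprintf("malformed XYZ: non-numeric token at line %d", bad[1]),
         call. = FALSE)
  m <- do.call(rbind, vals)
  if (ncol(m) < 3) stop("malformed XYZ: need at least 3 columns", call. = FALSE)
  cols <- if (ncol(m) >= 6) m[, 4:6, drop = FALSE]
  labs <- if (ncol(m) %in% c(4, 7)) m[, ncol(m)]
  point_cloud(m[, 1:3, drop = FALSE], cols, labs)
}

# LAS 1.2 classification codes used for the two-class problem
LAS_CLASS_GROUND <- 2L
LAS_CLASS_CANOPY <- 4L

write_las <- function(cloud, path) {
  n <- n_points(cloud)
  scale <- 1e-3
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2, endian = "little")      # source id, encoding
  writeBin(raw(16), con)                                      # GUID
  writeBin(as.raw(c(1, 2)), con)                              # version 1.2
  writeChar(formatC("phenofield", width = 32), con, 32, eos = NULL)
  writeChar(formatC("phenofield", width = 32), con, 32, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2, endian = "little")    # day, year
  writeBin(227L, con, size = 2, endian = "little")            # header size
  writeBin(227L, con, size = 4, endian = "little")            # offset to points
  writeBin(0L, con, size = 4, endian = "little")              # n VLRs
  writeBin(as.raw(2), con)                                    # point format 2
  writeBin(26L, con, size = 2, endian = "little")             # record length
  writeBin(n, con, size = 4, endian = "little")
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4, endian = "little")
  writeBin(rep(scale, 3), con, endian = "little")             # scales
  writeBin(rep(0, 3), con, endian = "little")                 # offsets
  rng <- apply(cloud$points, 2, range)
  writeBin(as.numeric(rbind(rng[2, ], rng[1, ])), con, endian = "little")

  xyz <- as.integer(round(t(cloud$points) / scale))
  cls <- if (is.null(cloud$labels)) rep(1L, n) else
    ifelse(cloud$labels == 1L, LAS_CLASS_CANOPY, LAS_CLASS_GROUND)
  rgb <- if (is.null(cloud$colors)) matrix(0L, n, 3) else
    matrix(as.integer(round(cloud$colors * 65535)), n, 3)
  # pack records column-wise: one 26-byte column per point
  m <- matrix(as.raw(0), 26L, n)
  m[1:12, ] <- matrix(writeBin(as.vector(xyz), raw(), size = 4,
                               endian = "little"), nrow = 12)
  m[15, ] <- as.raw(0x09)                                     # return 1 of 1
  m[16, ] <- as.raw(cls)
  m[21:26, ] <- matrix(writeBin(as.integer(t(rgb)), raw(), size = 2,
                                endian = "little"), nrow = 6)
  writeBin(as.vector(m), con)
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4)
  if (!identical(sig, "LASF")) stop("malformed LAS: bad signature", call. = FALSE)
  invisible(readBin(con, raw(), 20))
  ver <- as.integer(readBin(con, raw(), 2))
  invisible(readBin(con, raw(), 68))
  invisible(readBin(con, integer(), 1, size = 2, endian = "little")) # header size
  pt_offset <- readBin(con, integer(), 1, size = 4, endian = "little")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little")) # n VLRs
  fmt <- as.integer(readBin(con, raw(), 1))
  rec_len <- readBin(con, integer(), 1, size = 2, signed = FALSE, endian = "little")
  n <- readBin(con, integer(), 1, size = 4, endian = "little")
  invisible(readBin(con, integer(), 5, size = 4, endian = "little"))
  scale <- readBin(con, numeric(), 3, endian = "little")
  offs <- readBin(con, numeric(), 3, endian = "little")
  if (!fmt %in% c(2L, 3L))
    stop("unsupported LAS point format: ", fmt, call. = FALSE)
  seek(con, pt_offset)
  rec <- readBin(con, raw(), rec_len * n)
  if (length(rec) < rec_len * n) stop("malformed LAS: truncated point data", call. = FALSE)
  m <- matrix(rec, nrow = rec_len)
  int_at <- function(rows) {
    readBin(as.raw(m[rows, , drop = FALSE]), integer(), n, size = 4, endian = "little")
  }
  pts <- cbind(int_at(1:4), int_at(5:8), int_at(9:12))
  pts <- sweep(pts * rep(scale, each = nrow(pts)), 2, offs, `+`)
  cls <- as.integer(m[16, ])
  labs <- ifelse(cls == LAS_CLASS_CANOPY, 1L,
                 ifelse(cls == LAS_CLASS_GROUND, 0L, NA_integer_))
  u16 <- function(rows) {
    readBin(as.raw(m[rows, , drop = FALSE]), integer(), n, size = 2,
            signed = FALSE, endian = "little")
  }
  cols <- cbind(u16(21:22), u16(23:24), u16(25:26)) / 65535
  if (all(cols == 0)) cols <- NULL
  if (all(is.na(labs))) labs <- NULL
  point_cloud(pts, cols, labs)
}
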
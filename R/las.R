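#' Read a point cloud from LAS or CSV
#'
#' Reads the `.las` exchange format produced by photogrammetric software
#' (versions 1.2-1.4, any point record format: only the x, y, z triplet is
#' used by the pipeline; intensity, RGB and classification attributes are
#' ignored). A plain CSV with `x,y,z` columns is accepted as a fallback for
#' small fixtures. Compressed LAZ is not supported and raises a format error;
#' decompress to LAS first.
#'
#' @param path Path to a `.las` or `.csv` file.
#' @param crs Optional projected-CRS identifier to attach to the cloud
#'   (e.g. `"EPSG:25830"`). Geographic (lat/lon) identifiers are rejected.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, crs = NULL) {
  if (!file.exists(path))
    stop2("olivecloud_io", "file not found: ", path)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) == 4L && rawToChar(magic) == "LASF")
    return(read_las(path, crs = crs))
  if (grepl("\\.laz$", path, ignore.case = TRUE))
    stop2("olivecloud_format",
          "'", path, "' looks like compressed LAZ, which is not supported; ",
          "decompress to LAS first")
  if (grepl("\\.las$", path, ignore.case = TRUE))
    stop2("olivecloud_format", "'", path, "' is not a valid LAS file ",
          "(missing LASF signature)")
  read_xyz_csv(path, crs = crs)
}

read_xyz_csv <- function(path, crs = NULL) {
  d <- tryCatch(utils::read.csv(path),
                error = function(e) stop2("olivecloud_format",
                                          "cannot parse '", path, "': ",
                                          conditionMessage(e)))
  if (!all(c("x", "y", "z") %in% names(d)))
    stop2("olivecloud_format", "CSV point cloud needs x, y, z columns")
  point_cloud(d$x, d$y, d$z, h = d[["h"]], crs = crs)
}

# Minimal LAS reader. All point record formats store X, Y, Z as scaled
# little-endian int32 in the first 12 bytes of each record, which is all the
# pipeline consumes.
read_las <- function(path, crs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 375L)
  if (length(hdr) < 227L || rawToChar(hdr[1:4]) != "LASF")
    stop2("olivecloud_format", "'", path, "' is not a valid LAS file")
  u8  <- function(at) as.integer(hdr[at + 1L])
  u16 <- function(at) readBin(hdr[at + 1:2], "integer", size = 2L,
                              signed = FALSE, endian = "little")
  u32 <- function(at) {
    v <- readBin(hdr[at + 1:4], "integer", size = 4L, endian = "little")
    if (v < 0) v + 2^32 else as.double(v)
  }
  u64 <- function(at) u32(at) + u32(at + 4L) * 2^32
  f64 <- function(at, n = 1L) readBin(hdr[at + seq_len(8L * n)], "double",
                                      n = n, endian = "little")

  ver <- c(u8(24L), u8(25L))
  offset_points <- u32(96L)
  fmt <- u8(104L)
  if (fmt >= 128L)
    stop2("olivecloud_format",
          "'", path, "' is LAZ-compressed (point format ", fmt,
          "); decompress to LAS first")
  reclen <- u16(105L)
  if (reclen < 12L)
    stop2("olivecloud_format", "corrupt LAS header: point record length ",
          reclen)
  n <- u32(107L)
  if (n == 0 && ver[1] == 1L && ver[2] >= 4L && length(hdr) >= 255L)
    n <- u64(247L)  # LAS 1.4 stores the count in a 64-bit field
  scales  <- f64(131L, 3L)
  offsets <- f64(155L, 3L)

  if (n > .Machine$integer.max)
    stop2("olivecloud_format", "LAS file too large: ", n, " points")
  n <- as.integer(n)
  if (n == 0L)
    return(point_cloud(double(), double(), double(), crs = crs))

  seek(con, offset_points)
  body <- readBin(con, "raw", n = n * reclen)
  if (length(body) < n * reclen)
    stop2("olivecloud_format", "truncated LAS file: expected ", n, " points")
  dim(body) <- c(reclen, n)
  xyz <- readBin(as.vector(body[1:12, , drop = FALSE]), "integer",
                 n = 3L * n, endian = "little")
  dim(xyz) <- c(3L, n)
  point_cloud(xyz[1, ] * scales[1] + offsets[1],
              xyz[2, ] * scales[2] + offsets[2],
              xyz[3, ] * scales[3] + offsets[3],
              crs = crs)
}

#' Write a point cloud to LAS
#'
#' Writes LAS 1.2, point record format 0, with a declared coordinate scale
#' (default 1 mm). Coordinates survive a write/read round trip to within the
#' declared scale. Normalized heights (`h`) are not representable in format 0
#' and are dropped on write; use [write_xyz_csv()] to persist them.
#'
#' @param pc A [point_cloud()].
#' @param path Output path.
#' @param scale Coordinate resolution of the stored scaled integers, in
#'   meters.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(pc, path, scale = 0.001) {
  stopifnot(inherits(pc, "point_cloud"))
  n <- length(pc$x)
  offs <- if (n > 0) c(floor(min(pc$x)), floor(min(pc$y)), floor(min(pc$z)))
          else c(0, 0, 0)
  rng <- if (n > 0) c(max(pc$x), min(pc$x), max(pc$y), min(pc$y),
                      max(pc$z), min(pc$z))
         else rep(0, 6)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop2("olivecloud_io",
                                            "cannot write '", path, "'"))
  on.exit(close(con))
  w8  <- function(x) writeBin(as.raw(x), con)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf  <- function(x) writeBin(as.double(x), con, endian = "little")

  writeChar("LASF", con, 4L, eos = NULL)
  w16(0L); w16(0L)                       # file source id, global encoding
  w8(rep(0L, 16L))                       # project GUID
  w8(c(1L, 2L))                          # version 1.2
  w8(rep(0L, 32L)); w8(rep(0L, 32L))     # system id, generating software
  w16(1L); w16(2026L)                    # day, year
  w16(227L)                              # header size
  w32(227L)                              # offset to point data
  w32(0L)                                # number of VLRs
  w8(0L)                                 # point data format 0
  w16(20L)                               # point record length
  w32(n)                                 # number of point records
  w32(c(n, 0L, 0L, 0L, 0L))              # number by return
  wf(rep(scale, 3L))                     # x, y, z scale
  wf(offs)                               # x, y, z offset
  wf(rng)                                # max/min x, y, z

  if (n > 0) {
    ints <- rbind(as.integer(round((pc$x - offs[1]) / scale)),
                  as.integer(round((pc$y - offs[2]) / scale)),
                  as.integer(round((pc$z - offs[3]) / scale)))
    xyz_raw <- writeBin(as.vector(ints), raw(), size = 4L, endian = "little")
    dim(xyz_raw) <- c(12L, n)
    rec <- matrix(as.raw(0L), nrow = 20L, ncol = n)
    rec[1:12, ] <- xyz_raw
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' Write a point cloud to CSV
#'
#' Plain-text companion to [write_point_cloud()]; keeps the normalized
#' height column `h` when present.
#'
#' @param pc A [point_cloud()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_csv <- function(pc, path) {
  stopifnot(inherits(pc, "point_cloud"))
  utils::write.csv(as.data.frame(pc), path, row.names = FALSE)
  invisible(path)
}
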
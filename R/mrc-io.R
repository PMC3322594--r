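#' Read an MRC/CCP4 density map (modern subset)
#'
#' Reads the MRC2014-style binary map format under a deliberately strict
#' subset of the historical dialects: 32-bit float data (mode 2), axis order
#' x,y,z (`MAPC,MAPR,MAPS = 1,2,3`), orthogonal 90-degree cells, and a cubic
#' lattice (equal voxel spacing on all axes within 0.1%). Anything else is
#' rejected with an informative error. Byte order is auto-detected from
#' header plausibility (dimensions within 1..100000 and a known mode code),
#' so files from either endianness read identically.
#'
#' The map origin is taken from the ORIGIN header record when any component
#' is nonzero; otherwise it is computed from the start indices as
#' `(NXSTART, NYSTART, NZSTART) * width`.
#'
#' @param path file to read.
#' @return A [volume_map].
#' @seealso [write_mrc()], [read_situs()]
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("truncated MRC file: '", path, "'")
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 1024)

  parse_ints <- function(endian) readBin(raw_hdr, "integer", n = 256,
                                         size = 4, endian = endian)
  plausible <- function(ii) all(ii[1:3] >= 1 & ii[1:3] <= 100000) &&
    ii[4] %in% c(0L, 1L, 2L, 6L, 12L)
  endian <- NULL
  for (e in c("little", "big")) if (plausible(parse_ints(e))) { endian <- e; break }
  if (is.null(endian))
    stop("unrecognizable MRC header (neither byte order yields sane ",
         "dimensions/mode)")

  ints <- parse_ints(endian)
  flts <- readBin(raw_hdr, "double", n = 256, size = 4, endian = endian)
  dims <- ints[1:3]
  mode <- ints[4]
  if (mode != 2L)
    stop("unsupported MRC mode ", mode,
         " (only mode 2, 32-bit float, is accepted)")
  nstart <- ints[5:7]
  mgrid <- ints[8:10]
  cella <- flts[11:13]
  cellb <- flts[14:16]
  mapcrs <- ints[17:19]
  if (!all(mapcrs == 1:3))
    stop("permuted axis order (MAPC,MAPR,MAPS = ",
         paste(mapcrs, collapse = ","), "); only 1,2,3 is accepted")
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal cell angles (", paste(cellb, collapse = ", "),
         "); only 90-degree cells are accepted")
  if (any(mgrid < 1)) stop("invalid sampling intervals MX,MY,MZ")
  widths <- cella / mgrid
  if (any(widths <= 0) || (max(widths) - min(widths)) > 1e-3 * mean(widths))
    stop("non-cubic voxels (spacings ", paste(signif(widths, 6), collapse = ", "),
         "); a cubic lattice is required")
  width <- mean(widths)

  origin <- flts[50:52]
  if (all(origin == 0)) origin <- nstart * width

  nsymbt <- ints[24]
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  nvox <- prod(dims)
  dat <- readBin(con, "double", n = nvox, size = 4, endian = endian)
  if (length(dat) != nvox)
    stop("truncated MRC data section: expected ", nvox, " voxels, got ",
         length(dat))
  volume_map(dat, width = width, origin = origin, dims = dims)
}

#' Write an MRC/CCP4 density map (modern subset)
#'
#' Writes mode-2 (32-bit float) data in x,y,z axis order with an orthogonal
#' cell, the ORIGIN record set from the map origin, and min/max/mean/rms
#' statistics filled in. The file is the inverse of [read_mrc()].
#'
#' @param map a [volume_map].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "volume_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- map$dims
  w_i <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.vector(map$data)
  w_i(dims)                 # NX NY NZ
  w_i(2)                    # MODE: float32
  w_i(c(0, 0, 0))           # NXSTART..
  w_i(dims)                 # MX MY MZ
  w_f(dims * map$width)     # CELLA
  w_f(c(90, 90, 90))        # CELLB
  w_i(1:3)                  # MAPC MAPR MAPS
  w_f(c(min(v), max(v), mean(v)))   # DMIN DMAX DMEAN
  w_i(1)                    # ISPG: volume
  w_i(0)                    # NSYMBT
  w_i(rep(0, 25))           # EXTRA (words 25-49)
  w_f(map$origin)           # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)              # word 53
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)    # machine stamp, little-endian
  w_f(stats::sd(v) * sqrt(max(length(v) - 1, 1) / length(v)))  # RMS (population)
  w_i(1)                    # NLABL
  lab <- charToRaw(sprintf("%-80s", "minisitus volume map"))
  writeBin(c(lab, raw(800 - length(lab))), con)
  w_f(v)
  invisible(path)
}
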
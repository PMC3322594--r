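#' Read a Situs ASCII density map
#'
#' The Situs map format is a minimalist ASCII format: a header of seven
#' whitespace-separated numbers, `WIDTH ORIGX ORIGY ORIGZ NX NY NZ`, followed
#' by `NX*NY*NZ` density values with x indices changing fastest and z
#' slowest. Arbitrary whitespace and line breaks are tolerated in the data
#' section.
#'
#' @param path file to read.
#' @return A [volume_map].
#' @seealso [write_situs()], [read_mrc()]
#' @export
read_situs <- function(path) {
  tok <- tryCatch(scan(path, what = numeric(), quiet = TRUE),
                  error = function(e) stop("malformed Situs file '", path,
                                           "': ", conditionMessage(e)))
  if (length(tok) < 7)
    stop("malformed Situs header: fewer than 7 numeric values in '", path, "'")
  width <- tok[1]
  origin <- tok[2:4]
  dims <- tok[5:7]
  if (width <= 0) stop("non-positive voxel width in Situs header")
  if (any(dims < 1) || any(dims != round(dims)))
    stop("invalid dimensions in Situs header: ", paste(dims, collapse = " "))
  nvox <- prod(dims)
  dat <- tok[-(1:7)]
  if (length(dat) != nvox)
    stop("Situs data count mismatch: header promises ", nvox,
         " values, file has ", length(dat))
  volume_map(dat, width = width, origin = origin, dims = dims)
}

#' Write a Situs ASCII density map
#'
#' Writes the seven-value header on the first line, then densities in
#' x-fastest order, ten values per line, at six significant digits.
#'
#' @param map a [volume_map].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_situs <- function(map, path) {
  stopifnot(inherits(map, "volume_map"))
  con <- file(path, "w")
  on.exit(close(con))
  header <- paste(fmt_g6(c(map$width, map$origin)), collapse = " ")
  writeLines(paste(header, paste(map$dims, collapse = " ")), con)
  writeLines("", con)
  v <- fmt_g6(as.vector(map$data))
  n <- length(v)
  idx <- split(seq_len(n), (seq_len(n) - 1) %/% 10)
  writeLines(vapply(idx, function(i) paste(v[i], collapse = " "), ""), con)
  invisible(path)
}

# 6 significant digits, no scientific clutter for typical densities
fmt_g6 <- function(x) formatC(x, format = "g", digits = 6)
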
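#' @title Tree-cover tile naming and I/O
#' @description Filename conventions and GeoTIFF I/O for annual fractional
#'   tree cover tiles on the standard sinusoidal tile grid: 4800 x 4800
#'   cells per full tile, unsigned 8-bit percent values with nodata 255,
#'   band name "TreeCover".
#' @name tileio
NULL

TILE_ROWS <- 4800L
TILE_NODATA <- 255
SINU_TILE_SPAN <- 1111950.5196666666  # meters per tile edge
SINU_X0 <- -20015109.354              # western edge of tile h00
SINU_Y0 <- 10007554.677               # northern edge of tile v00

#' Compose a tile file name
#'
#' Pattern `<product>.AYYYY001.hHHvVV.<version>.tif` with two-digit
#' zero-padded tile indices, h in 0..35 and v in 0..17.
#'
#' @param year data year.
#' @param h,v horizontal and vertical tile indices.
#' @param product,version name components.
#' @return The file name string.
#' @export
tile_name <- function(year, h, v, product = "GLOBMAPFTC", version = "V01") {
  h <- as.integer(h); v <- as.integer(v); year <- as.integer(year)
  if (h < 0 || h > 35) stop("h must lie in 0..35")
  if (v < 0 || v > 17) stop("v must lie in 0..17")
  sprintf("%s.A%04d001.h%02dv%02d.%s.tif", product, year, h, v, version)
}

#' Parse a tile file name
#'
#' @param name a file name produced by [tile_name()].
#' @return List with `product`, `year`, `h`, `v`, `version`.
#' @export
parse_tile_name <- function(name) {
  bn <- basename(name)
  m <- regmatches(bn,
                  regexec("^([A-Za-z0-9]+)\\.A(\\d{4})001\\.h(\\d{2})v(\\d{2})\\.(V\\d+)\\.tif$",
                          bn))[[1]]
  if (length(m) == 0) stop("file name does not match the tile pattern: ", name)
  list(product = m[2], year = as.integer(m[3]),
       h = as.integer(m[4]), v = as.integer(m[5]), version = m[6])
}

#' Write an annual tree-cover tile
#'
#' Single-band unsigned 8-bit GeoTIFF, values 0..100 percent, nodata 255,
#' band "TreeCover", georeferenced to the sinusoidal tile grid.
#'
#' @param grid matrix of tree cover (%, 0..100 or NA).
#' @param path output path; when a directory, the [tile_name()] is appended.
#' @param year,h,v tile identity.
#' @param product,version name components (used when `path` is a directory).
#' @return The file path written, invisibly.
#' @export
write_tile <- function(grid, path, year, h, v,
                       product = "GLOBMAPFTC", version = "V01") {
  grid <- as.matrix(grid)
  if (any(grid < 0 | grid > 100, na.rm = TRUE))
    stop("tree cover values must lie in [0, 100] or be NA")
  if (dir.exists(path))
    path <- file.path(path, tile_name(year, h, v, product, version))
  px <- SINU_TILE_SPAN / TILE_ROWS
  origin <- c(SINU_X0 + h * SINU_TILE_SPAN, SINU_Y0 - v * SINU_TILE_SPAN)
  write_geotiff(path, round(grid), dtype = "uint8", nodata = TILE_NODATA,
                origin = origin, pixel_size = c(px, px),
                band_names = "TreeCover")
  invisible(path)
}

#' Read an annual tree-cover tile
#'
#' @param path tile file path (tile identity is recovered from the name when
#'   it matches the naming pattern).
#' @return List with `grid` (NA where nodata), `spec` (parsed name or NULL),
#'   `origin`, `pixel_size`.
#' @export
read_tile <- function(path) {
  g <- read_geotiff(path)
  spec <- tryCatch(parse_tile_name(path), error = function(e) NULL)
  list(grid = g$data, spec = spec, origin = g$origin,
       pixel_size = g$pixel_size)
}
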
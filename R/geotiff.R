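#' @title Minimal GeoTIFF reader and writer
#' @description Self-contained reader/writer for single-strip, uncompressed,
#'   pixel-interleaved (Geo)TIFF rasters in the data types this pipeline
#'   uses (uint8, int8, float32, float64), carrying georeferencing through
#'   the ModelPixelScale/ModelTiepoint tags plus the GDAL nodata and
#'   band-description metadata tags.
#' @name geotiff
NULL

tiff_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
tiff_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
tiff_dbl <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

tiff_dtype_info <- function(dtype) {
  switch(dtype,
         uint8 = list(bits = 8L, fmt = 1L, size = 1L),
         int8 = list(bits = 8L, fmt = 2L, size = 1L),
         float32 = list(bits = 32L, fmt = 3L, size = 4L),
         float64 = list(bits = 64L, fmt = 3L, size = 8L),
         stop("unsupported dtype: ", dtype))
}

tiff_encode_values <- function(v, dtype) {
  switch(dtype,
         uint8 = {
           if (any(v < 0 | v > 255)) stop("uint8 values must lie in 0..255")
           as.raw(v)
         },
         int8 = {
           if (any(v < -128 | v > 127)) stop("int8 values must lie in -128..127")
           as.raw(v %% 256)
         },
         float32 = writeBin(as.numeric(v), raw(), size = 4, endian = "little"),
         float64 = writeBin(as.numeric(v), raw(), size = 8, endian = "little"))
}

#' Write a (Geo)TIFF raster
#'
#' @param path output file path.
#' @param data matrix `rows x cols` or array `rows x cols x bands`.
#' @param dtype one of `"uint8"`, `"int8"`, `"float32"`, `"float64"`.
#' @param nodata optional nodata value; NA cells are written as `nodata`
#'   (NA cells without a nodata value are an error).
#' @param origin `c(x, y)` coordinate of the upper-left raster corner.
#' @param pixel_size `c(sx, sy)` ground pixel size (positive numbers).
#' @param band_names optional character vector of band descriptions.
#' @return The path, invisibly.
#' @export
write_geotiff <- function(path, data, dtype = "float32", nodata = NULL,
                          origin = c(0, 0), pixel_size = c(1, 1),
                          band_names = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3) stop("data must be a matrix or 3-d array")
  rows <- dim(data)[1]; cols <- dim(data)[2]; bands <- dim(data)[3]
  info <- tiff_dtype_info(dtype)
  v <- as.vector(aperm(data, c(3, 2, 1)))  # band fastest, then col, then row
  if (anyNA(v)) {
    if (is.null(nodata)) stop("data contains NA but no nodata value is set")
    v[is.na(v)] <- nodata
  }
  strip <- tiff_encode_values(v, dtype)

  entries <- list()
  add <- function(tag, type, values, raw_value = NULL) {
    entries[[length(entries) + 1L]] <<-
      list(tag = tag, type = type, values = values, raw_value = raw_value)
  }
  add(256L, 4L, cols)
  add(257L, 4L, rows)
  add(258L, 3L, rep(info$bits, bands))
  add(259L, 3L, 1L)
  add(262L, 3L, 1L)
  add(273L, 4L, 8L)
  add(277L, 3L, bands)
  add(278L, 4L, rows)
  add(279L, 4L, length(strip))
  add(284L, 3L, 1L)
  add(339L, 3L, rep(info$fmt, bands))
  add(33550L, 12L, c(pixel_size[1], pixel_size[2], 0))
  add(33922L, 12L, c(0, 0, 0, origin[1], origin[2], 0))
  add(34735L, 3L, c(1L, 1L, 0L, 1L, 1025L, 0L, 1L, 1L))
  if (!is.null(band_names)) {
    items <- paste0(sprintf('<Item name="DESCRIPTION" sample="%d" role="description">%s</Item>',
                            seq_along(band_names) - 1L, band_names),
                    collapse = "")
    xml <- paste0("<GDALMetadata>", items, "</GDALMetadata>")
    add(42112L, 2L, NULL, raw_value = c(charToRaw(xml), as.raw(0)))
  }
  if (!is.null(nodata)) {
    add(42113L, 2L, NULL,
        raw_value = c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0)))
  }

  type_size <- c(`2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  enc_entry_value <- function(e) {
    if (!is.null(e$raw_value)) return(e$raw_value)
    switch(as.character(e$type),
           `3` = tiff_u16(e$values),
           `4` = tiff_u32(e$values),
           `12` = tiff_dbl(e$values))
  }
  n_entries <- length(entries)
  ifd_offset <- 8L + length(strip)
  ext_offset <- ifd_offset + 2L + 12L * n_entries + 4L
  ifd <- tiff_u16(n_entries)
  ext <- raw(0)
  for (e in entries) {
    val <- enc_entry_value(e)
    count <- if (!is.null(e$raw_value)) length(e$raw_value)
             else length(e$values)
    ifd <- c(ifd, tiff_u16(e$tag), tiff_u16(e$type), tiff_u32(count))
    if (length(val) <= 4L) {
      ifd <- c(ifd, val, raw(4L - length(val)))
    } else {
      ifd <- c(ifd, tiff_u32(ext_offset + length(ext)))
      if (length(val) %% 2L == 1L) val <- c(val, raw(1))
      ext <- c(ext, val)
    }
  }
  ifd <- c(ifd, tiff_u32(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), tiff_u16(42L), tiff_u32(ifd_offset),
             strip, ifd, ext), con)
  invisible(path)
}

read_uint <- function(r, size, endian = "little") {
  if (size == 2) readBin(r, "integer", n = length(r) %/% 2, size = 2,
                         signed = FALSE, endian = endian)
  else {
    v <- readBin(r, "integer", n = length(r) %/% 4, size = 4, endian = endian)
    ifelse(v < 0, v + 2^32, v)
  }
}

#' Read a (Geo)TIFF raster
#'
#' Supports uncompressed, pixel-interleaved rasters (any strip layout) with
#' 8-bit integer or 32/64-bit float samples, in either byte order.
#'
#' @param path input file path.
#' @return A list: `data` (matrix or `rows x cols x bands` array, nodata as
#'   NA), `nodata`, `origin`, `pixel_size`, `band_names`, `dtype`.
#' @export
read_geotiff <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  order_tag <- rawToChar(r[1:2])
  endian <- if (order_tag == "II") "little"
            else if (order_tag == "MM") "big" else stop("not a TIFF file")
  if (read_uint(r[3:4], 2, endian) != 42) stop("not a TIFF file")
  ifd_off <- read_uint(r[5:8], 4, endian)
  n <- read_uint(r[ifd_off + (1:2)], 2, endian)
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd_off + 2L + 12L * (i - 1L)
    tag <- read_uint(r[e + (1:2)], 2, endian)
    type <- read_uint(r[e + (3:4)], 2, endian)
    count <- read_uint(r[e + (5:8)], 4, endian)
    ts <- type_size[as.character(type)]
    if (is.na(ts)) next
    nbytes <- ts * count
    vraw <- if (nbytes <= 4L) r[e + 8L + seq_len(nbytes)]
            else r[read_uint(r[e + (9:12)], 4, endian) + seq_len(nbytes)]
    vals <- switch(as.character(type),
                   `1` = as.integer(vraw),
                   `2` = {
                     nul <- which(vraw == as.raw(0))
                     rawToChar(if (length(nul)) vraw[seq_len(nul[1] - 1L)] else vraw)
                   },
                   `3` = read_uint(vraw, 2, endian),
                   `4` = read_uint(vraw, 4, endian),
                   `11` = readBin(vraw, "numeric", n = count, size = 4, endian = endian),
                   `12` = readBin(vraw, "numeric", n = count, size = 8, endian = endian))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tg) {
    v <- tags[[as.character(tg)]]
    if (is.null(v)) stop("missing required TIFF tag ", tg)
    v
  }
  cols <- need(256); rows <- need(257)
  bits <- tags[["258"]][1]; if (is.null(bits)) bits <- 1L
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
    stop("compressed TIFFs are not supported")
  bands <- tags[["277"]]; if (is.null(bands)) bands <- 1L
  fmt <- tags[["339"]][1]; if (is.null(fmt)) fmt <- 1L
  offsets <- need(273); counts <- need(279)
  strip <- do.call(c, lapply(seq_along(offsets),
                             function(i) r[offsets[i] + seq_len(counts[i])]))
  dtype <- if (bits == 8 && fmt == 1) "uint8"
           else if (bits == 8 && fmt == 2) "int8"
           else if (bits == 32 && fmt == 3) "float32"
           else if (bits == 64 && fmt == 3) "float64"
           else stop("unsupported sample layout (bits ", bits, ", format ", fmt, ")")
  v <- switch(dtype,
              uint8 = as.numeric(strip),
              int8 = { x <- as.numeric(strip); ifelse(x > 127, x - 256, x) },
              float32 = readBin(strip, "numeric", n = length(strip) %/% 4,
                                size = 4, endian = endian),
              float64 = readBin(strip, "numeric", n = length(strip) %/% 8,
                                size = 8, endian = endian))
  nodata <- if (!is.null(tags[["42113"]])) as.numeric(tags[["42113"]]) else NULL
  if (!is.null(nodata)) v[v == nodata] <- NA
  arr <- aperm(array(v, dim = c(bands, cols, rows)), c(3, 2, 1))
  band_names <- NULL
  if (!is.null(tags[["42112"]])) {
    m <- gregexpr('role="description">[^<]*', tags[["42112"]])[[1]]
    if (m[1] != -1)
      band_names <- substring(tags[["42112"]], m + nchar('role="description">'),
                              m + attr(m, "match.length") - 1L)
  }
  ps <- tags[["33550"]]; tp <- tags[["33922"]]
  list(data = if (bands == 1L) arr[, , 1L] else arr,
       nodata = nodata,
       origin = if (!is.null(tp)) tp[4:5] else c(0, 0),
       pixel_size = if (!is.null(ps)) ps[1:2] else c(1, 1),
       band_names = band_names,
       dtype = dtype)
}
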
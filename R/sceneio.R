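#' @title Scene input/output
#' @description Reads and writes simulated scenes as one multi-band GeoTIFF
#'   per variable (46 bands = 46 composites). QA flags are stored as a uint8
#'   band stack with codes 0 = clear, 1 = cloud, 2 = snow, 3 = water,
#'   4 = fill; the scene truth travels alongside as fraction (float32) and
#'   phenology-shift (int8) rasters, and the simulation configuration as
#'   JSON.
#' @name sceneio
NULL

QA_CODES <- c(clear = 0, cloud = 1, snow = 2, water = 3, fill = 4)

#' Write a scene to a directory
#'
#' @param scene an [simulate_scene()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- scene$truth$pixel_size
  geo <- list(origin = scene$truth$origin, pixel_size = c(px, px))
  wr <- function(x, name, dtype, nodata = NULL) {
    do.call(write_geotiff,
            c(list(file.path(dir, paste0(name, ".tif")), x, dtype = dtype,
                   nodata = nodata), geo))
  }
  for (band in c("ndvi", "red", "nir", "swir"))
    wr(scene[[band]], band, "float32", nodata = -9999)
  if (!is.null(scene$lst)) wr(scene$lst, "lst", "float32", nodata = -9999)
  qa_codes <- array(QA_CODES[scene$qa], dim = dim(scene$qa))
  wr(qa_codes, "qa", "uint8")
  wr(scene$truth$fraction, "truth_fraction", "float32", nodata = -9999)
  wr(scene$truth$pheno_shift, "truth_shift", "int8")
  cfg <- scene$cfg
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene from a directory
#'
#' @param dir directory written by [write_scene()].
#' @return An `ftc_scene` (band values at float32 precision).
#' @export
read_scene <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".tif"))
    if (!file.exists(path)) return(NULL)
    read_geotiff(path)
  }
  out <- list()
  for (band in c("ndvi", "red", "nir", "swir", "lst"))
    out[[band]] <- rd(band)$data
  qa_r <- rd("qa")
  code_names <- names(QA_CODES)[match(qa_r$data, QA_CODES)]
  out$qa <- array(code_names, dim = dim(qa_r$data))
  frac <- rd("truth_fraction")
  shift <- rd("truth_shift")
  truth <- scene_truth(frac$data, shift$data,
                       pixel_size = frac$pixel_size[1], origin = frac$origin)
  cfg_path <- file.path(dir, "config.json")
  cfg <- NULL
  if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    raw$product_error <- lapply(seq_len(nrow(raw$product_error)),
                                function(i) raw$product_error[i, ])
    cfg <- do.call(sim_config, raw)
  }
  structure(c(list(truth = truth, cfg = cfg), out), class = "ftc_scene")
}
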
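#' @title Synthetic MODIS-like scene simulation
#' @description Two-endmember (tree/herbaceous) spectral-temporal mixture
#'   simulator producing per-pixel annual series of 46 eight-day composites
#'   with known tree-cover truth, plus pseudo high-resolution categorical
#'   forest products for training-reference construction.
#' @name simscene
NULL

#' Number of 8-day composites per year
#'
#' Composite `c` (0-based) covers day of year `8c + 1` to `8c + 8`; the last
#' composite absorbs the 2-day year remainder.
#' @export
N_COMPOSITES <- 46L

#' Define a spectral-temporal endmember
#'
#' An endmember is the pure seasonal signature of one cover type. Its NDVI
#' follows a double logistic in composite index; red and SWIR2.1 reflectance
#' decrease affinely with greenness between a dormant-season base value and a
#' peak-season minimum. Tree endmembers use steep logistic rates (rapid leaf
#' flush and senescence, producing a sustained mid-season plateau); herbaceous
#' endmembers use shallow rates (a rounded, parabola-like seasonal curve).
#'
#' @param vmin,vmax NDVI floor and plateau (unitless, in -1..1, `vmax > vmin`
#'   unless degenerate with `vmax == vmin`).
#' @param green_up,senescence composite indices (0..45) of the green-up and
#'   senescence inflection points; `green_up < senescence` after reduction
#'   modulo 46.
#' @param steepness_up,steepness_down logistic rates per composite (> 0).
#' @param red_base,red_min red reflectance at dormancy and at peak greenness.
#' @param swir_base,swir_min SWIR2.1 reflectance at dormancy and peak.
#' @return An object of class `ftc_endmember`.
#' @export
endmember_spec <- function(vmin, vmax, green_up, senescence,
                           steepness_up, steepness_down,
                           red_base, red_min, swir_base, swir_min) {
  green_up <- green_up %% N_COMPOSITES
  senescence <- senescence %% N_COMPOSITES
  if (vmax < vmin) stop("vmax must be >= vmin")
  if (green_up >= senescence)
    stop("green_up must precede senescence after circular normalization")
  refl <- c(red_base = red_base, red_min = red_min,
            swir_base = swir_base, swir_min = swir_min)
  if (any(refl < 0 | refl > 1)) stop("reflectance fields must lie in [0, 1]")
  if (red_min > red_base) stop("red_min must not exceed red_base")
  if (swir_min > swir_base) stop("swir_min must not exceed swir_base")
  if (steepness_up <= 0 || steepness_down <= 0) stop("steepness must be > 0")
  if (vmax >= 1) stop("vmax must be < 1 (NIR would be unbounded)")
  structure(list(vmin = vmin, vmax = vmax, green_up = green_up,
                 senescence = senescence, steepness_up = steepness_up,
                 steepness_down = steepness_down, red_base = red_base,
                 red_min = red_min, swir_base = swir_base,
                 swir_min = swir_min),
            class = "ftc_endmember")
}

#' Default tree endmember (temperate deciduous broadleaf character)
#' @return An `ftc_endmember`.
#' @export
tree_endmember <- function() {
  endmember_spec(vmin = 0.25, vmax = 0.85, green_up = 12, senescence = 34,
                 steepness_up = 2.0, steepness_down = 2.0,
                 red_base = 0.12, red_min = 0.03,
                 swir_base = 0.25, swir_min = 0.08)
}

#' Default herbaceous endmember (grassland/cropland character)
#' @return An `ftc_endmember`.
#' @export
herb_endmember <- function() {
  endmember_spec(vmin = 0.15, vmax = 0.65, green_up = 15, senescence = 31,
                 steepness_up = 0.32, steepness_down = 0.32,
                 red_base = 0.18, red_min = 0.06,
                 swir_base = 0.32, swir_min = 0.15)
}

#' Evaluate endmember seasonal curves
#'
#' Produces the four 46-composite seasonal curves of an endmember. NDVI is
#' the double logistic
#' `vmin + (vmax - vmin) * (logis(s_up (c - green_up)) + logis(s_down (senescence - c)) - 1)`;
#' red and SWIR2.1 decrease affinely with the scaled NDVI between their base
#' and peak-season values; NIR is derived so that `(NIR - red)/(NIR + red)`
#' reproduces the NDVI curve exactly.
#'
#' @param spec an [endmember_spec()].
#' @return A list with numeric vectors `ndvi`, `red`, `nir`, `swir`
#'   (length 46, composites 0..45).
#' @export
endmember_curves <- function(spec) {
  stopifnot(inherits(spec, "ftc_endmember"))
  cc <- 0:(N_COMPOSITES - 1L)
  l1 <- 1 / (1 + exp(-spec$steepness_up * (cc - spec$green_up)))
  l2 <- 1 / (1 + exp(-spec$steepness_down * (spec$senescence - cc)))
  amp <- spec$vmax - spec$vmin
  ndvi <- spec$vmin + amp * (l1 + l2 - 1)
  scale <- if (amp > 0) (ndvi - spec$vmin) / amp else rep(0, N_COMPOSITES)
  red <- spec$red_base - (spec$red_base - spec$red_min) * scale
  swir <- spec$swir_base - (spec$swir_base - spec$swir_min) * scale
  nir <- red * (1 + ndvi) / (1 - ndvi)
  list(ndvi = ndvi, red = red, nir = nir, swir = swir)
}

#' Simulation configuration
#'
#' @param noise_sd Gaussian reflectance noise standard deviation (unitless).
#' @param cloud_prob independent per-composite probability that a composite is
#'   flagged cloudy.
#' @param seed integer seed governing all randomness of the simulation.
#' @param subgrid_factor high-resolution subcells per 250 m cell edge used by
#'   [simulate_products()].
#' @param product_error list of per-product `c(omission, commission)` rates.
#' @param tall_dense_threshold truth fraction (%) below which the last product
#'   suppresses tree labels entirely (mimicking products that only map tall
#'   dense canopy); `0` disables the suppression.
#' @param lst logical, simulate a daytime land-surface temperature band.
#' @return An object of class `ftc_simconfig`.
#' @export
sim_config <- function(noise_sd = 0.01, cloud_prob = 0.1, seed = 1L,
                       subgrid_factor = 10L,
                       product_error = list(c(0.05, 0.05), c(0.08, 0.03),
                                            c(0.03, 0.08), c(0.05, 0.02)),
                       tall_dense_threshold = 30, lst = TRUE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (cloud_prob < 0 || cloud_prob > 1) stop("cloud_prob must lie in [0, 1]")
  if (subgrid_factor < 1) stop("subgrid_factor must be >= 1")
  for (pe in product_error)
    if (any(pe < 0 | pe > 1)) stop("product error rates must lie in [0, 1]")
  structure(list(noise_sd = noise_sd, cloud_prob = cloud_prob,
                 seed = as.integer(seed),
                 subgrid_factor = as.integer(subgrid_factor),
                 product_error = product_error,
                 tall_dense_threshold = tall_dense_threshold, lst = lst),
            class = "ftc_simconfig")
}

#' Scene truth definition
#'
#' @param fraction matrix of true tree cover (%, 0..100).
#' @param pheno_shift integer matrix of per-pixel phenology offsets in
#'   composites (-45..45); positive values delay the season.
#' @param pixel_size ground pixel edge in meters (metadata only).
#' @param origin `c(x, y)` upper-left corner coordinate (metadata only).
#' @return An object of class `ftc_truth`.
#' @export
scene_truth <- function(fraction, pheno_shift = NULL,
                        pixel_size = 231.65635826, origin = c(0, 0)) {
  fraction <- as.matrix(fraction)
  if (any(fraction < 0 | fraction > 100, na.rm = TRUE))
    stop("fraction must lie in [0, 100]")
  if (is.null(pheno_shift)) {
    pheno_shift <- matrix(0L, nrow(fraction), ncol(fraction))
  } else {
    pheno_shift <- as.matrix(pheno_shift)
    if (!all(dim(pheno_shift) == dim(fraction)))
      stop("fraction and pheno_shift grids are not conformable")
    if (any(abs(pheno_shift) > 45)) stop("pheno_shift must lie in -45..45")
  }
  structure(list(fraction = fraction, pheno_shift = pheno_shift,
                 rows = nrow(fraction), cols = ncol(fraction),
                 pixel_size = pixel_size, origin = origin),
            class = "ftc_truth")
}

#' Draw a random scene truth
#'
#' Fractions are uniform on the integers 0..100 (integer percent so that
#' quota-based subcell labeling can reproduce them exactly); phenology shifts
#' are uniform integers in `-shift_range..shift_range`.
#'
#' @param rows,cols grid dimensions.
#' @param seed integer seed.
#' @param shift_range maximum absolute phenology shift in composites.
#' @return An `ftc_truth`.
#' @export
random_scene_truth <- function(rows, cols, seed = 1L, shift_range = 11L) {
  set.seed(as.integer(seed))
  fraction <- matrix(sample(0:100, rows * cols, replace = TRUE), rows, cols)
  pheno_shift <- matrix(sample(-shift_range:shift_range, rows * cols,
                               replace = TRUE), rows, cols)
  scene_truth(fraction, pheno_shift)
}

# rotate so the element originally at composite c lands at composite (c+k) mod 46
rotate_composites <- function(x, k) {
  n <- length(x)
  x[((seq_len(n) - 1L - as.integer(k)) %% n) + 1L]
}

# deterministic seasonal LST curve (kelvin), peak aligned with composite 23
lst_curve <- function() {
  cc <- 0:(N_COMPOSITES - 1L)
  270 + 25 * cos(2 * pi * (cc - 23) / N_COMPOSITES)
}

#' Simulate one pixel-year
#'
#' Red, NIR and SWIR2.1 reflectances of the two endmembers are mixed linearly
#' with weight `fraction/100` (area-weighted two-endmember mixing), circularly
#' rotated by the phenology shift, perturbed with Gaussian noise, and masked
#' as cloud independently per composite. NDVI is computed from the mixed
#' (noisy) red/NIR — not by mixing the endmember NDVI curves.
#'
#' @param fraction true tree cover (%, 0..100).
#' @param shift integer phenology offset in composites.
#' @param tree,herb endmember specs ([endmember_spec()]).
#' @param cfg a [sim_config()].
#' @param seed optional integer; when given, seeds the RNG for standalone
#'   reproducibility (scene simulation seeds once and leaves this `NULL`).
#' @return An object of class `ftc_series`: list with `ndvi`, `red`, `nir`,
#'   `swir`, `lst` (or `NULL`) and `qa` (character flags `"clear"`/`"cloud"`).
#' @export
simulate_pixel <- function(fraction, shift = 0L, tree = tree_endmember(),
                           herb = herb_endmember(), cfg = sim_config(),
                           seed = NULL) {
  if (is.na(fraction) || fraction < 0 || fraction > 100)
    stop("fraction must lie in [0, 100]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ct <- endmember_curves(tree)
  ch <- endmember_curves(herb)
  w <- fraction / 100
  red <- (1 - w) * ch$red + w * ct$red
  nir <- (1 - w) * ch$nir + w * ct$nir
  swir <- (1 - w) * ch$swir + w * ct$swir
  red <- rotate_composites(red, shift)
  nir <- rotate_composites(nir, shift)
  swir <- rotate_composites(swir, shift)
  if (cfg$noise_sd > 0) {
    red <- pmin(1, pmax(0, red + stats::rnorm(N_COMPOSITES, 0, cfg$noise_sd)))
    nir <- pmin(1, pmax(0, nir + stats::rnorm(N_COMPOSITES, 0, cfg$noise_sd)))
    swir <- pmin(1, pmax(0, swir + stats::rnorm(N_COMPOSITES, 0, cfg$noise_sd)))
  }
  qa <- rep("clear", N_COMPOSITES)
  if (cfg$cloud_prob > 0)
    qa[stats::runif(N_COMPOSITES) < cfg$cloud_prob] <- "cloud"
  lst <- if (isTRUE(cfg$lst)) rotate_composites(lst_curve(), shift) else NULL
  ftc_series(ndvi = compute_ndvi(red, nir), red = red, nir = nir,
             swir = swir, lst = lst, qa = qa)
}

#' Construct an annual series object
#'
#' @param ndvi,red,nir,swir numeric vectors of length 46 (NA = fill).
#' @param lst optional LST vector (kelvin).
#' @param qa character QA flags, one of `"clear"`, `"cloud"`, `"snow"`,
#'   `"water"`, `"fill"`.
#' @return An object of class `ftc_series`.
#' @export
ftc_series <- function(ndvi, red, nir, swir, lst = NULL,
                       qa = rep("clear", N_COMPOSITES)) {
  for (v in list(ndvi, red, nir, swir, qa))
    if (length(v) != N_COMPOSITES) stop("series arrays must have length 46")
  if (!all(qa %in% c("clear", "cloud", "snow", "water", "fill")))
    stop("unknown QA flag")
  structure(list(ndvi = ndvi, red = red, nir = nir, swir = swir,
                 lst = lst, qa = qa),
            class = "ftc_series")
}

#' Simulate a full scene
#'
#' One [simulate_pixel()] call per grid cell (row-major order) under a single
#' seed taken from `cfg$seed`; identical truth and config give bit-identical
#' output.
#'
#' @param truth an [scene_truth()].
#' @param tree,herb endmember specs.
#' @param cfg a [sim_config()].
#' @return An object of class `ftc_scene`: truth plus `[rows, cols, 46]`
#'   arrays `ndvi`, `red`, `nir`, `swir`, `lst` (optional) and `qa`.
#' @export
simulate_scene <- function(truth, tree = tree_endmember(),
                           herb = herb_endmember(), cfg = sim_config()) {
  stopifnot(inherits(truth, "ftc_truth"))
  if (!all(dim(truth$pheno_shift) == dim(truth$fraction)))
    stop("truth grids are not conformable")
  rows <- truth$rows; cols <- truth$cols
  dims <- c(rows, cols, N_COMPOSITES)
  out <- list(ndvi = array(NA_real_, dims), red = array(NA_real_, dims),
              nir = array(NA_real_, dims), swir = array(NA_real_, dims),
              lst = if (isTRUE(cfg$lst)) array(NA_real_, dims) else NULL,
              qa = array("clear", dims))
  set.seed(cfg$seed)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      s <- simulate_pixel(truth$fraction[i, j], truth$pheno_shift[i, j],
                          tree, herb, cfg, seed = NULL)
      out$ndvi[i, j, ] <- s$ndvi
      out$red[i, j, ] <- s$red
      out$nir[i, j, ] <- s$nir
      out$swir[i, j, ] <- s$swir
      if (!is.null(out$lst)) out$lst[i, j, ] <- s$lst
      out$qa[i, j, ] <- s$qa
    }
  }
  structure(c(list(truth = truth, cfg = cfg), out), class = "ftc_scene")
}

#' Extract the annual series of one scene pixel
#'
#' @param scene an `ftc_scene`.
#' @param i,j row and column index (1-based).
#' @return An `ftc_series`.
#' @export
scene_pixel <- function(scene, i, j) {
  ftc_series(ndvi = scene$ndvi[i, j, ], red = scene$red[i, j, ],
             nir = scene$nir[i, j, ], swir = scene$swir[i, j, ],
             lst = if (!is.null(scene$lst)) scene$lst[i, j, ] else NULL,
             qa = scene$qa[i, j, ])
}

#' Simulate pseudo high-resolution categorical forest products
#'
#' Each 250 m cell is subdivided into `subgrid_factor^2` subcells;
#' `round(fraction * subcells / 100)` of them are labeled tree at seeded
#' random positions (quota labeling, so zero-error aggregation recovers the
#' truth exactly for integer-percent truth). Each product is then perturbed
#' by its omission/commission rates, and the last product suppresses tree
#' labels in cells whose truth fraction is below `tall_dense_threshold`
#' (mimicking a product limited to tall dense canopy; threshold 0 disables).
#'
#' @param truth an [scene_truth()].
#' @param cfg a [sim_config()]; `length(cfg$product_error)` products are made.
#' @return List of binary 0/1 matrices of size
#'   `(rows*factor) x (cols*factor)`.
#' @export
simulate_products <- function(truth, cfg = sim_config()) {
  stopifnot(inherits(truth, "ftc_truth"))
  f <- cfg$subgrid_factor
  if (f < 1) stop("subgrid_factor must be >= 1")
  nsub <- f * f
  rows <- truth$rows; cols <- truth$cols
  nprod <- length(cfg$product_error)
  set.seed((cfg$seed + 777863L) %% .Machine$integer.max)
  products <- vector("list", nprod)
  for (p in seq_len(nprod)) {
    err <- cfg$product_error[[p]]
    m <- matrix(0L, rows * f, cols * f)
    for (i in seq_len(rows)) {
      for (j in seq_len(cols)) {
        frac <- truth$fraction[i, j]
        suppressed <- p == nprod && cfg$tall_dense_threshold > 0 &&
          frac < cfg$tall_dense_threshold
        ntree <- if (suppressed) 0L else as.integer(floor(frac * nsub / 100 + 0.5))
        cell <- integer(nsub)
        if (ntree > 0) cell[sample.int(nsub, ntree)] <- 1L
        if (err[1] > 0)
          cell[cell == 1L & stats::runif(nsub) < err[1]] <- 0L
        if (err[2] > 0)
          cell[cell == 0L & stats::runif(nsub) < err[2]] <- 1L
        m[(i - 1L) * f + seq_len(f), (j - 1L) * f + seq_len(f)] <-
          matrix(cell, f, f)
      }
    }
    products[[p]] <- m
  }
  products
}
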
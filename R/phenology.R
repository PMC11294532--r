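#' @title Growing-season detection and phenological realignment
#' @description Builds a multi-year NDVI reference curve per pixel, detects
#'   the growing season (seasonal or evergreen branch), and circularly
#'   rotates annual series so that the growing-season midpoint falls at
#'   composite 23 (DOY 185-192), the center of the calendar year.
#' @name phenology
NULL

#' Composite at the center of the calendar year (DOY 185-192)
#' @export
CENTER_COMPOSITE <- 23L

#' Multi-year NDVI reference seasonal series
#'
#' Per-composite mean of the smoothed NDVI over all available years,
#' ignoring fill values. Amplitude is `max - min` of the reference curve and
#' the growing-season threshold is `min + amplitude / 2`.
#'
#' @param ndvi_years list of gap-filled annual NDVI vectors (length 46), or
#'   a 46-row matrix with one column per year.
#' @param max_fill maximum number of composites allowed to have no finite
#'   value in any year (default 10); more marks the pixel unusable.
#' @return An object of class `ftc_refphen` with `ref_ndvi`, `amplitude`,
#'   `threshold`, `usable`.
#' @export
reference_series <- function(ndvi_years, max_fill = 10L) {
  m <- if (is.list(ndvi_years)) do.call(cbind, ndvi_years) else as.matrix(ndvi_years)
  if (nrow(m) != N_COMPOSITES) stop("each year must have 46 composites")
  ref <- rowMeans(m, na.rm = TRUE)
  ref[!is.finite(ref)] <- NA_real_
  usable <- sum(is.na(ref)) <= max_fill
  amp <- if (usable) max(ref, na.rm = TRUE) - min(ref, na.rm = TRUE) else NA_real_
  structure(list(ref_ndvi = ref,
                 amplitude = amp,
                 threshold = if (usable) min(ref, na.rm = TRUE) + amp / 2 else NA_real_,
                 usable = usable),
            class = "ftc_refphen")
}

# maximal circular runs of TRUE in a logical vector; returns list of
# c(start, length) with 0-based starts
circular_runs <- function(above) {
  n <- length(above)
  if (all(above)) return(list(c(start = 0L, length = n)))
  if (!any(above)) return(list())
  # rotate so position 1 is FALSE, find linear runs, rotate back
  off <- which(!above)[1] - 1L
  rot <- above[((seq_len(n) - 1L + off) %% n) + 1L]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      runs[[length(runs) + 1L]] <-
        c(start = (starts[k] - 1L + off) %% n, length = r$lengths[k])
    }
  }
  runs
}

# circular mean of 0-based composite indices, in fractional composites
circular_mean_composite <- function(idx, n = N_COMPOSITES) {
  theta <- 2 * pi * idx / n
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  (m / (2 * pi) * n) %% n
}

# round to nearest composite, exact halves toward the smaller index
round_composite <- function(x, n = N_COMPOSITES) {
  as.integer(floor(x + 0.5 - 1e-9)) %% n
}

#' Evergreen growing-season midpoint
#'
#' For low-amplitude (evergreen) pixels the midpoint is the circular mean of
#' the composite indices of the 18 highest reference NDVI values (ties broken
#' by ascending composite index), rounded to the nearest composite with exact
#' halves toward the smaller index. Nearly flat curves (amplitude < 0.02)
#' carry no timing information and map to composite 23 (identity shift).
#'
#' @param ref an [reference_series()] result.
#' @param n_top number of highest values used (default 18).
#' @return Midpoint composite index (0..45).
#' @export
midpoint_evergreen <- function(ref, n_top = 18L) {
  stopifnot(inherits(ref, "ftc_refphen"))
  if (ref$amplitude < 0.02) return(CENTER_COMPOSITE)
  ord <- order(-ref$ref_ndvi, seq_len(N_COMPOSITES))[seq_len(n_top)]
  round_composite(circular_mean_composite(ord - 1L))
}

#' Detect the growing season
#'
#' Pixels with reference NDVI amplitude below `evergreen_amplitude` take the
#' evergreen branch ([midpoint_evergreen()]). Otherwise maximal circular runs
#' of composites with reference NDVI above the half-amplitude threshold are
#' found; with multiple runs the primary season is the run with the highest
#' mean daytime LST when an LST series is available, else the longest run
#' (ties to the earliest start). The midpoint is the central composite of the
#' primary run, `start + floor((length - 1) / 2)` on the circle.
#'
#' @param ref an [reference_series()] result.
#' @param lst optional 46-vector of daytime land-surface temperature.
#' @param evergreen_amplitude NDVI amplitude below which a pixel is treated
#'   as evergreen (default 0.2).
#' @return An object of class `ftc_season` with `evergreen`, `runs`,
#'   `primary_run`, `midpoint`, `run_length`.
#' @export
detect_growing_season <- function(ref, lst = NULL, evergreen_amplitude = 0.2) {
  stopifnot(inherits(ref, "ftc_refphen"))
  if (!ref$usable) stop("reference series unusable (too many fill composites)")
  if (ref$amplitude < evergreen_amplitude) {
    return(structure(list(evergreen = TRUE, runs = list(), primary_run = NULL,
                          midpoint = midpoint_evergreen(ref),
                          run_length = NA_integer_),
                     class = "ftc_season"))
  }
  above <- !is.na(ref$ref_ndvi) & ref$ref_ndvi > ref$threshold
  runs <- circular_runs(above)
  stopifnot(length(runs) >= 1)  # max > threshold whenever amplitude > 0
  primary <- runs[[1]]
  if (length(runs) > 1) {
    if (!is.null(lst)) {
      means <- vapply(runs, function(r) {
        comps <- (r["start"] + 0:(r["length"] - 1L)) %% N_COMPOSITES
        mean(lst[comps + 1L], na.rm = TRUE)
      }, numeric(1))
      primary <- runs[[which.max(means)]]
    } else {
      lens <- vapply(runs, `[`, numeric(1), "length")
      starts <- vapply(runs, `[`, numeric(1), "start")
      best <- which(lens == max(lens))
      primary <- runs[[best[which.min(starts[best])]]]
    }
  }
  midpoint <- (primary["start"] + (primary["length"] - 1L) %/% 2L) %% N_COMPOSITES
  structure(list(evergreen = FALSE, runs = runs, primary_run = primary,
                 midpoint = as.integer(midpoint),
                 run_length = as.integer(primary["length"])),
            class = "ftc_season")
}

#' Realign an annual series to the common phenology
#'
#' Circularly rotates every band so that the element at the growing-season
#' midpoint composite lands at composite 23 (DOY 185-192). Rotation is a
#' permutation: the value multiset of every band is preserved.
#'
#' @param s an [ftc_series()].
#' @param midpoint midpoint composite index (0..45), e.g. from
#'   [detect_growing_season()].
#' @return An object of class `ftc_realigned`: `series` (rotated
#'   `ftc_series`), `shift` (signed composite offset in -22..23),
#'   `center_composite` (always 23).
#' @export
realign <- function(s, midpoint) {
  stopifnot(inherits(s, "ftc_series"))
  midpoint <- as.integer(midpoint)
  if (midpoint < 0 || midpoint > 45) stop("midpoint must lie in 0..45")
  k <- (CENTER_COMPOSITE - midpoint) %% N_COMPOSITES
  for (band in c("ndvi", "red", "nir", "swir"))
    s[[band]] <- rotate_composites(s[[band]], k)
  if (!is.null(s$lst)) s$lst <- rotate_composites(s$lst, k)
  s$qa <- rotate_composites(s$qa, k)
  structure(list(series = s,
                 shift = if (k > 23L) k - N_COMPOSITES else k,
                 center_composite = CENTER_COMPOSITE),
            class = "ftc_realigned")
}
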
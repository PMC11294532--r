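#' @title Phase-by-band feature extraction
#' @description Twelve predictors read from a realigned annual series at four
#'   temporal phases: the annual NDVI maximum, the annual NDVI minimum, and
#'   fixed composites about one and a half months before and after the
#'   growing-season midpoint.
#' @name features
NULL

#' Pre- and post-midpoint phase composites (DOY 137-144 and DOY 233-240)
#' @export
GROW_LEFT_COMPOSITE <- 17L
#' @rdname GROW_LEFT_COMPOSITE
#' @export
GROW_RIGHT_COMPOSITE <- 29L

#' Canonical feature names
#'
#' Order: phases (NDVI maximum, NDVI minimum, grow-left, grow-right) crossed
#' with bands (NDVI, red, SWIR2.1).
#'
#' @return Character vector of the 12 names.
#' @export
feature_names <- function() {
  as.vector(t(outer(c("ndvi_max", "ndvi_min", "grow_left", "grow_right"),
                    c("ndvi", "red", "swir"), paste, sep = ".")))
}

#' Locate the four feature-extraction phases
#'
#' On a realigned series: the composite of the annual NDVI maximum, the
#' composite of the annual NDVI minimum (ties at either extremum break to the
#' earliest composite), and the fixed pre/post-midpoint composites 17 and 29
#' (DOY 137-144 and 233-240; the midpoint itself always sits at composite 23
#' after realignment).
#'
#' @param r an [realign()] result (or an `ftc_series` already realigned).
#' @return An object of class `ftc_phases`: `c_ndvimax`, `c_ndvimin`,
#'   `c_left`, `c_right` (0-based composite indices).
#' @export
locate_phases <- function(r) {
  s <- if (inherits(r, "ftc_realigned")) r$series else r
  stopifnot(inherits(s, "ftc_series"))
  if (any(!is.finite(s$ndvi))) stop("realigned NDVI must be gap-free")
  structure(list(c_ndvimax = which.max(s$ndvi) - 1L,
                 c_ndvimin = which.min(s$ndvi) - 1L,
                 c_left = GROW_LEFT_COMPOSITE,
                 c_right = GROW_RIGHT_COMPOSITE),
            class = "ftc_phases")
}

#' Extract the twelve phase-by-band features
#'
#' Reads NDVI, red and SWIR2.1 at the four phase composites of a realigned
#' series, in the canonical order of [feature_names()].
#'
#' @param r an [realign()] result (or a realigned `ftc_series`).
#' @param p an [locate_phases()] result; located from `r` when omitted.
#' @return Named numeric vector of length 12.
#' @export
extract_features <- function(r, p = NULL) {
  s <- if (inherits(r, "ftc_realigned")) r$series else r
  stopifnot(inherits(s, "ftc_series"))
  if (is.null(p)) p <- locate_phases(s)
  stopifnot(inherits(p, "ftc_phases"))
  comps <- c(p$c_ndvimax, p$c_ndvimin, p$c_left, p$c_right) + 1L
  vals <- as.vector(t(cbind(s$ndvi[comps], s$red[comps], s$swir[comps])))
  if (any(!is.finite(vals))) stop("fill value at a phase composite; pixel rejected")
  stats::setNames(vals, feature_names())
}
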
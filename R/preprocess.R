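#' @title Preprocessing of annual composite series
#' @description QA masking, NDVI computation, periodic gap filling and
#'   upper-envelope smoothing, and coarse-band co-registration.
#' @name preprocess
NULL

#' Compute NDVI from red and NIR reflectance
#'
#' `(NIR - red) / (NIR + red)`, clipped to `[-1, 1]`. Non-finite inputs or a
#' zero denominator yield NA (fill).
#'
#' @param red,nir reflectance in `[0, 1]` (vectors recycle as usual).
#' @return NDVI values in `[-1, 1]` or NA.
#' @export
compute_ndvi <- function(red, nir) {
  denom <- nir + red
  out <- ifelse(is.finite(denom) & denom > 0, (nir - red) / denom, NA_real_)
  pmin(1, pmax(-1, out))
}

#' Mask non-clear composites
#'
#' Sets every band value at composites whose QA flag is not `"clear"` to NA
#' (fill); clear composites pass through bit-exactly. The count of clear
#' composites is stored in the returned series as `clear_count`.
#'
#' @param s an [ftc_series()].
#' @return The masked `ftc_series` with a `clear_count` element.
#' @export
mask_series <- function(s) {
  stopifnot(inherits(s, "ftc_series"))
  bad <- s$qa != "clear"
  for (band in c("ndvi", "red", "nir", "swir"))
    s[[band]][bad] <- NA_real_
  if (!is.null(s$lst)) s$lst[bad] <- NA_real_
  s$clear_count <- sum(!bad)
  s
}

# circulant low-pass projection row (Dirichlet kernel) for harmonics <= H
dirichlet_row <- function(n = N_COMPOSITES, H = 16L) {
  d <- 0:(n - 1L)
  vapply(d, function(dd) (1 + 2 * sum(cos(2 * pi * (1:H) * dd / n))) / n,
         numeric(1))
}

# exact-circulant matvec: identical summation order for every output index,
# which makes the operator bit-exactly equivariant under circular shifts
circulant_apply <- function(s_row, y) {
  n <- length(y)
  vapply(0:(n - 1L), function(i) sum(s_row[((0:(n - 1L) - i) %% n) + 1L] * y),
         numeric(1))
}

#' Circular linear interpolation across gaps
#'
#' Fills NA entries of a periodic series by linear interpolation between the
#' nearest finite neighbors on the circle.
#'
#' @param x numeric vector with NA gaps; at least one finite value.
#' @return Gap-free numeric vector.
#' @export
interp_gaps <- function(x) {
  n <- length(x)
  keep <- is.finite(x)
  if (all(keep)) return(x)
  if (!any(keep)) stop("no finite values to interpolate from")
  idx <- which(keep)
  out <- x
  for (i in which(!keep)) {
    dl <- (i - idx) %% n   # distance going left (backwards) to a kept point
    dr <- (idx - i) %% n   # distance going right
    l <- idx[which.min(dl)]; r <- idx[which.min(dr)]
    dlv <- min(dl); drv <- min(dr)
    out[i] <- (x[l] * drv + x[r] * dlv) / (dlv + drv)
  }
  out
}

#' Gap-fill and smooth an NDVI series toward its upper envelope
#'
#' Iterative upper-envelope smoother for periodic 46-composite NDVI series:
#' gaps are bridged by circular linear interpolation, the series is projected
#' onto the first `harmonics` Fourier harmonics (an exactly periodic,
#' shift-equivariant low-pass fit), observations falling more than `margin`
#' below the fit are discarded as cloud-dark outliers, and milder negative
#' residuals are raised to the fit ("capping" toward the upper envelope).
#' Iteration stops when no new outlier is found and the largest capping
#' adjustment is below `tol`, or after `max_iter` passes.
#'
#' @param ndvi numeric vector of length 46 with NA at fill composites.
#' @param harmonics number of Fourier harmonics retained (default 16).
#' @param margin NDVI drop below the fit that classifies an observation as a
#'   dark outlier (default 0.05).
#' @param tol convergence threshold on the capping adjustment (default 0.005
#'   NDVI).
#' @param max_iter maximum number of capping passes (default 10).
#' @param min_clear minimum clear composites required (default 8); fewer is
#'   an error (the pixel is unusable).
#' @return Gap-free smoothed NDVI vector of length 46.
#' @export
fill_smooth <- function(ndvi, harmonics = 16L, margin = 0.05, tol = 0.005,
                        max_iter = 10L, min_clear = 8L) {
  if (length(ndvi) != N_COMPOSITES) stop("ndvi must have length 46")
  keep <- is.finite(ndvi)
  if (sum(keep) < min_clear)
    stop("fewer than ", min_clear, " clear composites; pixel unusable")
  s_row <- dirichlet_row(N_COMPOSITES, harmonics)
  obs <- ndvi
  fit <- NULL
  for (it in seq_len(max_iter)) {
    work <- obs
    work[!keep] <- NA_real_
    work <- interp_gaps(work)
    fit <- circulant_apply(s_row, work)
    resid <- work - fit
    newdrop <- keep & (resid < -margin)
    # never drop below the usability floor
    if (sum(keep) - sum(newdrop) >= min_clear) keep[newdrop] <- FALSE
    else newdrop[] <- FALSE
    raise <- keep & (resid < 0)
    change <- if (any(raise)) max(-resid[raise]) else 0
    obs[raise] <- fit[raise]
    if (!any(newdrop) && change < tol) break
  }
  fit
}

#' Duplicate a 2x coarser grid to the target resolution
#'
#' Nearest-neighbor duplication: each coarse cell populates its 2x2 block of
#' fine cells; the result is cropped to `target_dim` when the target has odd
#' dimensions.
#'
#' @param coarse numeric matrix at 2x coarser resolution.
#' @param target_dim `c(rows, cols)` of the target grid; defaults to
#'   `2 * dim(coarse)`.
#' @return Matrix of dimensions `target_dim`.
#' @export
upsample_coarse_band <- function(coarse, target_dim = NULL) {
  coarse <- as.matrix(coarse)
  if (is.null(target_dim)) target_dim <- 2L * dim(coarse)
  if (any(dim(coarse) != ceiling(target_dim / 2)))
    stop("coarse grid dimensions must equal ceiling(target/2)")
  fine <- coarse[rep(seq_len(nrow(coarse)), each = 2L),
                 rep(seq_len(ncol(coarse)), each = 2L), drop = FALSE]
  fine[seq_len(target_dim[1]), seq_len(target_dim[2]), drop = FALSE]
}

#' Preprocess one annual series
#'
#' Masks non-clear composites, smooths NDVI toward its upper envelope and
#' fills red/NIR/SWIR (and LST) gaps by circular linear interpolation.
#'
#' @param s an [ftc_series()].
#' @param min_clear minimum usable clear composites (default 8).
#' @return The processed `ftc_series` (all bands gap-free, `clear_count`
#'   set), or `NULL` when the pixel has too few clear composites.
#' @export
preprocess_series <- function(s, min_clear = 8L) {
  s <- mask_series(s)
  if (s$clear_count < min_clear) return(NULL)
  s$ndvi <- fill_smooth(s$ndvi, min_clear = min_clear)
  for (band in c("red", "nir", "swir"))
    s[[band]] <- interp_gaps(s[[band]])
  if (!is.null(s$lst)) s$lst <- interp_gaps(s$lst)
  s
}
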
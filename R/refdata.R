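#' @title Training-reference construction from categorical forest maps
#' @description Aggregates fine-resolution binary tree/non-tree maps to
#'   fractional cover on the analysis grid, combines several products into a
#'   per-pixel mean reference (TC_RefMean) with a per-pixel agreement score
#'   (MAE_Ref), applies reliability exclusions, and balances the training
#'   sample histogram.
#' @name refdata
NULL

#' Aggregate a binary map to fractional cover
#'
#' Computes, for each analysis cell, the percentage of tree-labeled subcells
#' among its valid (non-NA) subcells. Cells with fewer than half their
#' subcells valid are set to NA.
#'
#' @param binary 0/1 (tree/non-tree) matrix, NA = invalid, with dimensions
#'   `factor * c(rows, cols)` of the target grid.
#' @param factor subcells per target cell edge.
#' @return Matrix of tree-cover percentages (0..100) on the target grid.
#' @export
aggregate_categorical <- function(binary, factor) {
  binary <- as.matrix(binary)
  factor <- as.integer(factor)
  if (any(dim(binary) %% factor != 0))
    stop("binary map dimensions must be multiples of factor")
  rows <- nrow(binary) %/% factor
  cols <- ncol(binary) %/% factor
  a <- array(binary, dim = c(factor, rows, factor, cols))
  valid <- apply(!is.na(a), c(2, 4), sum)
  trees <- apply(a, c(2, 4), sum, na.rm = TRUE)
  out <- ifelse(valid >= factor * factor / 2, trees / valid * 100, NA_real_)
  matrix(out, rows, cols)
}

#' Combine aggregated products into a reference cover set
#'
#' Per-pixel mean across products (`tc_ref_mean`) and per-pixel mean absolute
#' deviation of the products from that mean (`mae_ref`). Pixels where any
#' product is NA are NA in both outputs.
#'
#' @param fractions list of at least two conformable fraction matrices (%).
#' @return An object of class `ftc_refcover`: `product_fractions`,
#'   `tc_ref_mean`, `mae_ref`.
#' @export
combine_products <- function(fractions) {
  if (length(fractions) < 2) stop("at least two products are required")
  d <- dim(fractions[[1]])
  for (f in fractions) if (!all(dim(f) == d)) stop("products are not conformable")
  stack <- array(unlist(fractions), dim = c(d, length(fractions)))
  tc_mean <- apply(stack, c(1, 2), mean)
  mae <- apply(abs(sweep(stack, c(1, 2), tc_mean)), c(1, 2), mean)
  structure(list(product_fractions = fractions,
                 tc_ref_mean = tc_mean, mae_ref = mae),
            class = "ftc_refcover")
}

#' Reliability exclusions for training pixels
#'
#' A pixel is excluded when the products disagree (`mae_ref > mae_max`,
#' strictly greater so the boundary is retained), when the year has fewer
#' than `min_clear` clear-sky composites, when a seasonal (non-evergreen)
#' pixel has a growing season shorter than `min_season` composites, or when
#' its land-cover class is water, permanent snow/ice, or barren.
#'
#' @param ref an [combine_products()] result.
#' @param clear_counts matrix of clear-composite counts.
#' @param season_length matrix of primary-run lengths in composites (NA for
#'   evergreen pixels).
#' @param evergreen logical matrix of evergreen flags.
#' @param landcover optional character matrix; classes `"water"`,
#'   `"snow_ice"`, `"barren"` are excluded.
#' @param mae_max MAE_Ref exclusion threshold in percent (default 10).
#' @param min_clear minimum clear observations (default 25).
#' @param min_season minimum season length in composites (default 12,
#'   i.e. 96 days, the nearest whole-composite reading of three months).
#' @return Logical matrix: TRUE where the pixel is retained.
#' @export
apply_exclusions <- function(ref, clear_counts, season_length, evergreen,
                             landcover = NULL, mae_max = 10,
                             min_clear = 25L, min_season = 12L) {
  stopifnot(inherits(ref, "ftc_refcover"))
  valid <- is.finite(ref$mae_ref) & ref$mae_ref <= mae_max
  valid <- valid & clear_counts >= min_clear
  seasonal_ok <- evergreen | (is.finite(season_length) & season_length >= min_season)
  valid <- valid & seasonal_ok
  if (!is.null(landcover))
    valid <- valid & !(landcover %in% c("water", "snow_ice", "barren"))
  valid & is.finite(ref$tc_ref_mean)
}

#' Balance a training sample across tree-cover bins
#'
#' Targets are binned to the 101 integer percent bins (round half up). The
#' 0% and 100% bins are down-sampled uniformly at random to their caps; all
#' other bins are retained in full. Rows are never altered, only membership.
#'
#' @param candidates data frame with a `target` column (%, 0..100) plus
#'   feature columns and a pixel id.
#' @param cap0,cap100 maximum rows kept in the 0% and 100% bins (default
#'   `Inf`, no capping).
#' @param seed integer seed for the down-sampling draws.
#' @return An object of class `ftc_training`: `data` (the retained rows),
#'   `bin_counts` (named integer vector over bins 0..100), `seed`.
#' @export
balance_samples <- function(candidates, cap0 = Inf, cap100 = Inf, seed = 1L) {
  if (cap0 < 0 || cap100 < 0) stop("caps must be >= 0")
  if (!"target" %in% names(candidates)) stop("candidates must have a target column")
  bin <- floor(candidates$target + 0.5)
  if (any(bin < 0 | bin > 100)) stop("targets must lie in [0, 100]")
  set.seed(as.integer(seed))
  keep <- rep(TRUE, nrow(candidates))
  for (spec in list(list(b = 0, cap = cap0), list(b = 100, cap = cap100))) {
    rows <- which(bin == spec$b)
    if (length(rows) > spec$cap)
      keep[setdiff(rows, sample(rows, spec$cap))] <- FALSE
  }
  data <- candidates[keep, , drop = FALSE]
  counts <- table(factor(bin[keep], levels = 0:100))
  structure(list(data = data,
                 bin_counts = stats::setNames(as.integer(counts), names(counts)),
                 seed = as.integer(seed)),
            class = "ftc_training")
}
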
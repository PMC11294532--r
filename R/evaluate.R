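#' @title Stratified accuracy assessment and product comparison
#' @description Inclusion-probability-weighted error metrics for validation
#'   samples drawn by stratified random sampling, ordinary least-squares
#'   agreement statistics, reference-range subsetting, and per-pixel mean
#'   difference between cover products.
#' @name evaluate
NULL

#' Per-sample inclusion-probability weights
#'
#' Each sample in stratum `h` receives weight `omega = K_h / k_h`, the
#' inverse of its inclusion probability, where `K_h` and `k_h` are the
#' stratum population and sample sizes.
#'
#' @param K numeric vector of per-stratum population sizes.
#' @param k numeric vector of per-stratum sample sizes (>= 1).
#' @param assignment integer vector mapping each sample to its stratum.
#' @return Numeric vector of weights, one per sample.
#' @export
stratum_weights <- function(K, k, assignment = NULL) {
  if (length(K) != length(k)) stop("K and k must have equal length")
  if (any(k < 1)) stop("every sampled stratum needs k_h >= 1")
  if (any(K < k)) stop("population size K_h must be >= sample size k_h")
  w <- K / k
  if (is.null(assignment)) w else w[assignment]
}

#' Weighted error metrics
#'
#' `MAE = sum(w |pre - ref|) / sum(w)`,
#' `RMSE = sqrt(sum(w (pre - ref)^2) / sum(w))`,
#' `ME = sum(w (pre - ref)) / sum(w)`.
#'
#' @param pre predicted tree cover (%).
#' @param ref reference tree cover (%).
#' @param w positive weights (default all 1, the unweighted case).
#' @return Named list with `MAE`, `RMSE`, `ME`.
#' @export
weighted_metrics <- function(pre, ref, w = rep(1, length(pre))) {
  if (length(pre) == 0) stop("empty input")
  if (length(ref) != length(pre) || length(w) != length(pre))
    stop("pre, ref and w must have equal length")
  if (any(w <= 0)) stop("weights must be positive")
  d <- pre - ref
  sw <- sum(w)
  list(MAE = sum(w * abs(d)) / sw,
       RMSE = sqrt(sum(w * d^2) / sw),
       ME = sum(w * d) / sw)
}

#' Agreement regression
#'
#' Ordinary least squares of the reference on the prediction; `R2` is the
#' squared Pearson correlation (unweighted, reported alongside the weighted
#' error metrics).
#'
#' @param pre predicted tree cover (%), at least 3 values with nonzero
#'   variance.
#' @param ref reference tree cover (%).
#' @return Named list with `R2`, `slope`, `intercept`, `n`.
#' @export
r_squared <- function(pre, ref) {
  if (length(pre) < 3) stop("need at least 3 samples")
  if (stats::sd(pre) == 0) stop("zero variance in predictions")
  fit <- stats::lm(ref ~ pre)
  list(R2 = stats::cor(pre, ref)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(pre))
}

#' Subset paired samples by reference cover range
#'
#' Retains samples whose reference value lies in `[lo, hi]` (inclusive);
#' selection is by the reference value, not the prediction.
#'
#' @param samples data frame with columns `pre`, `ref` (and optionally `w`).
#' @param lo,hi range bounds in percent, `lo < hi`.
#' @return The subset data frame (warns when empty).
#' @export
subset_range <- function(samples, lo = 15, hi = 95) {
  if (lo >= hi) stop("lo must be < hi")
  out <- samples[samples$ref >= lo & samples$ref <= hi, , drop = FALSE]
  if (nrow(out) == 0) warning("no samples in the requested reference range")
  out
}

#' Full accuracy report
#'
#' Bundles the weighted error metrics and the agreement regression for a set
#' of paired validation samples.
#'
#' @param pre,ref predicted and reference tree cover (%).
#' @param w weights (default unweighted).
#' @return An object of class `ftc_accuracy` with `MAE`, `RMSE`, `ME`,
#'   `R2`, `slope`, `intercept`, `n`.
#' @export
accuracy_report <- function(pre, ref, w = rep(1, length(pre))) {
  m <- weighted_metrics(pre, ref, w)
  r <- r_squared(pre, ref)
  structure(c(m, r), class = "ftc_accuracy")
}

#' @export
print.ftc_accuracy <- function(x, ...) {
  cat(sprintf("Accuracy over n = %d samples:\n", x$n))
  cat(sprintf("  MAE  %6.2f %%\n  RMSE %6.2f %%\n  ME   %6.2f %%\n",
              x$MAE, x$RMSE, x$ME))
  cat(sprintf("  R2   %6.3f   slope %.3f   intercept %.2f\n",
              x$R2, x$slope, x$intercept))
  invisible(x)
}

#' Per-pixel mean difference between two cover products
#'
#' `MD_i = sum_y (A[i, y] - B[i, y]) / Y_i` over the years where both stacks
#' are valid at pixel `i`; pixels with no shared valid year are NA.
#'
#' @param A,B arrays `rows x cols x years` of tree cover (%); the third
#'   dimension is matched by `dimnames` year labels when both carry them,
#'   else positionally (equal year counts required).
#' @return Matrix of mean differences (%).
#' @export
mean_difference <- function(A, B) {
  ya <- dimnames(A)[[3]]; yb <- dimnames(B)[[3]]
  if (!is.null(ya) && !is.null(yb)) {
    shared <- intersect(ya, yb)
    if (length(shared) == 0) stop("no shared years")
    A <- A[, , shared, drop = FALSE]
    B <- B[, , shared, drop = FALSE]
  } else if (dim(A)[3] != dim(B)[3]) {
    stop("year dimensions differ and no year labels are available")
  }
  if (!all(dim(A)[1:2] == dim(B)[1:2])) stop("pixel grids differ")
  d <- A - B
  valid <- is.finite(A) & is.finite(B)
  d[!valid] <- NA_real_
  n <- apply(valid, c(1, 2), sum)
  md <- apply(d, c(1, 2), function(v) sum(v, na.rm = TRUE))
  out <- ifelse(n > 0, md / n, NA_real_)
  matrix(out, nrow(md), ncol(md))
}
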
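#' @title Scene-level pipeline
#' @description Drives the per-pixel chain - masking, smoothing, growing
#'   season detection, realignment, feature extraction - over a whole scene,
#'   builds the training reference from simulated categorical products, and
#'   runs the end-to-end estimation experiment used for verification.
#' @name pipeline
NULL

#' Process a scene into realigned features
#'
#' Runs, for every pixel: QA masking, upper-envelope NDVI smoothing and band
#' gap filling, growing-season detection on the (single-year) reference
#' curve, realignment to composite 23, phase location and extraction of the
#' twelve features. Pixels with fewer than `min_clear` clear composites are
#' left NA throughout.
#'
#' @param scene an [simulate_scene()] result (or compatible structure).
#' @param min_clear minimum usable clear composites per pixel (default 8).
#' @return An object of class `ftc_processed`: `features`
#'   (`n_pixels x 12` matrix, row order column-major over the grid),
#'   `max_ndvi`, `clear_counts`, `season_length`, `evergreen`, `shift`,
#'   `usable` (grids), and `dim`.
#' @export
process_scene <- function(scene, min_clear = 8L) {
  rows <- dim(scene$ndvi)[1]; cols <- dim(scene$ndvi)[2]
  npix <- rows * cols
  features <- matrix(NA_real_, npix, 12L,
                     dimnames = list(NULL, feature_names()))
  max_ndvi <- matrix(NA_real_, rows, cols)
  clear_counts <- matrix(0L, rows, cols)
  season_length <- matrix(NA_integer_, rows, cols)
  evergreen <- matrix(NA, rows, cols)
  shift <- matrix(NA_integer_, rows, cols)
  usable <- matrix(FALSE, rows, cols)
  for (j in seq_len(cols)) {
    for (i in seq_len(rows)) {
      s <- mask_series(scene_pixel(scene, i, j))
      clear_counts[i, j] <- s$clear_count
      if (s$clear_count < min_clear) next
      s$ndvi <- fill_smooth(s$ndvi, min_clear = min_clear)
      for (band in c("red", "nir", "swir"))
        s[[band]] <- interp_gaps(s[[band]])
      if (!is.null(s$lst)) s$lst <- interp_gaps(s$lst)
      ref <- reference_series(s$ndvi)
      season <- detect_growing_season(ref, lst = s$lst)
      evergreen[i, j] <- season$evergreen
      season_length[i, j] <- season$run_length
      r <- realign(s, season$midpoint)
      shift[i, j] <- r$shift
      fv <- extract_features(r)
      features[(j - 1L) * rows + i, ] <- fv
      max_ndvi[i, j] <- max(r$series$ndvi)
      usable[i, j] <- TRUE
    }
  }
  structure(list(features = features, max_ndvi = max_ndvi,
                 clear_counts = clear_counts, season_length = season_length,
                 evergreen = evergreen, shift = shift, usable = usable,
                 dim = c(rows, cols)),
            class = "ftc_processed")
}

#' Build a training set from a scene and simulated products
#'
#' Simulates the categorical products, aggregates them to fractional cover,
#' combines them into the TC_RefMean/MAE_Ref reference, applies the
#' reliability exclusions, pairs retained pixels with their features, and
#' balances the 0%/100% bins.
#'
#' @param processed an [process_scene()] result.
#' @param scene the scene (for its truth and simulation config).
#' @param cap0,cap100 balancing caps (default `Inf`).
#' @param seed balancing seed.
#' @param landcover optional land-cover class matrix for exclusions.
#' @return List: `training` (an `ftc_training`), `ref` (the
#'   `ftc_refcover`), `valid` (exclusion mask), `candidates`.
#' @export
build_training <- function(processed, scene, cap0 = Inf, cap100 = Inf,
                           seed = 1L, landcover = NULL) {
  products <- simulate_products(scene$truth, scene$cfg)
  fracs <- lapply(products, aggregate_categorical,
                  factor = scene$cfg$subgrid_factor)
  ref <- combine_products(fracs)
  valid <- apply_exclusions(ref, processed$clear_counts,
                            processed$season_length, processed$evergreen,
                            landcover = landcover)
  keep <- as.vector(valid) & as.vector(processed$usable) &
    apply(is.finite(processed$features), 1, all)
  candidates <- data.frame(processed$features[keep, , drop = FALSE],
                           check.names = FALSE)
  candidates$target <- as.vector(ref$tc_ref_mean)[keep]
  candidates$pixel_id <- which(keep)
  training <- balance_samples(candidates, cap0 = cap0, cap100 = cap100,
                              seed = seed)
  list(training = training, ref = ref, valid = valid,
       candidates = candidates)
}

#' End-to-end estimation experiment on a synthetic scene
#'
#' Simulates a scene with known truth, processes it, builds the training
#' reference from the pseudo categorical products, trains the network on a
#' random pixel split, predicts the held-out pixels, applies the
#' postprocessing mask, and scores the predictions against the simulation
#' truth.
#'
#' @param rows,cols scene dimensions.
#' @param seed master seed for truth, scene, training and the split.
#' @param cfg simulation configuration (defaults to [sim_config()] with
#'   this seed).
#' @param holdout fraction of usable pixels held out for scoring.
#' @param spec network architecture (default full-size [network_spec()]).
#' @param epochs maximum training epochs.
#' @return List with `report` (an `ftc_accuracy`), `spearman` (rank
#'   correlation of held-out predictions and truth), `model`, `n_train`,
#'   `n_test`, `pred`, `truth`.
#' @export
run_experiment <- function(rows = 64L, cols = 64L, seed = 1L, cfg = NULL,
                           holdout = 0.25, spec = network_spec(),
                           epochs = 60L) {
  seed <- as.integer(seed)
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  truth <- random_scene_truth(rows, cols, seed = seed)
  scene <- simulate_scene(truth, cfg = cfg)
  processed <- process_scene(scene)
  built <- build_training(processed, scene, seed = seed)
  df <- built$training$data
  set.seed(seed + 101L)
  n <- nrow(df)
  test_rows <- sample.int(n, max(1L, floor(holdout * n)))
  train_df <- df[-test_rows, , drop = FALSE]
  test_df <- df[test_rows, , drop = FALSE]
  model <- train_network(build_network(spec, seed = seed),
                         as.matrix(train_df[, feature_names()]),
                         train_df$target, epochs = epochs, seed = seed)
  pred <- predict(model, as.matrix(test_df[, feature_names()]))
  # postprocessing mask on the held-out pixels
  max_ndvi <- as.vector(processed$max_ndvi)[test_df$pixel_id]
  pred <- as.vector(postprocess(matrix(pred), matrix(max_ndvi)))
  truth_frac <- as.vector(scene$truth$fraction)[test_df$pixel_id]
  report <- accuracy_report(pred, truth_frac)
  list(report = report,
       spearman = stats::cor(pred, truth_frac, method = "spearman"),
       model = model, n_train = nrow(train_df), n_test = length(pred),
       pred = pred, truth = truth_frac)
}
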
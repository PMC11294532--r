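# shared fixtures: noise-free configuration and a one-pixel processing chain

noise_free_cfg <- function(seed = 1L) {
  sim_config(noise_sd = 0, cloud_prob = 0, seed = seed)
}

zero_error_cfg <- function(seed = 1L, subgrid_factor = 10L) {
  sim_config(noise_sd = 0, cloud_prob = 0, seed = seed,
             subgrid_factor = subgrid_factor,
             product_error = list(c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
             tall_dense_threshold = 0)
}

# mask -> smooth -> detect -> realign -> features for a single pixel
process_pixel <- function(s) {
  p <- preprocess_series(s)
  gs <- detect_growing_season(reference_series(p$ndvi), lst = p$lst)
  realign(p, gs$midpoint)
}

pixel_features <- function(s) extract_features(process_pixel(s))

# double logistic evaluated directly (independent of endmember_curves)
double_logistic <- function(cc, vmin, vmax, gu, sen, su, sd) {
  l1 <- 1 / (1 + exp(-su * (cc - gu)))
  l2 <- 1 / (1 + exp(-sd * (sen - cc)))
  vmin + (vmax - vmin) * (l1 + l2 - 1)
}

# naive loop oracle for the weighted error metrics
loop_metrics <- function(pre, ref, w) {
  sa <- 0; sq <- 0; sm <- 0; sw <- 0
  for (i in seq_along(pre)) {
    d <- pre[i] - ref[i]
    sa <- sa + w[i] * abs(d)
    sq <- sq + w[i] * d^2
    sm <- sm + w[i] * d
    sw <- sw + w[i]
  }
  list(MAE = sa / sw, RMSE = sqrt(sq / sw), ME = sm / sw)
}
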
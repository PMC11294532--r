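test_that("the default architecture builds the published layer widths", {
  net <- build_network(network_spec(), seed = 1)
  shapes <- lapply(net$W, dim)
  expect_equal(shapes,
               list(c(12L, 400L), c(400L, 200L), c(200L, 100L),
                    c(100L, 50L), c(50L, 25L), c(25L, 1L)))
  net2 <- build_network(network_spec(), seed = 1)
  expect_identical(net$W, net2$W)
  small <- build_network(network_spec(hidden = 2L), seed = 1)
  expect_equal(lapply(small$W, dim), list(c(12L, 2L), c(2L, 1L)))
  expect_error(network_spec(hidden = c(4, 0)), "widths")
})

test_that("training refuses degenerate input sizes", {
  X <- matrix(rnorm(50 * 12), 50, 12)
  expect_error(train_network(build_network(network_spec(hidden = 4)), X,
                             rep(50, 50)),
               "at least 100")
})

test_that("a constant target is fit to within 1%", {
  # feature vectors of noise-free mixtures at random fractions, all labeled 40
  set.seed(2)
  fracs <- runif(500, 0, 100)
  X <- t(vapply(fracs,
                function(f) pixel_features(simulate_pixel(f, 0,
                                                          cfg = noise_free_cfg())),
                numeric(12)))
  m <- train_network(build_network(network_spec(hidden = c(16, 8))), X,
                     rep(40, 500), epochs = 1000, batch_size = 64, lr = 0.02,
                     patience = 50, seed = 2)
  p <- predict(m, X)
  expect_true(all(abs(p - 40) < 1))
})

test_that("training is reproducible under a fixed seed", {
  set.seed(3)
  X <- matrix(rnorm(300 * 12), 300, 12)
  y <- pmin(100, pmax(0, 50 + 30 * X[, 1]))
  spec <- network_spec(hidden = c(8, 4))
  m1 <- train_network(build_network(spec), X, y, epochs = 5, seed = 9)
  m2 <- train_network(build_network(spec), X, y, epochs = 5, seed = 9)
  expect_identical(m1$net$W, m2$net$W)
  expect_identical(predict(m1, X), predict(m2, X))
})

test_that("the network inverts noise-free linear mixing to a few percent", {
  # features of noise-free two-endmember mixtures, computed directly from
  # the endmember curves (already phenology-aligned, shift 0)
  set.seed(42)
  n <- 50000
  f <- runif(n, 0, 100)
  ct <- endmember_curves(tree_endmember())
  ch <- endmember_curves(herb_endmember())
  w <- f / 100
  red <- outer(1 - w, ch$red) + outer(w, ct$red)
  nir <- outer(1 - w, ch$nir) + outer(w, ct$nir)
  swir <- outer(1 - w, ch$swir) + outer(w, ct$swir)
  ndvi <- (nir - red) / (nir + red)
  cmax <- max.col(ndvi, "first"); cmin <- max.col(-ndvi, "first")
  X <- matrix(NA_real_, n, 12)
  idx <- cbind(seq_len(n), cmax)
  X[, 1] <- ndvi[idx]; X[, 2] <- red[idx]; X[, 3] <- swir[idx]
  idx <- cbind(seq_len(n), cmin)
  X[, 4] <- ndvi[idx]; X[, 5] <- red[idx]; X[, 6] <- swir[idx]
  X[, 7] <- ndvi[, 18]; X[, 8] <- red[, 18]; X[, 9] <- swir[, 18]
  X[, 10] <- ndvi[, 30]; X[, 11] <- red[, 30]; X[, 12] <- swir[, 30]
  holdout <- sample(n, 5000)
  model <- train_network(build_network(network_spec()),
                         X[-holdout, ], f[-holdout], seed = 1, epochs = 40)
  pred <- predict(model, X[holdout, ])
  expect_lt(mean(abs(pred - f[holdout])), 5)
  # monotone consistency along the mixing path
  expect_gt(cor(pred, f[holdout], method = "spearman"), 0.99)
})

test_that("predictions are clipped, deterministic, and NA-propagating", {
  # hand-built identity-ish model: one linear path from feature 1
  spec <- network_spec(hidden = 1L, input = 12L)
  net <- build_network(spec, seed = 1)
  net$W[[1]][] <- 0; net$W[[1]][1, 1] <- 1
  net$b[[1]] <- 10   # keep the hidden ReLU active
  net$W[[2]][] <- 1
  net$b[[2]] <- -10
  model <- structure(list(net = net, mu = rep(0, 12), sdev = rep(1, 12),
                          y_scale = 100, history = NULL, seed = 1L,
                          spec = spec),
                     class = "ftc_model")
  # raw outputs -320 and 10450 clip to the percent range
  expect_equal(predict(model, c(-3.2, rep(0, 11))), 0)
  expect_equal(predict(model, c(104.5, rep(0, 11))), 100)
  expect_equal(predict(model, c(0.5, rep(0, 11))), 50)
  fv <- c(0.5, rep(0, 10), NA)
  expect_true(is.na(predict(model, fv)))
  expect_identical(predict(model, c(0.3, rep(0, 11))),
                   predict(model, c(0.3, rep(0, 11))))
})

test_that("model serialization round-trips predictions bit-exactly", {
  set.seed(6)
  X <- matrix(rnorm(200 * 12), 200, 12)
  y <- pmin(100, pmax(0, 50 + 20 * X[, 2]))
  m <- train_network(build_network(network_spec(hidden = c(8, 4))), X, y,
                     epochs = 5, seed = 6)
  path <- tempfile(fileext = ".rds")
  save_ftc_model(m, path)
  m2 <- load_ftc_model(path)
  expect_identical(predict(m, X), predict(m2, X))
})

test_that("the low-greenness postmask zeroes predictions below 0.35 max NDVI", {
  cover <- matrix(c(35, 35, 80), 1, 3)
  max_ndvi <- matrix(c(0.30, 0.35, 0.9), 1, 3)
  out <- postprocess(cover, max_ndvi)
  expect_equal(out[1, 1], 0)     # below the threshold -> non-tree
  expect_equal(out[1, 2], 35)    # exactly 0.35 keeps its prediction
  expect_equal(out[1, 3], 80)
  lc <- matrix(c("water", "forest", "snow_ice"), 1, 3)
  out2 <- postprocess(cover, max_ndvi, landcover = lc)
  expect_true(is.na(out2[1, 1]))
  expect_true(is.na(out2[1, 3]))
  expect_error(postprocess(cover, matrix(0.5, 2, 2)), "conformable")
})
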
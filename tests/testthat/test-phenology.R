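test_that("reference series averages years ignoring fill", {
  y <- double_logistic(0:45, 0.25, 0.85, 12, 34, 2, 2)
  ref <- reference_series(list(y, y))
  expect_equal(ref$ref_ndvi, y)
  ref2 <- reference_series(list(rep(0.4, 46), rep(0.6, 46)))
  expect_equal(ref2$ref_ndvi, rep(0.5, 46))
  expect_equal(ref2$amplitude, 0)
})

test_that("multi-year averaging tightens toward the true curve at the CLT rate", {
  y <- double_logistic(0:45, 0.25, 0.85, 12, 34, 2, 2)
  set.seed(25)
  years <- replicate(22, y + rnorm(46, 0, 0.05), simplify = FALSE)
  ref <- reference_series(years)
  expect_true(all(abs(ref$ref_ndvi - y) < 3 * 0.05 / sqrt(22)))
})

test_that("composites missing in every year propagate fill and can void the pixel", {
  y <- double_logistic(0:45, 0.25, 0.85, 12, 34, 2, 2)
  y1 <- y; y1[1:5] <- NA
  y2 <- y; y2[3:8] <- NA
  ref <- reference_series(list(y1, y2))
  expect_true(all(is.na(ref$ref_ndvi[3:5])))  # gap in both years
  expect_false(is.na(ref$ref_ndvi[1]))        # covered by year 2
  expect_true(ref$usable)
  y1[1:12] <- NA; y2[1:12] <- NA
  expect_false(reference_series(list(y1, y2))$usable)
})

test_that("a triangular seasonal curve yields the worked growing season", {
  y <- 0.2 + 0.6 * (1 - abs(0:45 - 23) / 23)
  ref <- reference_series(list(y))
  expect_equal(ref$amplitude, 0.6)
  expect_equal(ref$threshold, 0.5)
  gs <- detect_growing_season(ref)
  expect_false(gs$evergreen)
  expect_equal(length(gs$runs), 1L)
  expect_equal(unname(gs$primary_run["start"]), 12)
  expect_equal(gs$run_length, 23L)
  expect_equal(gs$midpoint, 23L)
})

test_that("the amplitude threshold separates the evergreen and seasonal branches", {
  expect_true(detect_growing_season(reference_series(list(rep(0.75, 46))))$evergreen)
  # amplitude at the threshold is seasonal (strict <); amplitudes built by
  # addition so the comparison sees the same floating-point value
  y <- rep(0.4, 46); y[13:35] <- 0.4 + 0.2
  gs <- detect_growing_season(reference_series(list(y)))
  expect_false(gs$evergreen)
  # just below: evergreen
  y2 <- rep(0.4, 46); y2[13:35] <- 0.4 + 0.199
  expect_true(detect_growing_season(reference_series(list(y2)))$evergreen)
})

test_that("with two peaks the warmer season wins when LST is available", {
  y <- rep(0.2, 46)
  y[8:13] <- 0.8    # bump centered near composite 10
  y[31:36] <- 0.8   # bump centered near composite 33
  lst <- rep(280, 46)
  lst[8:13] <- 290
  lst[31:36] <- 300
  ref <- reference_series(list(y))
  gs <- detect_growing_season(ref, lst = lst)
  expect_equal(length(gs$runs), 2L)
  expect_equal(unname(gs$primary_run["start"]), 30)  # the warmer bump
  expect_equal(gs$midpoint, 32L)
  # without LST, the longer run wins (ties -> earliest start)
  y2 <- y; y2[37] <- 0.8   # make the second bump longer
  gs2 <- detect_growing_season(reference_series(list(y2)))
  expect_equal(unname(gs2$primary_run["start"]), 30)
  gs3 <- detect_growing_season(ref)  # equal lengths -> earliest
  expect_equal(unname(gs3$primary_run["start"]), 7)
})

test_that("growing-season runs wrap across the year boundary", {
  y <- rep(0.2, 46)
  y[c(41:46, 1:6)] <- 0.8   # season spanning the new year
  gs <- detect_growing_season(reference_series(list(y)))
  expect_equal(length(gs$runs), 1L)
  expect_equal(unname(gs$primary_run["start"]), 40)
  expect_equal(gs$run_length, 12L)
  expect_equal(gs$midpoint, (40 + 5) %% 46)
})

test_that("evergreen midpoint follows the 18-highest circular mean", {
  flat <- reference_series(list(rep(0.7, 46) + 0.005 * sin(2 * pi * 0:45 / 46)))
  expect_equal(midpoint_evergreen(flat), 23L)   # amplitude < 0.02
  y <- rep(0.6, 46)
  y[15:32] <- 0.75   # 18 elevated composites at 0-based 14..31
  ref <- reference_series(list(y))
  expect_true(ref$amplitude < 0.2)
  expect_equal(midpoint_evergreen(ref), 22L)    # circular mean 22.5 -> 22
  yw <- rep(0.6, 46)
  yw[c(38:46, 1:9)] <- 0.75  # elevated block wrapping the boundary (37..45, 0..8)
  mw <- midpoint_evergreen(reference_series(list(yw)))
  expect_true(mw %in% c(45L, 0L))
  expect_equal(mw, 45L)       # mean 45.5, exact half rounds to smaller index
})

test_that("realignment rotates the midpoint to composite 23 and conserves values", {
  s <- simulate_pixel(85, 0, cfg = noise_free_cfg())
  r <- realign(s, 23)
  expect_equal(r$shift, 0)
  expect_identical(r$series$ndvi, s$ndvi)
  r2 <- realign(s, 10)
  expect_equal(r2$shift, 13)
  expect_equal(r2$series$ndvi[24], s$ndvi[11])  # composite 10 -> composite 23
  for (band in c("ndvi", "red", "nir", "swir")) {
    expect_equal(sort(r2$series[[band]]), sort(s[[band]]))
    expect_equal(sum(r2$series[[band]]), sum(s[[band]]))
  }
  expect_error(realign(s, 46), "midpoint")
})

test_that("realignment after any integer phenology shift recovers the same series", {
  cfg <- noise_free_cfg()
  base <- process_pixel(simulate_pixel(70, 0, cfg = cfg))
  for (k in 0:45) {
    r <- process_pixel(simulate_pixel(70, k, cfg = cfg))
    expect_identical(r$series$ndvi, base$series$ndvi)
  }
})

test_that("the midpoint of a symmetric single-peak curve is its argmax", {
  for (center in c(10, 23, 37)) {
    y <- 0.2 + 0.5 * exp(-((((0:45 - center + 23) %% 46) - 23) / 6)^2)
    gs <- detect_growing_season(reference_series(list(y)))
    expect_equal(gs$midpoint, center)
  }
})
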
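test_that("endmember curves reproduce the tree-plateau vs herb-parabola contrast", {
  tree <- endmember_curves(tree_endmember())
  # steep logistic rates give a sustained mid-season plateau
  expect_true(all(abs(tree$ndvi[18:30] - 0.85) < 0.02))
  herb <- endmember_curves(herb_endmember())
  # shallow rates give a single-composite maximum, strictly decreasing away
  peak <- which.max(herb$ndvi)
  expect_equal(sum(herb$ndvi == max(herb$ndvi)), 1)
  expect_true(all(diff(herb$ndvi[seq_len(peak)]) > 0))
  expect_true(all(diff(herb$ndvi[peak:46]) < 0))
  # double logistic matches the analytic form
  expect_equal(tree$ndvi,
               double_logistic(0:45, 0.25, 0.85, 12, 34, 2, 2))
  # reflectance curves decrease with greenness between base and min
  for (em in list(tree, herb)) {
    expect_true(all(em$red >= 0 & em$red <= 1))
    expect_true(all(em$swir >= 0 & em$swir <= 1))
    expect_true(all(diff(em$red[order(em$ndvi)]) <= 1e-12))
    expect_true(all(is.finite(unlist(em))))
  }
})

test_that("degenerate zero-amplitude endmember yields constant curves", {
  spec <- endmember_spec(0.5, 0.5, 12, 34, 2, 2, 0.1, 0.05, 0.2, 0.1)
  cur <- endmember_curves(spec)
  expect_equal(cur$ndvi, rep(0.5, 46))
  expect_equal(cur$red, rep(0.1, 46))
})

test_that("invalid endmember specs are rejected", {
  expect_error(endmember_spec(0.2, 0.8, 34, 12, 2, 2, 0.1, 0.05, 0.2, 0.1),
               "green_up")
  expect_error(endmember_spec(0.2, 0.8, 12, 34, 2, 2, 0.05, 0.1, 0.2, 0.1),
               "red_min")
  expect_error(endmember_spec(0.2, 0.8, 12, 34, 2, 2, 1.2, 0.05, 0.2, 0.1),
               "reflectance")
})

test_that("pure and mixed pixels follow linear reflectance mixing", {
  cfg <- noise_free_cfg()
  ct <- endmember_curves(tree_endmember())
  ch <- endmember_curves(herb_endmember())
  s100 <- simulate_pixel(100, 0, cfg = cfg)
  expect_equal(s100$red, ct$red)
  expect_equal(s100$swir, ct$swir)
  expect_equal(s100$ndvi, ct$ndvi)
  s0 <- simulate_pixel(0, 0, cfg = cfg)
  expect_equal(s0$ndvi, ch$ndvi)
  s50 <- simulate_pixel(50, 0, cfg = cfg)
  expect_equal(s50$red, (ct$red + ch$red) / 2)
  expect_error(simulate_pixel(101, 0, cfg = cfg), "fraction")
  expect_error(simulate_pixel(-1, 0, cfg = cfg), "fraction")
})

test_that("NDVI is computed from mixed reflectance, not mixed NDVI", {
  cfg <- noise_free_cfg()
  ct <- endmember_curves(tree_endmember())
  ch <- endmember_curves(herb_endmember())
  s50 <- simulate_pixel(50, 0, cfg = cfg)
  mixed_red <- (ct$red + ch$red) / 2
  mixed_nir <- (ct$nir + ch$nir) / 2
  expect_equal(s50$ndvi, (mixed_nir - mixed_red) / (mixed_nir + mixed_red))
  # which differs from averaging the endmember NDVI curves
  expect_gt(max(abs(s50$ndvi - (ct$ndvi + ch$ndvi) / 2)), 1e-4)
})

test_that("growing-season NDVI is monotone in tree fraction where tree exceeds herb", {
  cfg <- noise_free_cfg()
  ct <- endmember_curves(tree_endmember())
  ch <- endmember_curves(herb_endmember())
  fracs <- seq(0, 100, by = 5)
  ndvi <- sapply(fracs, function(f) simulate_pixel(f, 0, cfg = cfg)$ndvi)
  higher <- ct$ndvi > ch$ndvi
  for (c in which(higher))
    expect_true(all(diff(ndvi[c, ]) >= -1e-12))
})

test_that("scene simulation is deterministic and honors truth corners", {
  truth <- scene_truth(matrix(c(0, 50, 100, 50), 2, 2))
  cfg <- noise_free_cfg()
  sc <- simulate_scene(truth, cfg = cfg)
  ct <- endmember_curves(tree_endmember())
  ch <- endmember_curves(herb_endmember())
  expect_equal(sc$ndvi[1, 1, ], ch$ndvi)
  expect_equal(sc$ndvi[1, 2, ], ct$ndvi)
  cfg2 <- sim_config(noise_sd = 0.02, cloud_prob = 0.3, seed = 7)
  a <- simulate_scene(truth, cfg = cfg2)
  b <- simulate_scene(truth, cfg = cfg2)
  expect_identical(a, b)
})

test_that("cloud masking frequency matches its binomial expectation", {
  truth <- random_scene_truth(16, 16, seed = 3)
  sc <- simulate_scene(truth, cfg = sim_config(noise_sd = 0, cloud_prob = 0.2,
                                               seed = 3))
  frac_cloud <- mean(sc$qa == "cloud")
  expect_true(abs(frac_cloud - 0.2) < 0.05)
})

test_that("scene simulation rejects non-conformable grids", {
  truth <- scene_truth(matrix(50, 2, 2))
  truth$pheno_shift <- matrix(0L, 3, 2)
  expect_error(simulate_scene(truth, cfg = noise_free_cfg()), "conformable")
})

test_that("quota product labeling is exact at zero error", {
  truth <- scene_truth(matrix(c(100, 0, 40, 77), 2, 2))
  cfg <- zero_error_cfg(subgrid_factor = 10L)
  prods <- simulate_products(truth, cfg)
  expect_length(prods, 4)
  for (p in prods) {
    expect_equal(dim(p), c(20L, 20L))
    expect_equal(sum(p[1:10, 1:10]), 100)   # truth 100 -> all subcells tree
    expect_equal(sum(p[11:20, 1:10]), 0)    # truth 0 -> none
    expect_equal(sum(p[1:10, 11:20]), 40)   # truth 40 -> exactly 40 of 100
    expect_equal(sum(p[11:20, 11:20]), 77)
  }
})

test_that("the tall-dense product suppresses tree labels below its threshold", {
  truth <- scene_truth(matrix(c(25, 35), 1, 2))
  cfg <- sim_config(noise_sd = 0, cloud_prob = 0, seed = 1,
                    product_error = list(c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
                    tall_dense_threshold = 30)
  prods <- simulate_products(truth, cfg)
  expect_equal(sum(prods[[4]][, 1:10]), 0)     # 25% < 30% -> suppressed
  expect_equal(sum(prods[[4]][, 11:20]), 35)   # 35% kept
  expect_equal(sum(prods[[1]][, 1:10]), 25)    # other products unaffected
})
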
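make_mask <- function(nr, nc, blocks) {
  m <- matrix(0L, nr, nc)
  for (b in blocks) m[b$r, b$c] <- 1L
  binary_mask(m)
}

test_that("metaphase_untethering follows the largest-component overlap rule", {
  # DAPI components of 100 px (10x10) and 9 px (3x3); 10 FISH px, 7 on mass
  dapi <- make_mask(30, 30, list(list(r = 2:11, c = 2:11), list(r = 20:22, c = 20:22)))
  fish <- matrix(0L, 30, 30)
  fish[5, 2:8] <- 1L # 7 on the mass
  fish[25, 25:27] <- 1L # 3 off
  mm <- metaphase_untethering(dapi, binary_mask(fish))
  expect_equal(mm$genomic_mass_area_px, 100L)
  expect_equal(mm$myc_px_total, 10L)
  expect_equal(mm$myc_px_untethered, 3L)
  expect_equal(mm$untethered_pct, 30.0)
  # all FISH inside the mass -> 0
  fish2 <- matrix(0L, 30, 30)
  fish2[3:4, 3:4] <- 1L
  expect_equal(metaphase_untethering(dapi, binary_mask(fish2))$untethered_pct, 0)
  # no FISH -> missing; empty DAPI -> error
  expect_true(is.na(metaphase_untethering(dapi, binary_mask(matrix(0L, 30, 30)))$untethered_pct))
  expect_error(metaphase_untethering(binary_mask(matrix(0L, 5, 5)),
    binary_mask(matrix(0L, 5, 5))), class = "ect_invalid_input")
})

test_that("metaphase and micronuclei metrics are invariant to consistent flips", {
  sc <- generate_metaphase_scene(scene_spec("metaphase", seed = 61, noise_sigma = 0))
  d <- unclass(sc$truth$plate_mask)
  f <- unclass(sc$truth$fish_mask)
  base <- metaphase_untethering(binary_mask(d), binary_mask(f))$untethered_pct
  for (tr in list(function(m) m[nrow(m):1, ], function(m) m[, ncol(m):1], t)) {
    expect_equal(
      metaphase_untethering(binary_mask(tr(d)), binary_mask(tr(f)))$untethered_pct,
      base
    )
  }
  scd <- generate_daughter_pair_scene(scene_spec("daughter_pair", seed = 62, noise_sigma = 0))
  p <- unclass(scd$truth$partition)
  fp <- unclass(scd$truth$fish_mask)
  basem <- micronuclei_metrics(scd$truth$partition, binary_mask(fp))$myc_in_mn_pct
  for (tr in list(function(m) m[nrow(m):1, ], function(m) m[, ncol(m):1], t)) {
    got <- micronuclei_metrics(
      label_mask(tr(p), "daughter_pair", "ground_truth"), binary_mask(tr(fp))
    )$myc_in_mn_pct
    expect_equal(got, basem)
  }
})

test_that("partition_daughter_nuclei ranks by area and respects bounds", {
  # areas 500 (25x20), 480 (24x20), 20 (4x5), 3 (1x3)
  dapi <- make_mask(80, 80, list(
    list(r = 2:26, c = 2:21), list(r = 30:53, c = 30:49),
    list(r = 60:63, c = 60:64), list(r = 70, c = 70:72)
  ))
  part <- partition_daughter_nuclei(dapi,
    nuclei_partition_params(min_mn_area_px = 10, max_mn_area_frac = 0.5))
  pm <- unclass(part)
  expect_equal(sum(pm == 1L), 980L) # both primaries
  expect_equal(sum(pm == 2L), 20L) # the micronucleus
  expect_equal(sum(pm == 3L), 3L) # debris
  # annotation passthrough
  ann <- label_mask(pm, "daughter_pair", "imported")
  expect_identical(unclass(partition_daughter_nuclei(dapi, annotation = ann))[, ], pm[, ])
  # too few components
  solo <- make_mask(20, 20, list(list(r = 2:5, c = 2:5)))
  expect_error(partition_daughter_nuclei(solo), class = "ect_invalid_input")
})

test_that("micronuclei_metrics implements the share formulas", {
  part <- matrix(0L, 20, 40)
  part[2:11, 2:11] <- 1L # primary 1
  part[2:11, 20:29] <- 1L # primary 2
  part[15:18, 35:39] <- 2L # micronucleus of 20 px
  pm <- label_mask(part, "daughter_pair", "ground_truth")
  fish <- matrix(0L, 20, 40)
  fish[3, 2:10] <- 1L # 9 in primary 1
  fish[3, 20:29] <- 1L # 10 in primary 2
  fish[4, 21:26] <- 1L # 6 more -> 25 px in primaries
  fish[15, 35:39] <- 1L # 5 in the micronucleus -> total 30
  m <- micronuclei_metrics(pm, binary_mask(fish))
  expect_true(m$has_micronuclei)
  expect_equal(m$n_micronuclei, 1L)
  expect_equal(m$myc_in_mn_pct, 100 * 5 / 30)
  expect_equal(m$mn_composition_pct, 100 * 5 / 20) # 25.0
  # no micronuclei: flag false, share 0, composition missing
  part0 <- label_mask(part * (part != 2L), "daughter_pair", "ground_truth")
  m0 <- micronuclei_metrics(part0, binary_mask(fish * (part != 2L)))
  expect_false(m0$has_micronuclei)
  expect_equal(m0$myc_in_mn_pct, 0)
  expect_true(is.na(m0$mn_composition_pct))
})

test_that("count_foci applies the more-than-five-pixels rule", {
  m <- matrix(0L, 30, 30)
  m[2, 2:7] <- 1L # 6 px -> counted
  m[10:11, 10:14] <- 1L # 10 px -> counted
  m[20, 20:22] <- 1L # 3 px -> not counted
  expect_equal(count_foci(binary_mask(m)), 2L)
  five <- matrix(0L, 10, 10)
  five[4, 3:7] <- 1L # exactly 5 px
  expect_equal(count_foci(binary_mask(five)), 0L)
  expect_warning(n <- count_foci(fluor_image(matrix(3, 8, 8))), "degenerate")
  expect_equal(n, 0L)
  # adding sub-threshold components never changes the count; adding a
  # qualifying component increments it by exactly one
  base <- count_foci(binary_mask(m))
  m2 <- m
  m2[25, 25:28] <- 1L # 4 px
  expect_equal(count_foci(binary_mask(m2)), base)
  m3 <- m2
  m3[25:26, 1:3] <- 1L # 6 px
  expect_equal(count_foci(binary_mask(m3)), base + 1L)
})

test_that("integrated_density sums the region and is additive", {
  img <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(integrated_density(img, binary_mask(matrix(1L, 2, 2))), 10)
  expect_warning(z <- integrated_density(img, binary_mask(matrix(0L, 2, 2))), "empty")
  expect_equal(z, 0)
  a <- matrix(c(1L, 0L, 0L, 0L), 2)
  b <- matrix(c(0L, 0L, 0L, 1L), 2)
  expect_equal(
    integrated_density(img, binary_mask(a + b)),
    integrated_density(img, binary_mask(a)) + integrated_density(img, binary_mask(b))
  )
})

test_that("expression tiers follow the top-20%-of-expressing rule", {
  expect_equal(unique(classify_expression_tier(c(1, 2, 3), 10)), "negative")
  t10 <- classify_expression_tier(1:10, 0, 0.2)
  expect_equal(sum(t10 == "high"), 2L)
  expect_equal(which(t10 == "high"), c(9L, 10L))
  expect_equal(classify_expression_tier(c(0.1, 5), 1), c("negative", "high"))
  # tiers partition the cells; high set is roughly top_frac of expressers
  set.seed(71)
  d <- c(runif(20, 0, 1), runif(80, 2, 10))
  tiers <- classify_expression_tier(d, 2)
  expect_equal(length(tiers), 100L)
  expect_true(all(tiers %in% c("negative", "positive", "high")))
  n_exp <- sum(d >= 2)
  expect_lte(abs(sum(tiers == "high") - 0.2 * n_exp), 2)
})

test_that("line_profile_fit recovers exact polynomial structure", {
  grad <- outer(rep(1, 20), 1:20) # I(r, c) = c
  fit <- line_profile_fit(fluor_image(grad), c(5, 2), c(5, 18), degree = 1)
  co <- fit$channels[[1]]$coefficients
  expect_equal(co[2], 1, tolerance = 1e-8) # slope 1 per unit step
  expect_equal(co[1], 2, tolerance = 1e-8) # intercept = start column
  expect_lt(fit$channels[[1]]$residual_norm, 1e-8)
  cst <- line_profile_fit(fluor_image(matrix(7, 10, 10)), c(2, 2), c(9, 9), degree = 3)
  expect_equal(cst$channels[[1]]$coefficients[1], 7, tolerance = 1e-8)
  expect_lt(cst$channels[[1]]$residual_norm, 1e-8)
  # interpolating fit: degree = samples - 1
  set.seed(72)
  img <- fluor_image(matrix(runif(400, 0, 50), 20))
  prof <- line_profile_fit(img, c(3, 2), c(3, 9), degree = 7)
  expect_lt(prof$channels[[1]]$residual_norm, 1e-6)
  expect_error(line_profile_fit(img, c(3, 3), c(3, 3), degree = 1),
    class = "ect_invalid_input")
  expect_error(line_profile_fit(img, c(1, 1), c(25, 25), degree = 1),
    class = "ect_invalid_input")
})
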
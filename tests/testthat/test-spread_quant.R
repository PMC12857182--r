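test_that("adjacency_fraction reproduces hand-derived cases", {
  # isolated 2x2 block, no chromosome anywhere -> 0
  lab <- matrix(0L, 8, 8)
  lab[3:4, 3:4] <- 2L
  px <- cbind(row = c(3L, 3L, 4L, 4L), col = c(3L, 4L, 3L, 4L))
  lm <- label_mask(lab, "spread", "ground_truth")
  expect_equal(adjacency_fraction(px, lm)$frac, 0)
  # chromosome column one pixel to the left: the two left pixels qualify
  lab2 <- lab
  lab2[1:6, 2] <- 1L
  af <- adjacency_fraction(px, label_mask(lab2, "spread", "ground_truth"))
  expect_equal(af$frac, 0.5)
  expect_equal(af$boundary_px, 4L)
  expect_equal(af$boundary_adj_chrom_px, 2L)
  # single pixel with all 8 neighbours chromosome -> 1
  lab3 <- matrix(1L, 3, 3)
  lab3[2, 2] <- 2L
  af3 <- adjacency_fraction(cbind(2L, 2L), label_mask(lab3, "spread", "ground_truth"))
  expect_equal(af3$frac, 1)
  expect_error(adjacency_fraction(px[0, , drop = FALSE], lm),
    class = "ect_invalid_input")
})

test_that("adjacency_fraction agrees with the brute-force oracle on random masks", {
  for (seed in 1:40) {
    lm <- random_label_mask(seed)
    comps <- label_components(lm, class_code = CLASS_CODES[["ECDNA"]])
    for (j in seq_len(nrow(comps))) {
      got <- adjacency_fraction(comps$pixels[[j]], lm)
      want <- oracle_adjacency(comps$pixels[[j]], unclass(lm))
      expect_equal(got$frac, want$frac)
      expect_equal(got$boundary_px, want$boundary)
      expect_equal(got$boundary_adj_chrom_px, want$adj)
    }
  }
})

test_that("classify_tether implements the stated cutoffs", {
  expect_equal(classify_tether(0.10), "untethered")
  expect_equal(classify_tether(0.249999), "untethered")
  expect_equal(classify_tether(0.25), "tethered")
  expect_equal(classify_tether(0.999), "tethered")
  expect_equal(classify_tether(1.0), "surrounded")
  expect_equal(classify_tether(0), "untethered")
  expect_error(classify_tether(1.2), class = "ect_invalid_input")
  expect_error(classify_tether(-0.1), class = "ect_invalid_input")
})

test_that("summarize_spread computes the untethering percentage and counts", {
  # generator with fractions 0.5 / 0.2 of 10 ecDNA -> 5 untethered,
  # 2 surrounded, 3 tethered -> 100 * 5/8 = 62.5
  sc <- generate_spread_scene(scene_spec("spread", seed = 12, n_ecdna = 10,
    frac_untethered = 0.5, frac_surrounded = 0.2, noise_sigma = 0))
  sm <- summarize_spread(sc$truth$mask)
  expect_equal(sm$n_untethered, 5L)
  expect_equal(sm$n_tethered, 3L)
  expect_equal(sm$n_surrounded, 2L)
  expect_equal(sm$untethering_pct, 62.5)
  expect_equal(sm$n_chromosome_cc, 6L)
  # tether classes partition the ecDNA components
  expect_equal(sm$n_untethered + sm$n_tethered + sm$n_surrounded,
    length(sm$tether_classes))
  # no ecDNA: percentage missing, chromosome count still reported
  sc0 <- generate_spread_scene(scene_spec("spread", seed = 13, n_ecdna = 0,
    noise_sigma = 0))
  sm0 <- summarize_spread(sc0$truth$mask)
  expect_true(is.na(sm0$untethering_pct))
  expect_equal(sm0$n_chromosome_cc, 6L)
})

test_that("adjacency at contact is at least adjacency in isolation", {
  # slide a 2x2 ecDNA block toward a chromosome wall; the fraction is 0
  # until the 8-neighbourhood reaches the wall, then positive
  fracs <- vapply(6:2, function(col0) {
    lab <- matrix(0L, 10, 10)
    lab[1:10, 1] <- 1L
    lab[4:5, col0:(col0 + 1)] <- 2L
    px <- as.matrix(expand.grid(row = 4:5, col = col0:(col0 + 1)))
    adjacency_fraction(px, label_mask(lab, "spread", "ground_truth"))$frac
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_equal(fracs[1], 0)
  expect_gt(fracs[5], 0)
})

test_that("convex_hull_area reproduces frozen cases and dominates the union", {
  z <- binary_mask(matrix(0L, 12, 12))
  sq <- matrix(0L, 12, 12)
  sq[2:11, 2:11] <- 1L
  expect_equal(convex_hull_area(binary_mask(sq), z), 100L)
  two <- matrix(0L, 12, 12)
  two[3, 4] <- 1L
  two[3, 8] <- 1L
  expect_equal(convex_hull_area(binary_mask(two), z), 5L)
  ell <- matrix(0L, 12, 12)
  ell[1, 1:3] <- 1L
  ell[2:3, 1] <- 1L
  expect_equal(convex_hull_area(binary_mask(ell), z), 6L)
  expect_equal(convex_hull_area(z, z), 0L)
  # split across the two masks: the union is what counts
  d <- matrix(0L, 12, 12)
  d[3, 4] <- 1L
  f <- matrix(0L, 12, 12)
  f[3, 8] <- 1L
  expect_equal(convex_hull_area(binary_mask(d), binary_mask(f)), 5L)
})

test_that("convex_hull_area matches the point-in-hull oracle on random masks", {
  set.seed(41)
  for (i in 1:12) {
    m <- matrix(0L, 10, 10)
    n <- sample(1:12, 1)
    m[cbind(sample(10, n, TRUE), sample(10, n, TRUE))] <- 1L
    z <- binary_mask(matrix(0L, 10, 10))
    got <- convex_hull_area(binary_mask(m), z)
    pts <- which(m == 1L, arr.ind = TRUE)
    expect_equal(got, oracle_hull_area(pts, 10, 10))
    expect_gte(got, sum(m))
  }
})

test_that("class_intensity_ratio is the ratio of class means", {
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L
  lm <- label_mask(lab, "spread", "ground_truth")
  ifl <- matrix(200, 4, 4)
  dap <- matrix(100, 4, 4)
  expect_equal(class_intensity_ratio(ifl, dap, lm, 1L), 2.0)
  expect_equal(class_intensity_ratio(dap, dap, lm, 1L), 1.0)
  expect_true(is.na(class_intensity_ratio(ifl, dap, lm, 2L)))
  expect_error(class_intensity_ratio(ifl, matrix(0, 4, 4), lm, 1L),
    class = "ect_undefined_ratio")
})

test_that("acetylation ratio is recovered within 5% from noisy scenes", {
  sc <- generate_spread_scene(scene_spec("spread", seed = 51,
    h3ac_ratio_per_class = c(chromosome = 1.0, ecdna = 2.5)))
  labs <- sc$truth$mask
  r_ch <- class_intensity_ratio(sc$h3ac, sc$dapi, labs, CLASS_CODES[["CHROMOSOME"]])
  r_ec <- class_intensity_ratio(sc$h3ac, sc$dapi, labs, CLASS_CODES[["ECDNA"]])
  expect_lt(abs(r_ch - 1.0) / 1.0, 0.05)
  expect_lt(abs(r_ec - 2.5) / 2.5, 0.05)
})
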
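test_that("multi-Otsu separates well-separated populations and matches the oracle", {
  expect_error(multi_otsu_thresholds(fluor_image(matrix(5, 4, 4))),
    class = "ect_degenerate_histogram")
  # three equal populations at 0 / 100 / 200
  img <- fluor_image(matrix(rep(c(0, 100, 200), each = 10), 5, 6))
  th <- multi_otsu_thresholds(img)
  expect_length(th, 2)
  expect_true(th[1] > 0 && th[1] < 100)
  expect_true(th[2] > 100 && th[2] < 200)
  # exhaustive-search oracle equality on random images (coarse bins keep the
  # O(bins^2) oracle cheap)
  set.seed(21)
  sp <- seg_params(n_hist_bins = 32L)
  for (i in 1:8) {
    v <- c(rnorm(60, 10, 4), rnorm(30, 60, 6), rnorm(20, 140, 8))
    v <- pmax(0, v)
    img <- fluor_image(matrix(v, 11, 10))
    got <- multi_otsu_thresholds(img, sp)
    want <- oracle_otsu3_cuts(v, 32L)$thresholds
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("binarize_channel follows the >= rule and the higher/lower choice", {
  img <- fluor_image(matrix(c(50, 150), 1, 2))
  m <- binarize_channel(img, threshold = 100)
  expect_equal(as.vector(unclass(m)), c(0L, 1L))
  expect_equal(attr(m, "threshold_used"), 100)
  # lower rule marks both upper populations of a 3-population image
  img3 <- fluor_image(matrix(rep(c(0, 100, 200), each = 12), 6, 6))
  lower <- binarize_channel(img3, seg_lower)
  higher <- binarize_channel(img3, seg_higher)
  expect_equal(sum(lower), 24L)
  expect_equal(sum(higher), 12L)
  # higher-threshold mask is a subset of the lower-threshold mask
  set.seed(22)
  for (i in 1:5) {
    img <- fluor_image(matrix(pmax(0, rnorm(400, rep(c(10, 80, 200), length.out = 400), 10)), 20))
    hi <- binarize_channel(img, seg_higher)
    lo <- binarize_channel(img, seg_lower)
    expect_true(all(unclass(hi) <= unclass(lo)))
  }
  # image entirely at/above an injected threshold -> all foreground
  expect_true(all(binarize_channel(fluor_image(matrix(7, 3, 3)), threshold = 7) == 1L))
})

test_that("label_components matches flood fill and is deterministic", {
  expect_equal(nrow(label_components(matrix(c(1, 0, 0, 1), 2))), 1L)
  two <- matrix(0L, 5, 5)
  two[1:2, 1:2] <- 1L
  two[4:5, 4:5] <- 1L
  expect_equal(nrow(label_components(two)), 2L)
  expect_equal(nrow(label_components(matrix(0L, 4, 4))), 0L)
  # partition equality with the flood-fill oracle on random masks
  set.seed(23)
  for (i in 1:6) {
    fg <- matrix(runif(64 * 64) < 0.35, 64)
    comps <- label_components(fg)
    lab <- matrix(0L, 64, 64)
    for (j in seq_len(nrow(comps))) lab[comps$pixels[[j]]] <- j
    expect_identical(partition_signature(lab), partition_signature(oracle_flood_fill(fg)))
    # component areas partition the foreground
    expect_equal(sum(comps$area_px), sum(fg))
  }
  # ids follow row-major first-pixel order
  m <- matrix(0L, 4, 6)
  m[3, 1] <- 1L # first in column-major, *not* in row-major
  m[1, 5] <- 1L
  comps <- label_components(m)
  expect_equal(comps$pixels[[1]][1, ], c(row = 1L, col = 5L))
})

test_that("component partition is invariant to flips up to relabeling", {
  set.seed(24)
  fg <- matrix(runif(40 * 40) < 0.3, 40)
  sig <- function(m) {
    comps <- label_components(m)
    sort(vapply(comps$pixels, nrow, integer(1)))
  }
  expect_identical(sig(fg), sig(fg[nrow(fg):1, ]))
  expect_identical(sig(fg), sig(fg[, ncol(fg):1]))
  expect_identical(sig(fg), sig(t(fg)))
})

test_that("classify_spread_pixels applies the surrogate rules and the import override", {
  # imported ground truth passes through untouched
  imp <- random_label_mask(99)
  out <- classify_spread_pixels(NULL, NULL, imported = imp)
  expect_identical(unclass(out)[, ], unclass(imp)[, ])
  expect_identical(attr(out, "provenance"), "imported")
  expect_error(
    classify_spread_pixels(NULL, NULL, imported = matrix(7L, 4, 4)),
    class = "ect_bad_codes"
  )
  # big DAPI blob (no FISH) -> chromosome; small blob under FISH -> ecDNA
  dapi <- matrix(0L, 60, 60)
  dapi[2:41, 2:26] <- 1L # 1000 px
  dapi[50:54, 50:53] <- 1L # 20 px
  fish <- matrix(0L, 60, 60)
  fish[50:54, 50:53] <- 1L
  labs <- classify_spread_pixels(binary_mask(dapi), binary_mask(fish))
  expect_equal(unname(unclass(labs)[3, 3]), unname(CLASS_CODES[["CHROMOSOME"]]))
  expect_equal(unname(unclass(labs)[52, 51]), unname(CLASS_CODES[["ECDNA"]]))
  # class areas partition the mask
  comps <- rbind(
    label_components(labs, class_code = CLASS_CODES[["CHROMOSOME"]]),
    label_components(labs, class_code = CLASS_CODES[["ECDNA"]])
  )
  for (code in c(CLASS_CODES[["CHROMOSOME"]], CLASS_CODES[["ECDNA"]])) {
    expect_equal(
      sum(comps$area_px[comps$class_code == code]),
      sum(unclass(labs) == code)
    )
  }
  expect_error(classify_spread_pixels(binary_mask(dapi), binary_mask(fish[1:59, ])),
    class = "ect_shape_mismatch")
})

test_that("surrogate classification agrees pixelwise with truth on a zero-noise scene", {
  sc <- generate_spread_scene(scene_spec("spread", seed = 31, noise_sigma = 0))
  dm <- binarize_channel(sc$dapi, seg_lower)
  fm <- binarize_channel(sc$fish, seg_higher)
  labs <- classify_spread_pixels(dm, fm)
  agreement <- mean(unclass(labs) == unclass(sc$truth$mask))
  expect_gte(agreement, 0.99)
})
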
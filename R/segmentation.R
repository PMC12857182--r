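#' Multi-level Otsu thresholds
#'
#' Computes the `n_otsu_classes - 1` thresholds that maximize between-class
#' variance over a binned intensity histogram (256 uniform bins over the
#' observed min-max range by default). With three classes this reproduces the
#' three-class thresholding used to segment DAPI and FISH channels, where
#' the higher threshold isolates bright signal (FISH foci, metaphase
#' chromosomes) and the lower threshold captures dimmer interphase DAPI.
#'
#' The search is exhaustive over all bin-boundary combinations, so the result
#' is the global maximizer of the between-class variance for the binned
#' histogram (ties broken toward lower thresholds). Returned thresholds are
#' the lower edges of the first bin of each upper class, strictly increasing.
#'
#' @param image A [fluor_image()] or numeric matrix.
#' @param params A [seg_params()].
#' @return Numeric vector of thresholds, length `n_otsu_classes - 1`.
#' @export
multi_otsu_thresholds <- function(image, params = seg_params()) {
  image <- as_fluor_image(image)
  v <- as.vector(unclass(image))
  nb <- params$n_hist_bins
  k <- params$n_otsu_classes
  rng <- range(v)
  if (rng[1] == rng[2]) {
    ect_error("degenerate histogram: constant image", "ect_degenerate_histogram")
  }
  # bin index in 1..nb; top value goes into the last bin
  width <- (rng[2] - rng[1]) / nb
  bin <- pmin(nb, floor((v - rng[1]) / width) + 1L)
  counts <- tabulate(bin, nbins = nb)
  occupied <- which(counts > 0L)
  if (length(occupied) < k) {
    ect_error(
      sprintf("degenerate histogram: %d occupied bins for %d classes",
        length(occupied), k),
      "ect_degenerate_histogram"
    )
  }
  centers <- rng[1] + (seq_len(nb) - 0.5) * width
  p <- counts / sum(counts)
  cw <- c(0, cumsum(p)) # cumulative weight up to bin i
  cm <- c(0, cumsum(p * centers)) # cumulative mass
  # class over bins (a+1)..b given boundary vector; between-class variance is
  # sum w_c * mu_c^2 - mu^2 (constant mu dropped for the argmax)
  score_part <- function(a, b) {
    w <- cw[b + 1L] - cw[a + 1L]
    m <- cm[b + 1L] - cm[a + 1L]
    ifelse(w > 0, m^2 / w, 0)
  }
  best <- -Inf
  best_cut <- NULL
  # recursive enumeration of k-1 ordered cut points (bin boundaries);
  # k is 2 or 3 in practice so this stays cheap and vectorizable for k = 3
  if (k == 2L) {
    cuts <- seq_len(nb - 1L)
    sc <- score_part(0L, cuts) + score_part(cuts, nb)
    best_cut <- cuts[which.max(sc)]
  } else if (k == 3L) {
    for (t1 in seq_len(nb - 2L)) {
      t2 <- (t1 + 1L):(nb - 1L)
      sc <- score_part(0L, t1) + score_part(t1, t2) + score_part(t2, nb)
      j <- which.max(sc)
      if (sc[j] > best) {
        best <- sc[j]
        best_cut <- c(t1, t2[j])
      }
    }
  } else {
    combs <- utils::combn(nb - 1L, k - 1L)
    for (j in seq_len(ncol(combs))) {
      cut <- combs[, j]
      b <- c(0L, cut, nb)
      sc <- sum(score_part(b[-length(b)], b[-1]))
      if (sc > best) {
        best <- sc
        best_cut <- cut
      }
    }
  }
  # threshold = lower edge of the first bin of the upper class
  rng[1] + best_cut * width
}

#' Binarize a channel at one of the multi-Otsu thresholds
#'
#' A pixel is foreground iff its intensity is `>=` the selected threshold:
#' the higher threshold for FISH and metaphase DAPI signal, the lower
#' threshold for interphase DAPI signal.
#'
#' @param image A [fluor_image()] or numeric matrix.
#' @param params A [seg_params()]; `threshold_rule` picks the threshold.
#' @param threshold Optional fixed threshold overriding Otsu (used for
#'   injection in tests and for externally chosen cutoffs).
#' @return A [binary_mask()] with `threshold_used` recorded.
#' @export
binarize_channel <- function(image, params = seg_params(), threshold = NULL) {
  image <- as_fluor_image(image)
  if (is.null(threshold)) {
    th <- multi_otsu_thresholds(image, params)
    threshold <- switch(params$threshold_rule,
      higher = th[length(th)],
      lower = th[1]
    )
  }
  binary_mask(unclass(image) >= threshold,
    source_channel = attr(image, "channel"), threshold_used = threshold
  )
}

#' Label connected components
#'
#' Finds maximal connected components of the foreground (default
#' 8-neighbourhood, the "connectivity = 2" convention). Component ids are
#' assigned 1..N in row-major order of each component's first-encountered
#' pixel, making the labeling deterministic.
#'
#' @param mask A [binary_mask()], logical/0-1 matrix, or a [label_mask()]
#'   together with `class_code` to restrict to one class.
#' @param params A [seg_params()] (only `connectivity` is used).
#' @param class_code When `mask` is a label mask, the class to extract.
#' @return A data frame with one row per component: `component_id`,
#'   `class_code`, `area_px`, `boundary_px`, `boundary_adj_chrom_px` (both 0
#'   until filled by [adjacency_fraction()]), and a list column `pixels` of
#'   (row, col) integer matrices.
#' @export
label_components <- function(mask, params = seg_params(), class_code = NULL) {
  if (inherits(mask, "label_mask")) {
    if (is.null(class_code)) {
      ect_error("class_code required when labeling a label_mask", "ect_invalid_input")
    }
    fg <- unclass(mask) == class_code
  } else {
    if (inherits(mask, "binary_mask")) mask <- unclass(mask)
    if (is.logical(mask)) mask <- mask * 1L
    fg <- mask == 1L
    if (is.null(class_code)) class_code <- 1L
  }
  nr <- nrow(fg)
  nc <- ncol(fg)
  lab <- integer(nr * nc)
  off <- neighbor_offsets(params$connectivity)
  fg_idx <- which(fg)
  if (length(fg_idx) == 0L) {
    return(empty_components())
  }
  # visit seeds in row-major order so first-encountered pixels define ids
  ord <- order(row_major_key(((fg_idx - 1L) %% nr) + 1L, ((fg_idx - 1L) %/% nr) + 1L, nc))
  fg_idx <- fg_idx[ord]
  next_id <- 0L
  comp_pixels <- list()
  for (seed in fg_idx) {
    if (lab[seed] != 0L) next
    next_id <- next_id + 1L
    lab[seed] <- next_id
    frontier <- seed
    members <- seed
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      cand_r <- rep(r, each = nrow(off)) + off[, 1L]
      cand_c <- rep(c, each = nrow(off)) + off[, 2L]
      ok <- cand_r >= 1L & cand_r <= nr & cand_c >= 1L & cand_c <= nc
      cand <- unique((cand_c[ok] - 1L) * nr + cand_r[ok])
      cand <- cand[fg[cand] & lab[cand] == 0L]
      lab[cand] <- next_id
      members <- c(members, cand)
      frontier <- cand
    }
    comp_pixels[[next_id]] <- members
  }
  recs <- lapply(seq_len(next_id), function(id) {
    idx <- comp_pixels[[id]]
    px <- cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
    px[order(row_major_key(px[, 1L], px[, 2L], nc)), , drop = FALSE]
  })
  out <- data.frame(
    component_id = seq_len(next_id),
    class_code = as.integer(class_code),
    area_px = vapply(recs, nrow, integer(1)),
    boundary_px = 0L,
    boundary_adj_chrom_px = 0L
  )
  out$pixels <- recs
  out
}

empty_components <- function() {
  out <- data.frame(
    component_id = integer(0), class_code = integer(0), area_px = integer(0),
    boundary_px = integer(0), boundary_adj_chrom_px = integer(0)
  )
  out$pixels <- list()
  out
}

#' Classify spread pixels into chromosome / ecDNA classes
#'
#' Rule-based surrogate for a learned chromosome/ecDNA pixel classifier.
#' If an externally produced label mask is supplied it is validated and
#' passed through (`provenance = "imported"`) — that is the fidelity path for
#' real data. Otherwise: every FISH-positive pixel is classed ecDNA; the
#' remaining pixels of each DAPI component are classed by component area —
#' components of at most `surrogate_max_ecdna_area_px` become ecDNA, larger
#' ones (including intermediate-area FISH-negative bodies) become chromosome.
#' FISH-positive pixels outside the DAPI mask are ecDNA.
#'
#' This surrogate is explicitly not the published neural segmenter and claims
#' no parity with it; imported masks are authoritative when available.
#'
#' @param dapi_mask,fish_mask [binary_mask()] objects of identical shape.
#' @param params A [seg_params()].
#' @param imported Optional [label_mask()] (or integer matrix of codes 0/1/2)
#'   overriding the surrogate.
#' @return A [label_mask()] with context `"spread"`.
#' @export
classify_spread_pixels <- function(dapi_mask, fish_mask, params = seg_params(),
                                   imported = NULL) {
  if (!is.null(imported)) {
    if (!inherits(imported, "label_mask")) {
      imported <- label_mask(imported, context = "spread", provenance = "imported")
    } else {
      if (!all(unclass(imported) %in% 0:2)) {
        ect_error("imported mask has unknown class codes", "ect_bad_codes")
      }
      attr(imported, "provenance") <- "imported"
    }
    return(imported)
  }
  check_same_shape(dapi_mask, fish_mask, "DAPI and FISH masks")
  dapi <- unclass(dapi_mask) == 1L
  fish <- unclass(fish_mask) == 1L
  out <- matrix(CLASS_CODES[["BACKGROUND"]], nrow(dapi), ncol(dapi))
  comps <- label_components(dapi, params)
  for (i in seq_len(nrow(comps))) {
    px <- comps$pixels[[i]]
    code <- if (comps$area_px[i] <= params$surrogate_max_ecdna_area_px) {
      CLASS_CODES[["ECDNA"]]
    } else {
      CLASS_CODES[["CHROMOSOME"]]
    }
    out[px] <- code
  }
  out[fish] <- CLASS_CODES[["ECDNA"]]
  label_mask(out, context = "spread", provenance = "surrogate")
}
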
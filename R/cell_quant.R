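#' Metaphase-plate ecDNA untethering from pixel overlap
#'
#' The largest DAPI connected component is the genomic mass (chromosomes
#' aligned at the metaphase plate; ties broken by lowest component id).
#' FISH-positive pixels overlapping the mass are tethered; all other
#' FISH-positive pixels are untethered. The untethered percentage is
#' `100 * untethered FISH px / total FISH px`.
#'
#' @param dapi_mask,fish_mask [binary_mask()] objects of identical shape;
#'   `dapi_mask` must be nonempty.
#' @param params A [seg_params()].
#' @return A list of class `metaphase_metrics`: `genomic_mass_area_px`,
#'   `myc_px_total`, `myc_px_untethered`, `untethered_pct` (NA when the cell
#'   has no FISH signal).
#' @export
metaphase_untethering <- function(dapi_mask, fish_mask, params = seg_params()) {
  check_same_shape(dapi_mask, fish_mask, "DAPI and FISH masks")
  comps <- label_components(dapi_mask, params)
  if (nrow(comps) == 0L) {
    ect_error("empty DAPI mask: no genomic mass", "ect_invalid_input")
  }
  mass_id <- comps$component_id[which.max(comps$area_px)] # first max = lowest id
  mass_px <- comps$pixels[[mass_id]]
  mass <- matrix(FALSE, nrow(dapi_mask), ncol(dapi_mask))
  mass[mass_px] <- TRUE
  fish <- unclass(fish_mask) == 1L
  total <- sum(fish)
  unteth <- sum(fish & !mass)
  structure(list(
    genomic_mass_area_px = nrow(mass_px),
    myc_px_total = total,
    myc_px_untethered = unteth,
    untethered_pct = if (total > 0) 100 * unteth / total else NA_real_
  ), class = "metaphase_metrics")
}

#' Partition daughter-pair DAPI components into nuclei classes
#'
#' Automates the manual labeling of newly divided daughter cells: the
#' `n_primary` largest DAPI components are primary nuclei; remaining
#' components with area between `min_mn_area_px` and
#' `max_mn_area_frac x (smallest primary area)` are micronuclei — smaller
#' areas of DAPI signal outside the large primary nuclei; anything smaller is
#' discarded as debris. An imported annotation mask reproduces manual labels
#' verbatim.
#'
#' @param dapi_mask A nonempty [binary_mask()].
#' @param params A [nuclei_partition_params()].
#' @param annotation Optional [label_mask()] (context `"daughter_pair"`) or
#'   integer matrix of codes 0/1/2/3 passed through unchanged.
#' @param seg A [seg_params()].
#' @return A [label_mask()] with context `"daughter_pair"` (codes: 1 primary,
#'   2 micronucleus, 3 debris).
#' @export
partition_daughter_nuclei <- function(dapi_mask, params = nuclei_partition_params(),
                                      annotation = NULL, seg = seg_params()) {
  if (!is.null(annotation)) {
    if (!inherits(annotation, "label_mask")) {
      annotation <- label_mask(annotation, context = "daughter_pair",
        provenance = "imported")
    }
    return(annotation)
  }
  comps <- label_components(dapi_mask, seg)
  if (nrow(comps) < params$n_primary) {
    ect_error(sprintf(
      "found %d DAPI components, need at least %d primary nuclei",
      nrow(comps), params$n_primary
    ), "ect_invalid_input")
  }
  ord <- order(-comps$area_px, comps$component_id)
  primary_ids <- comps$component_id[ord[seq_len(params$n_primary)]]
  min_primary <- min(comps$area_px[comps$component_id %in% primary_ids])
  mn_max <- params$max_mn_area_frac * min_primary
  out <- matrix(0L, nrow(dapi_mask), ncol(dapi_mask))
  for (i in seq_len(nrow(comps))) {
    px <- comps$pixels[[i]]
    code <- if (comps$component_id[i] %in% primary_ids) {
      CLASS_CODES[["PRIMARY_NUCLEUS"]]
    } else if (comps$area_px[i] >= params$min_mn_area_px &&
      comps$area_px[i] <= mn_max) {
      CLASS_CODES[["MICRONUCLEUS"]]
    } else {
      CLASS_CODES[["DEBRIS"]]
    }
    out[px] <- code
  }
  label_mask(out, context = "daughter_pair", provenance = "surrogate")
}

#' Micronuclei content metrics for a daughter-cell pair
#'
#' `myc_in_mn_pct` is the percentage of all FISH-positive pixels (in primary
#' nuclei plus micronuclei) that fall inside micronuclei; `mn_composition_pct`
#' is the FISH-positive share of micronuclear DAPI pixels (what fraction of
#' micronuclear chromatin is the amplified locus).
#'
#' @param partition A daughter-pair [label_mask()] from
#'   [partition_daughter_nuclei()].
#' @param fish_mask A [binary_mask()] of the FISH channel, same shape.
#' @param seg A [seg_params()] used to count micronucleus components.
#' @return A list of class `daughter_pair_metrics`: `has_micronuclei`,
#'   `n_micronuclei`, `myc_in_mn_pct` (0 when no micronuclei, NA when there
#'   are no FISH pixels at all), `mn_composition_pct` (NA when there are no
#'   micronuclear DAPI pixels).
#' @export
micronuclei_metrics <- function(partition, fish_mask, seg = seg_params()) {
  check_same_shape(partition, fish_mask, "partition and FISH mask")
  part <- unclass(partition)
  fish <- unclass(fish_mask) == 1L
  in_mn <- part == CLASS_CODES[["MICRONUCLEUS"]]
  in_primary <- part == CLASS_CODES[["PRIMARY_NUCLEUS"]]
  n_mn <- nrow(label_components(in_mn, seg))
  fish_total <- sum(fish & (in_mn | in_primary))
  fish_mn <- sum(fish & in_mn)
  mn_dapi <- sum(in_mn)
  structure(list(
    has_micronuclei = n_mn > 0L,
    n_micronuclei = n_mn,
    myc_in_mn_pct = if (fish_total > 0) 100 * fish_mn / fish_total else NA_real_,
    mn_composition_pct = if (mn_dapi > 0) 100 * fish_mn / mn_dapi else NA_real_
  ), class = "daughter_pair_metrics")
}

#' Count immunofluorescence foci with a minimum-size rule
#'
#' Segments the IF channel by three-class Otsu (higher threshold), restricts
#' to the cell mask if given, labels 8-connected components, and counts the
#' components of more than five pixels (i.e. area `>= min_focus_px`, default
#' 6). A degenerate histogram (blank image) yields 0 with a warning.
#'
#' @param if_image A [fluor_image()] or numeric matrix, or a precomputed
#'   [binary_mask()] (used as-is, skipping thresholding).
#' @param params A [seg_params()] (`threshold_rule` forced to `"higher"`).
#' @param foci A [foci_params()].
#' @param cell_mask Optional [binary_mask()] restricting the count.
#' @return Nonnegative integer focus count.
#' @export
count_foci <- function(if_image, params = seg_params(), foci = foci_params(),
                       cell_mask = NULL) {
  if (inherits(if_image, "binary_mask")) {
    mask <- if_image
  } else {
    params$threshold_rule <- "higher"
    mask <- tryCatch(binarize_channel(as_fluor_image(if_image, "IF"), params),
      ect_degenerate_histogram = function(e) {
        warning("degenerate histogram; counting 0 foci", call. = FALSE)
        NULL
      }
    )
    if (is.null(mask)) return(0L)
  }
  m <- unclass(mask)
  if (!is.null(cell_mask)) {
    check_same_shape(mask, cell_mask, "IF mask and cell mask")
    m <- m * unclass(cell_mask)
  }
  comps <- label_components(m, params)
  sum(comps$area_px >= foci$min_focus_px)
}

#' Integrated density over a segmented region
#'
#' Sum of IF intensities over the region's pixels — the per-cell total-signal
#' measure used for expression quantification.
#'
#' @param if_image A [fluor_image()] or numeric matrix.
#' @param region A [binary_mask()] of identical shape.
#' @return Nonnegative scalar; 0 with a warning for an empty region.
#' @export
integrated_density <- function(if_image, region) {
  if_image <- as_fluor_image(if_image, "IF")
  check_same_shape(if_image, region, "image and region")
  sel <- unclass(region) == 1L
  if (!any(sel)) {
    warning("empty region; integrated density is 0", call. = FALSE)
    return(0)
  }
  sum(unclass(if_image)[sel])
}

#' Classify cells into expression tiers (- / + / ++)
#'
#' Cells below `background_cutoff` lack expression (negative). Among the
#' expressing cells, those at or above the `(1 - top_frac)` quantile of
#' integrated density (linear-interpolation quantile, ties inclusive) are
#' "high" (++, the top 20% tile by default); the rest are "positive" (+).
#'
#' @param densities Numeric vector of per-cell integrated densities.
#' @param background_cutoff Density below which a cell counts as negative.
#' @param top_frac Fraction of expressing cells tiered high (default 0.20).
#' @return Character vector of `"negative"` / `"positive"` / `"high"`.
#' @export
classify_expression_tier <- function(densities, background_cutoff,
                                     top_frac = 0.20) {
  if (length(densities) == 0L) ect_error("no densities given", "ect_invalid_input")
  if (!(top_frac > 0 && top_frac < 1)) {
    ect_error("top_frac must be in (0,1)", "ect_invalid_input")
  }
  tier <- rep("negative", length(densities))
  expressing <- densities >= background_cutoff
  if (any(expressing)) {
    q <- stats::quantile(densities[expressing], probs = 1 - top_frac,
      type = 7, names = FALSE)
    tier[expressing] <- ifelse(densities[expressing] >= q, "high", "positive")
  }
  tier
}

#' Line profile with polynomial fit
#'
#' Samples each channel by bilinear interpolation at unit steps along the
#' segment from `p0` to `p1` and fits a least-squares polynomial of the given
#' degree to each profile (the smoothing applied to intensity profiles drawn
#' across an ecDNA focus).
#'
#' @param images A [fluor_image()] or list of them (one per channel).
#' @param p0,p1 Numeric `(row, col)` endpoints inside the image.
#' @param degree Polynomial degree, `0 <= degree < number of samples`.
#' @return A list of class `line_profile_fit` with `distance` (sample
#'   positions), and per channel `profile`, `coefficients` (ascending powers)
#'   and `residual_norm`.
#' @export
line_profile_fit <- function(images, p0, p1, degree = 6L) {
  if (!is.list(images) || inherits(images, "fluor_image")) images <- list(images)
  images <- lapply(images, as_fluor_image)
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) ect_error("degenerate segment: p0 equals p1", "ect_invalid_input")
  d <- dim(images[[1]])
  for (p in list(p0, p1)) {
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2]) {
      ect_error("endpoint outside image", "ect_invalid_input")
    }
  }
  t_steps <- seq(0, len, by = 1)
  n <- length(t_steps)
  if (degree < 0L || degree >= n) {
    ect_error("degree must satisfy 0 <= degree < number of samples",
      "ect_invalid_input")
  }
  dir <- (p1 - p0) / len
  rs <- p0[1] + t_steps * dir[1]
  cs <- p0[2] + t_steps * dir[2]
  channels <- lapply(images, function(im) {
    y <- bilinear_sample(unclass(im), rs, cs)
    X <- outer(t_steps, 0:degree, `^`)
    fit <- stats::lm.fit(X, y)
    list(
      profile = y,
      coefficients = unname(fit$coefficients),
      residual_norm = sqrt(sum(fit$residuals^2))
    )
  })
  names(channels) <- vapply(images, function(im) attr(im, "channel"), character(1))
  structure(list(distance = t_steps, channels = channels),
    class = "line_profile_fit")
}

# bilinear interpolation at fractional (row, col) positions, clamped to edges
bilinear_sample <- function(m, rs, cs) {
  nr <- nrow(m)
  nc <- ncol(m)
  r0 <- pmin(pmax(floor(rs), 1), nr)
  c0 <- pmin(pmax(floor(cs), 1), nc)
  r1 <- pmin(r0 + 1, nr)
  c1 <- pmin(c0 + 1, nc)
  fr <- rs - r0
  fc <- cs - c0
  v00 <- m[cbind(r0, c0)]
  v01 <- m[cbind(r0, c1)]
  v10 <- m[cbind(r1, c0)]
  v11 <- m[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}
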
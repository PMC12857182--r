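#' Fraction of an ecDNA component's perimeter adjacent to chromosome pixels
#'
#' Boundary pixels are component pixels with at least one of their 8
#' neighbours outside the component (out-of-image neighbours count as
#' outside). The adjacency fraction is the share of boundary pixels that have
#' at least one 8-neighbour of chromosome class. Image-border sides are
#' non-chromosome by convention, so components touching the frame can never
#' be fully surrounded.
#'
#' @param pixels Integer (row, col) matrix of the component's pixels, or one
#'   row of the data frame returned by [label_components()] (its `pixels`
#'   entry is used).
#' @param labels A [label_mask()] in the spread context.
#' @return A list: `frac` in \[0,1\], `boundary_px`, `boundary_adj_chrom_px`.
#' @export
adjacency_fraction <- function(pixels, labels) {
  if (is.data.frame(pixels)) {
    if (nrow(pixels) != 1L) ect_error("pass a single component", "ect_invalid_input")
    pixels <- pixels$pixels[[1]]
  }
  if (is.null(dim(pixels)) || nrow(pixels) == 0L) {
    ect_error("component has no pixels", "ect_invalid_input")
  }
  lab <- unclass(labels)
  nr <- nrow(lab)
  nc <- ncol(lab)
  off <- neighbor_offsets(8L)
  in_comp <- matrix(FALSE, nr, nc)
  in_comp[pixels] <- TRUE
  n <- nrow(pixels)
  is_boundary <- logical(n)
  adj_chrom <- logical(n)
  for (j in seq_len(nrow(off))) {
    nb_r <- pixels[, 1L] + off[j, 1L]
    nb_c <- pixels[, 2L] + off[j, 2L]
    inside <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    nb_idx <- (pmax(nb_c, 1L) - 1L) * nr + pmax(nb_r, 1L)
    outside_comp <- !inside | !in_comp[nb_idx]
    is_boundary <- is_boundary | outside_comp
    adj_chrom <- adj_chrom |
      (inside & lab[nb_idx] == CLASS_CODES[["CHROMOSOME"]])
  }
  b <- sum(is_boundary)
  a <- sum(is_boundary & adj_chrom)
  list(
    frac = if (b > 0) a / b else 0,
    boundary_px = b,
    boundary_adj_chrom_px = a
  )
}

#' Tether class from a perimeter-adjacency fraction
#'
#' Classification cutoffs: adjacency below 25% of the perimeter is
#' untethered; 25% up to (but excluding) 100% is tethered; exactly 100% is
#' surrounded (fully enclosed by chromosome pixels) and excluded from the
#' untethering denominator. The printed upper bound "99.9%" is read as
#' display rounding of "anything short of all boundary pixels".
#'
#' @param frac Adjacency fraction in \[0,1\].
#' @param params A [tether_params()].
#' @return `"untethered"`, `"tethered"` or `"surrounded"`.
#' @export
classify_tether <- function(frac, params = tether_params()) {
  if (!is.numeric(frac) || anyNA(frac) || any(frac < 0) || any(frac > 1)) {
    ect_error("adjacency fraction must lie in [0,1]", "ect_invalid_input")
  }
  ifelse(frac >= params$surrounded_frac, "surrounded",
    ifelse(frac < params$untethered_max_frac, "untethered", "tethered")
  )
}

#' Summarize a prometaphase spread
#'
#' Computes the per-cell spread metrics: tether class counts, the ecDNA
#' untethering percentage (untethered / (untethered + tethered) x 100, with
#' fully surrounded components excluded from the denominator), and the
#' number of chromosome components (chromosome individualization).
#'
#' @param labels A spread-context [label_mask()].
#' @param components Optional precomputed components (both classes) from
#'   [label_components()]; recomputed from `labels` when omitted.
#' @param params A [tether_params()].
#' @param seg A [seg_params()] used when components must be recomputed.
#' @return A list of class `spread_metrics`: `n_chromosome_cc`,
#'   `n_untethered`, `n_tethered`, `n_surrounded`, `untethering_pct` (NA when
#'   no ecDNA outside chromosomes), and per-component details.
#' @export
summarize_spread <- function(labels, components = NULL,
                             params = tether_params(), seg = seg_params()) {
  if (is.null(components)) {
    components <- rbind(
      label_components(labels, seg, class_code = CLASS_CODES[["CHROMOSOME"]]),
      label_components(labels, seg, class_code = CLASS_CODES[["ECDNA"]])
    )
  }
  is_ec <- components$class_code == CLASS_CODES[["ECDNA"]]
  n_chrom <- sum(components$class_code == CLASS_CODES[["CHROMOSOME"]])
  tether <- character(0)
  fracs <- numeric(0)
  if (any(is_ec)) {
    ec <- components[is_ec, , drop = FALSE]
    fracs <- vapply(ec$pixels, function(px) adjacency_fraction(px, labels)$frac,
      numeric(1))
    tether <- classify_tether(fracs, params)
  }
  n_unt <- sum(tether == "untethered")
  n_tet <- sum(tether == "tethered")
  n_sur <- sum(tether == "surrounded")
  denom <- n_unt + n_tet
  structure(list(
    n_chromosome_cc = n_chrom,
    n_untethered = n_unt, n_tethered = n_tet, n_surrounded = n_sur,
    untethering_pct = if (denom > 0) 100 * n_unt / denom else NA_real_,
    adjacency_fractions = fracs, tether_classes = tether
  ), class = "spread_metrics")
}

#' Convex hull area of the DAPI + FISH union mask
#'
#' Area (in pixels) of the rasterized convex hull of all foreground pixel
#' centers of the union of the two masks — the drug-screen proxy for how
#' dispersed a spread is. A pixel counts if its center lies inside or on the
#' hull boundary (ties inclusive).
#'
#' @param dapi_mask,fish_mask [binary_mask()] objects of identical shape.
#' @return Nonnegative integer pixel count; 0 for an empty union.
#' @export
convex_hull_area <- function(dapi_mask, fish_mask) {
  check_same_shape(dapi_mask, fish_mask, "DAPI and FISH masks")
  u <- (unclass(dapi_mask) == 1L) | (unclass(fish_mask) == 1L)
  idx <- which(u)
  if (length(idx) == 0L) return(0L)
  nr <- nrow(u)
  pts <- cbind(r = ((idx - 1L) %% nr) + 1L, c = ((idx - 1L) %/% nr) + 1L)
  hull_raster_area(pts)
}

# Count integer lattice points inside/on the convex hull of pts (r, c).
# Convexity makes each row's intersection a single interval; accumulate the
# interval per row from hull edges with an inclusive epsilon.
hull_raster_area <- function(pts) {
  eps <- 1e-9
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  verts <- pts[h, , drop = FALSE]
  nv <- nrow(verts)
  rows <- min(pts[, 1L]):max(pts[, 1L])
  lo <- rep(Inf, length(rows))
  hi <- rep(-Inf, length(rows))
  edges <- cbind(seq_len(nv), c(seq_len(nv)[-1], 1L))
  if (nv == 1L) edges <- edges[1, , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    p <- verts[edges[e, 1L], ]
    q <- verts[edges[e, 2L], ]
    rmin <- min(p[1L], q[1L])
    rmax <- max(p[1L], q[1L])
    span <- rows >= rmin & rows <= rmax
    if (!any(span)) next
    rr <- rows[span]
    cc <- if (p[1L] == q[1L]) NULL else p[2L] + (rr - p[1L]) * (q[2L] - p[2L]) / (q[1L] - p[1L])
    i <- which(span)
    if (is.null(cc)) { # horizontal edge: both endpoints bound the row
      lo[i] <- pmin(lo[i], min(p[2L], q[2L]))
      hi[i] <- pmax(hi[i], max(p[2L], q[2L]))
    } else {
      lo[i] <- pmin(lo[i], cc)
      hi[i] <- pmax(hi[i], cc)
    }
  }
  total <- 0L
  for (i in seq_along(rows)) {
    if (is.finite(lo[i]) && is.finite(hi[i])) {
      cmin <- ceiling(lo[i] - eps)
      cmax <- floor(hi[i] + eps)
      if (cmax >= cmin) total <- total + (cmax - cmin + 1L)
    }
  }
  as.integer(total)
}

#' Per-class immunofluorescence / DAPI intensity ratio
#'
#' Mean IF intensity over the pixels of one class divided by the mean DAPI
#' intensity over the same pixels — e.g. pan-H3ac acetylation signal
#' normalized to DNA content for chromosome-class or ecDNA-class pixels.
#'
#' @param if_image,dapi_image [fluor_image()] objects sharing shape with
#'   `labels`.
#' @param labels A [label_mask()].
#' @param class_code Class to average over (see [CLASS_CODES]).
#' @return Positive ratio, or `NA_real_` if the class is empty.
#' @export
class_intensity_ratio <- function(if_image, dapi_image, labels, class_code) {
  if_image <- as_fluor_image(if_image, "IF")
  dapi_image <- as_fluor_image(dapi_image, "DAPI")
  check_same_shape(if_image, labels, "IF image and labels")
  check_same_shape(dapi_image, labels, "DAPI image and labels")
  sel <- unclass(labels) == class_code
  if (!any(sel)) return(NA_real_)
  dapi_mean <- mean(unclass(dapi_image)[sel])
  if (dapi_mean == 0) ect_error("zero DAPI mean over class", "ect_undefined_ratio")
  mean(unclass(if_image)[sel]) / dapi_mean
}
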
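# Pixel class codes used in spread-context label masks. ecDNA and chromosome
# are disjoint by construction: a pixel carries exactly one code.
#' Pixel class codes for label masks
#'
#' Integer codes used by [label_mask()]: `BACKGROUND = 0`, `CHROMOSOME = 1`,
#' `ECDNA = 2` in the prometaphase-spread context; `NUCLEUS = 1` in the
#' interphase-cell context. Daughter-pair partitions additionally use
#' `PRIMARY_NUCLEUS = 1`, `MICRONUCLEUS = 2`, `DEBRIS = 3`.
#'
#' @format A named integer vector.
#' @export
CLASS_CODES <- c(
  BACKGROUND = 0L, CHROMOSOME = 1L, ECDNA = 2L,
  NUCLEUS = 1L, PRIMARY_NUCLEUS = 1L, MICRONUCLEUS = 2L, DEBRIS = 3L
)

ect_error <- function(msg, class) {
  stop(structure(
    class = c(class, "ect_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Single-channel fluorescence image
#'
#' Wraps a numeric matrix of nonnegative intensities (arbitrary units) with a
#' channel label and an optional z-plane index.
#'
#' @param pixels Numeric matrix, all values >= 0, both dimensions >= 1.
#' @param channel Channel label, e.g. `"DAPI"`, `"FISH"`, `"IF"`.
#' @param z_index Optional integer plane index (0-based, as in the stack).
#' @return An object of class `fluor_image` (a matrix with attributes
#'   `channel` and `z_index`).
#' @export
fluor_image <- function(pixels, channel = "DAPI", z_index = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    ect_error("pixels must be a numeric matrix", "ect_invalid_input")
  }
  if (any(dim(pixels) < 1L) || length(pixels) == 0L) {
    ect_error("image must have both dimensions >= 1", "ect_invalid_input")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    ect_error("intensities must be finite and >= 0", "ect_invalid_input")
  }
  structure(pixels,
    channel = as.character(channel)[1],
    z_index = if (is.null(z_index)) NULL else as.integer(z_index)[1],
    class = c("fluor_image", "matrix", "array")
  )
}

as_fluor_image <- function(x, channel = "DAPI") {
  if (inherits(x, "fluor_image")) x else fluor_image(as.matrix(x), channel)
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf(
    "<fluor_image> %dx%d channel=%s%s range=[%.3g, %.3g]\n",
    nrow(x), ncol(x), attr(x, "channel"),
    if (is.null(attr(x, "z_index"))) "" else sprintf(" z=%d", attr(x, "z_index")),
    min(x), max(x)
  ))
  invisible(x)
}

#' Ordered z-stack of fluorescence images
#'
#' @param planes List of [fluor_image()] objects sharing shape and channel.
#' @param step_um Axial step between planes in micrometres (> 0); default 0.5.
#' @return An object of class `z_stack`.
#' @export
z_stack <- function(planes, step_um = 0.5) {
  if (!is.list(planes) || length(planes) < 1L) {
    ect_error("stack must contain at least one plane", "ect_invalid_input")
  }
  planes <- lapply(planes, as_fluor_image)
  d <- dim(planes[[1]])
  ch <- attr(planes[[1]], "channel")
  for (i in seq_along(planes)) {
    if (!identical(dim(planes[[i]]), d)) {
      ect_error("all planes must share the same shape", "ect_invalid_input")
    }
    if (!identical(attr(planes[[i]], "channel"), ch)) {
      ect_error("all planes must share the same channel", "ect_invalid_input")
    }
    attr(planes[[i]], "z_index") <- i - 1L
  }
  if (!is.numeric(step_um) || step_um <= 0) {
    ect_error("step_um must be > 0", "ect_invalid_input")
  }
  structure(list(planes = planes, step_um = step_um), class = "z_stack")
}

#' @export
length.z_stack <- function(x) length(x$planes)

#' @export
print.z_stack <- function(x, ...) {
  cat(sprintf(
    "<z_stack> %d planes of %dx%d, channel=%s, step=%.2f um\n",
    length(x$planes), nrow(x$planes[[1]]), ncol(x$planes[[1]]),
    attr(x$planes[[1]], "channel"), x$step_um
  ))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param pixels Matrix of 0/1 values (logical or numeric).
#' @param source_channel Label of the channel the mask was derived from.
#' @param threshold_used Numeric threshold that produced the mask (NA if the
#'   mask was constructed directly).
#' @return An object of class `binary_mask` (integer matrix with attributes).
#' @export
binary_mask <- function(pixels, source_channel = "", threshold_used = NA_real_) {
  if (is.logical(pixels)) pixels <- pixels * 1L
  if (!is.matrix(pixels) || !all(pixels %in% c(0L, 1L))) {
    ect_error("mask values must be 0 or 1", "ect_invalid_input")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels,
    source_channel = as.character(source_channel)[1],
    threshold_used = as.numeric(threshold_used)[1],
    class = c("binary_mask", "matrix", "array")
  )
}

#' Semantic pixel-class mask
#'
#' @param pixels Integer matrix of class codes. In the spread context codes are
#'   0 = background, 1 = chromosome, 2 = ecDNA; in the cell context 0/1
#'   (background/nucleus); in the daughter-pair context 0/1/2/3
#'   (background/primary/micronucleus/debris).
#' @param context One of `"spread"`, `"cell"`, `"daughter_pair"`.
#' @param provenance One of `"surrogate"`, `"imported"`, `"ground_truth"`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(pixels,
                       context = c("spread", "cell", "daughter_pair"),
                       provenance = c("surrogate", "imported", "ground_truth")) {
  context <- match.arg(context)
  provenance <- match.arg(provenance)
  if (!is.matrix(pixels)) ect_error("pixels must be a matrix", "ect_invalid_input")
  storage.mode(pixels) <- "integer"
  allowed <- switch(context,
    spread = 0:2, cell = 0:1, daughter_pair = 0:3
  )
  if (!all(pixels %in% allowed)) {
    ect_error(
      sprintf(
        "label mask for context '%s' contains codes outside {%s}",
        context, paste(allowed, collapse = ",")
      ),
      "ect_bad_codes"
    )
  }
  structure(pixels,
    context = context, provenance = provenance,
    class = c("label_mask", "matrix", "array")
  )
}

#' Segmentation parameters
#'
#' @param n_otsu_classes Number of intensity classes for multi-level Otsu
#'   (default 3, matching three-class thresholding of DAPI/FISH signal).
#' @param n_hist_bins Histogram bins over the observed min-max range (256).
#' @param threshold_rule `"higher"` (FISH, metaphase DAPI) or `"lower"`
#'   (interphase DAPI) — which Otsu threshold binarizes the channel.
#' @param connectivity Pixel connectivity for components: 8 (the 2-hop
#'   connectivity convention) or 4.
#' @param surrogate_min_chrom_area_px Minimum component area treated as a
#'   chromosome by the rule-based classifier (default 500 at synthetic scale).
#' @param surrogate_max_ecdna_area_px Maximum component area treated as ecDNA
#'   (default 200); must be smaller than `surrogate_min_chrom_area_px`.
#' @return A `seg_params` list.
#' @export
seg_params <- function(n_otsu_classes = 3L, n_hist_bins = 256L,
                       threshold_rule = c("higher", "lower"),
                       connectivity = 8L,
                       surrogate_min_chrom_area_px = 500L,
                       surrogate_max_ecdna_area_px = 200L) {
  threshold_rule <- match.arg(threshold_rule)
  if (n_otsu_classes < 2L) ect_error("n_otsu_classes must be >= 2", "ect_invalid_input")
  if (!connectivity %in% c(4L, 8L)) ect_error("connectivity must be 4 or 8", "ect_invalid_input")
  if (surrogate_max_ecdna_area_px >= surrogate_min_chrom_area_px) {
    ect_error("surrogate_max_ecdna_area_px must be < surrogate_min_chrom_area_px",
      "ect_invalid_input")
  }
  structure(list(
    n_otsu_classes = as.integer(n_otsu_classes),
    n_hist_bins = as.integer(n_hist_bins),
    threshold_rule = threshold_rule,
    connectivity = as.integer(connectivity),
    surrogate_min_chrom_area_px = as.integer(surrogate_min_chrom_area_px),
    surrogate_max_ecdna_area_px = as.integer(surrogate_max_ecdna_area_px)
  ), class = "seg_params")
}

#' Tether-classification parameters
#'
#' `untethered_max_frac` is the perimeter-adjacency fraction below which an
#' ecDNA component counts as untethered (< 25% of its perimeter adjacent to
#' chromosome pixels); components with exactly 100% adjacency are "surrounded"
#' and excluded from the untethering denominator.
#'
#' @param untethered_max_frac Upper bound (exclusive) for untethered; 0.25.
#' @param surrounded_frac Adjacency fraction defining "surrounded"; 1.0.
#' @return A `tether_params` list.
#' @export
tether_params <- function(untethered_max_frac = 0.25, surrounded_frac = 1.0) {
  if (!(untethered_max_frac > 0 && untethered_max_frac < surrounded_frac &&
    surrounded_frac <= 1)) {
    ect_error("need 0 < untethered_max_frac < surrounded_frac <= 1",
      "ect_invalid_input")
  }
  structure(list(
    untethered_max_frac = untethered_max_frac,
    surrounded_frac = surrounded_frac
  ), class = "tether_params")
}

#' Focus-counting parameters
#'
#' @param min_focus_px Minimum component area counted as a focus. Default 6:
#'   only components of more than five pixels are counted.
#' @return A `foci_params` list.
#' @export
foci_params <- function(min_focus_px = 6L) {
  if (min_focus_px < 1L) ect_error("min_focus_px must be >= 1", "ect_invalid_input")
  structure(list(min_focus_px = as.integer(min_focus_px)), class = "foci_params")
}

#' Daughter-pair nuclei partition parameters
#'
#' Automates the manual primary-nuclei / micronuclei labeling: the `n_primary`
#' largest DAPI components are primary nuclei, remaining components with area
#' in `[min_mn_area_px, max_mn_area_frac * smallest primary area]` are
#' micronuclei, smaller components are debris.
#'
#' @param n_primary Number of primary nuclei expected (2 for a daughter pair).
#' @param min_mn_area_px Minimum micronucleus area in pixels (default 10 at
#'   synthetic scale).
#' @param max_mn_area_frac Maximum micronucleus area as a fraction of the
#'   smallest primary nucleus (default 0.5).
#' @return A `nuclei_partition_params` list.
#' @export
nuclei_partition_params <- function(n_primary = 2L, min_mn_area_px = 10L,
                                    max_mn_area_frac = 0.5) {
  if (n_primary < 1L) ect_error("n_primary must be >= 1", "ect_invalid_input")
  if (min_mn_area_px < 1L) ect_error("min_mn_area_px must be >= 1", "ect_invalid_input")
  if (!(max_mn_area_frac > 0 && max_mn_area_frac < 1)) {
    ect_error("max_mn_area_frac must be in (0,1)", "ect_invalid_input")
  }
  structure(list(
    n_primary = as.integer(n_primary),
    min_mn_area_px = as.integer(min_mn_area_px),
    max_mn_area_frac = max_mn_area_frac
  ), class = "nuclei_partition_params")
}

# shared shape check
check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    ect_error(sprintf("%s must share the same shape", what), "ect_shape_mismatch")
  }
  invisible(TRUE)
}
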
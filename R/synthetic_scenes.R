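#' Synthetic-scene specification
#'
#' Describes one renderable scene with enough ground truth to verify every
#' pipeline metric by parameter recovery. Intensity levels give each channel
#' three separated populations (background, dim structure, bright signal) so
#' three-class Otsu thresholding is well posed even at zero noise.
#'
#' @param scene_kind One of `"spread"`, `"metaphase"`, `"daughter_pair"`,
#'   `"foci"`, `"focus_stack"`.
#' @param image_shape `(rows, cols)` of the rendered images.
#' @param seed Integer seed; the scene's single pseudo-random stream.
#' @param n_chromosomes,n_ecdna Spread object counts.
#' @param frac_untethered,frac_surrounded Target shares of ecDNA placed
#'   untethered / fully surrounded (remainder tethered); must sum to <= 1.
#' @param fish_px_total FISH-positive pixel budget for metaphase and
#'   daughter-pair scenes.
#' @param frac_fish_untethered Metaphase target share of off-plate FISH px.
#' @param n_micronuclei,myc_in_mn_frac Daughter-pair micronucleus count and
#'   target micronuclear share of FISH pixels.
#' @param n_foci,n_speckles Focus-scene counts of true foci (>= 6 px) and
#'   sub-threshold speckles (<= 5 px).
#' @param n_planes,focus_plane,blur_sigma Focus-stack geometry: number of
#'   planes, 0-based sharp plane, per-plane blur increment (the blur sigma of
#'   plane z is `blur_sigma * |z - focus_plane|`).
#' @param noise_sigma Gaussian read-noise s.d. added to every channel
#'   (clipped at 0). Default 10: moderate noise, ~1/11 of the smallest
#'   class-mean gap, so thresholding stays well posed without a small-object
#'   filter.
#' @param intensity_levels Named per-class channel means; see defaults.
#' @param h3ac_ratio_per_class Named IF/DAPI ratios rendered into the spread
#'   IF channel (`chromosome`, `ecdna`).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(scene_kind = c("spread", "metaphase", "daughter_pair",
                         "foci", "focus_stack"),
                       image_shape = c(256L, 256L), seed = 1L,
                       n_chromosomes = 6L, n_ecdna = 20L,
                       frac_untethered = 0.3, frac_surrounded = 0.1,
                       fish_px_total = 200L, frac_fish_untethered = 0.2,
                       n_micronuclei = 2L, myc_in_mn_frac = 0.1,
                       n_foci = 5L, n_speckles = 5L,
                       n_planes = 5L, focus_plane = 2L, blur_sigma = 1.5,
                       noise_sigma = 10,
                       intensity_levels = NULL,
                       h3ac_ratio_per_class = c(chromosome = 1.0, ecdna = 2.0)) {
  scene_kind <- match.arg(scene_kind)
  if (frac_untethered + frac_surrounded > 1 + 1e-12) {
    ect_error("frac_untethered + frac_surrounded must be <= 1", "ect_invalid_input")
  }
  if (any(c(n_chromosomes, n_ecdna, n_micronuclei, n_foci, n_speckles) < 0)) {
    ect_error("object counts must be >= 0", "ect_invalid_input")
  }
  if (noise_sigma < 0) ect_error("noise_sigma must be >= 0", "ect_invalid_input")
  if (scene_kind == "focus_stack" && focus_plane >= n_planes) {
    ect_error("focus_plane must be < n_planes", "ect_invalid_input")
  }
  defaults <- list(
    dapi_background = 10, dapi_ecdna = 120, dapi_chromosome = 200,
    dapi_nucleus = 180, dapi_micronucleus = 150, dapi_chromocenter = 300,
    dapi_plate = 200, dapi_offplate_ecdna = 100,
    fish_background = 5, fish_crosshyb = 30, fish_nucleus_bg = 40,
    fish_focus = 180,
    if_background = 2, if_nucleus = 60, if_focus = 200
  )
  if (!is.null(intensity_levels)) defaults[names(intensity_levels)] <- intensity_levels
  structure(list(
    scene_kind = scene_kind, image_shape = as.integer(image_shape),
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes), n_ecdna = as.integer(n_ecdna),
    frac_untethered = frac_untethered, frac_surrounded = frac_surrounded,
    fish_px_total = as.integer(fish_px_total),
    frac_fish_untethered = frac_fish_untethered,
    n_micronuclei = as.integer(n_micronuclei), myc_in_mn_frac = myc_in_mn_frac,
    n_foci = as.integer(n_foci), n_speckles = as.integer(n_speckles),
    n_planes = as.integer(n_planes), focus_plane = as.integer(focus_plane),
    blur_sigma = blur_sigma,
    noise_sigma = noise_sigma, intensity_levels = defaults,
    h3ac_ratio_per_class = h3ac_ratio_per_class
  ), class = "scene_spec")
}

# add clipped Gaussian noise to an intensity matrix
add_noise <- function(m, sigma) {
  if (sigma <= 0) return(m)
  pmax(m + matrix(stats::rnorm(length(m), 0, sigma), nrow(m)), 0)
}

gen_error <- function(what) {
  ect_error(sprintf("scene generation failed: %s", what), "ect_generation_error")
}

#' Generate a prometaphase spread scene
#'
#' Renders elongated chromosome bodies (anti-overlap capsules) and small
#' ecDNA discs whose realized perimeter adjacency satisfies the intended
#' tether class exactly: `round(frac_untethered * n)` discs are placed clear
#' of any chromosome, `round(frac_surrounded * n)` are carved fully inside a
#' chromosome, and the remainder touch a chromosome flank with adjacency in
#' `[0.25, 1)`. Each intended class is asserted against [classify_tether()]
#' on the realized adjacency at generation time. DAPI renders chromosomes
#' bright and ecDNA dim; FISH marks exactly the ecDNA pixels (with faint
#' chromosomal cross-hybridization as a third intensity level); an IF channel
#' applies the configured per-class IF/DAPI ratios.
#'
#' @param spec A [scene_spec()] with `scene_kind = "spread"`.
#' @return A list: `dapi`, `fish`, `h3ac` ([fluor_image()]), `truth` (a list
#'   with the ground-truth [label_mask()], per-object table `objects`
#'   (class, intended/realized tether, adjacency fraction), realized counts
#'   and `untethering_pct`).
#' @export
generate_spread_scene <- function(spec = scene_spec("spread")) {
  stopifnot(spec$scene_kind == "spread")
  with_local_seed(spec$seed, {
    nr <- spec$image_shape[1]
    nc <- spec$image_shape[2]
    lab <- matrix(0L, nr, nc)
    lvl <- spec$intensity_levels

    chrom_half_width <- 5.5
    chrom_len <- c(55, 75)
    chromosomes <- list()
    for (i in seq_len(spec$n_chromosomes)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        len <- stats::runif(1, chrom_len[1], chrom_len[2])
        ang <- stats::runif(1, 0, pi)
        r0 <- stats::runif(1, 15, nr - 15)
        c0 <- stats::runif(1, 15, nc - 15)
        r1 <- r0 + len * cos(ang)
        c1 <- c0 + len * sin(ang)
        if (r1 < 10 || r1 > nr - 10 || c1 < 10 || c1 > nc - 10) next
        px <- capsule_pixels(r0, c0, r1, c1, chrom_half_width, nr, nc)
        # 2-px clearance so chromosomes stay individual components
        guard <- capsule_pixels(r0, c0, r1, c1, chrom_half_width + 2, nr, nc)
        if (any(lab[guard] != 0L)) next
        lab[px] <- CLASS_CODES[["CHROMOSOME"]]
        chromosomes[[i]] <- list(px = px, r0 = r0, c0 = c0, r1 = r1, c1 = c1)
        placed <- TRUE
        break
      }
      if (!placed) gen_error("could not place chromosome")
    }

    n <- spec$n_ecdna
    n_unt <- round_half_up(spec$frac_untethered * n)
    n_sur <- round_half_up(spec$frac_surrounded * n)
    if (n_unt + n_sur > n) n_sur <- n - n_unt
    n_tet <- n - n_unt - n_sur
    intended <- c(
      rep("untethered", n_unt), rep("surrounded", n_sur), rep("tethered", n_tet)
    )
    objects <- data.frame(
      object_id = seq_len(spec$n_chromosomes + n),
      class = c(rep("chromosome", spec$n_chromosomes), rep("ecdna", n)),
      intended_tether = c(rep(NA_character_, spec$n_chromosomes), intended),
      adjacency_fraction = NA_real_, area_px = NA_integer_
    )
    ec_pixels <- vector("list", n)

    place_untethered <- function(radius) {
      for (try in seq_len(400)) {
        r0 <- stats::runif(1, radius + 2, nr - radius - 2)
        c0 <- stats::runif(1, radius + 2, nc - radius - 2)
        guard <- disc_pixels(r0, c0, radius + 2.5, nr, nc)
        if (any(lab[guard] != 0L)) next
        return(disc_pixels(r0, c0, radius, nr, nc))
      }
      NULL
    }
    place_surrounded <- function(radius) {
      for (try in seq_len(400)) {
        ch <- chromosomes[[sample.int(length(chromosomes), 1L)]]
        t <- stats::runif(1, 0.2, 0.8)
        r0 <- ch$r0 + t * (ch$r1 - ch$r0)
        c0 <- ch$c0 + t * (ch$c1 - ch$c0)
        px <- disc_pixels(r0, c0, radius, nr, nc)
        ring <- disc_pixels(r0, c0, radius + 1.9, nr, nc)
        halo <- ring[!px_index(ring, nr) %in% px_index(px, nr), , drop = FALSE]
        if (!all(lab[px] == CLASS_CODES[["CHROMOSOME"]])) next
        if (!all(lab[halo] == CLASS_CODES[["CHROMOSOME"]])) next
        return(px)
      }
      NULL
    }
    place_tethered <- function(radius) {
      for (try in seq_len(600)) {
        ch <- chromosomes[[sample.int(length(chromosomes), 1L)]]
        t <- stats::runif(1, 0.1, 0.9)
        ar <- ch$r0 + t * (ch$r1 - ch$r0)
        ac <- ch$c0 + t * (ch$c1 - ch$c0)
        ang <- stats::runif(1, 0, 2 * pi)
        # centre just outside the capsule so the disc overlaps its flank
        dist <- chrom_half_width + radius * stats::runif(1, 0.0, 0.6)
        r0 <- ar + dist * cos(ang)
        c0 <- ac + dist * sin(ang)
        if (r0 < radius + 2 || r0 > nr - radius - 2 ||
          c0 < radius + 2 || c0 > nc - radius - 2) next
        px <- disc_pixels(r0, c0, radius, nr, nc)
        px <- px[lab[px] == 0L, , drop = FALSE] # clip to free space
        if (nrow(px) < 5L) next
        # must not 8-touch any previously placed ecDNA (components would merge)
        ring <- disc_pixels(r0, c0, radius + 1.9, nr, nc)
        if (any(lab[ring] == CLASS_CODES[["ECDNA"]])) next
        trial <- lab
        trial[px] <- CLASS_CODES[["ECDNA"]]
        af <- adjacency_fraction(px, label_mask(trial, "spread", "ground_truth"))
        if (af$frac >= 0.25 && af$frac < 1) {
          # ensure the clipped disc is one 8-connected component
          sel <- matrix(FALSE, nr, nc)
          sel[px] <- TRUE
          if (nrow(label_components(sel)) == 1L) return(px)
        }
      }
      NULL
    }

    for (i in seq_len(n)) {
      # radius capped at 7 so disc area stays below the surrogate ecDNA cutoff
      radius <- stats::runif(1, 3, if (intended[i] == "surrounded") 3.4 else 7)
      px <- switch(intended[i],
        untethered = place_untethered(radius),
        surrounded = place_surrounded(radius),
        tethered = place_tethered(radius)
      )
      if (is.null(px)) gen_error(sprintf("could not place %s ecDNA", intended[i]))
      lab[px] <- CLASS_CODES[["ECDNA"]]
      ec_pixels[[i]] <- px
    }

    truth_mask <- label_mask(lab, context = "spread", provenance = "ground_truth")
    for (i in seq_len(n)) {
      af <- adjacency_fraction(ec_pixels[[i]], truth_mask)
      realized <- classify_tether(af$frac)
      if (realized != intended[i]) {
        gen_error(sprintf(
          "realized tether class '%s' != intended '%s' (frac %.3f)",
          realized, intended[i], af$frac
        ))
      }
      row <- spec$n_chromosomes + i
      objects$adjacency_fraction[row] <- af$frac
      objects$area_px[row] <- nrow(ec_pixels[[i]])
    }
    for (i in seq_len(spec$n_chromosomes)) {
      objects$area_px[i] <- nrow(chromosomes[[i]]$px)
    }

    dapi <- matrix(lvl$dapi_background, nr, nc)
    dapi[lab == CLASS_CODES[["CHROMOSOME"]]] <- lvl$dapi_chromosome
    dapi[lab == CLASS_CODES[["ECDNA"]]] <- lvl$dapi_ecdna
    fish <- matrix(lvl$fish_background, nr, nc)
    fish[lab == CLASS_CODES[["CHROMOSOME"]]] <- lvl$fish_crosshyb
    fish[lab == CLASS_CODES[["ECDNA"]]] <- lvl$fish_focus
    rr <- spec$h3ac_ratio_per_class
    h3ac <- matrix(lvl$if_background, nr, nc)
    h3ac[lab == CLASS_CODES[["CHROMOSOME"]]] <- rr[["chromosome"]] * lvl$dapi_chromosome
    h3ac[lab == CLASS_CODES[["ECDNA"]]] <- rr[["ecdna"]] * lvl$dapi_ecdna

    denom <- n_unt + n_tet
    list(
      dapi = fluor_image(add_noise(dapi, spec$noise_sigma), "DAPI"),
      fish = fluor_image(add_noise(fish, spec$noise_sigma), "FISH"),
      h3ac = fluor_image(add_noise(h3ac, spec$noise_sigma), "IF"),
      truth = list(
        mask = truth_mask, objects = objects,
        n_untethered = n_unt, n_tethered = n_tet, n_surrounded = n_sur,
        n_chromosome_cc = spec$n_chromosomes,
        untethering_pct = if (denom > 0) 100 * n_unt / denom else NA_real_,
        h3ac_ratio_per_class = rr
      ),
      spec = spec
    )
  })
}

#' Generate a metaphase-cell scene
#'
#' One dominant DAPI plate (the genomic mass) plus FISH signal split on/off
#' the plate: the off-plate FISH pixel count is
#' `round(frac_fish_untethered * fish_px_total)`, realized exactly by growing
#' pixel-exact blobs. Off-plate FISH blobs sit on dim DAPI discs (ecDNA DNA
#' content) that never touch the plate.
#'
#' @param spec A [scene_spec()] with `scene_kind = "metaphase"`.
#' @return A list: `dapi`, `fish`, `truth` (plate mask, FISH pixel counts,
#'   `untethered_pct`), `spec`.
#' @export
generate_metaphase_scene <- function(spec = scene_spec("metaphase")) {
  stopifnot(spec$scene_kind == "metaphase")
  with_local_seed(spec$seed, {
    nr <- spec$image_shape[1]
    nc <- spec$image_shape[2]
    lvl <- spec$intensity_levels
    plate <- matrix(FALSE, nr, nc)
    # elliptical plate in the centre
    a <- nr * 0.22
    b <- nc * 0.13
    ctr <- c(nr / 2, nc / 2) + stats::runif(2, -6, 6)
    g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    inside <- ((g$row - ctr[1]) / a)^2 + ((g$col - ctr[2]) / b)^2 <= 1
    plate[as.matrix(g[inside, ])] <- TRUE

    total <- spec$fish_px_total
    n_off <- round_half_up(spec$frac_fish_untethered * total)
    n_on <- total - n_off
    fish_px <- matrix(FALSE, nr, nc)
    # tethered FISH: compact blobs grown inside the plate
    remaining <- n_on
    while (remaining > 0L) {
      size <- min(remaining, sample(20:40, 1L))
      blob <- grow_blob(plate & !fish_px, size, which(plate & !fish_px))
      if (is.null(blob)) gen_error("could not place on-plate FISH")
      fish_px[blob] <- TRUE
      remaining <- remaining - size
    }
    # untethered FISH: dim DAPI discs off the plate carrying FISH blobs
    off_dapi <- matrix(FALSE, nr, nc)
    remaining <- n_off
    while (remaining > 0L) {
      size <- min(remaining, sample(15:30, 1L))
      placed <- FALSE
      for (try in seq_len(400)) {
        radius <- stats::runif(1, 4, 6)
        r0 <- stats::runif(1, radius + 2, nr - radius - 2)
        c0 <- stats::runif(1, radius + 2, nc - radius - 2)
        guard <- disc_pixels(r0, c0, radius + 2.5, nr, nc)
        if (any(plate[guard]) || any(off_dapi[guard])) next
        disc <- disc_pixels(r0, c0, radius, nr, nc)
        if (nrow(disc) < size) next
        off_dapi[disc] <- TRUE
        allowed <- matrix(FALSE, nr, nc)
        allowed[disc] <- TRUE
        blob <- grow_blob(allowed, size, px_index(disc, nr))
        fish_px[blob] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) gen_error("could not place off-plate FISH")
      remaining <- remaining - size
    }

    dapi <- matrix(lvl$dapi_background, nr, nc)
    dapi[off_dapi] <- lvl$dapi_offplate_ecdna
    dapi[plate] <- lvl$dapi_plate
    fish <- matrix(lvl$fish_background, nr, nc)
    fish[plate | off_dapi] <- lvl$fish_crosshyb
    fish[fish_px] <- lvl$fish_focus

    list(
      dapi = fluor_image(add_noise(dapi, spec$noise_sigma), "DAPI"),
      fish = fluor_image(add_noise(fish, spec$noise_sigma), "FISH"),
      truth = list(
        plate_mask = binary_mask(plate, "DAPI"),
        fish_mask = binary_mask(fish_px, "FISH"),
        myc_px_total = total, myc_px_untethered = n_off,
        untethered_pct = if (total > 0) 100 * n_off / total else NA_real_
      ),
      spec = spec
    )
  })
}

#' Generate a daughter-cell-pair scene
#'
#' Two large primary nuclei side by side plus `n_micronuclei` small DAPI
#' bodies. FISH pixels are placed so the micronuclear share equals
#' `round(myc_in_mn_frac * fish_px_total)` exactly (pixel-exact blobs).
#' Micronuclei are rendered slightly dimmer than primaries, giving the DAPI
#' histogram its third population.
#'
#' @param spec A [scene_spec()] with `scene_kind = "daughter_pair"`.
#' @return A list: `dapi`, `fish`, `truth` (partition [label_mask()], FISH
#'   counts, `myc_in_mn_pct`, `mn_composition_pct`), `spec`.
#' @export
generate_daughter_pair_scene <- function(spec = scene_spec("daughter_pair")) {
  stopifnot(spec$scene_kind == "daughter_pair")
  with_local_seed(spec$seed, {
    nr <- spec$image_shape[1]
    nc <- spec$image_shape[2]
    lvl <- spec$intensity_levels
    part <- matrix(0L, nr, nc)
    prim_r <- 28
    centres <- list(
      c(nr / 2 + stats::runif(1, -5, 5), nc * 0.3 + stats::runif(1, -5, 5)),
      c(nr / 2 + stats::runif(1, -5, 5), nc * 0.7 + stats::runif(1, -5, 5))
    )
    for (ct in centres) {
      px <- disc_pixels(ct[1], ct[2], prim_r, nr, nc)
      part[px] <- CLASS_CODES[["PRIMARY_NUCLEUS"]]
    }
    mn_list <- list()
    for (i in seq_len(spec$n_micronuclei)) {
      placed <- FALSE
      for (try in seq_len(400)) {
        radius <- stats::runif(1, 3, 6)
        r0 <- stats::runif(1, radius + 2, nr - radius - 2)
        c0 <- stats::runif(1, radius + 2, nc - radius - 2)
        guard <- disc_pixels(r0, c0, radius + 2.5, nr, nc)
        if (any(part[guard] != 0L)) next
        px <- disc_pixels(r0, c0, radius, nr, nc)
        part[px] <- CLASS_CODES[["MICRONUCLEUS"]]
        mn_list[[i]] <- px
        placed <- TRUE
        break
      }
      if (!placed) gen_error("could not place micronucleus")
    }

    total <- spec$fish_px_total
    n_mn_fish <- if (spec$n_micronuclei > 0) {
      round_half_up(spec$myc_in_mn_frac * total)
    } else 0L
    mn_area <- sum(part == CLASS_CODES[["MICRONUCLEUS"]])
    if (n_mn_fish > mn_area) gen_error("micronuclei too small for FISH budget")
    fish_px <- matrix(FALSE, nr, nc)
    if (n_mn_fish > 0L) {
      # spread the micronuclear FISH budget across micronuclei
      left <- n_mn_fish
      for (i in seq_along(mn_list)) {
        share <- if (i == length(mn_list)) left else min(left, ceiling(n_mn_fish / length(mn_list)))
        if (share <= 0L) break
        allowed <- matrix(FALSE, nr, nc)
        allowed[mn_list[[i]]] <- TRUE
        share <- min(share, nrow(mn_list[[i]]))
        blob <- grow_blob(allowed & !fish_px, share, which(allowed & !fish_px))
        if (is.null(blob)) gen_error("could not place micronuclear FISH")
        fish_px[blob] <- TRUE
        left <- left - share
      }
      if (left > 0L) gen_error("could not place micronuclear FISH budget")
    }
    in_primary <- part == CLASS_CODES[["PRIMARY_NUCLEUS"]]
    remaining <- total - n_mn_fish
    while (remaining > 0L) {
      size <- min(remaining, sample(15:30, 1L))
      blob <- grow_blob(in_primary & !fish_px, size, which(in_primary & !fish_px))
      if (is.null(blob)) gen_error("could not place primary-nucleus FISH")
      fish_px[blob] <- TRUE
      remaining <- remaining - size
    }

    dapi <- matrix(lvl$dapi_background, nr, nc)
    dapi[part == CLASS_CODES[["PRIMARY_NUCLEUS"]]] <- lvl$dapi_nucleus
    dapi[part == CLASS_CODES[["MICRONUCLEUS"]]] <- lvl$dapi_micronucleus
    # bright chromocenters inside the primaries: the third DAPI intensity
    # population interphase nuclei carry, which keeps three-class Otsu's
    # upper threshold out of the nuclear class (the lower threshold is the
    # one that segments interphase DAPI)
    for (ct in centres) {
      for (k in seq_len(4L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0, prim_r * 0.6)
        px <- disc_pixels(ct[1] + d * cos(ang), ct[2] + d * sin(ang),
          stats::runif(1, 4, 6), nr, nc)
        px <- px[part[px] == CLASS_CODES[["PRIMARY_NUCLEUS"]], , drop = FALSE]
        dapi[px] <- lvl$dapi_chromocenter
      }
    }
    fish <- matrix(lvl$fish_background, nr, nc)
    fish[part != 0L] <- lvl$fish_nucleus_bg
    fish[fish_px] <- lvl$fish_focus

    list(
      dapi = fluor_image(add_noise(dapi, spec$noise_sigma), "DAPI"),
      fish = fluor_image(add_noise(fish, spec$noise_sigma), "FISH"),
      truth = list(
        partition = label_mask(part, "daughter_pair", "ground_truth"),
        fish_mask = binary_mask(fish_px, "FISH"),
        n_micronuclei = spec$n_micronuclei,
        has_micronuclei = spec$n_micronuclei > 0L,
        myc_px_total = total, myc_px_in_mn = n_mn_fish,
        myc_in_mn_pct = if (total > 0) 100 * n_mn_fish / total else NA_real_,
        mn_composition_pct = if (mn_area > 0) 100 * n_mn_fish / mn_area else NA_real_
      ),
      spec = spec
    )
  })
}

#' Generate a foci scene
#'
#' A nucleus disc with `n_foci` bright IF components of at least 6 pixels and
#' `n_speckles` components of at most 5 pixels, mutually separated so the
#' components stay distinct under 8-connectivity; the nucleus interior is an
#' intermediate intensity level so three-class Otsu isolates the foci.
#'
#' @param spec A [scene_spec()] with `scene_kind = "foci"`.
#' @return A list: `if_image`, `cell_mask` ([binary_mask()]), `truth`
#'   (`n_foci`, `n_speckles`, per-component sizes), `spec`.
#' @export
generate_foci_scene <- function(spec = scene_spec("foci")) {
  stopifnot(spec$scene_kind == "foci")
  with_local_seed(spec$seed, {
    nr <- spec$image_shape[1]
    nc <- spec$image_shape[2]
    lvl <- spec$intensity_levels
    nucleus <- matrix(FALSE, nr, nc)
    px <- disc_pixels(nr / 2, nc / 2, min(nr, nc) * 0.4, nr, nc)
    nucleus[px] <- TRUE
    occupied <- matrix(FALSE, nr, nc)
    sizes <- c(
      if (spec$n_foci > 0) sample(6:25, spec$n_foci, replace = TRUE),
      if (spec$n_speckles > 0) sample(1:5, spec$n_speckles, replace = TRUE)
    )
    is_focus <- c(rep(TRUE, spec$n_foci), rep(FALSE, spec$n_speckles))
    comp_sizes <- integer(0)
    foci_px <- matrix(FALSE, nr, nc)
    for (i in seq_along(sizes)) {
      placed <- FALSE
      for (try in seq_len(400)) {
        allowed <- nucleus & !occupied
        blob <- grow_blob(allowed, sizes[i], which(allowed))
        if (is.null(blob)) next
        foci_px[blob] <- TRUE
        # 2-px guard so neighbouring components never 8-touch
        for (dr in -2:2) for (dc in -2:2) {
          gr <- pmin(pmax(blob[, 1L] + dr, 1L), nr)
          gc <- pmin(pmax(blob[, 2L] + dc, 1L), nc)
          occupied[cbind(gr, gc)] <- TRUE
        }
        comp_sizes <- c(comp_sizes, nrow(blob))
        placed <- TRUE
        break
      }
      if (!placed) gen_error("could not place focus/speckle")
    }
    img <- matrix(lvl$if_background, nr, nc)
    img[nucleus] <- lvl$if_nucleus
    img[foci_px] <- lvl$if_focus
    list(
      if_image = fluor_image(add_noise(img, spec$noise_sigma), "IF"),
      cell_mask = binary_mask(nucleus, "DAPI"),
      truth = list(
        n_foci = spec$n_foci, n_speckles = spec$n_speckles,
        component_sizes = comp_sizes, is_focus = is_focus,
        foci_mask = binary_mask(foci_px, "IF")
      ),
      spec = spec
    )
  })
}

#' Generate a defocused z-stack
#'
#' One textured sharp plane at `focus_plane`; every other plane is the same
#' texture blurred with a Gaussian whose sigma grows linearly with the
#' distance from the sharp plane (`blur_sigma` per plane).
#'
#' @param spec A [scene_spec()] with `scene_kind = "focus_stack"`.
#' @return A list: `stack` ([z_stack()]), `truth` (`focus_plane`), `spec`.
#' @export
generate_focus_stack <- function(spec = scene_spec("focus_stack")) {
  stopifnot(spec$scene_kind == "focus_stack")
  with_local_seed(spec$seed, {
    nr <- spec$image_shape[1]
    nc <- spec$image_shape[2]
    base <- matrix(stats::runif(nr * nc, 0, 255), nr, nc)
    base <- gaussian_blur(base, 0.8) # correlated texture, still sharp
    planes <- lapply(seq_len(spec$n_planes) - 1L, function(z) {
      s <- spec$blur_sigma * abs(z - spec$focus_plane)
      img <- gaussian_blur(base, s)
      fluor_image(add_noise(img, spec$noise_sigma), "DAPI")
    })
    list(
      stack = z_stack(planes, step_um = 0.5),
      truth = list(focus_plane = spec$focus_plane),
      spec = spec
    )
  })
}
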
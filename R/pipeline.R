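# Configuration-driven orchestration: fixtures generation, per-scene
# quantification, cohort statistics. The config is one declarative JSON file;
# every default is echoed into the run log so a run is self-describing.

#' Build a run configuration
#'
#' @param mode One of `"fixtures"`, `"spread"`, `"screen"`, `"metaphase"`,
#'   `"daughter_pair"`, `"foci"`, `"stats"`.
#' @param out_dir Output directory (created if missing).
#' @param scenes For fixtures mode: a list of argument lists forwarded to
#'   [scene_spec()] (each may omit `seed`; seeds default to
#'   `seed + scene index`).
#' @param input_dir For quantification modes: a directory produced by
#'   fixtures mode.
#' @param mask_source `"otsu"` (threshold the channels) or `"truth"` (use the
#'   ground-truth masks shipped with each fixture).
#' @param seed Base integer seed.
#' @param conditions Optional per-scene condition labels.
#' @param stats_input,tests For stats mode: metrics CSV path and the list of
#'   test requests (see [run_stats()]).
#' @param seg,tether,foci,nuclei Parameter blocks ([seg_params()] etc.).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(mode, out_dir, scenes = NULL, input_dir = NULL,
                       mask_source = c("otsu", "truth"), seed = 1L,
                       conditions = NULL, stats_input = NULL, tests = NULL,
                       seg = seg_params(), tether = tether_params(),
                       foci = foci_params(), nuclei = nuclei_partition_params(),
                       log_level = c("info", "quiet")) {
  modes <- c("fixtures", "spread", "screen", "metaphase", "daughter_pair",
    "foci", "stats")
  if (!mode %in% modes) {
    ect_error(sprintf("unknown mode '%s' (valid: %s)", mode,
      paste(modes, collapse = ", ")), "ect_invalid_input")
  }
  structure(list(
    mode = mode, out_dir = out_dir, scenes = scenes, input_dir = input_dir,
    mask_source = match.arg(mask_source), seed = as.integer(seed),
    conditions = conditions, stats_input = stats_input, tests = tests,
    seg = seg, tether = tether, foci = foci, nuclei = nuclei,
    log_level = match.arg(log_level)
  ), class = "run_config")
}

log_lines <- function(config, lines) {
  if (!is.null(config$out_dir)) {
    cat(lines, file = file.path(config$out_dir, "run.log"), sep = "\n",
      append = TRUE)
  }
  if (config$log_level == "info") message(paste(lines, collapse = "\n"))
  invisible(NULL)
}

scene_dir_name <- function(i) sprintf("scene_%03d", i)

#' Materialize synthetic fixture scenes on disk
#'
#' Writes, per scene, the rendered channels as 16-bit TIFF, the ground-truth
#' label/binary masks as 8-bit TIFF, and a `truth.json` sidecar with the
#' scene kind and realized truth values.
#'
#' @param config A [run_config()] with `mode = "fixtures"`.
#' @return Invisibly, the vector of scene directories written.
#' @export
run_fixtures <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$scenes) || length(config$scenes) == 0L) {
    ect_error("fixtures mode needs a nonempty 'scenes' list", "ect_invalid_input")
  }
  dirs <- character(length(config$scenes))
  for (i in seq_along(config$scenes)) {
    args <- config$scenes[[i]]
    if (is.null(args$seed)) args$seed <- config$seed + i
    spec <- do.call(scene_spec, args)
    d <- file.path(config$out_dir, scene_dir_name(i))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    truth_json <- list(scene_kind = spec$scene_kind, seed = spec$seed)
    if (spec$scene_kind == "spread") {
      sc <- generate_spread_scene(spec)
      write_tiff_gray(sc$dapi, file.path(d, "dapi.tif"))
      write_tiff_gray(sc$fish, file.path(d, "fish.tif"))
      write_tiff_gray(sc$h3ac, file.path(d, "h3ac.tif"))
      write_tiff_gray(fluor_image(unclass(sc$truth$mask) + 0, "labels"),
        file.path(d, "truth_mask.tif"), bits = 8L)
      truth_json <- c(truth_json, sc$truth[c(
        "n_untethered", "n_tethered", "n_surrounded", "n_chromosome_cc",
        "untethering_pct"
      )])
    } else if (spec$scene_kind == "metaphase") {
      sc <- generate_metaphase_scene(spec)
      write_tiff_gray(sc$dapi, file.path(d, "dapi.tif"))
      write_tiff_gray(sc$fish, file.path(d, "fish.tif"))
      write_tiff_gray(fluor_image(unclass(sc$truth$plate_mask) + 0, "labels"),
        file.path(d, "truth_plate.tif"), bits = 8L)
      write_tiff_gray(fluor_image(unclass(sc$truth$fish_mask) + 0, "labels"),
        file.path(d, "truth_fish.tif"), bits = 8L)
      truth_json <- c(truth_json, sc$truth[c(
        "myc_px_total", "myc_px_untethered", "untethered_pct"
      )])
    } else if (spec$scene_kind == "daughter_pair") {
      sc <- generate_daughter_pair_scene(spec)
      write_tiff_gray(sc$dapi, file.path(d, "dapi.tif"))
      write_tiff_gray(sc$fish, file.path(d, "fish.tif"))
      write_tiff_gray(fluor_image(unclass(sc$truth$partition) + 0, "labels"),
        file.path(d, "truth_partition.tif"), bits = 8L)
      write_tiff_gray(fluor_image(unclass(sc$truth$fish_mask) + 0, "labels"),
        file.path(d, "truth_fish.tif"), bits = 8L)
      truth_json <- c(truth_json, sc$truth[c(
        "n_micronuclei", "myc_px_total", "myc_px_in_mn", "myc_in_mn_pct",
        "mn_composition_pct"
      )])
    } else if (spec$scene_kind == "foci") {
      sc <- generate_foci_scene(spec)
      write_tiff_gray(sc$if_image, file.path(d, "if.tif"))
      write_tiff_gray(fluor_image(unclass(sc$cell_mask) + 0, "labels"),
        file.path(d, "cell_mask.tif"), bits = 8L)
      write_tiff_gray(fluor_image(unclass(sc$truth$foci_mask) + 0, "labels"),
        file.path(d, "truth_foci.tif"), bits = 8L)
      truth_json <- c(truth_json, sc$truth[c("n_foci", "n_speckles")])
    } else if (spec$scene_kind == "focus_stack") {
      sc <- generate_focus_stack(spec)
      write_tiff_gray(sc$stack$planes, file.path(d, "stack.tif"))
      truth_json <- c(truth_json, sc$truth["focus_plane"])
    }
    jsonlite::write_json(truth_json, file.path(d, "truth.json"),
      auto_unbox = TRUE, digits = NA)
    dirs[i] <- d
  }
  log_lines(config, c(
    sprintf("fixtures: wrote %d scenes to %s", length(dirs), config$out_dir),
    sprintf("seed: %d", config$seed)
  ))
  invisible(dirs)
}

read_scene <- function(d) {
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  list(dir = d, truth = truth, kind = truth$scene_kind)
}

quantify_scene <- function(scene, config) {
  d <- scene$dir
  seg_h <- config$seg
  seg_h$threshold_rule <- "higher"
  seg_l <- config$seg
  seg_l$threshold_rule <- "lower"
  kind <- scene$kind
  use_truth <- config$mask_source == "truth"
  if (kind == "spread") {
    if (use_truth) {
      labs <- label_mask(
        unclass(read_tiff_gray(file.path(d, "truth_mask.tif"))[[1]]) + 0L,
        context = "spread", provenance = "ground_truth"
      )
      dapi_m <- binary_mask(unclass(labs) != 0L, "DAPI")
      fish_m <- binary_mask(unclass(labs) == CLASS_CODES[["ECDNA"]], "FISH")
    } else {
      dapi <- read_tiff_gray(file.path(d, "dapi.tif"), "DAPI")[[1]]
      fish <- read_tiff_gray(file.path(d, "fish.tif"), "FISH")[[1]]
      dapi_m <- binarize_channel(dapi, seg_l)
      fish_m <- binarize_channel(fish, seg_h)
      labs <- classify_spread_pixels(dapi_m, fish_m, config$seg)
    }
    sm <- summarize_spread(labs, params = config$tether, seg = config$seg)
    h3ac_path <- file.path(d, "h3ac.tif")
    r_ch <- r_ec <- NA_real_
    if (file.exists(h3ac_path) && !use_truth) {
      h3ac <- read_tiff_gray(h3ac_path, "IF")[[1]]
      dapi <- read_tiff_gray(file.path(d, "dapi.tif"), "DAPI")[[1]]
      r_ch <- class_intensity_ratio(h3ac, dapi, labs, CLASS_CODES[["CHROMOSOME"]])
      r_ec <- class_intensity_ratio(h3ac, dapi, labs, CLASS_CODES[["ECDNA"]])
    }
    data.frame(
      n_chromosome_cc = sm$n_chromosome_cc, n_untethered = sm$n_untethered,
      n_tethered = sm$n_tethered, n_surrounded = sm$n_surrounded,
      untethering_pct = sm$untethering_pct,
      hull_area_px = convex_hull_area(dapi_m, fish_m),
      h3ac_ratio_chromosome = r_ch, h3ac_ratio_ecdna = r_ec
    )
  } else if (kind == "metaphase") {
    if (use_truth) {
      dapi_m <- binary_mask(
        unclass(read_tiff_gray(file.path(d, "truth_plate.tif"))[[1]]) > 0, "DAPI")
      fish_m <- binary_mask(
        unclass(read_tiff_gray(file.path(d, "truth_fish.tif"))[[1]]) > 0, "FISH")
    } else {
      dapi_m <- binarize_channel(read_tiff_gray(file.path(d, "dapi.tif"))[[1]], seg_h)
      fish_m <- binarize_channel(read_tiff_gray(file.path(d, "fish.tif"), "FISH")[[1]], seg_h)
    }
    mm <- metaphase_untethering(dapi_m, fish_m, config$seg)
    data.frame(
      genomic_mass_area_px = mm$genomic_mass_area_px,
      myc_px_total = mm$myc_px_total,
      myc_px_untethered = mm$myc_px_untethered,
      untethered_pct = mm$untethered_pct
    )
  } else if (kind == "daughter_pair") {
    if (use_truth) {
      part <- label_mask(
        unclass(read_tiff_gray(file.path(d, "truth_partition.tif"))[[1]]) + 0L,
        context = "daughter_pair", provenance = "ground_truth"
      )
      fish_m <- binary_mask(
        unclass(read_tiff_gray(file.path(d, "truth_fish.tif"))[[1]]) > 0, "FISH")
    } else {
      dapi_m <- binarize_channel(read_tiff_gray(file.path(d, "dapi.tif"))[[1]], seg_l)
      fish_m <- binarize_channel(read_tiff_gray(file.path(d, "fish.tif"), "FISH")[[1]], seg_h)
      part <- partition_daughter_nuclei(dapi_m, config$nuclei, seg = config$seg)
    }
    dm <- micronuclei_metrics(part, fish_m, config$seg)
    data.frame(
      has_micronuclei = dm$has_micronuclei, n_micronuclei = dm$n_micronuclei,
      myc_in_mn_pct = dm$myc_in_mn_pct,
      mn_composition_pct = dm$mn_composition_pct
    )
  } else if (kind == "foci") {
    cell <- binary_mask(
      unclass(read_tiff_gray(file.path(d, "cell_mask.tif"))[[1]]) > 0, "DAPI")
    n <- if (use_truth) {
      count_foci(binary_mask(
        unclass(read_tiff_gray(file.path(d, "truth_foci.tif"))[[1]]) > 0, "IF"
      ), config$seg, config$foci, cell)
    } else {
      count_foci(read_tiff_gray(file.path(d, "if.tif"), "IF")[[1]],
        config$seg, config$foci, cell)
    }
    data.frame(n_foci = n)
  } else {
    ect_error(sprintf("cannot quantify scene kind '%s'", kind), "ect_invalid_input")
  }
}

#' Quantify a directory of fixture scenes
#'
#' Runs the mode-appropriate segmentation and metric extraction over every
#' scene under `config$input_dir` whose kind matches `config$mode` (or all
#' scenes for `mode = "screen"`, which reports hull areas), and writes one
#' CSV row per scene to `<out_dir>/metrics.csv`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the metrics data frame.
#' @export
run_quantification <- function(config) {
  if (config$mode == "fixtures") {
    run_fixtures(config)
    return(invisible(NULL))
  }
  if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
    ect_error(sprintf("input directory '%s' does not exist",
      if (is.null(config$input_dir)) "<missing>" else config$input_dir),
      "ect_invalid_input")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- sort(list.dirs(config$input_dir, recursive = FALSE))
  dirs <- dirs[file.exists(file.path(dirs, "truth.json"))]
  scenes <- lapply(dirs, read_scene)
  want <- if (config$mode == "screen") "spread" else config$mode
  scenes <- Filter(function(s) s$kind == want, scenes)
  if (length(scenes) == 0L) {
    ect_error(sprintf("no scenes of kind '%s' under %s", want, config$input_dir),
      "ect_invalid_input")
  }
  rows <- list()
  failures <- character(0)
  for (i in seq_along(scenes)) {
    row <- tryCatch(quantify_scene(scenes[[i]], config), error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", scenes[[i]]$dir, conditionMessage(e)))
      NULL
    })
    if (is.null(row)) next
    cell_id <- basename(scenes[[i]]$dir)
    cond <- if (!is.null(config$conditions)) config$conditions[[i]] else NA
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(cell_id = cell_id, condition = cond), row
    )
  }
  if (length(rows) == 0L) {
    ect_error("all scenes failed quantification", "ect_internal_error")
  }
  metrics <- do.call(rbind, rows)
  out_csv <- file.path(config$out_dir, "metrics.csv")
  utils::write.csv(metrics, out_csv, row.names = FALSE)
  if (config$mode == "screen") {
    agg <- stats::aggregate(hull_area_px ~ condition, data = metrics, FUN = mean)
    names(agg)[2] <- "mean_hull_area_px"
    utils::write.csv(agg, file.path(config$out_dir, "screen_conditions.csv"),
      row.names = FALSE)
  }
  log_lines(config, c(
    sprintf("quantify: mode=%s scenes=%d failed=%d mask_source=%s",
      config$mode, nrow(metrics), length(failures), config$mask_source),
    sprintf("seg: otsu_classes=%d bins=%d connectivity=%d",
      config$seg$n_otsu_classes, config$seg$n_hist_bins, config$seg$connectivity),
    sprintf("tether: untethered<%.2f surrounded=%.2f",
      config$tether$untethered_max_frac, config$tether$surrounded_frac),
    failures
  ))
  invisible(metrics)
}

#' Run the configured statistical tests over a metrics table
#'
#' Each request in `config$tests` is a list with a `test` name and the
#' columns it consumes; results are appended to one tidy CSV
#' (`<out_dir>/stats.csv`) with columns test, term, statistic, df, p, p_adj.
#'
#' Valid tests: `one_way_anova` (+ Tukey HSD rows when p < 0.05),
#' `two_way_anova`, `chi_squared`, `linear_fit`, `t_test_bonferroni`.
#'
#' @param config A [run_config()] with `stats_input` (metrics CSV) and
#'   `tests`.
#' @return Invisibly, the tidy results data frame.
#' @export
run_stats <- function(config) {
  valid <- c("one_way_anova", "two_way_anova", "chi_squared", "linear_fit",
    "t_test_bonferroni")
  if (is.null(config$stats_input) || !file.exists(config$stats_input)) {
    ect_error("stats_input CSV missing", "ect_invalid_input")
  }
  tab <- utils::read.csv(config$stats_input)
  if (nrow(tab) == 0L) ect_error("empty input table", "ect_invalid_input")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  add <- function(test, term, statistic, df, p, p_adj = NA_real_) {
    out[[length(out) + 1L]] <<- data.frame(
      test = test, term = term, statistic = statistic, df = df, p = p,
      p_adj = p_adj
    )
  }
  for (req in config$tests) {
    if (is.null(req$test) || !req$test %in% valid) {
      ect_error(sprintf("unknown test '%s' (valid: %s)",
        if (is.null(req$test)) "<missing>" else req$test,
        paste(valid, collapse = ", ")), "ect_invalid_input")
    }
    value_col <- req$value %||% "untethering_pct"
    group_col <- req$group %||% "condition"
    if (req$test == "one_way_anova") {
      keep <- is.finite(tab[[value_col]])
      av <- one_way_anova(tab[[value_col]][keep], tab[[group_col]][keep])
      add("one_way_anova", "omnibus", av$F,
        sprintf("%d,%d", av$df_between, av$df_within), av$p)
      if (av$p < 0.05) { # HSD gated on the omnibus test
        hsd <- tukey_hsd(tab[[value_col]][keep], tab[[group_col]][keep])
        for (j in seq_len(nrow(hsd))) {
          add("tukey_hsd", sprintf("%s-%s", hsd$group1[j], hsd$group2[j]),
            hsd$mean_diff[j], NA, NA, hsd$p_adj[j])
        }
      }
    } else if (req$test == "two_way_anova") {
      keep <- is.finite(tab[[value_col]])
      res <- two_way_anova(tab[[value_col]][keep], tab[[group_col]][keep],
        tab[[req$factor2]][keep])
      for (j in which(res$term != "Residuals")) {
        add("two_way_anova", res$term[j], res$F[j],
          sprintf("%d", res$df[j]), res$p[j])
      }
    } else if (req$test == "chi_squared") {
      counts <- as.matrix(table(tab[[group_col]], tab[[req$outcome]]))
      res <- chi_squared_contingency(counts, yates = req$yates %||% TRUE)
      add("chi_squared", "independence", res$statistic, res$df, res$p)
    } else if (req$test == "linear_fit") {
      keep <- is.finite(tab[[req$x]]) & is.finite(tab[[req$y]])
      res <- linear_fit(tab[[req$x]][keep], tab[[req$y]][keep])
      add("linear_fit", "slope", res$slope, NA, res$p)
      add("linear_fit", "r", res$r, NA, NA)
    } else if (req$test == "t_test_bonferroni") {
      groups <- split(tab[[value_col]], tab[[group_col]])
      ctrl <- req$control %||% names(groups)[1]
      others <- setdiff(names(groups), ctrl)
      comps <- lapply(others, function(g) {
        list(treatment = groups[[g]], control = groups[[ctrl]])
      })
      res <- t_test_bonferroni(comps, m = req$m %||% length(comps))
      for (j in seq_len(nrow(res))) {
        add("t_test", sprintf("%s-%s", others[j], ctrl), res$t[j], NA,
          res$p_raw[j], res$p_adj[j])
      }
    }
  }
  results <- do.call(rbind, out)
  utils::write.csv(results, file.path(config$out_dir, "stats.csv"),
    row.names = FALSE)
  log_lines(config, sprintf("stats: %d result rows", nrow(results)))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  args <- list(
    mode = raw$mode %||% ect_error("config missing 'mode'", "ect_invalid_input"),
    out_dir = raw$out_dir %||% ".",
    scenes = raw$scenes,
    input_dir = raw$input_dir,
    mask_source = raw$mask_source %||% "otsu",
    seed = raw$seed %||% 1L,
    conditions = if (is.null(raw$conditions)) NULL else unlist(raw$conditions),
    stats_input = raw$stats_input,
    tests = raw$tests,
    log_level = raw$log_level %||% "quiet"
  )
  if (!is.null(raw$seg)) args$seg <- do.call(seg_params, raw$seg)
  if (!is.null(raw$tether)) args$tether <- do.call(tether_params, raw$tether)
  if (!is.null(raw$foci)) args$foci <- do.call(foci_params, raw$foci)
  if (!is.null(raw$nuclei)) args$nuclei <- do.call(nuclei_partition_params, raw$nuclei)
  do.call(run_config, args)
}

#' Command-line entry point
#'
#' Subcommands: `fixtures`, `quantify`, `stats`; each takes `--config FILE`
#' plus optional `--seed`, `--out`, `--log-level` overrides. Returns exit
#' code 0 on success, 1 for input errors, 2 for internal errors.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly.
#' @export
ect_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: ectether <fixtures|quantify|stats> --config FILE [--seed N] [--out DIR] [--log-level L]")
    return(invisible(1L))
  }
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--seed", type = "integer", default = NA_integer_),
    optparse::make_option("--out", type = "character", default = NA_character_),
    optparse::make_option("--log-level", dest = "log_level", type = "character",
      default = NA_character_)
  ))
  status <- tryCatch({
    opts <- optparse::parse_args(parser, args = args[-1])
    if (is.null(opts$config)) ect_error("--config is required", "ect_invalid_input")
    config <- config_from_json(opts$config)
    if (!is.na(opts$seed)) config$seed <- opts$seed
    if (!is.na(opts$out)) config$out_dir <- opts$out
    if (!is.na(opts$log_level)) config$log_level <- opts$log_level
    switch(sub,
      fixtures = {
        config$mode <- "fixtures"
        run_fixtures(config)
      },
      quantify = run_quantification(config),
      stats = run_stats(config),
      ect_error(sprintf("unknown subcommand '%s'", sub), "ect_invalid_input")
    )
    0L
  },
  ect_invalid_input = function(e) {
    message("input error: ", conditionMessage(e))
    1L
  },
  error = function(e) {
    message("internal error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
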
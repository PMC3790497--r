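# End-to-end orchestration: simulate -> (localize) -> map -> report.
# Configuration is a plain named list (read from JSON or YAML) validated
# against a fixed schema; unknown keys are rejected so typos cannot
# silently change a run. Config problems signal condition class
# `gbm_config_error`; stage failures signal `gbm_stage_error` naming the
# stage.

pipeline_schema <- list(
  seed = NULL, output_dir = NULL,
  simulation = list(
    n_regions = NULL, loc_error_sd = NULL, mid_radius = NULL,
    region_width = NULL, region_depth = NULL, variant = NULL,
    disruption = list(arc_fraction = NULL, diffuse_sd = NULL),
    frames = list(n_frames = NULL, on_prob = NULL, photons_mean = NULL,
                  psf_sd = NULL, pixel_size = NULL, camera_offset = NULL,
                  camera_gain = NULL, poisson_noise = NULL,
                  max_molecules = NULL)),
  mapping = list(bin_width = NULL, min_separation = NULL,
                 reference = NULL, targets = NULL))

config_error <- function(...) {
  stop(structure(class = c("gbm_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stage_error <- function(stage, parent) {
  stop(structure(class = c("gbm_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(parent)),
                      call = NULL)))
}

check_keys <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0L) {
    config_error("unknown config key(s): ",
                 paste0(path, unknown, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && k != "targets" && is.list(cfg[[k]])) {
      check_keys(cfg[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Validate (and default-fill) a pipeline configuration
#'
#' @param config named list with keys `seed`, `output_dir`, `simulation`
#'   (see [simulation_config()] plus an optional `frames` block) and
#'   `mapping` (`bin_width`, `min_separation`, `reference`, `targets` — a
#'   list of `list(channel =, modality =)`). Unknown keys anywhere are
#'   rejected.
#' @return validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (!is.list(config)) config_error("config must be a named list")
  check_keys(config, pipeline_schema)
  if (is.null(config$seed)) config_error("config needs a seed")
  if (is.null(config$output_dir)) config_error("config needs output_dir")
  sim <- config$simulation %||% list()
  map <- config$mapping %||% list()
  if (is.null(map$reference)) config_error("mapping needs a reference channel")
  if (is.null(map$targets) || length(map$targets) == 0L) {
    config_error("mapping needs at least one target")
  }
  for (tg in map$targets) {
    if (is.null(tg$channel) || is.null(tg$modality) ||
        !tg$modality %in% c("unimodal", "bimodal")) {
      config_error("each target needs channel and modality ",
                   "(unimodal|bimodal)")
    }
  }
  config$seed <- as.integer(config$seed)
  config$simulation <- utils::modifyList(
    list(n_regions = 60L, loc_error_sd = 15, mid_radius = 2000,
         region_width = 800, region_depth = 600, variant = "mouse"),
    sim)
  config$mapping <- utils::modifyList(
    list(bin_width = 10, min_separation = 40), map)
  config
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return validated config (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(cfg)
}

#' Run the full pipeline: simulate, map, report
#'
#' For every target channel a two-channel dataset is simulated (seed
#' derived deterministically from the master seed), regions are selected,
#' and [map_epitope()] is run with the configured reference. If the
#' simulation block carries a `frames` entry, a blinking movie of a
#' molecule subsample is additionally rendered and re-localized with
#' [localize_stack()] as an end-to-end check of the localizer, and its
#' recall is recorded in the manifest. Outputs (position map as CSV + JSON,
#' per-target accumulated histograms, run manifest with per-stage counts
#' and exclusion tallies) are written under `output_dir`.
#'
#' @param config a [pipeline_config()] (or plain list, validated here).
#' @return the manifest, invisibly; files under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- config$simulation
  map_cfg <- config$mapping
  manifest <- list(package_version = as.character(
                     utils::packageVersion("gbmstorm")),
                   seed = config$seed, stages = list(), outputs = character(0))

  maps <- list()
  histo_files <- character(0)
  for (ti in seq_along(map_cfg$targets)) {
    tg <- map_cfg$targets[[ti]]
    stage <- paste0("simulate:", tg$channel)
    sim <- tryCatch({
      cfg <- simulation_config(
        seed = derive_seed(config$seed, ti),
        n_regions = sim_cfg$n_regions,
        loc_error_sd = sim_cfg$loc_error_sd,
        mid_radius = sim_cfg$mid_radius,
        region_width = sim_cfg$region_width,
        region_depth = sim_cfg$region_depth,
        variant = sim_cfg$variant,
        disruption = sim_cfg$disruption)
      simulate_two_channel_dataset(cfg, map_cfg$reference, tg$channel)
    }, error = function(e) stage_error(stage, e))
    stage <- paste0("map:", tg$channel)
    res <- tryCatch({
      regions <- select_regions(sim, sim_cfg$n_regions)
      em <- map_epitope(sim$table, regions, map_cfg$reference, tg$channel,
                        tg$modality, bin = map_cfg$bin_width,
                        min_separation = map_cfg$min_separation)
      profiles <- lapply(regions[vapply(regions, function(r) {
        r$id %in% names(em$offsets)
      }, logical(1))], function(r) {
        project_region(sim$table, r, tg$channel, map_cfg$bin_width)
      })
      acc <- accumulate_histograms(profiles, em$offsets,
                                   bin = map_cfg$bin_width)
      list(em = em, acc = acc)
    }, error = function(e) stage_error(stage, e))
    maps[[tg$channel]] <- res$em
    hpath <- file.path(out_dir,
                       paste0("accumulated_", tg$channel, ".csv"))
    utils::write.csv(
      data.frame(center_nm = res$acc$centers,
                 count = res$acc$counts[[tg$channel]]),
      hpath, row.names = FALSE, quote = FALSE)
    histo_files <- c(histo_files, hpath)
    manifest$stages[[tg$channel]] <- list(
      simulated_localizations = nrow(sim$table),
      regions = sim_cfg$n_regions,
      regions_reference_accepted = length(res$em$offsets),
      regions_target_accepted = sum(res$em$log$target_ok),
      accumulated_count = res$acc$total)
  }

  if (!is.null(sim_cfg$frames)) {
    manifest$stages$localize <- tryCatch(
      run_localize_check(maps, sim_cfg, config$seed),
      error = function(e) stage_error("localize", e))
  }

  pm <- summarize_positions(maps)
  csv <- file.path(out_dir, "position_map.csv")
  js <- file.path(out_dir, "position_map.json")
  write_position_map(pm, csv, js)
  manifest$outputs <- c(csv, js, histo_files)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$outputs <- c(manifest$outputs, cfg_path)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Blinking-movie round trip on a small molecule subsample: simulate a
# stack, localize it, and report recall within 100 nm of a true emitter.
run_localize_check <- function(maps, sim_cfg, seed) {
  fr <- sim_cfg$frames
  n_keep <- fr$max_molecules %||% 100L
  px_nm <- fr$pixel_size %||% 160
  side <- ceiling(sqrt(n_keep))
  g <- expand.grid(gx = seq_len(side), gy = seq_len(side))[seq_len(n_keep), ]
  mol <- with_seed(derive_seed(seed, 999L), {
    # one molecule per 8-pixel grid cell with sub-pixel jitter, so spots
    # stay isolated and the check measures localization, not crowding
    data.frame(x = (g$gx * 8 + stats::runif(n_keep, -1, 1)) * px_nm,
               y = (g$gy * 8 + stats::runif(n_keep, -1, 1)) * px_nm)
  })
  movie <- simulate_frame_stack(
    mol, n_frames = fr$n_frames %||% 50L,
    on_prob = fr$on_prob %||% 0.02,
    photons_mean = fr$photons_mean %||% 2000,
    psf_sd = fr$psf_sd %||% 150,
    pixel_size = fr$pixel_size %||% 160,
    camera_offset = fr$camera_offset %||% 100,
    camera_gain = fr$camera_gain %||% 1,
    poisson_noise = isTRUE(fr$poisson_noise %||% TRUE),
    seed = derive_seed(seed, 1000L))
  locs <- localize_stack(movie$stack,
                         threshold = (fr$camera_offset %||% 100) + 50)
  matched <- 0L
  if (nrow(locs) > 0L && nrow(movie$emitters) > 0L) {
    for (i in seq_len(nrow(locs))) {
      dmin <- min(sqrt((movie$emitters$x - locs$x[i])^2 +
                       (movie$emitters$y - locs$y[i])^2))
      if (dmin <= 100) matched <- matched + 1L
    }
  }
  list(n_molecules = n_keep, n_emitter_events = nrow(movie$emitters),
       n_localized = nrow(locs), n_within_100nm = matched)
}
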
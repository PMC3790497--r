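# Parameter-recovery experiments: simulate a dataset whose ground truth is
# a published layer geometry, run the mapping pipeline, and report the
# recovered statistic. These are the workhorses of the analysis scripts
# and of the reproducibility checks.

#' Recover the reference channel's peak-to-peak distance from simulation
#'
#' Simulates `n_regions` analysis windows whose bimodal reference layers
#' sit at `+/- half_separation` (default noise: in-layer SD 20 nm,
#' localization SD 15 nm, 500 localizations per layer per window), runs
#' the per-region double-Gaussian fits and pools the peak-to-peak
#' distances.
#'
#' @param half_separation true layer offset from the midline in nm.
#' @param n_regions number of analysis windows.
#' @param seed simulation seed.
#' @param reference reference channel name (label only).
#' @param region_depth window depth in nm (600 mouse, 1200 human).
#' @param layer_sd,loc_error_sd,density noise model (see
#'   [epitope_layer_spec()] and [simulation_config()]).
#' @return list with `mean`, `sem`, `sd`, `n`, plus the `simulation` and
#'   `regions` used (for follow-up analyses on the same dataset).
#' @export
recover_peak_to_peak <- function(half_separation, n_regions, seed,
                                 reference = "agrinC",
                                 region_depth = 600, layer_sd = 20,
                                 loc_error_sd = 15, density = 500) {
  spec <- epitope_layer_spec(reference, "bimodal",
                             c(-half_separation, half_separation),
                             layer_sd = layer_sd, density = density)
  cfg <- simulation_config(seed = seed, n_regions = n_regions,
                           loc_error_sd = loc_error_sd,
                           region_depth = region_depth,
                           epitopes = stats::setNames(list(spec),
                                                      reference))
  sim <- simulate_two_channel_dataset(cfg, reference, reference)
  regions <- select_regions(sim, n_regions)
  pp <- peak_to_peak_summary(sim$table, regions, reference)
  c(pp[c("mean", "sem", "sd", "n")],
    list(simulation = sim, regions = regions))
}

#' Recover an epitope's mapped axial position from a two-channel simulation
#'
#' Simulates a two-channel dataset (reference + target drawn from an
#' epitope map), runs [map_epitope()] with the reference channel defining
#' the midpoint-zero frame, and returns the requested position estimate.
#'
#' @param target target epitope name in `epitopes`.
#' @param seed simulation seed.
#' @param n_regions number of analysis windows (default 60).
#' @param side for bimodal targets, `"endothelial"` or `"podocyte"`.
#' @param epitopes epitope map (default [gbm_epitope_map()] mouse).
#' @param reference reference channel (default `"agrinC"`).
#' @param region_depth window depth in nm.
#' @param loc_error_sd localization precision in nm.
#' @param simulation optionally, an existing `gbm_simulation` carrying both
#'   channels; skips the simulation step (seed then unused).
#' @return the [position_estimate]; its `mean`, `sem`, `sd`, `n_regions`
#'   are the reported statistics.
#' @export
recover_epitope_position <- function(target, seed, n_regions = 60L,
                                     side = NULL,
                                     epitopes = gbm_epitope_map("mouse"),
                                     reference = "agrinC",
                                     region_depth = 600,
                                     loc_error_sd = 15,
                                     simulation = NULL) {
  if (is.null(simulation)) {
    cfg <- simulation_config(seed = seed, n_regions = n_regions,
                             loc_error_sd = loc_error_sd,
                             region_depth = region_depth,
                             epitopes = epitopes)
    simulation <- simulate_two_channel_dataset(cfg, reference, target)
  }
  modality <- simulation$config$epitopes[[target]]$modality
  regions <- select_regions(simulation, simulation$config$n_regions)
  em <- map_epitope(simulation$table, regions, reference, target, modality)
  if (modality == "bimodal") {
    if (is.null(side)) stop("bimodal target needs side =", call. = FALSE)
    em$estimates[[side]]
  } else {
    em$estimates[[1L]]
  }
}
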
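# Synthetic GBM localization data: layered epitope clouds on circular
# capillary-loop geometry, with optional Alport-style segmental disruption.

#' Evaluate code under a fixed seed, restoring the RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a base seed (kept below 2^31)
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

#' Ground truth for one simulated capillary loop
#'
#' The GBM midline is a circle of radius `mid_radius` around `loop_center`;
#' the podocyte side is the outside of the loop (positive axial offsets lie
#' at radius greater than `mid_radius`). Each epitope is a layered cloud
#' described by an [epitope_layer_spec()]. A disruption descriptor (see
#' [apply_disruption()]) marks a contiguous arc on which the layered
#' organisation is replaced by a single diffuse layer.
#'
#' @param loop_center `(x, y)` in nm.
#' @param mid_radius GBM midline radius in nm (> 0).
#' @param epitopes named list of [epitope_layer_spec()]; names must be
#'   unique.
#' @param disruption `NULL` or list `(arc_start, arc_length, diffuse_sd)`
#'   (radians, radians, nm).
#' @export
gbm_ground_truth <- function(loop_center = c(0, 0), mid_radius = 2000,
                             epitopes = gbm_epitope_map("mouse"),
                             disruption = NULL) {
  stopifnot(mid_radius > 0, length(loop_center) == 2L)
  nms <- vapply(epitopes, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("epitope names must be unique", call. = FALSE)
  names(epitopes) <- nms
  structure(list(loop_center = as.numeric(loop_center),
                 mid_radius = mid_radius, epitopes = epitopes,
                 podocyte_side = "outward", disruption = disruption),
            class = "gbm_ground_truth")
}

in_arc <- function(theta, start, len) {
  if (len <= 0) return(rep(FALSE, length(theta)))
  ((theta - start) %% (2 * pi)) < len
}

#' Sample localizations for one epitope on an arc of the loop
#'
#' Localization angles are uniform on the arc; the radius of each point is
#' `mid_radius + offset + N(0, layer_sd) + N(0, loc_error_sd)` for its
#' layer, so the radial (axial) coordinate carries both the biological
#' in-layer spread and the localization error. The number of points per
#' layer is Poisson with mean `density * arc_length / window_width`, i.e.
#' `density` is calibrated as the expected count inside one analysis window
#' of width `window_width` along the membrane. On a disrupted arc the
#' layered structure collapses to a single diffuse layer at offset 0 whose
#' density is the sum of the spec's layer densities.
#'
#' @param truth a [gbm_ground_truth()].
#' @param spec an [epitope_layer_spec()] belonging to `truth` (or its name).
#' @param arc angular interval `c(from, to)` in radians, within `(0, 2*pi]`
#'   of length > 0.
#' @param loc_error_sd lateral localization precision (SD, nm).
#' @param window_width density normalisation width in nm (analysis-window
#'   width).
#' @param seed optional integer for a self-contained reproducible draw.
#' @return a [localization_table()] with channel = epitope name.
#' @export
sample_epitope_localizations <- function(truth, spec, arc = c(0, 2 * pi),
                                         loc_error_sd = 15,
                                         window_width = 800,
                                         seed = NULL) {
  if (is.character(spec)) {
    if (!spec %in% names(truth$epitopes)) {
      stop("unknown epitope: ", spec, call. = FALSE)
    }
    spec <- truth$epitopes[[spec]]
  }
  if (!isTRUE(diff(arc) > 0)) stop("empty arc", call. = FALSE)
  with_seed(seed, {
    arc_len_nm <- diff(arc) * truth$mid_radius
    mean_per_layer <- spec$density * arc_len_nm / window_width
    dis <- truth$disruption
    pieces <- lapply(spec$offsets, function(off) {
      n <- stats::rpois(1L, mean_per_layer)
      if (n == 0L) return(NULL)
      theta <- stats::runif(n, arc[1L], arc[2L])
      axial <- off + stats::rnorm(n, 0, spec$layer_sd)
      if (!is.null(dis)) {
        hit <- in_arc(theta, dis$arc_start, dis$arc_length)
        if (any(hit)) {
          axial[hit] <- stats::rnorm(sum(hit), 0, dis$diffuse_sd)
        }
      }
      radius <- truth$mid_radius + axial +
        stats::rnorm(n, 0, loc_error_sd)
      data.frame(theta = theta, radius = radius)
    })
    pieces <- Filter(Negate(is.null), pieces)
    if (length(pieces) == 0L) {
      rec <- data.frame(frame = integer(0), x = numeric(0),
                        y = numeric(0), channel = character(0))
    } else {
      pts <- do.call(rbind, pieces)
      n <- nrow(pts)
      rec <- data.frame(
        frame = 0L,
        x = truth$loop_center[1L] + pts$radius * cos(pts$theta),
        y = truth$loop_center[2L] + pts$radius * sin(pts$theta),
        channel = spec$name,
        photons = stats::rlnorm(n, log(1000), 0.5),
        width_x = 150, width_y = 150, background = 0,
        uncertainty = loc_error_sd)
    }
    localization_table(rec, channels = spec$name,
                       provenance = "gbm simulation")
  })
}

#' Apply an Alport-style segmental disruption to a loop
#'
#' On a randomly positioned contiguous arc covering `arc_fraction` of the
#' loop, the layered epitope organisation is replaced by a single diffuse
#' layer centred on the GBM midline with SD `diffuse_sd` — emulating the
#' segmental breakdown of the two-layered labeling pattern seen in the
#' Alport (collagen IV knockout) GBM. The rest of the loop is unchanged.
#'
#' @param truth a [gbm_ground_truth()].
#' @param arc_fraction fraction of the loop disrupted, in `[0, 1]`.
#' @param diffuse_sd SD of the diffuse layer in nm (> 0).
#' @param seed optional integer controlling the arc placement.
#' @return a [gbm_ground_truth()] with the disruption recorded.
#' @export
apply_disruption <- function(truth, arc_fraction, diffuse_sd = 60,
                             seed = NULL) {
  stopifnot(arc_fraction >= 0, arc_fraction <= 1)
  if (diffuse_sd <= 0) stop("diffuse_sd must be > 0", call. = FALSE)
  if (arc_fraction == 0) return(truth)
  start <- with_seed(seed, stats::runif(1L, 0, 2 * pi))
  truth$disruption <- list(arc_start = start,
                           arc_length = arc_fraction * 2 * pi,
                           diffuse_sd = diffuse_sd)
  truth
}

#' Simulation configuration
#'
#' Default noise model for recovery experiments: in-layer spread 20 nm,
#' localization error 15 nm, 500 localizations per layer per 800-nm
#' analysis window. Loops are perfect circles of radius 2000 nm; as many
#' loops are tiled side by side as are needed to host `n_regions`
#' non-overlapping windows (a loop holds `floor(2*pi*r/width)` of them).
#'
#' @param seed integer master seed; every random draw derives from it.
#' @param n_regions number of analysis windows the dataset must support.
#' @param loc_error_sd localization precision (SD, nm).
#' @param mid_radius loop midline radius (nm).
#' @param region_width analysis window width along the membrane (nm).
#' @param region_depth analysis window depth across the membrane (nm);
#'   600 for mouse-scale, 1200 for human-scale GBM.
#' @param epitopes named list of [epitope_layer_spec()] overriding the
#'   default map (`variant` is used otherwise).
#' @param variant default epitope map, `"mouse"` or `"human"`.
#' @param disruption `NULL`, or list `(arc_fraction, diffuse_sd)` applied
#'   independently to every loop.
#' @export
simulation_config <- function(seed = 1L, n_regions = 60L,
                              loc_error_sd = 15, mid_radius = 2000,
                              region_width = 800, region_depth = 600,
                              epitopes = NULL,
                              variant = c("mouse", "human"),
                              disruption = NULL) {
  variant <- match.arg(variant)
  if (is.null(epitopes)) epitopes <- gbm_epitope_map(variant)
  names(epitopes) <- vapply(epitopes, `[[`, "", "name")
  structure(list(seed = as.integer(seed), n_regions = as.integer(n_regions),
                 loc_error_sd = loc_error_sd, mid_radius = mid_radius,
                 region_width = region_width, region_depth = region_depth,
                 epitopes = epitopes, variant = variant,
                 disruption = disruption),
            class = "simulation_config")
}

regions_per_loop <- function(mid_radius, region_width) {
  max(1L, as.integer(floor(2 * pi * mid_radius / region_width)))
}

#' Simulate a two-channel GBM localization dataset
#'
#' Generates enough capillary loops to host `config$n_regions` analysis
#' windows, samples the reference and target channels over each full loop,
#' and returns one combined localization table together with the per-loop
#' ground truth for recovery scoring. Mapping the reference against itself
#' (`target == reference`) is allowed and samples the channel once.
#'
#' @param config a [simulation_config()].
#' @param reference name of the bimodal reference epitope (e.g. `"agrinC"`
#'   in mouse, `"integrinB1"` in human).
#' @param target name of the target epitope.
#' @return object of class `gbm_simulation`: list with `table`
#'   ([localization_table()]), `loops` (list of [gbm_ground_truth()]),
#'   `config`, `reference`, `target`.
#' @export
simulate_two_channel_dataset <- function(config, reference, target) {
  stopifnot(inherits(config, "simulation_config"))
  for (ch in unique(c(reference, target))) {
    if (!ch %in% names(config$epitopes)) {
      stop("unknown epitope name: ", ch, call. = FALSE)
    }
  }
  if (config$epitopes[[reference]]$modality != "bimodal") {
    stop("reference epitope must be bimodal", call. = FALSE)
  }
  rpl <- regions_per_loop(config$mid_radius, config$region_width)
  n_loops <- ceiling(config$n_regions / rpl)
  loop_pitch <- 2 * (config$mid_radius + config$region_depth) + 2000
  channels <- unique(c(reference, target))

  loops <- vector("list", n_loops)
  tabs <- list()
  for (i in seq_len(n_loops)) {
    truth <- gbm_ground_truth(
      loop_center = c((i - 1L) * loop_pitch, 0),
      mid_radius = config$mid_radius,
      epitopes = config$epitopes)
    if (!is.null(config$disruption)) {
      truth <- apply_disruption(
        truth, config$disruption$arc_fraction,
        diffuse_sd = config$disruption$diffuse_sd %||% 60,
        seed = derive_seed(config$seed, 7000L + i))
    }
    loops[[i]] <- truth
    for (j in seq_along(channels)) {
      tabs[[length(tabs) + 1L]] <- sample_epitope_localizations(
        truth, channels[j], arc = c(0, 2 * pi),
        loc_error_sd = config$loc_error_sd,
        window_width = config$region_width,
        seed = derive_seed(config$seed, 100L * i + j))
    }
  }
  rec <- do.call(rbind, lapply(tabs, as.data.frame))
  table <- localization_table(rec, channels = channels,
                              provenance = sprintf(
                                "gbm simulation (seed %d, %d loops)",
                                config$seed, n_loops))
  structure(list(table = table, loops = loops, config = config,
                 reference = reference, target = target),
            class = "gbm_simulation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
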
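# The region-iterating mapping procedure: per region, fit the bimodal
# reference channel, set the midpoint between its two layers to zero, and
# read off the target channel's centroid position(s) in that frame; then
# pool position statistics across regions.

new_position_estimate <- function(epitope, modality, side, positions) {
  n <- length(positions)
  s <- if (n > 1L) stats::sd(positions) else NA_real_
  structure(list(epitope = epitope, modality = modality, side = side,
                 per_region_positions = positions,
                 mean = mean(positions), sd = s, sem = s / sqrt(n),
                 n_regions = n),
            class = "position_estimate")
}

#' @export
print.position_estimate <- function(x, ...) {
  side <- if (is.na(x$side)) "" else paste0(" (", x$side, ")")
  cat(sprintf("<position_estimate> %s%s: %.2f +/- %.2f nm (SEM), SD %.2f, n = %d regions\n",
              x$epitope, side, x$mean, x$sem, x$sd, x$n_regions))
  invisible(x)
}

#' Map an epitope's axial position across regions
#'
#' For each region the reference channel is projected and fitted with a
#' double Gaussian; regions whose reference fit fails the acceptance gate
#' are excluded (and tallied). The midpoint between the two reference
#' layers defines zero; the target channel is projected, shifted into that
#' frame and fitted with a single Gaussian (unimodal targets) or a double
#' Gaussian (bimodal targets, the ordered components labeled endothelial /
#' podocyte). Position statistics (mean, SD, SEM = SD/sqrt(n)) are pooled
#' over the accepted regions.
#'
#' @param table a [localization_table()] holding both channels.
#' @param regions list of [gbm_region()].
#' @param reference bimodal reference channel label.
#' @param target target channel label (may equal `reference`).
#' @param target_modality `"unimodal"` or `"bimodal"`.
#' @param bin histogram bin width in nm.
#' @param min_separation reference (and bimodal-target) acceptance gate in
#'   nm.
#' @param min_positions_ref,min_positions_target minimum localization
#'   counts.
#' @return object of class `epitope_map`: list with `estimates` (one
#'   [position_estimate] if unimodal; endothelial and podocyte estimates if
#'   bimodal), `offsets` (named per-region reference offsets over accepted
#'   reference regions), `log` (per-region acceptance data frame), and the
#'   call parameters.
#' @export
map_epitope <- function(table, regions, reference, target,
                        target_modality = c("unimodal", "bimodal"),
                        bin = 10, min_separation = 40,
                        min_positions_ref = 40,
                        min_positions_target = 20) {
  target_modality <- match.arg(target_modality)
  stopifnot(length(regions) >= 1L)
  offsets <- numeric(0)
  uni <- numeric(0)
  lo <- numeric(0)
  hi <- numeric(0)
  log_rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    pref <- project_region(table, reg, reference, bin)
    dg <- fit_double_gaussian1d(pref, min_separation = min_separation,
                                min_positions = min_positions_ref)
    if (!dg$accepted) {
      log_rows[[i]] <- data.frame(region_id = reg$id, reference_ok = FALSE,
                                  target_ok = FALSE, reason = dg$reason)
      next
    }
    off <- build_reference_frame(dg)
    offsets[reg$id] <- off
    ptar <- if (identical(target, reference)) {
      shift_profile(pref, off)
    } else {
      shift_profile(project_region(table, reg, target, bin), off)
    }
    if (target_modality == "unimodal") {
      tf <- fit_gaussian1d(ptar, min_positions = min_positions_target)
      if (tf$accepted) uni <- c(uni, tf$mean)
      ok <- tf$accepted
      reason <- tf$reason
    } else {
      tf <- fit_double_gaussian1d(ptar, min_separation = min_separation,
                                  min_positions = min_positions_target)
      if (tf$accepted) {
        lo <- c(lo, tf$mean_lo)
        hi <- c(hi, tf$mean_hi)
      }
      ok <- tf$accepted
      reason <- tf$reason
    }
    log_rows[[i]] <- data.frame(region_id = reg$id, reference_ok = TRUE,
                                target_ok = ok, reason = reason)
  }
  log <- do.call(rbind, log_rows)
  if (length(offsets) == 0L) {
    stop("mapping failed at the reference stage: no region passed the ",
         "bimodal reference acceptance gate", call. = FALSE)
  }
  estimates <- if (target_modality == "unimodal") {
    if (length(uni) == 0L) {
      stop("mapping failed at the target stage: no region passed the ",
           "target fit acceptance gate", call. = FALSE)
    }
    list(new_position_estimate(target, "unimodal", NA_character_, uni))
  } else {
    if (length(lo) == 0L) {
      stop("mapping failed at the target stage: no region passed the ",
           "target fit acceptance gate", call. = FALSE)
    }
    list(endothelial = new_position_estimate(target, "bimodal",
                                             "endothelial", lo),
         podocyte = new_position_estimate(target, "bimodal",
                                          "podocyte", hi))
  }
  structure(list(estimates = estimates, offsets = offsets, log = log,
                 reference = reference, target = target,
                 target_modality = target_modality, bin = bin),
            class = "epitope_map")
}

#' Peak-to-peak distance of the reference channel across regions
#'
#' Fits the reference channel's double Gaussian in every region and pools
#' the peak-to-peak (layer separation) distances over the accepted regions.
#'
#' @inheritParams map_epitope
#' @return list with `mean`, `sem`, `sd`, `n`, `per_region` (nm), and the
#'   per-region acceptance `log`.
#' @export
peak_to_peak_summary <- function(table, regions, reference, bin = 10,
                                 min_separation = 40,
                                 min_positions_ref = 40) {
  d <- numeric(0)
  log_rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    pref <- project_region(table, reg, reference, bin)
    dg <- fit_double_gaussian1d(pref, min_separation = min_separation,
                                min_positions = min_positions_ref)
    if (dg$accepted) d <- c(d, dg$peak_to_peak)
    log_rows[[i]] <- data.frame(region_id = reg$id,
                                reference_ok = dg$accepted,
                                reason = dg$reason)
  }
  if (length(d) == 0L) {
    stop("peak-to-peak summary failed: no region passed the bimodal ",
         "reference acceptance gate", call. = FALSE)
  }
  s <- if (length(d) > 1L) stats::sd(d) else NA_real_
  list(mean = mean(d), sem = s / sqrt(length(d)), sd = s, n = length(d),
       per_region = d, log = do.call(rbind, log_rows))
}

#' Accumulate aligned per-region histograms
#'
#' Shifts every profile's axial positions by its region's reference offset
#' (so all regions share the midpoint-zero frame) and pools all
#' localizations into one histogram per channel. Total counts are
#' conserved.
#'
#' @param profiles list of `projection_profile`.
#' @param offsets named numeric vector of per-region offsets (names =
#'   region ids), e.g. `epitope_map$offsets`.
#' @param bin bin width of the accumulated histogram in nm.
#' @return object of class `accumulated_histogram`: `centers`, `counts`
#'   (named list per channel), `offsets_applied`, `total`.
#' @export
accumulate_histograms <- function(profiles, offsets, bin = 10) {
  shifted <- list()
  for (pr in profiles) {
    if (!pr$region_id %in% names(offsets)) {
      stop("no reference offset for region ", pr$region_id, call. = FALSE)
    }
    shifted[[length(shifted) + 1L]] <- data.frame(
      channel = rep(pr$channel, pr$n),
      position = pr$positions + offsets[[pr$region_id]])
  }
  all_pts <- do.call(rbind, shifted)
  channels <- unique(all_pts$channel)
  if (nrow(all_pts) == 0L) {
    return(structure(list(centers = numeric(0), counts = list(),
                          offsets_applied = offsets, total = 0L),
                     class = "accumulated_histogram"))
  }
  rng_idx <- range(floor(all_pts$position / bin + 0.5))
  centers <- (rng_idx[1L]:rng_idx[2L]) * bin
  counts <- lapply(channels, function(ch) {
    p <- all_pts$position[all_pts$channel == ch]
    idx <- floor(p / bin + 0.5)
    tabulate(idx - rng_idx[1L] + 1L, nbins = length(centers))
  })
  names(counts) <- channels
  structure(list(centers = centers, counts = counts,
                 offsets_applied = offsets,
                 total = nrow(all_pts)),
            class = "accumulated_histogram")
}

#' Summarize position estimates as a machine-readable epitope map
#'
#' @param estimates list of [position_estimate] objects (possibly nested,
#'   e.g. `epitope_map$estimates` entries concatenated).
#' @return data frame with `epitope`, `side`, `modality`, `mean_nm`,
#'   `sem_nm`, `sd_nm`, `n_regions`, ordered endothelial-to-podocyte
#'   (ascending mean).
#' @export
summarize_positions <- function(estimates) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "position_estimate")) {
      flat[[length(flat) + 1L]] <<- x
    } else if (inherits(x, "epitope_map")) {
      lapply(x$estimates, collect)
    } else if (is.list(x)) {
      lapply(x, collect)
    }
    invisible(NULL)
  }
  collect(estimates)
  if (length(flat) == 0L) stop("no position estimates", call. = FALSE)
  df <- do.call(rbind, lapply(flat, function(e) {
    data.frame(epitope = e$epitope, side = e$side, modality = e$modality,
               mean_nm = e$mean, sem_nm = e$sem, sd_nm = e$sd,
               n_regions = e$n_regions, stringsAsFactors = FALSE)
  }))
  df[order(df$mean_nm), , drop = FALSE]
}

#' Write (and read back) a position map
#'
#' @param map data frame from [summarize_positions()].
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @export
write_position_map <- function(map, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    utils::write.csv(map, path_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(map, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(map)
}

#' @rdname write_position_map
#' @export
read_position_map <- function(path_csv) {
  utils::read.csv(path_csv, stringsAsFactors = FALSE)
}
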
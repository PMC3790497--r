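#' Oriented analysis windows on the GBM
#'
#' A region is an ~800-nm window on the membrane: a centre on the GBM
#' midline, a unit normal pointing toward the podocyte side, a width along
#' the membrane tangent and a depth along the normal. All localizations
#' whose region-frame coordinates fall inside the (half-open) window are
#' projected onto the normal to build an axial profile.
#'
#' @param center `(x, y)` in nm.
#' @param normal unit vector toward the podocyte side (normalised if
#'   slightly off unit length); alternatively give `angle_deg`.
#' @param angle_deg normal direction in degrees (overrides `normal`).
#' @param width window width along the tangent in nm (default 800).
#' @param depth window depth along the normal in nm (600 mouse-scale,
#'   1200 human-scale).
#' @param id region identifier.
#' @param curvature signed curvature (1/nm) of the membrane through the
#'   window, positive when the podocyte side is the outside of the arc;
#'   0 (the default) treats the membrane as locally flat. When the host
#'   capillary-loop geometry is known (simulated regions), setting the
#'   curvature lets [project_region()] measure the axial coordinate
#'   radially, removing the O(width^2/radius) inward smear a flat
#'   projection picks up on a curved membrane.
#' @export
gbm_region <- function(center, normal = NULL, angle_deg = NULL,
                       width = 800, depth = 600, id = NA_character_,
                       curvature = 0) {
  stopifnot(length(center) == 2L, width > 0, depth > 0)
  if (!is.null(angle_deg)) {
    a <- angle_deg * pi / 180
    normal <- c(cos(a), sin(a))
  }
  if (is.null(normal)) stop("need normal or angle_deg", call. = FALSE)
  nrm <- sqrt(sum(normal^2))
  if (abs(nrm - 1) > 1e-6) {
    if (nrm == 0) stop("normal must be nonzero", call. = FALSE)
    normal <- normal / nrm
  } else {
    normal <- normal / nrm  # exact unit length within 1e-9
  }
  structure(list(id = as.character(id), center = as.numeric(center),
                 normal = as.numeric(normal), width = width, depth = depth,
                 curvature = curvature),
            class = "gbm_region")
}

#' Select analysis regions on simulated capillary loops
#'
#' Places `k` non-overlapping windows at equal angular spacing on the loop
#' midline(s), normals pointing radially outward (the podocyte side).
#' A loop of radius r holds at most `floor(2*pi*r/width)` windows; asking
#' for more from a single loop is an error stating the maximum. For a
#' multi-loop simulation the windows are distributed loop by loop.
#'
#' @param x a [gbm_ground_truth()], a `gbm_simulation`, or a list of
#'   ground truths.
#' @param k number of regions (>= 1).
#' @param width,depth window dimensions in nm; for a simulation they
#'   default to the values in its config.
#' @return list of [gbm_region()].
#' @export
select_regions <- function(x, k, width = 800, depth = 600) {
  stopifnot(k >= 1)
  if (inherits(x, "gbm_simulation")) {
    if (missing(width)) width <- x$config$region_width
    if (missing(depth)) depth <- x$config$region_depth
    loops <- x$loops
  } else if (inherits(x, "gbm_ground_truth")) {
    loops <- list(x)
  } else {
    loops <- x
  }
  rpl <- vapply(loops, function(tr) {
    regions_per_loop(tr$mid_radius, width)
  }, integer(1))
  if (k > sum(rpl)) {
    stop("cannot fit ", k, " non-overlapping ", width,
         "-nm windows; maximum is ", sum(rpl), call. = FALSE)
  }
  regions <- vector("list", k)
  made <- 0L
  for (i in seq_along(loops)) {
    tr <- loops[[i]]
    n_here <- min(rpl[i], k - made)
    if (n_here == 0L) break
    angles <- 2 * pi * (seq_len(rpl[i]) - 1L) / rpl[i]
    for (j in seq_len(n_here)) {
      made <- made + 1L
      th <- angles[j]
      regions[[made]] <- gbm_region(
        center = tr$loop_center + tr$mid_radius * c(cos(th), sin(th)),
        normal = c(cos(th), sin(th)),
        width = width, depth = depth,
        id = sprintf("loop%02d_r%02d", i, j),
        curvature = 1 / tr$mid_radius)
    }
  }
  regions
}

#' Read / write region definition files
#'
#' Delimited text with header
#' `id,center_x_nm,center_y_nm,normal_angle_deg,width_nm,depth_nm`.
#'
#' @param path file path.
#' @return list of [gbm_region()].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "center_x_nm", "center_y_nm", "normal_angle_deg",
            "width_nm", "depth_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("region file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    gbm_region(center = c(df$center_x_nm[i], df$center_y_nm[i]),
               angle_deg = df$normal_angle_deg[i],
               width = df$width_nm[i], depth = df$depth_nm[i],
               id = df$id[i])
  })
}

#' @rdname read_regions
#' @param regions list of [gbm_region()].
#' @export
write_regions <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r) {
    data.frame(id = r$id, center_x_nm = r$center[1L],
               center_y_nm = r$center[2L],
               normal_angle_deg = atan2(r$normal[2L], r$normal[1L]) *
                 180 / pi,
               width_nm = r$width, depth_nm = r$depth)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project localizations of one channel onto a region's normal
#'
#' The region frame has tangential coordinate `t = (p - center) . tangent`
#' and axial coordinate `a = (p - center) . normal` (positive toward the
#' podocyte side). A localization belongs to the window when
#' `t` is in `[-width/2, width/2)` and `a` is in `[-depth/2, depth/2)`
#' (half-open upper bounds, so adjacent windows partition the membrane).
#' The axial positions are binned into a histogram whose bin centres sit at
#' integer multiples of `bin` (so 0 is always a bin centre).
#'
#' For a region with non-zero `curvature` the membrane through the window
#' is the arc of the circle with centre `center - normal/curvature`; the
#' axial coordinate is then the signed radial distance from that arc and
#' the tangential coordinate the arc length from the window centre, which
#' reduces to the flat formulas as the curvature tends to zero.
#'
#' @param table a [localization_table()].
#' @param region a [gbm_region()].
#' @param channel channel label to project.
#' @param bin histogram bin width in nm (default 10).
#' @return object of class `projection_profile`: `region_id`, `channel`,
#'   `positions` (signed axial nm), `bin`, `centers`, `counts`, `depth`,
#'   `n`, `empty`.
#' @export
project_region <- function(table, region, channel, bin = 10) {
  stopifnot(inherits(region, "gbm_region"), bin > 0)
  keep <- table$channel == channel
  # cheap bounding-box prefilter: anything in the window lies within the
  # window half-diagonal (plus the arc sagitta for curved regions) of the
  # window centre
  rmax <- sqrt((region$width / 2)^2 + (region$depth / 2)^2) +
    abs(region$curvature) * region$width^2 / 8 + 1
  keep <- keep &
    abs(table$x - region$center[1L]) <= rmax &
    abs(table$y - region$center[2L]) <= rmax
  sel <- table[keep, , drop = FALSE]
  n1 <- region$normal[1L]
  n2 <- region$normal[2L]
  if (region$curvature != 0) {
    r0 <- 1 / region$curvature
    cc <- region$center - r0 * region$normal  # host circle centre
    px <- sel$x - cc[1L]
    py <- sel$y - cc[2L]
    rad <- sqrt(px^2 + py^2)
    axial <- sign(r0) * (rad - abs(r0))
    # arc length from the window centre; atan2 of the point direction
    # against the region normal, wrapped to (-pi, pi]
    dth <- atan2(py * n1 - px * n2, px * n1 + py * n2)
    tangential <- abs(r0) * dth
  } else {
    dx <- sel$x - region$center[1L]
    dy <- sel$y - region$center[2L]
    axial <- dx * n1 + dy * n2
    tangential <- -dx * n2 + dy * n1
  }
  inside <- tangential >= -region$width / 2 &
    tangential < region$width / 2 &
    axial >= -region$depth / 2 &
    axial < region$depth / 2
  positions <- axial[inside]
  new_projection_profile(positions, region$id, channel, bin, region$depth)
}

new_projection_profile <- function(positions, region_id, channel, bin,
                                   depth) {
  h <- axial_histogram(positions, bin)
  structure(list(region_id = region_id, channel = channel,
                 positions = positions, bin = bin,
                 centers = h$centers, counts = h$counts,
                 depth = depth, n = length(positions),
                 empty = length(positions) == 0L),
            class = "projection_profile")
}

# Histogram with bin centres at integer multiples of `bin`
# (bin k covers [ (k-0.5)*bin, (k+0.5)*bin )).
axial_histogram <- function(positions, bin) {
  if (length(positions) == 0L) {
    return(list(centers = numeric(0), counts = integer(0)))
  }
  idx <- floor(positions / bin + 0.5)
  rng <- range(idx)
  ks <- rng[1L]:rng[2L]
  list(centers = ks * bin,
       counts = tabulate(idx - rng[1L] + 1L, nbins = length(ks)))
}

#' Shift a profile's axial coordinates (e.g. into the reference frame)
#' @param profile a `projection_profile`.
#' @param offset axial shift in nm.
#' @return a re-binned `projection_profile`.
#' @export
shift_profile <- function(profile, offset) {
  new_projection_profile(profile$positions + offset, profile$region_id,
                         profile$channel, profile$bin, profile$depth)
}
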
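#' Camera frame stacks
#'
#' Container for a raw single-molecule movie: a `frame x row x column`
#' array of camera counts plus the calibration needed to convert fitted
#' amplitudes to photons. The coordinate convention places the centre of
#' pixel `(row r, col c)` (1-based) at `x = (c - 0.5) * pixel_size`,
#' `y = (r - 0.5) * pixel_size`.
#'
#' @param intensities numeric array `(frame, row, col)` of camera counts.
#' @param pixel_size nm per pixel (> 0).
#' @param camera_offset camera baseline in counts.
#' @param camera_gain counts per photon (> 0).
#' @export
frame_stack <- function(intensities, pixel_size,
                        camera_offset = 0, camera_gain = 1) {
  stopifnot(length(dim(intensities)) == 3L, pixel_size > 0, camera_gain > 0)
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 camera_offset = camera_offset, camera_gain = camera_gain),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%.0f nm/px)\n",
              d[1L], d[2L], d[3L], x$pixel_size))
  invisible(x)
}

#' Detect candidate emission peaks in one frame
#'
#' Local maxima above an absolute count threshold, non-maximum-suppressed:
#' candidates are visited in order of decreasing brightness (ties broken by
#' row, then column, so detection is fully deterministic) and any candidate
#' within `min_separation` pixels (Chebyshev distance) of an already
#' accepted brighter one is discarded.
#'
#' @param stack a [frame_stack()].
#' @param frame 1-based frame index.
#' @param threshold minimum count (above offset-subtracted background this
#'   should exceed the noise floor).
#' @param min_separation suppression radius in pixels.
#' @return data frame with `frame`, `row`, `col`, `peak_value`, sorted by
#'   decreasing `peak_value`.
#' @export
detect_peaks <- function(stack, frame, threshold, min_separation = 3L) {
  d <- dim(stack$intensities)
  if (frame < 1L || frame > d[1L]) {
    stop("frame index ", frame, " out of range 1..", d[1L], call. = FALSE)
  }
  img <- stack$intensities[frame, , ]
  nr <- nrow(img)
  nc <- ncol(img)
  # 8-neighbour local maximum (strictly greater than or equal to all
  # neighbours, strictly above threshold)
  is_max <- img >= threshold
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (s in seq_len(nrow(shifts))) {
    shifted <- shift_matrix(img, shifts$dr[s], shifts$dc[s])
    is_max <- is_max & img >= shifted
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(frame = integer(0), row = integer(0),
                      col = integer(0), peak_value = numeric(0)))
  }
  cand <- data.frame(frame = frame, row = idx[, 1L], col = idx[, 2L],
                     peak_value = img[idx])
  cand <- cand[order(-cand$peak_value, cand$row, cand$col), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    acc <- which(keep)
    if (length(acc) == 0L ||
        all(pmax(abs(cand$row[acc] - cand$row[i]),
                 abs(cand$col[acc] - cand$col[i])) >= min_separation)) {
      keep[i] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Fit an axis-aligned elliptical Gaussian to a pixel patch
#'
#' Least-squares fit of
#' \deqn{I(x, y) = A \exp\left(-\frac{(x-x_0)^2}{2\sigma_x^2}
#'   -\frac{(y-y_0)^2}{2\sigma_y^2}\right) + b}
#' to a small patch of camera counts (Levenberg-Marquardt), with
#' inverse-variance (Poisson) weights `1/max(counts, 1)` so the fit reaches
#' the shot-noise precision bound. The model has no rotation angle; an
#' axis-aligned ellipse is the standard 2-D SMLM PSF model. Failure to
#' converge is reported via `converged = FALSE`, never an exception.
#'
#' @param patch numeric matrix of counts, at least 7x7.
#' @param pixel_size nm per pixel.
#' @param origin `c(row0, col0)`: position of `patch[1,1]` in the parent
#'   frame (1-based); centres are reported in frame nm coordinates.
#' @param gain camera counts per photon (for the photon estimate).
#' @param init optional named list with any of `x0`, `y0` (nm, frame
#'   coordinates), `sd` (nm), `amplitude`, `offset`.
#' @param sd_bounds_px allowed width range in pixels.
#' @return list with `x0`, `y0`, `sd_x`, `sd_y` (nm), `amplitude`, `offset`
#'   (counts), `residual` (the objective: sum of squared weighted
#'   residuals), `photons`, `converged`.
#' @export
fit_elliptical_gaussian <- function(patch, pixel_size, origin = c(1L, 1L),
                                    gain = 1, init = list(),
                                    sd_bounds_px = c(0.3, 4)) {
  if (nrow(patch) < 7L || ncol(patch) < 7L) {
    stop("patch must be at least 7x7 pixels", call. = FALSE)
  }
  nr <- nrow(patch)
  nc <- ncol(patch)
  # pixel-centre coordinates local to the patch, in pixels
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  z <- as.vector(patch)

  med <- stats::median(z)
  peak_idx <- which.max(z)
  default_sd_px <- 150 / pixel_size
  p0 <- c(x0 = if (!is.null(init$x0)) {
            init$x0 / pixel_size - (origin[2L] - 1L)
          } else cx[peak_idx],
          y0 = if (!is.null(init$y0)) {
            init$y0 / pixel_size - (origin[1L] - 1L)
          } else cy[peak_idx],
          sdx = if (!is.null(init$sd)) init$sd / pixel_size else default_sd_px,
          sdy = if (!is.null(init$sd)) init$sd / pixel_size else default_sd_px,
          A = if (!is.null(init$amplitude)) init$amplitude
              else max(z[peak_idx] - med, 1e-3),
          b = if (!is.null(init$offset)) init$offset else med)
  p0["sdx"] <- min(max(p0["sdx"], sd_bounds_px[1L]), sd_bounds_px[2L])
  p0["sdy"] <- min(max(p0["sdy"], sd_bounds_px[1L]), sd_bounds_px[2L])

  # inverse-variance (Poisson) weights: shot-noise-limited counts have
  # var ~ counts, and unweighted LS would inflate the localization error
  # by ~sqrt(16/9) relative to the precision bound
  wts <- 1 / sqrt(pmax(z, 1))
  resid_fn <- function(p) {
    wts * (p["A"] * exp(-(cx - p["x0"])^2 / (2 * p["sdx"]^2) -
                        (cy - p["y0"])^2 / (2 * p["sdy"]^2)) + p["b"] - z)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      lower = c(x0 = -1, y0 = -1,
                sdx = sd_bounds_px[1L], sdy = sd_bounds_px[1L],
                A = 0, b = -Inf),
      upper = c(x0 = nc + 1, y0 = nr + 1,
                sdx = sd_bounds_px[2L], sdy = sd_bounds_px[2L],
                A = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200L)),
    error = function(e) NULL)

  failed <- is.null(fit) || !fit$info %in% 1:4
  p <- if (is.null(fit)) p0 else stats::coef(fit)
  amplitude <- unname(p["A"])
  sd_x_nm <- unname(p["sdx"]) * pixel_size
  sd_y_nm <- unname(p["sdy"]) * pixel_size
  list(
    x0 = (unname(p["x0"]) + (origin[2L] - 1L)) * pixel_size,
    y0 = (unname(p["y0"]) + (origin[1L] - 1L)) * pixel_size,
    sd_x = sd_x_nm,
    sd_y = sd_y_nm,
    amplitude = amplitude,
    offset = unname(p["b"]),
    residual = if (is.null(fit)) Inf else sum(resid_fn(p)^2),
    photons = 2 * pi * amplitude * sd_x_nm * sd_y_nm /
      (gain * pixel_size^2),
    converged = !failed && amplitude > 0
  )
}

#' Localize an entire frame stack
#'
#' Runs [detect_peaks()] on every frame, extracts a square patch around each
#' candidate, fits it with [fit_elliptical_gaussian()] and collects the
#' converged fits into a [localization_table()]. Candidates whose patch
#' would leave the frame are skipped; non-converged fits are dropped and
#' tallied in the attached summary.
#'
#' @param stack a [frame_stack()].
#' @param threshold detection threshold in counts (see [detect_peaks()]).
#' @param patch_half half-width of the fit patch in pixels (patch is
#'   `2 * patch_half + 1` square; default 5 gives 11x11).
#' @param min_separation suppression radius in pixels.
#' @return a [localization_table()] with attribute `fit_summary`
#'   (candidates, converged, dropped).
#' @export
localize_stack <- function(stack, threshold, patch_half = 5L,
                           min_separation = 3L) {
  if (2L * patch_half + 1L < 7L) {
    stop("patch_half must be >= 3 (7x7 minimum patch)", call. = FALSE)
  }
  d <- dim(stack$intensities)
  rows <- list()
  n_cand <- 0L
  n_conv <- 0L
  offset <- stack$camera_offset
  for (f in seq_len(d[1L])) {
    peaks <- detect_peaks(stack, f, threshold, min_separation)
    for (i in seq_len(nrow(peaks))) {
      r <- peaks$row[i]
      cc <- peaks$col[i]
      if (r - patch_half < 1L || r + patch_half > d[2L] ||
          cc - patch_half < 1L || cc + patch_half > d[3L]) next
      n_cand <- n_cand + 1L
      patch <- stack$intensities[f, (r - patch_half):(r + patch_half),
                                 (cc - patch_half):(cc + patch_half)]
      patch <- pmax(patch - offset, 0)
      fit <- fit_elliptical_gaussian(
        patch, stack$pixel_size,
        origin = c(r - patch_half, cc - patch_half),
        gain = stack$camera_gain)
      if (!fit$converged) next
      n_conv <- n_conv + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f - 1L, x = fit$x0, y = fit$y0, channel = "ch0",
        photons = max(fit$photons, .Machine$double.eps),
        width_x = fit$sd_x, width_y = fit$sd_y,
        background = fit$offset,
        uncertainty = mean(c(fit$sd_x, fit$sd_y)) /
          sqrt(max(fit$photons, 1)))
    }
  }
  records <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               channel = character(0))
  }
  tab <- localization_table(records, pixel_size = stack$pixel_size,
                            n_frames = d[1L], channels = "ch0",
                            provenance = "localize_stack")
  attr(tab, "fit_summary") <- list(candidates = n_cand, converged = n_conv,
                                   dropped = n_cand - n_conv)
  tab
}
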
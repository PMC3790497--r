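#' Simulate a blinking single-molecule movie
#'
#' Renders a photoswitching movie from a set of molecule positions: each
#' molecule turns on independently in each frame with probability
#' `on_prob`, emits `Poisson(photons_mean)` photons, and is rendered as a
#' pixel-integrated Gaussian PSF. Camera counts are
#' `gain * photons + offset`; with `poisson_noise = TRUE` the photon signal
#' (not the offset) is Poisson-distributed per pixel. With `on_prob = 0`
#' the stack is exactly the constant camera offset.
#'
#' @param molecules data frame with `x`, `y` in nm (e.g. a
#'   [localization_table()]), or a `gbm_simulation` whose table is used.
#' @param n_frames number of frames.
#' @param on_prob per-frame, per-molecule on probability.
#' @param photons_mean mean photons per emission event.
#' @param psf_sd PSF standard deviation in nm.
#' @param pixel_size camera pixel size in nm.
#' @param camera_offset,camera_gain camera calibration (counts, counts per
#'   photon).
#' @param poisson_noise add Poisson shot noise to the photon signal.
#' @param fov_px optional `c(n_rows, n_cols)`; derived from the molecule
#'   bounding box plus a 4-sigma margin when omitted.
#' @param seed optional integer for a reproducible movie.
#' @return list with `stack` (a [frame_stack()]) and `emitters` (data frame
#'   `frame`, `x`, `y`, `photons`: every on-event with its true position).
#' @export
simulate_frame_stack <- function(molecules, n_frames = 100L, on_prob = 0.01,
                                 photons_mean = 1000, psf_sd = 150,
                                 pixel_size = 160, camera_offset = 100,
                                 camera_gain = 1, poisson_noise = TRUE,
                                 fov_px = NULL, seed = NULL) {
  if (inherits(molecules, "gbm_simulation")) molecules <- molecules$table
  if (psf_sd <= 0 || pixel_size <= 0) {
    stop("psf_sd and pixel_size must be > 0", call. = FALSE)
  }
  stopifnot(on_prob >= 0, on_prob <= 1, n_frames >= 1)
  mx <- molecules$x
  my <- molecules$y
  n_mol <- length(mx)
  margin <- 4 * psf_sd
  if (is.null(fov_px)) {
    if (n_mol == 0L) {
      fov_px <- c(16L, 16L)
    } else {
      fov_px <- c(ceiling((max(my) + margin) / pixel_size),
                  ceiling((max(mx) + margin) / pixel_size))
    }
    if (n_mol > 0L && (min(mx) < margin || min(my) < margin)) {
      stop("molecules must lie at least 4*psf_sd inside the field of view; ",
           "shift coordinates or pass fov_px", call. = FALSE)
    }
  }
  nr <- as.integer(fov_px[1L])
  nc <- as.integer(fov_px[2L])
  half_px <- ceiling(4 * psf_sd / pixel_size)

  with_seed(seed, {
    stack <- array(0, dim = c(n_frames, nr, nc))
    emitters <- list()
    for (f in seq_len(n_frames)) {
      if (n_mol == 0L || on_prob == 0) next
      on <- which(stats::runif(n_mol) < on_prob)
      if (length(on) == 0L) next
      photons <- stats::rpois(length(on), photons_mean)
      frame_img <- matrix(0, nr, nc)
      for (k in seq_along(on)) {
        if (photons[k] == 0L) next
        i <- on[k]
        frame_img <- add_psf(frame_img, mx[i], my[i], photons[k],
                             psf_sd, pixel_size, half_px)
      }
      if (poisson_noise) {
        frame_img <- matrix(stats::rpois(nr * nc, frame_img), nr, nc)
      }
      stack[f, , ] <- frame_img
      emitters[[length(emitters) + 1L]] <- data.frame(
        frame = f, x = mx[on], y = my[on], photons = photons)
    }
    stack <- stack * camera_gain + camera_offset
    emitters <- if (length(emitters) > 0L) {
      do.call(rbind, emitters)
    } else {
      data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                 photons = numeric(0))
    }
    list(stack = frame_stack(stack, pixel_size, camera_offset, camera_gain),
         emitters = emitters)
  })
}

# Add one pixel-integrated Gaussian PSF (photon units) to a frame image.
add_psf <- function(img, x, y, photons, psf_sd, pixel_size, half_px) {
  nr <- nrow(img)
  nc <- ncol(img)
  c0 <- floor(x / pixel_size) + 1L
  r0 <- floor(y / pixel_size) + 1L
  cols <- max(1L, c0 - half_px):min(nc, c0 + half_px)
  rows <- max(1L, r0 - half_px):min(nr, r0 + half_px)
  # probability mass of the PSF over each pixel, via the Gaussian CDF
  px_frac_c <- stats::pnorm(cols * pixel_size, x, psf_sd) -
    stats::pnorm((cols - 1L) * pixel_size, x, psf_sd)
  px_frac_r <- stats::pnorm(rows * pixel_size, y, psf_sd) -
    stats::pnorm((rows - 1L) * pixel_size, y, psf_sd)
  img[rows, cols] <- img[rows, cols] +
    photons * outer(px_frac_r, px_frac_c)
  img
}
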
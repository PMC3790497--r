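px <- 160  # nm per pixel used throughout

test_that("peak detection finds isolated spots and suppresses neighbours", {
  empty <- frame_stack(array(0, c(2, 32, 32)), pixel_size = px)
  expect_equal(nrow(detect_peaks(empty, 1, threshold = 10)), 0L)
  expect_error(detect_peaks(empty, 3, threshold = 10), "out of range")

  spot <- synthetic_spot(32, 32, x = 15.5 * px, y = 11.5 * px,
                         photons = 1000, psf_sd = 150, pixel_size = px)
  st <- frame_stack(array(spot, c(1, 32, 32)), pixel_size = px)
  pk <- detect_peaks(st, 1, threshold = 100)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$row, pk$col), c(12L, 16L))

  # two spots 3 px apart, min_separation 5: the brighter survives
  two <- synthetic_spot(32, 32, 15.5 * px, 11.5 * px, 1000, 150, px) +
    synthetic_spot(32, 32, 18.5 * px, 11.5 * px, 600, 150, px)
  st2 <- frame_stack(array(two, c(1, 32, 32)), pixel_size = px)
  pk2 <- detect_peaks(st2, 1, threshold = 50, min_separation = 5)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$col, 16L)
  # with a smaller radius both survive, sorted by brightness
  pk3 <- detect_peaks(st2, 1, threshold = 50, min_separation = 2)
  expect_equal(nrow(pk3), 2L)
  expect_true(pk3$peak_value[1L] >= pk3$peak_value[2L])
})

test_that("noise-free Gaussian patches are recovered to numerical precision", {
  # symmetric spot on the central pixel centre of an 11x11 patch
  patch <- synthetic_spot(11, 11, 5.5 * px, 5.5 * px, 2000, 150, px)
  fit <- fit_elliptical_gaussian(patch, pixel_size = px)
  expect_true(fit$converged)
  expect_lt(abs(fit$x0 - 5.5 * px), 1e-6)
  expect_lt(abs(fit$y0 - 5.5 * px), 1e-6)
  expect_lt(abs(fit$sd_x - fit$sd_y), 1e-6)

  # elliptical spot at a known sub-pixel offset; patch generated from the
  # fit model itself, so truth is exact
  nr <- 11L
  cx <- rep(seq_len(nr) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nr)
  truth <- list(x0 = 5.8, y0 = 5.3, sdx = 1.2, sdy = 1.6, A = 800, b = 20)
  patch2 <- matrix(truth$A * exp(-(cx - truth$x0)^2 / (2 * truth$sdx^2) -
                                 (cy - truth$y0)^2 / (2 * truth$sdy^2)) +
                     truth$b, nr, nr)
  fit2 <- fit_elliptical_gaussian(patch2, pixel_size = px)
  expect_true(fit2$converged)
  expect_lt(abs(fit2$x0 / px - truth$x0), 1e-4)
  expect_lt(abs(fit2$y0 / px - truth$y0), 1e-4)
  expect_lt(abs(fit2$sd_x / px - truth$sdx), 1e-4)
  expect_lt(abs(fit2$sd_y / px - truth$sdy), 1e-4)
  expect_lt(abs(fit2$offset - truth$b), 1e-3)
  # analytic photon estimate: 2*pi*A*sdx*sdy / px^2 at unit gain
  expect_equal(fit2$photons,
               2 * pi * truth$A * truth$sdx * truth$sdy,
               tolerance = 1e-3)

  expect_error(fit_elliptical_gaussian(matrix(0, 5, 5), px), "7x7")
})

test_that("least-squares optimum matches a brute-force grid search", {
  set.seed(21)
  patch <- synthetic_spot(11, 11, 5.2 * px, 5.9 * px, 3000, 150, px)
  patch <- matrix(rpois(length(patch), patch + 20), 11, 11)
  fit <- fit_elliptical_gaussian(patch, pixel_size = px)
  oracle <- oracle_gaussian2d(patch,
                              x0_grid = seq(4.6, 5.8, by = 0.1),
                              y0_grid = seq(5.3, 6.5, by = 0.1),
                              sd_grid = seq(0.6, 1.4, by = 0.1))
  expect_lt(abs(fit$x0 / px - oracle$x0), 0.1 + 1e-9)
  expect_lt(abs(fit$y0 / px - oracle$y0), 0.1 + 1e-9)
  expect_lt(abs(fit$sd_x / px - oracle$sd_x), 0.1 + 1e-9)
  expect_lt(abs(fit$sd_y / px - oracle$sd_y), 0.1 + 1e-9)
  expect_lte(fit$residual, oracle$ssr + 1e-6 * oracle$ssr)
})

test_that("localization precision follows the sd_psf/sqrt(N) law", {
  set.seed(22)
  psf_sd <- 150
  reps <- 150L
  photon_levels <- c(250, 1000, 4000)
  emp_sd <- vapply(photon_levels, function(N) {
    err <- replicate(reps, {
      x <- (5 + runif(1, 0.3, 0.7)) * px
      y <- (5 + runif(1, 0.3, 0.7)) * px
      ideal <- synthetic_spot(11, 11, x, y, N, psf_sd, px)
      noisy <- matrix(rpois(length(ideal), ideal), 11, 11)
      fit <- fit_elliptical_gaussian(noisy, pixel_size = px)
      fit$x0 - x
    })
    sd(err)
  }, numeric(1))
  # monotone improvement with photon count
  expect_true(all(diff(emp_sd) < 0))
  # within 30% of the precision law (pixelation-corrected PSF width)
  sd_eff <- sqrt(psf_sd^2 + px^2 / 12)
  expect_true(all(abs(emp_sd / (sd_eff / sqrt(photon_levels)) - 1) < 0.3))
})

test_that("stack localization is deterministic and recovers emitters", {
  set.seed(23)
  # isolated emitters: 12-px grid pitch with sub-pixel jitter, kept a full
  # fit patch away from the field edge
  g <- expand.grid(gx = 1:7, gy = 1:7)
  truth <- data.frame(
    x = (g$gx * 12 - 2 + runif(nrow(g), -1, 1)) * px,
    y = (g$gy * 12 - 2 + runif(nrow(g), -1, 1)) * px)
  movie <- simulate_frame_stack(truth, n_frames = 12L, on_prob = 0.25,
                                photons_mean = 3000, psf_sd = 150,
                                pixel_size = px, camera_offset = 100,
                                poisson_noise = TRUE, fov_px = c(96, 96),
                                seed = 99)
  locs <- localize_stack(movie$stack, threshold = 160)
  locs2 <- localize_stack(movie$stack, threshold = 160)
  expect_identical(as.data.frame(locs), as.data.frame(locs2))

  # every localization lies near a true emitter of its frame; recall high
  ems <- movie$emitters
  matched <- 0L
  for (i in seq_len(nrow(locs))) {
    same_frame <- ems[ems$frame == locs$frame[i] + 1L, ]
    d <- sqrt((same_frame$x - locs$x[i])^2 + (same_frame$y - locs$y[i])^2)
    expect_lt(min(d), 100)
    if (min(d) < 100) matched <- matched + 1L
  }
  # recall over well-separated on-events
  expect_gt(nrow(locs) / nrow(ems), 0.9)
  expect_equal(attr(locs, "fit_summary")$converged, nrow(locs))

  empty <- frame_stack(array(100, c(10, 16, 16)), pixel_size = px,
                       camera_offset = 100)
  expect_equal(nrow(localize_stack(empty, threshold = 160)), 0L)
})
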
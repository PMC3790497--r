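test_that("layer specs and ground truth enforce their invariants", {
  expect_error(epitope_layer_spec("x", "bimodal", 5), "2 offset")
  expect_error(epitope_layer_spec("x", "unimodal", c(1, 2)), "1 offset")
  expect_error(epitope_layer_spec("x", "unimodal", 0, layer_sd = 0))
  specs <- gbm_epitope_map("mouse")
  expect_true(all(c("agrinC", "agrinN", "nidogen") %in% names(specs)))
  expect_equal(specs$agrinC$offsets, c(-68.9, 68.9))
  dup <- list(specs$agrinC, specs$agrinC)
  expect_error(gbm_ground_truth(epitopes = dup), "unique")
})

test_that("degenerate noise puts every localization at the exact offset", {
  tr <- gbm_ground_truth(epitopes = list(
    epitope_layer_spec("u", "unimodal", 68.9, layer_sd = 1e-12)))
  tab <- sample_epitope_localizations(tr, "u", loc_error_sd = 0, seed = 1)
  radii <- sqrt(tab$x^2 + tab$y^2)
  expect_true(all(abs(radii - (2000 + 68.9)) < 1e-6))
  # sign convention: positive offset = outside the midline (podocyte side)
  expect_true(all(radii > 2000))
})

test_that("bimodal sampling balances the two layers", {
  tr <- gbm_ground_truth(epitopes = list(
    epitope_layer_spec("b", "bimodal", c(-68.9, 68.9), density = 5000)))
  tab <- sample_epitope_localizations(tr, "b", loc_error_sd = 1e-12,
                                      seed = 2)
  radii <- sqrt(tab$x^2 + tab$y^2)
  n_in <- sum(radii < 2000)
  n_out <- sum(radii >= 2000)
  expect_gt(n_in + n_out, 1e4)
  expect_lt(abs(n_in - n_out) / (n_in + n_out), 0.05)
})

test_that("sampling is reproducible under a fixed seed", {
  tr <- gbm_ground_truth()
  a <- sample_epitope_localizations(tr, "agrinC", seed = 7)
  b <- sample_epitope_localizations(tr, "agrinC", seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- sample_epitope_localizations(tr, "agrinC", seed = 8)
  expect_false(identical(nrow(a), nrow(c2)) &&
                 isTRUE(all.equal(as.data.frame(a), as.data.frame(c2))))
  # different seeds, same distribution: mean radii agree within sampling
  # error (two-sample z-test at ~4 sigma)
  ra <- sqrt(a$x^2 + a$y^2)
  rc <- sqrt(c2$x^2 + c2$y^2)
  se <- sqrt(var(ra) / length(ra) + var(rc) / length(rc))
  expect_lt(abs(mean(ra) - mean(rc)), 4 * se)
})

test_that("radial histogram of a noiseless bimodal channel is two modes", {
  tr <- gbm_ground_truth(epitopes = list(
    epitope_layer_spec("b", "bimodal", c(-68.9, 68.9), layer_sd = 1e-12,
                       density = 2000)))
  tab <- sample_epitope_localizations(tr, "b", loc_error_sd = 0, seed = 3)
  radial <- sqrt(tab$x^2 + tab$y^2) - 2000
  h <- hist(radial, breaks = seq(-100, 100, by = 10), plot = FALSE)
  modes <- h$mids[order(-h$counts)][1:2]
  expect_equal(sort(modes), c(-65, 65))  # offsets fall in these 10-nm bins
})

test_that("two-channel datasets carry both channels and full ground truth", {
  cfg <- simulation_config(seed = 5, n_regions = 16)
  sim <- simulate_two_channel_dataset(cfg, "agrinC", "agrinN")
  expect_setequal(unique(sim$table$channel), c("agrinC", "agrinN"))
  expect_equal(length(sim$loops), 2L)  # 16 regions need two 15-window loops
  expect_equal(sim$config$n_regions, 16L)
  expect_error(simulate_two_channel_dataset(cfg, "agrinC", "nope"),
               "unknown epitope")
  expect_error(simulate_two_channel_dataset(cfg, "nidogen", "agrinC"),
               "bimodal")
  # reproducibility of the full dataset
  sim2 <- simulate_two_channel_dataset(cfg, "agrinC", "agrinN")
  expect_identical(as.data.frame(sim$table), as.data.frame(sim2$table))
})

test_that("disruption replaces the layered structure on the chosen arc", {
  tr <- gbm_ground_truth()
  expect_identical(apply_disruption(tr, 0), tr)
  expect_error(apply_disruption(tr, 0.5, diffuse_sd = 0), "diffuse_sd")
  dis <- apply_disruption(tr, 1, diffuse_sd = 60, seed = 4)
  expect_equal(dis$disruption$arc_length, 2 * pi)
  tab <- sample_epitope_localizations(dis, "agrinC", loc_error_sd = 1e-12,
                                      seed = 5)
  radial <- sqrt(tab$x^2 + tab$y^2) - 2000
  # fully disrupted: single broad mode at 0, not two layers at +/-68.9
  expect_lt(abs(mean(radial)), 5)
  expect_gt(sd(radial), 40)
  expect_lt(sd(radial), 80)
})

test_that("blinking movies honour the photophysics switches", {
  mol <- data.frame(x = 8.5 * 160, y = 8.5 * 160)
  # on-probability 0: constant camera offset
  off <- simulate_frame_stack(mol, n_frames = 5, on_prob = 0,
                              camera_offset = 100, fov_px = c(16, 16),
                              seed = 1)
  expect_true(all(off$stack$intensities == 100))
  expect_equal(nrow(off$emitters), 0L)
  # always on, noise free: one spot per frame, brightest pixel at truth
  on <- simulate_frame_stack(mol, n_frames = 4, on_prob = 1,
                             photons_mean = 2000, psf_sd = 150,
                             pixel_size = 160, camera_offset = 0,
                             poisson_noise = FALSE, fov_px = c(16, 16),
                             seed = 2)
  expect_equal(nrow(on$emitters), 4L)
  for (f in 1:4) {
    img <- on$stack$intensities[f, , ]
    peak <- which(img == max(img), arr.ind = TRUE)
    expect_equal(unname(peak[1, ]), c(9L, 9L))
  }
  expect_error(simulate_frame_stack(mol, psf_sd = -1), "psf_sd")
})
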
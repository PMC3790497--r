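# Small simulations shared by the mapping tests (built once per run).
mouse_sim <- local({
  specs <- gbm_epitope_map("mouse")
  cfg <- simulation_config(seed = 61, n_regions = 30,
                           epitopes = specs[c("agrinC", "nidogen",
                                              "agrinN")])
  simulate_two_channel_dataset(cfg, "agrinC", "nidogen")
})
mouse_regions <- select_regions(mouse_sim, 30)

test_that("a central unimodal target is mapped onto zero within error", {
  em <- map_epitope(mouse_sim$table, mouse_regions, "agrinC", "nidogen",
                    "unimodal")
  est <- em$estimates[[1]]
  expect_equal(est$n_regions, 30L)
  # truth -0.22 nm: recovered mean within 2 SEM of truth
  expect_lt(abs(est$mean + 0.22), 2 * est$sem + 0.5)
  expect_equal(est$sem, est$sd / sqrt(est$n_regions), tolerance = 1e-12)
})

test_that("mapping the reference against itself is symmetric about zero", {
  em <- map_epitope(mouse_sim$table, mouse_regions, "agrinC", "agrinC",
                    "bimodal")
  endo <- em$estimates$endothelial
  podo <- em$estimates$podocyte
  expect_lt(endo$mean, 0)
  expect_gt(podo$mean, 0)
  expect_lt(abs(endo$mean + podo$mean), 2 * (endo$sem + podo$sem))
  expect_equal(length(em$offsets), 30L)
})

test_that("peak-to-peak statistics follow the fitted separations", {
  pp <- peak_to_peak_summary(mouse_sim$table, mouse_regions, "agrinC")
  expect_equal(pp$n, length(pp$per_region))
  expect_equal(pp$mean, mean(pp$per_region))
  expect_equal(pp$sem, pp$sd / sqrt(pp$n), tolerance = 1e-12)
  expect_lt(abs(pp$mean - 137.8), 2 * pp$sem + 1)
})

test_that("noiseless layers give the exact doubled offset in every region", {
  specs <- list(epitope_layer_spec("agrinC", "bimodal", c(-66.35, 66.35),
                                   layer_sd = 1e-9))
  cfg <- simulation_config(seed = 62, n_regions = 10, loc_error_sd = 1e-9,
                           epitopes = specs)
  sim <- simulate_two_channel_dataset(cfg, "agrinC", "agrinC")
  regs <- select_regions(sim, 10)
  pp <- peak_to_peak_summary(sim$table, regs, "agrinC", bin = 1)
  # every region within bin resolution of 2 * 66.35 = 132.7
  expect_true(all(abs(pp$per_region - 132.7) <= 1))
})

test_that("mapping errors name the failing stage", {
  # a channel with no bimodal structure cannot serve as reference
  expect_error(map_epitope(mouse_sim$table, mouse_regions, "nidogen",
                           "agrinC", "bimodal"),
               "reference")
  expect_error(peak_to_peak_summary(mouse_sim$table, mouse_regions,
                                    "nidogen"),
               "reference")
})

test_that("accumulated histograms conserve and align localizations", {
  em <- map_epitope(mouse_sim$table, mouse_regions, "agrinC", "agrinC",
                    "bimodal")
  profiles <- lapply(mouse_regions, function(r) {
    project_region(mouse_sim$table, r, "agrinC")
  })
  acc <- accumulate_histograms(profiles, em$offsets)
  expect_equal(acc$total, sum(vapply(profiles, `[[`, 0L, "n")))
  expect_equal(sum(acc$counts$agrinC), acc$total)
  # pooled histogram is bimodal with modes at +/- half the separation
  modes <- acc$centers[order(-acc$counts$agrinC)][1:2]
  expect_lt(abs(sort(modes)[1] + 68.9), 10 + 1e-9)
  expect_lt(abs(sort(modes)[2] - 68.9), 10 + 1e-9)

  # single profile with zero offset reproduces its own histogram
  one <- accumulate_histograms(profiles[1],
                               stats::setNames(0, profiles[[1]]$region_id))
  expect_equal(sum(one$counts$agrinC), profiles[[1]]$n)
  expect_equal(one$counts$agrinC[match(profiles[[1]]$centers, one$centers)],
               profiles[[1]]$counts)
  # duplicated profile doubles every bin
  two <- accumulate_histograms(profiles[c(1, 1)],
                               stats::setNames(0, profiles[[1]]$region_id))
  expect_equal(two$counts$agrinC, 2 * one$counts$agrinC)
  # a profile without an offset is an error naming the region
  expect_error(accumulate_histograms(profiles[2],
                                     stats::setNames(0, "nope")),
               profiles[[2]]$region_id)
})

test_that("position maps are ordered and round trip losslessly", {
  em1 <- map_epitope(mouse_sim$table, mouse_regions, "agrinC", "nidogen",
                     "unimodal")
  em2 <- map_epitope(mouse_sim$table, mouse_regions, "agrinC", "agrinC",
                     "bimodal")
  pm <- summarize_positions(list(em1, em2))
  expect_equal(nrow(pm), 3L)
  expect_true(!is.unsorted(pm$mean_nm))
  expect_equal(pm$sem_nm, pm$sd_nm / sqrt(pm$n_regions), tolerance = 1e-12)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_position_map(pm, csv)
  back <- read_position_map(csv)
  expect_equal(back$mean_nm, pm$mean_nm, tolerance = 1e-12)
  expect_equal(back$epitope, pm$epitope)
  # single estimate echoes its fields
  single <- summarize_positions(em1)
  expect_equal(single$mean_nm, em1$estimates[[1]]$mean)
  expect_equal(single$n_regions, em1$estimates[[1]]$n_regions)
})
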
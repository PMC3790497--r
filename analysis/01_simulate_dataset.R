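#!/usr/bin/env Rscript

# Simulate a reference two-channel STORM dataset of the mouse GBM:
# agrinC (bimodal, +/-68.9 nm) imaged together with agrinN (bimodal,
# -57.5/+50.2 nm) on circular capillary loops. Writes the localization
# table, a rendered overview image and the ground-truth geometry under
# results/run01/.

suppressPackageStartupMessages(library(gbmstorm))

out <- "results/run01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1, n_regions = 30)
sim <- simulate_two_channel_dataset(cfg, "agrinC", "agrinN")

message(sprintf("simulated %d localizations over %d capillary loops",
                nrow(sim$table), length(sim$loops)))
for (ch in c("agrinC", "agrinN")) {
  message(sprintf("  %-8s %6d localizations", ch,
                  sum(sim$table$channel == ch)))
}

write_localizations(sim$table, file.path(out, "localizations.csv"))

img <- render_image(sim$table, bin_size = 20, blur_sd = 20)
write_rendered_image(img, file.path(out, "overview.tif"),
                     png_preview = file.path(out, "overview.png"))

truth <- lapply(sim$loops, function(l) {
  list(loop_center = l$loop_center, mid_radius = l$mid_radius,
       epitopes = lapply(l$epitopes, unclass))
})
jsonlite::write_json(list(seed = cfg$seed, n_regions = cfg$n_regions,
                          loc_error_sd = cfg$loc_error_sd, loops = truth),
                     file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

message("wrote ", out,
        "/{localizations.csv, overview.tif, overview.png, ground_truth.json}")
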
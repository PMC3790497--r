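#' Epitope layer specifications
#'
#' Describes how one labeled epitope is distributed across the GBM width:
#' either a single layer (unimodal) or two layers flanking the membrane
#' (bimodal), each centred at a signed axial offset from the GBM midline
#' (positive toward the podocyte side) with an in-layer Gaussian spread.
#'
#' @param name epitope label (also the channel label in simulated tables).
#' @param modality `"unimodal"` or `"bimodal"`.
#' @param offsets one (unimodal) or two (bimodal) signed offsets in nm.
#' @param layer_sd in-layer spread (SD, nm, > 0).
#' @param density expected localizations per analysis window per layer.
#' @export
epitope_layer_spec <- function(name, modality = c("unimodal", "bimodal"),
                               offsets, layer_sd = 20, density = 500) {
  modality <- match.arg(modality)
  n_expect <- if (modality == "bimodal") 2L else 1L
  if (length(offsets) != n_expect) {
    stop(name, ": ", modality, " spec needs ", n_expect, " offset(s)",
         call. = FALSE)
  }
  stopifnot(layer_sd > 0, density > 0)
  structure(list(name = name, modality = modality,
                 offsets = sort(as.numeric(offsets)),
                 layer_sd = layer_sd, density = density),
            class = "epitope_layer_spec")
}

#' Reference GBM epitope position maps
#'
#' Ground-truth axial positions used by the simulator, taken from published
#' STORM measurements of the mouse and human glomerular basement membrane:
#' agrinC flanks the GBM at +/-68.9 nm (mouse reference channel), agrinN
#' sits slightly internal at -57.5/+50.2 nm, integrin beta-1 slightly
#' external at -79.6/+77.1 nm, the laminin-521 short-arm epitopes
#' (beta2-LF, alpha5-LEb/L4b) and nidogen near the midline, the laminin
#' alpha5 LG domain at the outer aspects (-84.7/+88.3 nm), the collagen
#' alpha3alpha4alpha5(IV) network near the centre (broadly spread) and
#' collagen alpha1alpha1alpha2(IV) on the endothelial side. The human map
#' carries integrin beta-1 at +/-214 nm (peak-to-peak 428 nm), reflecting
#' the roughly two-fold thicker human GBM.
#'
#' @param variant `"mouse"` or `"human"`.
#' @return named list of [epitope_layer_spec()] objects.
#' @export
gbm_epitope_map <- function(variant = c("mouse", "human")) {
  variant <- match.arg(variant)
  specs <- if (variant == "mouse") {
    list(
      epitope_layer_spec("agrinC", "bimodal", c(-68.9, 68.9)),
      epitope_layer_spec("agrinN", "bimodal", c(-57.5, 50.2)),
      epitope_layer_spec("integrinB1", "bimodal", c(-79.6, 77.1)),
      epitope_layer_spec("LMb2_LF", "unimodal", -3.2),
      epitope_layer_spec("LMa5_LEbL4b", "unimodal", -1.8),
      epitope_layer_spec("LMa5_LG", "bimodal", c(-84.7, 88.3)),
      epitope_layer_spec("colIV_a345_NC1", "unimodal", 12.5, layer_sd = 40),
      epitope_layer_spec("colIV_a345_periN", "unimodal", 11.92),
      epitope_layer_spec("colIV_a112", "unimodal", -59.5),
      epitope_layer_spec("nidogen", "unimodal", -0.22)
    )
  } else {
    list(
      epitope_layer_spec("integrinB1", "bimodal", c(-214, 214)),
      epitope_layer_spec("agrinC", "bimodal", c(-214, 214))
    )
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
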
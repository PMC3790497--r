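# gbmstorm

Nanoscale axial mapping of extracellular-matrix protein epitopes across the
glomerular basement membrane (GBM) from multichannel STORM localization
data, together with a fully controlled synthetic-data generator so that
every stage of the pipeline can be validated by parameter recovery.

## The problem

The GBM is the ~200 nm (mouse) to ~400 nm (human) extracellular-matrix
sheet between glomerular endothelial cells and podocytes. Conventional
fluorescence shows its components (agrin, laminin-521, collagen IV,
nidogen, integrin receptors) as diffuse bands, but single-molecule
localization microscopy (STORM) resolves individual protein domains into
*layers* at reproducible depths. Quantifying those depths turns a STORM
image into an architectural map: for each labeled epitope, a mean axial
position (signed, positive toward the podocyte side) with SEM and SD
across many capillary-loop regions.

The pipeline implements the quantification scheme used for such maps:

1. **Regions.** ~800-nm-wide analysis windows are placed on the GBM of
   circular capillary loops, each with a unit normal pointing toward the
   podocyte side.
2. **Projection.** Localizations of each channel are projected onto the
   window normal, giving a 1-D axial profile (10-nm histogram bins).
3. **Reference frame.** The reference channel — agrinC in mouse, which
   forms two layers flanking the GBM; integrin β1 in the thicker human
   GBM — is fitted per region with a **double Gaussian**
   `A₁N(μ₁,σ₁²) + A₂N(μ₂,σ₂²) + b`. The midpoint `(μ₁+μ₂)/2` is set to
   zero; `μ₂ − μ₁` is the **peak-to-peak distance** between the layers.
   Regions whose reference fit fails the acceptance gates (minimum
   counts, minimum separation, component resolvability, amplitude
   balance) are excluded and tallied.
4. **Target position.** The co-imaged target channel is shifted into the
   midpoint-zero frame and fitted with a single Gaussian (unimodal
   epitopes) or a double Gaussian (bimodal epitopes, sides labeled
   endothelial/podocyte).
5. **Statistics.** Iterating over regions yields the per-epitope mean
   position, `SEM = SD/√n`, and SD — the position map — plus accumulated
   (midpoint-aligned) histograms pooled over regions.

Because published position maps come from tissue for which no raw data
are deposited, validation is by **parameter recovery**: the included
simulator draws layered localization clouds on capillary-loop geometry
(layer offsets/spreads per epitope, localization error, Poisson counts,
optional blinking-movie rendering and an Alport-style segmental
disruption mode), and the pipeline must recover the generating
parameters within its own reported uncertainty.

The package also ships a single-molecule localizer (`localize_stack()`):
peak detection plus axis-aligned elliptical-Gaussian PSF fitting with
Poisson weights, so raw frame stacks can be turned into localization
tables and the simulator→localizer→mapping chain can be tested end to
end.

## Worked example

Recover the mouse agrinC layer separation from an 80-region simulation
whose true layers sit at ±68.95 nm (in-layer SD 20 nm, localization SD
15 nm, 500 localizations per layer per region):

```r
library(gbmstorm)

pp <- recover_peak_to_peak(137.9 / 2, n_regions = 80, seed = 101)
sprintf("peak-to-peak %.2f +/- %.2f nm (SEM), SD %.2f, n = %d",
        pp$mean, pp$sem, pp$sd, pp$n)
#> [1] "peak-to-peak 137.87 +/- 0.24 nm (SEM), SD 2.11, n = 80"
```

The recovered mean (137.87 nm) agrees with the generating separation
(137.90 nm) well within its standard error; the SD of ~2 nm is the
per-region fit scatter at these noise settings. Mapping a second epitope
against the agrinC reference works the same way:

```r
est <- recover_epitope_position("agrinN", seed = 3, side = "endothelial")
print(est)
#> <position_estimate> agrinN (endothelial): -57.76 +/- 0.23 nm (SEM), SD 1.79, n = 60 regions
```

i.e. the endothelial agrinN layer is recovered at −57.8 nm against a
ground truth of −57.5 nm — inside the GBM relative to the agrinC layer
at −68.9 nm, as expected for an agrin molecule whose C-terminus faces
the cell surfaces.

The numbered scripts under `analysis/` run the full study line:
`01` simulates and renders a reference dataset, `02` the agrinC
peak-to-peak experiments, `03` the complete mouse epitope position map,
`04` the human-GBM variant (integrin β1 reference, 1200-nm-deep
windows), `05` the Alport-style disruption of the bimodal gate and `06`
the localizer precision-law validation. Each writes its tables under
`results/`.

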
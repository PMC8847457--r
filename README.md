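# retorg — intrinsic-signal optoretinography of dark adaptation

`retorg` quantifies how the rodent outer retina changes during dark
adaptation from ordinary structural OCT, and ships a layered-retina phantom
generator with known ground truth so that every stage of the measurement
chain is testable. It is aimed at researchers analysing functional OCT
(optoretinography / intrinsic optical signal) experiments: seven OCT
volumes acquired at 5-minute intervals after lights-off, plus a high-speed
B-scan recording of the light–dark transition itself.

## What it measures

From each volume the pipeline extracts one representative, flattened,
4x-upsampled depth profile (repeat averaging → ELM-anchored flattening →
averaging of the central 150 B-scans and 200 central A-lines), normalizes
it on the outer-nuclear-layer (ONL) intensity, and measures:

* **Thicknesses** from shared sub-pixel boundary operators — inner retina,
  outer retina, ONL, and the ELM–RPE complex, with
  `ONL + ELM–RPE = outer retina` holding exactly;
* **Relative band intensities** of IPL, OPL, ISe and RPE in ONL units;
* **ELM–RPE displacement** against the light-adapted baseline
  (negative = shortening), and the share of outer-retinal thinning carried
  by the ELM–RPE complex, `100 · Δ(ELM–RPE) / Δ(outer)`;
* **Double outer-segment-tip peaks**: the interdigitation-zone band splits
  into a cone-tip and a rod-tip peak, measured as peak-to-peak distances
  from the ISe band.

High-speed recordings become spatiotemporal M-scans (16-frame blocks →
one-second columns, ELM-aligned), from which per-second ISe intensity and
ELM–RPE displacement are tracked and tested for linear trends with Pearson
correlations. Group inference across the seven timestamps uses a one-way
repeated-measures ANOVA (`F = MS_time / MS_error` on
`(k−1, (k−1)(n−1))` df) with Bonferroni post-hoc tests against the
baseline.

The phantom renders a piecewise-constant ("staircase") axial reflectance
model through a Gaussian axial PSF (FWHM `(2 ln2/π)·λ²/Δλ`, 2.9 um for the
810/100 nm source), lateral curvature, and unit-mean gamma speckle whose
shape parameter is the number of averaged looks; dark-adaptation kinetics
ramp linearly to saturation at 30 minutes. See the methods vignette
(`vignettes/dark-adaptation-optoretinography.Rmd`) for the model, the
estimator choices and their rationale.

## Worked example

Render a phantom eye at the light-adapted baseline and after 30 minutes of
dark adaptation, and measure both:

```r
library(retorg)

model    <- retina_layer_model()       # light-adapted staircase geometry
kin      <- kinetics_params()          # linear ramp, saturation at 30 min
protocol <- acquisition_protocol(n_alines = 200, n_bscans = 150,
                                 n_repeats = 1, axial_px = 224,
                                 speckle_looks = 16, seed = 7)

vol_light <- render_volume(model, kin, protocol, t_min = 0)
vol_dark  <- render_volume(model, kin, protocol, t_min = 30)
light <- measure_profile(representative_profile(vol_light))
dark  <- measure_profile(representative_profile(vol_dark))

round(rbind(light = unlist(light[1:10]), dark = unlist(dark[1:10])), 2)
#>       inner_retina_um outer_retina_um onl_um elm_rpe_um ipl_intensity
#> light           79.45          106.95  58.31      48.64           3.2
#> dark            79.43          101.16  56.58      44.58           3.2
#>       opl_intensity ise_intensity rpe_intensity cone_distance_um
#> light          3.00          5.71          5.54            13.46
#> dark           3.01          4.50          5.58               NA
#>       rod_distance_um
#> light           21.39
#> dark               NA

dark$elm_rpe_um - light$elm_rpe_um
#> [1] -4.066
shortening_fraction(dark$elm_rpe_um - light$elm_rpe_um,
                    dark$outer_retina_um - light$outer_retina_um)
#> [1] 70.23
```

The inner retina is stable while the ELM–RPE complex shortens by ~4.07 um —
about 70% of the 5.8 um outer-retinal displacement — and the ISe band loses
a fifth of its relative intensity, recovering the generator's configured
kinetics. The tip peaks are resolved at baseline (13.5 and 21.4 um from the
ISe) and fade below the detection threshold in the fully dark-adapted
snapshot, as the interdigitation-zone band does in vivo.

## Analysis workflow

The `analysis/` directory holds the numbered study drivers, each a thin
script over the package that prints its findings and writes tables under
`results/`:

1. `01_protocol_checks.R` — axial resolution, frame period, M-scan column
   arithmetic;
2. `02_volume_dark_adaptation.R` — 14 phantom eyes x 7 timestamps:
   thickness/intensity series, RM-ANOVA with post-hoc tests, displacement
   summary;
3. `03_null_control.R` — the light-stable control scenario (no measure may
   reach significance);
4. `04_highspeed_kinetics.R` — 14 transition recordings: aggregated M-scan,
   per-second kinetics, Pearson correlations, double-peak distances.

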
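---
title: "Quantifying dark-adaptation kinetics in OCT depth profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dark-adaptation kinetics in OCT depth profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retorg)
```

## The measurement problem

Dark adaptation changes the optical properties of the outer retina on a
time scale of minutes: the mitochondria-rich inner-segment ellipsoid (ISe)
band loses reflectivity, the span from the external limiting membrane (ELM)
to the basal retinal pigment epithelium (RPE) shortens by a few micrometres,
the interdigitation-zone (IZ) tip bands fade, and the outer nuclear layer
(ONL) thins slightly. These intrinsic signals can be read out with ordinary
structural OCT, provided the analysis chain can resolve sub-micrometre
axial displacements and percent-level reflectivity changes in speckled
images. `retorg` implements that chain end to end, together with a
layered-retina phantom generator whose ground truth makes every stage
testable.

The pipeline mirrors a standard in-vivo mouse protocol: seven OCT volumes
(4 repeats x 600 B-scans x 600 A-lines over 1.2 x 1.2 mm) at 0, 5, ..., 30
minutes of dark adaptation, plus one high-speed recording at a fixed plane
(4800 B-scans at 16 fps, 62.5 ms frame period, lights switched off 30 s into
the recording).

## The generative model

### Staircase reflectance

`retina_layer_model()` describes the retina as contiguous axial layers with
piecewise-constant linear reflectance — a staircase. The default geometry
encodes the light-adapted baseline: inner retina 79.42 um, ONL 58.08 um
(OPL/ONL boundary to ELM band centre), ELM–RPE complex 48.73 um, and tip
bands at 13.4 um (cone) and 20.9 um (rod) beyond the ISe band centre. Two
modelling points deserve emphasis:

* **Hypo-reflective gaps are load-bearing.** A band can only appear as a
  distinct local maximum after convolution with the axial point-spread
  function (PSF) if a darker plateau separates it from its neighbours. The
  model therefore includes the ganglion-cell layer between NFL and IPL, the
  inner-segment myoid between ELM and ISe, the distal outer segment between
  the two tip bands, and a thin subretinal gap before the RPE. Without
  these, adjacent hyper-reflective plateaus merge into shoulders and no
  peak detector could separate them.
* **Band centres are the ground truth.** Thicknesses that involve the ELM
  are defined to its band centre, so the generator's bookkeeping
  (ONL + ELM–RPE = outer retina) is exact by construction and the same
  additivity holds for the measured quantities, which share boundary
  operators.

### Rendering

An A-line is rendered as staircase -> Gaussian axial PSF (FWHM from the
coherence length of the source, `axial_resolution(810, 100)` = 2.9 um) ->
lateral curvature shift (quadratic bowing, default ~40 um across the 1.2 mm
field) -> multiplicative unit-mean gamma speckle whose shape parameter is
the number of incoherently averaged looks (default 4). Fully developed
speckle gives exponential intensity statistics (one look); averaging N
independent looks yields a gamma(N) with variance 1/N — the renderer's
speckle model is exactly this family, so frame averaging in the pipeline has
the textbook variance behaviour and can be checked by simulation.

Because the sum of independent gammas with a common rate is gamma,
averaging k unit-mean gamma(a) speckle fields equals (in distribution) one
gamma(k a) field. The package uses this identity in three documented
places: repeat-averaged volumes can be rendered as single-repeat volumes at
`speckle_looks = 16`; laterally averaged A-line groups in high-speed
recordings can be rendered as fewer A-lines at proportionally more looks;
and `render_profile()` renders a fully averaged representative profile in
one pass with `effective_looks` equal to the total averaged look count.
These reductions are exact at the level of the averaged data the pipeline
measures; the full multi-repeat, wide-field code paths are exercised by
their own tests.

### Kinetics

`kinetics_params()` ramps the dark-adaptation changes linearly from
lights-off to saturation at 30 minutes (the gradual, linear time course is
what the volume series and the high-speed analysis both show); an
exponential approach with the same saturation state is available. Defaults:
ELM–RPE shortening 4.07 um and ONL shortening 1.76 um at saturation, so the
total outer-retinal displacement is 5.83 um and the ELM–RPE share is ~70%.
The ISe fractional intensity drop (0.2) and the tip-band contrast loss
(0.6) are not printed numbers in the source protocol; they were fixed once
at values typical of intrinsic scattering signals that are clearly visible
yet far from saturating the dynamic range, and the parameter-recovery tests
check recovery of whatever value is configured, not these constants.
Geometrically, a snapshot translates the ELM (and the ONL outer boundary)
inward by the ONL shortening and compresses the layers between the ELM and
the basal RPE affinely; inner retinal layers never move.

The null control (`null_kinetics()`) zeroes every drop and shortening: the
same acquisition, speckle and motion with a light-stable retina. It is the
scenario against which false-positive behaviour of the whole chain is
measured.

### Motion

High-speed recordings add per-frame axial jitter: a 1 Hz breathing sinusoid
plus a slow AR(1) drift (5 s time constant), both scaled by the jitter
amplitude (default 1.5 um where enabled; the drift's stationary sd is a
quarter of the amplitude). Motion of an anaesthetized animal is smooth on
the 62.5 ms frame scale — a white per-frame tremor would create artificial
frame-to-frame blur variation, which is why the drift is autocorrelated.

## The measurement chain

### Flattening and the representative profile

`detect_elm()` locates the ELM per A-line in three steps: coarse per-A-line
alignment by cross-correlation against the central A-line; anatomical
anchoring on the aligned average (the RPE is the deepest prominent peak at
least half as high as the tallest; the ISe is the tallest peak 25–60 um
inner to it; the ELM is the most prominent peak 5–18 um inner to the ISe);
and per-A-line normalized cross-correlation against an outer-retina
template around the anchored ELM, refined parabolically on the correlation
curve. The trace is median-filtered laterally (window 15 A-lines): the ELM
is smooth in the retina, so the filtered trace is the estimate, and
residual outliers are replaced and flagged with zero confidence. Detection
fails loudly when fewer than half the A-lines reach the confidence
threshold.

`flatten()` shifts each A-line (sub-pixel, linear interpolation) so the ELM
sits at a common reference; `representative_profile()` averages the
repeats, flattens every averaged B-scan to a volume-wide reference, averages
the central 150 B-scans and then the central 200 A-lines, and upsamples the
result 4x by linear interpolation (120,000 raw A-scans per profile at the
default protocol). All arithmetic is done on linear intensities; log
compression is considered display-only, since linear averaging is what
reduces speckle before quantification.

`normalize_onl()` divides by the mean over the central 50% of the ONL span
(estimated from the profile itself when not supplied). The mean rather than
the minimum is the default normalizer — the minimum of a speckled hypo
region is a biased order statistic — but the minimum is available.

### Bands and boundaries

`locate_bands()` smooths with a Gaussian of one original pixel, keeps local
maxima with prominence at least 0.1 of the ISe candidate height, anchors
the outer retina as above, assigns NFL/IPL/OPL in ELM-relative windows, and
refines every peak parabolically (never by more than one sample from its
discrete argmax). ELM, ISe and RPE are mandatory; their absence is an
error naming the band.

Boundary operators are shared by all thickness measures so that
ONL + ELM–RPE equals the outer retina exactly:

* inner surface — first crossing of 50% of the NFL peak height;
* OPL/ONL — half-prominence crossing on the outer OPL flank (midway
  between the OPL peak and the ONL plateau);
* ELM — the band peak;
* basal RPE — half-prominence crossing on the outer RPE flank (midway
  between the RPE peak and the choroidal plateau).

Half-prominence rather than absolute half-maximum is deliberate: under a
symmetric PSF the midpoint between two plateaus crosses exactly at the
reflectance step, so the operator is unbiased and gain-invariant. With an
elevated choroid an absolute half-maximum criterion would sit ~1.4 um too
deep.

`detect_double_peaks()` searches the open interval between the ISe and RPE
peaks (2 um guard bands) for up to two maxima with prominence >= 0.2 in
ONL-normalized units; two resolved maxima are cone (shallower) and rod
(deeper) tips, a single one is reported as the rod tip, and absence is
encoded rather than raised. Tips closer than the PSF FWHM merge — the
phantom reproduces the textbook two-point-resolution behaviour.

### M-scans and transition kinetics

`build_mscan()` averages 16-frame blocks (a trailing partial block is
dropped with a warning, keeping one column = one second exact), flattens
each averaged frame to a recording-wide ELM reference, averages the central
A-lines, upsamples 4x, ONL-normalizes each column over a span fixed from
the pre-lights-off mean, and finally aligns each column by normalized
cross-correlation against the ELM band of that mean. The final alignment
uses integer upsampled-sample shifts: a pure index shift has no
interpolation attenuation, so band heights remain comparable across
columns.

`transition_kinetics()` extracts, per column:

* the ELM position, by detrended NCC against the pre-lights-off ELM
  template (detrending removes the ONL-to-inner-segment background ramp,
  making the match insensitive to residual motion blur);
* the basal RPE, by the same half-prominence flank as the profile
  operators, within a window seeded by the baseline band set;
* the ELM–RPE distance as the difference of the two — both ends measured in
  the same column frame, so residual alignment errors cancel;
* the ISe intensity as the mean over a fixed window spanning the ELM–ISe
  band complex with edges on the flat ONL and outer-segment plateaus. This
  band-mass measure is exactly invariant to residual within-column motion
  blur (blur conserves mass and moves none across a flat-edged window) and
  first-order invariant to residual shifts; the bare peak height is
  neither. Only the ISe reflectance changes during dark adaptation, so the
  series tracks the ISe.

These estimator choices were validated on the null scenario: with them, the
three Pearson coefficients (time vs ISe, time vs displacement, ISe vs
displacement) have means indistinguishable from zero across independent
null phantoms, and on noiseless linear-ramp phantoms the fitted
displacement slope recovers the configured shortening rate within ~3%
(the residual comes from sub-sample discretisation of the flank operators).
Displacement is referenced to the mean over the pre-lights-off columns, and
trends and correlations are computed over post-lights-off columns only.
`aggregate_mscans()` averages recordings after bringing their reference
rows into register, mirroring how per-animal M-scans are combined before
the correlation analysis.

### Statistics

`rm_anova()` is the univariate within-subject decomposition
SS_total = SS_subject + SS_time + SS_error with
F = MS_time / MS_error on (k-1, (k-1)(n-1)) degrees of freedom. No
sphericity correction is applied to the primary p-value; the
Greenhouse–Geisser epsilon is reported as a diagnostic.
`bonferroni_vs_baseline()` runs paired two-sided t-tests of each dark
timestamp against the light-adapted baseline with a family of k-1 = 6
comparisons (the vs-baseline family matches how earliest-significant
timestamps are reported; the all-pairs family of 21 is available behind a
flag). `pearson_cor()` is the product-moment coefficient with the
two-sided t-transform p-value. Degenerate inputs (zero error variance, zero
series variance, missing cells, fewer than two subjects) raise typed
errors; a table with identical columns and arbitrary subject offsets
returns F = 0, p = 1 rather than 0/0.

## Problem sizes

Simulation sizes used by the tests and shipped analyses, chosen so each
study completes comfortably on a single core while leaving the statistical
conclusions unchanged:

| study | size |
|---|---|
| parameter recovery | 14 eyes x 2 timestamps, volumes 150 x 200 x 224 px, repeats folded (16 looks) |
| volume series analysis | 14 eyes x 7 timestamps, same volumes |
| type-I error | 1000 replicates of 14 subjects x 7 timestamps, profile-level rendering at 512 looks |
| transition pattern | 14 recordings, 4800 frames x 8 A-lines (100 looks) x 224 px, aggregated |
| null transition sweep | 100 recordings of 768 frames |

## What the phantom does and does not show

The generator reproduces the features the pipeline must cope with:
staircase band structure at realistic depths, PSF-limited resolution,
fully developed speckle with averaging statistics, lateral curvature, slow
axial motion, and the configured kinetics with a light-stable control. It
does **not** simulate vascular shadowing, choroidal flow, lateral eye
motion between volumes, detector noise floors, log compression, or
biological variability between eyes (all simulated eyes share one true
geometry; only noise differs). Passing recovery tests therefore
demonstrates that the measurement chain is unbiased and precise under the
modelled physics — not that the anatomical values themselves generalise to
any particular animal. The printed group statistics of the source study
come from real mice and are intentionally not reproduction targets; the
phantom tests recover the generator's configured truth instead.

## Known limitations

* 1-D profile segmentation: bands are located on averaged representative
  profiles, not by 2-D/3-D graph methods; severely disrupted retinas would
  need different anchoring rules.
* The ELM anchoring assumes the ONL is the darkest plateau inner to a
  bright ISe/RPE complex — true for healthy rodent retina, not for
  degenerations that invert the contrast.
* Sub-pixel operators (parabolic refinement, flank crossings) work on
  linearly-interpolated upsampled grids; their residual discretisation
  error (~2–3% on kinetic slopes) is visible in the noiseless checks.
* The tip bands fade into the RPE shoulder at strong contrast loss, as in
  late dark adaptation; tip metrics are therefore baseline measures.
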
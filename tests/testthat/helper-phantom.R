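# Shared phantom fixtures, built in code.

# Default model/kinetics at the light-adapted baseline geometry.
default_model <- function(...) retina_layer_model(...)
flat_model <- function(...) retina_layer_model(curvature_um_mm2 = 0, ...)

# Protocol with a 224-px (280 um) axial window that just contains the
# default model; lateral sizes chosen per test.
test_protocol <- function(n_alines = 16, n_bscans = 4, n_repeats = 1,
                          axial_px = 224, speckle_looks = Inf, seed = 1L,
                          ...) {
  acquisition_protocol(n_alines = n_alines, n_bscans = n_bscans,
                       n_repeats = n_repeats, axial_px = axial_px,
                       speckle_looks = speckle_looks, seed = seed, ...)
}

# Quarter-scale model fitting a 58.75 um (48 px) window, for lateral-shape
# and I/O tests where only geometry matters.
mini_model <- function(...) {
  retina_layer_model(inner_surface_um = 7.5, nfl_um = 2.5, gcl_um = 3,
                     ipl_um = 6.25, inl_um = 3.75, opl_um = 4.355,
                     onl_um = 14.52, elm_rpe_um = 12.18,
                     elm_width_um = 0.8, is_um = 1.4, ise_width_um = 1.8,
                     cone_tip_offset_um = 3.35, rod_tip_offset_um = 5.22,
                     tip_width_um = 0.7, subretinal_um = 0.8,
                     choroid_outer_um = 58, curvature_um_mm2 = 0, ...)
}

# Noiseless representative profile of a model snapshot (upsampled 4x).
noiseless_profile <- function(model, axial_px = 224) {
  render_profile(model, test_protocol(axial_px = axial_px),
                 effective_looks = Inf)
}

# A bare depth_profile around a supplied intensity vector.
make_profile <- function(intensity, pitch_um = 1.25 / 4,
                         pixel_pitch_um = 1.25,
                         normalized = "ONL-normalized") {
  retorg:::new_depth_profile(intensity, pitch_um = pitch_um,
                             pixel_pitch_um = pixel_pitch_um,
                             normalized = normalized)
}

# Brute-force local-maximum scan (independent oracle for peak finding):
# exhaustive walk over maximal runs of equal values; a run strictly higher
# than both neighbours is a maximum, reported at its centre sample.
brute_force_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1L
    if (i > 1L && j < n && y[i - 1] < y[i] && y[j + 1] < y[i])
      out <- c(out, (i + j) %/% 2L)
    i <- j + 1L
  }
  out
}
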
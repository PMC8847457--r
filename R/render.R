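# Forward rendering: staircase reflectance -> PSF blur -> curvature shift ->
# multiplicative gamma speckle.

# Noiseless axial profile of a model snapshot on a fine grid: the staircase
# convolved with the Gaussian axial PSF. Returned as a list(z, y) lookup.
render_profile_fine <- function(model, psf_fwhm_um, zmax_um = NULL,
                                dz = 0.05) {
  ly <- model$layers
  margin <- 8 * psf_fwhm_um + 5
  zmax <- max(ly$outer_um, zmax_um %||% 0) + margin
  z <- seq(-margin, zmax, by = dz)
  y <- numeric(length(z))
  for (i in seq_len(nrow(ly))) {
    sel <- z >= ly$inner_um[i] & z < ly$outer_um[i]
    y[sel] <- ly$reflectance[i]
  }
  sigma <- psf_fwhm_um / (2 * sqrt(2 * log(2)))
  k <- gaussian_kernel(sigma / dz)
  r <- (length(k) - 1L) / 2L
  yp <- c(rep(y[1L], r), y, rep(y[length(y)], r))
  yc <- as.numeric(stats::filter(yp, k, sides = 2L))[(r + 1L):(r + length(y))]
  list(z = z, y = yc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_layers_in_window <- function(model, window_um) {
  ly <- model$layers
  bad <- which(ly$outer_um > window_um + 1e-9)
  if (length(bad))
    retorg_error("render",
                 "layer '%s' (outer boundary %.1f um) exceeds the %.1f um axial window",
                 ly$name[bad[1L]], ly$outer_um[bad[1L]], window_um)
  invisible(TRUE)
}

curvature_shift_um <- function(model, x_mm, y_mm = 0) {
  model$curvature_um_mm2 * (x_mm^2 + y_mm^2)
}

#' Render a single A-line
#'
#' Samples the PSF-blurred staircase reflectance profile of a model snapshot
#' at the axial pixel grid, shifted deeper by the lateral curvature bow at
#' the requested position, and multiplied by unit-mean gamma speckle whose
#' shape parameter is the protocol's `speckle_looks` (set `speckle_looks =
#' Inf` for the noiseless limit). Deterministic given `seed`.
#'
#' @param model A [retina_layer_model()] snapshot (see [kinetics_at()]).
#' @param lateral_mm Lateral offset(s) from the field centre, `c(x, y)` mm.
#' @param protocol An [acquisition_protocol()].
#' @param seed Integer seed; default the protocol seed.
#' @return Numeric vector of `protocol$axial_px` non-negative intensities.
#' @export
render_aline <- function(model, lateral_mm = c(0, 0), protocol,
                         seed = protocol$seed) {
  lateral_mm <- rep_len(lateral_mm, 2L)
  half <- protocol$field_mm / 2
  if (abs(lateral_mm[1L]) > half[1L] + 1e-9 ||
      abs(lateral_mm[2L]) > half[2L] + 1e-9)
    retorg_error("parameter", "lateral position outside the %.2f x %.2f mm field",
                 protocol$field_mm[1L], protocol$field_mm[2L])
  window <- (protocol$axial_px - 1L) * protocol$pitch_um
  check_layers_in_window(model, window + protocol$pitch_um)
  fine <- render_profile_fine(model, protocol$psf_fwhm_um, zmax_um = window)
  zq <- (seq_len(protocol$axial_px) - 1L) * protocol$pitch_um -
    curvature_shift_um(model, lateral_mm[1L], lateral_mm[2L])
  y <- interp_zero(fine$z, fine$y, zq)
  y <- apply_speckle(y, protocol$speckle_looks, seed)
  pmax(y, 0)
}

apply_speckle <- function(y, looks, seed) {
  if (!is.finite(looks)) return(y)
  set.seed(seed)
  y * speckle_gamma(length(y), looks)
}

#' Fast profile-level phantom
#'
#' Renders representative depth profiles directly, modelling the profile
#' obtained after averaging many speckled A-lines: because the mean of `n`
#' independent unit-mean gamma(`looks`) variates is gamma(`n * looks`) with
#' unit mean, an averaged profile is rendered in one pass by using
#' `effective_looks = n * looks` as the speckle shape. Used for cheap
#' large-replicate simulations (e.g. type-I error studies); the full
#' volume-based path is [render_volume()] + [representative_profile()].
#'
#' @param model Model snapshot.
#' @param protocol Acquisition protocol.
#' @param effective_looks Total number of averaged looks.
#' @param upsample Linear-interpolation upsampling factor (default 4).
#' @param seed Integer seed.
#' @param n Number of independent profiles to draw (sharing one noiseless
#'   render).
#' @return A `depth_profile` (raw, un-normalized), or a list of `n` of them
#'   when `n > 1`.
#' @export
render_profile <- function(model, protocol, effective_looks = Inf,
                           upsample = 4L, seed = protocol$seed, n = 1L) {
  window <- (protocol$axial_px - 1L) * protocol$pitch_um
  check_layers_in_window(model, window + protocol$pitch_um)
  fine <- render_profile_fine(model, protocol$psf_fwhm_um, zmax_um = window)
  zq <- (seq_len(protocol$axial_px) - 1L) * protocol$pitch_um
  y0 <- interp_zero(fine$z, fine$y, zq)
  if (is.finite(effective_looks)) set.seed(seed)
  one <- function() {
    y <- if (is.finite(effective_looks))
      y0 * speckle_gamma(length(y0), effective_looks) else y0
    new_depth_profile(upsample_profile(y, upsample),
                      pitch_um = protocol$pitch_um / upsample,
                      pixel_pitch_um = protocol$pitch_um,
                      timestamp_min = NA_real_, n_contributing = NA_real_)
  }
  if (n == 1L) one() else lapply(seq_len(n), function(i) one())
}

# Render one noiseless B-scan as a [n_alines x axial_px] matrix by sampling
# the shared fine profile at per-A-line curvature shifts.
render_bscan_noiseless <- function(fine, model, protocol, y_mm) {
  na <- protocol$n_alines; nz <- protocol$axial_px
  dx <- protocol$field_mm[1L] / na
  x <- (seq_len(na) - (na + 1) / 2) * dx
  shift <- curvature_shift_um(model, x, y_mm)
  zpx <- (seq_len(nz) - 1L) * protocol$pitch_um
  zq <- outer(shift, zpx, function(s, z) z - s)  # [aline, depth]
  m <- interp_zero(fine$z, fine$y, as.numeric(zq))
  matrix(m, nrow = na, ncol = nz)
}

#' Render an OCT volume
#'
#' Renders a full volume (`n_repeats x n_bscans x n_alines x axial_px`) of
#' the kinetics snapshot at `t_min`, with independent speckle in every
#' repeat, B-scan and pixel. Intensities are snapped to the 32-bit float
#' grid so that on-disk storage ([write_volume()]) is lossless.
#'
#' @param model Baseline [retina_layer_model()].
#' @param kin A [kinetics_params()] (or `NULL` for the static baseline).
#' @param protocol An [acquisition_protocol()].
#' @param t_min Acquisition timestamp in minutes since lights-off.
#' @param seed Integer seed; default derives from the protocol seed and
#'   timestamp index.
#' @return An `oct_volume`.
#' @export
render_volume <- function(model, kin = NULL, protocol, t_min = 0,
                          seed = NULL) {
  snap <- if (is.null(kin)) model else kinetics_at(model, kin, t_min)
  window <- (protocol$axial_px - 1L) * protocol$pitch_um
  check_layers_in_window(snap, window + protocol$pitch_um)
  seed <- seed %||% sub_seed(protocol$seed, round(1000 * t_min))
  fine <- render_profile_fine(snap, protocol$psf_fwhm_um, zmax_um = window)
  nr <- protocol$n_repeats; nb <- protocol$n_bscans
  na <- protocol$n_alines; nz <- protocol$axial_px
  dy <- protocol$field_mm[2L] / nb
  yy <- (seq_len(nb) - (nb + 1) / 2) * dy
  looks <- protocol$speckle_looks
  vol <- array(0, dim = c(nr, nb, na, nz))
  set.seed(seed)
  for (b in seq_len(nb)) {
    clean <- render_bscan_noiseless(fine, snap, protocol, yy[b])  # [na, nz]
    ce <- matrix(clean, nrow = nr, ncol = na * nz, byrow = TRUE)
    if (is.finite(looks)) {
      sp <- speckle_gamma(nr * na * nz, looks)
      dim(sp) <- c(nr, na * nz)
      ce <- ce * sp
    }
    vol[, b, , ] <- snap_float32(ce)
  }
  oct_volume(vol, pitch_um = protocol$pitch_um,
             lateral_pitch_um = 1000 * protocol$field_mm[1L] / na,
             timestamp_min = t_min, seed = seed,
             provenance = sprintf("retorg phantom t=%g min", t_min))
}

#' Render a high-speed B-scan recording
#'
#' Renders `n_frames` B-scans at a fixed retinal plane with per-frame
#' timestamps. The kinetics clock starts at the protocol's lights-off time
#' (frames before it are drawn from the light-adapted baseline only); the
#' kinetic state is sampled on a `kinetics_dt_s` grid aligned to lights-off
#' (default 1 s, the M-scan column period). Optional per-frame axial jitter
#' emulates breathing motion: a sinusoid of amplitude `jitter_um` at
#' `jitter_freq_hz` plus Gaussian jitter of a quarter that amplitude.
#'
#' @param model Baseline model.
#' @param kin Kinetics (or `NULL` for a static scene).
#' @param protocol Acquisition protocol (frames, rate, lights-off time).
#' @param jitter_um Axial jitter amplitude in um (0 disables).
#' @param jitter_freq_hz Breathing frequency.
#' @param kinetics_dt_s Temporal quantization of the kinetic state, s.
#' @param seed Integer seed.
#' @return A `highspeed_recording`.
#' @export
render_highspeed <- function(model, kin = NULL, protocol, jitter_um = 0,
                             jitter_freq_hz = 1, kinetics_dt_s = 1,
                             seed = protocol$seed) {
  nf <- protocol$n_frames; na <- protocol$n_alines; nz <- protocol$axial_px
  window <- (nz - 1L) * protocol$pitch_um
  loff <- protocol$lights_off_s
  tf <- (seq_len(nf) - 1L) / protocol$frame_rate_hz
  # kinetic time (min since lights-off), quantized to column-period bins
  tkin <- ifelse(tf < loff, -1,
                 (floor((tf - loff) / kinetics_dt_s) + 0.5) * kinetics_dt_s / 60)
  snaps <- new.env(parent = emptyenv())
  get_fine <- function(t) {
    key <- sprintf("%.6f", t)
    if (is.null(snaps[[key]])) {
      s <- if (is.null(kin) || t < 0) model else kinetics_at(model, kin, t)
      check_layers_in_window(s, window + protocol$pitch_um)
      snaps[[key]] <- list(
        fine = render_profile_fine(s, protocol$psf_fwhm_um, zmax_um = window),
        model = s)
    }
    snaps[[key]]
  }
  dx <- protocol$field_mm[1L] / na
  x <- (seq_len(na) - (na + 1) / 2) * dx
  zpx <- (seq_len(nz) - 1L) * protocol$pitch_um
  looks <- protocol$speckle_looks

  # Breathing sinusoid plus a slow autocorrelated drift (AR(1), ~5 s time
  # constant, stationary sd = jitter_um / 4). Axial motion of an
  # anaesthetized animal is smooth on the frame-period scale; frame-to-frame
  # white jumps would be unphysical.
  set.seed(sub_seed(seed, 7L))
  jit <- numeric(nf)
  if (jitter_um > 0) {
    dt <- 1 / protocol$frame_rate_hz
    phi <- exp(-dt / 5)
    innov_sd <- (jitter_um / 4) * sqrt(1 - phi^2)
    drift <- numeric(nf)
    drift[1L] <- rnorm(1L, sd = jitter_um / 4)
    eps <- rnorm(nf, sd = innov_sd)
    for (f in 2:nf) drift[f] <- phi * drift[f - 1L] + eps[f]
    jit <- jitter_um * sin(2 * pi * jitter_freq_hz * tf) + drift
  }

  rec <- array(0, dim = c(nf, na, nz))
  set.seed(sub_seed(seed, 11L))
  for (f in seq_len(nf)) {
    sn <- get_fine(tkin[f])
    shift <- curvature_shift_um(sn$model, x, 0) + jit[f]
    zq <- outer(shift, zpx, function(s, z) z - s)
    clean <- matrix(interp_zero(sn$fine$z, sn$fine$y, as.numeric(zq)), na, nz)
    if (is.finite(looks))
      clean <- clean * speckle_gamma(na * nz, looks)
    rec[f, , ] <- snap_float32(clean)
  }
  highspeed_recording(rec, frame_rate_hz = protocol$frame_rate_hz,
                      lights_off_s = loff, pitch_um = protocol$pitch_um,
                      seed = seed,
                      provenance = "retorg phantom high-speed recording")
}
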
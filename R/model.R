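# Generative ground truth: layered retina model, dark-adaptation kinetics
# parameters, and the acquisition protocol.

LAYER_ORDER <- c("vitreous", "NFL", "GCL", "IPL", "INL", "OPL", "ONL", "ELM", "IS",
                 "ISe", "OS", "IZ_cone", "OS_distal", "IZ_rod", "subretinal",
                 "RPE", "choroid")

#' Layered retina reflectance model
#'
#' Builds the piecewise-constant ("staircase") axial reflectance model of the
#' mouse retina used as phantom ground truth: contiguous layers from the
#' vitreous to the choroid, each with a mean linear reflectance in arbitrary
#' units. Depths are micrometres from the top of the axial window (0-based,
#' increasing inner to outer). Default extents reproduce the light-adapted
#' baseline geometry: inner retina 79.42 um, ONL 58.08 um (outer plexiform
#' layer boundary to ELM band centre), ELM-RPE complex 48.73 um (ELM band
#' centre to basal RPE), and interdigitation-zone double peaks at 13.4 um
#' (cone outer-segment tips) and 20.9 um (rod tips) beyond the inner-segment
#' ellipsoid band centre.
#'
#' The hyper-reflective bands (ELM, ISe, cone-tip, rod-tip, RPE) are separated
#' by hypo-reflective plateaus (ONL, inner-segment myoid, outer segment,
#' distal outer segment, subretinal gap) so that each band is a distinct local
#' maximum after convolution with the axial point-spread function.
#'
#' @param inner_surface_um Depth of the inner retinal surface (top of NFL).
#' @param nfl_um,gcl_um,ipl_um,inl_um,opl_um Inner retinal layer
#'   thicknesses; their sum is the inner-retina thickness.
#' @param onl_um Outer nuclear layer extent: OPL/ONL boundary to ELM band
#'   centre.
#' @param elm_rpe_um ELM band centre to basal RPE boundary.
#' @param elm_width_um,is_um,ise_width_um ELM band width, inner-segment myoid
#'   length, and ISe band width.
#' @param cone_tip_offset_um,rod_tip_offset_um Distances from the ISe band
#'   centre to the cone and rod outer-segment tip band centres. The cone
#'   offset must be the smaller of the two.
#' @param tip_width_um Width of each tip band.
#' @param subretinal_um Hypo-reflective gap between the rod tip band and the
#'   apical RPE.
#' @param choroid_outer_um Outer extent of the modelled choroid.
#' @param reflectance Named vector of mean linear reflectances (arbitrary
#'   units) for all layers; see `retorg:::LAYER_ORDER` for the names.
#' @param curvature_um_mm2 Quadratic lateral bowing coefficient: all layers
#'   shift deeper by `curvature_um_mm2 * r^2` um at lateral distance `r` mm
#'   from the field centre (default ~40 um bowing at the edge of a 1.2 mm
#'   field).
#' @return A `retina_layer_model` with the layer table and derived landmark
#'   depths (ELM centre, ISe centre, tip centres, basal RPE).
#' @export
retina_layer_model <- function(inner_surface_um = 30,
                               nfl_um = 10, gcl_um = 12, ipl_um = 25,
                               inl_um = 15, opl_um = 17.42,
                               onl_um = 58.08,
                               elm_rpe_um = 48.73,
                               elm_width_um = 3, is_um = 5.5, ise_width_um = 7,
                               cone_tip_offset_um = 13.4,
                               rod_tip_offset_um = 20.9,
                               tip_width_um = 2.8,
                               subretinal_um = 3.2,
                               choroid_outer_um = 280,
                               reflectance = c(vitreous = 0.02, NFL = 2.0,
                                               GCL = 0.7,
                                               IPL = 1.6, INL = 0.7, OPL = 1.5,
                                               ONL = 0.5, ELM = 2.5, IS = 0.8,
                                               ISe = 3.0, OS = 0.6,
                                               IZ_cone = 1.7, OS_distal = 0.6,
                                               IZ_rod = 2.4, subretinal = 0.9,
                                               RPE = 2.8, choroid = 1.2),
                               curvature_um_mm2 = 111) {
  params <- as.list(environment())
  if (!all(LAYER_ORDER %in% names(reflectance)))
    retorg_error("parameter", "reflectance must name all layers: %s",
                 paste(setdiff(LAYER_ORDER, names(reflectance)), collapse = ", "))
  if (cone_tip_offset_um >= rod_tip_offset_um)
    retorg_error("parameter",
                 "cone tip offset (%.2f) must be smaller than rod tip offset (%.2f)",
                 cone_tip_offset_um, rod_tip_offset_um)

  nfl_in  <- inner_surface_um
  gcl_in  <- nfl_in + nfl_um
  ipl_in  <- gcl_in + gcl_um
  inl_in  <- ipl_in + ipl_um
  opl_in  <- inl_in + inl_um
  onl_in  <- opl_in + opl_um
  elm_c   <- onl_in + onl_um
  elm_in  <- elm_c - elm_width_um / 2
  elm_out <- elm_c + elm_width_um / 2
  ise_in  <- elm_out + is_um
  ise_out <- ise_in + ise_width_um
  ise_c   <- (ise_in + ise_out) / 2
  cone_c  <- ise_c + cone_tip_offset_um
  rod_c   <- ise_c + rod_tip_offset_um
  cone_in <- cone_c - tip_width_um / 2; cone_out <- cone_c + tip_width_um / 2
  rod_in  <- rod_c - tip_width_um / 2;  rod_out  <- rod_c + tip_width_um / 2
  rpe_in  <- rod_out + subretinal_um
  rpe_out <- elm_c + elm_rpe_um

  inner <- c(0, nfl_in, gcl_in, ipl_in, inl_in, opl_in, onl_in, elm_in, elm_out,
             ise_in, ise_out, cone_in, cone_out, rod_in, rod_out, rpe_in,
             rpe_out)
  outer <- c(inner[-1L], choroid_outer_um)
  layers <- data.frame(name = LAYER_ORDER, inner_um = inner, outer_um = outer,
                       reflectance = as.numeric(reflectance[LAYER_ORDER]),
                       stringsAsFactors = FALSE)
  model <- structure(list(layers = layers,
                          curvature_um_mm2 = curvature_um_mm2,
                          elm_center_um = elm_c,
                          ise_center_um = ise_c,
                          cone_tip_center_um = cone_c,
                          rod_tip_center_um = rod_c,
                          cone_tip_offset_um = cone_tip_offset_um,
                          rod_tip_offset_um = rod_tip_offset_um,
                          rpe_basal_um = rpe_out,
                          inner_surface_um = inner_surface_um,
                          oplonl_um = onl_in,
                          params = params),
                     class = "retina_layer_model")
  validate_retina_model(model)
  model
}

validate_retina_model <- function(model) {
  ly <- model$layers
  if (!identical(ly$name, LAYER_ORDER))
    retorg_error("parameter", "layer names/order must be: %s",
                 paste(LAYER_ORDER, collapse = ", "))
  if (any(ly$outer_um <= ly$inner_um))
    retorg_error("parameter", "layer '%s' has non-positive extent",
                 ly$name[which(ly$outer_um <= ly$inner_um)[1L]])
  if (any(abs(ly$inner_um[-1L] - ly$outer_um[-nrow(ly)]) > 1e-9))
    retorg_error("parameter", "layers must be contiguous (outer == next inner)")
  if (any(ly$reflectance < 0))
    retorg_error("parameter", "reflectances must be non-negative")
  r <- function(nm) ly$reflectance[ly$name == nm]
  if (!(r("ONL") < r("ELM") && r("ONL") < r("ISe") && r("ONL") < r("RPE")))
    retorg_error("parameter",
                 "ONL reflectance must be strictly below ELM, ISe and RPE")
  invisible(model)
}

#' @export
print.retina_layer_model <- function(x, ...) {
  cat("Layered retina model:", nrow(x$layers), "layers,",
      sprintf("ELM %.2f um, basal RPE %.2f um, curvature %.0f um/mm^2\n",
              x$elm_center_um, x$rpe_basal_um, x$curvature_um_mm2))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Dark-adaptation kinetics parameters
#'
#' Time courses of the intrinsic OCT signal changes after lights off: the ISe
#' band reflectance declines, the ELM-RPE complex and (more slowly) the ONL
#' shorten, and the interdigitation-zone tip bands lose contrast. All changes
#' ramp from the light-adapted baseline at lights-off to their saturation
#' value at `t_sat_min` and are clamped beyond. The default shape is a linear
#' ramp; an exponential approach (time constant `t_sat_min / 3`, rescaled to
#' reach saturation exactly) is available.
#'
#' @param lights_off_s Time of lights-off within a high-speed recording, s.
#' @param t_sat_min Saturation time in minutes after lights-off.
#' @param ise_drop Fractional ISe reflectance drop at saturation, in `[0, 1]`.
#' @param elmrpe_shortening_um ELM-RPE complex shortening at saturation, um.
#' @param onl_shortening_um ONL shortening at saturation, um (default the
#'   total outer-retinal displacement 5.83 um minus the ELM-RPE share 4.07 um).
#' @param iz_contrast_loss Fractional loss of tip-band contrast above the
#'   outer-segment background at saturation, in `[0, 1]`.
#' @param shape `"linear_ramp"` or `"exponential"`.
#' @return A `kinetics_params` object.
#' @seealso [null_kinetics()] for the light-stable control scenario.
#' @export
kinetics_params <- function(lights_off_s = 30,
                            t_sat_min = 30,
                            ise_drop = 0.2,
                            elmrpe_shortening_um = 4.07,
                            onl_shortening_um = 5.83 - 4.07,
                            iz_contrast_loss = 0.6,
                            shape = c("linear_ramp", "exponential")) {
  shape <- match.arg(shape)
  if (ise_drop < 0 || ise_drop > 1 || iz_contrast_loss < 0 || iz_contrast_loss > 1)
    retorg_error("parameter", "fractional drops must lie in [0, 1]")
  if (elmrpe_shortening_um < 0 || onl_shortening_um < 0)
    retorg_error("parameter", "shortenings must be non-negative")
  if (t_sat_min <= 0) retorg_error("parameter", "t_sat_min must be positive")
  structure(list(lights_off_s = lights_off_s, t_sat_min = t_sat_min,
                 ise_drop = ise_drop,
                 elmrpe_shortening_um = elmrpe_shortening_um,
                 onl_shortening_um = onl_shortening_um,
                 iz_contrast_loss = iz_contrast_loss, shape = shape),
            class = "kinetics_params")
}

#' Light-stable null-control kinetics
#'
#' Kinetics with all drops and shortenings set to zero: the retina is
#' simulated as unchanged throughout, the control scenario against which the
#' dark-adaptation effects are tested.
#'
#' @param ... Overrides passed to [kinetics_params()].
#' @export
null_kinetics <- function(...) {
  kinetics_params(ise_drop = 0, elmrpe_shortening_um = 0,
                  onl_shortening_um = 0, iz_contrast_loss = 0, ...)
}

kinetics_ramp <- function(kin, t_min) {
  tc <- min(max(t_min, 0), kin$t_sat_min)
  if (kin$shape == "linear_ramp") tc / kin$t_sat_min
  else (1 - exp(-3 * tc / kin$t_sat_min)) / (1 - exp(-3))
}

#' Kinetics snapshot of the retina model
#'
#' Returns the retina model as it stands `t_min` minutes after lights-off:
#' the ISe reflectance and tip-band contrasts are reduced, the ELM (with the
#' ONL above it) has moved inward by the ONL shortening, and the layers from
#' the ELM to the basal RPE are compressed affinely so that the ELM-RPE
#' extent has shrunk by the ELM-RPE shortening. Inner retinal layers
#' (NFL..OPL) are unchanged at all times; `t_min < 0` (before lights-off)
#' returns the baseline model unchanged, and `t_min >= t_sat_min` is clamped
#' at saturation.
#'
#' @param model A [retina_layer_model()].
#' @param kin A [kinetics_params()].
#' @param t_min Minutes since lights-off.
#' @return A `retina_layer_model` snapshot.
#' @export
kinetics_at <- function(model, kin, t_min) {
  stopifnot(inherits(model, "retina_layer_model"),
            inherits(kin, "kinetics_params"))
  if (t_min <= 0) return(model)
  f <- kinetics_ramp(kin, t_min)
  if (f == 0) return(model)
  onl_s <- kin$onl_shortening_um * f
  er_s <- kin$elmrpe_shortening_um * f

  ly <- model$layers
  i_elm <- match("ELM", ly$name)
  a0 <- ly$outer_um[i_elm]                 # baseline ELM outer boundary
  rpe_b0 <- model$rpe_basal_um
  L0 <- rpe_b0 - a0
  if (er_s >= L0)
    retorg_error("parameter", "ELM-RPE shortening exceeds the complex extent")
  ratio <- (L0 - er_s) / L0
  a1 <- a0 - onl_s

  # ELM band translates inward; ONL outer boundary follows it.
  ly$inner_um[i_elm] <- ly$inner_um[i_elm] - onl_s
  ly$outer_um[i_elm] <- a1
  ly$outer_um[ly$name == "ONL"] <- ly$inner_um[i_elm]
  # Layers between ELM outer boundary and basal RPE compress affinely.
  mid <- match(c("IS", "ISe", "OS", "IZ_cone", "OS_distal", "IZ_rod",
                 "subretinal", "RPE"), ly$name)
  ly$inner_um[mid] <- a1 + (ly$inner_um[mid] - a0) * ratio
  ly$outer_um[mid] <- a1 + (ly$outer_um[mid] - a0) * ratio
  ly$inner_um[ly$name == "choroid"] <- ly$outer_um[ly$name == "RPE"]

  r0 <- model$layers$reflectance
  names(r0) <- model$layers$name
  os_bg <- r0[["OS"]]
  ly$reflectance[ly$name == "ISe"] <- r0[["ISe"]] * (1 - kin$ise_drop * f)
  for (nm in c("IZ_cone", "IZ_rod"))
    ly$reflectance[ly$name == nm] <-
      os_bg + (r0[[nm]] - os_bg) * (1 - kin$iz_contrast_loss * f)

  out <- model
  out$layers <- ly
  out$elm_center_um <- model$elm_center_um - onl_s
  ise_in <- ly$inner_um[ly$name == "ISe"]; ise_out <- ly$outer_um[ly$name == "ISe"]
  out$ise_center_um <- (ise_in + ise_out) / 2
  out$cone_tip_center_um <- mean(unlist(ly[ly$name == "IZ_cone",
                                           c("inner_um", "outer_um")]))
  out$rod_tip_center_um <- mean(unlist(ly[ly$name == "IZ_rod",
                                          c("inner_um", "outer_um")]))
  out$cone_tip_offset_um <- out$cone_tip_center_um - out$ise_center_um
  out$rod_tip_offset_um <- out$rod_tip_center_um - out$ise_center_um
  out$rpe_basal_um <- ly$outer_um[ly$name == "RPE"]
  validate_retina_model(out)
  out
}

#' Acquisition protocol
#'
#' Geometry, timing and noise settings of the simulated acquisition. The
#' defaults follow the in-vivo protocol this pipeline targets: OCT volumes of
#' 4 repeats x 600 B-scans x 600 A-lines over a 1.2 x 1.2 mm field, acquired
#' at 0, 5, ..., 30 minutes, and high-speed recordings of 4800 B-scans at
#' 16 frames per second (62.5 ms frame period) with lights-off at 30 s.
#'
#' @param n_alines A-lines per B-scan.
#' @param n_bscans B-scans per volume.
#' @param n_repeats Repeated B-scans per slow-scan position.
#' @param field_mm Lateral field of view, `c(fast, slow)` in mm.
#' @param axial_px Axial samples per A-line.
#' @param pitch_um Axial pixel pitch in um.
#' @param frame_rate_hz High-speed frame rate.
#' @param n_frames High-speed recording length in frames.
#' @param timestamps_min Volume acquisition timestamps in minutes since
#'   lights-off (the first entry is the light-adapted baseline).
#' @param lights_off_s Lights-off time within the high-speed recording, s.
#' @param speckle_looks Shape parameter of the unit-mean gamma speckle, equal
#'   to the number of incoherently averaged looks per stored frame. `Inf`
#'   renders noiseless data.
#' @param psf_fwhm_um Axial point-spread-function FWHM in um (default the
#'   810/100 nm source value, [axial_resolution()]).
#' @param seed Integer seed from which all rendering randomness derives.
#' @return An `acquisition_protocol` object.
#' @export
acquisition_protocol <- function(n_alines = 600, n_bscans = 600,
                                 n_repeats = 4, field_mm = c(1.2, 1.2),
                                 axial_px = 512, pitch_um = 1.25,
                                 frame_rate_hz = 16, n_frames = 4800,
                                 timestamps_min = seq(0, 30, by = 5),
                                 lights_off_s = 30,
                                 speckle_looks = 4,
                                 psf_fwhm_um = axial_resolution(810, 100),
                                 seed = 1L) {
  if (n_repeats < 1) retorg_error("parameter", "n_repeats must be >= 1")
  if (frame_rate_hz <= 0) retorg_error("parameter", "frame rate must be > 0")
  if (is.unsorted(timestamps_min, strictly = TRUE))
    retorg_error("parameter", "timestamps must be strictly increasing")
  if (pitch_um <= 0 || axial_px < 2)
    retorg_error("parameter", "invalid axial sampling")
  if (!is.finite(seed) || abs(seed) >= 2^31)
    retorg_error("parameter", "seed must be a 32-bit integer")
  structure(list(n_alines = as.integer(n_alines),
                 n_bscans = as.integer(n_bscans),
                 n_repeats = as.integer(n_repeats),
                 field_mm = rep_len(field_mm, 2L),
                 axial_px = as.integer(axial_px), pitch_um = pitch_um,
                 frame_rate_hz = frame_rate_hz,
                 n_frames = as.integer(n_frames),
                 timestamps_min = timestamps_min,
                 lights_off_s = lights_off_s,
                 speckle_looks = speckle_looks,
                 psf_fwhm_um = psf_fwhm_um,
                 seed = as.integer(seed)),
            class = "acquisition_protocol")
}

#' Ground-truth table for a phantom experiment
#'
#' Landmark depths, thicknesses and band reflectances of the kinetics
#' snapshot at each volume timestamp: the oracle against which pipeline
#' recovery is tested.
#'
#' @param model A [retina_layer_model()].
#' @param kin A [kinetics_params()].
#' @param timestamps_min Timestamps (minutes since lights-off).
#' @return A data.frame with one row per timestamp.
#' @export
ground_truth <- function(model, kin, timestamps_min = seq(0, 30, by = 5)) {
  rows <- lapply(timestamps_min, function(t) {
    s <- kinetics_at(model, kin, t)
    r <- s$layers$reflectance; names(r) <- s$layers$name
    data.frame(timestamp_min = t,
               inner_surface_um = s$inner_surface_um,
               oplonl_um = s$oplonl_um,
               elm_um = s$elm_center_um,
               ise_um = s$ise_center_um,
               cone_tip_um = s$cone_tip_center_um,
               rod_tip_um = s$rod_tip_center_um,
               rpe_basal_um = s$rpe_basal_um,
               inner_retina_um = s$oplonl_um - s$inner_surface_um,
               onl_um = s$elm_center_um - s$oplonl_um,
               elm_rpe_um = s$rpe_basal_um - s$elm_center_um,
               outer_retina_um = s$rpe_basal_um - s$oplonl_um,
               cone_offset_um = s$cone_tip_offset_um,
               rod_offset_um = s$rod_tip_offset_um,
               ise_reflectance = r[["ISe"]],
               ise_rel_intensity = r[["ISe"]] / r[["ONL"]])
  })
  do.call(rbind, rows)
}

#' Write the ground-truth sidecar
#'
#' @param model,kin,timestamps_min As for [ground_truth()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(model, kin, path,
                               timestamps_min = seq(0, 30, by = 5)) {
  gt <- ground_truth(model, kin, timestamps_min)
  jsonlite::write_json(list(truth = gt,
                            kinetics = unclass(kin),
                            curvature_um_mm2 = model$curvature_um_mm2),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
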
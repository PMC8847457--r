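# Thickness, relative-intensity, displacement and peak-distance measures.

#' Thickness measures from a boundary set
#'
#' * inner retina: inner surface to OPL/ONL boundary;
#' * outer retina: OPL/ONL boundary to basal RPE;
#' * ONL: OPL/ONL boundary to ELM;
#' * ELM-RPE complex: ELM to basal RPE.
#' Because the four measures share boundaries, ONL + ELM-RPE equals the
#' outer retina exactly.
#'
#' @param boundaries A [locate_boundaries()] result.
#' @param timestamp_min Optional timestamp carried through.
#' @return A `thickness_set`: one-row data.frame of thicknesses in um.
#' @export
thickness_metrics <- function(boundaries, timestamp_min = NA_real_) {
  stopifnot(inherits(boundaries, "boundary_set"))
  b <- unclass(boundaries)
  out <- data.frame(
    inner_retina_um = b[["oplonl"]] - b[["inner_surface"]],
    outer_retina_um = b[["rpe_basal"]] - b[["oplonl"]],
    onl_um = b[["elm"]] - b[["oplonl"]],
    elm_rpe_um = b[["rpe_basal"]] - b[["elm"]],
    timestamp_min = timestamp_min)
  if (any(out[1L, 1:4] <= 0))
    retorg_error("segmentation", "non-positive thickness measure")
  structure(out, class = c("thickness_set", "data.frame"))
}

#' Relative band intensities
#'
#' Sub-pixel-refined peak heights of the IPL, OPL, ISe and RPE bands on an
#' ONL-normalized profile (so a value of 4 means four times the ONL
#' reflectance). Band-mean quantification over a +/- `band_mean_um` window
#' is available as an alternative.
#'
#' @param profile ONL-normalized `depth_profile`.
#' @param bands A [locate_bands()] result.
#' @param stat `"peak"` (default) or `"band_mean"`.
#' @param band_mean_um Half-width of the band-mean window, um.
#' @param timestamp_min Optional timestamp carried through.
#' @return An `intensity_set`: one-row data.frame of normalized intensities.
#' @export
relative_intensities <- function(profile, bands, stat = c("peak", "band_mean"),
                                 band_mean_um = 2, timestamp_min = NA_real_) {
  stopifnot(inherits(bands, "band_set"))
  stat <- match.arg(stat)
  if (!identical(profile$normalized, "ONL-normalized"))
    retorg_error("parameter", "relative intensities need an ONL-normalized profile")
  need <- c("IPL", "OPL", "ISe", "RPE")
  val <- vapply(need, function(nm) {
    d <- band_depth(bands, nm)
    if (is.na(d))
      retorg_error("segmentation", "band '%s' missing from profile", nm)
    if (stat == "peak") bands$intensity[bands$band == nm]
    else {
      sel <- abs(profile$depth_um - d) <= band_mean_um
      mean(profile$intensity[sel])
    }
  }, numeric(1))
  structure(data.frame(ipl = val[["IPL"]], opl = val[["OPL"]],
                       ise = val[["ISe"]], rpe = val[["RPE"]],
                       timestamp_min = timestamp_min),
            class = c("intensity_set", "data.frame"))
}

#' ELM-RPE displacement series
#'
#' Per-timestamp ELM-RPE displacement relative to the light-adapted baseline
#' volume; negative values mean shortening (movement of the basal RPE toward
#' the ELM).
#'
#' @param thicknesses Data.frame with `timestamp_min` and `elm_rpe_um`
#'   columns (e.g. row-bound [thickness_metrics()] results).
#' @param baseline_min Baseline timestamp (default the protocol baseline, 0).
#' @return The input with a `displacement_um` column appended.
#' @export
displacement_series <- function(thicknesses, baseline_min = 0) {
  if (!all(c("timestamp_min", "elm_rpe_um") %in% names(thicknesses)))
    retorg_error("parameter",
                 "need columns timestamp_min and elm_rpe_um")
  i <- which(thicknesses$timestamp_min == baseline_min)
  if (length(i) != 1L)
    retorg_error("protocol", "baseline timestamp %g min missing", baseline_min)
  thicknesses$displacement_um <-
    thicknesses$elm_rpe_um - thicknesses$elm_rpe_um[i]
  thicknesses
}

#' Share of outer-retinal thinning carried by the ELM-RPE complex
#'
#' @param elm_rpe_displacement_um ELM-RPE displacement (um, negative =
#'   shortening).
#' @param total_outer_displacement_um Total outer-retinal displacement (um).
#' @return The percentage `100 * elm_rpe / total`.
#' @examples
#' shortening_fraction(-4.07, -5.83)  # ~69.8%
#' @export
shortening_fraction <- function(elm_rpe_displacement_um,
                                total_outer_displacement_um) {
  if (!is.numeric(total_outer_displacement_um) ||
      total_outer_displacement_um == 0)
    retorg_error("undefined_fraction",
                 "total outer displacement is zero; fraction undefined")
  100 * elm_rpe_displacement_um / total_outer_displacement_um
}

#' ISe-to-tip peak distances
#'
#' Peak-to-peak distances from the ISe band to the cone and rod
#' outer-segment tip peaks; an unresolved tip yields an `NA` distance.
#'
#' @param double_peak A [detect_double_peaks()] result.
#' @param bands A [locate_bands()] result with ISe located.
#' @return Named numeric: `cone_um`, `rod_um`.
#' @export
peak_distances <- function(double_peak, bands) {
  stopifnot(inherits(double_peak, "double_peak"), inherits(bands, "band_set"))
  ise <- band_depth(bands, "ISe")
  if (is.na(ise)) retorg_error("segmentation", "ISe band missing")
  c(cone_um = double_peak$cone_um - ise,
    rod_um = double_peak$rod_um - ise)
}

#' Full measurement of one representative profile
#'
#' Convenience wrapper: normalizes (if raw), segments bands and boundaries,
#' and returns thicknesses, relative intensities and tip distances as one
#' row.
#'
#' @param profile A `depth_profile` (raw or ONL-normalized).
#' @param ... Passed to [locate_bands()].
#' @return One-row data.frame.
#' @export
measure_profile <- function(profile, ...) {
  if (!identical(profile$normalized, "ONL-normalized"))
    profile <- normalize_onl(profile)
  bands <- locate_bands(profile, ...)
  bounds <- locate_boundaries(profile, bands)
  th <- thickness_metrics(bounds, timestamp_min = profile$timestamp_min)
  ints <- relative_intensities(profile, bands,
                               timestamp_min = profile$timestamp_min)
  dp <- detect_double_peaks(profile, bands)
  pd <- peak_distances(dp, bands)
  cbind(th[, setdiff(names(th), "timestamp_min")],
        data.frame(ipl_intensity = ints$ipl, opl_intensity = ints$opl,
                   ise_intensity = ints$ise, rpe_intensity = ints$rpe,
                   cone_distance_um = unname(pd["cone_um"]),
                   rod_distance_um = unname(pd["rod_um"]),
                   tips_resolved = dp$resolved,
                   timestamp_min = profile$timestamp_min))
}

#' Fast ELM-RPE thickness of one profile
#'
#' Reduced measurement for large replicate studies: smooths the profile,
#' anchors the outer retina (same rules as [locate_bands()]), refines the
#' ELM peak parabolically, and crosses the basal RPE flank at half
#' prominence. Equivalent to `locate_boundaries()$rpe_basal - $elm` without
#' the inner-retina segmentation.
#'
#' @param profile A `depth_profile` (raw intensities are fine: the measure
#'   is gain-invariant).
#' @return ELM-RPE thickness in um.
#' @export
measure_elm_rpe <- function(profile) {
  y <- smooth_gaussian(profile$intensity, sigma_samples(profile))
  z <- profile$depth_um
  dz <- profile$pitch_um
  anchor <- locate_outer_anchor(y, dz)
  elm <- refine_peak(y, anchor$elm, z)
  rpk <- anchor$rpe
  ch_i <- which(z > z[rpk] + 2 & z <= min(z[rpk] + 25, max(z)))
  if (!length(ch_i))
    retorg_error("segmentation", "no choroid window beyond the RPE peak")
  lvl <- (y[rpk] + min(y[ch_i])) / 2
  cr <- first_crossing(y, lvl, rpk, max(ch_i), rising = FALSE)
  if (is.na(cr))
    retorg_error("segmentation", "basal RPE flank crossing not found")
  (z[1L] + (cr - 1) * dz) - elm$depth
}
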
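# 1-D segmentation of a representative profile: hyper-reflective band peaks,
# the double outer-segment-tip peaks, and layer boundaries.

# Anatomical anchoring of the outer retina on a smoothed profile `y`
# (sample pitch `dz` um). Scale-free rules:
#   RPE = deepest prominent peak that is also at least half as high as the
#         tallest prominent peak (the choroid beyond it is a plateau, and
#         the fading tip bands are rejected by the height rule);
#   ISe = tallest prominent peak 25-60 um inner to the RPE peak;
#   ELM = most prominent peak 5-18 um inner to the ISe peak.
# Errors name the first band that cannot be anchored.
locate_outer_anchor <- function(y, dz) {
  peaks <- local_maxima(y)
  if (!length(peaks))
    retorg_error("segmentation", "no ELM candidate: profile has no local maxima")
  prom <- peak_prominence(y, peaks)
  cand <- peaks[prom >= 0.25 * max(prom)]
  if (!length(cand))
    retorg_error("segmentation", "no ELM candidate: no prominent peaks")
  hmax <- max(y[cand])
  rpe_cand <- cand[y[cand] >= 0.5 * hmax]
  if (!length(rpe_cand))
    retorg_error("segmentation", "RPE band not found")
  rpe <- max(rpe_cand)
  ise_win <- cand[(rpe - cand) * dz >= 25 & (rpe - cand) * dz <= 60]
  if (!length(ise_win))
    retorg_error("segmentation", "ISe band not found")
  ise <- ise_win[which.max(y[ise_win])]
  elm_win <- peaks[(ise - peaks) * dz >= 5 & (ise - peaks) * dz <= 18]
  if (!length(elm_win))
    retorg_error("segmentation", "ELM band not found")
  elm <- elm_win[which.max(peak_prominence(y, elm_win))]
  list(elm = elm, ise = ise, rpe = rpe)
}

refine_peak <- function(y, i, z) {
  pr <- parabolic_refine(y, i)
  list(depth = z[i] + pr$delta * (z[2L] - z[1L]), height = pr$height)
}

#' Locate hyper-reflective band peaks
#'
#' Segments an ONL-normalized depth profile into the named hyper-reflective
#' bands. The profile is smoothed with a Gaussian kernel, local maxima with
#' prominence of at least `prominence_frac` times the ISe candidate height
#' are retained, the outer retina is anchored on the RPE/ISe/ELM rules (see
#' source), and NFL, IPL, OPL are assigned in ELM-relative search windows.
#' All depths are refined to sub-pixel by parabolic interpolation. The ELM,
#' ISe and RPE bands are mandatory; a profile in which one of them cannot be
#' found raises a segmentation error naming the band. NFL/IPL/OPL may be
#' `NA` when no qualifying peak falls in their window.
#'
#' @param profile An ONL-normalized `depth_profile`.
#' @param sigma_px Smoothing sigma in original axial pixels (default 1).
#' @param prominence_frac Prominence threshold as a fraction of the ISe
#'   candidate height (default 0.1).
#' @param windows Named list of ELM-relative search windows (um, inner
#'   negative) for `nfl`, `ipl`, `opl`.
#' @return A `band_set`: data.frame of band, depth_um, intensity, with the
#'   discrete anchor indices in attributes.
#' @export
locate_bands <- function(profile, sigma_px = 1, prominence_frac = 0.1,
                         windows = list(nfl = c(-145, -120),
                                        ipl = c(-118, -90),
                                        opl = c(-80, -50))) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!identical(profile$normalized, "ONL-normalized"))
    retorg_error("parameter", "locate_bands() needs an ONL-normalized profile")
  y <- smooth_gaussian(profile$intensity, sigma_samples(profile, sigma_px))
  z <- profile$depth_um
  anchor <- locate_outer_anchor(y, profile$pitch_um)
  peaks <- local_maxima(y)
  prom <- peak_prominence(y, peaks)
  thresh <- prominence_frac * y[anchor$ise]
  keep <- peaks[prom >= thresh]

  elm <- refine_peak(y, anchor$elm, z)
  ise <- refine_peak(y, anchor$ise, z)
  rpe <- refine_peak(y, anchor$rpe, z)

  pick <- function(win) {
    rel <- (keep - anchor$elm) * profile$pitch_um
    inwin <- keep[rel >= win[1L] & rel <= win[2L]]
    if (!length(inwin)) return(list(depth = NA_real_, height = NA_real_))
    refine_peak(y, inwin[which.max(peak_prominence(y, inwin))], z)
  }
  nfl <- pick(windows$nfl); ipl <- pick(windows$ipl); opl <- pick(windows$opl)

  bands <- data.frame(
    band = c("NFL", "IPL", "OPL", "ELM", "ISe", "RPE"),
    depth_um = c(nfl$depth, ipl$depth, opl$depth, elm$depth, ise$depth,
                 rpe$depth),
    intensity = c(nfl$height, ipl$height, opl$height, elm$height, ise$height,
                  rpe$height),
    stringsAsFactors = FALSE)
  dd <- bands$depth_um[!is.na(bands$depth_um)]
  if (is.unsorted(dd, strictly = TRUE))
    retorg_error("segmentation", "band depth ordering violated")
  structure(bands, anchor = anchor, pitch_um = profile$pitch_um,
            smoothed = y, class = c("band_set", "data.frame"))
}

band_depth <- function(bands, name) {
  bands$depth_um[bands$band == name]
}

#' Detect the double outer-segment tip peaks
#'
#' Searches the open interval between the ISe and RPE band peaks (with a
#' guard band at both ends) for up to two local maxima: the interdigitation
#' zone splits into a moderate cone-tip peak and a deeper rod-tip peak. The
#' `resolved` flag is `TRUE` only when two maxima exceed the prominence
#' threshold; a single qualifying maximum is reported as the rod tip.
#' Absence of peaks is encoded, not an error.
#'
#' @param profile ONL-normalized `depth_profile`.
#' @param bands A [locate_bands()] result.
#' @param guard_um Guard band beyond ISe and before RPE (default 2 um).
#' @param prominence_min Minimum prominence in ONL-normalized units.
#' @param sigma_px Smoothing sigma in original pixels.
#' @return A `double_peak`: list with `cone_um`, `rod_um`, prominences and
#'   the `resolved` flag.
#' @export
detect_double_peaks <- function(profile, bands, guard_um = 2,
                                prominence_min = 0.2, sigma_px = 1) {
  stopifnot(inherits(bands, "band_set"))
  y <- attr(bands, "smoothed") %||%
    smooth_gaussian(profile$intensity, sigma_samples(profile, sigma_px))
  z <- profile$depth_um
  ise_z <- band_depth(bands, "ISe"); rpe_z <- band_depth(bands, "RPE")
  if (is.na(ise_z) || is.na(rpe_z))
    retorg_error("segmentation", "double-peak search needs ISe and RPE bands")
  peaks <- local_maxima(y)
  inwin <- peaks[z[peaks] > ise_z + guard_um & z[peaks] < rpe_z - guard_um]
  res <- list(cone_um = NA_real_, rod_um = NA_real_,
              cone_prominence = NA_real_, rod_prominence = NA_real_,
              cone_intensity = NA_real_, rod_intensity = NA_real_,
              resolved = FALSE)
  if (length(inwin)) {
    prom <- peak_prominence(y, inwin)
    ok <- inwin[prom >= prominence_min]
    okp <- prom[prom >= prominence_min]
    if (length(ok) > 2L) {
      top <- order(okp, decreasing = TRUE)[1:2]
      ok <- ok[top]; okp <- okp[top]
    }
    o <- order(ok)
    ok <- ok[o]; okp <- okp[o]
    if (length(ok) == 2L) {
      cone <- refine_peak(y, ok[1L], z); rod <- refine_peak(y, ok[2L], z)
      res <- list(cone_um = cone$depth, rod_um = rod$depth,
                  cone_prominence = okp[1L], rod_prominence = okp[2L],
                  cone_intensity = cone$height, rod_intensity = rod$height,
                  resolved = TRUE)
    } else if (length(ok) == 1L) {
      rod <- refine_peak(y, ok, z)
      res$rod_um <- rod$depth
      res$rod_prominence <- okp
      res$rod_intensity <- rod$height
    }
  }
  if (res$resolved && !(res$cone_um < res$rod_um &&
                        res$cone_um > ise_z && res$rod_um < rpe_z))
    retorg_error("segmentation", "tip peak ordering violated")
  structure(res, class = "double_peak")
}

#' Locate layer boundaries
#'
#' Sub-pixel boundary operators shared by all thickness measures:
#' * inner retinal surface: first depth where the smoothed profile rises
#'   above 50% of the NFL peak height;
#' * OPL/ONL boundary: half-prominence crossing on the outer flank of the
#'   OPL peak (midway between the OPL peak and the ONL plateau level);
#' * ELM: the ELM band peak;
#' * basal RPE: half-prominence crossing on the outer flank of the RPE peak
#'   (midway between the RPE peak and the choroidal plateau level).
#' The half-prominence (rather than absolute half-maximum) criterion places
#' the crossing at the true reflectance step under symmetric PSF blur and is
#' invariant to global gain.
#'
#' @param profile ONL-normalized `depth_profile`.
#' @param bands A [locate_bands()] result with NFL and OPL present.
#' @return A `boundary_set`: named numeric vector (um) with elements
#'   `inner_surface`, `oplonl`, `elm`, `rpe_basal`, strictly increasing.
#' @export
locate_boundaries <- function(profile, bands) {
  stopifnot(inherits(bands, "band_set"))
  y <- attr(bands, "smoothed")
  z <- profile$depth_um
  dz <- profile$pitch_um
  ix <- function(depth) which.min(abs(z - depth))

  nfl_z <- band_depth(bands, "NFL"); opl_z <- band_depth(bands, "OPL")
  elm_z <- band_depth(bands, "ELM"); rpe_z <- band_depth(bands, "RPE")
  if (is.na(nfl_z) || is.na(opl_z))
    retorg_error("segmentation",
                 "boundary extraction needs the NFL and OPL bands")
  h <- function(name) bands$intensity[bands$band == name]

  cross_inner <- first_crossing(y, 0.5 * h("NFL"), 1L, ix(nfl_z), rising = TRUE)
  if (is.na(cross_inner))
    retorg_error("segmentation", "inner surface crossing not found")

  onl_i <- which(z > opl_z & z < elm_z - 5)
  onl_level <- min(y[onl_i])
  lvl <- (h("OPL") + onl_level) / 2
  cross_opl <- first_crossing(y, lvl, ix(opl_z), max(onl_i), rising = FALSE)
  if (is.na(cross_opl))
    retorg_error("segmentation", "OPL/ONL flank crossing not found")

  ch_i <- which(z > rpe_z + 2 & z <= min(rpe_z + 25, max(z)))
  if (!length(ch_i))
    retorg_error("segmentation", "no choroid window beyond the RPE peak")
  ch_level <- min(y[ch_i])
  lvl_r <- (h("RPE") + ch_level) / 2
  cross_rpe <- first_crossing(y, lvl_r, ix(rpe_z), max(ch_i), rising = FALSE)
  if (is.na(cross_rpe))
    retorg_error("segmentation", "basal RPE flank crossing not found")

  b <- c(inner_surface = z[1L] + (cross_inner - 1) * dz,
         oplonl = z[1L] + (cross_opl - 1) * dz,
         elm = elm_z,
         rpe_basal = z[1L] + (cross_rpe - 1) * dz)
  if (is.unsorted(b, strictly = TRUE))
    retorg_error("segmentation", "boundaries not strictly increasing")
  structure(b, class = "boundary_set")
}
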
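# Flattening by ELM realignment and reduction of a volume to one
# representative, upsampled depth profile.

upsample_profile <- function(y, factor = 4L) {
  n <- length(y)
  xout <- 1 + (seq_len(n * factor) - 1L) / factor
  stats::approx(seq_len(n), y, xout = xout, rule = 2L)$y
}

new_depth_profile <- function(intensity, pitch_um, pixel_pitch_um,
                              timestamp_min = NA_real_,
                              n_contributing = NA_real_,
                              normalized = "raw") {
  structure(list(intensity = as.numeric(intensity),
                 depth_um = (seq_along(intensity) - 1L) * pitch_um,
                 pitch_um = pitch_um, pixel_pitch_um = pixel_pitch_um,
                 timestamp_min = timestamp_min,
                 n_contributing = n_contributing,
                 normalized = normalized),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile: %d samples @ %.4g um (%s%s)\n",
              length(x$intensity), x$pitch_um, x$normalized,
              if (is.na(x$timestamp_min)) "" else
                sprintf(", t = %g min", x$timestamp_min)))
  invisible(x)
}

# Smoothing sigma in profile samples corresponding to one original pixel.
sigma_samples <- function(profile, sigma_px = 1) {
  sigma_px * profile$pixel_pitch_um / profile$pitch_um
}

#' Detect the ELM peak across a B-scan
#'
#' Per-A-line sub-pixel localisation of the external limiting membrane, the
#' flattening anchor. A coarse per-A-line axial shift is first estimated by
#' cross-correlation against the central A-line; the shift-aligned average
#' A-line is segmented (see the outer-retina anchoring rules in
#' [locate_bands()]) to locate the ELM and extract an outer-retina template
#' around it; each A-line is then matched against the template by normalized
#' cross-correlation with parabolic sub-pixel refinement of the correlation
#' maximum. A lateral running-median filter rejects outlier positions.
#'
#' @param bscan Matrix `[aline, depth]` of linear intensities.
#' @param pitch_um Axial pixel pitch, um.
#' @param median_window Lateral median filter window (A-lines).
#' @param max_jump_px Outlier bound: positions deviating from the lateral
#'   median by more than this many pixels are replaced by it.
#' @param min_confidence,min_fraction Detection fails when fewer than
#'   `min_fraction` of A-lines reach `min_confidence` correlation.
#' @param max_lag_px Coarse alignment search half-range, pixels.
#' @return An `elm_trace`: list with `position_px` (1-based, sub-pixel) and
#'   `confidence` in `[0, 1]` per A-line.
#' @export
detect_elm <- function(bscan, pitch_um = 1.25, median_window = 15,
                       max_jump_px = 4, min_confidence = 0.5,
                       min_fraction = 0.5, max_lag_px = NULL) {
  if (!is.matrix(bscan) || nrow(bscan) < 1L || ncol(bscan) < 8L)
    retorg_error("parameter", "bscan must be an [aline, depth] matrix")
  na <- nrow(bscan); nz <- ncol(bscan)
  max_lag_px <- max_lag_px %||% max(8L, min(nz %/% 4L, ceiling(60 / pitch_um)))
  sm <- t(smooth_gaussian(t(bscan), sigma = 1))

  ref <- sm[ceiling(na / 2), ]
  refc <- ref - mean(ref)
  lags <- (-max_lag_px):max_lag_px
  # coarse shift per A-line: argmax_l sum_z sm[a, z] * ref[z - l]
  scores <- matrix(-Inf, na, length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]
    zi <- max(1L, 1L + l):min(nz, nz + l)   # indices into A-line
    zr <- zi - l                            # indices into reference
    seg <- sm[, zi, drop = FALSE]
    scores[, k] <- as.numeric(seg %*% refc[zr])
  }
  rough <- lags[max.col(scores, ties.method = "first")]

  # rough-shift-aligned B-scan, its average A-line, and the ELM anchor
  A <- matrix(0, na, nz)
  cnt <- numeric(nz)
  for (a in seq_len(na)) {
    zi <- max(1L, 1L + rough[a]):min(nz, nz + rough[a])
    A[a, zi - rough[a]] <- sm[a, zi]
    cnt[zi - rough[a]] <- cnt[zi - rough[a]] + 1
  }
  avg <- colSums(A) / pmax(cnt, 1)
  anchor <- tryCatch(locate_outer_anchor(avg, pitch_um),
                     retorg_error = function(e)
                       retorg_error("detection", "ELM detection failed: %s",
                                    conditionMessage(e)))
  elm0 <- anchor$elm
  t_in <- round(10 / pitch_um); t_out <- round(15 / pitch_um)
  ti <- max(1L, elm0 - t_in):min(nz, elm0 + t_out)
  template <- avg[ti]
  tc <- template - mean(template)
  tnorm <- sqrt(sum(tc^2))
  tl <- length(template)

  # NCC of the template against every aligned A-line over a lag window
  w <- max(3L, round(8 / pitch_um))
  ncc_lags <- (-w):w
  cols0 <- ti
  ncc <- matrix(-1, na, length(ncc_lags))
  for (j in seq_along(ncc_lags)) {
    cc <- cols0 + ncc_lags[j]
    if (cc[1L] < 1L || cc[tl] > nz) next
    S <- A[, cc, drop = FALSE]
    cross <- as.numeric(S %*% tc)          # sum(tc) == 0: already centred
    ss <- rowSums(S * S) - tl * rowMeans(S)^2
    den <- sqrt(pmax(ss, 0)) * tnorm
    ncc[, j] <- ifelse(den > 0, cross / den, 0)
  }
  best <- max.col(ncc, ties.method = "first")
  pos <- numeric(na); conf <- numeric(na)
  for (a in seq_len(na)) {
    pr <- parabolic_refine(ncc[a, ], best[a])
    pos[a] <- elm0 + ncc_lags[best[a]] + pr$delta + rough[a]
    conf[a] <- max(0, min(1, ncc[a, best[a]]))
  }

  if (na >= 3L) {
    k <- min(median_window, if (na %% 2L == 0L) na - 1L else na)
    if (k %% 2L == 0L) k <- k - 1L
    med <- stats::runmed(pos, k)
    out <- abs(pos - med) > max_jump_px
    pos[out] <- med[out]
    conf[out] <- 0
    # lateral median smoothing: the ELM is laterally smooth, so the filtered
    # trace is the estimate (it also bounds adjacent-A-line jumps)
    pos <- stats::runmed(pos, k)
  }
  if (mean(conf >= min_confidence) < min_fraction)
    retorg_error("detection",
                 "ELM detection failed: only %.0f%% of A-lines reached confidence %.2f",
                 100 * mean(conf >= min_confidence), min_confidence)
  structure(list(position_px = pos, confidence = conf, pitch_um = pitch_um),
            class = "elm_trace")
}

#' Flatten a B-scan on its ELM trace
#'
#' Shifts every A-line axially (sub-pixel, linear interpolation) so that its
#' ELM position lands on a common reference depth; samples shifted in from
#' outside the axial window are zero-padded and flagged in the `"mask"`
#' attribute.
#'
#' @param bscan Matrix `[aline, depth]`.
#' @param trace An `elm_trace` from [detect_elm()] on the same B-scan.
#' @param reference_px Common ELM depth after flattening (pixels, 1-based);
#'   default the median trace position.
#' @return The flattened matrix with attributes `reference_px` and `mask`.
#' @export
flatten <- function(bscan, trace, reference_px = NULL) {
  stopifnot(is.matrix(bscan), inherits(trace, "elm_trace"))
  na <- nrow(bscan); nz <- ncol(bscan)
  if (length(trace$position_px) != na)
    retorg_error("parameter", "trace length %d does not match %d A-lines",
                 length(trace$position_px), na)
  ref <- reference_px %||% stats::median(trace$position_px)
  if (ref < 1 || ref > nz)
    retorg_error("parameter", "reference depth %.1f px outside window [1, %d]",
                 ref, nz)
  out <- matrix(0, na, nz)
  mask <- matrix(FALSE, na, nz)
  z <- seq_len(nz)
  for (a in seq_len(na)) {
    shift <- trace$position_px[a] - ref    # >0: A-line sits deeper than ref
    src <- z + shift
    ok <- src >= 1 & src <= nz
    i0 <- pmin.int(floor(src[ok]), nz - 1L)
    fr <- src[ok] - i0
    row <- bscan[a, ]
    out[a, ok] <- (1 - fr) * row[i0] + fr * row[i0 + 1L]
    mask[a, ] <- !ok
  }
  attr(out, "reference_px") <- ref
  attr(out, "mask") <- mask
  out
}

#' Representative depth profile of a volume
#'
#' Reduces an OCT volume to a single representative A-line: the repeated
#' B-scans at each slow-scan position are averaged, every averaged B-scan is
#' flattened on its ELM trace to a volume-wide common reference, the central
#' `n_bscans_avg` B-scans are averaged, the central `n_alines_avg` A-lines of
#' that mean B-scan are averaged, and the result is upsampled by linear
#' interpolation. The central region defaults to the geometric centre and can
#' be offset to emulate landmark-based selection.
#'
#' @param volume An [oct_volume()].
#' @param n_bscans_avg,n_alines_avg Number of central B-scans / A-lines
#'   averaged (defaults 150 and 200).
#' @param offset_bscan,offset_aline Centre offsets in B-scan / A-line indices.
#' @param upsample Upsampling factor (default 4).
#' @param reference_px Common flattening reference; default the median over
#'   all per-B-scan ELM trace medians.
#' @return A `depth_profile` of length `upsample * axial_px` with the number
#'   of contributing raw A-scans in `$n_contributing`.
#' @export
representative_profile <- function(volume, n_bscans_avg = 150,
                                   n_alines_avg = 200, offset_bscan = 0,
                                   offset_aline = 0, upsample = 4L,
                                   reference_px = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$data)
  if (d[2L] < n_bscans_avg || d[3L] < n_alines_avg)
    retorg_error("protocol",
                 "volume has %d B-scans x %d A-lines; need >= %d x %d",
                 d[2L], d[3L], n_bscans_avg, n_alines_avg)
  avg <- colMeans(volume$data)             # [bscan, aline, depth]

  b0 <- floor((d[2L] - n_bscans_avg) / 2) + offset_bscan
  bsel <- b0 + seq_len(n_bscans_avg)
  if (bsel[1L] < 1L || bsel[length(bsel)] > d[2L])
    retorg_error("protocol", "central B-scan window out of range")
  traces <- lapply(bsel, function(b)
    detect_elm(avg[b, , ], pitch_um = volume$pitch_um))
  ref <- reference_px %||%
    stats::median(vapply(traces, function(tr)
      stats::median(tr$position_px), numeric(1)))

  acc <- matrix(0, d[3L], d[4L])
  for (i in seq_along(bsel))
    acc <- acc + flatten(avg[bsel[i], , ], traces[[i]], reference_px = ref)
  acc <- acc / n_bscans_avg

  a0 <- floor((d[3L] - n_alines_avg) / 2) + offset_aline
  asel <- a0 + seq_len(n_alines_avg)
  if (asel[1L] < 1L || asel[length(asel)] > d[3L])
    retorg_error("protocol", "central A-line window out of range")
  prof <- colMeans(acc[asel, , drop = FALSE])
  up <- upsample_profile(prof, upsample)
  new_depth_profile(up, pitch_um = volume$pitch_um / upsample,
                    pixel_pitch_um = volume$pitch_um,
                    timestamp_min = volume$timestamp_min,
                    n_contributing = d[1L] * n_bscans_avg * n_alines_avg)
}

# Rough ONL span (inner, outer depths in um) from the profile itself: the
# hypo-reflective plateau between the OPL outer flank and the ELM band.
estimate_onl_span <- function(profile) {
  y <- smooth_gaussian(profile$intensity, sigma_samples(profile))
  z <- profile$depth_um
  anchor <- locate_outer_anchor(y, profile$pitch_um)
  elm_z <- z[anchor$elm]
  win <- which(z >= elm_z - 80 & z <= elm_z - 50)
  fallback <- c(elm_z - 45, elm_z - 8)
  if (!length(win)) return(fallback)
  pk <- win[which.max(y[win])]
  onl_i <- which(z > z[pk] & z < elm_z - 8)
  if (!length(onl_i)) return(fallback)
  onl_level <- min(y[onl_i])
  level <- (y[pk] + onl_level) / 2
  cross <- first_crossing(y, level, pk, max(onl_i), rising = FALSE)
  if (is.na(cross)) return(fallback)
  c(z[1L] + (cross - 1) * profile$pitch_um + 2, elm_z - 4)
}

#' Normalize a depth profile on its ONL intensity
#'
#' Divides the profile by the mean intensity over the central 50% of the
#' outer-nuclear-layer span, so that hyper-reflective band heights are
#' expressed relative to the ONL (which then has mean 1). The span is
#' estimated from the profile itself when not supplied.
#'
#' @param profile A `depth_profile`.
#' @param onl_span_um Optional `c(inner, outer)` ONL span in um.
#' @param stat `"mean"` (default) or `"min"`: the ONL statistic used as the
#'   normalizer.
#' @return The normalized `depth_profile`.
#' @export
normalize_onl <- function(profile, onl_span_um = NULL,
                          stat = c("mean", "min")) {
  stopifnot(inherits(profile, "depth_profile"))
  stat <- match.arg(stat)
  span <- onl_span_um %||% estimate_onl_span(profile)
  if (length(span) != 2L || span[1L] >= span[2L] ||
      span[1L] < min(profile$depth_um) || span[2L] > max(profile$depth_um))
    retorg_error("parameter", "invalid ONL span [%.1f, %.1f] um",
                 span[1L], span[2L])
  mid <- mean(span); half <- (span[2L] - span[1L]) / 4
  sel <- profile$depth_um >= mid - half & profile$depth_um <= mid + half
  m <- if (stat == "mean") mean(profile$intensity[sel]) else
    min(profile$intensity[sel])
  if (!is.finite(m) || m <= 0)
    retorg_error("normalization", "non-positive ONL intensity (%.3g)", m)
  out <- profile
  out$intensity <- profile$intensity / m
  out$normalized <- "ONL-normalized"
  out$onl_span_um <- span
  out
}
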
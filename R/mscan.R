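# Spatiotemporal M-scan: depth x time map of the ELM-aligned outer retina
# during the light-dark transition, and the kinetics extracted from it.

#' Build an M-scan from a high-speed recording
#'
#' Blocks of `block` consecutive frames are averaged (a trailing partial
#' block is dropped with a warning), each averaged frame is flattened on its
#' ELM trace to a recording-wide common reference, the central
#' `n_alines_avg` A-lines are averaged into one column, columns are
#' upsampled by linear interpolation, ONL-normalized, and finally re-aligned
#' so every column's ELM peak sits on the common reference row. With the
#' default 16-frame blocks at 16 fps each column represents one second.
#'
#' @param recording A [highspeed_recording()].
#' @param block Frames averaged per column (default 16).
#' @param n_alines_avg Central A-lines averaged per column.
#' @param upsample Upsampling factor (default 4).
#' @param normalize ONL-normalize the columns (default TRUE).
#' @return An `mscan`: matrix `[depth (upsampled), column]` with attributes
#'   `col_period_s`, `lights_off_col` (number of pre-lights-off columns),
#'   `pitch_um`, `elm_row_um`.
#' @export
build_mscan <- function(recording, block = 16L, n_alines_avg = 200L,
                        upsample = 4L, normalize = TRUE) {
  stopifnot(inherits(recording, "highspeed_recording"))
  d <- dim(recording$data)
  if (d[1L] < block)
    retorg_error("protocol", "recording has %d frames; need >= block = %d",
                 d[1L], block)
  n_alines_avg <- min(n_alines_avg, d[2L])
  ncols <- d[1L] %/% block
  dropped <- d[1L] - ncols * block
  if (dropped > 0)
    retorg_warn("partial_block",
                "dropping trailing partial block of %d frame(s)", dropped)
  pitch <- recording$pitch_um

  avg_frames <- vector("list", ncols)
  traces <- vector("list", ncols)
  for (k in seq_len(ncols)) {
    idx <- ((k - 1L) * block + 1L):(k * block)
    fr <- colMeans(recording$data[idx, , , drop = FALSE])   # [aline, depth]
    avg_frames[[k]] <- fr
    traces[[k]] <- detect_elm(fr, pitch_um = pitch)
  }
  ref <- stats::median(vapply(traces, function(tr)
    stats::median(tr$position_px), numeric(1)))

  a0 <- floor((d[2L] - n_alines_avg) / 2)
  asel <- a0 + seq_len(n_alines_avg)
  nz_up <- d[3L] * upsample
  m <- matrix(0, nz_up, ncols)
  for (k in seq_len(ncols)) {
    fl <- flatten(avg_frames[[k]], traces[[k]], reference_px = ref)
    m[, k] <- upsample_profile(colMeans(fl[asel, , drop = FALSE]), upsample)
  }
  up_pitch <- pitch / upsample
  z <- (seq_len(nz_up) - 1L) * up_pitch
  ref_um <- (ref - 1) * pitch

  col_period <- block / recording$frame_rate_hz
  loff_col <- as.integer(round(recording$lights_off_s / col_period))

  if (normalize) {
    pre <- seq_len(max(1L, min(loff_col, ncols)))
    mean_pre <- new_depth_profile(rowMeans(m[, pre, drop = FALSE]),
                                  pitch_um = up_pitch, pixel_pitch_um = pitch)
    span <- estimate_onl_span(mean_pre)
    mid <- mean(span); half <- (span[2L] - span[1L]) / 4
    sel <- z >= mid - half & z <= mid + half
    for (k in seq_len(ncols)) {
      mk <- mean(m[sel, k])
      if (mk <= 0) retorg_error("normalization",
                                "non-positive ONL mean in column %d", k)
      m[, k] <- m[, k] / mk
    }
  }

  # Final sub-pixel ELM alignment of every column to the reference row by
  # normalized cross-correlation against the ELM band of the mean
  # pre-lights-off column (matched filter: unbiased for a translating band,
  # where a parabolic fit of the linearly-upsampled peak is not).
  pre <- seq_len(max(1L, min(loff_col, ncols)))
  pre_mean <- rowMeans(m[, pre, drop = FALSE])
  tpl_rows <- which(z >= ref_um - 6 & z <= ref_um + 4)
  tplc <- pre_mean[tpl_rows] - mean(pre_mean[tpl_rows])
  tnorm <- sqrt(sum(tplc^2))
  lag_max <- max(2L, round(3 / up_pitch))
  lags <- (-lag_max):lag_max
  for (k in seq_len(ncols)) {
    ncc <- vapply(lags, function(l) {
      rr <- tpl_rows + l
      if (rr[1L] < 1L || rr[length(rr)] > nz_up) return(-1)
      seg <- m[rr, k]
      segc <- seg - mean(seg)
      den <- sqrt(sum(segc^2)) * tnorm
      if (den <= 0) return(0)
      sum(segc * tplc) / den
    }, numeric(1))
    b <- which.max(ncc)
    # integer-sample shift on the upsampled grid: a pure index shift has no
    # interpolation attenuation, so band heights stay comparable between
    # columns; the sub-sample residual is recovered by the per-column ELM
    # match in transition_kinetics()
    l <- lags[b]
    if (l > 0L) m[, k] <- c(m[-seq_len(l), k], rep(0, l))
    else if (l < 0L) m[, k] <- c(rep(0, -l), m[seq_len(nz_up + l), k])
  }

  structure(m, col_period_s = col_period, lights_off_col = loff_col,
            pitch_um = up_pitch, elm_row_um = ref_um,
            normalized = normalize, class = "mscan")
}

#' @export
print.mscan <- function(x, ...) {
  cat(sprintf("M-scan: %d depth samples x %d columns (%g s/column, lights off after column %d)\n",
              nrow(x), ncol(x), attr(x, "col_period_s"),
              attr(x, "lights_off_col")))
  invisible(x)
}

mscan_profile <- function(mscan, cols) {
  new_depth_profile(rowMeans(unclass(mscan)[, cols, drop = FALSE]),
                    pitch_um = attr(mscan, "pitch_um"),
                    pixel_pitch_um = attr(mscan, "pitch_um") * 4,
                    normalized = if (isTRUE(attr(mscan, "normalized")))
                      "ONL-normalized" else "raw")
}

#' Transition kinetics from an M-scan
#'
#' Tracks the ISe peak intensity and the ELM-to-basal-RPE distance in every
#' column (band positions re-located per column within windows seeded by the
#' baseline band set), expresses the distance as displacement against the
#' mean over the pre-lights-off columns, and quantifies the post-lights-off
#' trends: least-squares linear fits against time and the three Pearson
#' correlations (time vs ISe intensity, time vs displacement, ISe intensity
#' vs displacement).
#'
#' @param mscan An [build_mscan()] result (normalized).
#' @param baseline_bands Optional [locate_bands()] result for the mean
#'   pre-lights-off column; computed when `NULL`.
#' @param max_lost Error when bands are lost in more than this fraction of
#'   columns (default 0.2).
#' @return A `transition_kinetics` list: per-column series, fits and
#'   correlations.
#' @export
transition_kinetics <- function(mscan, baseline_bands = NULL,
                                max_lost = 0.2) {
  stopifnot(inherits(mscan, "mscan"))
  m <- unclass(mscan)
  ncols <- ncol(m)
  loff <- attr(mscan, "lights_off_col")
  if (ncols - loff < 2L)
    retorg_error("protocol", "need at least 2 post-lights-off columns")
  z <- (seq_len(nrow(m)) - 1L) * attr(mscan, "pitch_um")
  pre <- seq_len(max(1L, min(loff, ncols)))
  base_prof <- mscan_profile(mscan, pre)
  bands <- baseline_bands %||% locate_bands(base_prof)
  ise0 <- band_depth(bands, "ISe"); rpe0 <- band_depth(bands, "RPE")
  elm_um <- attr(mscan, "elm_row_um")
  sig <- sigma_samples(base_prof)
  up_pitch <- attr(mscan, "pitch_um")

  # ELM matched filter: the pre-lights-off mean column around the reference
  # row, with the template's own ELM peak as the position origin
  tpl_rows <- which(z >= elm_um - 6 & z <= elm_um + 4)
  # detrend: the ELM band sits on a ramp (hypo ONL inner, brighter inner
  # segment outer); removing the best-fit line leaves a near-symmetric bump
  # whose matched position is insensitive to residual motion blur
  detrend <- function(v) stats::lm.fit(cbind(1, seq_along(v)), v)$residuals
  tplc <- detrend(base_prof$intensity[tpl_rows])
  tnorm <- sqrt(sum(tplc^2))
  ys0 <- smooth_gaussian(base_prof$intensity, sig)
  ewin <- which(abs(z - elm_um) <= 3)
  epk <- ewin[which.max(ys0[ewin])]
  elm_tpl_um <- refine_peak(ys0, epk, z)$depth
  elm_lags <- -(max(2L, round(2 / up_pitch))):max(2L, round(2 / up_pitch))
  match_elm <- function(col) {
    ncc <- vapply(elm_lags, function(l) {
      rr <- tpl_rows + l
      if (rr[1L] < 1L || rr[length(rr)] > length(col)) return(-1)
      segc <- detrend(col[rr])
      den <- sqrt(sum(segc^2)) * tnorm
      if (den <= 0) return(0)
      sum(segc * tplc) / den
    }, numeric(1))
    b <- which.max(ncc)
    if (ncc[b] <= 0) return(NA_real_)
    pr <- parabolic_refine(ncc, b)
    elm_tpl_um + (elm_lags[b] + pr$delta) * up_pitch
  }

  # The ELM is re-measured per column (even though columns are already
  # aligned): taking both ends of the ELM-RPE span from the same column
  # frame cancels residual alignment and resampling errors in the distance.
  ise_int <- rep(NA_real_, ncols)
  rpe_basal <- rep(NA_real_, ncols)
  elm_pos <- rep(NA_real_, ncols)
  # ISe tracked as the mean over a window spanning the ELM-ISe band complex,
  # with the window edges on the flat ONL and outer-segment plateaus: band
  # mass is conserved under residual within-column motion blur and the
  # edge values nearly cancel under residual axial shifts, so the series is
  # blur- and shift-invariant where the bare peak height is not. Only the
  # ISe reflectance changes during dark adaptation, so the series tracks it.
  elm0 <- band_depth(bands, "ELM")
  iwin <- which(z >= elm0 - 6 & z <= ise0 + 8)
  for (k in seq_len(ncols)) {
    y <- smooth_gaussian(m[, k], sig)
    ise_int[k] <- mean(m[iwin, k])
    elm_pos[k] <- match_elm(m[, k])
    rwin <- which(abs(z - rpe0) <= 5)
    rpk <- rwin[which.max(y[rwin])]
    ch_i <- which(z > z[rpk] + 2 & z <= min(z[rpk] + 25, max(z)))
    if (length(ch_i)) {
      lvl <- (y[rpk] + min(y[ch_i])) / 2
      cr <- first_crossing(y, lvl, rpk, max(ch_i), rising = FALSE)
      if (!is.na(cr)) rpe_basal[k] <- z[1L] + (cr - 1) * attr(mscan, "pitch_um")
    }
  }
  lost <- mean(is.na(ise_int) | is.na(rpe_basal) | is.na(elm_pos))
  if (lost > max_lost)
    retorg_error("kinetics", "bands lost in %.0f%% of columns (> %.0f%%)",
                 100 * lost, 100 * max_lost)

  dist <- rpe_basal - elm_pos
  disp <- dist - mean(dist[pre], na.rm = TRUE)
  period <- attr(mscan, "col_period_s")
  t_s <- (seq_len(ncols) - 0.5) * period - loff * period  # s since lights-off
  post <- which(seq_len(ncols) > loff & !is.na(disp) & !is.na(ise_int))

  fit_ise <- stats::lm(ise_int[post] ~ t_s[post])
  fit_disp <- stats::lm(disp[post] ~ t_s[post])
  structure(list(
    time_s = t_s, ise_intensity = ise_int, elm_rpe_um = dist,
    elm_um = elm_pos, rpe_basal_um = rpe_basal,
    displacement_um = disp, lights_off_col = loff,
    slope_ise_per_s = unname(coef(fit_ise)[2L]),
    intercept_ise = unname(coef(fit_ise)[1L]),
    slope_disp_um_per_s = unname(coef(fit_disp)[2L]),
    intercept_disp = unname(coef(fit_disp)[1L]),
    r_time_ise = pearson_cor(t_s[post], ise_int[post])$r,
    r_time_disp = pearson_cor(t_s[post], disp[post])$r,
    r_ise_disp = pearson_cor(ise_int[post], disp[post])$r),
    class = "transition_kinetics")
}

#' Average several M-scans
#'
#' Element-wise mean after shifting every M-scan's columns so all ELM
#' reference rows coincide with the first M-scan's. Grids (size, column
#' period, lights-off column) must match.
#'
#' @param mscans List of [build_mscan()] results.
#' @return An `mscan`.
#' @export
aggregate_mscans <- function(mscans) {
  if (!length(mscans)) retorg_error("parameter", "empty M-scan list")
  ref <- mscans[[1L]]
  for (m in mscans[-1L]) {
    if (!all(dim(m) == dim(ref)) ||
        !identical(attr(m, "col_period_s"), attr(ref, "col_period_s")) ||
        !identical(attr(m, "lights_off_col"), attr(ref, "lights_off_col")) ||
        !identical(attr(m, "pitch_um"), attr(ref, "pitch_um")))
      retorg_error("aggregation", "M-scan grids do not match")
  }
  z <- (seq_len(nrow(ref)) - 1L) * attr(ref, "pitch_um")
  acc <- matrix(0, nrow(ref), ncol(ref))
  for (m in mscans) {
    delta <- attr(m, "elm_row_um") - attr(ref, "elm_row_um")
    mm <- unclass(m)
    if (abs(delta) > 0)
      mm <- apply(mm, 2L, function(col)
        stats::approx(z, col, xout = z + delta, yleft = 0, yright = 0)$y)
    acc <- acc + mm
  }
  acc <- acc / length(mscans)
  attributes(acc) <- attributes(ref)
  acc
}
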
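# Containers for acquired/simulated image stacks and their on-disk format:
# multi-page 32-bit-float TIFF plus a JSON metadata sidecar.

#' OCT volume container
#'
#' @param data Numeric array `[repeat, bscan, aline, depth]`, non-negative
#'   linear intensities.
#' @param pitch_um Axial pixel pitch, um.
#' @param lateral_pitch_um Lateral (fast-axis) pixel pitch, um.
#' @param timestamp_min Acquisition timestamp, minutes since lights-off.
#' @param seed Seed the volume was rendered with (`NA` for acquired data).
#' @param provenance Free-text provenance string.
#' @return An `oct_volume`.
#' @export
oct_volume <- function(data, pitch_um, lateral_pitch_um,
                       timestamp_min = 0, seed = NA_integer_,
                       provenance = "") {
  if (length(dim(data)) != 4L)
    retorg_error("format", "volume data must be a 4-D array [repeat, bscan, aline, depth]")
  if (anyNA(data) || any(!is.finite(data)))
    retorg_error("format", "volume intensities contain NA/NaN/Inf")
  if (any(data < 0))
    retorg_error("format", "volume intensities must be non-negative")
  if (pitch_um <= 0 || lateral_pitch_um <= 0)
    retorg_error("format", "pixel pitches must be positive")
  structure(list(data = data, pitch_um = pitch_um,
                 lateral_pitch_um = lateral_pitch_um,
                 timestamp_min = timestamp_min, seed = seed,
                 provenance = provenance),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("OCT volume: %d repeats x %d B-scans x %d A-lines x %d px (t = %g min)\n",
              d[1], d[2], d[3], d[4], x$timestamp_min))
  invisible(x)
}

#' High-speed recording container
#'
#' @param data Numeric array `[frame, aline, depth]`.
#' @param frame_rate_hz Frame rate.
#' @param lights_off_s Lights-off time within the recording, s.
#' @param pitch_um Axial pixel pitch, um.
#' @param seed,provenance Provenance metadata.
#' @return A `highspeed_recording`.
#' @export
highspeed_recording <- function(data, frame_rate_hz, lights_off_s,
                                pitch_um, seed = NA_integer_,
                                provenance = "") {
  if (length(dim(data)) != 3L)
    retorg_error("format", "recording data must be a 3-D array [frame, aline, depth]")
  if (anyNA(data) || any(!is.finite(data)))
    retorg_error("format", "recording intensities contain NA/NaN/Inf")
  if (any(data < 0))
    retorg_error("format", "recording intensities must be non-negative")
  duration <- dim(data)[1L] / frame_rate_hz
  if (lights_off_s < 0 || lights_off_s > duration)
    retorg_error("format", "lights-off time %.1f s outside recording [0, %.1f] s",
                 lights_off_s, duration)
  structure(list(data = data, frame_rate_hz = frame_rate_hz,
                 lights_off_s = lights_off_s, pitch_um = pitch_um,
                 duration_s = duration, seed = seed, provenance = provenance),
            class = "highspeed_recording")
}

#' @export
print.highspeed_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("High-speed recording: %d frames (%g fps, %.1f s) x %d A-lines x %d px, lights off %g s\n",
              d[1], x$frame_rate_hz, x$duration_s, d[2], d[3], x$lights_off_s))
  invisible(x)
}

# ---- minimal baseline TIFF writer (32-bit IEEE float, one strip/page) ----
# tiff::writeTIFF stores integer samples only; float stacks are written here
# and read back with tiff::readTIFF (which handles SampleFormat = 3).

tiff_entry <- function(tag, type, count, value) {
  val <- raw(4L)
  if (type == 3L) {           # SHORT
    v <- writeBin(as.integer(value), raw(), size = 2L, endian = "little")
    val[seq_along(v)] <- v
  } else {                    # LONG
    val <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
  }
  c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    val)
}

# pages: list of numeric matrices [rows x cols]; values stored as float32.
write_tiff_float <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")  # first IFD right after header
  # layout: header(8) | for each page: [IFD][strip data]
  n_entries <- 10L
  ifd_len <- 2L + 12L * n_entries + 4L
  offset <- 8
  n <- length(pages)
  for (p in seq_len(n)) {
    m <- pages[[p]]
    rows <- nrow(m); cols <- ncol(m)
    nbytes <- 4 * rows * cols
    ifd_off <- offset
    strip_off <- ifd_off + ifd_len
    next_off <- if (p < n) strip_off + nbytes else 0
    entries <- list(
      tiff_entry(256L, 4L, 1L, cols),        # ImageWidth
      tiff_entry(257L, 4L, 1L, rows),        # ImageLength
      tiff_entry(258L, 3L, 1L, 32L),         # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),          # Compression: none
      tiff_entry(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, strip_off),   # StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),          # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, rows),        # RowsPerStrip
      tiff_entry(279L, 4L, 1L, nbytes),      # StripByteCounts
      tiff_entry(339L, 3L, 1L, 3L))          # SampleFormat: IEEE float
    writeBin(n_entries, con, size = 2L, endian = "little")
    for (e in entries) writeBin(e, con)
    writeBin(as.integer(next_off), con, size = 4L, endian = "little")
    # row-major scanlines
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    offset <- strip_off + nbytes
  }
  invisible(path)
}

paths_for <- function(stem) {
  stem <- sub("\\.tiff?$", "", stem)
  list(tiff = paste0(stem, ".tiff"), meta = paste0(stem, ".meta.json"))
}

write_meta <- function(path, meta) {
  meta$retorg_version <- as.character(utils::packageVersion("retorg"))
  jsonlite::write_json(meta, path, digits = NA, auto_unbox = TRUE)
}

read_meta <- function(path) {
  if (!file.exists(path))
    retorg_error("format", "missing metadata sidecar: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read an OCT volume
#'
#' `write_volume()` stores a volume as a multi-page 32-bit-float TIFF
#' (`<stem>.tiff`, one page per B-scan image of depth rows x A-line columns,
#' repeats concatenated repeat-major: page `(r - 1) * n_bscans + b`) plus a
#' JSON metadata sidecar (`<stem>.meta.json`). `read_volume()` reverses it,
#' validating the page count and image shape against the sidecar; the round
#' trip is lossless (volumes hold float32-snapped intensities).
#'
#' @param volume An [oct_volume()].
#' @param stem Output path stem (with or without `.tiff`).
#' @return `write_volume()` the two paths, invisibly; `read_volume()` an
#'   `oct_volume`.
#' @export
write_volume <- function(volume, stem) {
  stopifnot(inherits(volume, "oct_volume"))
  p <- paths_for(stem)
  d <- dim(volume$data)
  pages <- vector("list", d[1L] * d[2L])
  for (r in seq_len(d[1L])) for (b in seq_len(d[2L]))
    pages[[(r - 1L) * d[2L] + b]] <- t(volume$data[r, b, , ])
  write_tiff_float(pages, p$tiff)
  write_meta(p$meta, list(
    type = "oct_volume", n_repeats = d[1L], n_bscans = d[2L],
    n_alines = d[3L], axial_px = d[4L], pitch_um = volume$pitch_um,
    lateral_pitch_um = volume$lateral_pitch_um,
    timestamp_min = volume$timestamp_min, seed = volume$seed,
    provenance = volume$provenance, page_order = "repeat-major"))
  invisible(unlist(p))
}

#' @rdname write_volume
#' @export
read_volume <- function(stem) {
  p <- paths_for(stem)
  meta <- read_meta(p$meta)
  if (!identical(meta$type, "oct_volume"))
    retorg_error("format", "sidecar type is '%s', expected 'oct_volume'", meta$type)
  pages <- tiff::readTIFF(p$tiff, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  want <- meta$n_repeats * meta$n_bscans
  if (length(pages) != want)
    retorg_error("format", "TIFF has %d pages but sidecar declares %d (%d repeats x %d B-scans)",
                 length(pages), want, meta$n_repeats, meta$n_bscans)
  if (nrow(pages[[1L]]) != meta$axial_px || ncol(pages[[1L]]) != meta$n_alines)
    retorg_error("format", "page shape %dx%d does not match sidecar %dx%d",
                 nrow(pages[[1L]]), ncol(pages[[1L]]), meta$axial_px, meta$n_alines)
  arr <- array(0, dim = c(meta$n_repeats, meta$n_bscans, meta$n_alines,
                          meta$axial_px))
  for (r in seq_len(meta$n_repeats)) for (b in seq_len(meta$n_bscans)) {
    pg <- pages[[(r - 1L) * meta$n_bscans + b]]
    if (anyNA(pg)) retorg_error("format", "TIFF page contains NA/NaN values")
    if (any(pg < 0)) retorg_error("format", "TIFF page contains negative intensities")
    arr[r, b, , ] <- t(pg)
  }
  oct_volume(arr, pitch_um = meta$pitch_um,
             lateral_pitch_um = meta$lateral_pitch_um,
             timestamp_min = meta$timestamp_min,
             seed = meta$seed %||% NA_integer_,
             provenance = meta$provenance %||% "")
}

#' Write / read a high-speed recording
#'
#' Same on-disk contract as [write_volume()], with one TIFF page per frame
#' and the frame rate and lights-off time in the sidecar.
#'
#' @param recording A [highspeed_recording()].
#' @param stem Path stem.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "highspeed_recording"))
  p <- paths_for(stem)
  d <- dim(recording$data)
  pages <- lapply(seq_len(d[1L]), function(f) t(recording$data[f, , ]))
  write_tiff_float(pages, p$tiff)
  write_meta(p$meta, list(
    type = "highspeed_recording", n_frames = d[1L], n_alines = d[2L],
    axial_px = d[3L], frame_rate_hz = recording$frame_rate_hz,
    lights_off_s = recording$lights_off_s, pitch_um = recording$pitch_um,
    seed = recording$seed, provenance = recording$provenance))
  invisible(unlist(p))
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  p <- paths_for(stem)
  meta <- read_meta(p$meta)
  if (!identical(meta$type, "highspeed_recording"))
    retorg_error("format", "sidecar type is '%s', expected 'highspeed_recording'",
                 meta$type)
  pages <- tiff::readTIFF(p$tiff, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_frames)
    retorg_error("format", "TIFF has %d pages but sidecar declares %d frames",
                 length(pages), meta$n_frames)
  arr <- array(0, dim = c(meta$n_frames, meta$n_alines, meta$axial_px))
  for (f in seq_len(meta$n_frames)) {
    pg <- pages[[f]]
    if (anyNA(pg)) retorg_error("format", "TIFF page contains NA/NaN values")
    if (any(pg < 0)) retorg_error("format", "TIFF page contains negative intensities")
    arr[f, , ] <- t(pg)
  }
  highspeed_recording(arr, frame_rate_hz = meta$frame_rate_hz,
                      lights_off_s = meta$lights_off_s,
                      pitch_um = meta$pitch_um,
                      seed = meta$seed %||% NA_integer_,
                      provenance = meta$provenance %||% "")
}
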
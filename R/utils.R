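# Internal helpers: error conditions, float32 snapping, deterministic
# sub-seeds, smoothing, peak finding and sub-sample refinement.

retorg_error <- function(type, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("retorg_", type, "_error"),
                                "retorg_error")))
}

retorg_warn <- function(type, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("retorg_", type, "_warning"),
                                     "retorg_warning")))
}

# Round doubles to the nearest IEEE single-precision value. Rendered image
# stacks are snapped so that the 32-bit float on-disk representation is exact.
snap_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               what = "double", size = 4L, n = length(x))
  dim(y) <- d
  y
}

# Deterministic sub-stream seed derivation (kept within 32-bit signed range;
# all intermediates stay below 2^53 so the arithmetic is exact).
sub_seed <- function(seed, i) {
  a <- (abs(as.numeric(seed)) %% 2147483647) + 1
  b <- abs(as.numeric(i)) %% 2147483647
  as.integer((a * 48271 + b * 104729) %% 2147483647)
}

# Short non-cryptographic hash of a config object, for provenance strings.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 17
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  z <- (-radius):radius
  k <- exp(-0.5 * (z / sigma)^2)
  k / sum(k)
}

# Gaussian smoothing with edge replication; sigma in samples. Matrices are
# smoothed along columns (one series per column) in a single filter pass.
smooth_gaussian <- function(y, sigma) {
  if (sigma <= 0) return(y)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  if (is.matrix(y)) {
    n <- nrow(y)
    yp <- rbind(y[rep(1L, r), , drop = FALSE], y,
                y[rep(n, r), , drop = FALSE])
    out <- stats::filter(yp, k, sides = 2L)[(r + 1L):(r + n), , drop = FALSE]
    return(matrix(as.numeric(out), n, ncol(y)))
  }
  yp <- c(rep(y[1L], r), y, rep(y[length(y)], r))
  as.numeric(stats::filter(yp, k, sides = 2L))[(r + 1L):(r + length(y))]
}

# Unit-mean multiplicative speckle: gamma(shape = looks, rate = looks).
# Integer shapes up to 8 are drawn as -log(prod of uniforms)/looks (sum of
# exponentials), which is considerably faster than rgamma here.
speckle_gamma <- function(n, looks) {
  if (!is.finite(looks) || looks <= 0)
    retorg_error("parameter", "speckle looks must be positive and finite")
  if (looks == round(looks) && looks <= 8) {
    u <- runif(n)
    for (i in seq_len(looks - 1L)) u <- u * runif(n)
    -log(u) / looks
  } else {
    rgamma(n, shape = looks, rate = looks)
  }
}

# Indices of local maxima; an interior plateau higher than both neighbours
# contributes its centre sample.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  s <- sign(diff(y))
  nzi <- which(s != 0)
  if (length(nzi) < 2L) return(integer(0))
  sv <- s[nzi]
  tr <- which(sv[-length(sv)] > 0 & sv[-1L] < 0)  # rise followed by fall
  if (!length(tr)) return(integer(0))
  rise_end <- nzi[tr]          # d[rise_end] > 0: plateau starts at rise_end+1
  fall_start <- nzi[tr + 1L]   # d[fall_start] < 0: plateau ends at fall_start
  idx <- ((rise_end + 1L) + fall_start) %/% 2L
  idx[idx > 1L & idx < n]
}

# Topographic prominence of peaks at indices `peaks` in profile y.
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    lhs <- y[seq_len(p - 1L)]
    higher_l <- which(lhs > h)
    lmin <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(p - 1L)]) else min(lhs)
    rhs <- y[(p + 1L):length(y)]
    higher_r <- which(rhs > h)
    rmin <- if (length(higher_r)) min(rhs[seq_len(min(higher_r) - 1L)]) else min(rhs)
    h - max(lmin, rmin)
  }, numeric(1))
}

# Parabolic (3-point) sub-sample refinement around a discrete maximum.
# Returns the fractional offset (clamped to +/- 1 sample) and refined height.
parabolic_refine <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(delta = 0, height = y[i]))
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(list(delta = 0, height = y[i]))
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  delta <- max(-1, min(1, delta))
  list(delta = delta, height = y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * delta)
}

# Linear interpolation with zero fill outside the support (vectorised).
interp_zero <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, method = "linear",
                       yleft = 0, yright = 0, ties = "ordered")$y
  out
}

# First sub-sample crossing of `level` between samples i and i+1 while
# scanning y[from..to] (direction given by from < to). Returns the
# interpolated position in sample units, or NA when no crossing occurs.
first_crossing <- function(y, level, from, to, rising = TRUE) {
  idx <- if (from <= to) from:to else from:to
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]; j <- idx[k + 1L]
    a <- y[i]; b <- y[j]
    hit <- if (rising) (a < level && b >= level) else (a > level && b <= level)
    if (hit) {
      f <- (level - a) / (b - a)
      return(i + f * (j - i))
    }
  }
  NA_real_
}
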
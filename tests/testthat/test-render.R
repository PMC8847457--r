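# Forward rendering: PSF blur, speckle statistics, curvature, determinism.

test_that("noiseless A-line peaks at the true ELM depth", {
  m <- flat_model()
  p <- test_protocol(speckle_looks = Inf)
  y <- render_aline(m, c(0, 0), p)
  z <- (seq_along(y) - 1) * p$pitch_um
  win <- which(abs(z - m$elm_center_um) < 6)
  expect_lt(abs(z[win[which.max(y[win])]] - m$elm_center_um),
            p$pitch_um / 2 + 1e-9)
})

test_that("speckle is unit-mean: Monte-Carlo mean matches the noiseless profile", {
  m <- flat_model()
  p0 <- test_protocol(speckle_looks = Inf)
  clean <- render_aline(m, c(0, 0), p0)
  probe <- c(30, 90, 135, 143, 168)   # ONL, ELM, ISe, tips, RPE pixels
  n <- 1e4
  p1 <- test_protocol(speckle_looks = 4)
  set.seed(42)
  draws <- matrix(0, n, length(probe))
  for (i in seq_len(n))
    draws[i, ] <- clean[probe] * retorg:::speckle_gamma(length(probe), 4)
  mc_mean <- colMeans(draws)
  mc_se <- apply(draws, 2, sd) / sqrt(n)
  expect_true(all(abs(mc_mean - clean[probe]) <= 3 * mc_se))
})

test_that("N-frame averaging reduces speckle variance by 1/N", {
  set.seed(7)
  n <- 4000; N <- 8
  single <- retorg:::speckle_gamma(n, 4)
  avg <- rowMeans(matrix(retorg:::speckle_gamma(n * N, 4), n, N))
  ratio <- var(avg) / var(single)
  expect_lt(abs(ratio - 1 / N), 0.35 / N)   # sampling error allowance
})

test_that("PSF convolution merges peaks closer than the FWHM", {
  # independent oracle: direct Gaussian-blur of two delta lines
  fwhm <- 2.9; sigma <- fwhm / (2 * sqrt(2 * log(2)))
  z <- seq(0, 60, by = 0.05)
  blur2 <- function(sep) {
    y <- dnorm(z, 30, sigma) + dnorm(z, 30 + sep, sigma)
    length(brute_force_maxima(y))
  }
  expect_equal(blur2(0.6 * fwhm), 1L)   # below FWHM: merged
  expect_equal(blur2(2.0 * fwhm), 2L)   # at 2x FWHM: resolved
  # the same behaviour through the renderer: tips 1.8 um apart merge
  m_close <- retina_layer_model(cone_tip_offset_um = 13.4,
                                rod_tip_offset_um = 15.2,
                                tip_width_um = 1.0, curvature_um_mm2 = 0)
  prof <- normalize_onl(noiseless_profile(m_close))
  b <- locate_bands(prof)
  dp <- detect_double_peaks(prof, b)
  expect_false(dp$resolved)
  m_far <- flat_model()                 # 7.5 um apart: resolved
  pr2 <- normalize_onl(noiseless_profile(m_far))
  dp2 <- detect_double_peaks(pr2, locate_bands(pr2))
  expect_true(dp2$resolved)
})

test_that("volume rendering is deterministic and carries the protocol shape", {
  m <- mini_model()
  p <- test_protocol(n_alines = 10, n_bscans = 6, n_repeats = 2,
                     axial_px = 48, speckle_looks = 4, seed = 9)
  v1 <- render_volume(m, NULL, p, t_min = 0)
  v2 <- render_volume(m, NULL, p, t_min = 0)
  expect_identical(v1$data, v2$data)
  expect_equal(dim(v1$data), c(2L, 6L, 10L, 48L))

  # protocol-default lateral shape: 4 repeats x 600 B-scans x 600 A-lines
  pfull <- acquisition_protocol(axial_px = 48, speckle_looks = Inf, seed = 1)
  vfull <- render_volume(m, NULL, pfull, t_min = 0)
  expect_equal(dim(vfull$data)[1:3], c(4L, 600L, 600L))
})

test_that("null kinetics renders identical scenes at 0 and 30 min", {
  m <- mini_model()
  p <- test_protocol(n_alines = 8, n_bscans = 4, axial_px = 48,
                     speckle_looks = Inf)
  v0 <- render_volume(m, null_kinetics(), p, t_min = 0, seed = 5)
  v30 <- render_volume(m, null_kinetics(), p, t_min = 30, seed = 5)
  expect_equal(v0$data, v30$data)
})

test_that("layers exceeding the axial window raise a render error naming them", {
  m <- default_model()   # choroid to 280 um
  p <- test_protocol(axial_px = 128)  # 158.75 um window
  err <- expect_error(render_aline(m, c(0, 0), p),
                      class = "retorg_render_error")
  expect_match(conditionMessage(err), "layer '")
})

test_that("high-speed recording timing and baseline behaviour", {
  m <- flat_model()
  p <- test_protocol(n_alines = 4, axial_px = 224, speckle_looks = Inf,
                     n_frames = 160, frame_rate_hz = 16, lights_off_s = 5)
  rec <- render_highspeed(m, kinetics_params(lights_off_s = 5), p,
                          jitter_um = 0)
  expect_equal(rec$duration_s, 10)
  expect_equal(frame_period_ms(rec$frame_rate_hz), 62.5)
  # frames before lights-off are drawn from the baseline snapshot only
  expect_equal(rec$data[1, , ], rec$data[5 * 16, , ])
  # after lights-off the scene changes
  expect_gt(max(abs(rec$data[1, , ] - rec$data[160, , ])), 0)
  # jitter 0: ELM argmax depth constant across frames
  amax <- apply(rec$data[, 1, ], 1, which.max)
  expect_equal(length(unique(amax)), 1L)
})
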
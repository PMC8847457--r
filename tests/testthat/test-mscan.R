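# Spatiotemporal M-scan construction and transition kinetics.

hs_protocol <- function(n_frames = 4800, n_alines = 4, looks = Inf,
                        seed = 1L, lights_off_s = NULL) {
  # short test recordings put lights-off at 2 s instead of the default 30 s
  lights_off_s <- lights_off_s %||% if (n_frames >= 960) 30 else 2
  test_protocol(n_alines = n_alines, speckle_looks = looks, seed = seed,
                n_frames = n_frames, frame_rate_hz = 16,
                lights_off_s = lights_off_s,
                field_mm = c(0.024 * n_alines / 4, 0.024))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("4800 frames in 16-frame blocks give 300 one-second columns", {
  m <- flat_model()
  rec <- render_highspeed(m, NULL, hs_protocol(), jitter_um = 0)
  ms <- build_mscan(rec, block = 16, n_alines_avg = 4)
  expect_equal(ncol(ms), 300L)
  expect_equal(attr(ms, "col_period_s"), 1)
  expect_equal(attr(ms, "lights_off_col"), 30L)
  expect_equal(nrow(ms), 4L * 224L)
})

test_that("a trailing partial block is dropped with a warning", {
  m <- flat_model()
  rec <- render_highspeed(m, NULL, hs_protocol(n_frames = 170), jitter_um = 0)
  expect_warning(ms <- build_mscan(rec, block = 16, n_alines_avg = 4),
                 class = "retorg_partial_block_warning")
  expect_equal(ncol(ms), 10L)
})

test_that("a constant noiseless recording yields identical columns", {
  m <- flat_model()
  rec <- render_highspeed(m, NULL, hs_protocol(n_frames = 96), jitter_um = 0)
  ms <- build_mscan(rec, block = 16, n_alines_avg = 4)
  expect_lt(max(abs(ms - ms[, 1])), 1e-9)
})

test_that("noiseless linear-ramp displacement slope matches -dL/T_sat", {
  m <- flat_model()
  kin <- kinetics_params()
  rec <- render_highspeed(m, kin, hs_protocol(n_frames = 1920), jitter_um = 0)
  ms <- build_mscan(rec, block = 16, n_alines_avg = 4)
  tk <- transition_kinetics(ms)
  expected <- -4.07 / (30 * 60)   # um per second
  expect_lt(abs(tk$slope_disp_um_per_s - expected) / abs(expected), 0.05)
  expect_equal(mean(tk$displacement_um[seq_len(30)]), 0, tolerance = 1e-9)
  expect_true(all(abs(c(tk$r_time_ise, tk$r_time_disp, tk$r_ise_disp)) <= 1))
})

test_that("flattening inside build_mscan removes per-frame axial jitter", {
  m <- flat_model()
  rec <- render_highspeed(m, NULL, hs_protocol(n_frames = 480),
                          jitter_um = 1.5, seed = 5)
  ms <- build_mscan(rec, block = 16, n_alines_avg = 4)
  # jitter spans ~5 upsampled samples peak-to-peak before flattening; after
  # alignment the ELM band row scatters by at most one upsampled sample
  z <- (seq_len(nrow(ms)) - 1) * attr(ms, "pitch_um")
  win <- which(abs(z - attr(ms, "elm_row_um")) <= 3)
  rows <- apply(unclass(ms), 2, function(col) {
    y <- retorg:::smooth_gaussian(col, 4)
    win[which.max(y[win])]
  })
  expect_lte(max(rows) - min(rows), 1L)
  # and the matched sub-pixel positions stay within the quantization bound
  # plus a small template-matching tolerance
  tk <- transition_kinetics(ms)
  expect_lt(max(tk$elm_um) - min(tk$elm_um), 1.5 * attr(ms, "pitch_um"))
})

test_that("aggregating copies is the identity; grids must match", {
  m <- flat_model()
  rec <- render_highspeed(m, NULL, hs_protocol(n_frames = 96), jitter_um = 0)
  ms <- build_mscan(rec, block = 16, n_alines_avg = 4)
  agg <- aggregate_mscans(list(ms, ms, ms))
  expect_equal(unclass(agg), unclass(ms), tolerance = 1e-12)
  rec2 <- render_highspeed(m, NULL, hs_protocol(n_frames = 64), jitter_um = 0)
  ms2 <- build_mscan(rec2, block = 16, n_alines_avg = 4)
  expect_error(aggregate_mscans(list(ms, ms2)),
               class = "retorg_aggregation_error")
})

test_that("the aggregate M-scan shows the staircase band set of the outer retina", {
  m <- flat_model()
  mss <- lapply(1:3, function(s) {
    rec <- render_highspeed(m, NULL, hs_protocol(n_frames = 96, n_alines = 8,
                                                 looks = 400, seed = s),
                            jitter_um = 0, seed = s)
    build_mscan(rec, block = 16, n_alines_avg = 8)
  })
  agg <- aggregate_mscans(mss)
  prof <- retorg:::mscan_profile(agg, seq_len(ncol(agg)))
  b <- locate_bands(prof)
  dp <- detect_double_peaks(prof, b)
  # five hyper-reflective levels between ONL and choroid: ELM, ISe, cone
  # tip, rod tip, RPE, with hypo plateaus between
  expect_false(any(is.na(b$depth_um[b$band %in% c("ELM", "ISe", "RPE")])))
  expect_true(dp$resolved)
  # aggregation reduces column noise
  v_agg <- mean(apply(agg, 1, var))
  v_one <- mean(apply(mss[[1]], 1, var))
  expect_lt(v_agg, v_one)
})

test_that("losing the bands in too many columns raises a kinetics error", {
  m <- flat_model()
  rec <- render_highspeed(m, kinetics_params(), hs_protocol(n_frames = 640),
                          jitter_um = 0)
  ms <- build_mscan(rec, block = 16, n_alines_avg = 4)
  broken <- ms
  # wipe the outer retina from most columns
  z <- (seq_len(nrow(ms)) - 1) * attr(ms, "pitch_um")
  broken[z > 170, 5:40] <- 1
  expect_error(transition_kinetics(broken), class = "retorg_error")
})
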
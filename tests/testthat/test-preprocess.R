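# ELM detection, flattening, representative profile, ONL normalization.

test_that("ELM trace is exact on a flat noiseless phantom", {
  m <- flat_model()
  p <- test_protocol(n_alines = 40, speckle_looks = Inf)
  vol <- render_volume(m, NULL, p)
  tr <- detect_elm(vol$data[1, 1, , ], pitch_um = p$pitch_um)
  truth_px <- m$elm_center_um / p$pitch_um + 1
  expect_lt(max(abs(tr$position_px - truth_px)), 0.5)
  expect_lt(diff(range(tr$position_px)), 0.2)
})

test_that("ELM trace follows the true quadratic bow on a curved phantom", {
  m <- default_model()   # 111 um/mm^2 curvature
  p <- test_protocol(n_alines = 120, n_bscans = 6, speckle_looks = Inf)
  vol <- render_volume(m, NULL, p)
  b <- 2L
  bs <- vol$data[1, b, , ]
  tr <- detect_elm(bs, pitch_um = p$pitch_um)
  na <- p$n_alines; nb <- p$n_bscans
  x <- (seq_len(na) - (na + 1) / 2) * p$field_mm[1] / na
  yoff <- (b - (nb + 1) / 2) * p$field_mm[2] / nb
  truth_px <- (m$elm_center_um + 111 * (x^2 + yoff^2)) / p$pitch_um + 1
  expect_lt(max(abs(tr$position_px - truth_px)), 0.5)
})

test_that("ELM detection stays within a pixel under 4-look speckle", {
  m <- default_model()
  p <- test_protocol(n_alines = 200, n_bscans = 2, speckle_looks = 4,
                     seed = 21)
  vol <- render_volume(m, NULL, p)
  bs <- vol$data[1, 1, , ]
  tr <- detect_elm(bs, pitch_um = p$pitch_um)
  na <- p$n_alines
  x <- (seq_len(na) - (na + 1) / 2) * p$field_mm[1] / na
  yoff <- (1 - (p$n_bscans + 1) / 2) * p$field_mm[2] / p$n_bscans
  truth_px <- (m$elm_center_um + 111 * (x^2 + yoff^2)) / p$pitch_um + 1
  expect_gte(mean(abs(tr$position_px - truth_px) <= 1), 0.99)
})

test_that("detection fails loudly on a featureless B-scan", {
  bs <- matrix(rep(seq(0, 1, length.out = 224), each = 20), 20, 224)
  expect_error(detect_elm(bs, pitch_um = 1.25),
               class = "retorg_detection_error")
})

test_that("flattening: identity, inverse-shift recovery, curvature removal", {
  m <- flat_model()
  p <- test_protocol(n_alines = 30, speckle_looks = Inf)
  vol <- render_volume(m, NULL, p)
  bs <- vol$data[1, 1, , ]
  tr <- detect_elm(bs, pitch_um = p$pitch_um)

  # constant trace at its own median: zero shifts, exact identity
  fl <- flatten(bs, tr, reference_px = stats::median(tr$position_px))
  expect_equal(max(abs(fl - bs)), 0, tolerance = 1e-6)

  # shifting all A-lines by +k and flattening back recovers the original
  k <- 7L
  shifted <- cbind(matrix(0, nrow(bs), k), bs[, 1:(ncol(bs) - k)])
  tr2 <- detect_elm(shifted, pitch_um = p$pitch_um)
  rec <- flatten(shifted, tr2, reference_px = stats::median(tr$position_px))
  interior <- (k + 2):(ncol(bs) - k - 1)
  expect_lt(max(abs(rec[, interior] - bs[, interior])), 1e-3)

  # curved noiseless phantom: post-flattening ELM residual <= 1 pixel
  mc <- default_model()
  pc <- test_protocol(n_alines = 120, n_bscans = 4, speckle_looks = Inf)
  vc <- render_volume(mc, NULL, pc)
  bsc <- vc$data[1, 2, , ]
  trc <- detect_elm(bsc, pitch_um = pc$pitch_um)
  flc <- flatten(bsc, trc)
  trc2 <- detect_elm(flc, pitch_um = pc$pitch_um)
  expect_lt(max(abs(trc2$position_px - attr(flc, "reference_px"))), 1)

  expect_error(flatten(bs, tr, reference_px = 4000),
               class = "retorg_parameter_error")
})

test_that("representative profile reduces to the upsampled A-line on a flat volume", {
  m <- flat_model()
  p <- test_protocol(n_alines = 24, n_bscans = 12, n_repeats = 2,
                     speckle_looks = Inf)
  vol <- render_volume(m, NULL, p)
  prof <- representative_profile(vol, n_bscans_avg = 12, n_alines_avg = 24)
  aline <- vol$data[1, 1, 1, ]
  expect_equal(prof$intensity, retorg:::upsample_profile(aline, 4L),
               tolerance = 1e-6)
  expect_length(prof$intensity, 4 * p$axial_px)
  expect_equal(prof$pitch_um, p$pitch_um / 4)
  expect_equal(prof$n_contributing, 2 * 12 * 24)
})

test_that("the protocol-default averaging contributes 120,000 raw A-scans", {
  # 4 repeats x 150 B-scans x 200 A-lines
  expect_equal(4 * 150 * 200, 120000)
  m <- flat_model()
  p <- test_protocol(n_alines = 200, n_bscans = 150, n_repeats = 4,
                     speckle_looks = Inf)
  vol <- render_volume(m, NULL, p)
  prof <- representative_profile(vol)
  expect_equal(prof$n_contributing, 120000)
})

test_that("insufficient volumes are rejected with a protocol error", {
  m <- flat_model()
  p <- test_protocol(n_alines = 24, n_bscans = 8, speckle_looks = Inf)
  vol <- render_volume(m, NULL, p)
  err <- expect_error(representative_profile(vol),
                      class = "retorg_protocol_error")
  expect_match(conditionMessage(err), "need >= 150 x 200")
})

test_that("representative profile commutes with global gain; normalization removes it", {
  m <- flat_model()
  p <- test_protocol(n_alines = 24, n_bscans = 12, n_repeats = 1,
                     speckle_looks = 64, seed = 31)
  vol <- render_volume(m, NULL, p)
  g <- 3.7
  vol_g <- oct_volume(vol$data * g, vol$pitch_um, vol$lateral_pitch_um,
                      vol$timestamp_min)
  prof <- representative_profile(vol, n_bscans_avg = 12, n_alines_avg = 24)
  prof_g <- representative_profile(vol_g, n_bscans_avg = 12, n_alines_avg = 24)
  expect_equal(prof_g$intensity, g * prof$intensity, tolerance = 1e-6)
  n1 <- normalize_onl(prof); n2 <- normalize_onl(prof_g)
  expect_equal(n1$intensity, n2$intensity, tolerance = 1e-6)
})

test_that("speckle in the representative profile shrinks with averaging", {
  m <- flat_model()
  clean <- normalize_onl(noiseless_profile(m))
  p <- test_protocol(n_alines = 24, n_bscans = 16, n_repeats = 4,
                     speckle_looks = 4, seed = 41)
  vol <- render_volume(m, NULL, p)
  prof <- normalize_onl(representative_profile(vol, n_bscans_avg = 16,
                                               n_alines_avg = 24))
  onl <- which(prof$depth_um > 120 & prof$depth_um < 160)
  resid <- prof$intensity[onl] / clean$intensity[onl] - 1
  # effective looks ~ 4 repeats x 16 B-scans x 24 A-lines x 4 looks / 4
  # (upsampled samples are correlated); demand agreement within factor 2
  pred <- 1 / sqrt(4 * 16 * 24 * 4)
  expect_lt(sd(resid), 4 * pred)
  expect_gt(sd(resid), pred / 4)
})

test_that("ONL normalization sets the reference region to exactly mean 1", {
  m <- flat_model()
  prof <- noiseless_profile(m)
  norm <- normalize_onl(prof)
  span <- norm$onl_span_um
  mid <- mean(span); half <- diff(span) / 4
  sel <- norm$depth_um >= mid - half & norm$depth_um <= mid + half
  expect_equal(mean(norm$intensity[sel]), 1, tolerance = 1e-12)
  # a profile with ONL mean 2 is halved
  doubled <- prof; doubled$intensity <- prof$intensity * 2
  n2 <- normalize_onl(doubled, onl_span_um = span)
  n1 <- normalize_onl(prof, onl_span_um = span)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  expect_error(normalize_onl(make_profile(rep(0, 896), normalized = "raw"),
                             onl_span_um = c(100, 150)),
               class = "retorg_normalization_error")
})
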
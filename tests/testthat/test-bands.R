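# Band peak, double-peak and boundary segmentation on depth profiles.

baseline_profile <- function() normalize_onl(noiseless_profile(flat_model()))

test_that("noiseless band depths recover the generator truth within 0.5 um", {
  m <- flat_model()
  prof <- normalize_onl(noiseless_profile(m))
  b <- locate_bands(prof)
  elm <- b$depth_um[b$band == "ELM"]
  expect_lt(abs(elm - m$elm_center_um), 0.5)
  rel <- function(nm) b$depth_um[b$band == nm] - elm
  expect_lt(abs(rel("ISe") - (m$ise_center_um - m$elm_center_um)), 0.5)
  truth_opl <- with(m, (layers$inner_um[layers$name == "OPL"] +
                          layers$outer_um[layers$name == "OPL"]) / 2)
  expect_lt(abs(rel("OPL") - (truth_opl - m$elm_center_um)), 0.7)
  expect_false(any(is.na(b$depth_um)))
  expect_true(all(diff(b$depth_um) > 0))
})

test_that("a monotone featureless profile raises a segmentation error", {
  prof <- make_profile(seq(0.1, 2, length.out = 896))
  expect_error(locate_bands(prof), class = "retorg_segmentation_error")
  flat <- make_profile(rep(1, 896))
  expect_error(locate_bands(flat), class = "retorg_segmentation_error")
})

test_that("band ordering and distance invariants hold over a 100-seed sweep", {
  m <- flat_model()
  p <- test_protocol()
  for (s in 1:100) {
    prof <- normalize_onl(render_profile(m, p, effective_looks = 256,
                                         seed = s))
    b <- locate_bands(prof)
    expect_true(all(diff(b$depth_um[!is.na(b$depth_um)]) > 0))
    bounds <- locate_boundaries(prof, b)
    expect_true(all(diff(unclass(bounds)) > 0))
    dp <- detect_double_peaks(prof, b)
    pd <- peak_distances(dp, b)
    pd <- pd[!is.na(pd)]
    th <- thickness_metrics(bounds)
    expect_true(all(pd > 0 & pd < th$elm_rpe_um))
  }
})

test_that("band peaks agree exactly with a brute-force local-maximum scan", {
  prof <- baseline_profile()
  y <- retorg:::smooth_gaussian(prof$intensity,
                                retorg:::sigma_samples(prof))
  oracle <- brute_force_maxima(y)
  expect_identical(retorg:::local_maxima(y), oracle)
  b <- locate_bands(prof)
  # every located band sits within one sample of a brute-force maximum
  idx <- round(b$depth_um[!is.na(b$depth_um)] / prof$pitch_um) + 1
  expect_true(all(vapply(idx, function(i) min(abs(oracle - i)) <= 1,
                         logical(1))))
})

test_that("sub-pixel refinement never exceeds one sample", {
  prof <- baseline_profile()
  y <- retorg:::smooth_gaussian(prof$intensity,
                                retorg:::sigma_samples(prof))
  b <- locate_bands(prof)
  for (d in b$depth_um[!is.na(b$depth_um)]) {
    i <- which.min(abs(prof$depth_um - d))
    expect_lte(abs(prof$depth_um[i] - d), prof$pitch_um)
  }
})

test_that("double peaks recover the cone and rod tip offsets", {
  m <- flat_model()
  prof <- normalize_onl(noiseless_profile(m))
  b <- locate_bands(prof)
  dp <- detect_double_peaks(prof, b)
  expect_true(dp$resolved)
  pd <- peak_distances(dp, b)
  expect_lt(abs(pd[["cone_um"]] - 13.4), 1)
  expect_lt(abs(pd[["rod_um"]] - 20.9), 1)
  expect_lt(dp$cone_um, dp$rod_um)
  expect_gt(dp$cone_um, b$depth_um[b$band == "ISe"])
  expect_lt(dp$rod_um, b$depth_um[b$band == "RPE"])
})

test_that("zero cone-tip contrast leaves a single rod-tip peak", {
  refl <- eval(formals(retina_layer_model)$reflectance)
  refl["IZ_cone"] <- refl["OS"]   # cone tip invisible
  m <- retina_layer_model(reflectance = refl, curvature_um_mm2 = 0)
  prof <- normalize_onl(noiseless_profile(m))
  b <- locate_bands(prof)
  dp <- detect_double_peaks(prof, b)
  expect_false(dp$resolved)
  expect_true(is.na(dp$cone_um))
  expect_false(is.na(dp$rod_um))
  pd <- peak_distances(dp, b)
  expect_true(is.na(pd[["cone_um"]]))
  expect_lt(abs(pd[["rod_um"]] - 20.9), 1)
})

test_that("boundaries recover the generator truth within 1 um", {
  m <- flat_model()
  prof <- normalize_onl(noiseless_profile(m))
  bounds <- locate_boundaries(prof, locate_bands(prof))
  expect_lt(abs(bounds[["inner_surface"]] - m$inner_surface_um), 1)
  expect_lt(abs(bounds[["oplonl"]] - m$oplonl_um), 1)
  expect_lt(abs(bounds[["elm"]] - m$elm_center_um), 1)
  expect_lt(abs(bounds[["rpe_basal"]] - m$rpe_basal_um), 1)
})

test_that("boundaries are gain-invariant", {
  prof <- baseline_profile()
  b1 <- locate_boundaries(prof, locate_bands(prof))
  scaled <- prof
  scaled$intensity <- prof$intensity * 2
  b2 <- locate_boundaries(scaled, locate_bands(scaled))
  expect_equal(unclass(b1), unclass(b2), tolerance = 1e-9)
  # and the lean ELM-RPE measure agrees with the boundary operators
  expect_equal(measure_elm_rpe(prof),
               b1[["rpe_basal"]] - b1[["elm"]], tolerance = 1e-6)
})
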
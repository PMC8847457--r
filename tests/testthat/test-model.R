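# Retina model construction, invariants, and dark-adaptation kinetics.

test_that("default model layers are contiguous, ordered, and consistent", {
  m <- default_model()
  ly <- m$layers
  expect_equal(ly$inner_um[-1], ly$outer_um[-nrow(ly)])
  expect_true(all(ly$outer_um > ly$inner_um))
  r <- function(nm) ly$reflectance[ly$name == nm]
  expect_true(r("ONL") < min(r("ELM"), r("ISe"), r("RPE")))
  # printed baseline geometry
  expect_equal(m$oplonl_um - m$inner_surface_um, 79.42)
  expect_equal(m$elm_center_um - m$oplonl_um, 58.08)
  expect_equal(m$rpe_basal_um - m$elm_center_um, 48.73)
  expect_equal(m$cone_tip_offset_um, 13.4)
  expect_equal(m$rod_tip_offset_um, 20.9)
  expect_lt(m$cone_tip_offset_um, m$rod_tip_offset_um)
})

test_that("invalid models are rejected", {
  expect_error(retina_layer_model(cone_tip_offset_um = 21,
                                  rod_tip_offset_um = 20.9),
               class = "retorg_parameter_error")
  refl <- formals(retina_layer_model)$reflectance
  refl <- eval(refl)
  refl["ONL"] <- 3.5   # ONL brighter than the hyper bands
  expect_error(retina_layer_model(reflectance = refl),
               class = "retorg_parameter_error")
  refl2 <- eval(formals(retina_layer_model)$reflectance)
  refl2["OS"] <- -0.1
  expect_error(retina_layer_model(reflectance = refl2),
               class = "retorg_parameter_error")
})

test_that("kinetics snapshots interpolate and clamp correctly", {
  m <- default_model()
  kin <- kinetics_params()  # linear ramp, T_sat = 30 min

  expect_identical(kinetics_at(m, kin, -1), m)   # pre-lights-off identity

  half <- kinetics_at(m, kin, 15)
  expect_equal((m$rpe_basal_um - m$elm_center_um) -
                 (half$rpe_basal_um - half$elm_center_um),
               4.07 / 2, tolerance = 1e-9)       # linear midpoint

  sat <- kinetics_at(m, kin, 30)
  expect_equal(kinetics_at(m, kin, 60)$layers, sat$layers)  # clamped

  # inner retinal layers unchanged for all t
  inner <- c("vitreous", "NFL", "GCL", "IPL", "INL", "OPL")
  for (t in c(2, 10, 30, 100)) {
    s <- kinetics_at(m, kin, t)
    expect_equal(s$layers[s$layers$name %in% inner, ],
                 m$layers[m$layers$name %in% inner, ])
  }
})

test_that("layer ordering and contiguity hold in every kinetics snapshot", {
  m <- default_model()
  for (shape in c("linear_ramp", "exponential")) {
    kin <- kinetics_params(shape = shape)
    for (t in seq(0, 45, by = 2.5)) {
      ly <- kinetics_at(m, kin, t)$layers
      expect_equal(ly$inner_um[-1], ly$outer_um[-nrow(ly)])
      expect_true(all(ly$outer_um > ly$inner_um))
    }
  }
})

test_that("exponential kinetics reach the same saturation state", {
  m <- default_model()
  lin <- kinetics_at(m, kinetics_params(shape = "linear_ramp"), 30)
  ex <- kinetics_at(m, kinetics_params(shape = "exponential"), 30)
  expect_equal(lin$layers, ex$layers, tolerance = 1e-12)
  # exponential leads the linear ramp before saturation
  ex10 <- kinetics_at(m, kinetics_params(shape = "exponential"), 10)
  lin10 <- kinetics_at(m, kinetics_params(shape = "linear_ramp"), 10)
  expect_lt(ex10$rpe_basal_um - ex10$elm_center_um,
            lin10$rpe_basal_um - lin10$elm_center_um)
})

test_that("the null scenario is the light-stable baseline at every time", {
  m <- default_model()
  kin0 <- null_kinetics()
  for (t in c(0, 5, 30, 60))
    expect_equal(kinetics_at(m, kin0, t)$layers, m$layers)
})

test_that("ground truth bookkeeping matches the displacement totals", {
  gt <- ground_truth(default_model(), kinetics_params())
  expect_equal(gt$timestamp_min, seq(0, 30, by = 5))
  expect_equal(gt$onl_um + gt$elm_rpe_um, gt$outer_retina_um)
  d_outer <- gt$outer_retina_um[7] - gt$outer_retina_um[1]
  d_er <- gt$elm_rpe_um[7] - gt$elm_rpe_um[1]
  expect_equal(d_er, -4.07)
  expect_equal(d_outer, -5.83)
  expect_equal(gt$inner_retina_um, rep(79.42, 7))
})

test_that("acquisition protocol validation", {
  expect_equal(dim_protocol <- acquisition_protocol()$n_alines, 600L)
  expect_error(acquisition_protocol(n_repeats = 0),
               class = "retorg_parameter_error")
  expect_error(acquisition_protocol(frame_rate_hz = 0),
               class = "retorg_parameter_error")
  expect_error(acquisition_protocol(timestamps_min = c(0, 5, 5)),
               class = "retorg_parameter_error")
  expect_error(kinetics_params(ise_drop = 1.4),
               class = "retorg_parameter_error")
  expect_error(kinetics_params(elmrpe_shortening_um = -1),
               class = "retorg_parameter_error")
})
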
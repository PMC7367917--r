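test_that("the total rate constant combines wash-out and crop removal", {
  expect_equal(rate_constant(mode = "rounded"), 0.006)
  k_exact <- rate_constant(mode = "exact")
  expect_equal(k_exact, 6.01e-3, tolerance = 0.005e-3 / 6.01e-3)
  expect_equal(k_exact,
               soil_params()$washout_rate_per_a +
                 removal_rate_constant(crop_basket()))
  # a basket that takes nothing up leaves wash-out as the only sink
  no_uptake <- single_crop(uf = 0)
  expect_equal(rate_constant(basket = crop_basket(no_uptake),
                             mode = "exact"), 2.0e-3)
})

test_that("closed-form concentrations hit the reference values", {
  m <- fixture_models()
  expect_equal(predict(m$B1, 100), 9, tolerance = 0.5 / 9)
  expect_equal(predict(m$B1, 0), 0.1)
  expect_equal(equilibrium(m$B1), 20, tolerance = 0.1)
  expect_equal(equilibrium(m$A1), 5, tolerance = 0.1)
  # pure first-order decay: one time constant drops the level by e
  decay <- soil_pb_model(0, 0.006, 70)
  expect_equal(predict(decay, 1 / 0.006), 70 / exp(1))
  expect_equal(equilibrium(decay), 0)
  expect_error(predict(m$B1, -1), "non-negative")
})

test_that("trajectories are monotone and bounded by initial and equilibrium", {
  t <- seq(0, 2000, by = 10)
  for (nm in names(pb_scenarios())) {
    m <- soil_pb_model(pb_scenario(nm))
    conc <- predict(m, t)
    lo <- min(m$initial_mg_kg, equilibrium(m))
    hi <- max(m$initial_mg_kg, equilibrium(m))
    expect_true(all(conc >= lo - 1e-12 & conc <= hi + 1e-12), info = nm)
    expect_true(all(diff(conc) * sign(equilibrium(m) - m$initial_mg_kg)
                    >= 0), info = nm)
    # the distance to equilibrium contracts by a factor e per 1/k years
    gap <- abs(conc - equilibrium(m))
    tau <- 1 / m$rate_constant_per_a
    expect_equal(abs(predict(m, t + tau) - equilibrium(m)),
                 gap / exp(1), tolerance = 1e-9, info = nm)
  }
})

test_that("time_to_concentration inverts the closed form", {
  m <- fixture_models()
  expect_equal(time_to_concentration(m$B1, 5), 50, tolerance = 0.1)
  expect_equal(time_to_concentration(m$C1, 5), 175, tolerance = 0.1)
  expect_identical(time_to_concentration(m$B1, m$B1$initial_mg_kg), 0)
  # round trip over three orders of magnitude in time
  for (t in c(0.01, 1, 10, 100, 500, 1000)) {
    back <- time_to_concentration(m$B1, predict(m$B1, t))
    expect_equal(back, t, tolerance = 1e-9, info = paste("t =", t))
  }
  # targets at or beyond the (never attained) equilibrium are rejected,
  # and the error reports the equilibrium so callers can branch
  expect_error(time_to_concentration(m$A1, equilibrium(m$A1)),
               "not reachable")
  expect_error(time_to_concentration(m$B1, 25), "19.8")
  expect_error(time_to_concentration(soil_pb_model(0, 0.006, 70), 80),
               "not reachable")
})

test_that("solutions superpose: forced response plus decaying initial state", {
  m <- fixture_models()$B1
  forced <- soil_pb_model(m$input_mg_kg_a, m$rate_constant_per_a, 0)
  t <- seq(0, 600, by = 25)
  expect_equal(predict(forced, t) +
                 m$initial_mg_kg * exp(-m$rate_constant_per_a * t),
               predict(m, t), tolerance = 1e-12)
})

test_that("numeric integration agrees with the closed form", {
  m <- fixture_models()$B1
  cf <- simulate(m, t_end_a = 600, n_points = 601)
  num <- simulate(m, t_end_a = 600, n_points = 601, method = "numeric")
  expect_equal(cf$time_a, num$time_a)
  expect_lt(max(abs(num$conc_mg_kg - cf$conc_mg_kg) /
                  pmax(abs(cf$conc_mg_kg), 1e-10)), 1e-8)
})

test_that("contaminated soils deplete toward the same equilibria", {
  for (nm in c("A2", "B2", "C2")) {
    m <- soil_pb_model(pb_scenario(nm))
    tr <- simulate(m, t_end_a = 600, n_points = 121)
    expect_true(all(diff(tr$conc_mg_kg) < 0), info = nm)
    expect_gt(tr$conc_mg_kg[nrow(tr)], equilibrium(m))
  }
  # stationary point: initial exactly at IN/k
  stat <- soil_pb_model(0.06, 0.006, 10)
  expect_equal(unique(simulate(stat, t_end_a = 100,
                               n_points = 11)$conc_mg_kg), 10)
})

test_that("simulate validates its grid and model inputs", {
  m <- fixture_models()$A1
  expect_error(simulate(m, t_end_a = 0))
  expect_error(simulate(m, t_end_a = 100, n_points = 1))
  expect_error(soil_pb_model(-0.1, 0.006, 0), "non-negative")
  expect_error(soil_pb_model(0.1, 0, 0), "positive")
  expect_error(soil_pb_model(0.1, 0.006, -1), "non-negative")
})
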
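test_that("TDIs derive from the BMDLs and required margins", {
  expect_equal(tdi("developmental_neurotoxicity"), 10)   # 0.5 ug/kg/d x 20 kg
  expect_equal(tdi("renal_failure"), 37.8)               # 0.63 x 60, printed 38
  expect_equal(tdi("kidney_cancer"), 51.9)               # 519 mg/d / 10,000
  expect_equal(round(tdi("renal_failure")), 38)
  expect_equal(round(tdi("kidney_cancer")), 52)
  blood <- structure(list(name = "x", bmdl_value = 12,
                          bmdl_basis = "blood_ug_per_L", body_weight_kg = 60,
                          required_margin = 1, population = "adult"),
                     class = "tox_endpoint")
  expect_error(tdi(blood), "unsupported BMDL basis")
  expect_error(tox_endpoint("melanoma"), "unknown endpoint")
})

test_that("allometric scaling converts animal BMDLs per body weight", {
  expect_equal(scale_animal_bmdl(30.5, 7, 60), 261.4, tolerance = 1e-3)
  expect_equal(scale_animal_bmdl(30.5, 1, 1), 30.5)
  # the shipped human kidney-cancer BMDL is the published constant, which
  # intentionally differs from the generic formula value
  expect_equal(tox_endpoint("kidney_cancer")$bmdl_value, 519)
})

test_that("daily exposure is the intake-weighted uptake times soil Pb", {
  # oracle: brute-force sum(intake x UF) from the raw fixture CSV
  tab <- raw_crops()
  swu_adult <- sum(tab$intake_adult_kg_d * tab$uptake_factor)
  expect_equal(swu_adult, 2.09e-3, tolerance = 0.005e-3 / 2.09e-3)
  e <- daily_exposure(18)
  expect_equal(e$intake_weighted_uptake_kg_d, swu_adult)
  expect_equal(e$exposure_ug_person_d, 18 * swu_adult * 1000)
  expect_equal(e$exposure_ug_person_d, 38, tolerance = 0.5 / 38)
  expect_equal(daily_exposure(0)$exposure_ug_person_d, 0)
  expect_equal(daily_exposure(36)$exposure_ug_person_d,
               2 * e$exposure_ug_person_d)
  e_child <- daily_exposure(18, population = "child")
  expect_equal(e_child$intake_weighted_uptake_kg_d,
               sum(tab$intake_child_kg_d * tab$uptake_factor))
})

test_that("critical soil concentrations reproduce the reference table", {
  expect_equal(round(critical_soil_conc("renal_failure")), 18)
  expect_equal(round(critical_soil_conc("kidney_cancer")), 25)
  # child endpoint: ~5.7 mg/kg at full precision, published rounded to 5
  crit_child <- critical_soil_conc("developmental_neurotoxicity")
  expect_equal(crit_child, 5.7, tolerance = 0.05 / 5.7)
  expect_error(critical_soil_conc("renal_failure", single_crop(uf = 0)),
               "positive")
})

test_that("exposure at the critical concentration equals the TDI", {
  for (nm in tox_endpoints()$name) {
    ep <- tox_endpoint(nm)
    crit <- critical_soil_conc(ep)
    e <- daily_exposure(crit, population = ep$population)
    expect_equal(e$exposure_ug_person_d, tdi(ep), tolerance = 1e-12,
                 info = nm)
  }
})

test_that("margins classify as MOS or MOE and scale inversely with exposure", {
  # threshold endpoint at exactly its TDI: MOS = 1, just tolerable
  mos <- safety_margin(tdi("renal_failure"), "renal_failure")
  expect_equal(mos$type, "MOS")
  expect_equal(mos$margin, 1)
  expect_true(mos$acceptable)
  # cancer endpoint at its TDI: MOE = the required 10,000
  moe <- safety_margin(51.9, "kidney_cancer")
  expect_equal(moe$type, "MOE")
  expect_equal(moe$margin, 10000)
  expect_true(moe$acceptable)
  expect_false(safety_margin(52.0, "kidney_cancer")$acceptable)
  # halving exposure doubles the margin
  expect_equal(safety_margin(10, "renal_failure")$margin,
               2 * safety_margin(20, "renal_failure")$margin)
  zero <- safety_margin(0, "renal_failure")
  expect_true(is.infinite(zero$margin) && zero$zero_exposure)
  # accepts an exposure_result directly
  expect_equal(safety_margin(daily_exposure(18), "renal_failure")$margin,
               safety_margin(daily_exposure(18)$exposure_ug_person_d,
                             "renal_failure")$margin)
})

test_that("maximum permissible input keeps equilibrium at the critical level", {
  mpi <- max_permissible_input(5, k = 0.006)
  expect_equal(mpi$mg_per_m2_a, 10.2)
  expect_equal(mpi$g_per_ha_a, 102)
  expect_equal(mpi$g_per_ha_a, 100, tolerance = 0.1)
  expect_equal(max_permissible_input(0)$g_per_ha_a, 0)
  expect_equal(max_permissible_input(5, k = 0.012)$g_per_ha_a,
               2 * mpi$g_per_ha_a)
  # consistency: feeding the permissible input back gives the critical
  # level as equilibrium
  m <- soil_pb_model(mpi$mg_per_kg_a, 0.006, 0)
  expect_equal(equilibrium(m), 5)
})

test_that("equilibria exceed critical levels exactly when t_crit is finite", {
  report <- risk_report()
  for (i in seq_len(nrow(report))) {
    reachable <- report$equilibrium_mg_kg[i] > report$critical_soil_mg_kg[i]
    expect_identical(is.finite(report$years_to_critical[i]), reachable,
                     info = paste(report$scenario[i], report$endpoint[i]))
  }
  # scenario B1 exceeds the renal and neurodevelopmental critical levels;
  # C1 exceeds the neurodevelopmental level only; no scenario reaches the
  # cancer level
  above <- report[is.finite(report$years_to_critical), ]
  expect_setequal(paste(above$scenario, above$endpoint),
                  c("B1 renal_failure", "B1 developmental_neurotoxicity",
                    "C1 developmental_neurotoxicity"))
})
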
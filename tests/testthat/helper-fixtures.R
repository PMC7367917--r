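# shared fixtures: reference models for the three simulated scenarios and
# a brute-force reader of the shipped crop CSV (independent of crop_table)

fixture_models <- function(k_mode = "rounded") {
  lapply(c(A1 = "A1", B1 = "B1", C1 = "C1"),
         function(nm) soil_pb_model(pb_scenario(nm), k_mode = k_mode))
}

raw_crops <- function() {
  read.csv(system.file("extdata", "crops.csv", package = "pbfate"))
}

# one-crop table for degenerate-basket tests
single_crop <- function(uf = 1e-3, yield = 1, adult = 0.1, child = 0.1) {
  data.frame(name = "solo", uptake_factor = uf, yield_kg_m2_a = yield,
             intake_adult_kg_d = adult, intake_child_kg_d = child)
}
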
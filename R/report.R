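#' Scenario-by-endpoint risk report
#'
#' Evaluates every (scenario, endpoint) pair: the equilibrium soil
#' concentration, the dietary exposure and margin at equilibrium, the
#' endpoint's critical soil concentration, the years of constant input
#' until the critical level is reached (NA when the equilibrium stays
#' below it, 0 when the initial concentration already exceeds it), and
#' the maximum permissible areal input.
#'
#' @param scenarios A list of [scenario_spec()] objects, or character
#'   names resolved via [pb_scenario()]. Default: A1, B1, C1, D1.
#' @param endpoints Character vector of endpoint names; default all three.
#' @param crops A crop table.
#' @param k_mode Passed to [rate_constant()].
#' @param preset Fertilizer preset for scenarios given by name.
#' @return A data.frame with one row per scenario x endpoint.
#' @examples
#' risk_report(c("B1", "C1"))
#' @export
risk_report <- function(scenarios = c("A1", "B1", "C1", "D1"),
                        endpoints = tox_endpoints()$name,
                        crops = crop_table(),
                        k_mode = c("rounded", "exact"),
                        preset = c("median", "p90", "published")) {
  k_mode <- match.arg(k_mode)
  preset <- match.arg(preset)
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, pb_scenario, preset = preset)
  basket <- crop_basket(crops)
  rows <- list()
  for (scen in scenarios) {
    model <- soil_pb_model(scen, basket = basket, k_mode = k_mode)
    eq <- equilibrium(model)
    for (ep_name in endpoints) {
      ep <- tox_endpoint(ep_name)
      crit <- critical_soil_conc(ep, crops)
      expo <- daily_exposure(eq, crops, ep$population)
      years <- if (model$initial_mg_kg >= crit) 0
               else if (eq > crit) time_to_concentration(model, crit)
               else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scen$name,
        endpoint = ep_name,
        population = ep$population,
        total_input_g_ha_a = total_input(scen),
        equilibrium_mg_kg = eq,
        exposure_at_equilibrium_ug_d = expo$exposure_ug_person_d,
        margin_at_equilibrium = safety_margin(expo, ep)$margin,
        critical_soil_mg_kg = crit,
        years_to_critical = years,
        max_permissible_input_g_ha_a =
          max_permissible_input(crit, model$rate_constant_per_a,
                                scen$soil)$g_per_ha_a)
    }
  }
  do.call(rbind, rows)
}

#' Run a batch of simulations and risk evaluations to files
#'
#' Deterministic batch driver: writes one trajectory file per scenario and
#' one combined risk table, plus a plain-text log with one line per stage
#' listing the resolved parameters. Identical manifests produce
#' byte-identical outputs.
#'
#' @param scenarios Scenario names (resolved via [pb_scenario()]) or
#'   [scenario_spec()] objects.
#' @param endpoints Endpoint names.
#' @param t_end_a Simulation horizon, years (> 0).
#' @param n_points Trajectory grid points.
#' @param out_dir Output directory (created if needed).
#' @param k_mode,preset,uf_source Model configuration flags, see
#'   [rate_constant()], [pb_scenario()], [crop_table()].
#' @param format `"csv"`, `"json"`, or both.
#' @return Invisibly, a character vector of the files written.
#' @export
run_report <- function(scenarios = c("A1", "B1", "C1", "D1"),
                       endpoints = tox_endpoints()$name,
                       t_end_a = 600, n_points = 601,
                       out_dir = ".",
                       k_mode = c("rounded", "exact"),
                       preset = c("median", "p90", "published"),
                       uf_source = c("table", "equations"),
                       format = c("csv", "json")) {
  k_mode <- match.arg(k_mode)
  preset <- match.arg(preset)
  uf_source <- match.arg(uf_source)
  format <- match.arg(format, several.ok = TRUE)
  if (!is.numeric(t_end_a) || t_end_a <= 0)
    stop("'t_end_a' must be strictly positive", call. = FALSE)
  known_ep <- tox_endpoints()$name
  bad <- setdiff(endpoints, known_ep)
  if (length(bad))
    stop("unknown endpoint(s) ", paste(sQuote(bad), collapse = ", "),
         "; available: ", paste(known_ep, collapse = ", "), call. = FALSE)
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, pb_scenario, preset = preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  crops <- crop_table(uf_source)
  basket <- crop_basket(crops)
  log <- c(sprintf("run_report: k_mode=%s preset=%s uf_source=%s t_end_a=%g",
                   k_mode, preset, uf_source, t_end_a))
  files <- character()
  emit <- function(x, stem) {
    if ("csv" %in% format) {
      f <- file.path(out_dir, paste0(stem, ".csv"))
      utils::write.csv(x, f, row.names = FALSE)
      files <<- c(files, f)
    }
    if ("json" %in% format) {
      f <- file.path(out_dir, paste0(stem, ".json"))
      jsonlite::write_json(x, f, dataframe = "rows", digits = NA,
                           pretty = TRUE)
      files <<- c(files, f)
    }
  }
  for (scen in scenarios) {
    model <- soil_pb_model(scen, basket = basket, k_mode = k_mode)
    log <- c(log, sprintf(
      "scenario %s: IN=%.6g mg/(kg a) k=%.6g 1/a initial=%.6g mg/kg",
      scen$name, model$input_mg_kg_a, model$rate_constant_per_a,
      model$initial_mg_kg))
    tr <- simulate(model, t_end_a = t_end_a, n_points = n_points)
    emit(as.data.frame(tr), paste0("trajectory_", scen$name))
  }
  risk <- risk_report(scenarios, endpoints, crops, k_mode = k_mode)
  emit(risk, "risk")
  log_file <- file.path(out_dir, "run.log")
  writeLines(log, log_file)
  invisible(c(files, log_file))
}

#' Self-check against the published reference values
#'
#' Recomputes, from the shipped parameterization, every headline number of
#' the reference assessment -- input totals and the unit chain, the sink
#' coefficients and surface weights, TDIs, critical soil concentrations,
#' the 100-year and equilibrium concentrations, times to the lowest
#' critical level, and the maximum permissible input -- and juxtaposes
#' them with the published values at the stated comparison tolerances
#' (exact for pure arithmetic, one unit in the last printed digit for
#' rounded table values, 10% for values published as approximate).
#'
#' @return A data.frame with columns `quantity`, `computed`, `reference`,
#'   `tolerance` (absolute) and `pass`.
#' @examples
#' chk <- reference_checks()
#' all(chk$pass)
#' @export
reference_checks <- function() {
  crops <- crop_table()
  basket <- crop_basket(crops)
  soil <- soil_params()
  w <- surface_weights(crops)
  models <- lapply(c(A1 = "A1", B1 = "B1", C1 = "C1"), function(nm)
    soil_pb_model(pb_scenario(nm), basket = basket))
  row <- function(quantity, computed, reference, tolerance)
    data.frame(quantity = quantity, computed = computed,
               reference = reference, tolerance = tolerance)
  last_digit <- function(x, digits) 0.5 * 10^(-digits) + 1e-9
  checks <- rbind(
    row("total input A [g/(ha a)]", total_input(pb_scenario("A1")),
        98.5, 1e-9),
    row("total input B, published preset [g/(ha a)]",
        total_input(pb_scenario("B1", preset = "published")), 405.6, 1e-9),
    row("total input C, published preset [g/(ha a)]",
        total_input(pb_scenario("C1", preset = "published")), 171.7, 1e-9),
    row("total input D, published preset [g/(ha a)]",
        total_input(pb_scenario("D1", preset = "published")), 98.8, 1e-9),
    row("input A [mg/(m2 a)]",
        input_conc_rate(total_input(pb_scenario("A1")), soil)$mg_per_m2_a,
        9.85, last_digit(9.85, 2)),
    row("input B [mg/(m2 a)]",
        input_conc_rate(total_input(pb_scenario("B1")), soil)$mg_per_m2_a,
        40.4, last_digit(40.4, 1)),
    row("input C [mg/(m2 a)]",
        input_conc_rate(total_input(pb_scenario("C1")), soil)$mg_per_m2_a,
        16.1, last_digit(16.1, 1)),
    row("input A [mg/(kg a)]",
        input_conc_rate(total_input(pb_scenario("A1")), soil)$mg_per_kg_a,
        0.029, last_digit(0.029, 3)),
    row("input B [mg/(kg a)]",
        input_conc_rate(total_input(pb_scenario("B1")), soil)$mg_per_kg_a,
        0.119, last_digit(0.119, 3)),
    row("input C [mg/(kg a)]",
        input_conc_rate(total_input(pb_scenario("C1")), soil)$mg_per_kg_a,
        0.047, last_digit(0.047, 3)),
    row("surface weight cereals", unname(w["cereals"]), 0.677,
        last_digit(0.677, 3)),
    row("surface weight potatoes", unname(w["potatoes"]), 0.036,
        last_digit(0.036, 3)),
    row("surface weight leafy vegetables", unname(w["leafy_vegetables"]),
        0.203, last_digit(0.203, 3)),
    row("surface weight other vegetables", unname(w["other_vegetables"]),
        0.084, last_digit(0.084, 3)),
    row("crop removal rate constant [1/a]", removal_rate_constant(basket),
        4.01e-3, last_digit(4.01e-3, 5)),
    row("total rate constant k [1/a]", rate_constant(soil, basket),
        0.006, 1e-12),
    row("TDI developmental neurotoxicity [ug/d]",
        tdi("developmental_neurotoxicity"), 10, 1e-9),
    row("TDI renal failure [ug/d]", tdi("renal_failure"), 38,
        last_digit(38, 0)),
    row("TDI kidney cancer [ug/d]", tdi("kidney_cancer"), 52,
        last_digit(52, 0)),
    row("critical soil Pb, renal failure [mg/kg]",
        critical_soil_conc("renal_failure", crops), 18, last_digit(18, 0)),
    row("critical soil Pb, kidney cancer [mg/kg]",
        critical_soil_conc("kidney_cancer", crops), 25, last_digit(25, 0)),
    row("critical soil Pb, dev. neurotoxicity [mg/kg]",
        critical_soil_conc("developmental_neurotoxicity", crops), 5,
        1),  # published rounds ~5.7 down to 5
    row("soil Pb after 100 a, B1 [mg/kg]", predict(models$B1, 100), 9,
        last_digit(9, 0)),
    row("equilibrium B1 [mg/kg]", equilibrium(models$B1), 20, 2),
    row("equilibrium A1 [mg/kg]", equilibrium(models$A1), 5, 0.5),
    row("years to 5 mg/kg, B1", time_to_concentration(models$B1, 5),
        50, 5),
    row("years to 5 mg/kg, C1", time_to_concentration(models$C1, 5),
        175, 17.5),
    row("max permissible input [mg/(m2 a)]",
        max_permissible_input(5, soil = soil)$mg_per_m2_a, 10, 1),
    row("max permissible input [g/(ha a)]",
        max_permissible_input(5, soil = soil)$g_per_ha_a, 100, 10))
  checks$pass <- abs(checks$computed - checks$reference) <= checks$tolerance
  checks
}
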
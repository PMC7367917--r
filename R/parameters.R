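#' Pb input source term
#'
#' A single lead input pathway onto agricultural soil, characterized by an
#' areal deposition rate in g/(ha a). The built-in scenarios combine three
#' such pathways: rural atmospheric deposition, fertilizer application and
#' hunting gunshot.
#'
#' @param name Pathway label, e.g. `"air"`, `"fertilizer"`, `"gunshot"`.
#' @param rate_g_per_ha_a Areal Pb deposition rate in g/(ha a); must be a
#'   single non-negative number.
#' @return An object of class `"source_term"`.
#' @examples
#' source_term("air", 11)
#' @export
source_term <- function(name, rate_g_per_ha_a) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  rate <- rate_g_per_ha_a
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate))
    stop("source '", name, "': 'rate_g_per_ha_a' must be a single number",
         call. = FALSE)
  if (rate < 0)
    stop("source '", name, "': 'rate_g_per_ha_a' must be non-negative (got ",
         rate, ")", call. = FALSE)
  structure(list(name = name, rate_g_per_ha_a = as.numeric(rate)),
            class = "source_term")
}

#' Physical parameters of the mixed soil layer
#'
#' The model treats the plough layer as a single well-mixed compartment.
#' Its areal dry mass, `mixing_depth_m * bulk_density_kg_m3` (kg/m^2),
#' converts areal deposition rates into concentration rates. The defaults
#' (0.2 m, 1700 kg/m^3, hence 340 kg/m^2) correspond to a standard 20 cm
#' plough layer of a mineral agricultural soil.
#'
#' @param mixing_depth_m Depth of the mixed layer, m.
#' @param bulk_density_kg_m3 Dry bulk density, kg/m^3.
#' @param washout_rate_per_a First-order rate constant for Pb loss by
#'   leaching plus wash-off, 1/a. Default 2.0e-3 (0.2 %/a field estimate).
#' @return An object of class `"soil_params"`.
#' @export
soil_params <- function(mixing_depth_m = 0.2,
                        bulk_density_kg_m3 = 1700,
                        washout_rate_per_a = 2.0e-3) {
  vals <- c(mixing_depth_m = mixing_depth_m,
            bulk_density_kg_m3 = bulk_density_kg_m3,
            washout_rate_per_a = washout_rate_per_a)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0))
    stop("all soil parameters must be strictly positive numbers",
         call. = FALSE)
  structure(as.list(vals), class = "soil_params")
}

#' Areal dry mass of the mixed soil layer
#'
#' @param soil A [soil_params()] object.
#' @return Mass of soil per unit surface, kg/m^2 (340 with the defaults).
#' @export
areal_soil_mass <- function(soil = soil_params()) {
  stopifnot(inherits(soil, "soil_params"))
  soil$mixing_depth_m * soil$bulk_density_kg_m3
}

#' Assemble a deposition scenario
#'
#' A scenario names a combination of Pb input pathways, an initial soil
#' concentration, and the soil-layer parameters. The built-in set
#' (see [pb_scenario()]) follows the convention that suffix "1" means an
#' initial concentration of 0.1 mg/kg (the German control level for crop
#' fields) and suffix "2" means 70 mg/kg (the precautionary level for silt
#' soil).
#'
#' @param name Scenario label, e.g. `"B1"`.
#' @param sources A list of [source_term()] objects (may be empty).
#' @param initial_soil_mg_kg Soil Pb concentration at t = 0, mg/kg.
#' @param soil A [soil_params()] object.
#' @param percentile Which fertilizer-load column the scenario encodes,
#'   `"median"` or `"p90"`; informational for built-in scenarios.
#' @return An object of class `"scenario_spec"`.
#' @seealso [load_scenario()], [pb_scenario()], [total_input()]
#' @export
scenario_spec <- function(name, sources = list(), initial_soil_mg_kg,
                          soil = soil_params(),
                          percentile = c("median", "p90")) {
  percentile <- match.arg(percentile)
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single string", call. = FALSE)
  if (!is.list(sources) || !all(vapply(sources, inherits, TRUE, "source_term")))
    stop("'sources' must be a list of source_term objects", call. = FALSE)
  if (!is.numeric(initial_soil_mg_kg) || length(initial_soil_mg_kg) != 1L ||
      is.na(initial_soil_mg_kg) || initial_soil_mg_kg < 0)
    stop("'initial_soil_mg_kg' must be a single non-negative number",
         call. = FALSE)
  stopifnot(inherits(soil, "soil_params"))
  structure(list(name = name,
                 sources = sources,
                 initial_soil_mg_kg = as.numeric(initial_soil_mg_kg),
                 soil = soil,
                 percentile = percentile),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Pb deposition scenario '", x$name, "'\n", sep = "")
  cat("  initial soil Pb: ", x$initial_soil_mg_kg, " mg/kg\n", sep = "")
  for (s in x$sources)
    cat(sprintf("  source %-12s %8.1f g/(ha a)\n", s$name, s$rate_g_per_ha_a))
  cat("  total input:     ", format(total_input(x)), " g/(ha a)\n", sep = "")
  invisible(x)
}

## ---- scenario configuration files -----------------------------------------

.scenario_keys <- c("name", "initial_soil_mg_kg", "percentile", "sources",
                    "soil")
.source_keys <- c("name", "rate_g_per_ha_a")
.soil_keys <- c("mixing_depth_m", "bulk_density_kg_m3", "washout_rate_per_a")

.check_keys <- function(have, allowed, required, where) {
  unknown <- setdiff(have, allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  missing <- setdiff(required, have)
  if (length(missing))
    stop("missing required key(s) in ", where, ": ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Load a scenario from a YAML configuration file
#'
#' The configuration dialect is plain YAML with units spelled out in key
#' names (e.g. `rate_g_per_ha_a`). Unknown keys are errors, not warnings,
#' so typos cannot silently drop a parameter. Required keys: `name`,
#' `initial_soil_mg_kg`, `sources` (each with `name` and `rate_g_per_ha_a`).
#' Optional: `percentile`, and a `soil` block overriding
#' `mixing_depth_m`, `bulk_density_kg_m3`, `washout_rate_per_a`.
#'
#' @param path Path to a YAML scenario file, or a parsed list.
#' @return A [scenario_spec()] object with defaults applied.
#' @examples
#' f <- system.file("extdata", "scenarios", "A1.yaml", package = "pbfate")
#' load_scenario(f)
#' @export
load_scenario <- function(path) {
  doc <- if (is.list(path)) path else yaml::read_yaml(path)
  if (!is.list(doc)) stop("scenario document must be a key/value mapping",
                          call. = FALSE)
  .check_keys(names(doc), .scenario_keys,
              c("name", "initial_soil_mg_kg", "sources"), "scenario document")
  if (!is.list(doc$sources))
    stop("'sources' must be a sequence of source mappings", call. = FALSE)
  sources <- lapply(seq_along(doc$sources), function(i) {
    s <- doc$sources[[i]]
    .check_keys(names(s), .source_keys, .source_keys,
                paste0("sources[", i, "]"))
    source_term(s$name, s$rate_g_per_ha_a)
  })
  soil_doc <- doc$soil
  soil <- if (is.null(soil_doc)) soil_params() else {
    .check_keys(names(soil_doc), .soil_keys, character(), "soil block")
    do.call(soil_params, soil_doc)
  }
  scenario_spec(name = doc$name,
                sources = sources,
                initial_soil_mg_kg = doc$initial_soil_mg_kg,
                soil = soil,
                percentile = if (is.null(doc$percentile)) "median"
                             else doc$percentile)
}

#' Built-in German farming scenarios
#'
#' Eight reference scenarios combining three input pathways: rural
#' atmospheric deposition (11 g/(ha a), median of the 8--14 range reported
#' for Germany), hunting gunshot (80 g/(ha a), 14,000 t/a spread over the
#' 174 Mha of EU agricultural land), and fertilizer-borne Pb for four
#' conventional farming regimes: A cattle manure + mineral fertilizer,
#' B compost + mineral, C sewage sludge + mineral, D mineral only.
#' The numeric suffix selects the initial soil concentration: 0.1 mg/kg
#' ("1") or 70 mg/kg ("2").
#'
#' @param name Scenario name: one of `"A1"`, `"A2"`, ..., `"D2"`.
#' @param preset Which fertilizer-load column to use: `"median"` (default),
#'   `"p90"` (90th percentile), or `"published"` which mixes the two the
#'   way the reference totals were reported (median for A, 90th percentile
#'   for B, C and D).
#' @return A [scenario_spec()] object ([pb_scenario()]) or a named list of
#'   all eight ([pb_scenarios()]).
#' @examples
#' pb_scenario("B1")
#' total_input(pb_scenario("B1", preset = "published"))  # 405.6
#' @export
pb_scenario <- function(name, preset = c("median", "p90", "published")) {
  preset <- match.arg(preset)
  m <- regmatches(name, regexec("^([ABCD])([12])$", name))[[1]]
  if (length(m) != 3L)
    stop("unknown scenario '", name, "'; available: ",
         paste(names(pb_scenarios()), collapse = ", "), call. = FALSE)
  farming <- m[2]
  fert <- fertilizer_input()
  col <- switch(preset,
                median = "median_g_per_ha_a",
                p90 = "p90_g_per_ha_a",
                published = if (farming == "A") "median_g_per_ha_a"
                            else "p90_g_per_ha_a")
  rate <- fert[fert$scenario == farming, col]
  scenario_spec(
    name = name,
    sources = list(source_term("air", 11),
                   source_term("gunshot", 80),
                   source_term("fertilizer", rate)),
    initial_soil_mg_kg = if (m[3] == "1") 0.1 else 70,
    soil = soil_params(),
    percentile = if (col == "median_g_per_ha_a") "median" else "p90")
}

#' @rdname pb_scenario
#' @export
pb_scenarios <- function(preset = c("median", "p90", "published")) {
  preset <- match.arg(preset)
  nm <- as.vector(outer(c("A", "B", "C", "D"), 1:2, paste0))
  stats::setNames(lapply(nm, pb_scenario, preset = preset), nm)
}

#' Fertilizer-borne Pb input by farming regime
#'
#' @return A data.frame with columns `scenario`, `median_g_per_ha_a`,
#'   `p90_g_per_ha_a`.
#' @export
fertilizer_input <- function() {
  utils::read.csv(system.file("extdata", "fertilizer_input.csv",
                              package = "pbfate"))
}

## ---- unit chain ------------------------------------------------------------

#' Total areal Pb input of a scenario
#'
#' @param scenario A [scenario_spec()].
#' @return Sum of all source rates, g/(ha a).
#' @examples
#' total_input(pb_scenario("A1"))  # 98.5
#' @export
total_input <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!length(scenario$sources)) return(0)
  sum(vapply(scenario$sources, `[[`, numeric(1), "rate_g_per_ha_a"))
}

#' Convert an areal deposition rate into a soil concentration rate
#'
#' The mass balance needs the input expressed per kilogram of soil.
#' 1 g/(ha a) = 0.1 mg/(m^2 a); dividing by the areal soil mass (kg/m^2)
#' yields mg/(kg a). Both the per-area intermediate and the per-mass rate
#' are returned.
#'
#' @param rate_g_per_ha_a Areal deposition rate, g/(ha a).
#' @param soil A [soil_params()] object.
#' @return A list with `mg_per_m2_a` and `mg_per_kg_a`.
#' @examples
#' input_conc_rate(98.5)  # 9.85 mg/(m^2 a), 0.029 mg/(kg a)
#' @export
input_conc_rate <- function(rate_g_per_ha_a, soil = soil_params()) {
  stopifnot(is.numeric(rate_g_per_ha_a), inherits(soil, "soil_params"))
  mg_m2 <- rate_g_per_ha_a * 0.1        # 1000 mg/g / 10000 m2/ha
  list(mg_per_m2_a = mg_m2,
       mg_per_kg_a = mg_m2 / areal_soil_mass(soil))
}

#' Areal deposition rate from a dispersed annual mass
#'
#' Converts an annual Pb tonnage spread over an area into g/(ha a); used
#' e.g. for the 14,000 t/a of hunting gunshot dispersed over 174 Mha of EU
#' agricultural land.
#'
#' @param mass_t_per_a Annual mass, metric tons.
#' @param area_ha Receiving area, hectares.
#' @return Rate, g/(ha a).
#' @examples
#' deposition_rate(14000, 174e6)  # ~80
#' @export
deposition_rate <- function(mass_t_per_a, area_ha) {
  stopifnot(is.numeric(mass_t_per_a), is.numeric(area_ha), all(area_ha > 0))
  mass_t_per_a * 1e6 / area_ha
}
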
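#' Toxicological endpoints for Pb
#'
#' Three benchmark-dose-derived reference points drive the risk
#' characterization: developmental neurotoxicity in children
#' (BMDL01 = 0.5 ug/(kg bw d), the dose equivalent of 12 ug Pb/L blood),
#' chronic nephrotoxicity in adults (BMDL01 = 0.63 ug/(kg bw d),
#' equivalent of 15 ug/L blood), and kidney cancer
#' (BMDL10 = 519 mg/(person d), scaled from a mouse study; treated as a
#' non-threshold endpoint requiring a margin of exposure of 10,000).
#' Blood-lead equivalents are carried as given constants; no toxicokinetic
#' blood-to-dose model is implemented.
#'
#' @param name For `tox_endpoint()`, one of
#'   `"developmental_neurotoxicity"`, `"renal_failure"`, `"kidney_cancer"`.
#' @return `tox_endpoints()`: a data.frame of all endpoints;
#'   `tox_endpoint()`: a single endpoint as an object of class
#'   `"tox_endpoint"`.
#' @export
tox_endpoints <- function() {
  utils::read.csv(system.file("extdata", "endpoints.csv", package = "pbfate"))
}

#' @rdname tox_endpoints
#' @export
tox_endpoint <- function(name) {
  tab <- tox_endpoints()
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown endpoint '", name, "'; available: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  ep <- as.list(row)
  if (ep$required_margin < 1)
    stop("required margin must be >= 1", call. = FALSE)
  structure(ep, class = "tox_endpoint")
}

#' Tolerable daily intake derived from an endpoint's BMDL
#'
#' Threshold endpoints (required margin 1): TDI = BMDL (ug/(kg bw d)) x
#' reference body weight. The cancer endpoint: TDI = BMDL10
#' (mg/(person d)) x 1000 / 10,000, i.e. the intake at which the margin of
#' exposure equals its required minimum.
#'
#' @param endpoint A [tox_endpoint()] or an endpoint name.
#' @return TDI in ug/(person d).
#' @examples
#' tdi("developmental_neurotoxicity")  # 10
#' tdi("renal_failure")                # 37.8 (printed as 38)
#' tdi("kidney_cancer")                # 51.9 (printed as 52)
#' @export
tdi <- function(endpoint) {
  if (is.character(endpoint)) endpoint <- tox_endpoint(endpoint)
  stopifnot(inherits(endpoint, "tox_endpoint"))
  value <- switch(endpoint$bmdl_basis,
    dose_ug_per_kg_bw_d =
      endpoint$bmdl_value * endpoint$body_weight_kg / endpoint$required_margin,
    dose_mg_per_person_d =
      endpoint$bmdl_value * 1000 / endpoint$required_margin,
    stop("unsupported BMDL basis '", endpoint$bmdl_basis,
         "': supply a dose-based BMDL (no blood-to-dose model is ",
         "implemented)", call. = FALSE))
  if (value <= 0) stop("derived TDI must be positive", call. = FALSE)
  value
}

#' Allometric scaling of an animal BMDL to a human per-person dose
#'
#' Generic body-weight conversion: BMDL (mg/(kg bw d)) x body weight /
#' oral scaling factor. Note that the shipped kidney-cancer reference
#' point of 519 mg/(person d) is carried as a published constant and does
#' not equal this formula applied to its mouse point of departure
#' (30.5 x 60/7 = 261.4); the constant is used verbatim for all reference
#' results.
#'
#' @param bmdl_mg_kg_d Animal BMDL, mg/(kg bw d).
#' @param scaling_factor Oral allometric scaling factor (> 0).
#' @param body_weight_kg Human reference body weight, kg.
#' @return Human BMDL, mg/(person d).
#' @examples
#' scale_animal_bmdl(30.5, 7, 60)  # 261.4
#' @export
scale_animal_bmdl <- function(bmdl_mg_kg_d, scaling_factor, body_weight_kg) {
  stopifnot(is.numeric(bmdl_mg_kg_d), bmdl_mg_kg_d > 0,
            is.numeric(scaling_factor), scaling_factor > 0,
            is.numeric(body_weight_kg), body_weight_kg > 0)
  bmdl_mg_kg_d * body_weight_kg / scaling_factor
}

#' Intake-weighted uptake sum of a food basket
#'
#' `sum(daily intake_i x UF_i)` over the crops, kg/d: the linear
#' coefficient linking soil Pb (mg/kg) to dietary Pb intake (mg/d).
#'
#' @param crops A crop table, see [crop_table()].
#' @param population `"adult"` or `"child"`.
#' @return Scalar, kg/d (2.09e-3 for the adult vegetarian basket).
#' @export
intake_weighted_uptake <- function(crops = crop_table(),
                                   population = c("adult", "child")) {
  .validate_crops(crops)
  sum(crops[[.intake_col(population)]] * crops$uptake_factor)
}

#' Daily oral Pb exposure via plant food
#'
#' Exposure = \[Pb\]_soil x sum(daily intake_i x UF_i), converted to
#' ug/(person d). Cooking is assumed not to reduce the Pb load, and plant
#' food is treated as the sole Pb source.
#'
#' @param pb_soil_mg_kg Soil Pb concentration, mg/kg (>= 0).
#' @param crops A crop table.
#' @param population `"adult"` or `"child"`.
#' @return An object of class `"exposure_result"`: list with
#'   `pb_soil_mg_kg`, `intake_weighted_uptake_kg_d`,
#'   `exposure_ug_person_d`, `population`.
#' @examples
#' daily_exposure(18)  # ~38 ug/d for an adult vegetarian
#' @export
daily_exposure <- function(pb_soil_mg_kg, crops = crop_table(),
                           population = c("adult", "child")) {
  population <- match.arg(population)
  stopifnot(is.numeric(pb_soil_mg_kg), length(pb_soil_mg_kg) == 1L,
            pb_soil_mg_kg >= 0)
  swu <- intake_weighted_uptake(crops, population)
  structure(list(pb_soil_mg_kg = pb_soil_mg_kg,
                 intake_weighted_uptake_kg_d = swu,
                 exposure_ug_person_d = pb_soil_mg_kg * swu * 1000,
                 population = population),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf(
    "Oral Pb exposure (%s): %.3g ug/(person d) at %.3g mg/kg soil Pb\n",
    x$population, x$exposure_ug_person_d, x$pb_soil_mg_kg))
  invisible(x)
}

#' Critical soil Pb concentration for an endpoint
#'
#' The soil concentration at which the dietary exposure of the endpoint's
#' population equals its TDI: \[Pb\]_crit = TDI / sum(m_i x UF_i). Values
#' are returned at full precision; the reference tabulation rounds them to
#' integers (18 and 25 mg/kg for the adult endpoints, 5 mg/kg for the
#' child endpoint whose full-precision value is ~5.7).
#'
#' @param endpoint A [tox_endpoint()] or name.
#' @param crops A crop table.
#' @param population Population whose intakes apply; defaults to the
#'   endpoint's own reference population.
#' @return Critical concentration, mg/kg.
#' @examples
#' critical_soil_conc("renal_failure")  # 18.1
#' @export
critical_soil_conc <- function(endpoint, crops = crop_table(),
                               population = NULL) {
  if (is.character(endpoint)) endpoint <- tox_endpoint(endpoint)
  if (is.null(population)) population <- endpoint$population
  swu <- intake_weighted_uptake(crops, population)
  if (swu <= 0)
    stop("intake-weighted uptake sum must be positive", call. = FALSE)
  tdi(endpoint) / (swu * 1000)
}

#' Margin of safety / margin of exposure
#'
#' Ratio of the endpoint's reference point (expressed per person and day)
#' to the estimated daily exposure. Threshold endpoints yield a margin of
#' safety (MOS, tolerable at >= 1); the genotoxic-carcinogenicity endpoint
#' yields a margin of exposure (MOE, required >= 10,000).
#'
#' @param exposure An [daily_exposure()] result, or exposure in
#'   ug/(person d).
#' @param endpoint A [tox_endpoint()] or name.
#' @return An object of class `"risk_margin"`: list with `margin`, `type`
#'   (`"MOS"` or `"MOE"`), `required`, `acceptable`, and `zero_exposure`
#'   flagging an infinite margin at zero exposure.
#' @examples
#' safety_margin(daily_exposure(18), "renal_failure")
#' @export
safety_margin <- function(exposure, endpoint) {
  if (inherits(exposure, "exposure_result"))
    exposure <- exposure$exposure_ug_person_d
  stopifnot(is.numeric(exposure), length(exposure) == 1L, exposure >= 0)
  if (is.character(endpoint)) endpoint <- tox_endpoint(endpoint)
  ref_ug <- switch(endpoint$bmdl_basis,
                   dose_ug_per_kg_bw_d =
                     endpoint$bmdl_value * endpoint$body_weight_kg,
                   dose_mg_per_person_d = endpoint$bmdl_value * 1000,
                   stop("unsupported BMDL basis", call. = FALSE))
  margin <- if (exposure == 0) Inf else ref_ug / exposure
  structure(list(margin = margin,
                 type = if (endpoint$required_margin > 1) "MOE" else "MOS",
                 required = endpoint$required_margin,
                 acceptable = margin >= endpoint$required_margin,
                 zero_exposure = exposure == 0,
                 endpoint = endpoint$name),
            class = "risk_margin")
}

#' @export
print.risk_margin <- function(x, ...) {
  cat(sprintf("%s = %.3g (required >= %g): %s%s\n", x$type, x$margin,
              x$required,
              if (x$acceptable) "acceptable" else "NOT acceptable",
              if (x$zero_exposure) " [zero exposure]" else ""))
  invisible(x)
}

#' Maximum permissible areal Pb input
#'
#' The input that keeps the equilibrium concentration IN/k at the critical
#' level: IN* = critical x k in mg/(kg a), converted through the areal
#' soil mass into mg/(m^2 a) and g/(ha a). With the lowest critical level
#' (5 mg/kg) and the reference parameters this is about 10 mg/(m^2 a) =
#' 100 g/(ha a).
#'
#' @param critical_mg_kg Critical soil concentration, mg/kg (>= 0).
#' @param k Total loss rate constant, 1/a.
#' @param soil A [soil_params()] object.
#' @return List with `mg_per_kg_a`, `mg_per_m2_a`, `g_per_ha_a`.
#' @examples
#' max_permissible_input(5)$g_per_ha_a  # ~100
#' @export
max_permissible_input <- function(critical_mg_kg, k = rate_constant(),
                                  soil = soil_params()) {
  stopifnot(is.numeric(critical_mg_kg), critical_mg_kg >= 0,
            is.numeric(k), k > 0)
  mg_kg_a <- critical_mg_kg * k
  mg_m2_a <- mg_kg_a * areal_soil_mass(soil)
  list(mg_per_kg_a = mg_kg_a, mg_per_m2_a = mg_m2_a,
       g_per_ha_a = mg_m2_a * 10)
}
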
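#' Crop parameter table
#'
#' Uptake factors (UF, mg/kg plant per mg/kg soil), annual edible yields
#' (Y, kg/(m^2 a)) and daily intakes for the four modeled crop groups:
#' cereals, potatoes (peeled tuber), leafy vegetables and other vegetables.
#' Intakes are the EU vegetarian food basket for a 60 kg adult and the
#' recommended food basket for a 20 kg child.
#'
#' Two UF assignments circulate for potatoes and leafy vegetables
#' (1.0e-2/3.0e-3 versus the swapped 3.0e-3/1.0e-2). Only the default
#' `"table"` assignment is consistent with the reference removal-rate
#' constant of 4.01e-3 1/a and with the published critical soil
#' concentrations; the alternative is available as `uf_source = "equations"`
#' for sensitivity analysis.
#'
#' @param uf_source Which uptake-factor assignment to use: `"table"`
#'   (default) or `"equations"`.
#' @return A data.frame with columns `name`, `uptake_factor`,
#'   `yield_kg_m2_a`, `intake_adult_kg_d`, `intake_child_kg_d`.
#' @export
crop_table <- function(uf_source = c("table", "equations")) {
  uf_source <- match.arg(uf_source)
  tab <- utils::read.csv(system.file("extdata", "crops.csv",
                                     package = "pbfate"))
  if (uf_source == "equations") tab$uptake_factor <- tab$uptake_factor_eq
  tab$uptake_factor_eq <- NULL
  .validate_crops(tab)
  tab
}

.validate_crops <- function(crops) {
  need <- c("name", "uptake_factor", "yield_kg_m2_a",
            "intake_adult_kg_d", "intake_child_kg_d")
  if (!is.data.frame(crops) || !all(need %in% names(crops)))
    stop("crop table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(crops$uptake_factor < 0) || any(crops$uptake_factor > 1))
    stop("uptake factors must lie in [0, 1]", call. = FALSE)
  if (any(crops$yield_kg_m2_a <= 0))
    stop("yields must be strictly positive", call. = FALSE)
  if (any(crops$intake_adult_kg_d < 0) || any(crops$intake_child_kg_d < 0))
    stop("intakes must be non-negative", call. = FALSE)
  invisible(crops)
}

.intake_col <- function(population = c("adult", "child")) {
  paste0("intake_", match.arg(population), "_kg_d")
}

#' Surface weighting factors of a food basket
#'
#' The cropped area is assumed to be planted so that it exactly supplies
#' the daily plant-food demand: each crop needs m2_i = DI_i / Y_i square
#' metres, and its surface weight is P_i = m2_i / sum(m2_i). With the
#' adult vegetarian basket the cereals demand of 0.283 kg/d at a yield of
#' 0.8 kg/(m^2 a) requires 0.354 m^2, i.e. P = 0.677 of the cropped area.
#'
#' @param crops A crop table, see [crop_table()].
#' @param population Whose intakes define the demand: `"adult"` (default,
#'   the basis of the reference soil balance) or `"child"`.
#' @return Named numeric vector of weights summing to 1, with the per-crop
#'   land requirement (m^2) attached as attribute `"m2"`.
#' @examples
#' surface_weights()  # cereals 0.677, potatoes 0.036, ...
#' @export
surface_weights <- function(crops = crop_table(),
                            population = c("adult", "child")) {
  .validate_crops(crops)
  di <- crops[[.intake_col(population)]]
  if (all(di == 0))
    stop("all intakes are zero: surface weights are undefined", call. = FALSE)
  m2 <- di / crops$yield_kg_m2_a
  p <- m2 / sum(m2)
  structure(stats::setNames(p, crops$name),
            m2 = stats::setNames(m2, crops$name))
}

#' Food basket with surface weights
#'
#' Bundles a crop table with the surface weights derived from a
#' population's intakes. The reference soil balance always uses the
#' adult-vegetarian weights, since those define the planting pattern.
#'
#' @inheritParams surface_weights
#' @return An object of class `"crop_basket"`: list with elements `crops`,
#'   `population`, `weights`, `m2`.
#' @export
crop_basket <- function(crops = crop_table(),
                        population = c("adult", "child")) {
  population <- match.arg(population)
  w <- surface_weights(crops, population)
  stopifnot(abs(sum(w) - 1) < 1e-12, all(w >= 0))
  structure(list(crops = crops, population = population,
                 weights = as.numeric(w), m2 = attr(w, "m2")),
            class = "crop_basket")
}

#' Crop-removal rate constant
#'
#' Harvesting the edible parts removes Pb from the field; non-edible
#' residues are assumed to stay on the soil. Each crop contributes
#' UF_i * P_i * Y_i, and the sum over the basket is the first-order
#' plant-uptake sink of the soil mass balance. With the reference
#' parameters it evaluates to 4.01e-3 1/a.
#'
#' @param basket A [crop_basket()].
#' @return Removal rate constant, 1/a.
#' @examples
#' removal_rate_constant(crop_basket())  # 4.01e-3
#' @export
removal_rate_constant <- function(basket = crop_basket()) {
  stopifnot(inherits(basket, "crop_basket"))
  sum(basket$crops$uptake_factor * basket$weights *
        basket$crops$yield_kg_m2_a)
}

# sublinear soil-to-plant coefficients [Pb]_plant = a * [Pb]_soil^b;
# published only for leafy vegetables
.sublinear_coefs <- list(
  leafy_vegetables = c(a = 0.03, b = 0.33)
)

#' Pb concentration in edible plant tissue
#'
#' The default transfer model is linear, `UF * [Pb]_soil`; a sublinear
#' power-law alternative `a * [Pb]_soil^b` (saturating uptake at high soil
#' Pb) is available for the crops where its coefficients have been
#' published (currently leafy vegetables only, a = 0.03, b = 0.33).
#'
#' @param pb_soil_mg_kg Soil Pb concentration(s), mg/kg, non-negative.
#' @param crop A crop name found in `crops`, or a single-row crop table.
#' @param model `"linear"` (default) or `"sublinear"`.
#' @param crops Crop table used for lookup by name.
#' @return Plant Pb concentration(s), mg/kg.
#' @examples
#' plant_concentration(10, "leafy_vegetables")  # 0.03
#' @export
plant_concentration <- function(pb_soil_mg_kg, crop,
                                model = c("linear", "sublinear"),
                                crops = crop_table()) {
  model <- match.arg(model)
  if (any(pb_soil_mg_kg < 0))
    stop("'pb_soil_mg_kg' must be non-negative", call. = FALSE)
  if (is.character(crop)) {
    row <- crops[crops$name == crop, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("unknown crop '", crop, "'; available: ",
           paste(crops$name, collapse = ", "), call. = FALSE)
  } else {
    row <- .validate_crops(crop)
    if (nrow(row) != 1L) stop("'crop' must be a single crop", call. = FALSE)
  }
  if (model == "linear") return(row$uptake_factor * pb_soil_mg_kg)
  cf <- .sublinear_coefs[[row$name]]
  if (is.null(cf))
    stop("no sublinear transfer coefficients available for '", row$name,
         "'", call. = FALSE)
  cf[["a"]] * pb_soil_mg_kg^cf[["b"]]
}
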
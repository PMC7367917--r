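---
title: "Modelling long-term lead accumulation in farmland soil and the dietary risk it implies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term lead accumulation in farmland soil and the dietary risk it implies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbfate)
```

## The question

Lead reaches agricultural soil continuously — as rural atmospheric
deposition, with fertilizers (above all compost and sewage sludge), and as
gunshot dispersed by hunting. Individually these fluxes are small, but the
removal processes are even slower, so the question is whether present-day
inputs can, over decades to centuries, push soil Pb to levels at which the
diet grown on that soil is no longer safe. `pbfate` answers this with a
deliberately minimal, fully deterministic model chain: soil mass balance →
soil-to-plant transfer → dietary exposure → comparison with
benchmark-dose-derived reference values.

## The soil mass balance

The plough layer (default 0.2 m deep, dry bulk density 1700 kg/m³, hence
340 kg of soil per m²) is treated as one well-mixed compartment. Input is a
constant concentration rate IN (mg Pb per kg soil per year), obtained from
the areal deposition rate via the areal soil mass. Removal is first order
with two contributions:

* **wash-out** (leaching plus wash-off), rate constant 2.0 × 10⁻³ a⁻¹,
  a field-derived estimate of ~0.2 % of the soil inventory lost per year;
* **crop removal**: harvesting the edible plant parts exports
  Σᵢ (UFᵢ · Pᵢ · Yᵢ) ≈ 4.01 × 10⁻³ a⁻¹, where UF is the soil-to-plant
  uptake factor, Y the edible yield per area and P the fraction of the
  cropped surface devoted to crop *i*. Non-edible residues are assumed to
  stay on the field.

The balance d[Pb]/dt = IN − k·[Pb] with k = 6 × 10⁻³ a⁻¹ has the closed
form

[Pb](t) = IN/k · (1 − e^(−kt)) + [Pb](0) · e^(−kt),

an exponential relaxation from the initial concentration toward the
equilibrium IN/k with time constant 1/k ≈ 167 a — hence the model's
headline message that equilibria lie centuries away. `rate_constant()`
defaults to the rounded k = 0.006 a⁻¹ because the reference closed-form
solution hard-codes it; the exact sum 6.01 × 10⁻³ is available via
`mode = "exact"` for sensitivity analysis (the difference is below 0.2 %
everywhere).

```{r}
m <- soil_pb_model(pb_scenario("B1"))
summary(m)
predict(m, times = c(10, 100))
time_to_concentration(m, 5)
```

## Scenarios

Eight built-in scenarios combine three pathways: air deposition
(11 g/(ha a), the midpoint of the 8–14 range reported for rural Germany),
gunshot (80 g/(ha a): 14,000 t/a over 174 Mha of EU farmland,
`deposition_rate(14000, 174e6)`), and fertilizer-borne Pb for four farming
regimes — A manure + mineral, B compost + mineral, C sewage sludge +
mineral, D mineral only. Suffix 1 starts at 0.1 mg/kg (the German control
level for crop fields), suffix 2 at 70 mg/kg (the precautionary level for
silt soil). Scenarios are also readable from YAML files
(`load_scenario()`); unknown keys are errors rather than warnings so a
misspelled parameter cannot silently fall back to a default.

The fertilizer source tables carry a median and a 90th-percentile column,
and the published input totals mix them (median for A, 90th percentile for
B–D) while the published concentration-rate table follows the medians
throughout. Because neither choice can be called wrong, both columns ship,
`preset = "median"` is the default, and `preset = "published"` reproduces
the reported totals (98.5, 405.6, 171.7, 98.8 g/(ha a)). A second known
inconsistency: the tabulated per-area rate for regime D is 9.9 mg/(m² a)
where the median arithmetic gives 9.72; the package reports the arithmetic
value (the per-mass rate, 0.029 mg/(kg a), agrees either way).

## Soil-to-plant transfer and the food basket

Transfer is linear by default, [Pb]_plant = UF · [Pb]_soil, with UF from
field studies: cereals 3 × 10⁻⁴, potatoes 1 × 10⁻², leafy vegetables
3 × 10⁻³, other vegetables 8 × 10⁻⁴. Two caveats are built in explicitly:

* The source equations and the source table disagree on which of the
  potato/leafy pair carries 10⁻² and which 3 × 10⁻³. Only the table
  assignment reproduces the removal constant 4.01 × 10⁻³ a⁻¹ and the
  critical concentrations of 18 and 25 mg/kg, so it is the default; the
  swapped assignment is available as `crop_table(uf_source = "equations")`.
* A sublinear (saturating) alternative [Pb]_plant = 0.03 · [Pb]_soil^0.33
  exists for leafy vegetables, the only crop with published coefficients;
  requesting it elsewhere is an error rather than an extrapolation. The
  linear default therefore tends to *under*estimate plant Pb at low soil
  concentrations.

The cropped area is assumed planted to exactly supply the adult-vegetarian
daily demand, giving surface weights Pᵢ = (DIᵢ/Yᵢ)/Σ(DIⱼ/Yⱼ) = 0.677,
0.036, 0.203, 0.084. The child basket supplies its own intakes for
exposure, but the soil balance always uses the adult-derived weights: the
planting pattern is a property of the farm, not of the consumer. Whether
UF is on a fresh- or dry-weight basis is not stated in its sources; the
package treats intake and UF as one consistent basis with no conversion.

## Exposure and risk characterization

Daily oral exposure is [Pb]_soil × Σᵢ (mᵢ · UFᵢ) with mᵢ the daily intake;
the adult-vegetarian sum is 2.09 × 10⁻³ kg/d. Cooking is assumed not to
remove Pb, and plant food is treated as the only Pb source — both
assumptions make the margins conservative in opposite directions and are
stated limitations, not options.

Three endpoints drive the assessment. The blood-lead equivalents of the
two epidemiological BMDLs are carried as given constants (no toxicokinetic
model is implemented):

| endpoint | reference point | TDI |
|---|---|---|
| developmental neurotoxicity (child, 20 kg) | BMDL01 0.5 µg/(kg bw d) | 10 µg/d |
| renal failure (adult, 60 kg) | BMDL01 0.63 µg/(kg bw d) | 37.8 µg/d |
| kidney cancer (adult) | BMDL10 519 mg/(person d), MOE ≥ 10,000 | 51.9 µg/d |

The kidney-cancer point of departure of 519 mg/(person d) is a published
constant that does not equal the generic allometric conversion of its
mouse origin (30.5 mg/(kg d) × 60 kg / 7 = 261.4); `scale_animal_bmdl()`
implements the generic formula, but the constant is used verbatim for all
reference results.

Inverting the exposure equation gives the critical soil concentration
TDI/Σ(mᵢ·UFᵢ): 18.1 mg/kg (renal), 24.8 (cancer), 5.72 (child
neurodevelopment). `critical_soil_conc()` returns full precision; the
reference tabulation rounds these to 18, 25 and — nonstandardly — 5. The
downstream results (time-to-critical, maximum permissible input of about
10 mg/(m² a) = 100 g/(ha a)) follow the tabulated 5 mg/kg, and
`reference_checks()` compares the child value at a tolerance of 1 mg/kg to
cover exactly this rounding gap.

```{r}
risk_report(c("B1", "C1"))
```

`time_to_concentration()` refuses targets at or beyond the equilibrium
IN/k (which the trajectory approaches but never attains) and reports the
equilibrium in the error message so callers can branch on reachability;
`risk_report()` encodes unreachable critical levels as `NA` years and an
already-exceeded level as 0.

## Numerical choices

Everything is closed-form; the only numerics are the rounding conventions
above and the cross-check integrator. `simulate(..., method = "numeric")`
integrates the balance ODE with `deSolve`'s lsoda (rtol 1e-10, atol 1e-12)
and agrees with the closed form to better than 10⁻⁸ relative over 600
years — its only purpose is to guard the algebra of the exact solution.
The default simulation horizon of 600 years with 601 grid points is where
the reference scenarios sit within ~3 % of equilibrium; tests use the same
sizes, which run in seconds. The pipeline contains no randomness at all;
seed arguments exist in the command-line driver for interface parity and
affect nothing.

## What the self-checks do and do not show

`reference_checks()` recomputes ~29 headline numbers of the reference
assessment (input totals, unit chain, sink coefficients, surface weights,
TDIs, critical levels, century-scale concentrations, times to critical,
permissible input) from the shipped parameterization and compares them at
the printed precision (±10 % for values published as "approximately").
Passing shows the implementation reproduces the reference arithmetic under
its stated conditions. It does not validate the model against field data:
constant input over centuries, homogeneous gunshot deposition, linear
uptake, a fixed planting pattern and plant food as the sole exposure route
are all simplifications, and the known figure-level statement that an
initial concentration of 5 mg/kg leaves "1 and 6 years" to the 5 mg/kg
critical level is not reproduced, because the inversion formula gives 0
when target equals start.
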
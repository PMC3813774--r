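#' Drinking-water dose received, mg/kg/day
#'
#' For a drug administered via drinking water, the daily dose per body mass
#' is `concentration (mg/ml) x intake (ml/day) / body mass (kg)`. Worked
#' case: a 25 g mouse drinking 3-4 ml/day of a 0.2 mg/ml solution receives
#' 24-32 mg/kg/day — short of a 50 mg/kg/day target, which motivates doubling
#' the concentration to 0.4 mg/ml.
#'
#' @param concentration Drug concentration in the water (mg/ml), >= 0.
#' @param intake Daily water intake (ml/day), >= 0.
#' @param body_mass Body mass (g), > 0.
#' @return Dose (mg/kg/day); vectorised over all arguments.
#' @export
#' @examples
#' dose_mg_per_kg_day(0.2, 3:4, 25)  # 24, 32
dose_mg_per_kg_day <- function(concentration, intake, body_mass) {
  if (any(concentration < 0) || any(intake < 0)) {
    abort("`concentration` and `intake` must be >= 0.")
  }
  if (any(body_mass <= 0)) abort("`body_mass` must be > 0 g.")
  concentration * intake / (body_mass / 1000)
}

#' Drinking-water concentration required for a target dose
#'
#' Algebraic inverse of [dose_mg_per_kg_day()]:
#' `concentration = target x (body mass / 1000) / intake`. Exact round trip:
#' `dose_mg_per_kg_day(required_concentration(d, i, m), i, m) == d`.
#'
#' @param target Target dose (mg/kg/day), >= 0.
#' @param intake Daily water intake (ml/day), > 0.
#' @param body_mass Body mass (g), > 0.
#' @return Required concentration (mg/ml); vectorised.
#' @export
#' @examples
#' required_concentration(50, 3.125, 25)  # 0.4 mg/ml
required_concentration <- function(target, intake, body_mass) {
  if (any(target < 0)) abort("`target` must be >= 0.")
  if (any(intake <= 0)) abort("`intake` must be > 0 ml/day.")
  if (any(body_mass <= 0)) abort("`body_mass` must be > 0 g.")
  target * (body_mass / 1000) / intake
}
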
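#' Physical activity level multipliers
#'
#' The conventional multipliers used with the Mifflin-St Jeor equation:
#' sedentary 1.2, light 1.375, moderate 1.55, heavy 1.725, athlete 1.9.
#' Override by passing a named vector to [tdee()].
#'
#' @export
pal_coefficients <- function() {
  c(sedentary = 1.2, light = 1.375, moderate = 1.55, heavy = 1.725, athlete = 1.9)
}

#' Basal metabolic rate (Mifflin-St Jeor)
#'
#' `BMR = 625 H + 10 W - 5 A + 5` for men and `... - 161` for women, with
#' height `H` in metres, weight `W` in kilograms and age `A` in years;
#' result in kcal/day.
#'
#' @param profile a [subject_profile()].
#' @return kcal/day.
#' @export
bmr <- function(profile) {
  if (!inherits(profile, "cogscreen_profile")) abort_validation("profile must be a cogscreen_profile")
  base <- 625 * profile$height_m + 10 * profile$weight_kg - 5 * profile$age_years
  base + if (profile$gender == "man") 5 else -161
}

#' Total daily energy expenditure
#'
#' `TDEE = BMR * PAL` with the configured activity multiplier.
#'
#' @param bmr_value basal metabolic rate in kcal/day, positive.
#' @param pal physical activity level name.
#' @param coefficients named PAL multiplier vector.
#' @return kcal/day.
#' @export
tdee <- function(bmr_value, pal, coefficients = pal_coefficients()) {
  if (bmr_value <= 0) abort_domain("bmr_value must be positive")
  if (!pal %in% names(coefficients)) abort_domain(sprintf("unknown PAL '%s'", pal))
  bmr_value * coefficients[[pal]]
}

#' Daily calories gained from the food diary
#'
#' Sum over diary items of `grams * kcal_per_100g / 100`.
#'
#' @param items data frame with columns `grams` and `kcal_per_100g` (an
#'   empty diary is valid and yields 0).
#' @return kcal.
#' @export
p_gained <- function(items) {
  if (is.null(items) || NROW(items) == 0) return(0)
  if (any(items$grams < 0)) abort_domain("grams must be non-negative")
  sum(items$grams * items$kcal_per_100g / 100)
}

#' Daily calories burned from the activity diary
#'
#' Sum over activities of `MET * W * D / 60` with weight `W` in kg and
#' duration `D` in minutes.
#'
#' @param activities data frame with columns `met` and `minutes`.
#' @param weight_kg subject weight, positive.
#' @return kcal.
#' @export
p_burned <- function(activities, weight_kg) {
  if (weight_kg <= 0) abort_domain("weight_kg must be positive")
  if (is.null(activities) || NROW(activities) == 0) return(0)
  sum(activities$met * weight_kg * activities$minutes / 60)
}

#' Daily calorie balance
#'
#' `P_balance = P_gained - P_burned`; negative values signal the negative
#' energy balance characteristic of hypermetabolic CNS disorders.
#'
#' @param gained,burned kcal.
#' @return kcal (exact difference).
#' @export
p_balance <- function(gained, burned) gained - burned

#' Full energy report for a session's diary task
#'
#' @param profile a [subject_profile()].
#' @param food food diary (see [p_gained()]).
#' @param activities activity diary (see [p_burned()]).
#' @param coefficients PAL multipliers.
#' @return tibble with one row: `bmr`, `tdee`, `p_gained`, `p_burned`,
#'   `p_balance` (all kcal or kcal/day).
#' @export
energy_report <- function(profile, food = NULL, activities = NULL,
                          coefficients = pal_coefficients()) {
  b <- bmr(profile)
  g <- p_gained(food)
  u <- p_burned(activities, profile$weight_kg)
  tibble::tibble(bmr = b, tdee = tdee(b, profile$pal, coefficients),
                 p_gained = g, p_burned = u, p_balance = p_balance(g, u))
}
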
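# Pediatric dose rules: the Salisbury weight rule, plain per-kg
# extrapolation, and clearance-ratio reference dosing.

#' Percent of the adult dose under the Salisbury rule
#'
#' For children below 30 kg the pediatric dose is `2 x weight` percent of
#' the adult dose; from 30 kg up to (but below) 70 kg it is `weight + 30`
#' percent. The two segments agree at 30 kg (both give 60%), so the rule
#' is continuous and strictly increasing up to 70 kg. At and above 70 kg
#' the percent is capped at 100 with a warning: the rule is defined only
#' below the adult reference weight and extrapolating beyond the full
#' adult dose would be unsafe.
#'
#' @param weight_kg Positive body weight(s) in kilograms. Vectorised.
#' @return Percent of the adult dose, in (0, 100].
#' @examples
#' salisbury_percent(10)  # 20
#' salisbury_percent(50)  # 80
#' salisbury_percent(30)  # 60, both segments agree
#' @export
salisbury_percent <- function(weight_kg) {
  check_positive(weight_kg, "weight_kg")
  if (any(weight_kg >= 70)) {
    rlang::warn(
      "Weight at or above the 70 kg adult reference: percent capped at 100.",
      class = "peddose_adult_weight_cap"
    )
  }
  pct <- ifelse(weight_kg < 30, 2 * weight_kg, weight_kg + 30)
  pmin(pct, 100)
}

#' Convert a dose to an absolute amount
#'
#' Per-kg doses are multiplied by the body weight; absolute doses pass
#' through unchanged.
#'
#' @param dose A [dose_spec()].
#' @param weight_kg Positive body weight(s) in kg. Vectorised.
#' @return Absolute dose amount(s) in the dose's mass unit.
#' @examples
#' to_absolute(dose_spec(400, "per_kg"), 70)  # 28000
#' @export
to_absolute <- function(dose, weight_kg) {
  if (!inherits(dose, "dose_spec")) {
    stop_invalid("`dose` must be a dose_spec object.")
  }
  check_positive(weight_kg, "weight_kg")
  if (dose$basis == "per_kg") dose$amount * weight_kg else rep(dose$amount, length(weight_kg))
}

#' Predict a pediatric dose with the Salisbury rule
#'
#' Applies the percent-of-adult-dose rule to the absolute adult dose and
#' reports the child dose on both bases. A notable algebraic property:
#' with a 70 kg adult reference, the predicted per-kg dose for any child
#' below 30 kg is exactly 1.4 times the adult per-kg dose, independent of
#' the child's weight (2W% of 70d, divided by W, is 1.4d).
#'
#' @param adult An [adult_reference()].
#' @param child_weight_kg Positive child body weight(s) in kg. Vectorised.
#' @return A tibble with one row per child weight: `child_weight_kg`,
#'   `percent_of_adult`, `dose_abs` (absolute amount), `dose_per_kg`,
#'   and `unit` (mass unit of the absolute dose).
#' @examples
#' # 400 mg/kg adult regimen, 2 kg neonate: 560 mg/kg (1120 mg)
#' salisbury_dose(adult_reference(dose_spec(400, "per_kg")), 2)
#' @export
salisbury_dose <- function(adult, child_weight_kg) {
  if (!inherits(adult, "adult_reference")) {
    stop_invalid("`adult` must be an adult_reference object.")
  }
  check_positive(child_weight_kg, "child_weight_kg")
  adult_abs <- to_absolute(adult$dose, adult$weight_kg)
  pct <- salisbury_percent(child_weight_kg)
  # multiply before dividing: keeps integer-valued percents exact, so
  # boundary cases (e.g. a fold error of exactly 1.3) classify cleanly
  dose_abs <- pct * adult_abs / 100
  mass_unit <- sub("/kg$", "", adult$dose$unit)
  tibble::tibble(
    child_weight_kg = as.numeric(child_weight_kg),
    percent_of_adult = pct,
    dose_abs = dose_abs,
    dose_per_kg = dose_abs / child_weight_kg,
    unit = mass_unit
  )
}

#' Per-kilogram extrapolated pediatric dose
#'
#' The linear scaling the Salisbury rule is designed to avoid below 30
#' kg: the child receives the adult mg/kg dose unchanged.
#'
#' @param adult_dose A [dose_spec()] for the adult regimen.
#' @param adult_weight_kg Adult body weight in kg (needed when the adult
#'   dose is absolute; default 70).
#' @param child_weight_kg Positive child weight(s) in kg. Vectorised.
#' @return A tibble with `child_weight_kg`, `dose_per_kg`, `dose_abs`.
#' @examples
#' perkg_dose(dose_spec(7000, "absolute"), 70, 10)  # 100 mg/kg, 1000 mg
#' @export
perkg_dose <- function(adult_dose, adult_weight_kg = 70, child_weight_kg) {
  if (!inherits(adult_dose, "dose_spec")) {
    stop_invalid("`adult_dose` must be a dose_spec object.")
  }
  check_positive(adult_weight_kg, "adult_weight_kg")
  check_positive(child_weight_kg, "child_weight_kg")
  per_kg <- if (adult_dose$basis == "per_kg") {
    adult_dose$amount
  } else {
    adult_dose$amount / adult_weight_kg
  }
  tibble::tibble(
    child_weight_kg = as.numeric(child_weight_kg),
    dose_per_kg = per_kg,
    dose_abs = per_kg * child_weight_kg
  )
}

#' Clearance-ratio pediatric dose
#'
#' The reference standard the rule is judged against:
#' `dose in children = adult dose x (pediatric CL / adult CL)`.
#' Both clearances must share the same basis and unit; a mismatch is a
#' hard error because it signals a silent per-kg/absolute confusion, and
#' the ratio would be meaningless.
#'
#' @param adult_dose A [dose_spec()] for the adult regimen.
#' @param cl_child Pediatric [clearance_spec()].
#' @param cl_adult Adult [clearance_spec()].
#' @return A [dose_spec()] with the same basis and unit as `adult_dose`.
#' @examples
#' cl_based_dose(
#'   dose_spec(100, "absolute"),
#'   clearance_spec(0.3, "absolute"),
#'   clearance_spec(1, "absolute")
#' ) # 30 mg
#' @export
cl_based_dose <- function(adult_dose, cl_child, cl_adult) {
  if (!inherits(adult_dose, "dose_spec")) {
    stop_invalid("`adult_dose` must be a dose_spec object.")
  }
  if (!inherits(cl_child, "clearance_spec") || !inherits(cl_adult, "clearance_spec")) {
    stop_invalid("`cl_child` and `cl_adult` must be clearance_spec objects.")
  }
  if (cl_child$basis != cl_adult$basis || cl_child$unit != cl_adult$unit) {
    stop_basis_mismatch(sprintf(
      "Clearance basis/unit mismatch: child is %s (%s), adult is %s (%s).",
      cl_child$basis, cl_child$unit, cl_adult$basis, cl_adult$unit
    ))
  }
  dose_spec(
    amount = adult_dose$amount * cl_child$value / cl_adult$value,
    basis = adult_dose$basis,
    unit = adult_dose$unit
  )
}
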
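# Domain value types: doses, clearances, subjects, adult references.
#
# Dose and clearance amounts always travel with an explicit basis
# ("per_kg" or "absolute") so per-kilogram and total quantities can never
# be silently confused -- the central bookkeeping hazard when mixing
# mg/kg label doses with absolute clearance arithmetic.

#' Create a dose specification
#'
#' A dose amount with an explicit basis. Per-kilogram doses (e.g. 400
#' mg/kg) and absolute doses (e.g. 28,000 mg) are distinct types of
#' quantity; every operation that consumes a dose requires the basis to
#' be stated rather than guessed from magnitude.
#'
#' @param amount Positive dose amount.
#' @param basis `"per_kg"` or `"absolute"`.
#' @param unit Unit label; defaults to `"mg/kg"` for per-kg doses and
#'   `"mg"` for absolute doses.
#' @return An object of class `dose_spec` with fields `amount`, `basis`,
#'   `unit`.
#' @examples
#' dose_spec(400, "per_kg")
#' dose_spec(100, "absolute", unit = "mg")
#' @export
dose_spec <- function(amount, basis = c("per_kg", "absolute"), unit = NULL) {
  basis <- match.arg(basis)
  if (length(amount) != 1L) {
    stop_invalid("`amount` must be a single value.")
  }
  check_positive(amount, "amount")
  if (is.null(unit)) {
    unit <- if (basis == "per_kg") "mg/kg" else "mg"
  }
  structure(
    list(amount = as.numeric(amount), basis = basis, unit = unit),
    class = "dose_spec"
  )
}

#' @export
print.dose_spec <- function(x, ...) {
  cat(sprintf("<dose> %s %s (%s)\n", format(x$amount), x$unit, x$basis))
  invisible(x)
}

#' Create a clearance specification
#'
#' A clearance value (volume of plasma cleared per unit time) with an
#' explicit basis. Clearance-ratio dosing requires the pediatric and
#' adult clearances to share basis and unit, so both are recorded.
#'
#' @param value Positive clearance value.
#' @param basis `"per_kg"` or `"absolute"`.
#' @param unit Unit label; defaults to `"mL/h/kg"` for per-kg values and
#'   `"mL/h"` for absolute values.
#' @return An object of class `clearance_spec`.
#' @examples
#' clearance_spec(2, "per_kg")
#' clearance_spec(140, "absolute")
#' @export
clearance_spec <- function(value, basis = c("per_kg", "absolute"), unit = NULL) {
  basis <- match.arg(basis)
  if (length(value) != 1L) {
    stop_invalid("`value` must be a single value.")
  }
  check_positive(value, "value")
  if (is.null(unit)) {
    unit <- if (basis == "per_kg") "mL/h/kg" else "mL/h"
  }
  structure(
    list(value = as.numeric(value), basis = basis, unit = unit),
    class = "clearance_spec"
  )
}

#' @export
print.clearance_spec <- function(x, ...) {
  cat(sprintf("<clearance> %s %s (%s)\n", format(x$value), x$unit, x$basis))
  invisible(x)
}

#' Age classes recognised by the package
#'
#' Preterm and term neonates are reported as a separate weight stratum in
#' summaries; `child` and `adolescent` fall into the below-30-kg or
#' 30-kg-and-above strata by body weight.
#'
#' @export
age_classes <- c("preterm_neonate", "term_neonate", "child", "adolescent")

#' Create a pediatric subject
#'
#' @param weight_kg Positive body weight in kilograms. Neonates (preterm
#'   or term) must weigh at most 5 kg.
#' @param age_class One of [age_classes].
#' @return An object of class `subject`.
#' @examples
#' subject(20)
#' subject(2, "preterm_neonate")
#' @export
subject <- function(weight_kg, age_class = "child") {
  age_class <- match.arg(age_class, age_classes)
  check_positive(weight_kg, "weight_kg")
  if (age_class %in% c("preterm_neonate", "term_neonate") && weight_kg > 5) {
    stop_invalid(sprintf(
      "Neonatal weight must be at most 5 kg; got %s kg.", format(weight_kg)
    ))
  }
  structure(
    list(weight_kg = as.numeric(weight_kg), age_class = age_class),
    class = "subject"
  )
}

#' Create an adult reference regimen
#'
#' The adult dose (and optionally adult clearance) against which a
#' pediatric dose is predicted. The reference body weight defaults to 70
#' kg, the weight at which the percent-of-adult-dose rule reaches 100%.
#'
#' @param dose A [dose_spec()] for the adult regimen.
#' @param weight_kg Adult reference body weight in kg (default 70).
#' @param clearance Optional adult [clearance_spec()].
#' @return An object of class `adult_reference`.
#' @examples
#' adult_reference(dose_spec(400, "per_kg"))
#' @export
adult_reference <- function(dose, weight_kg = 70, clearance = NULL) {
  if (!inherits(dose, "dose_spec")) {
    stop_invalid("`dose` must be a dose_spec object.")
  }
  check_positive(weight_kg, "weight_kg")
  if (!is.null(clearance) && !inherits(clearance, "clearance_spec")) {
    stop_invalid("`clearance` must be NULL or a clearance_spec object.")
  }
  structure(
    list(dose = dose, weight_kg = as.numeric(weight_kg), clearance = clearance),
    class = "adult_reference"
  )
}

#' @export
print.adult_reference <- function(x, ...) {
  cat(sprintf(
    "<adult reference> %s %s at %s kg%s\n",
    format(x$dose$amount), x$dose$unit, format(x$weight_kg),
    if (is.null(x$clearance)) "" else sprintf(
      ", CL %s %s", format(x$clearance$value), x$clearance$unit
    )
  ))
  invisible(x)
}

#' Drug classes recognised by the package
#' @export
drug_classes <- c("monoclonal", "polyclonal", "non_antibody")

#' Reference (observed-dose provenance) types
#'
#' How the observed pediatric dose was arrived at: `per_kg_label` (the
#' adult mg/kg dose extrapolated unchanged), `cl_based` (scaled by the
#' pediatric/adult clearance ratio), or `investigator_selected` (chosen
#' in a dose-finding study, typical of neonatal polyclonal antibodies).
#'
#' @export
reference_types <- c("per_kg_label", "cl_based", "investigator_selected")
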
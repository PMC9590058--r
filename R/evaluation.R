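# Prediction-error metrics and accuracy categories.
#
# Errors are computed on per-kg doses; because predicted and observed are
# scaled by the same child weight the fold ratio is identical on the
# absolute basis (asserted in the test suite).

#' Percent prediction error
#'
#' `(predicted - observed) / observed x 100`. Positive values are
#' over-predictions. Both amounts must be on the same basis and unit.
#'
#' @param predicted Predicted dose amount(s), positive.
#' @param observed Observed dose amount(s), positive.
#' @return Percent error(s), unrounded.
#' @examples
#' percent_error(560, 250)  # 124
#' percent_error(70, 100)   # -30
#' @export
percent_error <- function(predicted, observed) {
  check_positive(predicted, "predicted")
  check_positive(observed, "observed")
  (predicted - observed) / observed * 100
}

#' Fold (ratio) prediction error
#'
#' `predicted / observed`. Related to the percent error by
#' `fold = 1 + percent/100`.
#'
#' @inheritParams percent_error
#' @return Positive fold error(s).
#' @examples
#' fold_error(560, 250)  # 2.24
#' @export
fold_error <- function(predicted, observed) {
  check_positive(predicted, "predicted")
  check_positive(observed, "observed")
  predicted / observed
}

#' Classify fold errors into accuracy categories
#'
#' A prediction within 30% of the observed dose (fold error in the
#' closed interval \[0.7, 1.3\]) is considered reasonably accurate;
#' \[0.5, 1.5\] is the wider conventional band. Above 1.3 is
#' over-prediction, below 0.7 under-prediction, so
#' `within_narrow`/`over`/`under` partition every fold error; the wide
#' band overlaps the other three and is reported separately.
#'
#' @param fold Positive fold error(s).
#' @return A tibble with columns `fold`, `within_wide`, `within_narrow`,
#'   `over`, `under` (logicals).
#' @examples
#' classify_fold(c(1.4, 1.0, 0.7))
#' @export
classify_fold <- function(fold) {
  check_positive(fold, "fold")
  tibble::tibble(
    fold = as.numeric(fold),
    within_wide = fold >= 0.5 & fold <= 1.5,
    within_narrow = fold >= 0.7 & fold <= 1.3,
    over = fold > 1.3,
    under = fold < 0.7
  )
}

# Weight stratum used throughout summaries: neonates are reported
# separately; other subjects split at 30 kg.
weight_stratum <- function(weight_kg, age_class) {
  ifelse(
    age_class %in% c("preterm_neonate", "term_neonate"), "neonate",
    ifelse(weight_kg < 30, "lt30", "ge30")
  )
}

#' Evaluate a cohort of pediatric observations
#'
#' For every row, predicts the pediatric dose with the Salisbury rule
#' (from the row's adult regimen and reference weight) and compares it
#' with the observed dose on the per-kg basis. For `cl_based` rows whose
#' observed dose is not recorded, the observed dose is reconstructed
#' from the clearance ratio
#' (`adult dose x pediatric CL / adult CL`); such rows must carry both
#' clearances.
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()],
#'   [table1_scenario()] or [read_cohort()]. Required columns: `drug`,
#'   `class`, `age_class`, `weight_kg`, `adult_dose`, `adult_basis`,
#'   `adult_weight_kg`, `observed_dose`, `observed_basis`,
#'   `reference_type`; optional `cl_child`, `cl_adult`, `cl_basis`,
#'   `cl_unit`.
#' @return The cohort with added columns `stratum`, `predicted_per_kg`,
#'   `predicted_abs`, `observed_per_kg`, `percent_error`, `fold_error`,
#'   and the four category flags.
#' @examples
#' cohort <- table1_scenario("polyclonal", "lt30", n = 9, seed = 1)
#' evaluate_cohort(cohort)
#' @export
evaluate_cohort <- function(cohort) {
  required <- c(
    "drug", "class", "age_class", "weight_kg", "adult_dose", "adult_basis",
    "adult_weight_kg", "observed_dose", "observed_basis", "reference_type"
  )
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop_missing_field(sprintf(
      "Cohort is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(cohort) == 0) {
    out <- tibble::as_tibble(cohort)
    out$stratum <- character(0)
    out$predicted_per_kg <- numeric(0)
    out$predicted_abs <- numeric(0)
    out$observed_per_kg <- numeric(0)
    out$percent_error <- numeric(0)
    out$fold_error <- numeric(0)
    out$within_wide <- logical(0)
    out$within_narrow <- logical(0)
    out$over <- logical(0)
    out$under <- logical(0)
    return(out)
  }

  check_positive(cohort$weight_kg, "weight_kg")
  check_positive(cohort$adult_dose, "adult_dose")
  check_positive(cohort$adult_weight_kg, "adult_weight_kg")

  w <- cohort$weight_kg
  adult_abs <- ifelse(
    cohort$adult_basis == "per_kg",
    cohort$adult_dose * cohort$adult_weight_kg,
    cohort$adult_dose
  )
  pct <- salisbury_percent(w)
  pred_abs <- pct * adult_abs / 100  # multiply first: exact at boundaries
  pred_per_kg <- pred_abs / w

  # Observed dose on the per-kg basis; reconstruct cl_based rows from the
  # clearance ratio when no dose was recorded.
  obs <- cohort$observed_dose
  obs_per_kg <- ifelse(
    !is.na(obs) & cohort$observed_basis == "per_kg", obs,
    ifelse(!is.na(obs), obs / w, NA_real_)
  )
  needs_cl <- is.na(obs) & cohort$reference_type == "cl_based"
  if (any(needs_cl)) {
    has_cl <- all(c("cl_child", "cl_adult") %in% names(cohort))
    cl_ok <- if (has_cl) {
      !is.na(cohort$cl_child[needs_cl]) & !is.na(cohort$cl_adult[needs_cl])
    } else {
      rep(FALSE, sum(needs_cl))
    }
    if (!all(cl_ok)) {
      bad <- which(needs_cl)[!cl_ok][1L]
      stop_missing_field(sprintf(
        "Row %d (drug '%s') is cl_based with no observed dose but lacks a clearance value.",
        bad, cohort$drug[bad]
      ))
    }
    ratio <- cohort$cl_child / cohort$cl_adult
    cl_dose <- cohort$adult_dose * ratio  # same basis as the adult dose
    # A per-kg clearance ratio scales the per-kg dose directly; an
    # absolute ratio yields the child's absolute dose.
    obs_child_abs <- ifelse(cohort$adult_basis == "per_kg", cl_dose * w, cl_dose)
    obs_per_kg[needs_cl] <- (obs_child_abs / w)[needs_cl]
  }
  if (anyNA(obs_per_kg)) {
    bad <- which(is.na(obs_per_kg))[1L]
    stop_missing_field(sprintf(
      "Row %d (drug '%s') has no observed dose.", bad, cohort$drug[bad]
    ))
  }

  pe <- percent_error(pred_per_kg, obs_per_kg)
  fe <- fold_error(pred_per_kg, obs_per_kg)
  flags <- classify_fold(fe)

  out <- tibble::as_tibble(cohort)
  out$stratum <- weight_stratum(w, cohort$age_class)
  out$predicted_per_kg <- pred_per_kg
  out$predicted_abs <- pred_abs
  out$observed_per_kg <- obs_per_kg
  out$percent_error <- pe
  out$fold_error <- fe
  out$within_wide <- flags$within_wide
  out$within_narrow <- flags$within_narrow
  out$over <- flags$over
  out$under <- flags$under
  out
}
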
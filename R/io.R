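# Cohort CSV schema.
#
# Comma-separated, UTF-8, header required, decimal point. Dose and
# clearance values embed their unit string ("400 mg/kg", "28000 mg",
# "2.1 mL/h/kg", "140 mL/h"); the basis (per-kg vs absolute) is parsed
# from the unit, never guessed from magnitude. Columns:
#
#   drug, class, age_class, weight_kg, adult_dose, adult_weight_kg,
#   observed_dose, cl_child, cl_adult, reference_type
#
# observed_dose, cl_child and cl_adult may be empty; cl_based rows with
# an empty observed_dose must carry both clearances. This schema is
# transcription-ready for per-observation datasets of the same shape
# (drug, class, age group, weight, adult regimen, observed pediatric
# dose, clearances, dosing-policy provenance).

cohort_columns <- c(
  "drug", "class", "age_class", "weight_kg", "adult_dose",
  "adult_weight_kg", "observed_dose", "cl_child", "cl_adult",
  "reference_type"
)

# Parse "400 mg/kg" / "28000 mg" / "" into amount + basis + unit.
parse_quantity <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "") {
    return(list(amount = NA_real_, basis = NA_character_, unit = NA_character_))
  }
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*([A-Za-z/%]+)$", x))[[1]]
  if (length(m) != 3) {
    stop_invalid(sprintf("Cannot parse quantity '%s' (expected e.g. '400 mg/kg' or '28000 mg').", x))
  }
  amount <- suppressWarnings(as.numeric(m[2]))
  unit <- m[3]
  if (is.na(amount)) {
    stop_invalid(sprintf("Cannot parse the numeric part of quantity '%s'.", x))
  }
  known_per_kg <- grepl("/kg$", unit)
  basis <- if (known_per_kg) "per_kg" else "absolute"
  list(amount = amount, basis = basis, unit = unit)
}

format_quantity <- function(amount, unit) {
  ifelse(
    is.na(amount), "",
    paste(format(amount, digits = 15, trim = TRUE, scientific = FALSE), unit)
  )
}

#' Read a cohort from CSV
#'
#' Parses the documented cohort schema. Dose and clearance bases are
#' taken from the unit embedded in each value (`"mg/kg"` is per-kg,
#' `"mg"` absolute; likewise `"mL/h/kg"` vs `"mL/h"`). Rows that fail
#' validation (non-positive weight, unparseable quantity, unknown class
#' or reference type) are dropped, collected with their file line
#' numbers in the `problems` attribute, and reported in a warning.
#'
#' @param path Path to a CSV file with header
#'   `drug, class, age_class, weight_kg, adult_dose, adult_weight_kg,
#'   observed_dose, cl_child, cl_adult, reference_type`.
#' @return A cohort tibble for [evaluate_cohort()], with attribute
#'   `problems` (a tibble of line/message pairs) when rows were
#'   malformed.
#' @examples
#' path <- system.file("extdata", "synthetic_appendix_cohort.csv",
#'   package = "peddose"
#' )
#' read_cohort(path)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("Cohort file '%s' does not exist.", path))
  }
  raw <- utils::read.csv(
    path,
    colClasses = "character", strip.white = TRUE, check.names = TRUE
  )
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop_missing_field(sprintf(
      "Cohort file '%s' is missing column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    rlang::warn(sprintf("Cohort file '%s' contains a header but no rows.", path))
    return(empty_cohort())
  }

  problems <- list()
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    row <- raw[i, ]
    parsed <- tryCatch(
      parse_cohort_row(row),
      peddose_error = function(e) conditionMessage(e)
    )
    if (is.character(parsed)) {
      problems[[length(problems) + 1L]] <- tibble::tibble(
        line = line, message = parsed
      )
    } else {
      rows[[i]] <- parsed
    }
  }
  cohort <- dplyr::bind_rows(rows)
  if (nrow(cohort) == 0) cohort <- empty_cohort()
  if (length(problems) > 0) {
    prob <- dplyr::bind_rows(problems)
    attr(cohort, "problems") <- prob
    rlang::warn(sprintf(
      "Dropped %d malformed row(s) from '%s' (see attr(x, 'problems')); first: line %d: %s",
      nrow(prob), path, prob$line[1], prob$message[1]
    ))
  }
  cohort
}

empty_cohort <- function() {
  tibble::tibble(
    drug = character(0), class = character(0), age_class = character(0),
    weight_kg = numeric(0),
    adult_dose = numeric(0), adult_basis = character(0),
    adult_unit = character(0), adult_weight_kg = numeric(0),
    observed_dose = numeric(0), observed_basis = character(0),
    observed_unit = character(0),
    cl_child = numeric(0), cl_adult = numeric(0),
    cl_basis = character(0), cl_unit = character(0),
    reference_type = character(0)
  )
}

parse_cohort_row <- function(row) {
  if (!(row$class %in% drug_classes)) {
    stop_invalid(sprintf("Unknown drug class '%s'.", row$class))
  }
  if (!(row$age_class %in% age_classes)) {
    stop_invalid(sprintf("Unknown age class '%s'.", row$age_class))
  }
  if (!(row$reference_type %in% reference_types)) {
    stop_invalid(sprintf("Unknown reference type '%s'.", row$reference_type))
  }
  weight <- suppressWarnings(as.numeric(row$weight_kg))
  if (is.na(weight) || weight <= 0) {
    stop_invalid(sprintf("Invalid weight '%s' (must be a positive number).", row$weight_kg))
  }
  adult_w <- suppressWarnings(as.numeric(row$adult_weight_kg))
  if (is.na(adult_w)) adult_w <- 70
  if (adult_w <= 0) {
    stop_invalid(sprintf("Invalid adult weight '%s'.", row$adult_weight_kg))
  }
  adult <- parse_quantity(row$adult_dose)
  if (is.na(adult$amount)) {
    stop_missing_field("Missing adult dose.")
  }
  obs <- parse_quantity(row$observed_dose)
  clc <- parse_quantity(row$cl_child)
  cla <- parse_quantity(row$cl_adult)
  if (!is.na(clc$amount) && !is.na(cla$amount) &&
      (clc$basis != cla$basis || clc$unit != cla$unit)) {
    stop_basis_mismatch(sprintf(
      "Clearance basis/unit mismatch: child '%s' vs adult '%s'.",
      row$cl_child, row$cl_adult
    ))
  }
  tibble::tibble(
    drug = row$drug, class = row$class, age_class = row$age_class,
    weight_kg = weight,
    adult_dose = adult$amount, adult_basis = adult$basis,
    adult_unit = adult$unit, adult_weight_kg = adult_w,
    observed_dose = obs$amount, observed_basis = obs$basis,
    observed_unit = obs$unit,
    cl_child = clc$amount, cl_adult = cla$amount,
    cl_basis = clc$basis, cl_unit = clc$unit,
    reference_type = row$reference_type
  )
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: units are embedded back into the dose and
#' clearance values, so a write/read round trip reproduces the cohort.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(
    drug = cohort$drug,
    class = cohort$class,
    age_class = cohort$age_class,
    weight_kg = format(cohort$weight_kg, digits = 15, trim = TRUE, scientific = FALSE),
    adult_dose = format_quantity(cohort$adult_dose, cohort$adult_unit),
    adult_weight_kg = format(cohort$adult_weight_kg, digits = 15, trim = TRUE, scientific = FALSE),
    observed_dose = format_quantity(cohort$observed_dose, cohort$observed_unit),
    cl_child = format_quantity(cohort$cl_child, cohort$cl_unit),
    cl_adult = format_quantity(cohort$cl_adult, cohort$cl_unit),
    reference_type = cohort$reference_type,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
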
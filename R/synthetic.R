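# Synthetic drug cohorts with the statistical structure the analysis
# assumes: per-drug adult regimens, pediatric body weights drawn within
# weight strata, and pediatric clearance scaling sub-linearly with
# weight (CL ~ W^b, b < 1), so that per-kg clearance -- and hence the
# clearance-based dose -- is higher in smaller children.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the cohorts the analysis was designed for: neonates
#' of 1–3 kg, children of 4.5 up to 30 kg, and children of 30–60 kg;
#' allometric clearance exponent 0.75 with 15% log-normal
#' between-subject noise; investigator-selected neonatal doses on a
#' 250–1000 mg/kg grid; adult per-kg doses log-uniform over 1–500
#' mg/kg (monoclonal antibody to pooled immunoglobulin scales); adult
#' reference weight 70 kg.
#'
#' @param n_drugs Named integer vector: drugs per class
#'   (`monoclonal`, `polyclonal`, `non_antibody`).
#' @param obs_per_drug Observations per drug.
#' @param weight_ranges Named list of `c(min, max)` kg per stratum
#'   (`neonate`, `lt30`, `ge30`); ranges must be positive, ordered and
#'   non-overlapping.
#' @param stratum_mix Named probabilities for assigning each observation
#'   to a weight stratum.
#' @param adult_dose_range Range (mg/kg) for log-uniform adult per-kg
#'   doses.
#' @param adult_weight_kg Adult reference weight (kg).
#' @param allometric_b Allometric clearance exponent, in (0, 1.25].
#' @param cl_cv Coefficient of variation of the log-normal clearance
#'   noise (0 disables noise).
#' @param policy_mix Named probabilities over reference types
#'   (`per_kg_label`, `cl_based`, `investigator_selected`).
#' @param investigator_grid Per-kg dose grid (mg/kg) for
#'   investigator-selected observations.
#' @param seed Optional integer seed; equal seeds give identical
#'   cohorts.
#' @return A validated object of class `synthetic_config`.
#' @examples
#' synthetic_config(seed = 42)
#' @export
synthetic_config <- function(n_drugs = c(monoclonal = 21, polyclonal = 5, non_antibody = 11),
                             obs_per_drug = 2,
                             weight_ranges = list(
                               neonate = c(1, 3),
                               lt30 = c(4.5, 30),
                               ge30 = c(30, 60)
                             ),
                             stratum_mix = c(neonate = 0, lt30 = 0.5, ge30 = 0.5),
                             adult_dose_range = c(1, 500),
                             adult_weight_kg = 70,
                             allometric_b = 0.75,
                             cl_cv = 0.15,
                             policy_mix = c(
                               per_kg_label = 0.55, cl_based = 0.45,
                               investigator_selected = 0
                             ),
                             investigator_grid = c(250, 500, 750, 1000),
                             seed = NULL) {
  problems <- character(0)
  need <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  need(
    is.numeric(n_drugs) && all(drug_classes %in% names(n_drugs)) &&
      all(n_drugs >= 0) && sum(n_drugs) > 0,
    "`n_drugs` must name all drug classes with non-negative counts, at least one positive."
  )
  need(
    is.numeric(obs_per_drug) && length(obs_per_drug) == 1 && obs_per_drug >= 1,
    "`obs_per_drug` must be a single count >= 1."
  )
  ranges_ok <- is.list(weight_ranges) &&
    all(c("neonate", "lt30", "ge30") %in% names(weight_ranges)) &&
    all(vapply(weight_ranges, function(r) {
      is.numeric(r) && length(r) == 2 && all(r > 0) && r[1] < r[2]
    }, logical(1)))
  need(ranges_ok, "`weight_ranges` must give positive increasing c(min, max) for neonate, lt30, ge30.")
  if (ranges_ok) {
    need(
      weight_ranges$neonate[2] <= weight_ranges$lt30[1] &&
        weight_ranges$lt30[2] <= weight_ranges$ge30[1],
      "`weight_ranges` strata must be ordered and non-overlapping (neonate < lt30 < ge30)."
    )
    need(weight_ranges$lt30[2] <= 30, "`lt30` range must stay below 30 kg.")
    need(weight_ranges$ge30[1] >= 30, "`ge30` range must start at or above 30 kg.")
  }
  need(
    is.numeric(stratum_mix) && all(names(weight_ranges) %in% names(stratum_mix)) &&
      all(stratum_mix >= 0) && sum(stratum_mix) > 0,
    "`stratum_mix` must be non-negative weights over the strata, not all zero."
  )
  need(
    is.numeric(adult_dose_range) && length(adult_dose_range) == 2 &&
      all(adult_dose_range > 0) && adult_dose_range[1] <= adult_dose_range[2],
    "`adult_dose_range` must be a positive increasing pair (mg/kg)."
  )
  need(
    is.numeric(adult_weight_kg) && length(adult_weight_kg) == 1 && adult_weight_kg > 0,
    "`adult_weight_kg` must be a single positive weight."
  )
  need(
    is.numeric(allometric_b) && length(allometric_b) == 1 &&
      allometric_b > 0 && allometric_b <= 1.25,
    "`allometric_b` must lie in (0, 1.25]."
  )
  need(
    is.numeric(cl_cv) && length(cl_cv) == 1 && cl_cv >= 0,
    "`cl_cv` must be a single non-negative number."
  )
  need(
    is.numeric(policy_mix) && all(reference_types %in% names(policy_mix)) &&
      all(policy_mix >= 0) && sum(policy_mix) > 0,
    "`policy_mix` must be non-negative weights over the reference types, not all zero."
  )
  need(
    is.numeric(investigator_grid) && length(investigator_grid) >= 1 &&
      all(investigator_grid > 0),
    "`investigator_grid` must be positive per-kg doses."
  )
  need(
    is.null(seed) || (is.numeric(seed) && length(seed) == 1 && is.finite(seed)),
    "`seed` must be NULL or a single integer."
  )
  if (length(problems) > 0) {
    stop_config(paste(
      c("Invalid synthetic configuration:", paste0("- ", problems)),
      collapse = "\n"
    ))
  }
  structure(
    list(
      n_drugs = n_drugs, obs_per_drug = as.integer(obs_per_drug),
      weight_ranges = weight_ranges,
      stratum_mix = stratum_mix / sum(stratum_mix),
      adult_dose_range = adult_dose_range,
      adult_weight_kg = adult_weight_kg,
      allometric_b = allometric_b, cl_cv = cl_cv,
      policy_mix = policy_mix / sum(policy_mix),
      investigator_grid = investigator_grid,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Log-normal multiplicative noise with a given coefficient of variation;
# mean 1 on the natural scale.
lognormal_noise <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

generate_cohort_impl <- function(config) {
  rows <- list()
  drug_idx <- 0L
  for (cls in drug_classes) {
    n_cls <- as.integer(config$n_drugs[[cls]])
    if (n_cls == 0) next
    for (d in seq_len(n_cls)) {
      drug_idx <- drug_idx + 1L
      drug_id <- sprintf("%s_%02d", cls, d)
      # One adult reference per drug, shared across its observations.
      adult_per_kg <- if (config$adult_dose_range[1] == config$adult_dose_range[2]) {
        config$adult_dose_range[1]  # fixed regimen, drawn exactly
      } else {
        exp(runif(
          1, log(config$adult_dose_range[1]), log(config$adult_dose_range[2])
        ))
      }
      # Adult absolute clearance (mL/h); log-uniform over a typical
      # therapeutic-protein range. Only the child/adult ratio matters
      # for dosing.
      cl_adult_abs <- exp(runif(1, log(10), log(1000)))

      n_obs <- config$obs_per_drug
      stratum <- sample(
        names(config$stratum_mix), n_obs,
        replace = TRUE, prob = config$stratum_mix
      )
      w <- unname(vapply(stratum, function(s) {
        r <- config$weight_ranges[[s]]
        runif(1, r[1], r[2])
      }, numeric(1)))
      age_class <- ifelse(stratum == "neonate", "term_neonate", "child")
      policy <- sample(
        names(config$policy_mix), n_obs,
        replace = TRUE, prob = config$policy_mix
      )
      # Sub-linear allometric clearance with log-normal noise.
      cl_child_abs <- cl_adult_abs * (w / config$adult_weight_kg)^config$allometric_b *
        lognormal_noise(n_obs, config$cl_cv)
      cl_ratio_abs <- cl_child_abs / cl_adult_abs
      adult_abs <- adult_per_kg * config$adult_weight_kg
      observed_per_kg <- ifelse(
        policy == "per_kg_label", adult_per_kg,
        ifelse(
          policy == "cl_based",
          adult_abs * cl_ratio_abs / w,
          sample(config$investigator_grid, n_obs, replace = TRUE)
        )
      )
      rows[[drug_idx]] <- tibble::tibble(
        drug = drug_id,
        class = cls,
        age_class = age_class,
        weight_kg = unname(w),
        adult_dose = adult_per_kg,
        adult_basis = "per_kg",
        adult_unit = "mg/kg",
        adult_weight_kg = config$adult_weight_kg,
        observed_dose = observed_per_kg,
        observed_basis = "per_kg",
        observed_unit = "mg/kg",
        cl_child = cl_child_abs,
        cl_adult = cl_adult_abs,
        cl_basis = "absolute",
        cl_unit = "mL/h",
        reference_type = policy
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic drug cohort
#'
#' Draws one adult reference per drug (per-kg dose and absolute
#' clearance), then per observation a weight stratum, a body weight
#' uniform within the stratum's range, a pediatric clearance
#' `CL_adult x (W/70)^b` with log-normal noise, and an observed dose
#' according to the dosing policy: the adult per-kg dose unchanged
#' (`per_kg_label`), the clearance-ratio dose (`cl_based`), or a draw
#' from the investigator grid (`investigator_selected`).
#'
#' @param config A [synthetic_config()]. When the config carries a seed
#'   the cohort is fully reproducible and the caller's RNG state is left
#'   untouched.
#' @return A cohort tibble (one row per observation) ready for
#'   [evaluate_cohort()].
#' @examples
#' cohort <- generate_cohort(synthetic_config(seed = 7))
#' head(cohort)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_config("`config` must be created with synthetic_config().")
  }
  if (is.null(config$seed)) {
    generate_cohort_impl(config)
  } else {
    withr::with_seed(config$seed, generate_cohort_impl(config))
  }
}

# Scenario presets reproducing the published cohort structures.
scenario_presets <- function() {
  list(
    polyclonal.lt30 = list(
      weights = c(15, 30), age_class = "child", policy = "per_kg_label",
      adult_per_kg = 400
    ),
    polyclonal.ge30 = list(
      weights = c(30, 50), age_class = "child", policy = "per_kg_label",
      adult_per_kg = 400
    ),
    polyclonal.neonate = list(
      weights = c(1, 3), age_class = "term_neonate",
      policy = "investigator_selected", adult_per_kg = 400
    ),
    monoclonal.lt30 = list(
      weights = c(4.5, 30), age_class = "child", policy = "mixed",
      adult_per_kg = NULL
    ),
    monoclonal.ge30 = list(
      weights = c(30, 60), age_class = "child", policy = "mixed",
      adult_per_kg = NULL
    ),
    non_antibody.lt30 = list(
      weights = c(4, 30), age_class = "child", policy = "mixed",
      adult_per_kg = NULL
    ),
    non_antibody.ge30 = list(
      weights = c(30, 60), age_class = "child", policy = "mixed",
      adult_per_kg = NULL
    )
  )
}

#' Preset cohorts mirroring the published scenarios
#'
#' Returns a cohort whose weight range and dosing policy reproduce a
#' published stratum: polyclonal antibodies in children (15–50 kg,
#' per-kg extrapolated dosing, IVIG-like 400 mg/kg adult regimen),
#' polyclonal antibodies in neonates (1–3 kg, investigator-selected
#' doses on the 250–1000 mg/kg grid), and monoclonal/non-antibody
#' strata with a mixed per-kg/clearance-based policy. There is no
#' neonatal stratum for monoclonal antibodies or non-antibody proteins.
#'
#' @param class Drug class (one of [drug_classes]).
#' @param stratum Weight stratum: `"lt30"`, `"ge30"` or `"neonate"`.
#' @param n Number of observations.
#' @param seed Optional integer seed for reproducibility.
#' @return A cohort tibble ready for [evaluate_cohort()].
#' @examples
#' table1_scenario("polyclonal", "lt30", n = 9, seed = 1)
#' @export
table1_scenario <- function(class, stratum = c("lt30", "ge30", "neonate"), n,
                            seed = NULL) {
  class <- match.arg(class, drug_classes)
  stratum <- match.arg(stratum)
  key <- paste(class, stratum, sep = ".")
  preset <- scenario_presets()[[key]]
  if (is.null(preset)) {
    stop_unsupported(sprintf(
      "No published scenario for class '%s' in stratum '%s'.", class, stratum
    ))
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_invalid("`n` must be a single count >= 1.")
  }
  policy_mix <- switch(preset$policy,
    per_kg_label = c(per_kg_label = 1, cl_based = 0, investigator_selected = 0),
    investigator_selected = c(per_kg_label = 0, cl_based = 0, investigator_selected = 1),
    mixed = c(per_kg_label = 0.55, cl_based = 0.45, investigator_selected = 0)
  )
  mix <- c(neonate = 0, lt30 = 0, ge30 = 0)
  mix[[stratum]] <- 1
  ranges <- list(neonate = c(1, 3), lt30 = c(4.5, 30), ge30 = c(30, 60))
  ranges[[stratum]] <- preset$weights
  dose_range <- if (is.null(preset$adult_per_kg)) {
    c(1, 50)  # mg/kg; typical monoclonal / non-antibody protein regimens
  } else {
    rep(preset$adult_per_kg, 2)
  }
  config <- synthetic_config(
    n_drugs = setNames(
      as.numeric(drug_classes == class), drug_classes
    ),
    obs_per_drug = n,
    weight_ranges = ranges,
    stratum_mix = mix,
    adult_dose_range = dose_range,
    policy_mix = policy_mix,
    seed = seed
  )
  cohort <- generate_cohort(config)
  cohort$age_class <- preset$age_class
  cohort
}
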
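# Independent brute-force oracles used across the suite. These stay
# deliberately naive (scalar loops, direct formulas) so they cannot
# share a defect with the vectorised implementation.

# Category recount by explicit scalar comparison.
brute_count_categories <- function(folds) {
  wide <- narrow <- over <- under <- 0L
  for (f in folds) {
    if (f >= 0.5 && f <= 1.5) wide <- wide + 1L
    if (f >= 0.7 && f <= 1.3) narrow <- narrow + 1L
    if (f > 1.3) over <- over + 1L
    if (f < 0.7) under <- under + 1L
  }
  c(wide = wide, narrow = narrow, over = over, under = under)
}

# Salisbury fold error against per-kg extrapolated dosing, computed the
# long way: absolute doses at each step, no per-kg shortcut.
brute_salisbury_fold_vs_perkg <- function(w, adult_per_kg = 400, adult_w = 70) {
  adult_abs <- adult_per_kg * adult_w
  pct <- if (w < 30) 2 * w else if (w < 70) w + 30 else 100
  pred_abs <- pct / 100 * adult_abs
  obs_abs <- adult_per_kg * w
  pred_abs / obs_abs
}

# A tiny hand-built cohort with known per-kg doses.
manual_cohort <- function() {
  tibble::tibble(
    drug = c("a", "a", "b"),
    class = c("monoclonal", "monoclonal", "polyclonal"),
    age_class = c("child", "child", "term_neonate"),
    weight_kg = c(20, 35, 2),
    adult_dose = c(10, 10, 400),
    adult_basis = "per_kg",
    adult_unit = "mg/kg",
    adult_weight_kg = 70,
    observed_dose = c(10, 10, 250),
    observed_basis = "per_kg",
    observed_unit = "mg/kg",
    cl_child = NA_real_,
    cl_adult = NA_real_,
    cl_basis = NA_character_,
    cl_unit = NA_character_,
    reference_type = c("per_kg_label", "per_kg_label", "investigator_selected")
  )
}
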
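---
title: "Weight-based pediatric dose prediction for therapeutic proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-based pediatric dose prediction for therapeutic proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peddose)
```

## The dosing problem

Therapeutic proteins — monoclonal antibodies, pooled polyclonal
immunoglobulins (IVIG), and non-antibody proteins such as enzymes — are
usually introduced into pediatrics by giving children the adult mg/kg
dose unchanged. Because clearance scales sub-linearly with body weight,
small children clear drug faster *per kilogram* than adults, so linear
per-kg extrapolation tends to under-dose them; conversely, a dose
matched to pediatric clearance is widely regarded as the better
reference standard. `peddose` implements and evaluates a simple
non-linear alternative that needs nothing but body weight.

## The model

**The Salisbury rule.** The pediatric dose as a percent of the adult
dose is

$$
\%\,\text{of adult dose} =
\begin{cases}
2W, & W < 30\ \text{kg},\\
W + 30, & 30 \le W < 70\ \text{kg},
\end{cases}
$$

with $W$ the child's weight in kg. Both segments give 60% at 30 kg, so
the rule is continuous and strictly increasing. The percent is applied
to the *absolute* adult dose (per-kg regimens are first multiplied by
the adult reference weight), and the resulting absolute child dose is
renormalised by the child's weight to report a per-kg dose.

**Adult reference weight.** The rule's percent reaches 100 at 70 kg,
which fixes 70 kg as the natural adult reference; it is the package
default and is configurable per drug (`adult_reference()`). At or above
70 kg the percent is capped at 100 with a warning — the rule is defined
only below the reference weight, and extrapolating beyond the full
adult dose would be unsafe.

**Clearance-ratio reference dosing.** The comparator dose is
$\text{child dose} = \text{adult dose} \times CL_\text{child}/CL_\text{adult}$.
Both clearances must share basis (per-kg or absolute) and unit; a
mismatch is a hard error rather than a silent conversion, because a
per-kg/absolute mix-up changes the ratio by the factor $70/W$ and is
the easiest way to corrupt this analysis undetectably.

**Error metrics.** Percent error is
$(\text{predicted}-\text{observed})/\text{observed}\times 100$ (positive
means over-prediction) and fold error is
$\text{predicted}/\text{observed}$; they are linked by
$\text{fold} = 1 + \%/100$. Errors are computed on per-kg doses;
since predicted and observed are divided by the same child weight the
fold error is identical on the absolute basis (asserted in the tests).

**Accuracy bands.** Within 0.7–1.3-fold (±30%) counts as reasonably
accurate; 0.5–1.5-fold is the wider conventional band; above 1.3-fold
is over-prediction and below 0.7-fold under-prediction. The narrow band
is taken as the *closed* interval, so narrow/over/under partition every
observation exactly — this resolves an ambiguity between "< 0.7" in
prose definitions and "≤ 0.7" in table row labels in favour of the
partition; no real observation in the motivating datasets sits on a
boundary, so the choice is unobservable there, but the partition
invariant makes the summary internally consistent and testable.

## Useful algebra

With a 70 kg reference and per-kg extrapolated observed dosing:

- below 30 kg the predicted per-kg dose is $1.4\times$ the adult per-kg
  dose for *every* weight (the $W$ cancels: $2W\%$ of $70d$ over $W$),
  so the fold error is exactly 1.4 and the percent error exactly 40%;
- at $W \ge 30$ the fold error is $(W+30)\cdot 70/(100\,W)$, strictly
  decreasing to 1.0 at 70 kg — e.g. 12% at 50 kg.

With noise-free allometric clearance ($CL \propto W^{0.75}$) the fold
error against clearance-based dosing is
$\frac{\%(W)/100}{(W/70)^{0.75}}$, which stays inside the narrow
0.7–1.3 band for all weights from 5 to 70 kg: the rule tracks
clearance-based dosing, not linear per-kg dosing. That is precisely why
it over-predicts per-kg extrapolated label doses below 30 kg.

## The synthetic cohort generator

Per-drug and per-observation datasets underlying published evaluations
are rarely reprinted; the generator (`synthetic_config()` +
`generate_cohort()`) produces cohorts with the structure the analysis
assumes so every pipeline stage is testable:

- one adult reference per drug: per-kg dose log-uniform over 1–500
  mg/kg (spanning monoclonal-antibody to IVIG scales) and an absolute
  adult clearance whose magnitude is irrelevant (only the child/adult
  ratio enters the dose);
- body weights uniform within each stratum's range — neonates 1–3 kg,
  below-30-kg children 4.5 up to 30 kg, heavier children 30–60 kg.
  Only ranges, not distributions, are typically reported for such
  cohorts, so uniform is the least-committal choice;
- pediatric clearance $CL_\text{adult}\,(W/70)^{b}$ with $b = 0.75$
  (the conventional allometric clearance exponent) and log-normal
  between-subject noise with CV 0.15, a typical inter-individual
  magnitude for protein clearance. With $b<1$, per-kg clearance is
  higher in children than adults — the generator reproduces that
  premise by construction;
- observed doses by dosing policy: `per_kg_label` copies the adult
  per-kg dose, `cl_based` applies the clearance ratio (with its noise),
  `investigator_selected` draws from a configurable grid defaulting to
  {250, 500, 750, 1000} mg/kg, the neonatal polyclonal dose-finding
  range.

`table1_scenario()` wraps the generator in presets mirroring the
published strata (e.g. polyclonal children 15–30 kg dosed per kg;
polyclonal neonates 1–3 kg on the investigator grid; monoclonal strata
with a 55/45 per-kg/clearance policy mix). There is no neonatal
monoclonal or non-antibody preset because no such stratum exists in the
motivating data; requesting one is an explicit error.

**What passing tests do and do not show.** The generator emulates the
*structure* of real cohorts — strata, policies, sub-linear clearance —
not any particular drug: real data have discrete label doses, mixed
adult reference weights, correlated observations within drugs, and
clearance ontogeny beyond a single power law (especially in neonates,
where maturation matters). Tests passing on synthetic cohorts therefore
validate the arithmetic and bookkeeping of the pipeline, not the
clinical performance of the rule on any new drug.

## Numerical choices

- Internal arithmetic is full precision; percents are rounded only at
  report time, half-away-from-zero to one decimal (matching how such
  tables are conventionally printed). `round_half_out()` adds a
  `sqrt(eps)` nudge before truncation to absorb binary representation
  error in values like 87.05.
- The predicted absolute dose is computed as
  `percent × adult_abs / 100` (multiply before divide) so that
  integer-friendly inputs land exactly on band boundaries — a 35 kg
  child under a 10 mg/kg label yields a fold error of exactly 1.3 and
  classifies as narrow, not over.
- The 30 kg boundary uses the upper segment ("at or above 30"); the two
  segments coincide there, so no discontinuity arises either way.
- Zero or negative doses, weights and clearances raise classed errors
  naming the offending value; they are never silently dropped or
  clamped.
- Generator determinism uses `withr::with_seed`, so a seeded call is
  reproducible *and* leaves the caller's RNG state untouched.
- Empty cohorts summarise to a zero-row table flagged with the
  `empty_cohort` attribute rather than raising, so batch pipelines can
  distinguish "no data" from "bad data".

## Problem sizes

The property suites run on deliberately modest sizes that already
exercise every branch: 10,000 random fold errors for the
partition/nesting recount, dense weight grids of a few hundred points
for the closed forms, and synthetic cohorts of 74–370 observations
(37 drugs × 2–10 observations). All are far above the 14–59
observations per stratum typical of real therapeutic-protein
evaluations, and the full suite runs in seconds.

## Known limitations

- The rule is undefined above the adult reference weight; the cap at
  100% is a safety choice, not part of the rule.
- Real published evaluations contain occasional errors slightly off the
  exact algebra (e.g. a 37% error where the 70 kg reference implies
  exactly 40%), presumably from a different adult weight or rounding in
  the source study; the package reproduces the exact algebra and makes
  the adult weight explicit instead.
- Whether historical clearance-ratio doses used per-kg or absolute
  clearances is usually unstated; the package supports both but forces
  the user to label them.
- No statistical inference is performed on the error distributions —
  the evaluation framework is descriptive binning, as is standard for
  this kind of dose-prediction audit.
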
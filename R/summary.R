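# Stratified accuracy summaries shaped like the familiar four-category
# report: wide band, narrow band, over-, and under-prediction, per drug
# class, weight stratum and observed-dose provenance.

#' Summarise evaluated predictions by stratum
#'
#' Counts and percentages of the four accuracy categories per
#' (drug class, weight stratum, reference type) cell. The narrow band,
#' over- and under-prediction partition each cell (their counts sum to
#' `n`); the wide band overlaps them and is reported alongside.
#' Percentages are rounded half-away-from-zero to one decimal; raw
#' counts are exact.
#'
#' @param results An evaluated cohort from [evaluate_cohort()].
#' @return A tibble with one row per stratum: `class`, `stratum`,
#'   `reference_type`, `n`, and count/percent pairs
#'   `wide_n`/`wide_pct`, `narrow_n`/`narrow_pct`, `over_n`/`over_pct`,
#'   `under_n`/`under_pct`. An empty input yields a zero-row tibble
#'   carrying attribute `empty_cohort = TRUE`.
#' @examples
#' res <- evaluate_cohort(table1_scenario("polyclonal", "lt30", 9, seed = 1))
#' summarize_predictions(res)
#' @export
summarize_predictions <- function(results) {
  needed <- c(
    "class", "stratum", "reference_type",
    "within_wide", "within_narrow", "over", "under"
  )
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0) {
    stop_missing_field(sprintf(
      "Results are missing column(s): %s. Run evaluate_cohort() first.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  empty_out <- function() {
    out <- tibble::tibble(
      class = character(0), stratum = character(0),
      reference_type = character(0), n = integer(0),
      wide_n = integer(0), wide_pct = numeric(0),
      narrow_n = integer(0), narrow_pct = numeric(0),
      over_n = integer(0), over_pct = numeric(0),
      under_n = integer(0), under_pct = numeric(0)
    )
    attr(out, "empty_cohort") <- TRUE
    out
  }
  if (nrow(results) == 0) {
    return(empty_out())
  }
  pct1 <- function(k, n) round_half_out(100 * k / n, 1)
  out <- results |>
    dplyr::group_by(.data$class, .data$stratum, .data$reference_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      wide_n = sum(.data$within_wide),
      narrow_n = sum(.data$within_narrow),
      over_n = sum(.data$over),
      under_n = sum(.data$under),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      wide_pct = pct1(.data$wide_n, .data$n),
      narrow_pct = pct1(.data$narrow_n, .data$n),
      over_pct = pct1(.data$over_n, .data$n),
      under_pct = pct1(.data$under_n, .data$n)
    ) |>
    dplyr::select(
      "class", "stratum", "reference_type", "n",
      "wide_n", "wide_pct", "narrow_n", "narrow_pct",
      "over_n", "over_pct", "under_n", "under_pct"
    )
  out
}

# Category row labels used in the rendered report.
category_labels <- function() {
  c(
    wide = "0.5\u20131.5-fold",
    narrow = "\u226430% (\u22650.7\u2013\u22641.3)",
    over = "\u2265130% (>1.3-fold)",
    under = "\u226470% (\u22640.7-fold)"
  )
}

#' Render a summary as a markdown table
#'
#' One markdown table per drug class with the four category rows and one
#' column per (weight stratum, reference type) present for any class;
#' cells are `count (percent%)`. Strata absent for a class are printed
#' as `NA` rather than omitted.
#'
#' @param summary A summary tibble from [summarize_predictions()].
#' @return A character vector of markdown lines (invisibly printable
#'   with `cat(x, sep = "\n")`).
#' @examples
#' res <- evaluate_cohort(table1_scenario("polyclonal", "lt30", 9, seed = 1))
#' cat(summary_markdown(summarize_predictions(res)), sep = "\n")
#' @export
summary_markdown <- function(summary) {
  if (nrow(summary) == 0) {
    return("*(empty cohort: no observations to summarise)*")
  }
  stratum_label <- c(lt30 = "<30 kg", ge30 = "\u226530 kg", neonate = "neonates")
  ref_label <- c(
    per_kg_label = "per-kg label", cl_based = "CL based",
    investigator_selected = "investigator selected"
  )
  labels <- category_labels()
  lines <- character(0)
  cols <- unique(summary[, c("stratum", "reference_type")])
  cols <- cols[order(
    match(cols$stratum, names(stratum_label)),
    match(cols$reference_type, names(ref_label))
  ), ]
  for (cls in unique(summary$class)) {
    sub <- summary[summary$class == cls, ]
    header <- sprintf(
      "%s, %s (n = %d)",
      stratum_label[cols$stratum], ref_label[cols$reference_type],
      vapply(seq_len(nrow(cols)), function(i) {
        m <- sub[sub$stratum == cols$stratum[i] &
                   sub$reference_type == cols$reference_type[i], ]
        if (nrow(m) == 1) as.integer(m$n) else 0L
      }, integer(1))
    )
    lines <- c(lines, sprintf("**%s**", cls), "")
    lines <- c(lines, paste0("| Error | ", paste(header, collapse = " | "), " |"))
    lines <- c(lines, paste0("|", paste(rep("---", nrow(cols) + 1), collapse = "|"), "|"))
    for (cat in names(labels)) {
      cells <- vapply(seq_len(nrow(cols)), function(i) {
        m <- sub[sub$stratum == cols$stratum[i] &
                   sub$reference_type == cols$reference_type[i], ]
        if (nrow(m) != 1) return("NA")
        sprintf(
          "%d (%s%%)", as.integer(m[[paste0(cat, "_n")]]),
          format(m[[paste0(cat, "_pct")]], nsmall = 1)
        )
      }, character(1))
      lines <- c(lines, paste0(
        "| ", labels[[cat]], " | ", paste(cells, collapse = " | "), " |"
      ))
    }
    lines <- c(lines, "")
  }
  lines
}
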
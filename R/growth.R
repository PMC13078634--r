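#' Proliferation index
#'
#' Percent of cells in a compartment that are EdU-positive after a pulse:
#' `100 * edu_pos / total`. Vectorized; additive over sub-fields, so pooling
#' fields before or after counting gives the same index.
#'
#' @param edu_pos EdU-positive nucleus count(s).
#' @param total total nucleus count(s); must be > 0.
#' @return Percentage(s).
#' @export
proliferation_index <- function(edu_pos, total) {
  if (any(total <= 0)) abort("proliferation_index: total must be > 0.")
  if (any(edu_pos < 0) || any(edu_pos > total)) {
    abort("proliferation_index: need 0 <= edu_pos <= total.")
  }
  100 * edu_pos / total
}

#' Distribution of animals by EdU+ cell count
#'
#' Tallies animals into count bins `0, 1, 2, ..., (max_bin)+` per condition
#' (and any other grouping columns passed), with percentages.
#'
#' @param edu_table tibble with at least `edu_pos`; grouping columns are
#'   given via `by` (default `"condition"` when present).
#' @param max_bin counts at or above this are pooled into an open top bin.
#' @param by character vector of grouping columns; columns absent from the
#'   table are ignored.
#' @return Tibble: grouping columns, `bin` (factor `"0"`, `"1"`, ...,
#'   `"3+"`), `n_animals`, `percent`.
#' @export
edu_count_distribution <- function(edu_table, max_bin = 3, by = "condition") {
  if (nrow(edu_table) == 0) abort("edu_count_distribution: empty table.")
  by <- intersect(by, names(edu_table))
  lev <- c(as.character(seq_len(max_bin) - 1L), paste0(max_bin, "+"))
  tbl <- edu_table |>
    dplyr::mutate(bin = factor(ifelse(.data$edu_pos >= max_bin, paste0(max_bin, "+"),
                                      as.character(.data$edu_pos)), levels = lev))
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::count(.data$bin, name = "n_animals", .drop = FALSE) |>
    dplyr::mutate(percent = 100 * .data$n_animals / sum(.data$n_animals)) |>
    dplyr::ungroup()
}

#' Division rate from an EdU pulse/chase pair
#'
#' Estimates divisions per 24 h as the ratio of the mean EdU+ nucleus count
#' in the chase arm to the mean in the pulse-only arm, divided by
#' `chase_hours / 24` (36 h gives the divisor 1.5; a value of 1 indicates
#' one division per day). Animals with a zero EdU+ count are excluded from
#' both means.
#'
#' @param pulse,chase EdU tables (rows = animals) with `edu_pos` and
#'   optionally grouping columns.
#' @param chase_hours chase duration in hours.
#' @param by grouping columns (intersected with those present in *both*
#'   tables); default condition and compartment.
#' @param exclude_zero drop zero counts from both arms (the estimator's
#'   stated rule).
#' @return Tibble: grouping columns, `rate` (divisions / 24 h), `n_pulse`,
#'   `n_chase` (animals used), `excluded_zero` (animals dropped).
#' @export
division_rate <- function(pulse, chase, chase_hours = 36,
                          by = c("condition", "compartment"),
                          exclude_zero = TRUE) {
  stopifnot(chase_hours > 0)
  by <- intersect(by, intersect(names(pulse), names(chase)))
  one_arm <- function(tbl) {
    kept <- if (exclude_zero) tbl[tbl$edu_pos > 0, , drop = FALSE] else tbl
    kept |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(mean_arm = mean(.data$edu_pos), n_arm = dplyr::n(),
                       .groups = "drop")
  }
  excl <- function(tbl) if (exclude_zero) sum(tbl$edu_pos == 0) else 0L
  p <- dplyr::rename(one_arm(pulse), mean_pulse = "mean_arm", n_pulse = "n_arm")
  c_ <- dplyr::rename(one_arm(chase), mean_chase = "mean_arm", n_chase = "n_arm")
  if (nrow(p) == 0 || nrow(c_) == 0 ||
      any(p$n_pulse == 0) || any(c_$n_chase == 0) ||
      any(!is.finite(p$mean_pulse)) || any(!is.finite(c_$mean_chase))) {
    abort("division_rate: an arm is empty after zero exclusion.")
  }
  out <- if (length(by)) dplyr::inner_join(p, c_, by = by) else dplyr::cross_join(p, c_)
  if (any(out$mean_pulse == 0)) abort("division_rate: zero mean pulse count.")
  out |>
    dplyr::transmute(dplyr::across(dplyr::all_of(by)),
                     rate = (.data$mean_chase / .data$mean_pulse) / (chase_hours / 24),
                     n_pulse = .data$n_pulse, n_chase = .data$n_chase,
                     excluded_zero = excl(pulse) + excl(chase))
}

#' Normalize trial counts to the trial's control mean
#'
#' Divides every animal's count by the mean count of the control animals in
#' the same trial, removing the per-trial scale; the control condition's
#' normalized mean is 1 in every trial. Per-trial per-condition averages of
#' the normalized counts are returned alongside. A single-reference-animal
#' mode divides by one designated control animal's count instead.
#'
#' @param trials tibble with `trial`, `condition`, `count` (and optionally
#'   `animal`).
#' @param control label of the control condition.
#' @param reference_animal optional animal id (in `animal`): divide by that
#'   animal's count per trial instead of the control mean.
#' @return List with `table` (input plus `norm_count`) and `trial_means`
#'   (tibble `trial`, `condition`, `mean_norm`, `n`).
#' @export
normalize_ul_counts <- function(trials, control = "control", reference_animal = NULL) {
  stopifnot(all(c("trial", "condition", "count") %in% names(trials)))
  refs <- trials |>
    dplyr::filter(.data$condition == control) |>
    dplyr::group_by(.data$trial)
  if (is.null(reference_animal)) {
    refs <- dplyr::summarise(refs, ref = mean(.data$count), .groups = "drop")
  } else {
    refs <- refs |>
      dplyr::filter(.data$animal == reference_animal) |>
      dplyr::summarise(ref = mean(.data$count), .groups = "drop")
  }
  missing_t <- setdiff(unique(trials$trial), refs$trial)
  if (length(missing_t)) {
    abort(sprintf("normalize_ul_counts: trial(s) without control animals: %s",
                  paste(missing_t, collapse = ", ")))
  }
  if (any(refs$ref <= 0)) {
    abort("normalize_ul_counts: a trial has control mean 0; cannot normalize.")
  }
  tbl <- trials |>
    dplyr::left_join(refs, by = "trial") |>
    dplyr::mutate(norm_count = .data$count / .data$ref) |>
    dplyr::select(-"ref")
  means <- tbl |>
    dplyr::group_by(.data$trial, .data$condition) |>
    dplyr::summarise(mean_norm = mean(.data$norm_count), n = dplyr::n(),
                     .groups = "drop")
  list(table = tbl, trial_means = means)
}
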
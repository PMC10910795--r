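#' Merge hospital encounters less than 24 h apart into admissions
#'
#' Per patient, encounters sorted by start time are chained into one
#' admission while the gap from the running end of the chain to the next
#' start is strictly below `gap_hours` (ties at exactly the threshold start a
#' new admission). Overlapping encounters merge. The admission start/end are
#' the min/max over members and its code set is the union of member codes.
#' The operation is idempotent: merging admissions again changes nothing.
#'
#' @param encounters Tibble with `patient_id`, `start`, `end`, `codes`
#'   (`";"`-separated string) and optionally `death_date`, `sex`,
#'   `age_at_start` (carried through; age from the first member).
#' @param gap_hours Merge threshold in hours.
#' @return A tibble of admissions with `admission_id`, the encounter fields,
#'   and `n_encounters`.
#' @export
merge_encounters <- function(encounters, gap_hours = 24) {
  assert_fields(encounters, c("patient_id", "start", "end"), "encounters")
  if (any(encounters$start > encounters$end)) {
    stop("encounter with start > end", call. = FALSE)
  }
  if (!"codes" %in% names(encounters)) encounters$codes <- ""
  gap_secs <- gap_hours * 3600
  out <- encounters |>
    dplyr::arrange(.data$patient_id, .data$start, .data$end) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      run_end = cummax(as.numeric(.data$end)),
      new_chain = c(TRUE, (as.numeric(.data$start) -
                             dplyr::lag(.data$run_end))[-1] >= gap_secs),
      chain = cumsum(.data$new_chain)
    ) |>
    dplyr::group_by(.data$patient_id, .data$chain)
  merged <- out |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      codes = union_codes(.data$codes),
      n_encounters = dplyr::n(),
      dplyr::across(dplyr::any_of(c("death_date", "sex")), dplyr::first),
      dplyr::across(dplyr::any_of("age_at_start"), min),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_id, .data$start) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(admission_id = sprintf("%s_A%03d", .data$patient_id,
                                         dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select(-"chain") |>
    dplyr::relocate("admission_id")
  merged
}

union_codes <- function(codes) {
  parts <- unique(unlist(strsplit(codes[!is.na(codes) & codes != ""], ";")))
  paste(sort(parts), collapse = ";")
}

#' Attach laboratory records to admissions within a one-sided window
#'
#' A record attaches to an admission iff they share the patient and the
#' record's timestamp lies in the closed window
#' `[admission start, admission start + window_hours]` — the window is
#' one-sided after admission. A record attaches to at most one admission (the
#' earliest qualifying one); records matching none are dropped and counted.
#'
#' @param admissions Tibble from [merge_encounters()].
#' @param records Lab-record tibble (a `record_id` column is added if
#'   absent).
#' @param window_hours Window length in hours after admission start.
#' @return The attached records with an `admission_id` column; the number of
#'   dropped records is attached as attribute `n_dropped` and reported via
#'   `message()`.
#' @export
attach_labs <- function(admissions, records, window_hours = 24) {
  assert_fields(admissions, c("admission_id", "patient_id", "start"),
                "admissions")
  assert_fields(records, c("patient_id", "timestamp"), "records")
  if (!"record_id" %in% names(records)) {
    records$record_id <- sprintf("R%07d", seq_len(nrow(records)))
  }
  win <- window_hours * 3600
  attached <- records |>
    dplyr::inner_join(
      admissions[, c("admission_id", "patient_id", "start")],
      by = "patient_id", relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$timestamp >= .data$start,
                  .data$timestamp <= .data$start + .env$win) |>
    dplyr::group_by(.data$record_id) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"start")
  n_dropped <- nrow(records) - nrow(attached)
  message(sprintf("attach_labs: %d of %d records attached, %d dropped",
                  nrow(attached), nrow(records), n_dropped))
  attr(attached, "n_dropped") <- n_dropped
  attached
}

#' Select the most abnormal repeat per admission and test
#'
#' Among repeated measurements of one test within an admission's window,
#' keeps the record with a nonzero abnormality flag whose deviation beyond
#' the nearer interval bound — normalized by the interval width so tests on
#' different scales compare — is largest (this also resolves a -1 against a
#' +1). If every repeat is within the interval, the last record by timestamp
#' is kept with flag 0.
#'
#' @param flagged Records with `admission_id`, `test_name`, `specimen`,
#'   `value`, `timestamp`, and the applicable `lower`/`upper` bounds (from a
#'   [make_ri_provider()] function, so selection is version-specific).
#' @return One record per admission x test, with `flag` and `rel_dev`
#'   columns.
#' @export
select_most_abnormal <- function(flagged) {
  assert_fields(flagged, c("admission_id", "test_name", "specimen", "value",
                           "timestamp", "lower", "upper"), "flagged records")
  if (any(flagged$lower >= flagged$upper)) {
    stop("reference interval with lower >= upper", call. = FALSE)
  }
  flagged |>
    dplyr::mutate(
      flag = ri_flag(.data$value, .data$lower, .data$upper),
      rel_dev = flag_depth(.data$value, .data$lower, .data$upper,
                           .data$upper - .data$lower)
    ) |>
    dplyr::group_by(.data$admission_id, .data$test_name, .data$specimen) |>
    dplyr::arrange(dplyr::desc(.data$rel_dev), dplyr::desc(.data$timestamp),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Apply cohort filters and report attrition
#'
#' Applies, in order: (1) age eligibility (records by age at draw,
#' admissions by age at start); (2) truncation of diagnosis codes to ICD-10
#' level 3 (first three characters); (3) test coverage — a test is kept iff
#' it was measured (attached) in at least `coverage_frac` of the remaining
#' admissions; (4) outcome prevalence — a code is kept iff at least
#' `min_patients` unique patients have an admission carrying it; (5) a
#' fitting mask excluding records of patients who died within `survival_days`
#' of the draw's admission start (these records stay in the cohort; they are
#' only excluded from seasonal fitting).
#'
#' @param attached Attached records from [attach_labs()].
#' @param admissions Admissions from [merge_encounters()] (with `codes`,
#'   `age_at_start`, `death_date`).
#' @param min_age Minimum age (years), inclusive.
#' @param coverage_frac Minimum fraction of admissions a test must be
#'   measured in.
#' @param min_patients Minimum unique patients per outcome code.
#' @param survival_days Survivor threshold for the fitting mask.
#' @return A list: `records`, `admissions`, `outcome_codes` (kept codes),
#'   `fitting_ids` (record IDs eligible for seasonal fitting), and `report`
#'   (tibble of per-rule removals).
#' @export
apply_cohort_filters <- function(attached, admissions, min_age = 20,
                                 coverage_frac = 0.2, min_patients = 1000,
                                 survival_days = 28) {
  assert_fields(attached, c("record_id", "admission_id", "patient_id",
                            "test_name", "specimen", "age_at_draw"),
                "attached records")
  assert_fields(admissions, c("admission_id", "patient_id", "codes"),
                "admissions")
  report <- list()

  # (1) age eligibility
  n_r <- nrow(attached); n_a <- nrow(admissions)
  attached <- attached[attached$age_at_draw >= min_age, ]
  if ("age_at_start" %in% names(admissions)) {
    admissions <- admissions[is.na(admissions$age_at_start) |
                               admissions$age_at_start >= min_age, ]
  }
  attached <- attached[attached$admission_id %in% admissions$admission_id, ]
  report$age <- tibble::tibble(
    rule = "age", detail = sprintf("age >= %d", min_age),
    records_removed = n_r - nrow(attached),
    admissions_removed = n_a - nrow(admissions)
  )

  # (2) level-3 code truncation
  admissions$codes <- vapply(strsplit(admissions$codes, ";"), function(cs) {
    paste(sort(unique(substr(cs, 1, 3))), collapse = ";")
  }, "")
  report$level3 <- tibble::tibble(
    rule = "level3_codes", detail = "codes truncated to 3 characters",
    records_removed = 0L, admissions_removed = 0L
  )

  # (3) test coverage
  n_adm <- nrow(admissions)
  if (n_adm == 0) stop("empty cohort after age filter", call. = FALSE)
  coverage <- attached |>
    dplyr::distinct(.data$test_name, .data$specimen, .data$admission_id) |>
    dplyr::count(.data$test_name, .data$specimen) |>
    dplyr::mutate(frac = .data$n / n_adm)
  kept_tests <- coverage[coverage$frac >= coverage_frac,
                         c("test_name", "specimen")]
  n_r <- nrow(attached)
  attached <- dplyr::semi_join(attached, kept_tests,
                               by = c("test_name", "specimen"))
  report$coverage <- tibble::tibble(
    rule = "test_coverage",
    detail = sprintf("measured in >= %.0f%% of %d admissions (%d of %d tests kept)",
                     100 * coverage_frac, n_adm, nrow(kept_tests),
                     nrow(coverage)),
    records_removed = n_r - nrow(attached), admissions_removed = 0L
  )

  # (4) outcome prevalence
  code_tbl <- admissions |>
    dplyr::filter(.data$codes != "") |>
    dplyr::mutate(code = strsplit(.data$codes, ";")) |>
    tidyr::unnest("code") |>
    dplyr::distinct(.data$code, .data$patient_id) |>
    dplyr::count(.data$code)
  outcome_codes <- sort(code_tbl$code[code_tbl$n >= min_patients])
  report$prevalence <- tibble::tibble(
    rule = "outcome_prevalence",
    detail = sprintf(">= %d unique patients (%d of %d codes kept)",
                     min_patients, length(outcome_codes), nrow(code_tbl)),
    records_removed = 0L, admissions_removed = 0L
  )

  # (5) fitting mask: 28-day survivors
  if ("death_date" %in% names(admissions)) {
    adm_death <- admissions[, c("admission_id", "start", "death_date")]
    mask <- attached |>
      dplyr::left_join(adm_death, by = "admission_id") |>
      dplyr::mutate(ok = is.na(.data$death_date) |
                      as.numeric(.data$death_date - .data$start,
                                 units = "days") > survival_days)
    fitting_ids <- mask$record_id[mask$ok]
  } else {
    fitting_ids <- attached$record_id
  }
  report$survivor <- tibble::tibble(
    rule = "fitting_survivors",
    detail = sprintf("fitting excludes draws with death <= %d days after admission",
                     survival_days),
    records_removed = nrow(attached) - length(fitting_ids),
    admissions_removed = 0L
  )

  if (nrow(attached) == 0) stop("empty cohort after filters", call. = FALSE)
  list(records = attached, admissions = admissions,
       outcome_codes = outcome_codes, fitting_ids = fitting_ids,
       report = dplyr::bind_rows(report))
}
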
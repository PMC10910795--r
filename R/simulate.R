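#' Specify a synthetic laboratory test
#'
#' A test specification carries the measurement scale of one laboratory test
#' (name + specimen defines the unique test), its standard reference
#' interval, and the ground-truth seasonal parameters of the generating
#' cosinor: in normalized units the seasonal deviation at week `w` is
#' `true_beta0 + true_beta1 * cos(2*pi*(w - true_theta)/52)`.
#'
#' @param test_name,specimen,unit,lab_id Identity of the test and reporting
#'   laboratory (all part of the fitting stratum).
#' @param standard_ri Length-2 numeric, `c(lower, upper)` in measurement
#'   units; applied across sex and age groups of this test.
#' @param baseline_mean,baseline_sd Location and scale of the generated
#'   values (measurement units); `value = baseline_mean + baseline_sd *
#'   (seasonal deviation + N(0,1) noise)`.
#' @param true_beta0,true_beta1 Ground-truth offset and amplitude in
#'   normalized units, within `[-1, 1]` (the bounds the fitter enforces).
#' @param true_theta Ground-truth phase in weeks, within `[0, 52)`.
#' @return A `test_spec` list.
#' @export
test_spec <- function(test_name, specimen = "P", unit = "mmol/L",
                      lab_id = "LAB1", standard_ri,
                      baseline_mean, baseline_sd,
                      true_beta0 = 0, true_beta1 = 0, true_theta = 0) {
  stopifnot(length(standard_ri) == 2)
  if (!(standard_ri[1] < standard_ri[2])) {
    stop("invalid test_spec: 'standard_ri' must satisfy lower < upper",
         call. = FALSE)
  }
  if (!(baseline_sd > 0)) {
    stop("invalid test_spec: 'baseline_sd' must be > 0", call. = FALSE)
  }
  if (abs(true_beta0) > 1 || abs(true_beta1) > 1) {
    stop("invalid test_spec: 'true_beta0'/'true_beta1' must lie in [-1, 1]",
         call. = FALSE)
  }
  if (true_theta < 0 || true_theta >= 52) {
    stop("invalid test_spec: 'true_theta' must lie in [0, 52)", call. = FALSE)
  }
  structure(list(
    test_name = test_name, specimen = specimen, unit = unit, lab_id = lab_id,
    standard_ri = as.numeric(standard_ri),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    true_beta0 = true_beta0, true_beta1 = true_beta1, true_theta = true_theta
  ), class = "test_spec")
}

#' Specify a synthetic diagnosis outcome
#'
#' Outcome labels are sampled per admission from a logistic model on
#' abnormality flags: `logit(p) = intercept + sum_t weights[t] * flag_t +
#' sex_weight * is_male`. With `uses_seasonal_truth = TRUE` the flags are
#' computed against the seasonally-true (shifted) reference interval — the
#' condition under which a seasonally adjusted encoding carries true signal —
#' otherwise against the standard interval.
#'
#' @param code Synthetic ICD-10-like level-3 code (e.g. `"I21"`).
#' @param intercept Log-odds intercept.
#' @param weights Named numeric vector/list, test name to log-odds per
#'   abnormality unit (the -1/0/+1 flag enters multiplicatively).
#' @param sex_weight Log-odds added for male patients.
#' @param uses_seasonal_truth Logical; see above.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(code, intercept, weights, sex_weight = 0,
                         uses_seasonal_truth = TRUE) {
  weights <- unlist(weights)
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  structure(list(
    code = code, intercept = intercept, weights = weights,
    sex_weight = sex_weight,
    uses_seasonal_truth = isTRUE(uses_seasonal_truth)
  ), class = "outcome_spec")
}

#' Configure the synthetic EHR generator
#'
#' @param n_patients Number of patients (>= 1).
#' @param tests List of [test_spec()] objects.
#' @param outcomes List of [outcome_spec()] objects; every weight name must
#'   be a configured test.
#' @param years Study duration in calendar years (consecutive, starting at
#'   `start_year`).
#' @param start_year First calendar year of the study window.
#' @param sex_ratio Fraction of female patients.
#' @param age_range Integer `c(min, max)` age at entry, min >= 20.
#' @param encounter_rate Mean admissions per patient-year (Poisson; at least
#'   one admission per patient is guaranteed).
#' @param transfer_prob Probability an admission is recorded as two hospital
#'   encounters separated by a gap under 24 h (a transfer).
#' @param missing_prob Per-test probability the test is not measured at an
#'   admission.
#' @param repeat_prob Probability a measured test is repeated within the 24 h
#'   window.
#' @param death_prob Fraction of patients given a death date within 28 days
#'   of one of their admissions (exercises the fitting survivor filter).
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients, tests, outcomes = list(), years = 4,
                       start_year = 2012, sex_ratio = 0.5,
                       age_range = c(20, 100), encounter_rate = 1,
                       transfer_prob = 0.1, missing_prob = 0.2,
                       repeat_prob = 0.1, death_prob = 0.02, seed = 1) {
  check_count(n_patients, "n_patients")
  check_count(years, "years")
  check_prob(sex_ratio, "sex_ratio")
  check_prob(transfer_prob, "transfer_prob")
  check_prob(missing_prob, "missing_prob")
  check_prob(repeat_prob, "repeat_prob")
  check_prob(death_prob, "death_prob")
  if (!is.numeric(encounter_rate) || encounter_rate <= 0) {
    stop("invalid config: 'encounter_rate' must be > 0", call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[1] < 20 ||
      age_range[2] <= age_range[1]) {
    stop("invalid config: 'age_range' must be c(min, max) with min >= 20",
         call. = FALSE)
  }
  if (length(tests) == 0 || !all(vapply(tests, inherits, TRUE, "test_spec"))) {
    stop("invalid config: 'tests' must be a non-empty list of test_spec",
         call. = FALSE)
  }
  if (!all(vapply(outcomes, inherits, TRUE, "outcome_spec"))) {
    stop("invalid config: 'outcomes' must be a list of outcome_spec",
         call. = FALSE)
  }
  test_names <- vapply(tests, `[[`, "", "test_name")
  for (oc in outcomes) {
    unknown <- setdiff(names(oc$weights), test_names)
    if (length(unknown) > 0) {
      stop(sprintf(
        "invalid config: outcome '%s' weights reference unknown test(s): %s",
        oc$code, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), tests = tests, outcomes = outcomes,
    years = as.integer(years), start_year = as.integer(start_year),
    sex_ratio = sex_ratio, age_range = as.integer(age_range),
    encounter_rate = encounter_rate, transfer_prob = transfer_prob,
    missing_prob = missing_prob, repeat_prob = repeat_prob,
    death_prob = death_prob, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Standard reference-interval table of a simulation config
#'
#' Expands each test's standard interval across both sexes and all 10-year
#' age groups covered by the configured age range, keyed by the stratum
#' fields, i.e. the table a health authority would publish.
#'
#' @param config A [sim_config()].
#' @return A tibble with the stratum keys plus `lower` and `upper`.
#' @export
standard_ri_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lo <- (config$age_range[1] %/% 10L) * 10L
  hi <- ((config$age_range[2] + config$years - 1L) %/% 10L) * 10L
  bands <- age_group_of(seq(lo, hi, by = 10L))
  purrr::map_dfr(config$tests, function(ts) {
    tidyr::expand_grid(sex = c("F", "M"), age_group = bands) |>
      dplyr::mutate(test_name = ts$test_name, specimen = ts$specimen,
                    unit = ts$unit, lab_id = ts$lab_id,
                    lower = ts$standard_ri[1], upper = ts$standard_ri[2])
  }) |>
    dplyr::select(dplyr::all_of(c(stratum_keys, "lower", "upper")))
}

test_param_table <- function(tests) {
  purrr::map_dfr(tests, function(ts) {
    tibble::tibble(
      test_name = ts$test_name, specimen = ts$specimen, unit = ts$unit,
      lab_id = ts$lab_id, ri_lower = ts$standard_ri[1],
      ri_upper = ts$standard_ri[2], baseline_mean = ts$baseline_mean,
      baseline_sd = ts$baseline_sd, true_beta0 = ts$true_beta0,
      true_beta1 = ts$true_beta1, true_theta = ts$true_theta
    )
  })
}

#' Simulate an EHR-like cohort
#'
#' Generates laboratory records, hospital encounters and a truth bundle with
#' the statistical structure the downstream analysis assumes:
#' per-stratum seasonal cosinor signal in lab values, admissions optionally
#' split into <24 h transfer encounters, repeated measurements within the
#' 24 h window, per-test missingness, deaths within 28 days of an admission,
#' and per-admission diagnosis outcomes whose probability depends on
#' abnormality relative to the seasonally-true (or standard) reference
#' interval.
#'
#' Time is modelled on a 52-week calendar: an admission lands in a uniformly
#' drawn ISO week (1--52) of a uniformly drawn study year, at a uniform
#' offset within that week. Separate admissions of one patient are spaced at
#' least 72 h apart so only deliberate transfer splits ever merge downstream.
#'
#' @param config A [sim_config()].
#' @return A list with `lab_records` (tibble), `encounters` (tibble), and
#'   `truth` (generating parameters, per-record true abnormality flags, and
#'   the per-admission outcome table).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  study_start <- iso_week_start(config$start_year, 1)

  patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = ifelse(runif(n) < config$sex_ratio, "F", "M"),
    age_entry = sample(config$age_range[1]:(config$age_range[2] - 1L), n,
                       replace = TRUE)
  )

  # --- admissions: Poisson count per patient (min 1), spaced >= 72 h -------
  n_adm <- pmax(1L, rpois(n, config$encounter_rate * config$years))
  adm <- tibble::tibble(
    patient_id = rep(patients$patient_id, n_adm),
    year = config$start_year +
      sample.int(config$years, sum(n_adm), replace = TRUE) - 1L,
    week = sample.int(52L, sum(n_adm), replace = TRUE)
  )
  adm$start <- iso_week_start(adm$year, adm$week) +
    floor(runif(nrow(adm), 0, 7 * 86400))
  adm$end <- adm$start + floor(runif(nrow(adm), 0.25, 7) * 86400)
  adm <- adm |>
    dplyr::arrange(.data$patient_id, .data$start) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter({
      keep <- rep(TRUE, dplyr::n())
      if (dplyr::n() > 1) {
        last_end <- end[1]
        for (i in 2:dplyr::n()) {
          if (as.numeric(start[i]) - as.numeric(last_end) < 72 * 3600) {
            keep[i] <- FALSE
          } else {
            last_end <- end[i]
          }
        }
      }
      keep
    }) |>
    dplyr::mutate(adm_id = sprintf("%s_S%02d", .data$patient_id,
                                   dplyr::row_number())) |>
    dplyr::ungroup()
  adm <- dplyr::left_join(adm, patients, by = "patient_id")
  adm$age_at_start <- pmin(
    adm$age_entry + floor(as.numeric(adm$start - study_start,
                                     units = "days") / 365.25),
    config$age_range[2] + config$years
  )

  # --- lab records ---------------------------------------------------------
  params <- test_param_table(config$tests)
  grid <- tidyr::expand_grid(adm_id = adm$adm_id,
                             test_name = params$test_name)
  grid <- grid[runif(nrow(grid)) >= config$missing_prob, ]
  n_rep <- 1L + rbinom(nrow(grid), 1L, config$repeat_prob)
  grid <- grid[rep(seq_len(nrow(grid)), n_rep), ]
  recs <- grid |>
    dplyr::left_join(adm[, c("adm_id", "patient_id", "start", "sex",
                             "age_entry")], by = "adm_id") |>
    dplyr::left_join(params, by = "test_name")
  recs$timestamp <- recs$start + floor(runif(nrow(recs), 0, 24 * 3600))
  recs$week <- week_of_year(recs$timestamp)
  seasonal_dev <- cosinor_value(recs$true_beta0, recs$true_beta1,
                                recs$true_theta, recs$week)
  recs$value <- recs$baseline_mean +
    recs$baseline_sd * (seasonal_dev + rnorm(nrow(recs)))
  recs$age_at_draw <- pmin(
    recs$age_entry + floor(as.numeric(recs$timestamp - study_start,
                                      units = "days") / 365.25),
    config$age_range[2] + config$years
  )
  recs <- recs[order(recs$adm_id, recs$test_name, recs$timestamp), ]
  recs$record_id <- sprintf("R%07d", seq_len(nrow(recs)))

  # true abnormality flags against the standard and seasonally-true RI
  shift <- recs$baseline_sd * seasonal_dev
  recs$flag_standard_true <- ri_flag(recs$value, recs$ri_lower, recs$ri_upper)
  recs$flag_seasonal_true <- ri_flag(recs$value, recs$ri_lower + shift,
                                     recs$ri_upper + shift)
  ri_width <- recs$ri_upper - recs$ri_lower
  recs$dev_standard <- flag_depth(recs$value, recs$ri_lower, recs$ri_upper,
                                  ri_width)
  recs$dev_seasonal <- flag_depth(recs$value, recs$ri_lower + shift,
                                  recs$ri_upper + shift, ri_width)

  # --- outcome labels per admission ---------------------------------------
  adm_flags <- recs |>
    dplyr::group_by(.data$adm_id, .data$test_name) |>
    dplyr::summarise(
      flag_standard = .data$flag_standard_true[which.max(.data$dev_standard)],
      flag_seasonal = .data$flag_seasonal_true[which.max(.data$dev_seasonal)],
      .groups = "drop"
    )
  adm$codes <- ""
  outcome_truth <- NULL
  for (oc in config$outcomes) {
    col <- if (oc$uses_seasonal_truth) "flag_seasonal" else "flag_standard"
    contrib <- adm_flags |>
      dplyr::filter(.data$test_name %in% names(oc$weights)) |>
      dplyr::mutate(w = oc$weights[.data$test_name] * .data[[col]]) |>
      dplyr::group_by(.data$adm_id) |>
      dplyr::summarise(lp = sum(.data$w), .groups = "drop")
    lp <- stats::setNames(rep(0, nrow(adm)), adm$adm_id)
    lp[contrib$adm_id] <- contrib$lp
    logit <- oc$intercept + lp + oc$sex_weight * (adm$sex == "M")
    label <- rbinom(nrow(adm), 1L, plogis(logit))
    adm$codes <- ifelse(
      label == 1L,
      ifelse(adm$codes == "", oc$code, paste(adm$codes, oc$code, sep = ";")),
      adm$codes
    )
    outcome_truth <- dplyr::bind_rows(outcome_truth, tibble::tibble(
      adm_id = adm$adm_id, code = oc$code, prob = plogis(logit),
      label = label
    ))
  }

  # --- deaths within 28 days of a random admission ------------------------
  dead <- patients$patient_id[runif(n) < config$death_prob]
  death_tbl <- adm |>
    dplyr::filter(.data$patient_id %in% dead) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(death_date = .data$start +
                    floor(runif(dplyr::n(), 0, 28 * 86400))) |>
    dplyr::select("patient_id", "death_date")
  adm <- dplyr::left_join(adm, death_tbl, by = "patient_id")

  # --- encounters: optionally split an admission into a <24 h transfer ----
  split <- runif(nrow(adm)) < config$transfer_prob
  dur <- as.numeric(adm$end - adm$start, units = "secs")
  cut_at <- floor(dur * runif(nrow(adm), 0.3, 0.7))
  gap <- floor(runif(nrow(adm), 1, 23) * 3600)
  enc_cols <- c("patient_id", "start", "end", "codes", "death_date", "sex",
                "age_at_start")
  first <- adm
  first$end <- dplyr::if_else(split, adm$start + cut_at, adm$end)
  second <- adm[split, ]
  second$start <- second$start + cut_at[split] + gap[split]
  second$end <- second$start + (dur[split] - cut_at[split])
  second$codes <- ""  # codes registered on the admitting encounter
  encounters <- dplyr::bind_rows(first[, enc_cols], second[, enc_cols]) |>
    dplyr::arrange(.data$patient_id, .data$start)

  lab_records <- recs |>
    dplyr::select("record_id", "patient_id", "test_name", "specimen", "unit",
                  "lab_id", "value", "timestamp", "sex", "age_at_draw") |>
    dplyr::arrange(.data$record_id)

  truth <- list(
    config = config,
    params = params,
    record_flags = recs |>
      dplyr::select("record_id", "adm_id", "week", "flag_standard_true",
                    "flag_seasonal_true"),
    admissions = adm |>
      dplyr::select("adm_id", "patient_id", "start", "end", "codes"),
    outcomes = outcome_truth
  )
  list(lab_records = lab_records, encounters = encounters, truth = truth)
}

# Depth of abnormality relative to an interval, normalized by its width;
# 0 inside the interval.
flag_depth <- function(value, lower, upper, width) {
  pmax(0, pmax(value - upper, lower - value) / width)
}

ts_fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
ts_parse <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` serializes the lab-record and encounter tables as UTF-8
#' CSV with ISO-8601 second-precision timestamps; `read_cohort()` reads them
#' back, restoring types. The round trip is the identity.
#'
#' @param cohort A list with `lab_records` and `encounters` (as from
#'   [simulate_cohort()]).
#' @param path Directory to write to / read from (created if needed).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a list
#'   with `lab_records` and `encounters`.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  labs <- cohort$lab_records
  labs$timestamp <- ts_fmt(labs$timestamp)
  readr::write_csv(labs, file.path(path, "lab_records.csv"), progress = FALSE)
  enc <- cohort$encounters
  enc$start <- ts_fmt(enc$start)
  enc$end <- ts_fmt(enc$end)
  enc$death_date <- ifelse(is.na(enc$death_date), "", ts_fmt(enc$death_date))
  readr::write_csv(enc, file.path(path, "encounters.csv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lab_file <- file.path(path, "lab_records.csv")
  enc_file <- file.path(path, "encounters.csv")
  labs <- suppressWarnings(readr::read_csv(
    lab_file, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      record_id = "c", patient_id = "c", test_name = "c", specimen = "c",
      unit = "c", lab_id = "c", value = "d", timestamp = "c", sex = "c",
      age_at_draw = "d"
    )
  ))
  stop_on_parse_problems(labs, lab_file)
  labs$timestamp <- ts_parse(labs$timestamp)
  enc <- suppressWarnings(readr::read_csv(
    enc_file, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = "c", start = "c", end = "c", codes = "c",
      death_date = "c", sex = "c", age_at_start = "d"
    )
  ))
  stop_on_parse_problems(enc, enc_file)
  enc$codes[is.na(enc$codes)] <- ""
  enc$start <- ts_parse(enc$start)
  enc$end <- ts_parse(enc$end)
  enc$death_date <- ts_parse(ifelse(enc$death_date %in% c("", NA),
                                    NA_character_, enc$death_date))
  list(lab_records = labs, encounters = enc)
}

stop_on_parse_problems <- function(df, file) {
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error in %s at line %d: expected %s, got '%s'",
                 basename(file), probs$row[1], probs$expected[1],
                 probs$actual[1]), call. = FALSE)
  }
  invisible(df)
}
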
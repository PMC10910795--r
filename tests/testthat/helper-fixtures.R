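# Shared fixtures: small configs and hand-built tables used across tests.

tiny_tests <- function(beta1 = c(0.5, 0.3), theta = c(2, 40)) {
  list(
    test_spec("crp", "P", "mg/L", "LAB1", standard_ri = c(0, 10),
              baseline_mean = 6, baseline_sd = 4,
              true_beta1 = beta1[1], true_theta = theta[1]),
    test_spec("hgb", "B", "mmol/L", "LAB1", standard_ri = c(7.4, 10.0),
              baseline_mean = 8.7, baseline_sd = 0.9,
              true_beta1 = beta1[2], true_theta = theta[2])
  )
}

tiny_outcome <- function() {
  list(outcome_spec("I21", intercept = -2, weights = c(crp = 1.5, hgb = -1),
                    sex_weight = 0.5, uses_seasonal_truth = TRUE))
}

tiny_config <- function(n_patients = 200, seed = 1, tests = tiny_tests(),
                        ...) {
  sim_config(n_patients = n_patients, tests = tests,
             outcomes = tiny_outcome(), years = 2, encounter_rate = 1.5,
             seed = seed, ...)
}

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Hand-written encounter table: patient/start/end/codes (+ optional fields).
make_encounters <- function(patient_id, start, end, codes = "",
                            age_at_start = 50, sex = "F") {
  tibble::tibble(
    patient_id = patient_id, start = ts_utc(start), end = ts_utc(end),
    codes = codes, death_date = ts_utc(NA_character_),
    sex = sex, age_at_start = age_at_start
  )
}

# Lab record rows with explicit values/timestamps for one test.
make_records <- function(patient_id, value, timestamp, test_name = "crp",
                         specimen = "P", unit = "mg/L", lab_id = "LAB1",
                         sex = "F", age_at_draw = 50) {
  tibble::tibble(
    record_id = sprintf("R%03d", seq_along(value)),
    patient_id = patient_id, test_name = test_name, specimen = specimen,
    unit = unit, lab_id = lab_id, value = value,
    timestamp = ts_utc(timestamp), sex = sex, age_at_draw = age_at_draw
  )
}

# Weekly means generated noiselessly from the cosinor.
noiseless_weekly <- function(beta0, beta1, theta, n = 100) {
  tibble::tibble(week = 1:52,
                 mean = cosinor_value(beta0, beta1, theta, 1:52),
                 n = n)
}

# Simulate one stratum of weekly data in normalized units and fit it.
simulate_and_fit_stratum <- function(beta0, beta1, theta, per_week_n = 100,
                                     noise_sd = 1, seed = 1) {
  set.seed(seed)
  week <- rep(1:52, each = per_week_n)
  value <- cosinor_value(beta0, beta1, theta, week) +
    rnorm(length(week), sd = noise_sd)
  fit_sinusoid(weekly_aggregate(week, value))
}

angular_error <- function(a, b) {
  d <- abs(a - b) %% 52
  pmin(d, 52 - d)
}

# Brute-force Shapley oracle: average marginal contribution over all
# orderings, with the off-coalition features drawn from each background row.
brute_force_shap <- function(f, x_row, background) {
  p <- length(x_row)
  perms <- seasonri:::all_permutations(p)
  phi <- numeric(p)
  for (b in seq_len(nrow(background))) {
    for (ord in perms) {
      z <- background[b, ]
      for (j in ord) {
        before <- f(matrix(z, 1))
        z[j] <- x_row[j]
        phi[j] <- phi[j] + (f(matrix(z, 1)) - before)
      }
    }
  }
  phi / (length(perms) * nrow(background))
}
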
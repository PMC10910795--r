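test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_cohort(tiny_config(seed = 11))
  s2 <- simulate_cohort(tiny_config(seed = 11))
  expect_identical(s1$lab_records, s2$lab_records)
  expect_identical(s1$encounters, s2$encounters)
  s3 <- simulate_cohort(tiny_config(seed = 12))
  expect_false(identical(s1$lab_records, s3$lab_records))
})

test_that("invalid configs raise errors naming the offending field", {
  expect_error(tiny_config(sex_ratio = 1.4), "sex_ratio")
  expect_error(tiny_config(n_patients = 0), "n_patients")
  expect_error(tiny_config(missing_prob = -0.1), "missing_prob")
  expect_error(sim_config(10, tiny_tests(),
                          list(outcome_spec("X01", 0, c(nope = 1)))),
               "nope")
  expect_error(test_spec("a", standard_ri = c(5, 2), baseline_mean = 1,
                         baseline_sd = 1), "lower < upper")
  expect_error(test_spec("a", standard_ri = c(0, 1), baseline_mean = 1,
                         baseline_sd = 1, true_beta1 = 1.5), "true_beta1")
})

test_that("weekly means carry the generating cosine", {
  # strong amplitude, phase at week 2: week 2 must beat week 28, and the
  # weekly profile must track the closed-form cosine
  cfg <- sim_config(
    n_patients = 1500,
    tests = list(test_spec("crp", "P", "mg/L", "LAB1", c(0, 10),
                           baseline_mean = 6, baseline_sd = 4,
                           true_beta1 = 0.5, true_theta = 2)),
    years = 2, encounter_rate = 2, missing_prob = 0, repeat_prob = 0,
    transfer_prob = 0, death_prob = 0, seed = 5
  )
  sim <- simulate_cohort(cfg)
  recs <- sim$lab_records
  z <- (recs$value - 6) / 4  # back to normalized units
  wk <- pmin(lubridate::isoweek(recs$timestamp), 52)
  weekly <- tapply(z, wk, mean)
  expect_gt(weekly[["2"]], weekly[["28"]])
  expect_equal(sign(weekly[["2"]] - weekly[["28"]]),
               sign(cosinor_value(0, 0.5, 2, 2) - cosinor_value(0, 0.5, 2, 28)))
  truth <- cosinor_value(0, 0.5, 2, as.integer(names(weekly)))
  expect_lt(max(abs(weekly - truth)), 0.35)  # Monte-Carlo error at ~100/wk
})

test_that("no seasonal signal leaves weekly means at baseline", {
  cfg <- sim_config(
    n_patients = 800,
    tests = list(test_spec("flat", "P", "U", "LAB1", c(-2, 2),
                           baseline_mean = 0, baseline_sd = 1)),
    years = 2, encounter_rate = 2, missing_prob = 0, repeat_prob = 0,
    death_prob = 0, seed = 6
  )
  sim <- simulate_cohort(cfg)
  wk <- pmin(lubridate::isoweek(sim$lab_records$timestamp), 52)
  weekly <- tapply(sim$lab_records$value, wk, mean)
  se <- sd(sim$lab_records$value) / sqrt(length(weekly) *
                                           mean(table(wk)))
  expect_lt(abs(mean(weekly) - 0), 3 * sd(sim$lab_records$value) /
              sqrt(nrow(sim$lab_records)) * sqrt(52))
  expect_lt(abs(mean(sim$lab_records$value)), 3 * se * sqrt(52))
})

test_that("sex ratio is honoured within binomial error", {
  cfg <- tiny_config(n_patients = 1000, seed = 7, sex_ratio = 0.6)
  sim <- simulate_cohort(cfg)
  pats <- unique(sim$encounters[, c("patient_id", "sex")])
  frac <- mean(pats$sex == "F")
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(pats)))
})

test_that("without transfers no two encounters of a patient start <24h apart", {
  sim <- simulate_cohort(tiny_config(n_patients = 300, seed = 8,
                                     transfer_prob = 0))
  gaps <- sim$encounters |>
    dplyr::arrange(patient_id, start) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(min_gap = ifelse(dplyr::n() > 1,
                                      min(diff(as.numeric(start))), Inf))
  expect_true(all(gaps$min_gap >= 24 * 3600))
  with_tr <- simulate_cohort(tiny_config(n_patients = 500, seed = 8,
                                         transfer_prob = 0.5))
  gaps2 <- with_tr$encounters |>
    dplyr::arrange(patient_id, start) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(min_gap = ifelse(dplyr::n() > 1,
                                      min(diff(as.numeric(start))), Inf))
  expect_true(any(gaps2$min_gap < 24 * 3600))
})

test_that("outcome truth has more cases when seasonal flags fire", {
  sim <- simulate_cohort(tiny_config(n_patients = 500, seed = 9))
  expect_true(all(c("record_flags", "outcomes", "params") %in%
                    names(sim$truth)))
  oc <- sim$truth$outcomes
  expect_true(all(oc$label %in% 0:1))
  expect_true(all(oc$prob > 0 & oc$prob < 1))
  # admissions with positive seasonal-true CRP flag should be enriched
  flags <- sim$truth$record_flags |>
    dplyr::group_by(adm_id) |>
    dplyr::summarise(any_abn = any(flag_seasonal_true != 0))
  joined <- dplyr::inner_join(oc, flags, by = "adm_id")
  expect_gt(mean(joined$label[joined$any_abn]),
            mean(joined$label[!joined$any_abn]))
})

test_that("cohort round-trips through CSV exactly", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(tiny_config(n_patients = 50, seed = 10))
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$lab_records),
               as.data.frame(sim$lab_records))
  expect_equal(as.data.frame(back$encounters),
               as.data.frame(sim$encounters))
})

test_that("empty and malformed cohort files are handled explicitly", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(tiny_config(n_patients = 5, seed = 1))
  empty <- list(lab_records = sim$lab_records[0, ],
                encounters = sim$encounters[0, ])
  write_cohort(empty, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$lab_records), 0)

  write_cohort(sim, dir)
  labfile <- file.path(dir, "lab_records.csv")
  lines <- readLines(labfile)
  bad <- strsplit(lines[3], ",")[[1]]
  bad[7] <- "not-a-number"
  lines[3] <- paste(bad, collapse = ",")
  writeLines(lines, labfile)
  expect_error(read_cohort(dir), "line 3")
})

test_that("hand-written rows parse into matching records", {
  dir <- withr::local_tempdir()
  labs <- make_records("P1", c(1.5, 2.5, 3.5),
                       c("2012-01-02 08:00:00", "2012-01-03 09:30:00",
                         "2012-02-01 10:00:00"))
  enc <- make_encounters("P1", "2012-01-02 08:00:00", "2012-01-04 08:00:00")
  write_cohort(list(lab_records = labs, encounters = enc), dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$lab_records), 3)
  expect_equal(back$lab_records$value, c(1.5, 2.5, 3.5))
  expect_equal(back$lab_records$timestamp, labs$timestamp)
})
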
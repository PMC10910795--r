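test_that("encounters separated by under 24h merge, others do not", {
  enc <- make_encounters(
    c("P1", "P1"),
    c("2012-03-01 08:00:00", "2012-03-02 08:00:00"),  # 23h after first end
    c("2012-03-01 09:00:00", "2012-03-02 12:00:00")
  )
  expect_equal(nrow(merge_encounters(enc)), 1)

  enc25 <- make_encounters(
    c("P1", "P1"),
    c("2012-03-01 08:00:00", "2012-03-02 10:00:00"),  # 25h gap
    c("2012-03-01 09:00:00", "2012-03-02 12:00:00")
  )
  expect_equal(nrow(merge_encounters(enc25)), 2)

  # tie at exactly 24h starts a new admission (strict < rule)
  enc24 <- make_encounters(
    c("P1", "P1"),
    c("2012-03-01 08:00:00", "2012-03-02 09:00:00"),
    c("2012-03-01 09:00:00", "2012-03-02 12:00:00")
  )
  expect_equal(nrow(merge_encounters(enc24)), 2)
})

test_that("six encounters across two patients chain by the gap rule", {
  # P1 gaps: 2h, 30h, 5h -> admissions {e1,e2}, {e3,e4}; P2 gap 40h -> 2
  enc <- make_encounters(
    c("P1", "P1", "P1", "P1", "P2", "P2"),
    c("2012-01-02 08:00:00", "2012-01-02 12:00:00", "2012-01-03 20:00:00",
      "2012-01-04 03:00:00", "2012-02-01 08:00:00", "2012-02-03 02:00:00"),
    c("2012-01-02 10:00:00", "2012-01-02 14:00:00", "2012-01-03 22:00:00",
      "2012-01-04 06:00:00", "2012-02-01 10:00:00", "2012-02-03 04:00:00"),
    codes = c("I21.2", "I10", "", "I50.0", "I64", "")
  )
  adm <- merge_encounters(enc)
  expect_equal(nrow(adm), 4)
  expect_equal(adm$n_encounters, c(2L, 2L, 1L, 1L))
  # codes are unioned across members
  expect_equal(adm$codes[1], "I10;I21.2")
  # merging admissions again is a no-op (idempotence)
  again <- merge_encounters(adm)
  expect_equal(nrow(again), 4)
  expect_equal(again$start, adm$start)
  expect_equal(again$end, adm$end)
  expect_equal(again$codes, adm$codes)
})

test_that("overlapping encounters merge rather than error", {
  enc <- make_encounters(
    c("P1", "P1"),
    c("2012-03-01 08:00:00", "2012-03-01 06:00:00"),
    c("2012-03-02 09:00:00", "2012-03-01 10:00:00")
  )
  adm <- merge_encounters(enc)
  expect_equal(nrow(adm), 1)
  expect_equal(adm$start, ts_utc("2012-03-01 06:00:00"))
  expect_equal(adm$end, ts_utc("2012-03-02 09:00:00"))
  expect_error(merge_encounters(make_encounters("P1", "2012-03-02 08:00:00",
                                                "2012-03-01 08:00:00")),
               "start > end")
})

test_that("lab window is closed, one-sided, and single-assignment", {
  adm <- merge_encounters(make_encounters("P1", "2012-03-01 08:00:00",
                                          "2012-03-05 08:00:00"))
  recs <- make_records(
    "P1", c(1, 2, 3, 4),
    c("2012-03-02 07:54:00",   # +23.9h -> inside
      "2012-03-02 08:06:00",   # +24.1h -> outside
      "2012-02-29 07:00:00",   # 1h before admission -> outside
      "2012-03-01 08:00:00")   # exactly at start -> inside
  )
  att <- suppressMessages(attach_labs(adm, recs))
  expect_setequal(att$record_id, c("R001", "R004"))
  expect_equal(attr(att, "n_dropped"), 2)

  # two qualifying admissions: record goes to the earliest only
  adm2 <- merge_encounters(make_encounters(
    c("P1", "P1"),
    c("2012-03-01 08:00:00", "2012-03-01 20:00:00"),
    c("2012-03-01 09:00:00", "2012-03-01 21:00:00")
  ))
  # 12h gap: these merge into one admission; use pre-merge encounters
  expect_equal(nrow(adm2), 1)
  enc_sep <- make_encounters(
    c("P1", "P1"),
    c("2012-03-01 08:00:00", "2012-03-03 08:00:00"),
    c("2012-03-01 09:00:00", "2012-03-03 09:00:00")
  )
  adm_sep <- merge_encounters(enc_sep)
  rec_both <- make_records("P1", 1, "2012-03-03 08:30:00")
  att2 <- suppressMessages(attach_labs(adm_sep, rec_both))
  expect_equal(nrow(att2), 1)
  expect_equal(att2$admission_id, adm_sep$admission_id[2])
  # accounting: attached + dropped = total
  expect_equal(nrow(att2) + attr(att2, "n_dropped"), 1)
})

test_that("most abnormal repeat wins; all-normal keeps the last", {
  base <- tibble::tibble(
    admission_id = "A1", test_name = "crp", specimen = "P",
    lower = 0, upper = 10
  )
  # flags {0, +1}: the abnormal record wins
  two <- dplyr::bind_rows(base, base)
  two$value <- c(5, 12)
  two$timestamp <- ts_utc(c("2012-01-02 10:00:00", "2012-01-02 08:00:00"))
  two$record_id <- c("a", "b")
  expect_equal(select_most_abnormal(two)$record_id, "b")
  expect_equal(select_most_abnormal(two)$flag, 1L)

  # all flags 0: last by timestamp, feature value 0
  two$value <- c(5, 6)
  sel <- select_most_abnormal(two)
  expect_equal(sel$record_id, "a")
  expect_equal(sel$flag, 0L)

  # -1 at relative depth 0.4 beats +1 at depth 0.1
  two$value <- c(-4, 11)
  sel <- select_most_abnormal(two)
  expect_equal(sel$record_id, "a")
  expect_equal(sel$flag, -1L)
  expect_equal(sel$rel_dev, 0.4)

  # order invariance when deviations are distinct
  expect_equal(select_most_abnormal(two[2:1, ])$record_id, "a")
})

test_that("cohort filters apply in order with exact counts", {
  enc <- make_encounters(
    sprintf("P%02d", 1:10),
    rep("2012-03-01 08:00:00", 10), rep("2012-03-02 08:00:00", 10),
    codes = c(rep("I21.2", 6), rep("I50.1", 2), "", ""),
    age_at_start = c(19, rep(50, 9))
  )
  adm <- merge_encounters(enc)
  # test A measured at 1 of the 9 age-eligible admissions (1/9 < 20%),
  # test B at all 10
  recs <- dplyr::bind_rows(
    make_records("P02", 1, "2012-03-01 09:00:00", test_name = "A"),
    make_records(sprintf("P%02d", 1:10), 1:10,
                 rep("2012-03-01 10:00:00", 10), test_name = "B")
  )
  recs$record_id <- sprintf("R%03d", seq_len(nrow(recs)))
  recs$age_at_draw <- c(50, 19, rep(50, 9))
  att <- suppressMessages(attach_labs(adm, recs))
  out <- apply_cohort_filters(att, adm, min_patients = 3)

  # rule 1: patient P01 (age 19) dropped: 1 admission, 1 record (its B draw)
  expect_equal(out$report$admissions_removed[out$report$rule == "age"], 1)
  expect_equal(out$report$records_removed[out$report$rule == "age"], 1)
  # rule 2: codes truncated to level 3
  expect_true(all(!grepl("\\.", out$admissions$codes)))
  expect_true("I21" %in% unlist(strsplit(out$admissions$codes, ";")))
  # rule 3: test A dropped (1/9 < 20%)
  expect_false("A" %in% out$records$test_name)
  expect_equal(out$report$records_removed[out$report$rule == "test_coverage"],
               1)
  # rule 4: I21 kept (5 patients >= 3), I50 dropped (2 < 3)
  expect_equal(out$outcome_codes, "I21")
  expect_equal(sum(out$report$records_removed), 2)
})

test_that("survivor mask excludes draws near death; empty cohort errors", {
  enc <- make_encounters(
    c("P1", "P2"), rep("2012-03-01 08:00:00", 2),
    rep("2012-03-02 08:00:00", 2)
  )
  enc$death_date <- ts_utc(c("2012-03-10 08:00:00", NA))  # P1 dies day 9
  adm <- merge_encounters(enc)
  recs <- make_records(c("P1", "P2"), c(1, 2),
                       rep("2012-03-01 09:00:00", 2))
  att <- suppressMessages(attach_labs(adm, recs))
  out <- apply_cohort_filters(att, adm, min_patients = 1)
  expect_equal(out$fitting_ids, "R002")  # P1's draw masked from fitting
  expect_equal(nrow(out$records), 2)     # but retained in the cohort

  # death 40 days after admission: not masked
  enc$death_date <- ts_utc(c("2012-04-10 08:00:00", NA))
  adm2 <- merge_encounters(enc)
  att2 <- suppressMessages(attach_labs(adm2, recs))
  out2 <- apply_cohort_filters(att2, adm2, min_patients = 1)
  expect_setequal(out2$fitting_ids, c("R001", "R002"))

  recs_young <- make_records("P1", 1, "2012-03-01 09:00:00",
                             age_at_draw = 10)
  enc_young <- make_encounters("P1", "2012-03-01 08:00:00",
                               "2012-03-02 08:00:00", age_at_start = 10)
  adm_young <- merge_encounters(enc_young)
  att_young <- suppressMessages(attach_labs(adm_young, recs_young))
  expect_error(apply_cohort_filters(att_young, adm_young, min_patients = 1),
               "empty cohort")
})
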
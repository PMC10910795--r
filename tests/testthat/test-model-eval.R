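test_that("AUROC and AUPRC match independent oracles", {
  set.seed(61)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  skip_if_not_installed("pROC")
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
  # hand-enumerated AP on a tiny case: scores sorted .9(1) .8(0) .7(1) .6(0)
  s <- c(0.9, 0.8, 0.7, 0.6)
  y <- c(1, 0, 1, 0)
  # thresholds: P = 1/1, 1/2, 2/3, 2/4; recall steps at positives: 1/2, 1/2
  ap <- 0.5 * 1 + 0.5 * (2 / 3)
  expect_equal(auprc(s, y), ap)
  # perfect and random floors
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("patient-level split keeps patients whole and is seeded", {
  pats <- sprintf("P%02d", rep(1:10, times = 1 + (1:10 %% 3)))
  sp <- split_by_patient(pats, 0.7, seed = 3)
  expect_length(sp$dev_patients, 7)
  expect_length(sp$test_patients, 3)
  sp2 <- split_by_patient(pats, 0.7, seed = 3)
  expect_identical(sp$dev_patients, sp2$dev_patients)
  # all admissions of each patient on one side
  side <- tapply(sp$dev, pats, function(v) length(unique(v)))
  expect_true(all(side == 1))
  expect_error(split_by_patient(rep("P1", 5)), ">= 2 patients")
})

test_that("balanced resampling equalizes classes by oversampling", {
  labels <- c(rep(1, 10), rep(0, 90))
  idx <- balanced_resample(labels, seed = 4)
  expect_length(idx, 180)
  expect_equal(sum(labels[idx] == 1), 90)
  expect_equal(sum(labels[idx] == 0), 90)
  expect_setequal(unique(idx[labels[idx] == 0]), 11:100)  # majority intact
  expect_identical(balanced_resample(labels, seed = 4), idx)

  even <- rep(c(0, 1), 25)
  idx2 <- balanced_resample(even, seed = 5)
  expect_length(idx2, 50)
  expect_equal(sort(idx2), 1:50)  # both classes kept as-is, only shuffled
  expect_error(balanced_resample(rep(0, 10)), "one class")
})

test_that("random search selects the best-F1 configuration", {
  set.seed(62)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "sex")))
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(n, sd = 0.3) > 0)
  pats <- sprintf("P%03d", rep(1:100, each = 4))

  grid1 <- data.frame(maxdepth = 4, minsplit = 10, cp = 0.001)
  m <- tune_and_fit("decision_tree", x, y, pats, n_search = 1,
                    cv_folds = 3, grid = grid1, seed = 6)
  expect_equal(nrow(m$search_log), 1)
  expect_true(m$search_log$selected)

  m2 <- tune_and_fit("decision_tree", x, y, pats, n_search = 5,
                     cv_folds = 3, seed = 6)
  log <- m2$search_log
  expect_equal(which(log$selected), which.max(log$mean_f1))
  expect_error(tune_and_fit("decision_tree", x, rep(1L, n), pats),
               "single class")
})

test_that("separable data reaches near-perfect development F1", {
  set.seed(63)
  n <- 300
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- as.integer(x[, 1] > 0)
  pats <- sprintf("P%03d", rep(1:75, each = 4))
  for (fam in c("decision_tree", "neural_net", "adaboost",
                "random_forest")) {
    m <- tune_and_fit(fam, x, y, pats, n_search = 2, cv_folds = 3, seed = 7)
    f1 <- f1_score(predict_scores(m, x), y)
    expect_gte(f1, 0.95)
  }
})

test_that("identical models give an all-zero paired difference distribution", {
  set.seed(64)
  n <- 200
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(x[, 1]))
  m <- fit_classifier("decision_tree", x, y,
                      list(maxdepth = 3, minsplit = 20, cp = 0.01))
  cmp <- evaluate_pair(m, m, x, x, y, n_boots = 50, bca_boots = 500,
                       seed = 8)
  expect_true(all(cmp$diff_auroc == 0))
  expect_true(all(cmp$diff_auprc == 0))
  expect_equal(unname(cmp$bca_auroc), c(0, 0))
  expect_equal(cmp$verdict_auroc, "no_difference")
})

test_that("a perfect model beats a random scorer in every boot", {
  set.seed(65)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(0, n, 1, dimnames = list(NULL, "f"))
  perfect <- structure(list(fit = NULL, family = "mock",
                            feature_names = "f"), class = "seasonri_model")
  # stub: dispatch through scores computed outside the model interface
  s_perfect <- as.numeric(y)
  s_random <- runif(n)
  expect_equal(auroc(s_perfect, y), 1)
  boots <- replicate(200, {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) NA_real_
    else auroc(s_perfect[idx], y[idx]) - auroc(s_random[idx], y[idx])
  })
  boots <- boots[!is.na(boots)]
  expect_true(all(boots > 0))
  expect_lt(abs(mean(boots) - 0.5), 0.1)
})

test_that("boot resamples are paired, indexed by seed, and class-complete", {
  set.seed(66)
  n <- 120
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  m1 <- fit_classifier("decision_tree", x, y,
                       list(maxdepth = 2, minsplit = 20, cp = 0.01))
  m2 <- fit_classifier("neural_net", x, y,
                       list(size = 3, decay = 0.01, maxit = 100))
  cmp_a <- evaluate_pair(m1, m2, x, x, y, n_boots = 80, bca_boots = 500,
                         seed = 9)
  cmp_b <- evaluate_pair(m1, m2, x, x, y, n_boots = 80, bca_boots = 500,
                         seed = 9)
  expect_identical(cmp_a$diff_auroc, cmp_b$diff_auroc)
  expect_length(cmp_a$diff_auroc, 80)
  # the point estimate lies inside its own percentile CI
  expect_gte(cmp_a$auroc_v1, cmp_a$ci["2.5%", "auroc_v1"] - 0.05)
  expect_lte(cmp_a$auroc_v1, cmp_a$ci["97.5%", "auroc_v1"] + 0.05)

  # heavily imbalanced labels force single-class redraws but keep n_boots
  y_rare <- c(rep(1L, 3), rep(0L, n - 3))
  cmp_r <- evaluate_pair(m1, m2, x, x, y_rare, n_boots = 40,
                         bca_boots = 500, seed = 10)
  expect_length(cmp_r$diff_auroc, 40)
  expect_true(all(is.finite(cmp_r$diff_auroc)))
})

test_that("BCa matches the percentile interval for symmetric samples", {
  set.seed(67)
  x <- rnorm(1000)
  bca <- bca_interval(x, n_boots = 4000, seed = 11)
  # brute-force percentile oracle for the mean
  set.seed(991)
  boots <- replicate(4000, mean(sample(x, replace = TRUE)))
  perc <- unname(quantile(boots, c(0.025, 0.975)))
  expect_lt(abs(bca[["lower"]] - perc[1]), 0.02)
  expect_lt(abs(bca[["upper"]] - perc[2]), 0.02)

  expect_equal(unname(bca_interval(rep(0, 100))), c(0, 0))

  shifted <- rnorm(1000, mean = 5)
  ci <- bca_interval(shifted, n_boots = 2000, seed = 12)
  expect_gt(ci[["lower"]], 0)
})

test_that("BCa agrees with the boot package on skewed samples", {
  skip_if_not_installed("boot")
  set.seed(68)
  x <- rexp(300) - 0.8  # skewed, mean near 0.2
  ours <- bca_interval(x, n_boots = 5000, seed = 13)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 5000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_lt(abs(ours[["lower"]] - ref[1]), 0.03)
  expect_lt(abs(ours[["upper"]] - ref[2]), 0.03)
})
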
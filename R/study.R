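#' Canonical synthetic study configuration
#'
#' The fixed study conditions used by the package's end-to-end experiments:
#' three seasonally varying laboratory tests with amplitudes of 0.5--0.8
#' normalized units and phases away from the week-0/52 seam (where a Wald
#' test of the phase against zero is powerless), a four-year window, one
#' cardiovascular-style outcome whose risk depends on abnormality relative
#' to the seasonally-true reference interval, and desk-scale model-search
#' and bootstrap sizes (3 random-search configurations over a small
#' neural-net grid, 3 patient-grouped CV folds, 200 paired boots, 2,000 BCa
#' boots). With `seasonal = FALSE` every true amplitude is zero — the null
#' condition under which version 1 and version 2 must coincide.
#'
#' @param n_patients Number of synthetic patients.
#' @param seasonal `TRUE` for the seasonal-signal condition, `FALSE` for the
#'   null (all true amplitudes 0).
#' @param seed Master seed.
#' @param families Model families to evaluate.
#' @return A [pipeline_config()].
#' @export
synthetic_study_config <- function(n_patients = 2000, seasonal = TRUE,
                                   seed = 1, families = "neural_net") {
  amp <- function(a) if (seasonal) a else 0
  tests <- list(
    test_spec("crp", "P", "mg/L", "LAB1", standard_ri = c(0, 10),
              baseline_mean = 6, baseline_sd = 4,
              true_beta1 = amp(0.8), true_theta = 8),
    test_spec("hgb", "B", "mmol/L", "LAB1", standard_ri = c(7.4, 10.0),
              baseline_mean = 8.7, baseline_sd = 0.9,
              true_beta1 = amp(0.6), true_theta = 30),
    test_spec("egfr", "P", "mL/min", "LAB1", standard_ri = c(48, 115),
              baseline_mean = 78, baseline_sd = 22,
              true_beta1 = amp(0.5), true_theta = 20)
  )
  outcomes <- list(
    outcome_spec("I21", intercept = -2.2,
                 weights = c(crp = 1.3, hgb = -1.0, egfr = -1.3),
                 sex_weight = 0.4, uses_seasonal_truth = TRUE)
  )
  sim <- sim_config(
    n_patients = n_patients, tests = tests, outcomes = outcomes,
    years = 4, start_year = 2012, sex_ratio = 0.5, age_range = c(20, 60),
    encounter_rate = 1, transfer_prob = 0.1, missing_prob = 0.15,
    repeat_prob = 0.1, death_prob = 0.02, seed = seed
  )
  pipeline_config(
    sim,
    cohort = list(min_patients = 50),
    seasonal = list(rule = "amplitude_phase"),
    model = list(
      families = families, n_search = 3, cv_folds = 3,
      grids = list(neural_net = expand.grid(size = c(2L, 4L),
                                            decay = c(1e-3, 1e-2),
                                            maxit = 150L))
    ),
    eval = list(n_boots = 200, bca_boots = 2000),
    seed = seed
  )
}
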
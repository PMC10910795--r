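default_pipeline_opts <- list(
  cohort = list(gap_hours = 24, window_hours = 24, min_age = 20,
                coverage_frac = 0.2, min_patients = 1000, survival_days = 28),
  seasonal = list(alpha = 0.05, min_weeks = 26, min_n = 20, rule = "all"),
  model = list(families = "neural_net", n_search = 40, cv_folds = 5,
               dev_frac = 0.7, outcomes = NULL, grids = NULL),
  eval = list(n_boots = 1000, bca_boots = 10000, level = 0.95),
  shap = list(enabled = FALSE, n_permutations = 200, background_n = 100,
              max_rows = 200, exhaustive = FALSE)
)

#' Assemble a full pipeline configuration
#'
#' Gathers every tunable threshold of the analysis in one place, with the
#' conventional clinical-registry defaults: 24 h encounter merging and lab
#' window, age >= 20, 20% test coverage, 1,000-patient outcome prevalence,
#' 28-day fitting survivors, alpha 0.05, 70/30 patient-level split, up to 40
#' random-search configurations with 5-fold cross-validation, 1,000 paired
#' boots and 10,000 BCa boots. Override any subset via the stage lists.
#'
#' @param sim A [sim_config()] describing the synthetic cohort (or `NULL`
#'   when you run stages manually on your own tables).
#' @param cohort,seasonal,model,eval,shap Named lists overriding stage
#'   defaults (see `seasonri:::default_pipeline_opts`).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim, cohort = list(), seasonal = list(),
                            model = list(), eval = list(), shap = list(),
                            seed = 1) {
  cfg <- list(
    sim = sim,
    cohort = utils::modifyList(default_pipeline_opts$cohort, cohort),
    seasonal = utils::modifyList(default_pipeline_opts$seasonal, seasonal),
    model = utils::modifyList(default_pipeline_opts$model, model),
    eval = utils::modifyList(default_pipeline_opts$eval, eval),
    shap = utils::modifyList(default_pipeline_opts$shap, shap),
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: a `sim` block (with `tests` and
#' `outcomes` lists of field maps) plus optional `cohort`, `seasonal`,
#' `model`, `eval`, `shap` blocks and a `seed`. See
#' `system.file("extdata", "example-config.yaml", package = "seasonri")`
#' for a complete example.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$sim))
  tests <- lapply(y$sim$tests, function(t) do.call(test_spec, t))
  outcomes <- lapply(y$sim$outcomes, function(o) {
    o$weights <- unlist(o$weights)
    do.call(outcome_spec, o)
  })
  sim_args <- y$sim
  sim_args$tests <- tests
  sim_args$outcomes <- outcomes
  if (!is.null(sim_args$age_range)) {
    sim_args$age_range <- as.integer(unlist(sim_args$age_range))
  }
  sim <- do.call(sim_config, sim_args)
  pipeline_config(sim,
                  cohort = y$cohort %||% list(),
                  seasonal = y$seasonal %||% list(),
                  model = y$model %||% list(),
                  eval = y$eval %||% list(),
                  shap = y$shap %||% list(),
                  seed = y$seed %||% 1)
}

#' Run the full seasonal-adjustment analysis pipeline
#'
#' Stage order: simulate (or ingest) -> merge encounters -> attach labs ->
#' cohort filters -> stratum cosinor fits + FDR -> version 1 / version 2
#' feature encoding -> patient-level split, tuning and training per outcome
#' and family -> paired-bootstrap evaluation -> optional permutation-SHAP
#' explanation -> report. Each stage is seeded from the master seed, logged,
#' timed, and (when `output_dir` is given) checkpointed so a failed run can
#' resume; a stage failure halts with the stage name.
#'
#' @param config A `pipeline_config` (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @param output_dir Optional directory for stage outputs (CSV/JSON), the
#'   manifest, and checkpoints.
#' @param resume Reuse checkpoints found in `output_dir`.
#' @param quiet Suppress stage log lines.
#' @return A report list: `comparisons` (tidy tibble, one row per outcome x
#'   family), `net_gains`, `fits`, `filter_report`, `n_differing_cells`
#'   (feature cells differing between versions), optional `shap`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL, resume = FALSE,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6)
  timings <- list()
  ckpt_dir <- if (!is.null(output_dir)) {
    dir.create(file.path(output_dir, "checkpoints"), showWarnings = FALSE,
               recursive = TRUE)
    file.path(output_dir, "checkpoints")
  }
  stage <- function(name, fun) {
    if (resume && !is.null(ckpt_dir)) {
      f <- file.path(ckpt_dir, paste0(name, ".rds"))
      if (file.exists(f)) {
        if (!quiet) message(sprintf("[%s] resumed from checkpoint", name))
        return(readRDS(f))
      }
    }
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    if (!quiet) message(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    if (!is.null(ckpt_dir)) {
      saveRDS(out, file.path(ckpt_dir, paste0(name, ".rds")))
    }
    out
  }

  sim <- stage("simulate", function() simulate_cohort(config$sim))
  co <- config$cohort
  cohort <- stage("cohort", function() {
    adm <- merge_encounters(sim$encounters, gap_hours = co$gap_hours)
    attached <- suppressMessages(
      attach_labs(adm, sim$lab_records, window_hours = co$window_hours))
    apply_cohort_filters(attached, adm, min_age = co$min_age,
                         coverage_frac = co$coverage_frac,
                         min_patients = co$min_patients,
                         survival_days = co$survival_days)
  })
  se <- config$seasonal
  fits <- stage("seasonal_fit", function() {
    fitting <- cohort$records[cohort$records$record_id %in%
                                cohort$fitting_ids, ]
    fit_seasonality(fitting, min_weeks = se$min_weeks, min_n = se$min_n) |>
      fdr_correct(alpha = se$alpha, rule = se$rule)
  })

  ri_table <- standard_ri_table(config$sim)
  enc <- stage("encode", function() {
    tests <- dplyr::distinct(cohort$records[, c("test_name", "specimen")])
    p1 <- make_ri_provider(ri_table, version = 1)
    p2 <- make_ri_provider(ri_table, fits = fits, version = 2)
    m1 <- build_feature_matrix(cohort$admissions, cohort$records, p1, tests, 1)
    m2 <- build_feature_matrix(cohort$admissions, cohort$records, p2, tests, 2)
    split <- split_by_patient(cohort$admissions$patient_id,
                              dev_frac = config$model$dev_frac,
                              seed = seeds[2])
    scaler1 <- suppressWarnings(fit_scaler(m1$x[split$dev, , drop = FALSE]))
    scaler2 <- suppressWarnings(fit_scaler(m2$x[split$dev, , drop = FALSE]))
    list(
      m1 = m1, m2 = m2, split = split,
      n_differing_cells = sum(m1$x != m2$x),
      dev_v1 = apply_scaler(m1$x[split$dev, , drop = FALSE], scaler1),
      dev_v2 = apply_scaler(m2$x[split$dev, , drop = FALSE], scaler2),
      test_v1 = apply_scaler(m1$x[!split$dev, , drop = FALSE], scaler1),
      test_v2 = apply_scaler(m2$x[!split$dev, , drop = FALSE], scaler2)
    )
  })

  outcomes <- config$model$outcomes %||% cohort$outcome_codes
  outcomes <- intersect(outcomes, cohort$outcome_codes)
  families <- config$model$families
  ev <- config$eval
  eval_out <- stage("evaluate", function() {
    if (length(outcomes) == 0) {
      stop("no outcome passed the prevalence filter", call. = FALSE)
    }
    adm_codes <- strsplit(cohort$admissions$codes, ";")
    dev <- enc$split$dev
    pat_dev <- cohort$admissions$patient_id[dev]
    combos <- tidyr::expand_grid(outcome = outcomes, family = families)
    combo_seeds <- derive_seeds(seeds[3], nrow(combos) * 2)
    rows <- list()
    models <- list()
    for (i in seq_len(nrow(combos))) {
      oc <- combos$outcome[i]; fam <- combos$family[i]
      y <- vapply(adm_codes, function(cs) as.integer(oc %in% cs), 1L)
      grid <- config$model$grids[[fam]]
      # both versions share one tuning seed, so the comparison is paired all
      # the way through training: identical inputs give identical models
      mv1 <- tune_and_fit(fam, enc$dev_v1, y[dev], pat_dev,
                          n_search = config$model$n_search,
                          cv_folds = config$model$cv_folds, grid = grid,
                          seed = combo_seeds[2 * i - 1])
      mv2 <- tune_and_fit(fam, enc$dev_v2, y[dev], pat_dev,
                          n_search = config$model$n_search,
                          cv_folds = config$model$cv_folds, grid = grid,
                          seed = combo_seeds[2 * i - 1])
      cmp <- evaluate_pair(mv1, mv2, enc$test_v1, enc$test_v2, y[!dev],
                           n_boots = ev$n_boots, bca_boots = ev$bca_boots,
                           level = ev$level, seed = combo_seeds[2 * i])
      models[[paste(oc, fam, sep = ".")]] <- list(v1 = mv1, v2 = mv2)
      rows[[i]] <- tibble::tibble(
        outcome = oc, family = fam,
        auroc_v1 = cmp$auroc_v1, auroc_v2 = cmp$auroc_v2,
        auprc_v1 = cmp$auprc_v1, auprc_v2 = cmp$auprc_v2,
        median_diff_auroc = cmp$median_diff_auroc,
        median_diff_auprc = cmp$median_diff_auprc,
        bca_lower_auroc = cmp$bca_auroc[["lower"]],
        bca_upper_auroc = cmp$bca_auroc[["upper"]],
        bca_lower_auprc = cmp$bca_auprc[["lower"]],
        bca_upper_auprc = cmp$bca_auprc[["upper"]],
        verdict_auroc = cmp$verdict_auroc,
        verdict_auprc = cmp$verdict_auprc
      )
    }
    list(comparisons = dplyr::bind_rows(rows), models = models)
  })

  sh <- config$shap
  shap_out <- NULL
  if (isTRUE(sh$enabled)) {
    shap_out <- stage("explain", function() {
      first <- eval_out$models[[1]]
      dev <- enc$split$dev
      sseed <- derive_seeds(seeds[4], 2)
      old <- globalenv()$.Random.seed
      set.seed(sseed[1])
      bg_idx <- sample.int(nrow(enc$dev_v2),
                           min(sh$background_n, nrow(enc$dev_v2)))
      row_idx <- sample.int(nrow(enc$test_v2),
                            min(sh$max_rows, nrow(enc$test_v2)))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      shap <- permutation_shap(
        function(m) predict_scores(first$v2, m),
        enc$test_v2[row_idx, , drop = FALSE],
        enc$dev_v2[bg_idx, , drop = FALSE],
        n_permutations = sh$n_permutations, seed = sseed[2],
        exhaustive = isTRUE(sh$exhaustive)
      )
      raw_levels <- enc$m2$x[!dev, , drop = FALSE][row_idx, , drop = FALSE]
      list(shap = shap,
           summary = mean_abs_shap(shap, scale = TRUE),
           level_tests = anova_by_level(shap, raw_levels))
    })
  }

  net <- summarize_net_gains(eval_out$comparisons)
  manifest <- list(
    package_version = as.character(utils::packageVersion("seasonri")),
    config_hash = digest::digest(unclass(config)),
    master_seed = config$seed,
    stage_seeds = as.list(stats::setNames(
      seeds, c("simulate", "split", "evaluate", "explain", "spare1",
               "spare2"))),
    timings = timings,
    created = ts_fmt(Sys.time())
  )
  report <- list(comparisons = eval_out$comparisons, net_gains = net,
                 fits = fits, filter_report = cohort$report,
                 n_differing_cells = enc$n_differing_cells,
                 outcome_codes = outcomes, shap = shap_out,
                 manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(eval_out$comparisons,
                     file.path(output_dir, "comparisons.csv"),
                     progress = FALSE)
    readr::write_csv(net$table, file.path(output_dir, "net_gains.csv"),
                     progress = FALSE)
    readr::write_csv(fits, file.path(output_dir, "seasonal_fits.csv"),
                     progress = FALSE)
    files <- file.path(output_dir, c("comparisons.csv", "net_gains.csv",
                                     "seasonal_fits.csv"))
    manifest$file_digests <- lapply(
      stats::setNames(files, basename(files)), digest::digest, file = TRUE)
    report$manifest <- manifest
    jsonlite::write_json(
      list(comparisons = eval_out$comparisons, net_gains = net$net,
           n_differing_cells = enc$n_differing_cells, manifest = manifest),
      file.path(output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' Net AUROC gain per model family across outcomes
#'
#' Per outcome x family, the gain is the median paired AUROC difference
#' (version 2 - version 1), zeroed when the BCa verdict is `no_difference`;
#' the per-family net gain sums these over outcomes — the total behind a
#' "which family benefits most from seasonal adjustment" ranking.
#'
#' @param report A pipeline report (list with `comparisons`) or the
#'   comparisons tibble itself.
#' @return A list with `table` (outcome x family gains, `gain` zeroed where
#'   non-significant) and `net` (per-family totals, descending).
#' @export
summarize_net_gains <- function(report) {
  comparisons <- if (is.data.frame(report)) report else report$comparisons
  if (is.null(comparisons) || nrow(comparisons) == 0) {
    stop("summarize_net_gains: no comparison results", call. = FALSE)
  }
  table <- comparisons |>
    dplyr::mutate(
      significant = .data$verdict_auroc != "no_difference",
      gain = ifelse(.data$significant, .data$median_diff_auroc, 0)
    ) |>
    dplyr::select("outcome", "family", "median_diff_auroc", "significant",
                  "gain")
  net <- table |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(net_gain = sum(.data$gain), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$net_gain))
  list(table = table, net = net)
}
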
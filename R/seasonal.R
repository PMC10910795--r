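#' Single-harmonic cosinor value
#'
#' Evaluates the seasonal model
#' \deqn{y = \beta_0 + \beta_1 \cos\left(2\pi \frac{week - \theta}{52}\right)}
#' a cosine with mean offset `beta0`, amplitude `beta1`, and phase `theta`
#' (the week of the peak) over a 52-week period. Periodic with period 52 in
#' `week`.
#'
#' @param beta0 Mean offset, in normalized (z-score) units.
#' @param beta1 Amplitude, in normalized units; the peak-to-mean distance.
#' @param theta Phase, in weeks; the model peaks at `week == theta`.
#' @param week Week of year (real-valued allowed); vectorized.
#' @return Numeric vector of model values in normalized units.
#' @examples
#' cosinor_value(0, 1, 0, 0)   # 1, the peak
#' cosinor_value(0, 1, 0, 26)  # -1, the trough
#' @export
cosinor_value <- function(beta0, beta1, theta, week) {
  beta0 + beta1 * cos(2 * pi * (week - theta) / 52)
}

#' Normalize a stratum's values to zero mean and unit variance
#'
#' Laboratory values within one stratum (test, unit, lab, sex, age group) are
#' z-scored before seasonal fitting so that the bounded parameters of
#' [fit_sinusoid()] are comparable across tests with different measurement
#' scales. The mean and standard deviation are computed over the values given
#' (the fitting subset) and retained for de-normalizing interval shifts later.
#'
#' @param values Numeric vector of raw measurement values (>= 2 needed).
#' @return A list with `normalized` (numeric vector, mean 0 and sd 1),
#'   `stratum_mean`, and `stratum_sd`.
#' @export
normalize_stratum <- function(values) {
  if (length(values) < 2) {
    stop("stratum unfittable: fewer than 2 values", call. = FALSE)
  }
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop("stratum unfittable: zero variance", call. = FALSE)
  }
  list(normalized = (values - m) / s, stratum_mean = m, stratum_sd = s)
}

#' Aggregate normalized values into weekly means
#'
#' Pools observations across years by week-of-year (1--52) and returns the
#' per-week mean and observation count. Weeks with no observations have `NA`
#' mean and count 0.
#'
#' @param week Integer vector of weeks in 1..52.
#' @param value Numeric vector of (normalized) values, same length.
#' @return A tibble with 52 rows: `week`, `mean`, `n`.
#' @export
weekly_aggregate <- function(week, value) {
  stopifnot(length(week) == length(value))
  if (length(week) > 0 && (any(week < 1) || any(week > 52))) {
    stop("weeks must lie in 1..52 (fold week 53 into 52 upstream)",
         call. = FALSE)
  }
  agg <- tibble::tibble(week = as.integer(week), value = value) |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  tibble::tibble(week = 1:52) |>
    dplyr::left_join(agg, by = "week") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Fit the bounded seasonal cosinor to weekly means
#'
#' Weighted nonlinear least squares of the single-harmonic cosinor
#' (see [cosinor_value()]) to 52 weekly means, using `nls()` with the "port"
#' algorithm so that `beta0` and `beta1` are constrained to `[-1, 1]` and
#' `theta` to `[0, 52]`. The fit is multi-started over phases spread across
#' the year to escape local minima; the converged start with the lowest
#' residual sum of squares wins. P-values are Wald tests of each parameter
#' against zero, from the asymptotic covariance reported by `summary.nls()`.
#'
#' Fits are canonicalized to `beta1 >= 0` (a negative amplitude equals a
#' positive one phase-shifted by 26 weeks), so `theta` is always the week of
#' the peak.
#'
#' @param weekly A tibble as returned by [weekly_aggregate()]: columns
#'   `week`, `mean` (NA where unobserved), `n`.
#' @param min_weeks Minimum number of non-missing weekly means required for a
#'   fit (identifiability of the 3 parameters across the season).
#' @return A one-row tibble with `beta0`, `beta1`, `theta`, per-parameter
#'   standard errors (`se_*`) and p-values (`p_*`), `n_points` (total
#'   observations), `n_weeks`, and `converged`.
#' @export
fit_sinusoid <- function(weekly, min_weeks = 26) {
  assert_fields(weekly, c("week", "mean", "n"), "weekly aggregate")
  obs <- weekly[!is.na(weekly$mean) & weekly$n > 0, ]
  failed <- tibble::tibble(
    beta0 = NA_real_, beta1 = NA_real_, theta = NA_real_,
    se_beta0 = NA_real_, se_beta1 = NA_real_, se_theta = NA_real_,
    p_beta0 = NA_real_, p_beta1 = NA_real_, p_theta = NA_real_,
    n_points = sum(weekly$n), n_weeks = nrow(obs), converged = FALSE
  )
  if (nrow(obs) < min_weeks) {
    return(failed)
  }
  dat <- data.frame(week = obs$week, y = obs$mean, w = obs$n)
  b0_start <- max(-0.99, min(0.99, stats::weighted.mean(dat$y, dat$w)))
  amp_guess <- max(0.05, min(0.95, (max(dat$y) - min(dat$y)) / 2))

  best <- NULL
  for (th0 in c(1, 13, 26, 39)) {
    fit <- tryCatch(
      nls(y ~ b0 + b1 * cos(2 * pi * (week - th) / 52),
          data = dat, weights = dat$w,
          start = list(b0 = b0_start, b1 = amp_guess, th = th0),
          lower = c(b0 = -1, b1 = -1, th = 0),
          upper = c(b0 = 1, b1 = 1, th = 52),
          algorithm = "port",
          control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    rss <- sum(dat$w * resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(failed)
  }
  est <- coef(best$fit)
  sm <- tryCatch(summary(best$fit)$coefficients, error = function(e) NULL)
  if (is.null(sm)) {
    se <- p <- c(b0 = NA_real_, b1 = NA_real_, th = NA_real_)
  } else {
    se <- sm[, "Std. Error"]
    p <- sm[, "Pr(>|t|)"]
  }
  b0 <- unname(est["b0"]); b1 <- unname(est["b1"]); th <- unname(est["th"])
  if (b1 < 0) {  # canonical form: positive amplitude, theta = week of peak
    b1 <- -b1
    th <- (th + 26) %% 52
  }
  tibble::tibble(
    beta0 = b0, beta1 = b1, theta = th,
    se_beta0 = unname(se["b0"]), se_beta1 = unname(se["b1"]),
    se_theta = unname(se["th"]),
    p_beta0 = unname(p["b0"]), p_beta1 = unname(p["b1"]),
    p_theta = unname(p["th"]),
    n_points = sum(weekly$n), n_weeks = nrow(obs), converged = TRUE
  )
}

#' Fit seasonal cosinors for every stratum of a lab-record table
#'
#' Groups records by stratum (test name, specimen, unit, lab ID, sex, 10-year
#' age group), z-scores each stratum's values over the supplied fitting
#' subset, aggregates to weekly means and fits the bounded cosinor. Strata
#' with too few values, zero variance, or too few observed weeks are returned
#' with `converged = FALSE` and never reach significance testing.
#'
#' @param records Lab-record tibble with at least the stratum key fields,
#'   `value` and `timestamp`. Restrict to the fitting subset (e.g. 28-day
#'   survivors) before calling.
#' @param min_weeks Passed to [fit_sinusoid()].
#' @param min_n Minimum records per stratum to attempt a fit.
#' @return A tibble with one row per stratum: the stratum keys,
#'   `stratum_mean`, `stratum_sd`, and the [fit_sinusoid()] columns.
#' @export
fit_seasonality <- function(records, min_weeks = 26, min_n = 20) {
  assert_fields(records, c("test_name", "specimen", "unit", "lab_id", "sex",
                           "age_at_draw", "value", "timestamp"), "records")
  records <- add_stratum(records)
  records$week <- week_of_year(records$timestamp)
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratum_keys))) |>
    dplyr::group_modify(function(g, key) {
      base <- tibble::tibble(stratum_mean = NA_real_, stratum_sd = NA_real_)
      if (nrow(g) < max(2, min_n) || sd(g$value) == 0) {
        fit <- fit_sinusoid(weekly_aggregate(integer(), numeric()),
                            min_weeks = min_weeks)  # unfittable placeholder
        return(dplyr::bind_cols(base, fit))
      }
      norm <- normalize_stratum(g$value)
      weekly <- weekly_aggregate(g$week, norm$normalized)
      fit <- fit_sinusoid(weekly, min_weeks = min_weeks)
      dplyr::bind_cols(
        tibble::tibble(stratum_mean = norm$stratum_mean,
                       stratum_sd = norm$stratum_sd),
        fit
      )
    }) |>
    dplyr::ungroup()
}

#' Benjamini-Hochberg correction per parameter family and significance call
#'
#' Applies BH FDR correction separately within each parameter family (all
#' `beta0` p-values together, all `beta1`, all `theta`) across the converged
#' strata, then classifies a stratum as having a significant seasonality
#' shift. Under the default rule all three q-values must fall below `alpha`;
#' the `"amplitude_phase"` rule requires only `beta1` and `theta` (testing
#' the mean offset against zero is optional because normalization already
#' centres it).
#'
#' @param fits Tibble from [fit_seasonality()] (or a compatible table with
#'   `p_beta0`, `p_beta1`, `p_theta`, `converged`).
#' @param alpha Significance level on the FDR-adjusted q-values.
#' @param rule `"all"` (default) or `"amplitude_phase"`.
#' @return `fits` with added `q_beta0`, `q_beta1`, `q_theta`, `significant`.
#' @export
fdr_correct <- function(fits, alpha = 0.05,
                        rule = c("all", "amplitude_phase")) {
  rule <- match.arg(rule)
  assert_fields(fits, c("p_beta0", "p_beta1", "p_theta", "converged"), "fits")
  fits$q_beta0 <- fits$q_beta1 <- fits$q_theta <- NA_real_
  ok <- fits$converged & !is.na(fits$p_beta0) & !is.na(fits$p_beta1) &
    !is.na(fits$p_theta)
  fits$q_beta0[ok] <- p.adjust(fits$p_beta0[ok], method = "BH")
  fits$q_beta1[ok] <- p.adjust(fits$p_beta1[ok], method = "BH")
  fits$q_theta[ok] <- p.adjust(fits$p_theta[ok], method = "BH")
  sig <- if (rule == "all") {
    fits$q_beta0 < alpha & fits$q_beta1 < alpha & fits$q_theta < alpha
  } else {
    fits$q_beta1 < alpha & fits$q_theta < alpha
  }
  fits$significant <- ok & !is.na(sig) & sig
  fits
}

#' Seasonally adjusted reference-interval bounds at a given week
#'
#' Translates a standard reference interval by the de-normalized seasonal
#' deviation of its stratum: both bounds shift by
#' `stratum_sd * cosinor_value(beta0, beta1, theta, week)`, preserving the
#' interval width. Non-significant (or non-converged) fits leave the standard
#' bounds untouched, mirroring the policy of keeping authority-defined
#' intervals where no seasonality was demonstrated.
#'
#' @param lower,upper Standard reference-interval bounds (measurement units).
#' @param fit A one-row fit (list or tibble row) with `beta0`, `beta1`,
#'   `theta`, `significant`.
#' @param stratum_sd Standard deviation used in the stratum normalization.
#' @param week Week(s) of year; vectorized.
#' @return A tibble with columns `lower` and `upper`.
#' @export
adjusted_bounds <- function(lower, upper, fit, stratum_sd, week) {
  stopifnot(all(lower < upper))
  sig <- isTRUE(fit$significant[1])
  if (!sig) {
    return(tibble::tibble(lower = rep_len(lower, length(week)),
                          upper = rep_len(upper, length(week))))
  }
  shift <- stratum_sd * cosinor_value(fit$beta0[1], fit$beta1[1],
                                      fit$theta[1], week)
  tibble::tibble(lower = lower + shift, upper = upper + shift)
}

#' Reference-interval provider for a feature-encoding version
#'
#' Returns a function that, given attached lab records, appends the
#' applicable reference-interval bounds at each record's week: the standard
#' bounds for version 1, or the seasonally translated bounds of
#' [adjusted_bounds()] (for strata with a significant fit) for version 2.
#'
#' @param ri_table Standard-interval table keyed by the stratum fields
#'   (`test_name`, `specimen`, `unit`, `lab_id`, `sex`, `age_group`) with
#'   `lower` and `upper` columns.
#' @param fits FDR-annotated fits from [fdr_correct()]; may be `NULL` for
#'   version 1.
#' @param version 1 (standard) or 2 (seasonally adjusted).
#' @return A function `f(records)` returning `records` with `week`, `lower`,
#'   `upper` columns added. Records whose stratum is absent from `ri_table`
#'   raise an error naming the stratum.
#' @export
make_ri_provider <- function(ri_table, fits = NULL, version = 1) {
  stopifnot(version %in% c(1, 2))
  assert_fields(ri_table, c(stratum_keys, "lower", "upper"), "ri_table")
  if (version == 2 && is.null(fits)) {
    stop("version 2 provider needs seasonal fits", call. = FALSE)
  }
  force(ri_table); force(fits)
  function(records) {
    recs <- add_stratum(records)
    recs$week <- week_of_year(recs$timestamp)
    out <- dplyr::left_join(recs, ri_table, by = stratum_keys)
    if (anyNA(out$lower) || anyNA(out$upper)) {
      bad <- out[is.na(out$lower) | is.na(out$upper), stratum_keys] |>
        dplyr::distinct()
      stop("no standard reference interval for stratum/strata: ",
           paste(apply(bad, 1, paste, collapse = "|"), collapse = "; "),
           call. = FALSE)
    }
    if (version == 1) {
      return(out)
    }
    sig <- fits[fits$significant %in% TRUE,
                c(stratum_keys, "beta0", "beta1", "theta", "stratum_sd")]
    out <- dplyr::left_join(out, sig, by = stratum_keys)
    shift <- ifelse(
      is.na(out$beta1), 0,
      out$stratum_sd * cosinor_value(out$beta0, out$beta1, out$theta, out$week)
    )
    out$lower <- out$lower + shift
    out$upper <- out$upper + shift
    out[setdiff(names(out), c("beta0", "beta1", "theta", "stratum_sd"))]
  }
}
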
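all_permutations <- function(p) {
  if (p == 1) return(list(1L))
  sub <- all_permutations(p - 1L)
  out <- vector("list", p * length(sub))
  k <- 0L
  for (first in seq_len(p)) {
    rest <- setdiff(seq_len(p), first)
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(first, rest[s])
    }
  }
  out
}

#' Permutation-sampled Shapley attributions
#'
#' Approximates Shapley values of a model's score by iterating through
#' permutations of the input features: starting from a background row,
#' features are switched in to the explained row's values in permutation
#' order, and each feature is credited the marginal change in model output
#' at its turn. Attributions are Monte-Carlo averages over sampled
#' (permutation, background row) pairs shared across explained rows. With
#' `exhaustive = TRUE` all `p!` orderings are combined with every background
#' row, which yields exact Shapley values (per-row attributions then sum to
#' `f(x) - base_value` exactly).
#'
#' @param predict_fun Function mapping a feature matrix to numeric scores.
#' @param x Matrix of rows to explain.
#' @param background Matrix of background rows defining the baseline
#'   distribution.
#' @param n_permutations Number of sampled (permutation, background) pairs;
#'   ignored when `exhaustive = TRUE`.
#' @param seed Integer seed for sampling.
#' @param exhaustive Enumerate all orderings x all background rows (feature
#'   count must be small).
#' @return A list of class `ri_shap`: `values` (rows x features attribution
#'   matrix), `base_value` (mean model output on the background), and
#'   `n_samples`.
#' @export
permutation_shap <- function(predict_fun, x, background,
                             n_permutations = 200, seed = 1,
                             exhaustive = FALSE) {
  stopifnot(is.matrix(x), is.matrix(background),
            ncol(x) == ncol(background), nrow(background) >= 1)
  p <- ncol(x)
  if (!exhaustive) check_count(n_permutations, "n_permutations")
  if (exhaustive && p > 7) {
    stop("exhaustive enumeration is limited to <= 7 features", call. = FALSE)
  }
  if (exhaustive) {
    perms <- all_permutations(p)
    samples <- tidyr::expand_grid(perm = seq_along(perms),
                                  bg = seq_len(nrow(background)))
  } else {
    old <- globalenv()$.Random.seed
    set.seed(as.integer(seed))
    samples <- tibble::tibble(
      perm = NA_integer_,
      bg = sample.int(nrow(background), n_permutations, replace = TRUE)
    )
    perm_draws <- lapply(seq_len(n_permutations), function(i) sample.int(p))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  values <- matrix(0, nrow(x), p, dimnames = dimnames(x))
  for (s in seq_len(nrow(samples))) {
    ord <- if (exhaustive) perms[[samples$perm[s]]] else perm_draws[[s]]
    z <- background[rep(samples$bg[s], nrow(x)), , drop = FALSE]
    prev <- predict_fun(z)
    for (j in ord) {
      z[, j] <- x[, j]
      cur <- predict_fun(z)
      values[, j] <- values[, j] + (cur - prev)
      prev <- cur
    }
  }
  values <- values / nrow(samples)
  structure(list(values = values,
                 base_value = mean(predict_fun(background)),
                 n_samples = nrow(samples)),
            class = "ri_shap")
}

#' Mean absolute Shapley attribution per feature
#'
#' Summarizes an attribution matrix as the mean of absolute attributions
#' across rows (admissions), optionally scaled by the per-outcome maximum so
#' values rank features within one outcome in `[0, 1]`.
#'
#' @param shap An `ri_shap` from [permutation_shap()] (or a bare matrix).
#' @param scale Add a `scaled` column dividing by the maximum mean.
#' @return A tibble with `feature`, `mean_abs` (and `scaled`), sorted by
#'   `mean_abs` descending.
#' @export
mean_abs_shap <- function(shap, scale = FALSE) {
  values <- if (inherits(shap, "ri_shap")) shap$values else shap
  stopifnot(is.matrix(values), nrow(values) >= 1)
  m <- colMeans(abs(values))
  out <- tibble::tibble(feature = colnames(values) %||%
                          paste0("f", seq_along(m)),
                        mean_abs = unname(m))
  if (scale) {
    top <- max(out$mean_abs)
    out$scaled <- if (top == 0) rep(0, nrow(out)) else out$mean_abs / top
  }
  dplyr::arrange(out, dplyr::desc(.data$mean_abs))
}

#' One-way ANOVA of attributions across input levels, Bonferroni-corrected
#'
#' For each feature, compares the distribution of its Shapley attributions
#' across the pre-standardization input levels (-1/0/+1 for test features;
#' 0/1 for sex) by one-way ANOVA. Features with fewer than two levels
#' represented by at least two rows each are reported as untested, not
#' dropped. The Bonferroni correction multiplies p by the number of features
#' actually tested for this outcome.
#'
#' @param shap An `ri_shap` (or attribution matrix), rows aligned with
#'   `levels`.
#' @param levels Matrix of pre-standardization feature levels, same shape
#'   and column names as the attribution matrix.
#' @param alpha Significance level applied to the corrected p-value.
#' @return A tibble with `feature`, `n_levels`, `f_statistic`, `p`,
#'   `p_bonferroni`, `significant`, `tested`.
#' @export
anova_by_level <- function(shap, levels, alpha = 0.05) {
  values <- if (inherits(shap, "ri_shap")) shap$values else shap
  stopifnot(is.matrix(values), identical(dim(values), dim(levels)))
  per_feature <- lapply(seq_len(ncol(values)), function(j) {
    lv <- levels[, j]
    counts <- table(lv)
    good <- names(counts)[counts >= 2]
    if (length(good) < 2) {
      return(tibble::tibble(
        feature = colnames(values)[j], n_levels = length(good),
        f_statistic = NA_real_, p = NA_real_, tested = FALSE))
    }
    keep <- lv %in% good
    fit <- aov(values[keep, j] ~ factor(lv[keep]))
    tab <- summary(fit)[[1]]
    tibble::tibble(feature = colnames(values)[j], n_levels = length(good),
                   f_statistic = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
                   tested = TRUE)
  })
  out <- dplyr::bind_rows(per_feature)
  m <- sum(out$tested)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$significant <- out$tested & !is.na(out$p_bonferroni) &
    out$p_bonferroni < alpha
  dplyr::relocate(out, "p_bonferroni", .after = "p")
}
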
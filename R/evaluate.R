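#' Paired-bootstrap comparison of the two encoding versions
#'
#' Computes point AUROC/AUPRC for both models on the full test set, then
#' draws `n_boots` bootstrap resamples of the test admissions — identical
#' resamples for both versions, so each bootstrap difference reflects model
#' difference rather than sample noise. Per-boot resamples are derived from
#' indexed sub-seeds, so the distribution is invariant to execution order.
#' Resamples with a single outcome class are redrawn (and counted), keeping
#' the number of boots fixed. The mean of each difference distribution gets
#' a BCa interval ([bca_interval()]); the median is reported as the effect
#' size; significance means the BCa interval excludes zero.
#'
#' @param model_v1,model_v2 Fitted `seasonri_model`s for versions 1 and 2.
#' @param x1,x2 Standardized test feature matrices for the two versions
#'   (same rows).
#' @param labels 0/1 outcome labels of the test admissions.
#' @param n_boots Number of paired bootstrap resamples.
#' @param bca_boots Outer bootstrap count for the BCa interval.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A list of class `ri_comparison`: point metrics, percentile CIs
#'   per version and metric, paired difference distributions (`diff_auroc`,
#'   `diff_auprc`, each of length `n_boots`), `bca_auroc`/`bca_auprc`,
#'   median differences, and `verdict_auroc`/`verdict_auprc` in
#'   `{"v2_better", "v1_better", "no_difference"}`.
#' @export
evaluate_pair <- function(model_v1, model_v2, x1, x2, labels,
                          n_boots = 1000, bca_boots = 10000, level = 0.95,
                          seed = 1) {
  stopifnot(nrow(x1) == nrow(x2), nrow(x1) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("evaluate_pair: test labels contain a single class", call. = FALSE)
  }
  s1 <- predict_scores(model_v1, x1)
  s2 <- predict_scores(model_v2, x2)
  n <- length(labels)

  point <- list(
    auroc_v1 = auroc(s1, labels), auroc_v2 = auroc(s2, labels),
    auprc_v1 = auprc(s1, labels), auprc_v2 = auprc(s2, labels)
  )

  seeds <- derive_seeds(seed, n_boots + 1L)
  boot <- matrix(NA_real_, n_boots, 4,
                 dimnames = list(NULL, c("auroc_v1", "auroc_v2",
                                         "auprc_v1", "auprc_v2")))
  n_redrawn <- 0L
  old <- globalenv()$.Random.seed
  for (b in seq_len(n_boots)) {
    set.seed(seeds[b])
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    boot[b, ] <- c(auroc(s1[idx], labels[idx]), auroc(s2[idx], labels[idx]),
                   auprc(s1[idx], labels[idx]), auprc(s2[idx], labels[idx]))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha))
  diff_auroc <- boot[, "auroc_v2"] - boot[, "auroc_v1"]
  diff_auprc <- boot[, "auprc_v2"] - boot[, "auprc_v1"]
  bca_auroc <- bca_interval(diff_auroc, n_boots = bca_boots, level = level,
                            seed = seeds[n_boots + 1L])
  bca_auprc <- bca_interval(diff_auprc, n_boots = bca_boots, level = level,
                            seed = seeds[n_boots + 1L])

  verdict <- function(bca) {
    if (bca[["lower"]] > 0) "v2_better"
    else if (bca[["upper"]] < 0) "v1_better"
    else "no_difference"
  }
  structure(c(point, list(
    ci = ci, diff_auroc = diff_auroc, diff_auprc = diff_auprc,
    bca_auroc = bca_auroc, bca_auprc = bca_auprc,
    median_diff_auroc = median(diff_auroc),
    median_diff_auprc = median(diff_auprc),
    verdict_auroc = verdict(bca_auroc), verdict_auprc = verdict(bca_auprc),
    n_boots = n_boots, n_redrawn = n_redrawn
  )), class = "ri_comparison")
}

#' @export
print.ri_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison (v2 - v1), %d boots\n", x$n_boots))
  cat(sprintf("  AUROC v1 %.4f  v2 %.4f  median diff %+.4f  BCa [%.4f, %.4f]  %s\n",
              x$auroc_v1, x$auroc_v2, x$median_diff_auroc,
              x$bca_auroc[["lower"]], x$bca_auroc[["upper"]],
              x$verdict_auroc))
  cat(sprintf("  AUPRC v1 %.4f  v2 %.4f  median diff %+.4f  BCa [%.4f, %.4f]  %s\n",
              x$auprc_v1, x$auprc_v2, x$median_diff_auprc,
              x$bca_auprc[["lower"]], x$bca_auprc[["upper"]],
              x$verdict_auprc))
  invisible(x)
}
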
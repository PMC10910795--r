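#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney rank statistic (with midranks for tied
#' scores), i.e. the probability that a random case outscores a random
#' control, with ties counting one half.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels 0/1 (or logical) outcome labels; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: precision at each distinct score
#' threshold weighted by the recall gained there (tied scores enter as one
#' threshold).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0 || n_pos == length(labels)) {
    stop("auprc needs both classes", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

# F1 at a fixed 0.5 score threshold; 0 when no positives are predicted.
f1_score <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  labels <- as.integer(labels)
  tp <- sum(pred == 1L & labels == 1L)
  if (tp == 0) return(0)
  prec <- tp / sum(pred == 1L)
  rec <- tp / sum(labels == 1L)
  2 * prec * rec / (prec + rec)
}

#' Patient-level development/test split
#'
#' Randomly assigns unique patients (not admissions) to the development or
#' test side, so all admissions of one patient land on the same side.
#'
#' @param patient_ids Character vector, one entry per admission.
#' @param dev_frac Fraction of patients in the development set.
#' @param seed Integer seed; the split is deterministic under it.
#' @return A list with `dev` (logical vector along `patient_ids`),
#'   `dev_patients`, `test_patients`.
#' @export
split_by_patient <- function(patient_ids, dev_frac = 0.7, seed = 1) {
  patients <- unique(patient_ids)
  if (length(patients) < 2) stop("need >= 2 patients to split", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  shuffled <- sample(patients)
  n_dev <- round(dev_frac * length(patients))
  dev_patients <- shuffled[seq_len(n_dev)]
  dev <- patient_ids %in% dev_patients
  stopifnot(!any(dev & patient_ids %in% setdiff(patients, dev_patients)))
  list(dev = dev, dev_patients = sort(dev_patients),
       test_patients = sort(setdiff(patients, dev_patients)))
}

#' Balanced case/control resample
#'
#' Returns row indices with equal case and control counts: the majority
#' class is kept as-is and the minority class is oversampled with
#' replacement up to the majority size. Deterministic under `seed`.
#'
#' @param labels 0/1 outcome labels.
#' @param seed Integer seed.
#' @return Integer index vector of length `2 * max(class count)`.
#' @export
balanced_resample <- function(labels, seed = 1) {
  labels <- as.integer(labels)
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  if (length(idx1) == 0 || length(idx0) == 0) {
    stop("balanced_resample: only one class present", call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  n <- max(length(idx1), length(idx0))
  up <- function(idx) if (length(idx) == n) idx else
    sample(idx, n, replace = TRUE)
  sample(c(up(idx1), up(idx0)))
}

#' Bias-corrected and accelerated bootstrap interval of a mean
#'
#' BCa confidence interval for the mean of a sample (here: a paired
#' bootstrap difference distribution). The bias correction `z0` comes from
#' the fraction of outer bootstrap means below the observed mean; the
#' acceleration `a` from the jackknife skewness of the mean; the interval
#' endpoints are the correspondingly adjusted percentiles of the outer
#' bootstrap means. A degenerate all-equal sample returns a zero-width
#' interval at that value.
#'
#' @param x Numeric sample.
#' @param n_boots Number of outer bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed for the outer resampling.
#' @return Named numeric `c(lower, upper)`.
#' @export
bca_interval <- function(x, n_boots = 10000, level = 0.95, seed = 1) {
  stopifnot(length(x) >= 1, n_boots >= 1)
  if (length(unique(x)) == 1) {
    return(c(lower = x[1], upper = x[1]))
  }
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  n <- length(x)
  obs <- mean(x)
  boots <- vapply(seq_len(n_boots),
                  function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                  0)
  # bias correction: proportion of bootstrap means below the observed mean
  prop <- (sum(boots < obs) + 0.5 * sum(boots == obs)) / n_boots
  prop <- min(max(prop, 1 / (2 * n_boots)), 1 - 1 / (2 * n_boots))
  z0 <- qnorm(prop)
  # acceleration from jackknife skewness of the mean
  jack <- (sum(x) - x) / (n - 1)
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  alpha <- (1 - level) / 2
  adj <- function(z_alpha) pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  probs <- c(adj(qnorm(alpha)), adj(qnorm(1 - alpha)))
  out <- unname(quantile(boots, probs, type = 6))
  c(lower = out[1], upper = out[2])
}
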
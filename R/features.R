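#' Abnormality flag of a value relative to a reference interval
#'
#' `+1` above the interval, `-1` below, `0` within; values exactly on a bound
#' are normal (the closed interval is the normal band).
#'
#' @param value,lower,upper Numeric vectors (recycled).
#' @return Integer vector in `{-1, 0, 1}`.
#' @export
ri_flag <- function(value, lower, upper) {
  ifelse(value > upper, 1L, ifelse(value < lower, -1L, 0L))
}

feature_col <- function(test_name, specimen) {
  paste(test_name, specimen, sep = "_")
}

#' Build an abnormality-flag feature matrix for one encoding version
#'
#' For each admission and included test, the most abnormal repeat (selected
#' under this version's bounds — selection is version-specific because the
#' flag defines "most abnormal") is encoded `-1/0/+1` against the version's
#' reference interval at the record's week. Tests not measured at an
#' admission are imputed with 0 (within interval). Patient sex is appended
#' as a 0/1 column (`F = 0`, `M = 1`). Columns are ordered by sorted test
#' key with `sex` last; rows follow `admissions`.
#'
#' @param admissions Admission tibble (must include `admission_id` and
#'   `sex`).
#' @param attached Attached records from [attach_labs()].
#' @param ri_provider A function from [make_ri_provider()] supplying the
#'   version's bounds.
#' @param tests Tibble with `test_name` and `specimen` of the included tests
#'   (defines the column set even if a test is unmeasured everywhere).
#' @param version 1 or 2, recorded in the result.
#' @return A list of class `ri_feature_matrix`: `x` (numeric matrix,
#'   admissions x features, pre-standardization), `admission_id`,
#'   `features`, `version`.
#' @export
build_feature_matrix <- function(admissions, attached, ri_provider, tests,
                                 version) {
  assert_fields(admissions, c("admission_id", "sex"), "admissions")
  assert_fields(tests, c("test_name", "specimen"), "tests")
  tests <- dplyr::arrange(dplyr::distinct(tests[, c("test_name", "specimen")]),
                          .data$test_name, .data$specimen)
  cols <- feature_col(tests$test_name, tests$specimen)

  keep <- dplyr::semi_join(attached, tests, by = c("test_name", "specimen"))
  x <- matrix(0, nrow = nrow(admissions), ncol = length(cols) + 1L,
              dimnames = list(admissions$admission_id, c(cols, "sex")))
  if (nrow(keep) > 0) {
    selected <- select_most_abnormal(ri_provider(keep))
    selected <- selected[selected$admission_id %in% admissions$admission_id, ]
    ij <- cbind(
      match(selected$admission_id, admissions$admission_id),
      match(feature_col(selected$test_name, selected$specimen), cols)
    )
    x[ij] <- selected$flag
  }
  x[, "sex"] <- as.numeric(admissions$sex == "M")
  structure(list(x = x, admission_id = admissions$admission_id,
                 features = c(cols, "sex"), version = version),
            class = "ri_feature_matrix")
}

#' Fit / apply a per-column standardizer
#'
#' `fit_scaler()` learns per-column means and standard deviations on the
#' development split; `apply_scaler()` centres and scales any matrix with
#' them (so test data is scaled leakage-free). Zero-variance columns pass
#' through unscaled with a warning.
#'
#' @param x Numeric matrix (pre-standardization features).
#' @param scaler A scaler from `fit_scaler()`.
#' @return `fit_scaler()`: list with `center` and `scale`; `apply_scaler()`:
#'   the standardized matrix.
#' @export
fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning("zero-variance column(s) left unscaled: ",
            paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
    scale[zero] <- 1
  }
  list(center = center, scale = scale)
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(identical(colnames(x), names(scaler$center)))
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
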
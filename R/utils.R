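#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data .env %||%
#' @importFrom stats rnorm runif rpois rbinom plogis qnorm pnorm quantile
#'   median sd nls coef resid p.adjust aov predict setNames complete.cases
#' @importFrom utils head tail
NULL

# Week-of-year on a 52-week calendar: ISO week with week 53 folded into 52,
# matching the 52-week period of the seasonal model.
week_of_year <- function(ts) {
  pmin(lubridate::isoweek(ts), 52L)
}

# Monday (00:00 UTC) starting ISO week `week` of `year`; Jan 4 is always in
# ISO week 1.
iso_week_start <- function(year, week) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  monday1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  as.POSIXct(as.character(monday1 + (week - 1L) * 7L), tz = "UTC")
}

# Derive a stream of independent sub-seeds from one master seed, so each
# pipeline stage (or replicate) is reproducible in isolation.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# 10-year age band label, lower bound a multiple of 10 (e.g. "[20,30)").
age_group_of <- function(age) {
  lo <- (age %/% 10L) * 10L
  sprintf("[%d,%d)", lo, lo + 10L)
}

stratum_keys <- c("test_name", "specimen", "unit", "lab_id", "sex", "age_group")

# Add stratum columns (age_group from age at draw) to a lab-record table.
add_stratum <- function(records) {
  dplyr::mutate(records, age_group = age_group_of(.data$age_at_draw))
}

assert_fields <- function(x, fields, what) {
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing field(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_prob <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1) {
    stop(sprintf("invalid config: '%s' must be a probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(value)
}

check_count <- function(value, name, min = 1) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < min || value != as.integer(value)) {
    stop(sprintf("invalid config: '%s' must be an integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(value)
}
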
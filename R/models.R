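#' Default hyperparameter grids for the four classifier families
#'
#' Modest random-search grids per family: tree depth/complexity for the
#' decision tree, rounds/depth/learning rate for AdaBoost, hidden size and
#' weight decay for the single-hidden-layer neural net, and forest
#' size/mtry/node size for the random forest. All ranges are plain data
#' frames, so callers can supply their own.
#'
#' @param family One of `"adaboost"`, `"decision_tree"`, `"neural_net"`,
#'   `"random_forest"`.
#' @return A data frame, one row per hyperparameter configuration.
#' @export
default_hyper_grid <- function(family) {
  switch(
    match.arg(family, model_families),
    adaboost = expand.grid(n_rounds = c(25L, 50L, 100L),
                           maxdepth = c(1L, 2L, 3L),
                           learning_rate = c(0.1, 0.5, 1.0)),
    decision_tree = expand.grid(maxdepth = c(2L, 4L, 6L, 10L),
                                minsplit = c(10L, 20L, 50L),
                                cp = c(1e-4, 1e-3, 1e-2)),
    neural_net = expand.grid(size = c(2L, 4L, 8L, 16L),
                             decay = c(1e-4, 1e-3, 1e-2, 1e-1),
                             maxit = c(100L, 200L)),
    random_forest = expand.grid(num_trees = c(100L, 300L, 500L),
                                mtry_frac = c(0.3, 0.6, 1.0),
                                min_node_size = c(1L, 5L, 10L))
  )
}

model_families <- c("adaboost", "decision_tree", "neural_net",
                    "random_forest")

#' Fit one classifier of a given family
#'
#' Thin uniform interface over the four families: rpart (decision tree),
#' ranger (random forest), nnet (single-hidden-layer neural net), and an
#' in-package discrete AdaBoost over weighted rpart trees. All return an
#' object whose [predict_scores()] yields case probabilities.
#'
#' @param family Family name; see [default_hyper_grid()].
#' @param x Numeric feature matrix.
#' @param y 0/1 labels.
#' @param params One row of the family's hyperparameter grid (list-like).
#' @param seed Integer seed for stochastic learners.
#' @return An object of class `seasonri_model`.
#' @export
fit_classifier <- function(family, x, y, params, seed = 1) {
  family <- match.arg(family, model_families)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x))
  feature_names <- names(df)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fit <- switch(
    family,
    decision_tree = {
      df$.y <- factor(y, levels = c(0L, 1L))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth, minsplit = params$minsplit,
                     cp = params$cp, xval = 0))
    },
    random_forest = ranger::ranger(
      x = df, y = factor(y, levels = c(0L, 1L)), probability = TRUE,
      num.trees = params$num_trees,
      mtry = max(1L, ceiling(params$mtry_frac * ncol(df))),
      min.node.size = params$min_node_size,
      seed = as.integer(seed), num.threads = 1
    ),
    neural_net = nnet::nnet(
      as.matrix(df), y, size = params$size, decay = params$decay,
      maxit = params$maxit, entropy = TRUE, trace = FALSE,
      MaxNWts = 10000
    ),
    adaboost = fit_adaboost(df, y, n_rounds = params$n_rounds,
                            maxdepth = params$maxdepth,
                            learning_rate = params$learning_rate)
  )
  structure(list(fit = fit, family = family, params = as.list(params),
                 feature_names = feature_names),
            class = "seasonri_model")
}

# Discrete AdaBoost (AdaBoost.M1) over weighted rpart trees: reweight
# misclassified rows by exp(alpha), score by the alpha-weighted vote,
# mapped to (0, 1) through the logistic of twice the additive score.
fit_adaboost <- function(df, y, n_rounds, maxdepth, learning_rate) {
  yy <- ifelse(y == 1L, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  df$.y <- factor(y, levels = c(0L, 1L))
  for (m in seq_len(n_rounds)) {
    tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = maxdepth, cp = 0, minsplit = 10,
                           xval = 0))
    pred <- ifelse(predict(tree, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy]) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break  # perfect learner; voting is decided
  }
  list(learners = learners, alphas = alphas)
}

predict_adaboost <- function(model, df) {
  if (length(model$learners) == 0) return(rep(0.5, nrow(df)))
  f <- rep(0, nrow(df))
  for (m in seq_along(model$learners)) {
    pred <- ifelse(predict(model$learners[[m]], df, type = "class") == "1",
                   1, -1)
    f <- f + model$alphas[m] * pred
  }
  plogis(2 * f)
}

#' Case-probability scores of a fitted classifier
#'
#' @param model A `seasonri_model` from [fit_classifier()] or
#'   [tune_and_fit()].
#' @param x Numeric feature matrix with the training columns.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "seasonri_model"))
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x))
  stopifnot(identical(names(df), model$feature_names))
  switch(
    model$family,
    decision_tree = unname(predict(model$fit, df, type = "prob")[, "1"]),
    random_forest = unname(predict(model$fit, data = df,
                                   num.threads = 1)$predictions[, "1"]),
    neural_net = as.numeric(predict(model$fit, as.matrix(df))),
    adaboost = predict_adaboost(model$fit, df)
  )
}

#' Random-search hyperparameter tuning with patient-grouped cross-validation
#'
#' Samples up to `n_search` configurations from the family's grid, scores
#' each by mean F1 (fixed 0.5 threshold) over `cv_folds` cross-validation
#' folds grouped by patient, with balanced case/control resampling applied
#' to the training folds only, and refits the best configuration (ties:
#' earliest sampled) on the full development set (balanced-resampled).
#'
#' @inheritParams fit_classifier
#' @param patient_ids Patient ID per row of `x`; folds never split a
#'   patient.
#' @param n_search Maximum configurations sampled.
#' @param cv_folds Number of cross-validation folds.
#' @param grid Optional custom hyperparameter data frame.
#' @param seed Integer seed driving sampling, folds, resampling and fits.
#' @return A `seasonri_model` with a `search_log` tibble attached
#'   (configuration, mean F1, rank).
#' @export
tune_and_fit <- function(family, x, y, patient_ids, n_search = 40,
                         cv_folds = 5, grid = NULL, seed = 1) {
  family <- match.arg(family, model_families)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("tune_and_fit: development set has a single class", call. = FALSE)
  }
  check_count(n_search, "n_search")
  grid <- grid %||% default_hyper_grid(family)
  seeds <- derive_seeds(seed, 4)

  old <- globalenv()$.Random.seed
  set.seed(seeds[1])
  rows <- sample.int(nrow(grid), min(n_search, nrow(grid)))
  patients <- unique(patient_ids)
  set.seed(seeds[2])
  fold_of_patient <- stats::setNames(
    sample(rep_len(seq_len(cv_folds), length(patients))), patients)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  fold <- unname(fold_of_patient[patient_ids])

  fit_seeds <- derive_seeds(seeds[3], length(rows) * cv_folds)
  mean_f1 <- numeric(length(rows))
  for (i in seq_along(rows)) {
    params <- grid[rows[i], , drop = FALSE]
    f1s <- rep(NA_real_, cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- which(fold != f)
      va <- which(fold == f)
      if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2) next
      s <- fit_seeds[(i - 1) * cv_folds + f]
      bal <- balanced_resample(y[tr], seed = s)
      model <- tryCatch(
        fit_classifier(family, x[tr, , drop = FALSE][bal, , drop = FALSE],
                       y[tr][bal], params, seed = s),
        error = function(e) NULL
      )
      if (is.null(model)) next
      f1s[f] <- f1_score(predict_scores(model, x[va, , drop = FALSE]), y[va])
    }
    mean_f1[i] <- if (all(is.na(f1s))) NA_real_ else mean(f1s, na.rm = TRUE)
  }
  if (all(is.na(mean_f1))) {
    stop("tune_and_fit: no configuration could be fitted; search log:\n",
         paste(utils::capture.output(print(grid[rows, ])), collapse = "\n"),
         call. = FALSE)
  }
  best <- which.max(mean_f1)  # first max: ties go to the earliest sampled
  bal <- balanced_resample(y, seed = seeds[4])
  model <- fit_classifier(family, x[bal, , drop = FALSE], y[bal],
                          grid[rows[best], , drop = FALSE], seed = seeds[4])
  model$search_log <- dplyr::bind_cols(
    tibble::as_tibble(grid[rows, , drop = FALSE]),
    tibble::tibble(mean_f1 = mean_f1, selected = seq_along(rows) == best)
  )
  model
}
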
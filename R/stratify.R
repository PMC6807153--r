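# Scenario 2: decision-tree age prediction as a sequential acquisition
# policy, with an all-modality kernel regressor as the comparison baseline.

#' Split a cohort into training and holdout sets
#'
#' The holdout contains `round(fraction * n)` randomly selected subjects;
#' the split is disjoint, exhaustive, deterministic given the seed, and
#' (by design) performed once per experiment rather than pooled over
#' repeated partitions.
#'
#' @param cohort a `cohort_table` with >= 10 subjects.
#' @param holdout_fraction proportion held out, in (0, 1); default 0.20.
#' @param seed integer seed.
#' @return A list with `train` and `holdout` `cohort_table`s.
#' @export
train_holdout_split <- function(cohort, holdout_fraction = 0.2, seed = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- length(cohort$subjects)
  if (n < 10) stop("cohort must have >= 10 subjects")
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("`holdout_fraction` must be in (0, 1)")
  n_hold <- round(holdout_fraction * n)
  if (n_hold < 1 || n_hold >= n)
    stop("`holdout_fraction` produces an empty partition")
  hold <- with_seed(seed, sample.int(n, n_hold))
  subset_cohort <- function(idx)
    cohort_table(cohort$subjects[idx], cohort$ages[idx],
                 cohort$values[idx, , drop = FALSE], cohort$modalities)
  list(train = subset_cohort(setdiff(seq_len(n), hold)),
       holdout = subset_cohort(sort(hold)))
}

# k-fold CV mean squared error of an age regressor; `fit_fun(train_df)`
# returns a model, `pred_fun(model, df)` predictions.
cv_mse <- function(df, fit_fun, pred_fun, folds = 5, seed = 1) {
  n <- nrow(df)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  err <- 0
  for (f in seq_len(folds)) {
    te <- fold_id == f
    fit <- fit_fun(df[!te, , drop = FALSE])
    pr <- pred_fun(fit, df[te, , drop = FALSE])
    err <- err + sum((df$age[te] - pr)^2)
  }
  err / n
}

fit_rpart <- function(df, max_depth, min_leaf) {
  rpart::rpart(age ~ ., data = df, method = "anova",
               control = rpart::rpart.control(
                 maxdepth = max_depth, minbucket = min_leaf,
                 minsplit = max(2L, 2L * min_leaf), cp = 0, xval = 0,
                 maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
}

#' Fit the decision-tree age model with tuned hyperparameters
#'
#' Z-scores each modality on the training statistics, then fits a regression
#' tree (squared-error CART) whose hyperparameters -- maximum depth in
#' `[2, 8]` and minimum leaf size in `[5, 50]` -- are tuned by
#' cross-validated search driven by the package's GP/expected-improvement
#' engine over the integer hyperparameter grid (`tuner = "grid"` evaluates
#' the full grid instead). The best configuration is refit on all training
#' subjects.
#'
#' @param train a `cohort_table`.
#' @param tuning_budget number of hyperparameter configurations evaluated
#'   (>= 1) when `tuner = "gpei"`.
#' @param seed integer seed (CV folds and tuner burn-in).
#' @param depth_range,leaf_range integer candidate ranges.
#' @param cv_folds folds for the tuning cross-validation.
#' @param tuner `"gpei"` (default) or `"grid"`.
#' @return A `decision_tree_model`: list with `tree` (node structure),
#'   `center`/`scale` (training means/SDs used for z-scoring), `modalities`,
#'   `hyper`, `cv_mse`, `age_range` and the underlying `rpart` fit.
#' @export
fit_tree <- function(train, tuning_budget = 15, seed = 1,
                     depth_range = 2:8, leaf_range = 5:50, cv_folds = 5,
                     tuner = c("gpei", "grid")) {
  stopifnot(inherits(train, "cohort_table"))
  tuner <- match.arg(tuner)
  if (tuning_budget < 1) stop("`tuning_budget` must be >= 1")
  center <- colMeans(train$values)
  scale <- apply(train$values, 2, stats::sd)
  if (any(scale <= 0)) stop("constant modality column: cannot z-score")
  z <- sweep(sweep(train$values, 2, center), 2, scale, `/`)
  df <- data.frame(age = train$ages, z, check.names = FALSE)
  leaf_max <- min(max(leaf_range), max(2L, floor(nrow(df) / 2)))
  grid <- as.matrix(expand.grid(depth = depth_range,
                                leaf = leaf_range[leaf_range <= leaf_max]))
  objective <- function(par) {
    tryCatch(
      cv_mse(df,
             function(d) fit_rpart(d, par[1], par[2]),
             function(fit, d) stats::predict(fit, d),
             folds = cv_folds, seed = child_seed(seed, "cv-folds")),
      error = function(e) NA_real_)
  }
  tuned <- if (tuner == "grid") {
    vals <- apply(grid, 1, objective)
    if (all(!is.finite(vals))) stop("all tuning evaluations failed")
    list(best = grid[which.min(vals), ], best_value = min(vals, na.rm = TRUE))
  } else {
    gpei_optimise(objective, grid, budget = tuning_budget,
                  n_burn = min(5, tuning_budget),
                  seed = child_seed(seed, "tuner"))
  }
  best <- tuned$best
  fit <- fit_rpart(df, best[1], best[2])
  structure(list(tree = rpart_to_tree(fit), center = center, scale = scale,
                 modalities = train$modalities,
                 hyper = list(max_depth = unname(best[1]),
                              min_leaf = unname(best[2])),
                 cv_mse = tuned$best_value,
                 age_range = range(train$ages), rpart_fit = fit),
            class = "decision_tree_model")
}

#' @export
print.decision_tree_model <- function(x, ...) {
  cat(sprintf(paste0("<decision_tree_model: depth %d, %d leaves ",
                     "(max_depth=%d, min_leaf=%d), ages %.1f-%.1f>\n"),
              tree_depth(x$tree), length(tree_leaf_values(x$tree)),
              x$hyper$max_depth, x$hyper$min_leaf,
              x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Evaluate a tree model on a holdout cohort by sequential acquisition
#'
#' Each holdout subject is predicted sequentially ([sequential_predict()]):
#' a modality's raw value is z-scored with the model's training statistics
#' only when the tree path requests it.
#'
#' @param model a `decision_tree_model`.
#' @param holdout a `cohort_table`.
#' @return A list: `mae` and `median_ae` (years), `mean_scans` (mean number
#'   of modalities acquired), plus per-subject `predictions` and `n_scans`.
#' @export
evaluate_holdout <- function(model, holdout) {
  stopifnot(inherits(model, "decision_tree_model"),
            inherits(holdout, "cohort_table"))
  n <- length(holdout$subjects)
  if (n == 0) stop("holdout is empty")
  preds <- numeric(n)
  nscans <- integer(n)
  for (i in seq_len(n)) {
    row <- holdout$values[i, ]
    res <- sequential_predict(model$tree, function(m)
      (row[[m]] - model$center[[m]]) / model$scale[[m]])
    preds[i] <- res$prediction
    nscans[i] <- length(res$acquired)
  }
  ae <- abs(preds - holdout$ages)
  list(mae = mean(ae), median_ae = stats::median(ae),
       mean_scans = mean(nscans), predictions = preds, n_scans = nscans)
}

#' Fit the all-modality baseline regressor
#'
#' A support-vector regression (RBF kernel) on all modalities
#' simultaneously, tuned over a log2 cost x gamma grid with the same GP-EI
#' engine and CV scheme as [fit_tree()]. Unlike the tree policy it always
#' acquires every modality.
#'
#' @param train a `cohort_table`.
#' @param tuning_budget configurations evaluated.
#' @param seed integer seed.
#' @param cv_folds tuning CV folds.
#' @return A `baseline_model` (svm fit + training z-scoring statistics).
#' @export
fit_baseline <- function(train, tuning_budget = 12, seed = 1, cv_folds = 5) {
  stopifnot(inherits(train, "cohort_table"))
  center <- colMeans(train$values)
  scale <- apply(train$values, 2, stats::sd)
  if (any(scale <= 0)) stop("constant modality column: cannot z-score")
  z <- sweep(sweep(train$values, 2, center), 2, scale, `/`)
  df <- data.frame(age = train$ages, z, check.names = FALSE)
  grid <- as.matrix(expand.grid(log2cost = seq(-2, 6, by = 2),
                                log2gamma = seq(-7, 1, by = 2)))
  objective <- function(par) {
    tryCatch(
      cv_mse(df,
             function(d) e1071::svm(age ~ ., data = d, type = "eps-regression",
                                    kernel = "radial", cost = 2^par[1],
                                    gamma = 2^par[2], scale = FALSE),
             function(fit, d) stats::predict(fit, d),
             folds = cv_folds, seed = child_seed(seed, "cv-folds")),
      error = function(e) NA_real_)
  }
  tuned <- gpei_optimise(objective, grid, budget = tuning_budget,
                         n_burn = min(5, tuning_budget),
                         seed = child_seed(seed, "svm-tuner"))
  fit <- e1071::svm(age ~ ., data = df, type = "eps-regression",
                    kernel = "radial", cost = 2^tuned$best[1],
                    gamma = 2^tuned$best[2], scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale,
                 modalities = train$modalities,
                 hyper = list(cost = unname(2^tuned$best[1]),
                              gamma = unname(2^tuned$best[2])),
                 cv_mse = tuned$best_value),
            class = "baseline_model")
}

#' Evaluate the all-modality baseline on a holdout cohort
#'
#' @param model a `baseline_model`.
#' @param holdout a `cohort_table`.
#' @return A list like [evaluate_holdout()]'s; `mean_scans` always equals
#'   the number of modalities.
#' @export
evaluate_baseline <- function(model, holdout) {
  stopifnot(inherits(model, "baseline_model"),
            inherits(holdout, "cohort_table"))
  z <- sweep(sweep(holdout$values, 2, model$center), 2, model$scale, `/`)
  preds <- as.numeric(stats::predict(model$fit,
                                     data.frame(z, check.names = FALSE)))
  ae <- abs(preds - holdout$ages)
  list(mae = mean(ae), median_ae = stats::median(ae),
       mean_scans = length(model$modalities), predictions = preds,
       n_scans = rep(length(model$modalities), length(preds)))
}
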
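test_that("the holdout split is disjoint, exhaustive and reproducible", {
  co <- simulate_cohort(cohort_spec(611, 6, seed = 1))
  sp <- train_holdout_split(co, 0.2, seed = 3)
  expect_length(sp$holdout$subjects, 122)
  expect_length(sp$train$subjects, 489)
  expect_length(intersect(sp$train$subjects, sp$holdout$subjects), 0)
  expect_setequal(c(sp$train$subjects, sp$holdout$subjects), co$subjects)

  sp2 <- train_holdout_split(co, 0.2, seed = 3)
  expect_identical(sp2$holdout$subjects, sp$holdout$subjects)
  expect_error(train_holdout_split(co, 0.0001), "empty")
  small <- simulate_cohort(cohort_spec(8, 3, seed = 1))
  expect_error(train_holdout_split(small), ">= 10")
})

test_that("fit_tree recovers a planted step on a single modality", {
  co <- step_cohort(200, step = 0.3, seed = 4)
  m <- fit_tree(co, tuning_budget = 8, seed = 1)
  root <- m$tree
  expect_false(root$leaf)
  expect_identical(root$modality, "mod_1")
  thr_raw <- root$threshold * m$scale[["mod_1"]] + m$center[["mod_1"]]
  # within one inter-point gap: at most one training value between the
  # fitted threshold and the true step (exhaustive-scan equivalence)
  between <- sum(co$values[, "mod_1"] > min(thr_raw, 0.3) &
                 co$values[, "mod_1"] < max(thr_raw, 0.3))
  expect_lte(between, 1)
})

test_that("degenerate targets give degenerate trees", {
  set.seed(5)
  x <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, paste0("mod_", 1:3)))
  co <- cohort_table(sprintf("s%03d", 1:120), rep(50, 120), x)
  m <- fit_tree(co, tuning_budget = 4, seed = 1)
  expect_true(m$tree$leaf)
  expect_equal(m$tree$value, 50)
})

test_that("deeper trees never fit the training data worse than a stump", {
  co <- step_cohort(150, seed = 6)
  z <- function(m) sweep(sweep(co$values, 2, m$center), 2, m$scale, `/`)
  m <- fit_tree(co, tuning_budget = 8, seed = 2)
  stump <- activeacq:::fit_rpart(
    data.frame(age = co$ages, z(m), check.names = FALSE), 1, 5)
  mse <- function(p) mean((p - co$ages)^2)
  expect_lte(mse(stats::predict(m$rpart_fit,
                                data.frame(z(m), check.names = FALSE))),
             mse(stats::predict(stump,
                                data.frame(z(m), check.names = FALSE))))
})

test_that("holdout evaluation reports MAE, median AE and acquisition cost", {
  co <- simulate_cohort(cohort_spec(300, 6, loadings = rep(0.4, 6),
                                    noise_sd = rep(0.5, 6),
                                    age_slopes = c(-0.03, 0, 0, 0, 0, 0.03),
                                    seed = 8))
  sp <- train_holdout_split(co, 0.2, seed = 1)
  m <- fit_tree(sp$train, tuning_budget = 8, seed = 1)
  ev <- evaluate_holdout(m, sp$holdout)
  expect_lte(ev$mean_scans, activeacq:::tree_depth(m$tree))
  expect_lte(ev$mean_scans, 6)
  expect_gte(ev$mae, ev$median_ae * 0)  # both defined and non-negative
  # all leaf predictions stay within the training age range
  lv <- activeacq:::tree_leaf_values(m$tree)
  expect_true(all(lv >= m$age_range[1] & lv <= m$age_range[2]))

  # a single-leaf model's MAE equals the direct recomputation
  stump_model <- m
  stump_model$tree <- activeacq:::tree_leaf(mean(sp$train$ages))
  ev0 <- evaluate_holdout(stump_model, sp$holdout)
  expect_equal(ev0$mae, mean(abs(sp$holdout$ages - mean(sp$train$ages))))
  expect_equal(ev0$mean_scans, 0)
})

test_that("the all-modality baseline recovers a clean linear age signal", {
  set.seed(9)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("mod_", 1:6)))
  age <- 50 + 10 * x[, 1] + rnorm(n, 0, 1)
  co <- cohort_table(sprintf("s%03d", 1:n), age, x)
  b <- fit_baseline(co, tuning_budget = 10, seed = 1)
  ev <- evaluate_baseline(b, co)
  expect_lt(ev$mae, 2 * 1)
  expect_equal(ev$mean_scans, 6)
  expect_true(all(ev$n_scans == 6))
})

test_that("a one-informative-modality cohort lets the tree match the baseline cheaply", {
  set.seed(10)
  n <- 400
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("mod_", 1:6)))
  age <- ifelse(x[, 2] < -0.5, 35, ifelse(x[, 2] < 0.5, 55, 75)) + rnorm(n, 0, 3)
  co <- cohort_table(sprintf("s%03d", 1:n), age, x)
  sp <- train_holdout_split(co, 0.2, seed = 2)
  m <- fit_tree(sp$train, tuning_budget = 10, seed = 3)
  b <- fit_baseline(sp$train, tuning_budget = 10, seed = 3)
  ev_t <- evaluate_holdout(m, sp$holdout)
  ev_b <- evaluate_baseline(b, sp$holdout)
  expect_lt(ev_t$mae, ev_b$mae * 1.25)
  expect_lt(ev_t$mean_scans, 6)
})
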
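fixed_space <- function(K = 6) {
  mods <- paste0("mod_", seq_len(K))
  structure(list(modalities = mods,
                 coordinates = stats::setNames(seq_len(K), mods),
                 loadings = stats::setNames(rep(0, K), mods),
                 method = "fixed"),
            class = "search_space")
}

test_that("z-scoring uses training statistics only", {
  co <- simulate_cohort(cohort_spec(100, 4, seed = 1))
  train <- co$subjects[1:80]
  zt <- zscore_table(co, train)
  ztr <- zt$z[1:80, ]
  expect_lt(max(abs(colMeans(ztr))), 1e-10)
  expect_lt(max(abs(apply(ztr, 2, stats::sd) - 1)), 1e-10)

  # toy column oracle: {1,2,3} has mean 2, sd 1 -> x = 4 gives z = 2
  toy <- cohort_table(c("a", "b", "c", "d"), c(20, 30, 40, 50),
                      matrix(c(1, 2, 3, 4), 4, 1,
                             dimnames = list(NULL, "mod_1")),
                      "mod_1")
  zt2 <- zscore_table(toy, c("a", "b", "c"))
  expect_equal(unname(zt2$z[4, 1]), 2)
  expect_equal(unname(zt2$z[2, 1]), 0)

  const <- cohort_table(c("a", "b", "c"), 1:3,
                        matrix(1, 3, 1, dimnames = list(NULL, "mod_1")))
  expect_error(zscore_table(const, c("a", "b", "c")), "zero training SD")
})

test_that("factor ordering recovers generator loadings and fixes the sign", {
  hits <- 0
  for (s in 1:20) {
    co <- simulate_cohort(cohort_spec(2000, 6,
                                      loadings = c(0.9, 0.7, 0.5, 0.3, 0.1, -0.2),
                                      noise_sd = rep(0.3, 6), seed = s))
    zt <- zscore_table(co, co$subjects)
    sp <- factor_order(zt)
    if (identical(sp$modalities, paste0("mod_", 1:6))) hits <- hits + 1
  }
  expect_gte(hits, 18)

  # global sign flip leaves the ordering unchanged
  co <- simulate_cohort(cohort_spec(1000, 4, loadings = c(0.8, 0.6, 0.4, -0.5),
                                    noise_sd = rep(0.3, 4), seed = 3))
  sp1 <- factor_order(co$values)
  sp2 <- factor_order(-co$values)
  expect_identical(sp1$modalities, sp2$modalities)
  expect_equal(sp1$loadings, sp2$loadings, tolerance = 1e-6)

  # duplicated modality columns land on adjacent coordinates
  dup <- cbind(co$values, mod_1_copy = co$values[, 1])
  spd <- factor_order(dup)
  cd <- spd$coordinates
  expect_equal(abs(cd[["mod_1"]] - cd[["mod_1_copy"]]), 1)

  expect_error(factor_order(co$values[, 1:2]), ">= 3 modalities")
  expect_error(factor_order(co$values[1:10, ]), "3x more subjects")
})

test_that("GP posterior matches a direct kernel-matrix solve", {
  X <- c(1, 3, 5)
  y <- c(-0.5, 0.2, 1.0)
  st <- gp_state(X, y, lengthscale = 1.5, signal_sd = 1, noise_sd = 0)
  po <- gp_posterior(st, 1:6)
  K <- outer(X, X, function(a, b) exp(-0.5 * (a - b)^2 / 1.5^2))
  ks <- outer(1:6, X, function(a, b) exp(-0.5 * (a - b)^2 / 1.5^2))
  expect_equal(po$mean, as.numeric(ks %*% solve(K, y)), tolerance = 1e-9)
  v <- 1 - rowSums(ks * t(solve(K, t(ks))))
  expect_equal(po$sd, sqrt(pmax(v, 0)), tolerance = 1e-6)

  # exact interpolation at sampled points; prior reversion far away
  expect_equal(po$mean[c(1, 3, 5)], y, tolerance = 1e-8)
  expect_equal(po$sd[c(1, 3, 5)], rep(0, 3), tolerance = 1e-6)
  far <- gp_posterior(st, 500)
  expect_equal(far$mean, 0, tolerance = 1e-8)
  expect_equal(far$sd, 1, tolerance = 1e-8)

  # random instances against the brute-force solve
  set.seed(6)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    Xr <- sort(sample(1:10, n))
    yr <- rnorm(n)
    ell <- runif(1, 0.5, 3)
    sn <- runif(1, 0, 0.3)
    str <- gp_state(Xr, yr, lengthscale = ell, signal_sd = 1.3, noise_sd = sn)
    q <- seq(0, 11, by = 0.5)
    po2 <- gp_posterior(str, q)
    Kr <- 1.3^2 * outer(Xr, Xr, function(a, b) exp(-0.5 * (a - b)^2 / ell^2)) +
      diag(sn^2, n)
    kr <- 1.3^2 * outer(q, Xr, function(a, b) exp(-0.5 * (a - b)^2 / ell^2))
    expect_equal(po2$mean, as.numeric(kr %*% solve(Kr, yr)), tolerance = 1e-8)
  }
})

test_that("expected improvement has its closed-form limits and MC expectation", {
  # sd = 0 limits via an exactly interpolated point
  st <- gp_state(c(1, 2), c(0.5, -0.3), noise_sd = 0)
  expect_equal(expected_improvement(st, 1), 0)          # mu >= f_best
  expect_equal(expected_improvement(st, 2), 0)          # mu == f_best
  st2 <- gp_state(c(1, 2), c(1, 2), noise_sd = 0)
  # incumbent above a deterministic value: EI = f_best - mu
  expect_equal(expected_improvement(st2, 1, f_best = 2), 1)

  expect_true(all(expected_improvement(st, seq(0, 4, by = 0.25)) >= 0))

  # Monte-Carlo oracle at a genuinely uncertain point
  st3 <- gp_state(c(1, 4), c(0.3, -0.2), noise_sd = 1e-4)
  po <- gp_posterior(st3, 2.5)
  ei <- expected_improvement(st3, 2.5)
  set.seed(7)
  draws <- rnorm(1e6, po$mean, po$sd)
  mc <- mean(pmax(0, min(st3$y) - draws))
  mc_se <- stats::sd(pmax(0, min(st3$y) - draws)) / 1000
  expect_lt(abs(ei - mc), 3 * mc_se)
})

test_that("the modality search is deterministic, exhaustive when allowed, and finds sampled minima", {
  sp <- fixed_space(6)
  z <- stats::setNames(c(0.3, -1.2, 0.8, 0.1, -0.4, 1.5), sp$modalities)

  tr1 <- run_search(z, sp, seed = 42)
  tr2 <- run_search(z, sp, seed = 42)
  expect_identical(tr1$trace, tr2$trace)
  expect_equal(nrow(tr1$trace), 4)
  expect_equal(sum(tr1$trace$burn_in), 3)
  expect_false(any(duplicated(tr1$trace$coordinate)))
  # the reported minimum is the minimum over the sampled set
  expect_equal(tr1$reported_z, min(tr1$trace$z))
  if (2 %in% tr1$trace$coordinate) expect_true(tr1$success)

  # K = 4, n_total = 4: exhaustive, always succeeds
  sp4 <- fixed_space(4)
  for (s in 1:10) {
    z4 <- stats::setNames(rnorm(4), sp4$modalities)
    expect_true(run_search(z4, sp4, n_burn = 3, n_total = 4, seed = s)$success)
  }

  expect_error(run_search(z, sp, n_total = 7), "exceed")
  expect_error(run_search(z, sp, n_burn = 4, n_total = 4), "below")
})

test_that("the maximisation and absolute objectives target the right modality", {
  sp <- fixed_space(4)
  z <- stats::setNames(c(0.1, 2.5, -0.2, 0.4), sp$modalities)
  expect_identical(run_search(z, sp, n_total = 4, seed = 1,
                              objective = "max")$true_modality, "mod_2")
  expect_identical(run_search(z, sp, n_total = 4, seed = 1,
                              objective = "absmax")$true_modality, "mod_2")
  expect_identical(run_search(z, sp, n_total = 4, seed = 1,
                              objective = "min")$true_modality, "mod_3")
})

test_that("success is monotone in the sampling budget", {
  sp <- fixed_space(6)
  set.seed(8)
  rates <- sapply(3:6, function(nt) {
    mean(sapply(1:300, function(i) {
      z <- stats::setNames(rnorm(6), sp$modalities)
      run_search(z, sp, n_burn = 2, n_total = nt,
                 seed = child_seed(nt, paste0("mono-", i)))$success
    }))
  })
  expect_true(all(diff(rates) >= -0.05))
  expect_equal(rates[4], 1)  # exhaustive
})

test_that("informed ordering beats random ordering on a strongly one-factor cohort", {
  co <- simulate_cohort(cohort_spec(300, 6,
                                    loadings = c(0.95, 0.9, 0.85, -0.85, -0.9, -0.95),
                                    noise_sd = rep(0.3, 6), seed = 14))
  sp <- train_holdout_split(co, 0.2, seed = 1)
  zt <- zscore_table(co, sp$train$subjects)
  space <- factor_order(zt)
  zh <- zt$z[match(sp$holdout$subjects, zt$subjects), , drop = FALSE]
  ev <- evaluate_orderings(zh, space, n_reps = 40, seed = 2)

  # one-sided comparison across repetitions
  pr <- ev$per_rep
  tt <- pr$success_prop[pr$condition == "true"]
  rr <- pr$success_prop[pr$condition == "random"]
  expect_gt(mean(tt), mean(rr))
  expect_lt(stats::t.test(tt, rr, alternative = "greater")$p.value, 0.01)

  # paired minimum-z comparison on the same subjects and seeds
  expect_lte(ev$summary$true$min_z[["mean"]], ev$summary$random$min_z[["mean"]])
})
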
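# Gaussian-process regression with a squared-exponential kernel, the
# expected-improvement acquisition function, and a small EI-driven
# optimiser over discrete candidate sets. This one engine serves both the
# per-subject modality search and decision-tree/SVR hyperparameter tuning.

sqexp_kernel <- function(A, B, lengthscale, signal_sd) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  signal_sd^2 * exp(-0.5 * d2 / lengthscale^2)
}

#' Gaussian-process state over sampled points
#'
#' Holds the sampled coordinates and observations together with the
#' squared-exponential kernel hyperparameters. With `noise_sd = 0` the
#' posterior interpolates the observations exactly; far from all data it
#' reverts to the prior (mean `prior_mean`, SD `signal_sd`). The defaults
#' (length-scale 1.5 coordinates, unit signal SD, near-zero noise) suit
#' small integer search spaces, which cannot support marginal-likelihood
#' hyperparameter tuning.
#'
#' @param X numeric matrix of sampled coordinates (rows = points), or a
#'   vector for a 1-D space.
#' @param y numeric observations, one per row of `X`.
#' @param lengthscale kernel length-scale, in coordinate units.
#' @param signal_sd prior (kernel) SD.
#' @param noise_sd observation noise SD.
#' @param prior_mean prior mean of the latent function.
#' @return An object of class `gp_state`.
#' @export
gp_state <- function(X, y, lengthscale = 1.5, signal_sd = 1,
                     noise_sd = 1e-4, prior_mean = 0) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 1 || nrow(X) != length(y))
    stop("need >= 1 sample with matching X rows and y values")
  structure(list(X = X, y = y, lengthscale = lengthscale,
                 signal_sd = signal_sd, noise_sd = noise_sd,
                 prior_mean = prior_mean),
            class = "gp_state")
}

#' GP posterior mean and SD at query points
#'
#' Standard Gaussian-process regression posterior under the
#' squared-exponential kernel. If the kernel matrix is numerically
#' singular, a jitter of 1e-8 is added to its diagonal (noted via a
#' warning).
#'
#' @param state a `gp_state`.
#' @param Xstar query coordinates (matrix of rows, or vector for 1-D).
#' @return A list with numeric vectors `mean` and `sd` (one per query).
#' @export
gp_posterior <- function(state, Xstar) {
  stopifnot(inherits(state, "gp_state"))
  Xs <- as.matrix(Xstar)
  if (ncol(Xs) != ncol(state$X)) Xs <- matrix(as.numeric(Xstar), ncol = ncol(state$X))
  K <- sqexp_kernel(state$X, state$X, state$lengthscale, state$signal_sd)
  diag(K) <- diag(K) + state$noise_sd^2
  ch <- tryCatch(chol(K), error = function(e) {
    warning("kernel matrix singular; adding 1e-8 jitter")
    chol(K + diag(1e-8, nrow(K)))
  })
  ks <- sqexp_kernel(Xs, state$X, state$lengthscale, state$signal_sd)
  alpha <- backsolve(ch, forwardsolve(t(ch), state$y - state$prior_mean))
  mu <- state$prior_mean + as.numeric(ks %*% alpha)
  v <- forwardsolve(t(ch), t(ks))
  var <- state$signal_sd^2 - colSums(v^2)
  list(mean = mu, sd = sqrt(pmax(var, 0)))
}

#' Expected improvement (minimisation)
#'
#' The expected reduction below the best (lowest) observation so far under
#' the GP posterior: `EI = (f_best - mu) * Phi(u) + sd * phi(u)` with
#' `u = (f_best - mu)/sd`; in the `sd = 0` limit, `max(0, f_best - mu)`.
#' Always non-negative.
#'
#' @param state a `gp_state`.
#' @param Xstar query coordinates.
#' @param f_best incumbent (minimum observed value); default `min(state$y)`.
#' @return Numeric vector of EI values, one per query.
#' @export
expected_improvement <- function(state, Xstar, f_best = min(state$y)) {
  post <- gp_posterior(state, Xstar)
  mu <- post$mean
  s <- post$sd
  ei <- numeric(length(mu))
  z <- s > 0
  u <- (f_best - mu[z]) / s[z]
  ei[z] <- (f_best - mu[z]) * stats::pnorm(u) + s[z] * stats::dnorm(u)
  ei[!z] <- pmax(0, f_best - mu[!z])
  pmax(ei, 0)
}

# EI-driven minimisation of an expensive function over a finite candidate
# set (rows of `grid`). Burn-in points are drawn uniformly without
# replacement; each subsequent point maximises EI among unsampled
# candidates (ties -> lowest row index). Used for hyperparameter tuning.
gpei_optimise <- function(f, grid, budget, n_burn = 5, seed = 1,
                          lengthscale = NULL, signal_sd = NULL) {
  grid <- as.matrix(grid)
  m <- nrow(grid)
  budget <- min(budget, m)
  n_burn <- min(n_burn, budget)
  # standardise coordinates so one length-scale suits anisotropic grids
  scl <- apply(grid, 2, function(col) max(stats::sd(col), 1e-12))
  gs <- sweep(grid, 2, scl, `/`)
  if (is.null(lengthscale)) lengthscale <- 0.5
  sampled <- with_seed(seed, sample.int(m, n_burn))
  vals <- vapply(sampled, function(i) f(grid[i, ]), numeric(1))
  while (length(sampled) < budget) {
    ok <- is.finite(vals)
    if (!any(ok)) stop("all evaluations failed during tuning")
    ysd <- max(stats::sd(vals[ok]), 1e-12)
    st <- gp_state(gs[sampled[ok], , drop = FALSE],
                   (vals[ok] - mean(vals[ok])) / ysd,
                   lengthscale = lengthscale,
                   signal_sd = signal_sd %||% 1, noise_sd = 1e-3)
    cand <- setdiff(seq_len(m), sampled)
    ei <- expected_improvement(st, gs[cand, , drop = FALSE])
    pick <- cand[which.max(ei)]
    sampled <- c(sampled, pick)
    vals <- c(vals, f(grid[pick, ]))
  }
  ok <- is.finite(vals)
  if (!any(ok)) stop("all evaluations failed during tuning")
  best <- sampled[ok][which.min(vals[ok])]
  list(best = grid[best, ], best_value = min(vals[ok]),
       evaluated = grid[sampled, , drop = FALSE], values = vals)
}
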
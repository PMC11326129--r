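test_that("rank-Q data are reduced losslessly with zero residual variance", {
  set.seed(1)
  T_ <- 40; V <- 100; Q <- 3
  A <- matrix(rnorm(T_ * Q), T_, Q)
  S <- matrix(rnorm(V * Q), V, Q)
  y <- A %*% t(S)
  red <- reduce_dimension(y, Q)
  expect_lt(red$residual_var, 1e-10)
  expect_equal(tcrossprod(red$projection), diag(Q), tolerance = 1e-10)
  yc <- sweep(y, 2, colMeans(y))
  recon <- t(red$projection) %*% red$y_reduced
  expect_lt(max(abs(recon - yc)), 1e-8)
})

test_that("reduction rejects too many components and reports numerical rank", {
  y <- matrix(rnorm(10 * 20), 10, 20)
  expect_error(reduce_dimension(y, 10), "more frames than components")
  A <- matrix(rnorm(30 * 2), 30, 2); S <- matrix(rnorm(50 * 2), 50, 2)
  expect_error(reduce_dimension(A %*% t(S), 5), "rank 2")
})

test_that("white-noise residual variance estimates the noise variance", {
  set.seed(2)
  sigma <- 1.7
  y <- matrix(rnorm(500 * 2000, sd = sigma), 500, 2000)
  red <- reduce_dimension(y, 8)
  expect_equal(red$residual_var, sigma^2, tolerance = 0.1)
})

test_that("posterior update reproduces the 1-D conjugate hand computation", {
  pu <- posterior_update(2, matrix(1, 1, 1), 1, 0, 1)
  expect_equal(pu$mean, 1)
  expect_equal(drop(pu$cov), 0.5)
})

test_that("posterior limits: infinite prior precision and noiseless data", {
  set.seed(3)
  Q <- 3; Tp <- 3
  A <- matrix(rnorm(Tp * Q), Tp, Q) + diag(Q)
  y <- rnorm(Tp); m0 <- rnorm(Q)
  tight <- posterior_update(y, A, 1, m0, rep(1e-12, Q))
  expect_equal(tight$mean, m0, tolerance = 1e-5)
  loose <- posterior_update(y, A, 1e-12, m0, rep(1, Q))
  expect_equal(loose$mean, drop(solve(A, y)), tolerance = 1e-4)
})

test_that("posterior update matches explicit joint-Gaussian conditioning", {
  set.seed(4)
  for (k in 1:100) {
    Q <- sample(1:3, 1); Tp <- sample(1:3, 1)
    A <- matrix(rnorm(Tp * Q), Tp, Q)
    nv <- runif(1, 0.1, 3)
    m0 <- rnorm(Q); p0 <- runif(Q, 0.1, 4)
    y <- rnorm(Tp)
    got <- posterior_update(y, A, nv, m0, p0)
    want <- brute_posterior(y, A, nv, m0, p0)
    expect_equal(got$mean, want$mean, tolerance = 1e-8)
    expect_equal(got$cov, unname(want$cov), tolerance = 1e-8)
  }
})

test_that("shrinkage toward the prior mean is monotone in the noise variance", {
  set.seed(5)
  for (k in 1:25) {
    Q <- sample(1:3, 1); Tp <- Q
    A <- matrix(rnorm(Tp * Q), Tp, Q) + diag(Q)
    m0 <- rnorm(Q); p0 <- runif(Q, 0.2, 2)
    y <- rnorm(Tp, sd = 2)
    dist <- vapply(10^seq(-2, 3, length.out = 12), function(nv)
      sqrt(sum((posterior_update(y, A, nv, m0, p0)$mean - m0)^2)),
      numeric(1))
    expect_true(all(diff(dist) < 1e-10))
    expect_lt(dist[12], 0.05 * max(dist[1], 1e-8) + 1e-6)
  }
})

test_that("EM log-likelihood is non-decreasing and recovery beats dual regression", {
  mesh <- tiny_mesh(3)   # 642 vertices
  inc <- !mesh$exclusion_mask
  wins <- 0L
  n_subj <- 4
  coh <- make_cohort(mesh, n_subj, 300, 8, noise_sd = 3,
                     deviation_sd = 0.3, seed = 77)
  pri <- prior_on_included(truth_prior(coh), inc)
  for (i in seq_len(n_subj)) {
    red <- reduce_dimension(coh$runs[[i]]$data[, inc], 8)
    fit <- em_fit(red, pri)
    ll <- fit$loglik_trace
    expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
    truth <- coh$truth$subject_maps[[i]][inc, ]
    dr <- dual_regression(coh$runs[[i]]$data[, inc],
                          coh$truth$group_maps[inc, ])$subject_maps
    better <- vapply(1:8, function(q)
      cor(fit$mean[, q], truth[, q]) > cor(dr[, q], truth[, q]), logical(1))
    wins <- wins + sum(better)
  }
  expect_gte(wins, 0.9 * n_subj * 8)
})

test_that("a degenerate (floor-only) prior pins the posterior to the template", {
  mesh <- tiny_mesh()
  inc <- !mesh$exclusion_mask
  coh <- make_cohort(mesh, 1, 100, 3, noise_sd = 2, seed = 8)
  pri <- prior_on_included(truth_prior(coh), inc)
  pri$between_var[] <- 1e-10
  red <- reduce_dimension(coh$runs[[1]]$data[, inc], 3)
  fit <- suppressWarnings(em_fit(red, pri))
  expect_equal(fit$mean, pri$mean, tolerance = 1e-3)
  expect_gt(fit$noise_var, 0)
})

test_that("posterior standard deviations are calibrated on cohort data", {
  mesh <- tiny_mesh()
  inc <- !mesh$exclusion_mask
  coh <- make_cohort(mesh, 40, 150, 4, noise_sd = 3, deviation_sd = 0.3,
                     seed = 91)
  pri <- prior_on_included(truth_prior(coh), inc)
  zs <- unlist(lapply(seq_len(40), function(i) {
    red <- reduce_dimension(coh$runs[[i]]$data[, inc], 4)
    fit <- suppressWarnings(em_fit(red, pri))
    (fit$mean - coh$truth$subject_maps[[i]][inc, ]) / fit$sd
  }))
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("non-convergence warns but still returns a posterior", {
  mesh <- tiny_mesh(1)
  inc <- !mesh$exclusion_mask
  coh <- make_cohort(mesh, 1, 60, 2, noise_sd = 2, seed = 10)
  red <- reduce_dimension(coh$runs[[1]]$data[, inc], 2)
  pri <- prior_on_included(truth_prior(coh), inc)
  expect_warning(fit <- em_fit(red, pri, max_iter = 2), "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2)
  expect_true(all(is.finite(fit$mean)))
})
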
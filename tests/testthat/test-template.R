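test_that("noiseless dual regression recovers the group maps exactly", {
  set.seed(1)
  V <- 80; Q <- 3; T_ <- 40
  G <- matrix(rnorm(V * Q), V, Q)
  C <- matrix(rnorm(T_ * Q), T_, Q) + 2  # non-zero column means on purpose
  y <- C %*% t(G)
  dr <- dual_regression(y, G)
  expect_equal(dr$subject_maps, G, tolerance = 1e-8)
  expect_equal(dr$timecourses, C, tolerance = 1e-8)
})

test_that("rank-deficient group maps raise an error naming the collinear columns", {
  set.seed(2)
  G <- matrix(rnorm(50 * 2), 50, 2)
  G <- cbind(G, G[, 1] + G[, 2])
  y <- matrix(rnorm(20 * 50), 20, 50)
  expect_error(dual_regression(y, G), "collinear column")
})

test_that("single-map dual regression reduces to ordinary least squares", {
  set.seed(3)
  V <- 60; T_ <- 30
  g <- rnorm(V); g <- g / sqrt(sum(g^2))
  y <- matrix(rnorm(T_ * V), T_, V)
  dr <- dual_regression(y, matrix(g))
  # stage 1: projection onto g
  expect_equal(drop(dr$timecourses), drop(y %*% g), tolerance = 1e-10)
  # stage 2: per-vertex OLS on the demeaned timecourse
  tc <- drop(scale(y %*% g, scale = FALSE))
  beta <- drop(crossprod(y, tc)) / sum(tc^2)
  expect_equal(drop(dr$subject_maps), beta, tolerance = 1e-10)
})

test_that("map error decreases with scan length", {
  set.seed(4)
  V <- 100; Q <- 2
  G <- matrix(rnorm(V * Q), V, Q)
  mse <- function(T_, seed) {
    set.seed(seed)
    C <- matrix(rnorm(T_ * Q), T_, Q)
    y <- C %*% t(G) + matrix(rnorm(T_ * V, sd = 3), T_, V)
    mean((dual_regression(y, G)$subject_maps - G)^2)
  }
  m100 <- mean(vapply(1:20, function(s) mse(100, s), numeric(1)))
  m800 <- mean(vapply(1:20, function(s) mse(800, s + 100), numeric(1)))
  expect_lt(m800, m100)
})

test_that("pseudo-session split is a contiguous exact partition", {
  y <- matrix(seq_len(11 * 3), 11, 3)
  sp <- split_pseudo_sessions(y)
  expect_equal(nrow(sp$first), 5)
  expect_equal(nrow(sp$second), 6)
  expect_identical(rbind(sp$first, sp$second), y)
  y1600 <- matrix(0, 1600, 2)
  sp2 <- split_pseudo_sessions(y1600)
  expect_equal(c(nrow(sp2$first), nrow(sp2$second)), c(800, 800))
  expect_error(split_pseudo_sessions(matrix(0, 3, 2)), "at least 4")
})

test_that("template variance decomposition matches hand computation", {
  # three subjects, session-constant values (1,1), (3,3), (5,5)
  maps <- lapply(c(1, 3, 5), function(v)
    list(matrix(v, 1, 1), matrix(v, 1, 1)))
  pr <- estimate_template(maps, variance_floor = 0)
  expect_equal(pr$mean[1, 1], 3)
  expect_equal(pr$sigma_tot[1, 1], 4)
  expect_equal(pr$sigma_noise[1, 1], 0)
  expect_equal(pr$between_var[1, 1], 4)
})

test_that("identical sessions give zero within-subject variance", {
  set.seed(5)
  maps <- lapply(1:6, function(i) {
    m <- matrix(rnorm(20 * 2), 20, 2)
    list(m, m)
  })
  pr <- estimate_template(maps, variance_floor = 0)
  expect_equal(pr$sigma_noise, matrix(0, 20, 2))
  expect_equal(pr$between_var, pr$sigma_tot)
})

test_that("variance decomposition identity holds exactly before clamping", {
  set.seed(6)
  maps <- lapply(1:10, function(i)
    list(matrix(rnorm(30 * 3), 30, 3), matrix(rnorm(30 * 3), 30, 3)))
  pr <- estimate_template(maps)
  expect_equal(pr$sigma_tot, pr$between_var_raw + pr$sigma_noise,
               tolerance = 1e-12)
})

test_that("pure session noise drives between-subject variance to the clamp", {
  # With one shared true map and independent session noise, the raw
  # between-subject variance reduces algebraically to the cross-session
  # sample covariance, which is symmetric about zero: about half the
  # vertices come out negative and clamp at the floor.
  set.seed(7)
  V <- 200
  shared <- matrix(rnorm(V), V, 1)
  frac_clamped <- vapply(1:20, function(s) {
    set.seed(100 + s)
    sess <- lapply(1:12, function(i)
      list(shared + matrix(rnorm(V, sd = 0.5), V, 1),
           shared + matrix(rnorm(V, sd = 0.5), V, 1)))
    pr <- estimate_template(sess)
    # raw estimate is exactly the covariance of the two sessions
    s1 <- sapply(sess, function(m) m[[1]][, 1])
    s2 <- sapply(sess, function(m) m[[2]][, 1])
    cov12 <- sapply(seq_len(V), function(v) cov(s1[v, ], s2[v, ]))
    expect_equal(pr$between_var_raw[, 1], cov12, tolerance = 1e-10)
    mean(pr$between_var == pr$variance_floor)
  }, numeric(1))
  expect_true(all(frac_clamped > 0.3 & frac_clamped < 0.7))
  expect_equal(mean(frac_clamped), 0.5, tolerance = 0.1)
})

test_that("template estimation rejects degenerate inputs", {
  maps2 <- lapply(1:2, function(i) list(matrix(1, 2, 1), matrix(1, 2, 1)))
  expect_error(estimate_template(maps2), "at least 3")
  maps_nf <- lapply(1:3, function(i) list(matrix(NA_real_, 2, 1),
                                          matrix(1, 2, 1)))
  expect_error(estimate_template(maps_nf), "non-finite")
})

test_that("template recovery: mean and variance track the generator truth", {
  mesh <- tiny_mesh()
  inc <- !mesh$exclusion_mask
  coh <- make_cohort(mesh, 50, 300, 4, noise_sd = 2, deviation_sd = 0.4,
                     seed = 44)
  maps <- lapply(coh$runs, function(r) {
    h <- split_pseudo_sessions(r$data[, inc])
    lapply(h, function(y)
      dual_regression(y, coh$truth$group_maps[inc, ])$subject_maps)
  })
  pr <- estimate_template(maps)
  for (q in 1:4) {
    expect_gt(cor(pr$mean[, q], coh$truth$group_maps[inc, q]), 0.95)
    expect_gt(cor(pr$between_var[, q], coh$truth$deviation_var[inc, q]), 0.7)
  }
})
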
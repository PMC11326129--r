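fake_post <- function(mean, sd) list(mean = mean, sd = sd)

test_that("t-maps are mean over sd with odd symmetry", {
  m <- matrix(c(2, 0, -3), 3, 1)
  s <- matrix(1, 3, 1)
  expect_equal(t_map(fake_post(m, s)), m)
  expect_equal(t_map(fake_post(m, s * 2)), m / 2)
  expect_equal(t_map(fake_post(-m, s)), -t_map(fake_post(m, s)))
  s0 <- s; s0[2, 1] <- 0
  expect_error(t_map(fake_post(m, s0)), "SD is zero")
})

test_that("Bonferroni level and critical value match a quantile oracle", {
  tm <- matrix(rnorm(1000), 1000, 1)
  em <- engagement_mask(tm, df = 30, alpha = 0.05)
  expect_equal(em$level, 5e-5)
  expect_equal(em$critical, qt(1 - 5e-5, 30), tolerance = 1e-6)
  # joint correction divides further by Q
  tm2 <- matrix(rnorm(2000), 1000, 2)
  em2 <- engagement_mask(tm2, df = 30, alpha = 0.05,
                         correction = "vertices_by_ics")
  expect_equal(em2$level, 5e-5 / 2)
})

test_that("non-positive t never engages and masks shrink as alpha drops", {
  tm <- matrix(seq(-2, 8, length.out = 200), 200, 1)
  em <- engagement_mask(tm, df = 50, alpha = 0.05)
  expect_true(all(tm[em$masks] > 0))
  tm_neg <- matrix(pmin(tm, 0), 200, 1)
  expect_equal(sum(engagement_mask(tm_neg, df = 50)$masks), 0)
  sizes <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a)
    sum(engagement_mask(tm, df = 50, alpha = a)$masks), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("engagement respects the include mask and supports df = Inf", {
  tm <- matrix(10, 50, 1)
  inc <- rep(c(TRUE, FALSE), 25)
  em <- engagement_mask(tm, df = Inf, alpha = 0.05, include_mask = inc)
  expect_true(all(!em$masks[!inc]))
  expect_equal(em$critical, qnorm(1 - 0.05 / 25))
})

test_that("WTA labels match a brute-force argmax oracle including ties", {
  # single positive IC labels every included vertex 1
  expect_equal(wta_parcellation(matrix(2, 5, 1)), rep(1L, 5))
  # documented tie rule: lowest index wins
  expect_equal(wta_parcellation(matrix(c(2, 2, 1), 1, 3)), 1L)
  set.seed(11)
  for (k in 1:20) {
    V <- 100; Q <- sample(2:6, 1)
    tm <- matrix(rnorm(V * Q), V, Q)
    tm[sample(V, 10), 1] <- tm[sample(V, 10), 2]  # exercise exact ties
    got <- wta_parcellation(tm)
    want <- vapply(seq_len(V), function(v) {
      r <- tm[v, ]
      if (max(r) <= 0) 0L else which.max(r)
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("nuisance ICs never win and excluded vertices stay unlabeled", {
  tm <- cbind(rep(1, 10), rep(5, 10), rep(2, 10))
  lab <- wta_parcellation(tm, signal_ics = c(1, 3))
  expect_true(all(lab == 3))
  inc <- c(rep(TRUE, 6), rep(FALSE, 4))
  lab2 <- wta_parcellation(tm, include_mask = inc, signal_ics = c(1, 3))
  expect_true(all(lab2[7:10] == 0))
  # all-negative rows are unassigned
  expect_equal(wta_parcellation(matrix(-1, 4, 2)), rep(0L, 4))
})

test_that("frequency map reports the modal label and its prevalence", {
  p1 <- c(1L, 1L, 2L, 0L)
  p2 <- c(1L, 2L, 2L, 0L)
  fm <- frequency_map(list(p1, p2))
  expect_equal(fm$modal_label, c(1L, 1L, 2L, 0L))
  expect_equal(fm$frequency, c(1, 0.5, 1, 1))
  expect_error(frequency_map(list(p1, c(1L, 2L))), "length")
  # label 0 ignored unless unanimous
  fm2 <- frequency_map(list(c(0L, 0L), c(3L, 0L)))
  expect_equal(fm2$modal_label, c(3L, 0L))
  expect_equal(fm2$frequency, c(0.5, 1))
})

test_that("uniform random labels concentrate near the multinomial modal mass", {
  set.seed(12)
  Q <- 8; N <- 200; V <- 300
  P <- matrix(sample.int(Q, N * V, replace = TRUE), N, V)
  fm <- frequency_map(P)
  expect_true(all(fm$frequency > 1 / Q))
  # oracle: simulate the expected max count of a uniform multinomial
  sims <- replicate(2000, max(tabulate(sample.int(Q, N, TRUE), Q))) / N
  expect_equal(mean(fm$frequency), mean(sims), tolerance = 0.01)
})

test_that("parcellation of the group maps recovers the generator's bumps", {
  mesh <- tiny_mesh(3)
  inc <- !mesh$exclusion_mask
  G <- make_group_maps(mesh, 6, seed = 3)
  # t-analog of the group maps: the maps themselves (positive bumps)
  lab <- wta_parcellation(G, include_mask = inc)
  want <- max.col(G, ties.method = "first")
  agree <- mean(lab[inc] == want[inc])
  expect_gt(agree, 0.95)
})
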
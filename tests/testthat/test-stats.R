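test_that("connectivity strength is the area-weighted mean t", {
  # constant t inside the mask -> the constant, any areas
  expect_equal(connectivity_strength(rep(4.2, 5), rep(TRUE, 5),
                                     runif(5, 0.5, 2)), 4.2)
  # hand computation
  expect_equal(connectivity_strength(c(1, 3), c(TRUE, TRUE), c(1, 3)), 2.5)
  # equal areas reduce to the simple mean
  set.seed(1)
  t_v <- rnorm(30); m <- runif(30) > 0.5
  expect_equal(connectivity_strength(t_v, m, rep(0.7, 30)),
               mean(t_v[m]), tolerance = 1e-12)
  expect_warning(s <- connectivity_strength(t_v, rep(FALSE, 30),
                                            rep(1, 30)), "empty")
  expect_true(is.na(s))
})

test_that("strength is invariant under vertex relabeling", {
  set.seed(2)
  t_v <- rnorm(50); m <- runif(50) > 0.3; a <- runif(50, 0.2, 3)
  perm <- sample(50)
  expect_equal(connectivity_strength(t_v, m, a),
               connectivity_strength(t_v[perm], m[perm], a[perm]))
})

test_that("partial Spearman handles perfect monotone association", {
  age <- 1:20
  strength <- age^2 + 3
  z <- matrix(rnorm(20), 20, 1)
  ps <- partial_spearman(strength, age, NULL)
  expect_equal(ps$rho, 1)
  expect_lt(ps$p_value, 1e-4)
})

test_that("partial Spearman with no covariates equals plain Spearman", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  ps <- partial_spearman(x, y, NULL)
  ct <- cor.test(x, y, method = "spearman")
  expect_equal(ps$rho, unname(ct$estimate))
  expect_equal(ps$p_value, ct$p.value)
})

test_that("AS 89 p-values equal exhaustive permutation for n = 7", {
  set.seed(4)
  for (k in 1:5) {
    x <- sample(7); y <- sample(7)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(ct$p.value, perm_spearman_p(x, y), tolerance = 1e-10)
  }
  # through the partial interface: residualizing on an empty design is
  # rank-preserving, so the same exactness applies
  x <- c(0.3, 1.9, 0.8, 2.7, 1.1, 0.2, 2.2)
  y <- c(1.4, 0.1, 2.8, 0.9, 2.1, 0.5, 1.7)
  ps <- partial_spearman(x, y, NULL)
  expect_equal(ps$p_value, perm_spearman_p(x, y), tolerance = 1e-10)
  expect_equal(ps$p_method, "AS89")
})

test_that("independent variables rarely reach significance", {
  set.seed(5)
  hits <- 0; big_rho <- 0
  for (k in 1:100) {
    x <- rnorm(200); y <- rnorm(200)
    z <- cbind(rnorm(200), rnorm(200))
    ps <- partial_spearman(x, y, z)
    hits <- hits + (ps$p_value < 0.05)
    big_rho <- big_rho + (abs(ps$rho) >= 0.2)
  }
  expect_lte(hits, 10)       # >= 90% of replicates non-significant
  expect_lte(big_rho, 10)    # |rho| < 0.2 in >= 90% of replicates
})

test_that("residualization removes a strong covariate effect", {
  set.seed(6)
  n <- 80
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 37, 45)
  strength <- 5 * sex + rnorm(n)          # driven by sex, not age
  raw <- suppressWarnings(cor.test(strength, age, method = "spearman"))
  ps <- partial_spearman(strength, age, cbind(sex))
  expect_gt(ps$p_value, 0.05)
  expect_lt(abs(ps$rho), 0.3)
})

test_that("degenerate inputs are rejected", {
  expect_error(partial_spearman(rep(1, 10), rnorm(10), NULL), "constant")
  z <- cbind(1:10, 2 * (1:10))
  expect_error(partial_spearman(rnorm(10), rnorm(10),
                                cbind(1:10, 1:10)), "rank deficient")
})

test_that("run_age_trend reports per-IC tests and drops thin ICs", {
  set.seed(7)
  n <- 30
  tab <- do.call(rbind, lapply(1:2, function(q) tibble::tibble(
    subject_id = sprintf("s%02d", 1:n), ic = q,
    strength = (q == 1) * seq_len(n) * 0.5 + rnorm(n, sd = 0.2),
    age = seq(37, 45, length.out = n) + rnorm(n, sd = 0.01),
    sex = rbinom(n, 1, 0.5), motion = rpois(n, 2))))
  tab$strength[tab$ic == 2] <- NA
  tab$strength[tab$ic == 2][1:3] <- rnorm(3)
  out <- run_age_trend(tab)
  expect_equal(nrow(out), 2)
  expect_true(out$evaluable[1])
  expect_gt(out$rho[1], 0)
  expect_lt(out$p[1], 0.05)
  expect_false(out$evaluable[2])
  expect_true(is.na(out$rho[2]))
})

test_that("permuting ages destroys a real age trend", {
  set.seed(8)
  n <- 60
  age <- runif(n, 37, 45)
  strength <- 2 * scale(age) + rnorm(n, sd = 0.5)
  ps <- partial_spearman(drop(strength), age, NULL)
  expect_lt(ps$p_value, 0.001)
  hits <- sum(vapply(1:50, function(k)
    partial_spearman(drop(strength), sample(age), NULL)$p_value < 0.05,
    logical(1)))
  expect_lte(hits, 8)  # near-nominal rate under permutation
})
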
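# Shared small fixtures, built in code at test time.

tiny_mesh <- function(subdiv = 2, seed = 5, ...) make_mesh(subdiv, seed = seed, ...)

# restrict a template_prior (or prior-like list) to included vertices
prior_on_included <- function(prior, inc) {
  for (f in c("mean", "between_var", "sigma_tot", "sigma_noise",
              "between_var_raw"))
    prior[[f]] <- prior[[f]][inc, , drop = FALSE]
  prior
}

# brute-force window scan oracle for select_block
brute_select_block <- function(flags, block_length) {
  T_len <- length(flags)
  counts <- vapply(seq_len(T_len - block_length + 1), function(s)
    sum(flags[s:(s + block_length - 1)]), numeric(1))
  best <- which.min(counts)
  list(block_start = best, n_outliers = counts[best])
}

# numerically condition the explicit joint Gaussian of (s, y)
brute_posterior <- function(y_v, A, noise_var, prior_mean_v, prior_var_v) {
  Q <- length(prior_mean_v); Tp <- nrow(A)
  S0 <- diag(prior_var_v, Q)
  joint_mean <- c(prior_mean_v, A %*% prior_mean_v)
  cov_sy <- S0 %*% t(A)
  cov_yy <- A %*% S0 %*% t(A) + noise_var * diag(Tp)
  m <- prior_mean_v + cov_sy %*% solve(cov_yy, y_v - A %*% prior_mean_v)
  C <- S0 - cov_sy %*% solve(cov_yy, t(cov_sy))
  list(mean = drop(m), cov = C)
}

# exhaustive Spearman permutation p-value (two-sided, via the S statistic)
perm_spearman_p <- function(x, y) {
  n <- length(x)
  P <- gtools_permutations(n)
  rx <- rank(x); ry <- rank(y)
  s_obs <- sum((rx - ry)^2)
  S <- apply(P, 1, function(pp) sum((rx - ry[pp])^2))
  min(1, 2 * min(mean(S <= s_obs), mean(S >= s_obs)))
}

# all permutations of 1:n (n small)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  p <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# triangle areas re-derived locally (independent of the package's path)
triangle_areas_for_test <- function(m) {
  v <- m$coordinates; tr <- m$triangles
  vapply(seq_len(nrow(tr)), function(f) {
    e1 <- v[tr[f, 2], ] - v[tr[f, 1], ]
    e2 <- v[tr[f, 3], ] - v[tr[f, 1], ]
    0.5 * sqrt(sum(crossprod_vec(e1, e2)^2))
  }, numeric(1))
}
crossprod_vec <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

mean_edge <- function(mesh) {
  e <- mesh_edges(mesh)
  mean(sqrt(rowSums((mesh$coordinates[e[, 1], ] -
                     mesh$coordinates[e[, 2], ])^2)))
}
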
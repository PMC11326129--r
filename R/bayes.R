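#' Temporal dimension reduction of a BOLD run
#'
#' Centers each vertex time series, then projects onto the top-Q temporal
#' principal directions (eigenvectors of the T x T temporal covariance,
#' equivalently the left singular vectors of the data). The retained data
#' have T' = Q rows; the mean of the discarded eigenvalues estimates the
#' residual (isotropic noise) variance and initializes the model's noise
#' parameter.
#'
#' @param y T x V matrix (or `bold_run`), T > `n_ics`.
#' @param n_ics Number of components Q to retain.
#' @return A `reduced_data`: `y_reduced` (Q x V), `projection` (Q x T,
#'   orthonormal rows), `residual_var` (>= 0), `n_ics`, `n_timepoints`.
#' @export
reduce_dimension <- function(y, n_ics) {
  y <- run_data(y)
  T_len <- nrow(y)
  if (T_len <= n_ics) stop("need strictly more frames than components")
  yc <- sweep(y, 2, colMeans(y))
  Ct <- tcrossprod(yc) / ncol(yc)
  eg <- eigen(Ct, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev[1], .Machine$double.eps) * T_len * .Machine$double.eps)
  if (rank < n_ics)
    stop(sprintf("data have numerical rank %d < %d requested components",
                 rank, n_ics))
  U <- eg$vectors[, seq_len(n_ics), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(n_ics)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) U[, k] <- -U[, k]
  }
  structure(
    list(y_reduced = t(U) %*% yc, projection = t(U),
         residual_var = mean(ev[(n_ics + 1):T_len]),
         n_ics = n_ics, n_timepoints = T_len),
    class = "reduced_data")
}

#' Closed-form vertex-wise Gaussian posterior update
#'
#' Conjugate update for one vertex of the model `y = A s + e`,
#' `e ~ N(0, noise_var * I)`, `s ~ N(prior_mean, diag(prior_var))`:
#' posterior covariance `(diag(1/prior_var) + A'A / noise_var)^(-1)` and
#' mean `cov %*% (prior_mean / prior_var + A'y / noise_var)`.
#'
#' @param y_v Data vector at the vertex (length T').
#' @param A T' x Q mixing matrix.
#' @param noise_var Positive scalar noise variance.
#' @param prior_mean_v,prior_var_v Length-Q prior mean and (strictly
#'   positive) prior variance at the vertex.
#' @return List with `mean` (length Q) and `cov` (Q x Q, symmetric
#'   positive definite).
#' @export
posterior_update <- function(y_v, A, noise_var, prior_mean_v, prior_var_v) {
  stopifnot(noise_var > 0, all(prior_var_v > 0))
  P <- diag(1 / prior_var_v, length(prior_var_v)) + crossprod(A) / noise_var
  covm <- chol2inv(chol(P))
  m <- covm %*% (prior_mean_v / prior_var_v + crossprod(A, y_v) / noise_var)
  list(mean = drop(m), cov = (covm + t(covm)) / 2)
}

#' EM fit of the template-ICA model for one subject
#'
#' Alternates an E-step — the closed-form Gaussian posterior of the source
#' vector at every included vertex, accumulating its first and second
#' moments — with an M-step updating the mixing matrix
#' `A <- (sum_v y_v E[s_v]') (sum_v E[s_v s_v'])^(-1)` and the spherical
#' noise variance `noise_var <- mean_v E||y_v - A s_v||^2 / T'`. The
#' observed-data log-likelihood is recorded at the start of every
#' iteration and is non-decreasing (the EM ascent property, used as an
#' internal correctness check). Convergence is declared when the maximum
#' relative change of `A` and `noise_var` drops below `tol`.
#'
#' @param reduced A `reduced_data` from [reduce_dimension()].
#' @param prior A `template_prior`; its floored `between_var` must be
#'   strictly positive.
#' @param A_init Optional T' x Q initial mixing matrix; default is the
#'   stage-1 dual-regression estimate of the reduced data against the
#'   prior mean maps.
#' @param tol Relative-change convergence tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations (default 100). Non-convergence
#'   returns the current posterior with `converged = FALSE` and a warning.
#' @param exclusion_mask Optional V-length logical; excluded vertices are
#'   skipped entirely (no posterior, no M-step contribution) and reported
#'   as `NA` in the output maps.
#' @return A `subject_posterior`: `mean`, `sd` (V x Q, `NA` at excluded
#'   vertices), `mixing` (T' x Q), `noise_var`, `n_iter`, `converged`,
#'   `loglik_trace`, and `prior_mean` (for derived deviation maps).
#' @export
em_fit <- function(reduced, prior, A_init = NULL, tol = 1e-4,
                   max_iter = 100, exclusion_mask = NULL) {
  stopifnot(inherits(reduced, "reduced_data"), inherits(prior, "template_prior"))
  Y <- reduced$y_reduced                      # T' x V, T' = Q
  Tp <- nrow(Y); Q <- reduced$n_ics
  V <- ncol(Y)
  stopifnot(nrow(prior$mean) == V, ncol(prior$mean) == Q)
  inc <- if (is.null(exclusion_mask)) rep(TRUE, V) else !exclusion_mask
  Yi <- Y[, inc, drop = FALSE]
  M <- prior$mean[inc, , drop = FALSE]
  Pv <- prior$between_var[inc, , drop = FALSE]
  if (any(Pv <= 0)) stop("prior between-subject variance must be floored > 0")
  Vi <- ncol(Yi)

  if (is.null(A_init)) {
    qm <- qr(M)
    if (qm$rank < Q) stop("prior mean maps are rank deficient")
    A <- t(qr.coef(qm, t(Yi)))
  } else {
    A <- as.matrix(A_init)
    stopifnot(nrow(A) == Tp, ncol(A) == Q, qr(A)$rank == Q)
  }
  nv <- reduced$residual_var
  if (!is.finite(nv) || nv <= 0) nv <- 1e-3 * mean(Yi^2) + 1e-12

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0
  post <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    es <- em_estep(Yi, A, nv, M, Pv)
    loglik <- c(loglik, es$loglik)
    if (min(eigen(es$S2, symmetric = TRUE, only.values = TRUE)$values) <=
        1e-12 * max(abs(es$S2)))
      stop("singular M-step moment matrix")
    A_new <- es$S1 %*% solve(es$S2)
    nv_new <- (es$sum_y2 - 2 * sum(A_new * es$S1) +
               sum(crossprod(A_new) * es$S2)) / (Tp * Vi)
    nv_new <- max(nv_new, 1e-12)
    rel <- max(max(abs(A_new - A)) / (max(abs(A)) + 1e-12),
               abs(nv_new - nv) / (nv + 1e-12))
    A <- A_new; nv <- nv_new
    post <- es
    if (rel < tol) { converged <- TRUE; break }
  }
  # final E-step so the reported posterior matches the final parameters
  post <- em_estep(Yi, A, nv, M, Pv)
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations", max_iter))

  mean_full <- matrix(NA_real_, V, Q)
  sd_full <- matrix(NA_real_, V, Q)
  mean_full[inc, ] <- post$post_mean
  sd_full[inc, ] <- sqrt(post$post_var)
  structure(
    list(mean = mean_full, sd = sd_full, mixing = A, noise_var = nv,
         n_iter = iter, converged = converged, loglik_trace = loglik,
         prior_mean = prior$mean, include_mask = inc),
    class = "subject_posterior")
}

#' Deviation of a subject's posterior mean from the population template
#'
#' @param posterior A `subject_posterior`.
#' @return V x Q matrix `posterior$mean - prior mean`.
#' @export
posterior_deviation <- function(posterior) {
  posterior$mean - posterior$prior_mean
}

#' @export
print.subject_posterior <- function(x, ...) {
  cat(sprintf(
    "subject_posterior: V=%d, Q=%d, noise_var=%.4g, %d EM iterations (%s)\n",
    nrow(x$mean), ncol(x$mean), x$noise_var, x$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
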
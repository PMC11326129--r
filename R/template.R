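#' Dual regression of one run against group spatial maps
#'
#' Stage 1 regresses every time frame on the group spatial maps (multiple
#' spatial regression), producing subject timecourses; stage 2 regresses
#' every vertex's time series on the column-demeaned timecourses (multiple
#' temporal regression), producing subject spatial maps. Timecourses are
#' demeaned but not variance-normalized, so the stage-2 coefficients keep
#' the units of the group maps (the convention used throughout the
#' template-estimation and Bayesian stages).
#'
#' @param y T x V data matrix (or `bold_run`), T > Q.
#' @param group_maps V x Q matrix of group-level spatial maps, full column
#'   rank.
#' @return A `dual_regression_result`: `timecourses` (T x Q),
#'   `subject_maps` (V x Q).
#' @export
dual_regression <- function(y, group_maps) {
  y <- run_data(y)
  G <- as.matrix(group_maps)
  stopifnot(nrow(y) > ncol(G), nrow(G) == ncol(y))
  qg <- qr(G)
  if (qg$rank < ncol(G)) {
    bad <- qg$pivot[(qg$rank + 1):ncol(G)]
    stop(sprintf("group maps are rank deficient; collinear column(s): %s",
                 paste(sort(bad), collapse = ", ")))
  }
  tc <- t(qr.coef(qg, t(y)))                     # T x Q
  tc_d <- scale(tc, center = TRUE, scale = FALSE)
  maps <- t(qr.coef(qr(tc_d), y))                # V x Q
  dimnames(maps) <- NULL
  structure(list(timecourses = tc, subject_maps = maps),
            class = "dual_regression_result")
}

#' Split a run into two contiguous pseudo-sessions
#'
#' The first half gets `floor(T/2)` frames, the second the remainder; no
#' frame is shared and concatenation reproduces the input. Contiguous
#' halves (rather than interleaved frames) preserve the temporal
#' autocorrelation within each half.
#'
#' @param y T x V matrix (or `bold_run`), T >= 4.
#' @return List with `first` and `second` matrices.
#' @export
split_pseudo_sessions <- function(y) {
  y <- run_data(y)
  T_len <- nrow(y)
  if (T_len < 4) stop("need at least 4 frames to form pseudo-sessions")
  h <- floor(T_len / 2)
  list(first = y[seq_len(h), , drop = FALSE],
       second = y[(h + 1):T_len, , drop = FALSE])
}

#' Empirical population prior from pseudo test-retest maps
#'
#' Given dual-regression map estimates `s_ij(v,q)` for N subjects and two
#' pseudo-sessions each, estimates the population mean
#' `mu0 = (1/2N) * sum_ij s_ij` and decomposes the variance across
#' subjects: the total variance is the average over sessions of the
#' between-subject variance of each session's maps, the within-subject
#' (noise) variance is half the between-subject variance of the session
#' difference, and the between-subject variance of the prior is their
#' difference, clamped below at `variance_floor` (negative estimates can
#' occur by sampling noise; clamping keeps the prior proper). All variances
#' use the unbiased N-1 estimator.
#'
#' @param maps Either an N x 2 x V x Q array, or a list of length N whose
#'   elements are lists of two V x Q matrices (sessions 1 and 2).
#' @param variance_floor Non-negative floor for the between-subject
#'   variance; default `1e-6 * median(sigma_tot^2)`.
#' @return A `template_prior`: `mean`, `between_var` (clamped),
#'   `between_var_raw`, `sigma_tot`, `sigma_noise` (all V x Q),
#'   `n_template_subjects`, `variance_floor`.
#' @export
estimate_template <- function(maps, variance_floor = NULL) {
  if (is.array(maps) && length(dim(maps)) == 4) {
    N <- dim(maps)[1]; V <- dim(maps)[3]; Q <- dim(maps)[4]
    s1 <- matrix(maps[, 1, , ], N, V * Q)
    s2 <- matrix(maps[, 2, , ], N, V * Q)
  } else if (is.list(maps)) {
    N <- length(maps)
    V <- nrow(maps[[1]][[1]]); Q <- ncol(maps[[1]][[1]])
    s1 <- do.call(rbind, lapply(maps, function(m) as.numeric(m[[1]])))
    s2 <- do.call(rbind, lapply(maps, function(m) as.numeric(m[[2]])))
  } else stop("maps must be an N x 2 x V x Q array or a list of session pairs")
  if (N < 3) stop("need at least 3 template subjects")
  if (any(!is.finite(s1)) || any(!is.finite(s2)))
    stop("non-finite values in template maps")

  colvar <- function(m) colSums(sweep(m, 2, colMeans(m))^2) / (N - 1)
  mu0 <- (colMeans(s1) + colMeans(s2)) / 2
  sigma_tot <- (colvar(s1) + colvar(s2)) / 2
  sigma_noise <- colvar(s2 - s1) / 2
  raw <- sigma_tot - sigma_noise
  if (is.null(variance_floor))
    variance_floor <- 1e-6 * stats::median(sigma_tot)
  stopifnot(variance_floor >= 0)
  new_template_prior(
    mean = matrix(mu0, V, Q),
    between_var = matrix(pmax(raw, variance_floor), V, Q),
    sigma_tot = matrix(sigma_tot, V, Q),
    sigma_noise = matrix(sigma_noise, V, Q),
    between_var_raw = matrix(raw, V, Q),
    n_template_subjects = N, variance_floor = variance_floor)
}

new_template_prior <- function(mean, between_var, sigma_tot, sigma_noise,
                               between_var_raw, n_template_subjects,
                               variance_floor) {
  structure(list(mean = mean, between_var = between_var,
                 sigma_tot = sigma_tot, sigma_noise = sigma_noise,
                 between_var_raw = between_var_raw,
                 n_template_subjects = n_template_subjects,
                 variance_floor = variance_floor),
            class = "template_prior")
}

#' @export
print.template_prior <- function(x, ...) {
  cat(sprintf("template_prior: V=%d, Q=%d, N=%d template subjects, floor=%.3g\n",
              nrow(x$mean), ncol(x$mean), x$n_template_subjects,
              x$variance_floor))
  invisible(x)
}

#' Pseudo test-retest dual-regression maps for a set of runs
#'
#' Splits each run into pseudo-sessions and dual-regresses each half
#' against the group maps; the output feeds [estimate_template()].
#'
#' @param runs List of `bold_run`s (or T x V matrices).
#' @param group_maps V x Q group spatial maps.
#' @return List (length N) of lists of two V x Q map matrices.
#' @export
pseudo_session_maps <- function(runs, group_maps) {
  lapply(runs, function(r) {
    halves <- split_pseudo_sessions(r)
    list(dual_regression(halves$first, group_maps)$subject_maps,
         dual_regression(halves$second, group_maps)$subject_maps)
  })
}
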
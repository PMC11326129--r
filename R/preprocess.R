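#' Global temporal signal-to-noise map in decibels
#'
#' Per subject the vertex-wise tSNR is the temporal mean over the temporal
#' standard deviation of the BOLD series. The global map averages the
#' subject tSNR maps across the sample and converts to decibels,
#' `10 * log10(mean_i SNR_i(v))`. Vertices with zero temporal SD in any
#' subject (or with a non-positive averaged SNR, for which decibels are
#' undefined) are marked invalid and returned as `NA` rather than silently
#' infinite.
#'
#' @param runs List of `bold_run` objects (or plain T x V matrices).
#' @param exclusion_mask Optional V-length logical; excluded vertices are
#'   returned as `NA`.
#' @return Numeric V-vector of dB values with attribute `invalid`
#'   (logical V-vector marking vertices dropped for zero SD / non-positive
#'   mean SNR).
#' @export
compute_tsnr_map <- function(runs, exclusion_mask = NULL) {
  stopifnot(length(runs) >= 1)
  mats <- lapply(runs, run_data)
  V <- ncol(mats[[1]])
  invalid <- rep(FALSE, V)
  acc <- numeric(V)
  for (y in mats) {
    stopifnot(ncol(y) == V, nrow(y) >= 2)
    m <- colMeans(y)
    sd_v <- sqrt(colSums(sweep(y, 2, m)^2) / (nrow(y) - 1))
    zero <- sd_v <= 0
    invalid <- invalid | zero
    snr <- ifelse(zero, NA_real_, m / sd_v)
    acc <- acc + ifelse(zero, 0, snr)
  }
  avg <- acc / length(mats)
  invalid <- invalid | (!is.na(avg) & avg <= 0)
  out <- ifelse(invalid, NA_real_, 10 * log10(avg))
  if (!is.null(exclusion_mask)) out[exclusion_mask] <- NA_real_
  attr(out, "invalid") <- invalid
  out
}

#' DVARS: root-mean-squared frame-to-frame BOLD change
#'
#' `dvars[t] = sqrt(mean_v (y[t,v] - y[t-1,v])^2)` over included vertices,
#' with `dvars[1] = 0` by convention so the vector aligns with frames.
#' Computed on the data as provided (no intensity normalization; see the
#' methods vignette).
#'
#' @param run A `bold_run` or T x V matrix, T >= 2.
#' @param exclusion_mask Optional V-length logical of vertices to drop.
#' @return Numeric T-vector.
#' @export
compute_dvars <- function(run, exclusion_mask = NULL) {
  y <- run_data(run)
  if (nrow(y) < 2) stop("DVARS needs at least two frames")
  if (!is.null(exclusion_mask)) y <- y[, !exclusion_mask, drop = FALSE]
  d <- diff(y)
  c(0, sqrt(rowMeans(d^2)))
}

#' Flag motion-corrupted frames from a DVARS trace
#'
#' A frame is flagged when its DVARS exceeds 1.5 times the interquartile
#' range above the 75th percentile of the whole run (frame 1, conventionally
#' zero, is included in the quartiles). Quartiles use linear interpolation
#' (R's default type 7).
#'
#' @param dvars Numeric T-vector, T >= 4.
#' @return Logical T-vector.
#' @export
flag_outliers <- function(dvars) {
  stopifnot(length(dvars) >= 4)
  q <- stats::quantile(dvars, c(0.25, 0.75), names = FALSE, type = 7)
  dvars > q[2] + 1.5 * (q[2] - q[1])
}

#' Select the cleanest contiguous block of frames
#'
#' Finds the start of the contiguous window of `block_length` frames with
#' the fewest flagged frames (earliest start on ties). The subject is
#' excluded when the chosen window still contains strictly more than
#' `floor(max_bad_frac * block_length)` flagged frames (e.g. more than 160
#' of 1600 at the default 10%).
#'
#' @param flags Logical T-vector from [flag_outliers()].
#' @param block_length Window length in frames (<= T).
#' @param max_bad_frac Exclusion threshold as a fraction (default 0.10).
#' @return A `censor_result`: `outlier_flags`, `block_start` (1-based),
#'   `block_length`, `n_outliers` (within the chosen window), `excluded`.
#' @export
select_block <- function(flags, block_length, max_bad_frac = 0.10) {
  T_len <- length(flags)
  if (block_length > T_len) stop("block_length exceeds run length")
  stopifnot(block_length >= 1)
  cs <- cumsum(c(0L, as.integer(flags)))
  counts <- cs[(block_length + 1):(T_len + 1)] - cs[1:(T_len - block_length + 1)]
  start <- which.min(counts) # earliest minimum
  n_out <- counts[start]
  structure(
    list(outlier_flags = flags, block_start = start,
         block_length = block_length, n_outliers = n_out,
         excluded = n_out > floor(max_bad_frac * block_length)),
    class = "censor_result")
}

#' Censor one BOLD run: DVARS, flags, block selection
#'
#' Convenience wrapper chaining [compute_dvars()], [flag_outliers()] and
#' [select_block()].
#'
#' @inheritParams compute_dvars
#' @inheritParams select_block
#' @return A `censor_result` additionally carrying `dvars`.
#' @export
censor_run <- function(run, block_length, max_bad_frac = 0.10,
                       exclusion_mask = NULL) {
  dv <- compute_dvars(run, exclusion_mask)
  res <- select_block(flag_outliers(dv), block_length, max_bad_frac)
  res$dvars <- dv
  res
}

#' Frames retained by a censor result
#'
#' @param censor A `censor_result`.
#' @return Integer vector of 1-based frame indices of the chosen block.
#' @export
retained_frames <- function(censor) {
  seq(censor$block_start, length.out = censor$block_length)
}

run_data <- function(run) {
  y <- if (inherits(run, "bold_run")) run$data else run
  y <- as.matrix(y)
  if (any(!is.finite(y))) stop("BOLD data contain non-finite values")
  y
}
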
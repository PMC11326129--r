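#' t-statistic maps from a subject posterior
#'
#' `t(v,q) = posterior mean / posterior SD`, the vertex-wise evidence that
#' the subject engages network q at vertex v.
#'
#' @param posterior A `subject_posterior`, or a list with `mean` and `sd`
#'   matrices.
#' @return V x Q matrix (`NA` at excluded vertices).
#' @export
t_map <- function(posterior) {
  m <- posterior$mean; s <- posterior$sd
  bad <- !is.na(s) & s <= 0
  if (any(bad)) stop("posterior SD is zero at an included vertex")
  m / s
}

#' Engagement masks by one-sided t-test with Bonferroni correction
#'
#' Tests engagement > 0 at every included vertex of every map, at per-test
#' level `alpha / V_included` (Bonferroni over vertices, separately per
#' IC; set `correction = "vertices_by_ics"` for the stricter joint
#' correction over `V * Q` tests). A normal approximation is available via
#' `df = Inf`. Two-sided testing (`alternative = "two.sided"`) masks on
#' `|t|` at the halved level.
#'
#' @param t_maps V x Q t-statistic matrix (`NA` treated as excluded).
#' @param df Degrees of freedom (>= 1, or `Inf` for the normal
#'   approximation). The pipeline default is retained frames minus Q.
#' @param alpha Family-wise significance level (default 0.05).
#' @param correction `"vertices"` (default) or `"vertices_by_ics"`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param include_mask Optional V-length logical of vertices in the family
#'   (defaults to vertices with finite t in each column).
#' @return An `engagement_result`: `t_maps`, `df`, `alpha`, `level`
#'   (per-test), `critical` (t threshold), `masks` (V x Q logical, FALSE
#'   at excluded vertices).
#' @export
engagement_mask <- function(t_maps, df, alpha = 0.05,
                            correction = c("vertices", "vertices_by_ics"),
                            alternative = c("greater", "two.sided"),
                            include_mask = NULL) {
  correction <- match.arg(correction)
  alternative <- match.arg(alternative)
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  t_maps <- as.matrix(t_maps)
  Q <- ncol(t_maps)
  inc <- if (is.null(include_mask)) rowSums(is.na(t_maps)) == 0 else include_mask
  V_inc <- sum(inc)
  stopifnot(V_inc >= 1)
  level <- alpha / V_inc
  if (correction == "vertices_by_ics") level <- level / Q
  crit <- if (alternative == "greater") stats::qt(1 - level, df)
          else stats::qt(1 - level / 2, df)
  stat <- if (alternative == "greater") t_maps else abs(t_maps)
  masks <- !is.na(stat) & stat > crit & inc
  structure(list(t_maps = t_maps, df = df, alpha = alpha, level = level,
                 critical = crit, masks = masks,
                 alternative = alternative, correction = correction),
            class = "engagement_result")
}

#' Winner-takes-all parcellation of t-maps
#'
#' Assigns each included vertex the label of the signal IC with the
#' highest t-score there, provided that maximum is positive; other
#' vertices (excluded, non-positive maximum, or any NA among signal ICs)
#' get label 0 (unassigned). Ties go to the lowest IC index. Nuisance ICs
#' (not listed in `signal_ics`) can never win a vertex.
#'
#' @param t_maps V x Q t-statistic matrix.
#' @param include_mask Optional V-length logical of vertices eligible for
#'   labelling (e.g. an SNR mask); default all.
#' @param signal_ics Integer indices of the signal ICs (default all
#'   columns). Labels refer to these original column indices.
#' @return Integer V-vector of labels in {0, ..., Q}.
#' @export
wta_parcellation <- function(t_maps, include_mask = NULL, signal_ics = NULL) {
  t_maps <- as.matrix(t_maps)
  V <- nrow(t_maps)
  if (is.null(signal_ics)) signal_ics <- seq_len(ncol(t_maps))
  stopifnot(length(signal_ics) >= 1)
  ts <- t_maps[, signal_ics, drop = FALSE]
  inc <- if (is.null(include_mask)) rep(TRUE, V) else include_mask
  inc <- inc & rowSums(is.na(ts)) == 0
  labels <- integer(V)
  if (any(inc)) {
    sub <- ts[inc, , drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    pos <- sub[cbind(seq_len(nrow(sub)), best)] > 0
    lab <- ifelse(pos, signal_ics[best], 0L)
    labels[inc] <- lab
  }
  labels
}

#' Cohort frequency map of a set of parcellations
#'
#' Per vertex, the dominant (modal) label across subjects — label 0 is
#' ignored unless every subject is unassigned there — and the fraction of
#' subjects carrying that label.
#'
#' @param parcellations List (>= 2 subjects) of equal-length integer label
#'   vectors, or a subjects x V matrix.
#' @return List with `frequency` (V-vector in \[0, 1\]) and `modal_label`
#'   (integer V-vector; modal ties go to the lowest label).
#' @export
frequency_map <- function(parcellations) {
  P <- if (is.matrix(parcellations)) parcellations
       else do.call(rbind, parcellations)
  if (is.list(parcellations) &&
      length(unique(vapply(parcellations, length, integer(1)))) != 1)
    stop("parcellations differ in length")
  N <- nrow(P)
  stopifnot(N >= 2)
  labs <- 0:max(P)
  counts <- vapply(labs, function(l) colSums(P == l),
                   numeric(ncol(P)))             # V x (L+1)
  counts <- matrix(counts, ncol = length(labs))
  nonzero_any <- if (length(labs) > 1)
    rowSums(counts[, -1, drop = FALSE]) > 0 else rep(FALSE, ncol(P))
  scored <- counts
  scored[nonzero_any, 1] <- -1                   # ignore 0 unless all zero
  modal_idx <- max.col(scored, ties.method = "first")
  modal <- labs[modal_idx]
  freq <- counts[cbind(seq_len(ncol(P)), modal_idx)] / N
  list(frequency = freq, modal_label = modal)
}
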
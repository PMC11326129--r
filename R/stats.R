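#' Vertex-area-weighted connectivity strength
#'
#' Mean t-score within an engagement mask, weighted by midthickness vertex
#' area so large- and small-area vertices contribute proportionally:
#' `sum(area * t) / sum(area)` over mask vertices.
#'
#' @param t_map_q Numeric V-vector (one IC's t-map).
#' @param mask_q Logical V-vector (that IC's engagement mask).
#' @param vertex_areas Positive V-vector of vertex areas.
#' @return Scalar strength, or `NA` with a warning when the mask is empty
#'   (the subject x IC pair is then dropped from trend tests).
#' @export
connectivity_strength <- function(t_map_q, mask_q, vertex_areas) {
  stopifnot(length(t_map_q) == length(mask_q),
            length(vertex_areas) == length(t_map_q))
  if (!any(mask_q)) {
    warning("empty engagement mask; strength undefined")
    return(NA_real_)
  }
  w <- vertex_areas[mask_q]
  sum(w * t_map_q[mask_q]) / sum(w)
}

#' Partial Spearman correlation with AS 89 p-values
#'
#' Residualizes both variables on an intercept plus the covariates by
#' least squares, then computes Spearman's rank correlation between the
#' residuals. Two-sided p-values come from the null distribution of
#' Spearman's statistic as evaluated by the AS 89 algorithm in R's
#' `stats::cor.test` (exact for small tie-free samples, Edgeworth series
#' otherwise); with ties in the residual ranks the t-approximation is
#' used instead (AS 89 assumes no ties) and midranks are applied.
#'
#' @param x,y Numeric vectors of equal length N >= 5.
#' @param covariates Optional N x k numeric matrix (NULL or zero columns
#'   reduces to a plain Spearman correlation of `x` and `y`).
#' @return List with `rho`, `p_value`, `n`, and `p_method`
#'   (`"AS89"`/`"t-approximation"`).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 5)
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    stopifnot(nrow(Z) == n)
  } else Z <- matrix(numeric(0), n, 0)
  X <- cbind(1, Z)
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient (with intercept)")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  near_const <- function(r, raw)
    diff(range(r)) <= 1e-10 * max(1, diff(range(raw)))
  if (near_const(rx, x) || near_const(ry, y))
    stop("constant residual vector; rho undefined")
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  ct <- suppressWarnings(
    stats::cor.test(rx, ry, method = "spearman", exact = !ties))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       p_method = if (ties) "t-approximation" else "AS89")
}

#' Per-network age-trend test across a cohort
#'
#' Applies [partial_spearman()] of connectivity strength against age at
#' scan, controlling for the covariate columns, separately for each
#' signal IC. No correction across ICs is applied (each network is
#' reported at its own level; significance convention p < 0.05).
#'
#' @param table Data frame with columns `subject_id`, `ic`, `strength`,
#'   `age` and the covariate columns; one row per subject x signal IC.
#'   Rows with missing strength are dropped per IC.
#' @param covariate_cols Character vector of covariate column names
#'   (default `c("sex", "motion")`).
#' @param min_n Minimum subjects per IC to evaluate the test (default 5).
#' @return A tibble with one row per IC: `ic`, `n`, `rho`, `p`,
#'   `evaluable`.
#' @export
run_age_trend <- function(table, covariate_cols = c("sex", "motion"),
                          min_n = 5) {
  stopifnot(all(c("ic", "strength", "age") %in% names(table)),
            all(covariate_cols %in% names(table)))
  ics <- sort(unique(table$ic))
  rows <- lapply(ics, function(q) {
    d <- table[table$ic == q & !is.na(table$strength), , drop = FALSE]
    if (nrow(d) < min_n)
      return(tibble::tibble(ic = q, n = nrow(d), rho = NA_real_,
                            p = NA_real_, evaluable = FALSE))
    Z <- if (length(covariate_cols))
      as.matrix(d[, covariate_cols, drop = FALSE]) else NULL
    # drop constant covariates (e.g. all-zero motion in clean cohorts)
    if (!is.null(Z)) {
      keep <- apply(Z, 2, function(z) stats::sd(z) > 0)
      Z <- if (any(keep)) Z[, keep, drop = FALSE] else NULL
    }
    ps <- partial_spearman(d$strength, d$age, Z)
    tibble::tibble(ic = q, n = ps$n, rho = ps$rho, p = ps$p_value,
                   evaluable = TRUE)
  })
  do.call(rbind, rows)
}

#' Strength table from posteriors and engagement masks
#'
#' Builds the tidy (subject x IC) connectivity-strength table consumed by
#' [run_age_trend()].
#'
#' @param posteriors Named list of `subject_posterior`s.
#' @param engagements List of `engagement_result`s (same order).
#' @param mesh The `surf_mesh` supplying vertex areas.
#' @param covariates Data frame with `subject_id`, `age`, `sex`, `motion`.
#' @param signal_ics Integer indices of signal ICs (default all).
#' @return Tibble with columns `subject_id`, `ic`, `strength`, `age`,
#'   `sex`, `motion`.
#' @export
strength_table <- function(posteriors, engagements, mesh, covariates,
                           signal_ics = NULL) {
  va <- mesh$vertex_areas
  rows <- list()
  for (i in seq_along(posteriors)) {
    tm <- t_map(posteriors[[i]])
    masks <- engagements[[i]]$masks
    qs <- if (is.null(signal_ics)) seq_len(ncol(tm)) else signal_ics
    cv <- covariates[i, ]
    for (q in qs) {
      s <- withCallingHandlers(
        connectivity_strength(tm[, q], masks[, q], va),
        warning = function(w) invokeRestart("muffleWarning"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = cv$subject_id, ic = q, strength = s,
        age = cv$age, sex = cv$sex, motion = cv$motion)
    }
  }
  do.call(rbind, rows)
}
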
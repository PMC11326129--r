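#' Ground-truth group-level network maps
#'
#' Q smooth, localized spatial maps on a mesh: Gaussian bumps of the
#' vertex-to-centre distance, with centres chosen by farthest-point sampling
#' among included vertices so the peaks are disjoint. This mimics the
#' localized topography of resting-state networks and keeps the toy
#' decomposition identifiable.
#'
#' @param mesh A `surf_mesh`.
#' @param n_ics Number of networks Q.
#' @param width_factor Bump standard deviation as a fraction of the minimum
#'   inter-centre distance. Default 0.4.
#' @param seed Integer seed (first centre is drawn at random).
#' @return V x Q matrix of group maps, peak value 1.
#' @export
make_group_maps <- function(mesh, n_ics, width_factor = 0.4, seed = 1) {
  stopifnot(n_ics >= 1)
  inc <- which(!mesh$exclusion_mask)
  xyz <- mesh$coordinates
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  centres <- integer(n_ics)
  centres[1] <- sample(inc, 1)
  if (n_ics > 1) {
    d2min <- colSums((t(xyz) - xyz[centres[1], ])^2)
    for (q in 2:n_ics) {
      cand <- inc[which.max(d2min[inc])]
      centres[q] <- cand
      d2min <- pmin(d2min, colSums((t(xyz) - xyz[cand, ])^2))
    }
  }
  .Random.seed_restore(old)
  dmat <- sapply(centres, function(cv) sqrt(colSums((t(xyz) - xyz[cv, ])^2)))
  if (n_ics > 1) {
    cd <- as.matrix(stats::dist(xyz[centres, , drop = FALSE]))
    min_sep <- min(cd[upper.tri(cd)])
  } else {
    min_sep <- 2 * max(dmat) / 3
  }
  sigma_b <- width_factor * min_sep
  G <- exp(-dmat^2 / (2 * sigma_b^2))
  attr(G, "centres") <- centres
  G
}

#' Synthetic surface cohort from the generative network model
#'
#' Runs the hierarchical model forward. Each subject's spatial maps are
#' `s_i(v) = g_q(v) + delta_i(v)` where `g_q` are the group maps and
#' `delta_i(v,q) ~ N(0, deviation_var(v,q))` are vertex-wise Gaussian
#' subject deviations with network-specific variance. The network
#' amplitude `a_iq = 1 + beta * z(age_i)` (age z-scored within the
#' cohort, so `beta` is a unitless effect size) scales the engagement of
#' IC q in the data by multiplying its mixing timecourse: a stronger
#' network drives more BOLD variance relative to the fixed noise floor,
#' which is how a maturational connectivity increase manifests and what
#' the downstream t-statistics can detect (a scale placed on the spatial
#' map itself would simply be re-absorbed by the mixing matrix during
#' estimation). Data are `y_i = (A_i diag(a_i)) s_i' + e_i`,
#' `e ~ N(0, noise_sd^2)`, with smooth variance-normalized mixing
#' timecourses `A_i`. Frames listed in `spike_frames` receive a large
#' additive offset on all vertices, emulating transient head-motion
#' spikes.
#'
#' The between-subject variance is
#' `deviation_var(v,q) = deviation_sd^2 * scale_q^2 * (0.25 + g_q(v))`
#' with `scale_q` spread over `[0.75, 1.25]`, so variance is larger inside
#' a network's own territory and differs between networks.
#'
#' A transient offset at frame k corrupts the temporal derivative at both
#' k and k+1; `truth$dvars_affected_frames` records that set per subject,
#' which is the ground truth against which DVARS flagging is judged.
#'
#' @param mesh A `surf_mesh`.
#' @param n_subjects Number of subjects.
#' @param n_timepoints Frames per run (must exceed `n_ics`).
#' @param n_ics Number of networks Q (>= 1).
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param deviation_sd Baseline between-subject deviation SD.
#' @param age_effect_beta Age effect size on network amplitude.
#' @param spike_frames NULL, or a list (length `n_subjects`) of 1-based
#'   frame indices to corrupt.
#' @param seed Integer seed; identical inputs give bit-identical cohorts.
#' @param tr_seconds Repetition time (default 0.392 s, a fast multiband
#'   neonatal acquisition: 2300 frames in ~15 min).
#' @param baseline Constant added to every sample (0 keeps the pure linear
#'   model; a positive value, e.g. 1000, makes tSNR maps meaningful).
#' @param spike_magnitude Offset added to spiked frames; default
#'   `10 * noise_sd`, large enough that DVARS detection is guaranteed.
#' @param age_range Age-at-scan range in weeks postmenstrual age.
#' @return List with `runs` (list of `bold_run`: `data` T x V, `tr_seconds`,
#'   `subject_id`, `covariates`) and `truth` (class `ground_truth`).
#' @export
make_cohort <- function(mesh, n_subjects, n_timepoints, n_ics,
                        noise_sd = 1, deviation_sd = 0.3,
                        age_effect_beta = 0, spike_frames = NULL,
                        seed = 1, tr_seconds = 0.392, baseline = 0,
                        spike_magnitude = 10 * noise_sd,
                        age_range = c(37, 45)) {
  stopifnot(n_ics >= 1, n_timepoints > n_ics, noise_sd >= 0,
            n_subjects >= 1)
  V <- nrow(mesh$coordinates)
  if (!is.null(spike_frames)) {
    stopifnot(length(spike_frames) == n_subjects)
    for (sf in spike_frames) {
      if (length(sf) && (any(sf < 1) || any(sf > n_timepoints)))
        stop("spike frame index outside [1, n_timepoints]")
    }
  } else {
    spike_frames <- rep(list(integer(0)), n_subjects)
  }

  old <- .Random.seed_save()
  set.seed(as.integer(seed))

  G <- make_group_maps(mesh, n_ics, seed = seed)
  attr(G, "centres") <- NULL
  scale_q <- if (n_ics > 1) seq(0.75, 1.25, length.out = n_ics) else 1
  deviation_var <- sweep(0.25 + G, 2, (deviation_sd * scale_q)^2, "*")

  age <- stats::runif(n_subjects, age_range[1], age_range[2])
  sex <- stats::rbinom(n_subjects, 1, 0.5)
  z_age <- if (n_subjects > 1) as.numeric(scale(age)) else 0
  amplitudes <- matrix(1 + age_effect_beta * z_age, n_subjects, n_ics)

  runs <- vector("list", n_subjects)
  subject_maps <- vector("list", n_subjects)
  mixing <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    delta <- matrix(stats::rnorm(V * n_ics), V, n_ics) * sqrt(deviation_var)
    s_i <- G + delta
    A_i <- sweep(smooth_timecourses(n_timepoints, n_ics), 2,
                 amplitudes[i, ], "*")
    y <- A_i %*% t(s_i)
    if (noise_sd > 0)
      y <- y + matrix(stats::rnorm(n_timepoints * V, sd = noise_sd),
                      n_timepoints, V)
    y <- y + baseline
    if (length(spike_frames[[i]]))
      y[spike_frames[[i]], ] <- y[spike_frames[[i]], ] + spike_magnitude
    runs[[i]] <- structure(
      list(data = y, tr_seconds = tr_seconds,
           subject_id = sprintf("sub-%03d", i),
           covariates = list(age_pma_weeks = age[i], sex = sex[i],
                             motion = length(spike_frames[[i]]))),
      class = "bold_run")
    subject_maps[[i]] <- s_i
    mixing[[i]] <- A_i
  }

  affected <- lapply(spike_frames, function(sf) {
    if (!length(sf)) return(integer(0))
    sort(unique(c(sf[sf > 1], (sf + 1)[sf + 1 <= n_timepoints])))
  })

  .Random.seed_restore(old)
  truth <- structure(
    list(group_maps = G, subject_maps = subject_maps, mixing = mixing,
         deviation_var = deviation_var, amplitudes = amplitudes,
         age = age, sex = sex,
         motion = vapply(spike_frames, length, integer(1)),
         spike_frames = spike_frames, dvars_affected_frames = affected,
         spike_magnitude = spike_magnitude, noise_sd = noise_sd),
    class = "ground_truth")
  list(runs = runs, truth = truth, mesh = mesh)
}

# Smooth autocorrelated timecourses: white noise convolved with a Gaussian
# window, each column variance-normalized to SD 1.
smooth_timecourses <- function(n_timepoints, n_ics, smooth_sd = 3) {
  half <- ceiling(3 * smooth_sd)
  w <- stats::dnorm(-half:half, sd = smooth_sd)
  A <- matrix(0, n_timepoints, n_ics)
  for (q in seq_len(n_ics)) {
    x <- stats::rnorm(n_timepoints + 2 * half)
    xc <- stats::filter(x, w, sides = 2)
    xc <- xc[(half + 1):(half + n_timepoints)]
    A[, q] <- (xc - mean(xc)) / stats::sd(xc)
  }
  A
}

#' Random isolated spike frames
#'
#' Draws motion-spike frame indices with a minimum gap so individual spikes
#' produce separable DVARS excursions.
#'
#' @param n_timepoints Frames per run.
#' @param n_spikes Spikes to place.
#' @param min_gap Minimum index separation between spikes (default 3).
#' @return Sorted integer vector of 1-based frame indices (may be shorter
#'   than `n_spikes` if the run is too short to fit them all).
#' @export
random_spike_frames <- function(n_timepoints, n_spikes, min_gap = 3) {
  if (n_spikes <= 0) return(integer(0))
  # frame 1 avoided: a spike there corrupts only the derivative at frame 2
  cand <- sample(2:n_timepoints)
  chosen <- integer(0)
  for (k in cand) {
    if (!length(chosen) || min(abs(chosen - k)) >= min_gap) {
      chosen <- c(chosen, k)
      if (length(chosen) == n_spikes) break
    }
  }
  sort(chosen)
}

#' Template prior from generator ground truth
#'
#' Packs the true group maps and true between-subject variances into a
#' `template_prior`, for validation runs that isolate the posterior
#' machinery from template-estimation noise.
#'
#' @param cohort A cohort list from [make_cohort()].
#' @param variance_floor Floor for the between-subject variance
#'   (default `1e-6 * median`).
#' @return A `template_prior`.
#' @export
truth_prior <- function(cohort, variance_floor = NULL) {
  bv <- cohort$truth$deviation_var
  if (is.null(variance_floor)) variance_floor <- 1e-6 * stats::median(bv)
  new_template_prior(mean = cohort$truth$group_maps,
                     between_var = pmax(bv, variance_floor),
                     sigma_tot = bv, sigma_noise = bv * 0,
                     between_var_raw = bv,
                     n_template_subjects = 0L,
                     variance_floor = variance_floor)
}
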
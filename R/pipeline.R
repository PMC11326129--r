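#' Configuration for a synthetic end-to-end pipeline run
#'
#' Validates and assembles the parameters of a full synthetic analysis.
#' Reference acquisition/analysis defaults (20 ICs, 1600-frame block, 10%
#' exclusion, 3 mm FWHM, alpha 0.05) are always recorded in the run
#' manifest beside the values actually used, so any deviation from the
#' reference protocol is auditable.
#'
#' @param n_subdivisions Mesh subdivision level (V = 12, 42, 162, 642,
#'   2562, ...).
#' @param n_template_subjects,n_analysis_subjects Cohort split; the
#'   template and analysis sets are disjoint by construction (template
#'   subjects are excluded from all further analysis).
#' @param n_timepoints Frames per synthetic run.
#' @param n_ics Number of networks Q.
#' @param signal_ics Indices of signal ICs (default all — every synthetic
#'   network is a signal network).
#' @param noise_sd,deviation_sd,age_effect_beta Generator parameters, see
#'   [make_cohort()].
#' @param spikes_per_subject Expected motion spikes injected per run
#'   (Poisson; isolated frames).
#' @param block_frames Censoring block length (must be <= `n_timepoints`).
#' @param max_bad_frac Subject-exclusion threshold (default 0.10).
#' @param fwhm Surface smoothing FWHM in mesh units (0 disables).
#' @param mesh_radius Sphere radius of the synthetic atlas.
#' @param alpha Engagement significance level.
#' @param variance_floor Template variance floor; NULL (default) floors at
#'   `variance_floor_frac` of the median total variance.
#' @param variance_floor_frac Automatic floor fraction (default 0.05).
#'   With desk-scale template cohorts the raw between-subject variance is
#'   frequently negative at weakly engaged vertices; a floor at a few
#'   percent of the total variance keeps the prior honestly uncertain
#'   there, where a near-zero floor would pin every subject to the
#'   template with arbitrarily large t-statistics.
#' @param tol,max_iter EM convergence controls.
#' @param seed Integer seed governing every random draw of the run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_subdivisions = 3,
                            n_template_subjects = 12,
                            n_analysis_subjects = 40,
                            n_timepoints = 300,
                            n_ics = 8,
                            signal_ics = NULL,
                            noise_sd = 3,
                            deviation_sd = 0.3,
                            age_effect_beta = 0.5,
                            spikes_per_subject = 4,
                            block_frames = 200,
                            max_bad_frac = 0.10,
                            fwhm = 0,
                            mesh_radius = 50,
                            alpha = 0.05,
                            variance_floor = NULL,
                            variance_floor_frac = 0.05,
                            tol = 1e-4,
                            max_iter = 100,
                            seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$signal_ics)) cfg$signal_ics <- seq_len(n_ics)
  stopifnot(n_template_subjects >= 3, n_analysis_subjects >= 1,
            n_timepoints > n_ics, block_frames <= n_timepoints,
            block_frames >= 4, max_bad_frac >= 0, max_bad_frac < 1,
            alpha > 0, alpha < 1,
            all(cfg$signal_ics %in% seq_len(n_ics)))
  cfg$reference_defaults <- list(n_ics = 20, block_frames = 1600,
                                 max_bad_frac = 0.10, fwhm_mm = 3.0,
                                 alpha = 0.05)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Stage order: simulate cohort -> DVARS censoring and block selection ->
#' surface smoothing -> pseudo test-retest dual regression on the template
#' subjects -> empirical template estimation -> per-subject EM fit of the
#' hierarchical model -> t-maps and Bonferroni engagement masks ->
#' winner-takes-all parcellation and cohort frequency map -> vertex-area-
#' weighted connectivity strength and partial Spearman age trend. The
#' template and analysis subject sets are disjoint (validated before any
#' compute); every random draw is governed by `config$seed`, so reruns
#' are bit-identical.
#'
#' @param config A `pipeline_config`.
#' @param output_dir Optional directory; when given, each stage writes
#'   its artifact (censor report, template, label/frequency/age-trend
#'   tables and a JSON manifest).
#' @return A list with elements `mesh`, `cohort`, `censors`,
#'   `censor_report`, `excluded_subjects`, `template_ids`, `analysis_ids`,
#'   `prior`, `posteriors`, `engagements`, `t_maps`, `parcellations`,
#'   `frequency`, `strengths`, `age_trend`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(config$seed))

  n_total <- config$n_template_subjects + config$n_analysis_subjects
  template_ids <- seq_len(config$n_template_subjects)
  analysis_ids <- setdiff(seq_len(n_total), template_ids)
  if (length(intersect(template_ids, analysis_ids)))
    stop("template and analysis subject sets overlap")

  mesh <- make_mesh(config$n_subdivisions, seed = config$seed,
                    radius = config$mesh_radius)
  spikes <- lapply(seq_len(n_total), function(i)
    random_spike_frames(config$n_timepoints,
                        stats::rpois(1, config$spikes_per_subject)))
  cohort <- make_cohort(
    mesh, n_total, config$n_timepoints, config$n_ics,
    noise_sd = config$noise_sd, deviation_sd = config$deviation_sd,
    age_effect_beta = config$age_effect_beta, spike_frames = spikes,
    seed = config$seed + 1L)

  # --- censoring -----------------------------------------------------
  censors <- lapply(cohort$runs, censor_run,
                    block_length = config$block_frames,
                    max_bad_frac = config$max_bad_frac,
                    exclusion_mask = mesh$exclusion_mask)
  names(censors) <- vapply(cohort$runs, function(r) r$subject_id, "")
  censor_report <- write_censor_report(
    censors, if (!is.null(output_dir)) file.path(output_dir, "censor_report.tsv"))
  excluded_subjects <- which(censor_report$excluded)
  keep <- function(ids) setdiff(ids, excluded_subjects)

  blocks <- lapply(seq_len(n_total), function(i) {
    fr <- retained_frames(censors[[i]])
    cohort$runs[[i]]$data[fr, , drop = FALSE]
  })
  motion <- vapply(seq_len(n_total), function(i)
    sum(censors[[i]]$outlier_flags[retained_frames(censors[[i]])]),
    numeric(1))

  # --- smoothing -----------------------------------------------------
  if (config$fwhm > 0)
    blocks <- lapply(blocks, smooth_surface, mesh = mesh, fwhm = config$fwhm)

  # --- template ------------------------------------------------------
  t_ids <- keep(template_ids)
  if (length(t_ids) < 3) stop("fewer than 3 template subjects survive censoring")
  inc <- !mesh$exclusion_mask
  G_inc <- cohort$truth$group_maps[inc, , drop = FALSE]
  pseudo <- lapply(blocks[t_ids], function(y)
    lapply(split_pseudo_sessions(y[, inc, drop = FALSE]),
           function(h) dual_regression(h, G_inc)$subject_maps))
  prior_inc <- estimate_template(pseudo, variance_floor = config$variance_floor)
  if (is.null(config$variance_floor)) {
    fl <- config$variance_floor_frac * stats::median(prior_inc$sigma_tot)
    prior_inc$between_var <- pmax(prior_inc$between_var_raw, fl)
    prior_inc$variance_floor <- fl
  }
  prior <- prior_inc
  for (f in c("mean", "between_var", "sigma_tot", "sigma_noise", "between_var_raw")) {
    full <- matrix(NA_real_, nrow(mesh$coordinates), config$n_ics)
    full[inc, ] <- prior_inc[[f]]
    prior[[f]] <- full
  }

  # --- per-subject fits (excluded vertices skipped entirely) ----------
  a_ids <- keep(analysis_ids)
  warnings_log <- character(0)
  V_full <- nrow(mesh$coordinates)
  posteriors <- lapply(a_ids, function(i) {
    red <- reduce_dimension(blocks[[i]][, inc, drop = FALSE], config$n_ics)
    p <- withCallingHandlers(
      em_fit(red, prior_inc, tol = config$tol, max_iter = config$max_iter),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("subject %d: %s", i, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    for (f in c("mean", "sd", "prior_mean")) {
      full <- matrix(NA_real_, V_full, config$n_ics)
      full[inc, ] <- p[[f]]
      p[[f]] <- full
    }
    p$include_mask <- inc
    p
  })
  names(posteriors) <- names(censors)[a_ids]

  # --- subject maps ---------------------------------------------------
  df <- config$block_frames - config$n_ics
  t_maps <- lapply(posteriors, t_map)
  engagements <- lapply(t_maps, engagement_mask, df = df,
                        alpha = config$alpha, include_mask = inc)
  parcellations <- lapply(t_maps, wta_parcellation, include_mask = inc,
                          signal_ics = config$signal_ics)
  freq <- frequency_map(parcellations)

  # --- cohort statistics ----------------------------------------------
  covs <- tibble::tibble(
    subject_id = names(censors)[a_ids],
    age = cohort$truth$age[a_ids],
    sex = cohort$truth$sex[a_ids],
    motion = motion[a_ids])
  strengths <- strength_table(posteriors, engagements, mesh, covs,
                              signal_ics = config$signal_ics)
  trend <- run_age_trend(strengths)

  manifest <- list(
    package_version = as.character(utils::packageVersion("surftica")),
    r_version = R.version.string,
    parameters = config[!(names(config) %in% "reference_defaults")],
    reference_defaults = config$reference_defaults,
    n_vertices = nrow(mesh$coordinates),
    n_included_vertices = sum(inc),
    template_subjects = t_ids, analysis_subjects = a_ids,
    excluded_subjects = excluded_subjects,
    em_converged = vapply(posteriors, function(p) p$converged, logical(1)),
    warnings = warnings_log)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_mesh_text(mesh, file.path(output_dir, "mesh"))
    write_template(prior_inc, file.path(output_dir, "template"))
    utils::write.table(
      data.frame(subject_id = rep(names(posteriors),
                                  each = nrow(mesh$coordinates)),
                 vertex = rep(seq_len(nrow(mesh$coordinates)),
                              length(posteriors)),
                 label = unlist(parcellations)),
      file.path(output_dir, "parcellations.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(vertex = seq_along(freq$frequency),
                 modal_label = freq$modal_label,
                 frequency = freq$frequency),
      file.path(output_dir, "frequency_map.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(strengths, file.path(output_dir, "strengths.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(trend, file.path(output_dir, "age_trend.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(mesh = mesh, cohort = cohort, censors = censors,
       censor_report = censor_report, excluded_subjects = excluded_subjects,
       template_ids = t_ids, analysis_ids = a_ids, prior = prior,
       posteriors = posteriors, engagements = engagements,
       t_maps = t_maps, parcellations = parcellations, frequency = freq,
       strengths = strengths, age_trend = trend, manifest = manifest)
}
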
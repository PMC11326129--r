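# Shared study configuration for the numbered analysis scripts.
#
# One synthetic cohort stands in for the neonatal sample: 35 template
# subjects (the reference template-cohort size) plus 40 analysis
# subjects on a 642-vertex spherical atlas, 300 frames per run, eight
# networks, moderate noise, a monotone age effect on network engagement,
# and sporadic injected motion spikes. Every script regenerates the
# cohort deterministically from STUDY_SEED through the package, so the
# stages can be run independently and in any order.

library(surftica)

STUDY_SEED <- 20240901

study_config <- function(seed = STUDY_SEED) {
  pipeline_config(
    n_subdivisions = 3,          # 642 vertices
    n_template_subjects = 35,
    n_analysis_subjects = 40,
    n_timepoints = 300,
    n_ics = 8,
    noise_sd = 3,
    deviation_sd = 0.3,
    age_effect_beta = 0.5,
    spikes_per_subject = 4,
    block_frames = 200,
    seed = seed)
}

results_dir <- function() {
  d <- file.path("results", "analysis")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(df, name) {
  path <- file.path(results_dir(), name)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
}
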
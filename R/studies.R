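# Canonical scaled-down simulation studies.
#
# These configurations define the package's reference experiments on the
# default synthetic head: a sparse single-axis on-scalp array (55 mm packing,
# 6.5 mm offset), 20 sources per surface and 50 trials per source, sized to
# run on a single CPU in minutes while preserving the qualitative structure
# of full-scale laminar sweeps.

#' Reference study: laminar recovery across single-trial SNR
#'
#' MSP source reconstruction with the ROI analysis over single-trial SNRs of
#' -40 to -5 dB. Classification accuracy should rise from chance to ceiling
#' with SNR, with no pial/white bias at high SNR.
#'
#' @param seed master seed.
#' @return a `sweep_config`.
#' @export
study_snr_recovery <- function(seed = 1) {
  sweep_config(snr_db = c(-40, -30, -20, -10, -5), methods = "MSP",
               analyses = "roi", n_sources = 20, n_trials = 50,
               n_patch_centres = 64, min_distance_mm = 55, seed = seed)
}

#' Reference study: unstructured priors cannot separate laminae
#'
#' Minimum-norm-like (IID) and smoothness (COH) priors at high SNR with the
#' ROI analysis: both lack the sparse laminar structure of the simulated
#' sources and stay near chance accuracy, replicating the known negative
#' result for MNE/LORETA-style laminar inference.
#'
#' @param seed master seed.
#' @return a `sweep_config`.
#' @export
study_prior_mismatch <- function(seed = 1) {
  sweep_config(snr_db = -5, methods = c("IID", "COH"), analyses = "roi",
               n_sources = 20, n_trials = 50, min_distance_mm = 55,
               seed = seed)
}
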
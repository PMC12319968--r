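# Laminar decision procedures: whole-brain free-energy model comparison and
# the ROI-based paired t-statistic.

#' Evidence ratio implied by a log model-evidence difference
#'
#' A free-energy difference of 3 nats corresponds to one model being
#' `exp(3) ~ 20` times more likely than the other.
#'
#' @param delta_f free-energy difference (nats).
#' @export
evidence_ratio <- function(delta_f) exp(delta_f)

#' Two-tailed critical t value
#' @param df degrees of freedom (e.g. 199 for 200 trials).
#' @param alpha significance level (default 0.05).
#' @export
critical_t <- function(df, alpha = 0.05) stats::qt(1 - alpha / 2, df)

#' Bundle the reconstruction model for laminar inference
#'
#' Precomputes, for one source space + sensor array + conductor, the three
#' source models (pial-only, white-only, combined) and their lead fields, so
#' that many simulated sources can be analysed without re-assembly.
#'
#' @param space the reconstruction `source_space`.
#' @param array the (possibly co-registration-perturbed) `sensor_array`.
#' @param conductor a `head_conductor`.
#' @return object of class `laminar_setup` with `models` and `leadfields`
#'   (each a list with entries `pial`, `white`, `combined`), plus the inputs.
#' @export
laminar_setup <- function(space, array, conductor) {
  models <- list(pial = source_model(space, "pial"),
                 white = source_model(space, "white"),
                 combined = source_model(space, c("pial", "white")))
  leadfields <- lapply(models, assemble_leadfield, array = array,
                       conductor = conductor)
  structure(list(models = models, leadfields = leadfields, space = space,
                 array = array, conductor = conductor),
            class = "laminar_setup")
}

new_decision <- function(analysis, metric, threshold, truth, method,
                         converged = TRUE, extra = list()) {
  structure(c(list(
    analysis = analysis, metric = metric,
    inferred_surface = if (metric > 0) "pial" else "white",
    significant = abs(metric) > threshold, threshold = threshold,
    ground_truth = truth, method = method, converged = converged), extra),
    class = "laminar_decision")
}

#' @export
print.laminar_decision <- function(x, ...) {
  cat(sprintf("laminar_decision [%s/%s]: metric = %.3f -> %s%s (truth: %s)\n",
              x$analysis, x$method, x$metric, x$inferred_surface,
              if (x$significant) "*" else "", x$ground_truth))
  invisible(x)
}

#' Whole-brain laminar inference by free-energy model comparison
#'
#' Inverts the data separately onto the pial-only and white-only source
#' models (Hann taper + band-pass) and compares the variational free
#' energies: `dF = F_pial - F_white` is positive when the superficial model
#' is more likely; `|dF| > 3` (evidence ratio ~20) marks a significant
#' single-simulation decision.
#'
#' @param dataset a `trial_dataset`.
#' @param setup a `laminar_setup`.
#' @param method source reconstruction approach (`"EBB"`, `"MSP"`, `"IID"`,
#'   `"COH"`).
#' @param include_vertices per-surface vertex indices (on the single-surface
#'   meshes) whose patches must be in the MSP library, or NULL.
#' @param band,hann,n_temporal_modes passed to [preprocess()].
#' @param ... further arguments to [reml_invert()].
#' @return a `laminar_decision` with `metric = dF` (nats) and the two
#'   inversion free energies in `F_pial`/`F_white`.
#' @export
whole_brain_decision <- function(dataset, setup, method = "MSP",
                                 include_vertices = NULL, band = c(10, 30),
                                 hann = TRUE, n_temporal_modes = 4, ...) {
  invs <- lapply(c("pial", "white"), function(surf) {
    red <- preprocess(dataset, setup$leadfields[[surf]], band = band,
                      hann = hann, n_temporal_modes = n_temporal_modes)
    reml_invert(red, setup$models[[surf]], method = method,
                include_vertices = include_vertices,
                compute_posterior = FALSE, ...)
  })
  dF <- invs[[1]]$F - invs[[2]]$F
  new_decision("whole_brain", dF, threshold = 3,
               truth = dataset$ground_truth$surface, method = method,
               converged = invs[[1]]$converged && invs[[2]]$converged,
               extra = list(F_pial = invs[[1]]$F, F_white = invs[[2]]$F))
}

#' ROI-based laminar inference by regularised paired t-statistic
#'
#' Inverts once on the combined pial + white source model (no Hann taper),
#' computes per-vertex, per-trial band power in the active and baseline
#' windows from the posterior source time courses, defines a functional ROI
#' (vertices with a baseline-to-active paired t at or above the 75th
#' percentile within their surface, united with their correspondence
#' partners on the other surface), and compares per-trial ROI values (mean
#' absolute power change within the ROI) between surfaces with a paired t
#' test with a variance floor. Positive t favours the pial surface;
#' significance at the two-tailed critical t with `n_trials - 1` df.
#'
#' @param dataset a `trial_dataset`.
#' @param setup a `laminar_setup`.
#' @param method source reconstruction approach.
#' @param include_vertices global indices into the combined model for MSP.
#' @param active_ms,baseline_ms analysis windows (ms); defaults
#'   `c(100, 500)` and `c(-500, 100)`.
#' @param band power band in Hz (default `c(10, 30)`).
#' @param roi_quantile within-surface t-statistic quantile for ROI inclusion
#'   (default 0.75, signed t).
#' @param variance_floor_rel relative variance floor `s0^2` of the final
#'   paired t (default 1e-6 x mean squared ROI value).
#' @param ... further arguments to [reml_invert()].
#' @return a `laminar_decision` with `metric = t`, ROI size and the
#'   per-trial ROI values attached.
#' @export
roi_decision <- function(dataset, setup, method = "MSP",
                         include_vertices = NULL,
                         active_ms = c(100, 500), baseline_ms = c(-500, 100),
                         band = c(10, 30), roi_quantile = 0.75,
                         variance_floor_rel = 1e-6, ...) {
  model <- setup$models$combined
  red <- preprocess(dataset, setup$leadfields$combined, band = band,
                    hann = FALSE)
  inv <- reml_invert(red, model, method = method,
                     include_vertices = include_vertices, ...)
  ntr <- red$n_trials
  nsrc <- nrow(inv$M)
  tm <- red$time_ms
  act <- which(tm >= active_ms[1] & tm < active_ms[2])
  base <- which(tm >= baseline_ms[1] & tm < baseline_ms[2])
  win_power <- function(Xtr, idx) {
    W <- Xtr[, idx, drop = FALSE]
    W <- W - rowMeans(W)
    Sw <- tcrossprod(W) / (length(idx) - 1)
    rowSums((inv$M %*% Sw) * inv$M)
  }
  Pa <- matrix(0, nsrc, ntr)
  Pb <- matrix(0, nsrc, ntr)
  for (tr in seq_len(ntr)) {
    Xtr <- red$Xs[, , tr]
    Pa[, tr] <- win_power(Xtr, act)
    Pb[, tr] <- win_power(Xtr, base)
  }
  D <- Pa - Pb
  mu <- rowMeans(D)
  sdv <- apply(D, 1, stats::sd)
  tvert <- ifelse(sdv > 0, mu / (sdv / sqrt(ntr)), 0)
  nv <- nrow(model$meshes[[1]]$vertices)
  surf1 <- seq_len(nv)            # first listed surface (pial)
  surf2 <- nv + seq_len(nv)
  roi1 <- surf1[tvert[surf1] >= stats::quantile(tvert[surf1], roi_quantile, type = 7)]
  roi2 <- surf2[tvert[surf2] >= stats::quantile(tvert[surf2], roi_quantile, type = 7)]
  roi_local <- sort(unique(c(roi1, roi2 - nv)))  # correspondence union
  v1 <- colMeans(abs(D[roi_local, , drop = FALSE]))
  v2 <- colMeans(abs(D[roi_local + nv, , drop = FALSE]))
  dd <- v1 - v2
  if (all(dd == 0)) {
    tstat <- 0
  } else {
    s0sq <- variance_floor_rel * mean(c(v1, v2)^2)
    tstat <- mean(dd) / sqrt((stats::var(dd) + s0sq) / ntr)
  }
  labels <- names(setup$models$combined$meshes)
  # metric sign: positive = pial; flip if the first stacked surface is white
  if (labels[1] != "pial") tstat <- -tstat
  new_decision("roi", tstat, threshold = critical_t(ntr - 1),
               truth = dataset$ground_truth$surface, method = method,
               converged = inv$converged,
               extra = list(df = ntr - 1, roi_size = length(roi_local) * 2L,
                            n_vertices_per_surface = nv,
                            roi_vertices = roi_local))
}
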
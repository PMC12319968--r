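# Sweep orchestration and summary statistics: laminar inference repeated
# over randomly sampled sources on each surface across array designs, SNR
# levels, co-registration errors, patch-size pairs, interfering sources and
# generative-model variants, with exact binomial / exact McNemar tests and
# logistic regressions over condition levels.

#' Sweep configuration
#'
#' Defines the factorial design of a simulation sweep. Each supplied level
#' vector is crossed with all others; each cell is simulated for `n_sources`
#' randomly chosen vertices on each of the two surfaces.
#'
#' @param snr_db single-trial SNR levels in dB (per-trial noise mode), or
#'   noise magnitudes in dB (fixed mode); default -5.
#' @param noise_mode `"per_trial_snr"` (default) or `"fixed_magnitude"`.
#' @param reference_amplitude reference amplitude for fixed-magnitude noise.
#' @param min_distance_mm inter-sensor packing distances (mm); default 55.
#' @param n_axes numbers of measurement axes; default 1.
#' @param offset_mm scalp-sensor offsets (mm); default 6.5.
#' @param fiducial_sd_mm fiducial displacement SDs (mm); default 0.
#' @param patch_fwhm_pairs list of `c(simulated, reconstructed)` patch FWHMs
#'   (mm); default `list(c(5, 5))`.
#' @param brain_noise NULL, or `list(n_sources =, relative_strength =)`.
#' @param generative_model `"GM"` (same forward model for simulation and
#'   reconstruction) or `"AGM"` (perturbed simulation-side geometry).
#' @param methods subset of `"EBB"`, `"MSP"`, `"IID"`, `"COH"`.
#' @param analyses subset of `"whole_brain"`, `"roi"`.
#' @param n_sources sources per surface per cell (default 60).
#' @param n_trials trials per simulated source (default 200).
#' @param amplitude_nAm,freq_hz,active_ms source waveform parameters.
#' @param geometry list of [make_head_geometry()] arguments.
#' @param n_patch_centres MSP library size per surface (default 128).
#' @param include_true_vertices logical; add the true source location (and
#'   its correspondence partner) to the MSP library. Default TRUE; forced
#'   FALSE for AGM runs, whose simulation vertices do not exist in the
#'   reconstruction model.
#' @param seed master seed; all cell and source seeds derive from it.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(snr_db = -5, noise_mode = "per_trial_snr",
                         reference_amplitude = 0.01,
                         min_distance_mm = 55, n_axes = 1, offset_mm = 6.5,
                         fiducial_sd_mm = 0, patch_fwhm_pairs = list(c(5, 5)),
                         brain_noise = NULL, generative_model = "GM",
                         methods = "MSP", analyses = c("whole_brain", "roi"),
                         n_sources = 60, n_trials = 200, amplitude_nAm = 10,
                         freq_hz = 20, active_ms = c(100, 500),
                         geometry = list(), n_patch_centres = 128,
                         include_true_vertices = TRUE, seed = 1) {
  stopifnot(length(snr_db) >= 1, n_sources >= 1,
            generative_model %in% c("GM", "AGM"),
            all(methods %in% c("EBB", "MSP", "IID", "COH")),
            all(analyses %in% c("whole_brain", "roi")),
            noise_mode %in% c("per_trial_snr", "fixed_magnitude"))
  if (generative_model == "AGM") include_true_vertices <- FALSE
  structure(as.list(environment()), class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cells <- length(x$snr_db) * length(x$min_distance_mm) * length(x$n_axes) *
    length(x$offset_mm) * length(x$fiducial_sd_mm) * length(x$patch_fwhm_pairs)
  cat(sprintf("sweep_config: %d condition cell(s) x 2 surfaces x %d sources x %d method(s) x %d analysis/es (%s, seed %d)\n",
              cells, x$n_sources, length(x$methods), length(x$analyses),
              x$generative_model, x$seed))
  invisible(x)
}

condition_grid <- function(config) {
  g <- expand.grid(snr_db = config$snr_db,
                   min_distance_mm = config$min_distance_mm,
                   n_axes = config$n_axes,
                   offset_mm = config$offset_mm,
                   fiducial_sd_mm = config$fiducial_sd_mm,
                   patch_pair = seq_along(config$patch_fwhm_pairs),
                   KEEP.OUT.ATTRS = FALSE)
  g$sim_fwhm <- vapply(config$patch_fwhm_pairs[g$patch_pair], `[`, numeric(1), 1)
  g$rec_fwhm <- vapply(config$patch_fwhm_pairs[g$patch_pair], `[`, numeric(1), 2)
  g$patch_pair <- NULL
  g
}

default_conductor <- function(space, array) {
  r_src <- max(row_norms(space$pial$vertices))
  r_sen <- min(row_norms(array$positions))
  head_conductor(c(0, 0, 0), (r_src + r_sen) / 2)
}

#' Run a laminar-inference simulation sweep
#'
#' For every condition cell and every sampled source vertex on each surface:
#' build the sensor array, simulate the patch source, add noise, run the
#' requested analyses and methods, and record one decision row each. All
#' randomness derives from the master seed via stable per-cell hashing, so
#' the same configuration reproduces the identical table and adding a
#' condition level does not change other cells' draws. Failed cells are
#' recorded per-row (column `error`), never aborting the sweep.
#'
#' @param config a `sweep_config`.
#' @param cache_dir optional directory for per-cell TSV caching; re-running
#'   with the same config resumes from completed cells.
#' @param verbose print per-cell progress.
#' @return data.frame (class `experiment_table`): one row per condition x
#'   source x surface x analysis x method with metric, decision, correctness
#'   and significance.
#' @export
run_sweep <- function(config, cache_dir = NULL, verbose = FALSE) {
  geo <- do.call(make_head_geometry,
                 c(config$geometry, list(seed = derive_seed(config$seed, "geometry"))))
  space <- geo$space
  for (nm in c("white", "pial", "mid")) space[[nm]] <- cache_mesh_graph(space[[nm]])
  nv <- space$n_vertices
  src_pial <- with_seed(derive_seed(config$seed, "sources", "pial"),
                        sample.int(nv, config$n_sources))
  src_white <- with_seed(derive_seed(config$seed, "sources", "white"),
                         sample.int(nv, config$n_sources))
  grid <- condition_grid(config)
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    cell_key <- paste(format(unlist(cell), digits = 10), collapse = "_")
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0("cell_", gsub("[^0-9A-Za-z_.-]", "x", cell_key), ".tsv"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      cached <- utils::read.delim(cache_file, sep = "\t", stringsAsFactors = FALSE)
      cached$error <- as.character(cached$error)
      cached$inferred_surface <- as.character(cached$inferred_surface)
      rows[[ci]] <- cached
      next
    }
    if (verbose) message(sprintf("cell %d/%d: %s", ci, nrow(grid), cell_key))
    res <- tryCatch(
      run_cell(config, space, geo$scalp, cell, src_pial, src_white),
      error = function(e) cell_error_rows(config, cell, conditionMessage(e)))
    rows[[ci]] <- res
    if (!is.null(cache_file)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv_atomic(res, cache_file)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("experiment_table", "data.frame")
  out
}

run_cell <- function(config, space, scalp, cell, src_pial, src_white) {
  cell_seed <- derive_seed(config$seed, "cell", cell$snr_db, cell$min_distance_mm,
                           cell$n_axes, cell$offset_mm, cell$fiducial_sd_mm,
                           cell$sim_fwhm, cell$rec_fwhm)
  arr <- pack_sensors(scalp, cell$min_distance_mm,
                      seed = derive_seed(config$seed, "pack", cell$min_distance_mm))
  arr <- build_channel_axes(arr, cell$n_axes)
  arr <- offset_sensors(arr, scalp, cell$offset_mm)
  conductor <- default_conductor(space, arr)

  # simulation-side geometry: identical to reconstruction (GM) or perturbed (AGM)
  if (config$generative_model == "AGM") {
    agm <- make_alternative_geometry(space, arr, seed = derive_seed(cell_seed, "agm"))
    sim_space <- agm$space; sim_arr <- agm$array
  } else {
    sim_space <- space; sim_arr <- arr
  }
  sim_lf <- list(pial = assemble_leadfield(sim_space$pial, sim_arr, conductor),
                 white = assemble_leadfield(sim_space$white, sim_arr, conductor))
  mid_lf <- if (!is.null(config$brain_noise))
    assemble_leadfield(sim_space$mid, sim_arr, conductor)

  rebuild_setup <- cell$fiducial_sd_mm > 0
  setup <- if (!rebuild_setup) laminar_setup(space, arr, conductor)

  out <- list()
  for (surface in c("pial", "white")) {
    src <- if (surface == "pial") src_pial else src_white
    for (k in seq_along(src)) {
      v0 <- src[k]
      src_seed <- derive_seed(cell_seed, surface, k)
      dec_rows <- tryCatch(
        run_one_source(config, cell, space, setup, arr, conductor, sim_space,
                       sim_lf, mid_lf, surface, v0, src_seed, rebuild_setup),
        error = function(e) source_error_rows(config, cell, surface, v0,
                                              conditionMessage(e)))
      out[[length(out) + 1]] <- dec_rows
    }
  }
  do.call(rbind, out)
}

run_one_source <- function(config, cell, space, setup, arr, conductor,
                           sim_space, sim_lf, mid_lf, surface, v0,
                           src_seed, rebuild_setup) {
  patch <- suppressWarnings(gaussian_patch(sim_space[[surface]], v0, cell$sim_fwhm))
  ds <- simulate_signal(patch, sim_lf[[surface]],
                        amplitude_nAm = config$amplitude_nAm,
                        freq_hz = config$freq_hz, active_ms = config$active_ms,
                        fs = 200, n_trials = config$n_trials, surface = surface)
  if (!is.null(config$brain_noise))
    ds <- add_brain_noise(ds, mid_lf, sim_space$mid,
                          n_sources = config$brain_noise$n_sources,
                          relative_strength = config$brain_noise$relative_strength,
                          seed = derive_seed(src_seed, "brain"))
  ds <- add_noise(ds, snr_spec(config$noise_mode, cell$snr_db,
                               config$reference_amplitude),
                  seed = derive_seed(src_seed, "noise"))
  if (rebuild_setup) {
    # fresh fiducial error per simulated source; the reconstruction model
    # uses the misaligned array while the data came from the true one
    pert <- perturb_fiducials(arr, cell$fiducial_sd_mm,
                              seed = derive_seed(src_seed, "fiducial"))
    setup <- laminar_setup(space, pert$array, conductor)
  }
  inc_single <- if (config$include_true_vertices) v0
  inc_combined <- if (config$include_true_vertices) {
    nv <- space$n_vertices
    c(v0, v0 + nv)  # combined model stacks pial then white
  }
  rows <- list()
  for (method in config$methods) {
    for (analysis in config$analyses) {
      dec <- if (analysis == "whole_brain") {
        whole_brain_decision(ds, setup, method = method,
                             include_vertices = inc_single,
                             patch_fwhm_mm = cell$rec_fwhm,
                             n_patch_centres = config$n_patch_centres,
                             seed = derive_seed(config$seed, "msplib"))
      } else {
        roi_decision(ds, setup, method = method,
                     include_vertices = inc_combined,
                     patch_fwhm_mm = cell$rec_fwhm,
                     n_patch_centres = config$n_patch_centres,
                     seed = derive_seed(config$seed, "msplib"))
      }
      rows[[length(rows) + 1]] <- data.frame(
        cell, source_id = v0, true_surface = surface, analysis = analysis,
        method = method, metric = dec$metric,
        inferred_surface = dec$inferred_surface,
        correct = dec$inferred_surface == surface,
        significant = dec$significant, converged = dec$converged,
        error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

decision_skeleton <- function(config, cell, surface, v0, msg) {
  expand.grid(analysis = config$analyses, method = config$methods,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

source_error_rows <- function(config, cell, surface, v0, msg) {
  g <- decision_skeleton(config, cell, surface, v0, msg)
  data.frame(cell, source_id = v0, true_surface = surface,
             analysis = g$analysis, method = g$method, metric = NA_real_,
             inferred_surface = NA_character_, correct = NA,
             significant = NA, converged = NA, error = msg,
             stringsAsFactors = FALSE, row.names = NULL)
}

cell_error_rows <- function(config, cell, msg) {
  out <- list()
  for (surface in c("pial", "white"))
    out[[surface]] <- source_error_rows(config, cell, surface, NA_integer_, msg)
  do.call(rbind, out)
}

#' Summarise an experiment table per condition
#'
#' Percent correct, percent classified as pial, and percent significant, with
#' binomial standard errors, grouped by condition x analysis x method.
#'
#' @param table an `experiment_table` from [run_sweep()].
#' @return data.frame with columns `n`, `pct_correct`, `pct_pial`,
#'   `pct_significant` and their standard errors (`se_*`).
#' @export
summarize_decisions <- function(table) {
  if (nrow(table) == 0) stop("empty experiment table")
  tab <- table[is.na(table$error) | table$error == "", , drop = FALSE]
  keys <- intersect(c("snr_db", "min_distance_mm", "n_axes", "offset_mm",
                      "fiducial_sd_mm", "sim_fwhm", "rec_fwhm",
                      "analysis", "method"), names(tab))
  split_idx <- interaction(tab[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(tab, split_idx)
  out <- lapply(parts, function(p) {
    n <- nrow(p)
    pc <- mean(p$correct); pp <- mean(p$inferred_surface == "pial")
    ps <- mean(p$significant)
    se <- function(x) 100 * sqrt(x * (1 - x) / n)
    cbind(p[1, keys, drop = FALSE],
          data.frame(n = n, pct_correct = 100 * pc, se_correct = se(pc),
                     pct_pial = 100 * pp, se_pial = se(pp),
                     pct_significant = 100 * ps, se_significant = se(ps)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ---- statistical tests -----------------------------------------------------

#' Exact two-sided binomial test against a chance level
#'
#' Exact two-sided p-value (sum of all outcome probabilities not exceeding
#' that of the observed count), as used to test classification percentages
#' against the 50% chance level.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @return the p-value.
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (k < 0 || k > n) stop("'k' must be in 0..n")
  stats::binom.test(k, n, p = p0)$p.value
}

#' Exact McNemar test for paired binary classifiers
#'
#' Conditional exact test on the discordant pairs:
#' `p = min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#'
#' @param b,c discordant pair counts (method A correct only / method B
#'   correct only).
#' @return the p-value (1 when `b == c`, including `b == c == 0`).
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0) stop("'b' and 'c' must be non-negative")
  if (b + c == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
}

#' Logistic regression of a binary outcome on ordered condition levels
#'
#' Maximum-likelihood logistic slope (IRLS via `glm`) of the outcome on the
#' standardised index of the ordered condition levels, with the Wald p-value.
#' Perfect separation is flagged rather than an error.
#'
#' @param outcome logical/0-1 vector.
#' @param predictor condition level per observation (ordered by value).
#' @param standardise standardise the level index (default TRUE); with
#'   FALSE the raw 0, 1, ... index is used.
#' @return list with `beta`, `p`, `se` and `separated`.
#' @export
logistic_fit <- function(outcome, predictor, standardise = TRUE) {
  levels_sorted <- sort(unique(predictor))
  if (length(levels_sorted) < 2) stop("need at least two predictor levels")
  x <- match(predictor, levels_sorted) - 1
  if (standardise) x <- as.numeric(scale(x))
  y <- as.numeric(outcome)
  if (all(y == y[1])) {
    return(list(beta = NA_real_, p = NA_real_, se = NA_real_, separated = TRUE))
  }
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  co <- summary(fit)$coefficients
  list(beta = co["x", "Estimate"], p = co["x", "Pr(>|z|)"],
       se = co["x", "Std. Error"], separated = separated)
}
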
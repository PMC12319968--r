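# Trial-level data simulation: Gaussian source patches on a cortical mesh,
# sinusoidal dipole activity, white sensor noise at controlled single-trial
# SNR (or fixed magnitude), and interfering band-limited brain-noise sources.

# ---- geodesic distances ----------------------------------------------------

mesh_graph <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  w <- row_norms(mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# distances from several source vertices at once (matrix: length(v0) x n)
geodesic_all <- function(mesh, v0) {
  g <- attr(mesh, ".graph")
  if (is.null(g)) g <- mesh_graph(mesh)
  igraph::distances(g, v = v0, weights = igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

# attach a cached edge graph (meshes are reused heavily in sweeps)
cache_mesh_graph <- function(mesh) {
  if (is.null(attr(mesh, ".graph"))) attr(mesh, ".graph") <- mesh_graph(mesh)
  mesh
}

#' Geodesic distances from a vertex along the mesh edge graph
#'
#' Dijkstra shortest paths over the triangulation's edge graph with Euclidean
#' edge weights, an upper bound on the true surface geodesic. Vertices
#' farther than `max_dist_mm` (or unreachable) are omitted.
#'
#' @param mesh a `surface_mesh`.
#' @param v0 source vertex index.
#' @param max_dist_mm cutoff distance (mm).
#' @return named numeric vector of distances (mm) for vertices within the
#'   cutoff; names are vertex indices, `d[v0] == 0`.
#' @export
geodesic_distances <- function(mesh, v0, max_dist_mm) {
  if (v0 < 1 || v0 > nrow(mesh$vertices)) stop("'v0' out of range")
  d <- as.numeric(geodesic_all(mesh, v0))
  keep <- which(is.finite(d) & d <= max_dist_mm)
  stats::setNames(d[keep], keep)
}

# ---- Gaussian source patch -------------------------------------------------

#' Smooth Gaussian source patch on a cortical mesh
#'
#' Patch weights follow a Gaussian of the geodesic distance to the centre
#' vertex, `exp(-d^2 / (2 sigma^2))` with `sigma = FWHM / 2.355`, truncated
#' to zero beyond one FWHM and normalised to sum to 1.
#'
#' @param mesh a `surface_mesh`.
#' @param v0 centre vertex index.
#' @param fwhm_mm full width at half maximum (mm, > 0); default 5.
#' @return object of class `source_patch`: `centre`, `fwhm`, `sigma`,
#'   `vertices` (indices with non-zero weight) and `weights` (sum to 1,
#'   maximal at the centre).
#' @export
gaussian_patch <- function(mesh, v0, fwhm_mm = 5) {
  stopifnot_scalar(fwhm_mm, "fwhm_mm", lower = 1e-12)
  d <- geodesic_distances(mesh, v0, max_dist_mm = fwhm_mm)
  if (length(d) == 1) {
    warning("patch degenerates to a single vertex (no neighbour within one FWHM)")
    return(structure(list(centre = v0, fwhm = fwhm_mm, sigma = fwhm_mm / 2.355,
                          vertices = v0, weights = 1), class = "source_patch"))
  }
  sigma <- fwhm_mm / 2.355
  w <- exp(-d^2 / (2 * sigma^2))
  w <- w / sum(w)
  structure(list(centre = v0, fwhm = fwhm_mm, sigma = sigma,
                 vertices = as.integer(names(d)), weights = as.numeric(w)),
            class = "source_patch")
}

# ---- trial dataset ---------------------------------------------------------

trial_time_axis <- function(fs, duration_ms = 1000, start_ms = -500) {
  n <- round(fs * duration_ms / 1000)
  seq(start_ms, by = 1000 / fs, length.out = n)
}

#' Simulate noiseless sensor trials from a sinusoidal source patch
#'
#' The current density is the patch weight times a sinusoid of amplitude
#' `amplitude_nAm` inside the active window and zero outside; sensor data are
#' the patch-weighted sum of lead-field columns. All trials are identical
#' before noise.
#'
#' @param patch a `source_patch` on the simulation mesh.
#' @param leadfield a `lead_field` whose source columns index the same mesh.
#' @param amplitude_nAm peak dipole moment of the patch (nAm); default 10.
#' @param freq_hz sinusoid frequency (default 20 Hz, must be below Nyquist).
#' @param active_ms active window `[on, off)` in ms (default `c(100, 500)`).
#' @param fs sampling rate (Hz; default 200).
#' @param n_trials number of trials (default 200).
#' @param surface label of the true surface ("pial"/"white"), bookkeeping.
#' @return object of class `trial_dataset` with `data`
#'   (channels x samples x trials, fT), `signal` (the noiseless single-trial
#'   matrix), `fs`, `time_ms` and a `ground_truth` record.
#' @export
simulate_signal <- function(patch, leadfield, amplitude_nAm = 10, freq_hz = 20,
                            active_ms = c(100, 500), fs = 200, n_trials = 200,
                            surface = NA_character_) {
  if (freq_hz >= fs / 2) stop("'freq_hz' must be below the Nyquist frequency")
  time_ms <- trial_time_axis(fs)
  if (active_ms[1] < time_ms[1] || active_ms[2] > time_ms[length(time_ms)] + 1000 / fs)
    stop("active window must lie within the trial")
  topo <- as.numeric(leadfield$gain[, patch$vertices, drop = FALSE] %*% patch$weights)
  s <- numeric(length(time_ms))
  act <- time_ms >= active_ms[1] & time_ms < active_ms[2]
  s[act] <- amplitude_nAm * sin(2 * pi * freq_hz * (time_ms[act] - active_ms[1]) / 1000)
  D <- topo %*% t(s)                      # channels x samples
  data <- base::array(D, dim = c(nrow(D), ncol(D), n_trials))
  structure(list(
    data = data, signal = D, fs = fs, time_ms = time_ms,
    ground_truth = list(surface = surface, centre = patch$centre,
                        fwhm = patch$fwhm, freq_hz = freq_hz,
                        active_ms = active_ms, amplitude_nAm = amplitude_nAm),
    noise = NULL, brain_noise = NULL,
    channels = leadfield$channels),
    class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_dataset: %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Noise specification for sensor-level white noise
#'
#' In `per_trial_snr` mode the noise amplitude is derived from the simulated
#' signal via `A_noise = A_signal * 10^(-SNR_dB / 20)`, with `A_signal` the
#' mean over channels of the per-channel standard deviation of the noiseless
#' sensor matrix. In `fixed_magnitude` mode the noise amplitude is
#' `reference_amplitude * 10^(value_db / 20)` irrespective of the signal
#' (larger dB = more noise), which preserves the advantage of sensors closer
#' to the scalp when sweeping offsets.
#'
#' @param mode `"per_trial_snr"` or `"fixed_magnitude"`.
#' @param value_db single-trial SNR in dB (per-trial mode) or noise magnitude
#'   in dB re `reference_amplitude` (fixed mode).
#' @param reference_amplitude reference amplitude for fixed mode (fT);
#'   default 0.01.
#' @return object of class `snr_spec`.
#' @export
snr_spec <- function(mode = c("per_trial_snr", "fixed_magnitude"), value_db,
                     reference_amplitude = 0.01) {
  mode <- match.arg(mode)
  stopifnot_scalar(value_db, "value_db")
  structure(list(mode = mode, value_db = value_db,
                 reference_amplitude = reference_amplitude),
            class = "snr_spec")
}

signal_amplitude <- function(D) mean(apply(D, 1, stats::sd))

#' Add white Gaussian sensor noise at a controlled level
#'
#' @param dataset a noiseless `trial_dataset`.
#' @param spec an `snr_spec`.
#' @param seed seed for the noise draw.
#' @return the dataset with iid Gaussian noise added to every sample of every
#'   trial and a `noise` record (`A_signal`, `A_noise`, spec).
#' @export
add_noise <- function(dataset, spec, seed = 1) {
  if (!is.null(dataset$noise)) stop("dataset already carries sensor noise")
  A_signal <- signal_amplitude(dataset$signal)
  A_noise <- switch(spec$mode,
    per_trial_snr = A_signal * 10^(-spec$value_db / 20),
    fixed_magnitude = spec$reference_amplitude * 10^(spec$value_db / 20))
  d <- dim(dataset$data)
  noise <- with_seed(seed,
                     base::array(stats::rnorm(prod(d), 0, A_noise), dim = d))
  dataset$data <- dataset$data + noise
  dataset$noise <- list(spec = spec, A_signal = A_signal, A_noise = A_noise,
                        seed = seed)
  dataset
}

#' Empirical SNR of a noisy dataset (single-trial and trial-averaged)
#'
#' Recomputes amplitude SNRs from the generated data: the noise amplitude is
#' the mean channel standard deviation of the residual after subtracting the
#' known noiseless signal, per trial and for the trial average.
#'
#' @param dataset a `trial_dataset` with noise added.
#' @return list with `single_trial_db` (mean over trials), `trial_averaged_db`
#'   and `gain_db` (their difference).
#' @export
snr_decibels <- function(dataset) {
  A_signal <- signal_amplitude(dataset$signal)
  ntr <- dim(dataset$data)[3]
  per_trial <- vapply(seq_len(ntr), function(tr) {
    20 * log10(A_signal / signal_amplitude(dataset$data[, , tr] - dataset$signal))
  }, numeric(1))
  avg <- apply(dataset$data, c(1, 2), mean)
  avg_db <- 20 * log10(A_signal / signal_amplitude(avg - dataset$signal))
  list(single_trial_db = mean(per_trial), trial_averaged_db = avg_db,
       gain_db = avg_db - mean(per_trial))
}

# ---- band-limited Gaussian noise ------------------------------------------

#' Band-limited Gaussian noise via spectral synthesis
#'
#' Draws independent complex Gaussian Fourier coefficients on the frequency
#' bins inside the pass band (zero elsewhere), inverse-transforms, and scales
#' to unit standard deviation: exactly band-limited, Gaussian, zero-phase.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param band pass band `c(low, high)` in Hz.
#' @param seed optional seed.
#' @return numeric vector of length `n` with sd 1.
#' @export
band_limited_noise <- function(n, fs, band = c(10, 30), seed = NULL) {
  gen <- function() {
    freq <- (0:(n - 1)) * fs / n
    half <- 2:ceiling(n / 2)              # positive, non-DC bins
    inband <- half[freq[half] >= band[1] & freq[half] <= band[2]]
    spec <- complex(real = rep(0, n), imaginary = rep(0, n))
    spec[inband] <- complex(real = stats::rnorm(length(inband)),
                            imaginary = stats::rnorm(length(inband)))
    spec[n + 2 - inband] <- Conj(spec[inband])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x / stats::sd(x)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Add interfering brain-noise sources on the mid-cortical surface
#'
#' Places `n_sources` Gaussian patches at random vertices of the mid surface;
#' each receives a band-limited Gaussian dipole time course whose standard
#' deviation is `relative_strength` times the RMS dipole moment of the
#' source of interest. Time courses are drawn independently per trial by
#' default; with `coherent = TRUE` the same waveform repeats across trials
#' (noise then survives trial averaging).
#'
#' @param dataset a `trial_dataset`.
#' @param mid_leadfield `lead_field` of the mid surface.
#' @param mid_mesh the mid `surface_mesh` (for patch construction).
#' @param n_sources number of interfering sources (default 5).
#' @param relative_strength source strength relative to the source of
#'   interest (default 0.4).
#' @param band frequency band in Hz (default `c(10, 30)`).
#' @param seed seed for locations and time courses.
#' @param coherent logical; repeat waveforms across trials (default FALSE).
#' @return the dataset with projected brain noise added and a `brain_noise`
#'   record (vertices, strength, band).
#' @export
add_brain_noise <- function(dataset, mid_leadfield, mid_mesh, n_sources = 5,
                            relative_strength = 0.4, band = c(10, 30),
                            seed = 1, coherent = FALSE) {
  nv <- nrow(mid_mesh$vertices)
  if (n_sources > nv) stop("'n_sources' exceeds available mid-surface vertices")
  if (relative_strength == 0) return(dataset)
  verts <- with_seed(derive_seed(seed, "bn_loc"), sample.int(nv, n_sources))
  d <- dim(dataset$data)
  nsamp <- d[2]; ntr <- d[3]
  # RMS dipole moment of the sinusoidal source of interest: A / sqrt(2)
  sd_dip <- relative_strength * dataset$ground_truth$amplitude_nAm / sqrt(2)
  fwhm <- dataset$ground_truth$fwhm
  for (j in seq_len(n_sources)) {
    patch <- suppressWarnings(gaussian_patch(mid_mesh, verts[j], fwhm))
    topo <- as.numeric(mid_leadfield$gain[, patch$vertices, drop = FALSE] %*%
                         patch$weights)
    if (coherent) {
      s <- sd_dip * band_limited_noise(nsamp, dataset$fs, band,
                                       seed = derive_seed(seed, "bn_tc", j))
      add <- topo %*% t(s)
      for (tr in seq_len(ntr)) dataset$data[, , tr] <- dataset$data[, , tr] + add
    } else {
      for (tr in seq_len(ntr)) {
        s <- sd_dip * band_limited_noise(nsamp, dataset$fs, band,
                                         seed = derive_seed(seed, "bn_tc", j, tr))
        dataset$data[, , tr] <- dataset$data[, , tr] + topo %*% t(s)
      }
    }
  }
  dataset$brain_noise <- list(vertices = verts, relative_strength = relative_strength,
                              band = band, n_sources = n_sources,
                              coherent = coherent, seed = seed)
  dataset
}
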
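# Gaussian patches, sinusoidal trials, sensor noise at controlled SNR and
# interfering brain-noise sources.

test_that("geodesic distances match a brute-force Dijkstra oracle", {
  base <- icosphere(1)                       # 42 vertices
  mesh <- surface_mesh(base$vertices * 50, base$faces)
  # plain O(n^2) Dijkstra over the edge graph, written independently
  f <- mesh$faces
  edges <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  n <- nrow(mesh$vertices)
  W <- matrix(Inf, n, n)
  for (i in seq_len(nrow(edges))) {
    d <- sqrt(sum((mesh$vertices[edges[i, 1], ] - mesh$vertices[edges[i, 2], ])^2))
    W[edges[i, 1], edges[i, 2]] <- d
    W[edges[i, 2], edges[i, 1]] <- d
  }
  dijkstra <- function(v0) {
    dist <- rep(Inf, n); dist[v0] <- 0; done <- rep(FALSE, n)
    for (k in seq_len(n)) {
      u <- which(!done)[which.min(dist[!done])]
      done[u] <- TRUE
      relax <- which(W[u, ] < Inf)
      dist[relax] <- pmin(dist[relax], dist[u] + W[u, relax])
    }
    dist
  }
  for (v0 in c(1, 17, 42)) {
    want <- dijkstra(v0)
    got <- geodesic_distances(mesh, v0, max_dist_mm = Inf)
    expect_equal(unname(got[as.character(seq_len(n))]), want, tolerance = 1e-12)
    expect_identical(unname(got[as.character(v0)]), 0)
  }
  # cutoff omits far vertices
  near <- geodesic_distances(mesh, 1, max_dist_mm = 30)
  expect_true(all(near <= 30))
  expect_lt(length(near), n)
})

test_that("edge-graph distances are never below the straight-line distance", {
  # graph paths cannot undercut the Euclidean chord (triangle inequality);
  # note they can undercut the great-circle arc for one-hop neighbours,
  # where the path is a single chord
  base <- icosphere(2)
  R <- 60
  mesh <- surface_mesh(base$vertices * R, base$faces)
  d <- geodesic_distances(mesh, 1, Inf)
  chord <- sqrt(rowSums(sweep(mesh$vertices, 2, mesh$vertices[1, ])^2))
  expect_true(all(d >= chord[as.integer(names(d))] - 1e-9))
})

test_that("gaussian patches follow the truncated Gaussian of geodesic distance", {
  mesh <- tiny_head()$space$pial
  patch <- gaussian_patch(mesh, 50, fwhm_mm = 12)
  expect_equal(patch$sigma, 12 / 2.355)
  expect_equal(suppressWarnings(gaussian_patch(mesh, 50, 5))$sigma, 2.1231,
               tolerance = 1e-4)
  expect_equal(sum(patch$weights), 1, tolerance = 1e-12)
  expect_equal(patch$vertices[which.max(patch$weights)], 50)
  # weight ratios reproduce exp(-d^2 / (2 sigma^2)); the ratio at half-FWHM
  # distance is 1/2 (up to the conventional 2.355 rounding of the constant)
  d <- geodesic_distances(mesh, 50, 12)
  d <- d[match(patch$vertices, as.integer(names(d)))]
  ratio <- patch$weights / max(patch$weights)
  expect_equal(ratio, exp(-d^2 / (2 * patch$sigma^2)) /
                 max(exp(-d^2 / (2 * patch$sigma^2))), tolerance = 1e-12,
               ignore_attr = TRUE)
  # half-maximum at half-FWHM distance (up to the 2.355 rounding of the
  # 2 sqrt(2 log 2) constant)
  expect_equal(exp(-(12 / 2)^2 / (2 * patch$sigma^2)), 0.5, tolerance = 2e-4)
  # truncation: nothing beyond one FWHM
  all_d <- geodesic_distances(mesh, 50, Inf)
  expect_true(all(all_d[match(patch$vertices, as.integer(names(all_d)))] <= 12))
  # degenerate patch: warn and collapse to the centre vertex
  expect_warning(p1 <- gaussian_patch(mesh, 50, 0.5), "single vertex")
  expect_identical(p1$weights, 1)
})

test_that("simulated trials are sinusoidal inside the active window only", {
  setup <- tiny_setup()
  patch <- suppressWarnings(gaussian_patch(tiny_head()$space$pial, 123, 5))
  ds <- simulate_signal(patch, setup$leadfields$pial, n_trials = 3)
  expect_equal(dim(ds$data)[2], 200)                 # fs * 1 s
  outside <- ds$time_ms < 100 | ds$time_ms >= 500
  expect_true(all(ds$data[, outside, ] == 0))
  # doubling the amplitude doubles every sample
  ds2 <- simulate_signal(patch, setup$leadfields$pial, amplitude_nAm = 20,
                         n_trials = 3)
  expect_equal(ds2$data, 2 * ds$data, tolerance = 1e-14)
  # the active window holds exactly 8 cycles of 20 Hz: channel RMS = A/sqrt(2)
  topo <- as.numeric(setup$leadfields$pial$gain[, patch$vertices, drop = FALSE] %*%
                       patch$weights)
  ch <- which.max(abs(topo))
  active <- ds$signal[ch, !outside]
  amp <- 10 * abs(topo[ch])               # default 10 nAm dipole moment
  expect_lt(abs(sqrt(mean(active^2)) / (amp / sqrt(2)) - 1), 0.005)
  expect_error(simulate_signal(patch, setup$leadfields$pial, freq_hz = 120),
               "Nyquist")
})

test_that("white-noise amplitudes follow the SNR equations", {
  setup <- tiny_setup()
  patch <- suppressWarnings(gaussian_patch(tiny_head()$space$pial, 123, 5))
  ds <- simulate_signal(patch, setup$leadfields$pial, n_trials = 2)
  As <- opmlaminar:::signal_amplitude(ds$signal)
  d0 <- add_noise(ds, snr_spec("per_trial_snr", 0), seed = 1)
  expect_equal(d0$noise$A_noise, As)                       # 0 dB: equality
  dm20 <- add_noise(ds, snr_spec("per_trial_snr", -20), seed = 1)
  expect_equal(dm20$noise$A_noise, 10 * As)                # -20 dB: 10x
  # fixed-magnitude mode ignores the signal
  dfix <- add_noise(ds, snr_spec("fixed_magnitude", 30,
                                 reference_amplitude = 0.01), seed = 1)
  expect_equal(dfix$noise$A_noise, 0.01 * 10^(30 / 20))
  expect_error(add_noise(d0, snr_spec("per_trial_snr", -5)), "already")
})

test_that("requested single-trial SNR is realised empirically", {
  setup <- tiny_setup()
  patch <- suppressWarnings(gaussian_patch(tiny_head()$space$pial, 123, 5))
  base <- simulate_signal(patch, setup$leadfields$pial, n_trials = 5)
  got <- mean(vapply(1:50, function(s) {
    snr_decibels(add_noise(base, snr_spec("per_trial_snr", -5), seed = s))$single_trial_db
  }, numeric(1)))
  expect_lt(abs(got - (-5)), 0.2)
})

test_that("identical seeds reproduce identical datasets bit for bit", {
  setup <- tiny_setup()
  patch <- suppressWarnings(gaussian_patch(tiny_head()$space$pial, 44, 5))
  mk <- function() {
    ds <- simulate_signal(patch, setup$leadfields$pial, n_trials = 4)
    ds <- add_brain_noise(ds, setup$leadfields$pial, tiny_head()$space$pial,
                          n_sources = 2, seed = 5)
    add_noise(ds, snr_spec("per_trial_snr", -10), seed = 7)
  }
  expect_identical(mk()$data, mk()$data)
})

test_that("band-limited noise is Gaussian-scaled and spectrally confined", {
  x <- band_limited_noise(20000, fs = 200, band = c(10, 30), seed = 3)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  sp <- Mod(fft(x))^2
  freq <- (0:(length(x) - 1)) * 200 / length(x)
  freq <- ifelse(freq > 100, 200 - freq, freq)
  inband <- freq >= 10 & freq <= 30
  expect_lt(sum(sp[!inband]) / sum(sp[inband]), 0.01)
})

test_that("brain-noise strength scales the added component linearly", {
  setup <- tiny_setup()
  geo <- tiny_head()
  patch <- suppressWarnings(gaussian_patch(geo$space$pial, 123, 5))
  ds <- simulate_signal(patch, setup$leadfields$pial, n_trials = 3)
  mid_lf <- assemble_leadfield(geo$space$mid, setup$array, setup$conductor)
  ds0 <- add_brain_noise(ds, mid_lf, geo$space$mid, relative_strength = 0,
                         seed = 9)
  expect_identical(ds0$data, ds$data)
  d02 <- add_brain_noise(ds, mid_lf, geo$space$mid, relative_strength = 0.2,
                         seed = 9)
  d04 <- add_brain_noise(ds, mid_lf, geo$space$mid, relative_strength = 0.4,
                         seed = 9)
  expect_equal(d04$data - ds$data, 2 * (d02$data - ds$data), tolerance = 1e-9)
  # coherent mode repeats the waveform across trials
  dc <- add_brain_noise(ds, mid_lf, geo$space$mid, seed = 9, coherent = TRUE)
  add <- dc$data - ds$data
  expect_equal(add[, , 1], add[, , 3], tolerance = 1e-12)
  # independent mode does not
  di <- add_brain_noise(ds, mid_lf, geo$space$mid, seed = 9)
  addi <- di$data - ds$data
  expect_gt(max(abs(addi[, , 1] - addi[, , 3])), 1e-6)
})
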
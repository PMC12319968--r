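# Data reduction, functional priors and ReML free energy.

test_that("preprocess retains all channels as spatial modes when below the cap", {
  ds <- tiny_dataset(n_trials = 8)
  red <- preprocess(ds, tiny_setup()$leadfields$pial)
  expect_equal(nrow(red$S), n_channels(tiny_setup()$array))
  expect_equal(dim(red$Y)[2], 4)
  expect_equal(red$N, 8 * 4)
  # projectors are orthonormal
  expect_lt(max(abs(crossprod(red$Us) - diag(ncol(red$Us)))), 1e-9)
  expect_lt(max(abs(crossprod(red$Tproj) - diag(ncol(red$Tproj)))), 1e-9)
})

test_that("the temporal projector is idempotent and captures a sinusoid", {
  setup <- tiny_setup()
  patch <- suppressWarnings(gaussian_patch(tiny_head()$space$pial, 123, 5))
  ds <- simulate_signal(patch, setup$leadfields$pial, n_trials = 5)
  red <- preprocess(ds, setup$leadfields$pial)
  P <- tcrossprod(red$Tproj)
  expect_lt(max(abs(P %*% P - P)), 1e-12)
  # noiseless single sinusoid: 4 temporal modes capture >= 99.9% variance
  sv <- red$temporal_sv
  expect_gte(sum(sv[1:4]^2) / sum(sv^2), 0.999)
  expect_error(preprocess(ds, setup$leadfields$pial, band = c(10, 150)),
               "Nyquist")
})

test_that("EBB weights follow the closed form for identity covariance", {
  setup <- tiny_setup()
  A <- setup$leadfields$pial$gain[, 1:40]
  m <- nrow(A)
  red <- structure(list(S = diag(m), N = 100, A = A), class = "reduced_data")
  pr <- build_prior_ebb(red, lambda_reg = 0, normalise = "none")
  want <- 1 / colSums(A^2)
  expect_equal(pr$w, want / sum(want), tolerance = 1e-12)
  expect_equal(sum(pr$w), 1, tolerance = 1e-12)
  # identical lead-field columns receive identical weights
  A2 <- cbind(A, A[, 7])
  red2 <- structure(list(S = diag(m), N = 100, A = A2), class = "reduced_data")
  pr2 <- build_prior_ebb(red2, lambda_reg = 0, normalise = "none")
  expect_equal(pr2$w[7], pr2$w[41], tolerance = 1e-12)
})

test_that("EBB peaks at the true source for high-SNR data", {
  setup <- tiny_setup()
  hits <- vapply(1:20, function(s) {
    v0 <- 100 + 17 * s
    patch <- suppressWarnings(gaussian_patch(tiny_head()$space$pial, v0, 5))
    ds <- simulate_signal(patch, setup$leadfields$pial, n_trials = 10,
                          surface = "pial")
    ds <- add_noise(ds, snr_spec("per_trial_snr", 5), seed = s)
    red <- preprocess(ds, setup$leadfields$pial)
    pr <- build_prior_ebb(red, normalise = "leadfield")
    which.max(pr$w) == v0
  }, logical(1))
  expect_gte(mean(hits), 0.55)
})

test_that("the MSP library contains rank-one unit-trace patch components", {
  setup <- tiny_setup()
  lib <- build_prior_msp_library(setup$models$pial, n_patch_centres = 12,
                                 include_vertices = 77, seed = 4)
  expect_true(77 %in% attr(lib, "centres"))
  for (comp in lib[1:5]) {
    expect_gt(sum(comp$q^2), 0)
    expect_equal(sum(comp$q), 1, tolerance = 1e-12)
    # q q' is PSD with rank 1 by construction; check via its mode projection
    G <- opmlaminar:::component_to_modes(comp, setup$leadfields$pial$gain[1:8, ])
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
    expect_equal(sum(ev > 1e-9 * max(ev)), 1)
  }
})

test_that("fixed-hyperparameter free energy equals the Gaussian log evidence", {
  # tiny instance: 8 channels, 4 sources, known covariance model
  set.seed(31)
  m <- 8; nsrc <- 4; N <- 25
  A <- matrix(rnorm(m * nsrc), m)
  Qs <- list(diag(m), tcrossprod(A %*% c(1, 0.5, 0, 0)),
             tcrossprod(A %*% c(0, 0, 1, -1)))
  lam <- c(-0.3, 0.7, -1.1)
  C <- exp(lam[1]) * Qs[[1]] + exp(lam[2]) * Qs[[2]] + exp(lam[3]) * Qs[[3]]
  Y <- t(chol(C)) %*% matrix(rnorm(m * N), m)
  S <- tcrossprod(Y) / N
  fit <- opmlaminar:::reml_fit(S, N, Qs, fixed_lambda = lam)
  # independent brute-force evaluation: per-column Gaussian log density via
  # the eigendecomposition of C
  ev <- eigen(C, symmetric = TRUE)
  want <- sum(vapply(seq_len(N), function(i) {
    y <- Y[, i]
    z <- crossprod(ev$vectors, y)
    -0.5 * (m * log(2 * pi) + sum(log(ev$values)) + sum(z^2 / ev$values))
  }, numeric(1)))
  expect_equal(fit$F, want, tolerance = 1e-8)
})

test_that("ReML iterations never decrease the objective", {
  set.seed(5)
  m <- 12; N <- 60
  A <- matrix(rnorm(m * 6), m)
  Qs <- list(diag(m), tcrossprod(A[, 1:2]) / 2, tcrossprod(A[, 3:6]) / 4)
  C_true <- 0.5 * Qs[[1]] + 2 * Qs[[2]]
  Y <- t(chol(C_true)) %*% matrix(rnorm(m * N), m)
  fit <- opmlaminar:::reml_fit(tcrossprod(Y) / N, N, Qs)
  expect_true(all(diff(fit$objective_trace) > -1e-6))
  expect_true(fit$converged)
  expect_true(is.finite(fit$F))
})

test_that("duplicating the data changes F but preserves model ranking", {
  set.seed(8)
  m <- 10
  A <- matrix(rnorm(m * 8), m)
  QsA <- list(diag(m), tcrossprod(A[, 1:2]))
  QsB <- list(diag(m), tcrossprod(A[, 5:8]))
  agree <- vapply(1:10, function(s) {
    set.seed(100 + s)
    C_true <- diag(m) * 0.05 + tcrossprod(A[, 1:2])
    Y <- t(chol(C_true)) %*% matrix(rnorm(m * 30), m)
    S <- tcrossprod(Y) / 30
    f <- function(Qs, N) opmlaminar:::reml_fit(S, N, Qs)$F
    d1 <- f(QsA, 30) - f(QsB, 30)
    d2 <- f(QsA, 60) - f(QsB, 60)
    sign(d1) == sign(d2)
  }, logical(1))
  expect_true(all(agree))
})

test_that("greedy MSP selects a patch near the true source at high SNR", {
  setup <- tiny_setup()
  space <- tiny_head()$space
  hits <- vapply(1:10, function(s) {
    v0 <- 30 + 61 * s
    patch <- suppressWarnings(gaussian_patch(space$pial, v0, 5))
    ds <- simulate_signal(patch, setup$leadfields$pial, n_trials = 10,
                          surface = "pial")
    ds <- add_noise(ds, snr_spec("per_trial_snr", 0), seed = s)
    red <- preprocess(ds, setup$leadfields$pial)
    inv <- reml_invert(red, setup$models$pial, method = "MSP",
                       include_vertices = v0, n_patch_centres = 32, seed = 5,
                       compute_posterior = FALSE)
    sel <- inv$components
    centres <- as.integer(sub(".*_patch_", "", sel))
    d <- geodesic_distances(space$pial, v0, max_dist_mm = 5)
    any(centres %in% as.integer(names(d)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("inversion is deterministic given the seed", {
  ds <- tiny_dataset(n_trials = 10)
  setup <- tiny_setup()
  red <- preprocess(ds, setup$leadfields$pial)
  f1 <- reml_invert(red, setup$models$pial, method = "MSP", n_patch_centres = 16,
                    seed = 3, compute_posterior = FALSE)$F
  f2 <- reml_invert(red, setup$models$pial, method = "MSP", n_patch_centres = 16,
                    seed = 3, compute_posterior = FALSE)$F
  expect_identical(f1, f2)
})
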
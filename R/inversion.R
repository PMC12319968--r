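# Empirical Bayes source inversion.
#
# Sensor data are reduced to orthonormal spatial (lead-field SVD) and
# temporal (trial-average SVD) modes; the model covariance in mode space is
# a positive mixture C = h0 I + sum_k h_k (L Q_k L') of a sensor-noise
# component and source-covariance components (beamformer-weighted diagonal,
# sparse cortical patches, identity, or distance-decaying smoothness).
# Hyperparameters h = exp(lambda) are optimised by restricted maximum
# likelihood (Fisher scoring with log-normal hyperpriors and monotone
# backtracking), and models are compared by the variational free energy
# (Laplace approximation to the log model evidence).

# ---- spectral band-pass ----------------------------------------------------

# Zero-phase band-pass: multiply the spectrum by the squared-magnitude
# response of an order-4 Butterworth band-pass (half power at the band
# edges), applied forward/backward-equivalently in the frequency domain.
# X: channels x samples.
bandpass_mat <- function(X, fs, band, order = 4) {
  n <- ncol(X)
  k <- 0:(n - 1)
  f <- k * fs / n
  f <- ifelse(f > fs / 2, fs - f, f)       # two-sided (aliased) frequencies
  B <- band[2] - band[1]
  w2 <- f^2 - band[1] * band[2]
  arg <- ifelse(f > 0, w2 / (f * B), -Inf)
  H2 <- 1 / (1 + arg^(2 * order))
  H2[f == 0] <- 0
  sp <- t(stats::mvfft(t(X)))
  Re(t(stats::mvfft(t(sp * rep(H2, each = nrow(X))), inverse = TRUE))) / n
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# ---- data reduction --------------------------------------------------------

#' Reduce a trial dataset to spatial and temporal modes
#'
#' Optionally applies a full-trial Hann taper, band-pass filters (zero-phase,
#' Butterworth magnitude, default 10-30 Hz), projects channels onto the
#' orthonormal spatial modes of the lead field (retaining at most
#' `n_spatial_modes`), and projects time onto the leading right singular
#' vectors of the trial-averaged data (at most `n_temporal_modes`). The
#' reduced sample covariance is rescaled to unit mean eigenvalue; the scale
#' depends only on the data, so free energies of different source models on
#' the same dataset remain comparable.
#'
#' @param dataset a `trial_dataset`.
#' @param leadfield the `lead_field` of the reconstruction source model.
#' @param band band-pass in Hz (default `c(10, 30)`).
#' @param hann logical, apply a full-trial Hann taper (default TRUE; the ROI
#'   analysis uses FALSE).
#' @param n_temporal_modes maximal temporal modes (default 4).
#' @param n_spatial_modes maximal spatial modes (default 274).
#' @return object of class `reduced_data`: `Y` (modes x temporal modes x
#'   trials), `S` (sample covariance of `Y`), `N` (effective sample count),
#'   `A` (reduced lead field, modes x sources), `Us` (spatial projector),
#'   `Tproj` (temporal projector, orthonormal columns), `temporal_sv`
#'   (singular values of the trial average), `Xs` (spatially projected
#'   filtered time series, for posterior time-course reconstruction),
#'   `scale`, `fs`, `time_ms`.
#' @export
preprocess <- function(dataset, leadfield, band = c(10, 30), hann = TRUE,
                       n_temporal_modes = 4, n_spatial_modes = 274) {
  fs <- dataset$fs
  if (band[2] >= fs / 2) stop("band must lie below the Nyquist frequency")
  d <- dim(dataset$data)
  nch <- d[1]; nsamp <- d[2]; ntr <- d[3]
  if (nsamp < n_temporal_modes) stop("fewer samples than temporal modes")
  taper <- if (hann) hann_window(nsamp) else rep(1, nsamp)
  sv <- svd(leadfield$gain)
  m <- min(nch, n_spatial_modes, sum(sv$d > sv$d[1] * 1e-12))
  Us <- sv$u[, seq_len(m), drop = FALSE]
  Xs <- base::array(0, dim = c(m, nsamp, ntr))
  for (tr in seq_len(ntr)) {
    X <- dataset$data[, , tr] * rep(taper, each = nch)
    Xs[, , tr] <- crossprod(Us, bandpass_mat(X, fs, band))
  }
  avg <- apply(Xs, c(1, 2), mean)
  tsvd <- svd(avg)
  k <- min(n_temporal_modes, length(tsvd$d))
  Tproj <- tsvd$v[, seq_len(k), drop = FALSE]
  Y <- base::array(0, dim = c(m, k, ntr))
  for (tr in seq_len(ntr)) Y[, , tr] <- Xs[, , tr] %*% Tproj
  N <- ntr * k
  S <- matrix(0, m, m)
  for (tr in seq_len(ntr)) S <- S + tcrossprod(Y[, , tr])
  S <- S / N
  scale <- sum(diag(S)) / m
  if (scale <= 0) scale <- 1
  S <- S / scale
  Y <- Y / sqrt(scale)
  Xs <- Xs / sqrt(scale)
  structure(list(Y = Y, S = S, N = N, A = crossprod(Us, leadfield$gain),
                 Us = Us, Tproj = Tproj, temporal_sv = tsvd$d, Xs = Xs,
                 scale = scale, fs = fs, time_ms = dataset$time_ms,
                 band = band, hann = hann, n_trials = ntr),
            class = "reduced_data")
}

# ---- prior components ------------------------------------------------------

#' Empirical Bayes beamformer source-variance prior
#'
#' Diagonal source covariance with per-source weights derived from the
#' inverse of the (regularised) reduced data covariance:
#' `w_i = 1 / (l_i' Cy^-1 l_i)` (`normalise = "none"`), or the unit-gain
#' variant `w_i = (l_i' l_i) / (l_i' Cy^-1 l_i)` (`normalise = "leadfield"`,
#' the default) which is robust to near-silent (near-radially oriented)
#' sources. Weights are normalised to unit sum (unit-trace component).
#'
#' @param reduced a `reduced_data`.
#' @param lambda_reg scaled-identity regularisation of the data covariance,
#'   `Cy = S + lambda_reg * tr(S)/m * I` (default 1e-4).
#' @param normalise `"leadfield"` or `"none"`.
#' @return object of class `prior_component` with `type = "diag"` and
#'   weights `w` over sources.
#' @export
build_prior_ebb <- function(reduced, lambda_reg = 1e-4,
                            normalise = c("leadfield", "none")) {
  normalise <- match.arg(normalise)
  m <- nrow(reduced$S)
  Cy <- reduced$S + lambda_reg * sum(diag(reduced$S)) / m * diag(m)
  R <- tryCatch(chol(Cy), error = function(e)
    stop("regularised data covariance is singular; condition number ~ ",
         format(kappa(Cy))))
  Ci <- chol2inv(R)
  A <- reduced$A
  denom <- colSums(A * (Ci %*% A))
  w <- if (normalise == "leadfield") colSums(A^2) / denom else 1 / denom
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  structure(list(label = "EBB", type = "diag", w = w), class = "prior_component")
}

#' Library of sparse cortical patch priors (MSP)
#'
#' One rank-one covariance component `q q'` per patch, from Gaussian patches
#' (default 5 mm FWHM) centred at uniformly sampled vertices of each surface
#' of the source model, plus any explicitly included vertices (e.g. the true
#' source locations for a matched, idealised library).
#'
#' @param model a `source_model` (see [source_model()]).
#' @param patch_fwhm_mm patch FWHM (mm, default 5).
#' @param n_patch_centres number of sampled centres per surface (default 128).
#' @param include_vertices optional integer vector of *global* source indices
#'   that must be patch centres.
#' @param seed seed for centre sampling.
#' @return list of `prior_component` objects with `type = "patch"`, each with
#'   `vertices` (global indices) and `q` weights; attribute `"centres"`
#'   stores the global centre indices.
#' @export
build_prior_msp_library <- function(model, patch_fwhm_mm = 5,
                                    n_patch_centres = 128,
                                    include_vertices = NULL, seed = 1) {
  if (n_patch_centres < 1) stop("'n_patch_centres' must be >= 1")
  comps <- list()
  centres_global <- integer(0)
  for (si in seq_along(model$meshes)) {
    mesh <- model$meshes[[si]]
    off <- model$offsets[si]
    nv <- nrow(mesh$vertices)
    centres <- with_seed(derive_seed(seed, "msp", names(model$meshes)[si]),
                         sample.int(nv, min(n_patch_centres, nv)))
    inc <- include_vertices[include_vertices > off &
                              include_vertices <= off + nv] - off
    centres <- unique(c(inc, centres))
    D <- geodesic_all(mesh, centres)
    sigma <- patch_fwhm_mm / 2.355
    for (j in seq_along(centres)) {
      d <- D[j, ]
      keep <- which(is.finite(d) & d <= patch_fwhm_mm)
      w <- exp(-d[keep]^2 / (2 * sigma^2))
      w <- w / sum(w)
      comps[[length(comps) + 1]] <-
        structure(list(label = sprintf("%s_patch_%d",
                                       names(model$meshes)[si], centres[j]),
                       type = "patch", vertices = keep + off, q = w,
                       centre = centres[j] + off),
                  class = "prior_component")
      centres_global <- c(centres_global, centres[j] + off)
    }
  }
  attr(comps, "centres") <- centres_global
  comps
}

#' Identity (minimum-norm-like) source covariance prior
#' @param n_sources number of sources in the model.
#' @export
build_prior_iid <- function(n_sources) {
  structure(list(label = "IID", type = "diag", w = rep(1 / n_sources, n_sources)),
            class = "prior_component")
}

#' Distance-decaying smooth (LORETA-like) source covariance prior
#'
#' Gaussian kernel of Euclidean inter-source distance, `exp(-d^2/(2 s^2))`;
#' positive semi-definite by construction.
#'
#' @param model a `source_model`.
#' @param sigma_mm kernel length scale (mm, default 10).
#' @export
build_prior_coh <- function(model, sigma_mm = 10) {
  D2 <- as.matrix(stats::dist(model$vertices))^2
  structure(list(label = "COH", type = "dense",
                 Q = exp(-D2 / (2 * sigma_mm^2))), class = "prior_component")
}

# project a source-space prior component into mode space (m x m), scaled to
# trace m so hyperparameters are comparable; returns NULL for null components
component_to_modes <- function(comp, A) {
  m <- nrow(A)
  G <- switch(comp$type,
    diag = tcrossprod(A * rep(sqrt(comp$w), each = m)),
    patch = tcrossprod(as.numeric(A[, comp$vertices, drop = FALSE] %*% comp$q)),
    dense = A %*% comp$Q %*% t(A),
    stop("unknown component type"))
  tr <- sum(diag(G))
  if (!is.finite(tr) || tr <= m * 1e-300) return(NULL)
  G * (m / tr)
}

# ---- ReML / free energy ----------------------------------------------------

gaussian_loglik <- function(S, N, C) {
  m <- nrow(C)
  R <- chol(C)
  logdet <- 2 * sum(log(diag(R)))
  Ci <- chol2inv(R)
  -N / 2 * (sum(Ci * S) + logdet + m * log(2 * pi))
}

# Fisher-scoring ReML over log hyperparameters with log-normal hyperpriors
# and monotone backtracking. Qs: list of m x m PSD components (component 1
# is conventionally the sensor-noise identity). Returns lambda, the Laplace
# free energy F, and the (non-decreasing) objective trace.
reml_fit <- function(S, N, Qs, eta = -4, prior_var = 16, max_iter = 64,
                     tol = 1e-4, lambda0 = NULL, fixed_lambda = NULL) {
  m <- nrow(S)
  k <- length(Qs)
  if (!is.null(fixed_lambda)) {
    C <- Reduce(`+`, Map(function(Q, l) exp(l) * Q, Qs, fixed_lambda))
    ll <- gaussian_loglik(S, N, C)
    return(list(lambda = fixed_lambda, F = ll, loglik = ll,
                objective_trace = ll, converged = TRUE))
  }
  Pi_ <- rep(1 / prior_var, k)
  objective <- function(lam) {
    C <- Reduce(`+`, Map(function(Q, l) exp(l) * Q, Qs, lam))
    ll <- tryCatch(gaussian_loglik(S, N, C), error = function(e) -Inf)
    ll - 0.5 * sum((lam - eta)^2 * Pi_)
  }
  lam <- lambda0 %||% rep(-log(k), k)
  obj <- objective(lam)
  trace_ <- obj
  converged <- FALSE
  H <- diag(Pi_, k)
  for (it in seq_len(max_iter)) {
    C <- Reduce(`+`, Map(function(Q, l) exp(l) * Q, Qs, lam))
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) break
    Ci <- chol2inv(R)
    CiS <- Ci %*% S
    M <- CiS %*% Ci                       # C^-1 S C^-1
    g <- numeric(k)
    dC <- vector("list", k)
    for (j in seq_len(k)) {
      dC[[j]] <- exp(lam[j]) * Qs[[j]]
      g[j] <- -N / 2 * (sum(Ci * dC[[j]]) - sum(M * dC[[j]])) -
        Pi_[j] * (lam[j] - eta)
    }
    H <- matrix(0, k, k)
    PdC <- lapply(dC, function(D) Ci %*% D)
    for (j in seq_len(k)) for (l in j:k) {
      H[j, l] <- H[l, j] <- N / 2 * sum(t(PdC[[j]]) * PdC[[l]])
    }
    H <- H + diag(Pi_, k)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    improved <- FALSE
    for (half in 0:11) {
      cand <- pmin(pmax(lam + step / 2^half, -32), 32)
      obj_cand <- objective(cand)
      if (obj_cand >= obj - 1e-9) { improved <- TRUE; break }
    }
    if (!improved) { converged <- TRUE; break }
    delta <- obj_cand - obj
    lam <- cand
    obj <- obj_cand
    trace_ <- c(trace_, obj)
    if (delta < tol && it > 1) { converged <- TRUE; break }
  }
  C <- Reduce(`+`, Map(function(Q, l) exp(l) * Q, Qs, lam))
  ll <- gaussian_loglik(S, N, C)
  # Laplace free energy: objective + 0.5 log |Sigma_lambda Pi|
  Fe <- obj + 0.5 * (sum(log(Pi_)) - determinant(H, logarithm = TRUE)$modulus[1])
  list(lambda = lam, F = as.numeric(Fe), loglik = ll,
       objective_trace = trace_, converged = converged)
}

# ---- source models ---------------------------------------------------------

#' Source model over one or two cortical surfaces
#'
#' Stacks the requested surfaces of a layered source space into a single
#' oriented source set (vertices + normals), remembering per-surface index
#' offsets; with both surfaces the vertex correspondence is `i <-> i + nv`.
#'
#' @param space a `source_space`.
#' @param surfaces character vector among `"pial"`, `"white"` (order kept).
#' @return object of class `source_model` with `vertices`, `normals`,
#'   `meshes`, `offsets`, `labels`.
#' @export
source_model <- function(space, surfaces = c("pial", "white")) {
  surfaces <- match.arg(surfaces, c("pial", "white"), several.ok = TRUE)
  meshes <- lapply(surfaces, function(s) cache_mesh_graph(space[[s]]))
  names(meshes) <- surfaces
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  offsets <- c(0L, cumsum(nv))[seq_along(nv)]
  structure(list(
    vertices = do.call(rbind, lapply(meshes, `[[`, "vertices")),
    normals = do.call(rbind, lapply(meshes, `[[`, "normals")),
    meshes = meshes, offsets = offsets,
    labels = rep(surfaces, nv),
    cache = new.env(parent = emptyenv())), class = "source_model")
}

# ---- inversion front end ---------------------------------------------------

#' Invert reduced sensor data onto a source model
#'
#' Builds the requested functional prior(s), optimises hyperparameters by
#' ReML and returns the variational free energy and the posterior projector.
#' For MSP, a greedy search adds one patch component at a time, each time
#' keeping the candidate that maximises free energy (ties broken by lowest
#' library index), until the improvement falls below `msp_min_gain`.
#'
#' @param reduced a `reduced_data` built with this model's lead field.
#' @param model the `source_model`.
#' @param method `"EBB"`, `"MSP"`, `"IID"` or `"COH"`.
#' @param priors optional pre-built prior list (MSP library) to avoid
#'   rebuilding across calls.
#' @param patch_fwhm_mm,n_patch_centres,include_vertices,seed MSP library
#'   parameters (used when `priors` is NULL).
#' @param max_iter,tol ReML iteration controls.
#' @param msp_max_components,msp_min_gain greedy search controls.
#' @param lambda_reg EBB covariance regularisation.
#' @param compute_posterior logical; compute the posterior source projector
#'   `M` with `J = M %*% Ymodes` (default TRUE).
#' @return object of class `inversion_result`: `F` (free energy, nats),
#'   `lambda` (log hyperparameters), `M` (sources x modes posterior
#'   projector, or NULL), `method`, `converged`, `components` (labels),
#'   `objective_trace`.
#' @export
reml_invert <- function(reduced, model, method = c("EBB", "MSP", "IID", "COH"),
                        priors = NULL, patch_fwhm_mm = 5, n_patch_centres = 128,
                        include_vertices = NULL, seed = 1,
                        max_iter = 64, tol = 1e-4,
                        msp_max_components = 8, msp_min_gain = 0.01,
                        lambda_reg = 1e-4, compute_posterior = TRUE) {
  method <- match.arg(method)
  A <- reduced$A
  m <- nrow(A)
  noise <- diag(m)
  if (method == "MSP") {
    if (is.null(priors))
      priors <- build_prior_msp_library(model, patch_fwhm_mm, n_patch_centres,
                                        include_vertices, seed)
    cand <- lapply(priors, component_to_modes, A = A)
    ok <- !vapply(cand, is.null, logical(1))
    priors <- priors[ok]; cand <- cand[ok]
    sel <- integer(0)
    fit <- reml_fit(reduced$S, reduced$N, list(noise), max_iter = max_iter, tol = tol)
    repeat {
      if (length(sel) >= msp_max_components || length(sel) == length(cand)) break
      remaining <- setdiff(seq_along(cand), sel)
      best <- NULL; bestF <- -Inf
      for (j in remaining) {
        f <- reml_fit(reduced$S, reduced$N, c(list(noise), cand[c(sel, j)]),
                      max_iter = 16, tol = tol,
                      lambda0 = c(fit$lambda, -2))
        if (f$F > bestF + 1e-12) { bestF <- f$F; best <- j }
      }
      if (is.null(best) || bestF <= fit$F + msp_min_gain) break
      sel <- c(sel, best)
      fit <- reml_fit(reduced$S, reduced$N, c(list(noise), cand[sel]),
                      max_iter = max_iter, tol = tol,
                      lambda0 = c(fit$lambda, -2))
    }
    used <- priors[sel]
    Qs <- c(list(noise), cand[sel])
  } else {
    prior <- if (!is.null(priors)) priors[[1]] else switch(method,
      EBB = build_prior_ebb(reduced, lambda_reg = lambda_reg),
      IID = build_prior_iid(ncol(A)),
      COH = {
        # the smoothness kernel depends only on the source geometry: cache it
        if (is.null(model$cache$coh))
          model$cache$coh <- build_prior_coh(model)
        model$cache$coh
      })
    used <- list(prior)
    Qs <- list(noise, component_to_modes(prior, A))
    if (is.null(Qs[[2]])) stop("prior component has zero gain through the lead field")
    fit <- reml_fit(reduced$S, reduced$N, Qs, max_iter = max_iter, tol = tol)
  }
  M <- NULL
  if (compute_posterior) {
    C <- Reduce(`+`, Map(function(Q, l) exp(l) * Q, Qs, fit$lambda))
    Ci <- chol2inv(chol(C))
    QAt <- matrix(0, ncol(A), m)
    if (length(fit$lambda) > 1) {
      for (j in seq_along(used)) {
        h <- exp(fit$lambda[j + 1])
        comp <- used[[j]]
        sc <- attr(Qs[[j + 1]], "src_scale") %||% 1
        QAt <- QAt + h * switch(comp$type,
          diag = {
            w <- comp$w * (m / mode_trace(comp, A))
            w * t(A)
          },
          patch = {
            a <- as.numeric(A[, comp$vertices, drop = FALSE] %*% comp$q)
            sc2 <- m / sum(a^2)
            out <- matrix(0, ncol(A), m)
            out[comp$vertices, ] <- sc2 * outer(comp$q, a)
            out
          },
          dense = {
            G <- A %*% comp$Q %*% t(A)
            (m / sum(diag(G))) * comp$Q %*% t(A)
          })
      }
    }
    M <- QAt %*% Ci
  }
  structure(list(F = fit$F, lambda = fit$lambda, M = M, method = method,
                 converged = fit$converged,
                 components = vapply(used, `[[`, character(1), "label"),
                 objective_trace = fit$objective_trace,
                 n_modes = m, N = reduced$N),
            class = "inversion_result")
}

mode_trace <- function(comp, A) {
  m <- nrow(A)
  switch(comp$type,
    diag = sum(colSums(A^2) * comp$w),
    patch = sum(as.numeric(A[, comp$vertices, drop = FALSE] %*% comp$q)^2),
    dense = sum(diag(A %*% comp$Q %*% t(A))))
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("inversion_result [%s]: F = %.3f nats, %d component(s)%s\n",
              x$method, x$F, length(x$components),
              if (x$converged) "" else " (non-converged)"))
  invisible(x)
}
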
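# Synthetic layered head geometry and sensor-array construction.
#
# The cortical sheet is emulated by nested near-parallel icosphere meshes
# (white, mid, pial) sharing one triangulation, surrounded by a scalp sphere
# on which magnetometers are packed. A smooth seeded radial "bump" field,
# identical across layers, makes the surfaces non-spherical so that vertex
# normals (= dipole orientations) acquire tangential components, as real
# cortical normals do. Purely radial dipoles are silent in a spherically
# symmetric conductor, so the bump is what gives the sources measurable
# fields.

# ---- basic meshes ----------------------------------------------------------

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midcache <- new.env(hash = TRUE, parent = emptyenv())
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    idx <- midcache[[key]]
    if (!is.null(idx)) return(idx)
    m <- unit((v[a, ] + v[b, ]) / 2)
    verts[[length(verts) + 1]] <<- m
    idx <- length(verts)
    midcache[[key]] <- idx
    idx
  }
  nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    nf[4 * i - 3, ] <- c(a, ab, ca)
    nf[4 * i - 2, ] <- c(b, bc, ab)
    nf[4 * i - 1, ] <- c(cc, ca, bc)
    nf[4 * i, ] <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, verts), faces = nf)
}

#' Unit icosphere
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected to the
#' unit sphere; has `10 * 4^subdivisions + 2` vertices.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0).
#' @return list with `vertices` (n x 3, unit norm) and `faces` (m x 3 indices).
#' @export
icosphere <- function(subdivisions) {
  if (subdivisions < 0) stop("'subdivisions' must be >= 0")
  mesh <- icosahedron()
  for (i in seq_len(subdivisions)) mesh <- subdivide_once(mesh)
  mesh
}

#' Construct a triangulated surface mesh with outward vertex normals
#'
#' @param vertices n x 3 matrix of positions (mm).
#' @param faces m x 3 integer matrix of triangle vertex indices.
#' @return object of class `surface_mesh` with fields `vertices`, `faces`,
#'   `normals` (unit outward vertex normals).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  e1 <- vertices[faces[, 2], ] - vertices[faces[, 1], ]
  e2 <- vertices[faces[, 3], ] - vertices[faces[, 1], ]
  fn <- cross_rows(e1, e2)            # area-weighted face normals
  areas <- row_norms(fn) / 2
  if (any(areas <= 0)) stop("degenerate (zero-area) triangle in mesh")
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    idx <- faces[, k]
    vn[, 1] <- vn[, 1] + tapply_sum(fn[, 1], idx, nrow(vertices))
    vn[, 2] <- vn[, 2] + tapply_sum(fn[, 2], idx, nrow(vertices))
    vn[, 3] <- vn[, 3] + tapply_sum(fn[, 3], idx, nrow(vertices))
  }
  vn <- normalize_rows(vn)
  centre <- colMeans(vertices)
  flip <- rowSums(vn * sweep(vertices, 2, centre)) < 0
  vn[flip, ] <- -vn[flip, ]
  structure(list(vertices = vertices, faces = faces, normals = vn),
            class = "surface_mesh")
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Smooth seeded scalar field on the unit sphere, scaled to max|.| = 1.
# Used as a radial perturbation shared by all layers.
bump_field <- function(directions, seed, n_lobes = 400L, width = 0.005) {
  coef <- with_seed(seed, list(a = stats::rnorm(n_lobes),
                               d = normalize_rows(matrix(stats::rnorm(3 * n_lobes), ncol = 3))))
  raw <- numeric(nrow(directions))
  for (j in seq_len(n_lobes))
    raw <- raw + coef$a[j] * exp((as.numeric(directions %*% coef$d[j, ]) - 1) / width)
  raw <- raw - mean(raw)
  m <- max(abs(raw))
  if (m == 0) raw else raw / m
}

#' Generate nested layered cortical geometry and a scalp surface
#'
#' Builds white, mid and pial surfaces as concentric perturbed icospheres with
#' identity vertex correspondence, plus a scalp sphere for sensor packing.
#' The radial bump pattern is identical on every layer, so the local
#' white-to-pial separation equals `pial_radius_mm - white_radius_mm`
#' everywhere, mimicking a cortical sheet of constant thickness.
#'
#' @param white_radius_mm,pial_radius_mm,scalp_radius_mm strictly increasing
#'   radii (mm); defaults 70/72/85 give a 2 mm layer separation in the range
#'   of human cortical thickness.
#' @param subdivisions icosphere subdivision level of the cortical layers
#'   (default 4: 2562 vertices per surface, ~4.7 mm vertex spacing).
#' @param bump_amplitude_mm maximal radial perturbation (mm); the default 6
#'   tilts vertex normals away from radial (median ~8 degrees) so sources
#'   have measurable fields; 0 gives exact spheres (whose sources are nearly
#'   silent in the spherical conductor).
#' @param seed seed for the bump pattern.
#' @param scalp_subdivisions subdivision level of the scalp mesh (default 3).
#' @return list with `space` (class `source_space`: `white`, `pial`, `mid`
#'   surface meshes) and `scalp` (a `surface_mesh` carrying canonical
#'   fiducial positions as attribute `"fiducials"`).
#' @export
make_head_geometry <- function(white_radius_mm = 70, pial_radius_mm = 72,
                               scalp_radius_mm = 85, subdivisions = 4,
                               bump_amplitude_mm = 6, seed = 1,
                               scalp_subdivisions = 3) {
  if (!(white_radius_mm > 0 && pial_radius_mm > white_radius_mm &&
        scalp_radius_mm > pial_radius_mm))
    stop("radii must satisfy 0 < white < pial < scalp")
  if (subdivisions < 1) stop("'subdivisions' must be >= 1")
  base <- icosphere(subdivisions)
  u <- base$vertices
  bump <- if (bump_amplitude_mm > 0)
    bump_amplitude_mm * bump_field(u, seed) else numeric(nrow(u))
  layer <- function(r) surface_mesh(u * (r + bump), base$faces)
  white <- layer(white_radius_mm)
  pial <- layer(pial_radius_mm)
  mid <- layer((white_radius_mm + pial_radius_mm) / 2)
  space <- structure(list(white = white, pial = pial, mid = mid,
                          n_vertices = nrow(u)),
                     class = "source_space")
  sc <- icosphere(scalp_subdivisions)
  scalp <- surface_mesh(sc$vertices * scalp_radius_mm, sc$faces)
  fid <- rbind(nasion = unit(c(0, 0.95, 0.31)),
               lpa = c(-1, 0, 0),
               rpa = c(1, 0, 0)) * scalp_radius_mm
  attr(scalp, "fiducials") <- fid
  list(space = space, scalp = scalp)
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: white/mid/pial surfaces, %d vertices each\n",
              x$n_vertices))
  invisible(x)
}

# ---- sensor arrays ---------------------------------------------------------

new_sensor_array <- function(positions, radial, anchors, fiducials,
                             n_axes = 1L, offset_mm = 0, axes = NULL) {
  fid <- as.matrix(fiducials)
  if (qr(sweep(fid, 2, colMeans(fid)))$rank < 2)
    stop("fiducials are collinear")
  if (is.null(axes)) {
    axes <- array(NA_real_, dim = c(nrow(positions), 3, 1))
    axes[, , 1] <- radial
  }
  structure(list(positions = positions, radial = radial, axes = axes,
                 n_axes = as.integer(n_axes), offset_mm = offset_mm,
                 anchors = anchors, fiducials = fid),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d sensors x %d axes = %d channels, offset %.1f mm\n",
              nrow(x$positions), x$n_axes, n_channels(x), x$offset_mm))
  invisible(x)
}

#' Number of channels of a sensor array (sensors x measurement axes)
#' @param array a `sensor_array`.
#' @export
n_channels <- function(array) nrow(array$positions) * array$n_axes

#' Pack sensors on a scalp surface at a minimum inter-sensor distance
#'
#' Farthest-point greedy selection over scalp mesh vertices: starting from a
#' seeded random vertex, the vertex farthest from the current set is added
#' until no vertex at distance >= `min_distance_mm` remains, yielding a
#' maximal packing (no further vertex can be added). Each sensor's radial
#' axis is the outward scalp normal at its vertex.
#'
#' @param scalp a `surface_mesh`.
#' @param min_distance_mm minimal pairwise Euclidean distance (mm).
#' @param seed seed for the starting vertex.
#' @return a `sensor_array` with a single radial axis and offset 0.
#' @export
pack_sensors <- function(scalp, min_distance_mm, seed = 1) {
  if (!inherits(scalp, "surface_mesh") || nrow(scalp$vertices) == 0)
    stop("'scalp' must be a non-empty surface_mesh")
  stopifnot_scalar(min_distance_mm, "min_distance_mm", lower = 1e-12)
  v <- scalp$vertices
  n <- nrow(v)
  start <- with_seed(seed, sample.int(n, 1))
  sel <- start
  mind <- row_norms(sweep(v, 2, v[start, ]))
  mind[start] <- 0
  repeat {
    nxt <- which.max(mind)              # ties -> lowest index
    if (mind[nxt] < min_distance_mm) break
    sel <- c(sel, nxt)
    d <- row_norms(sweep(v, 2, v[nxt, ]))
    mind <- pmin(mind, d)
  }
  fid <- attr(scalp, "fiducials")
  if (is.null(fid)) {
    r <- mean(row_norms(v))
    fid <- rbind(nasion = unit(c(0, 0.95, 0.31)), lpa = c(-1, 0, 0),
                 rpa = c(1, 0, 0)) * r
  }
  new_sensor_array(positions = v[sel, , drop = FALSE],
                   radial = scalp$normals[sel, , drop = FALSE],
                   anchors = v[sel, , drop = FALSE],
                   fiducials = fid)
}

#' Attach 1-3 orthonormal measurement axes to each sensor
#'
#' Axis 1 is the radial axis `[x, y, z]`. Axis 2 is the normalised tangential
#' direction `[y, -x, 0]`, orthogonal to the radial axis by construction.
#' Axis 3 is the cross product radial x axis2. Where the tangential formula
#' degenerates (radial parallel to z), axis 2 falls back to the projection of
#' `[1, 0, 0]` onto the tangent plane.
#'
#' @param array a `sensor_array` with unit radial axes.
#' @param n_axes 1, 2 or 3 measurement axes per sensor.
#' @return the array with `axes` (sensor x 3 x n_axes) and `n_axes` set.
#' @export
build_channel_axes <- function(array, n_axes) {
  if (!n_axes %in% 1:3) stop("'n_axes' must be 1, 2 or 3")
  r <- array$radial
  t1 <- cbind(r[, 2], -r[, 1], 0)
  nrm <- row_norms(t1)
  degen <- nrm < 1e-12
  if (any(degen)) {
    # fallback tangent: e_x projected onto the tangent plane
    proj <- cbind(1 - r[degen, 1]^2, -r[degen, 1] * r[degen, 2],
                  -r[degen, 1] * r[degen, 3])
    t1[degen, ] <- normalize_rows(matrix(proj, ncol = 3))
  }
  t1[!degen, ] <- t1[!degen, , drop = FALSE] / nrm[!degen]
  t2 <- cross_rows(r, t1)
  axes <- base::array(NA_real_, dim = c(nrow(r), 3, n_axes))
  axes[, , 1] <- r
  if (n_axes >= 2) axes[, , 2] <- t1
  if (n_axes >= 3) axes[, , 3] <- t2
  array$axes <- axes
  array$n_axes <- as.integer(n_axes)
  array
}

#' Reposition sensors along their radial axes to a target scalp offset
#'
#' Each sensor is placed at its scalp anchor point plus `target_offset_mm`
#' along its radial axis, so the along-axis distance to the scalp equals the
#' target. Measurement axes are unchanged.
#'
#' @param array a `sensor_array` (carrying scalp anchor points).
#' @param scalp the scalp `surface_mesh` (used to recover anchors if absent).
#' @param target_offset_mm desired scalp-sensor offset (mm, >= 0); typical
#'   values: 6.5 (on-scalp OPM), 20-40 (cryogenic MEG stand-ins).
#' @return the array with updated positions and `offset_mm`.
#' @export
offset_sensors <- function(array, scalp = NULL, target_offset_mm) {
  stopifnot_scalar(target_offset_mm, "target_offset_mm", lower = 0)
  anchors <- array$anchors
  if (is.null(anchors)) anchors <- array$positions - array$offset_mm * array$radial
  array$positions <- anchors + target_offset_mm * array$radial
  array$anchors <- anchors
  array$offset_mm <- target_offset_mm
  array
}

#' Keep the first `n` sensors of an array
#' @param array a `sensor_array`.
#' @param n number of sensors to keep.
#' @export
subset_sensors <- function(array, n) {
  if (n < 1 || n > nrow(array$positions)) stop("'n' out of range")
  idx <- seq_len(n)
  array$positions <- array$positions[idx, , drop = FALSE]
  array$radial <- array$radial[idx, , drop = FALSE]
  array$anchors <- array$anchors[idx, , drop = FALSE]
  array$axes <- array$axes[idx, , , drop = FALSE]
  array
}

# ---- rigid transforms and co-registration error ----------------------------

#' Least-squares rigid alignment (Kabsch) of paired point sets
#'
#' @param from,to n x 3 matrices of corresponding points.
#' @return class `rigid_transform`: list with `rotation` (3 x 3, det +1) and
#'   `translation` (length-3), mapping `from` onto `to` in the least-squares
#'   sense: `x %*% t(rotation) + translation`.
#' @export
fit_rigid_transform <- function(from, to) {
  cp <- colMeans(from); cq <- colMeans(to)
  H <- t(sweep(from, 2, cp)) %*% sweep(to, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp)),
            class = "rigid_transform")
}

apply_rigid <- function(points, tf) {
  sweep(points %*% t(tf$rotation), 2, tf$translation, `+`)
}

rotate_only <- function(vectors, tf) vectors %*% t(tf$rotation)

#' Simulate co-registration error via fiducial displacement
#'
#' Displaces each of the three fiducials by iid Gaussian noise per coordinate,
#' estimates the least-squares rigid transform from the true to the displaced
#' fiducials, and applies it to the whole (rigid) sensor array: positions,
#' anchors, and all measurement axes. This models the systematic array
#' misalignment a fiducial-based co-registration would produce.
#'
#' @param array a `sensor_array`.
#' @param sd_mm per-coordinate displacement standard deviation (mm, >= 0).
#' @param seed seed for the displacement draw.
#' @return list with the transformed `array`, the `transform`
#'   (`rigid_transform`) and the raw `displaced_fiducials`, for audit.
#' @export
perturb_fiducials <- function(array, sd_mm, seed = 1) {
  stopifnot_scalar(sd_mm, "sd_mm", lower = 0)
  fid <- array$fiducials
  disp <- with_seed(seed, matrix(stats::rnorm(9, 0, sd_mm), 3, 3))
  tf <- fit_rigid_transform(fid, fid + disp)
  array$positions <- apply_rigid(array$positions, tf)
  array$anchors <- apply_rigid(array$anchors, tf)
  array$radial <- rotate_only(array$radial, tf)
  for (k in seq_len(dim(array$axes)[3]))
    array$axes[, , k] <- rotate_only(array$axes[, , k], tf)
  array$fiducials <- apply_rigid(fid, tf)
  list(array = array, transform = tf, displaced_fiducials = fid + disp)
}

# ---- alternative generative model geometry ---------------------------------

#' Perturbed geometry for an alternative generative model (AGM)
#'
#' Returns a simulation-side geometry that deliberately mismatches the
#' reconstruction model, avoiding the "inverse crime" of simulating and
#' inverting with identical forward models: (1) sensor positions receive iid
#' Gaussian jitter (axes re-orthonormalised), and (2) when the requested
#' alternative source-sampling density differs from the reconstruction one,
#' the source meshes are rigidly rotated by half the mean inter-vertex
#' angular spacing about a seeded random axis, so simulated dipole positions
#' fall between reconstruction vertices.
#'
#' @param space a `source_space`.
#' @param array a `sensor_array`.
#' @param sensor_jitter_sd_mm per-coordinate sensor jitter (mm; default 1).
#' @param alt_vertex_fraction nominal vertex fraction of the simulation mesh
#'   relative to a dense base mesh (default 0.11).
#' @param recon_vertex_fraction same for the reconstruction mesh (default
#'   0.10); equal fractions and zero jitter leave the geometry untouched.
#' @param seed seed for jitter and rotation axis.
#' @return list with perturbed `space` and `array`.
#' @export
make_alternative_geometry <- function(space, array, sensor_jitter_sd_mm = 1,
                                      alt_vertex_fraction = 0.11,
                                      recon_vertex_fraction = 0.10,
                                      seed = 1) {
  if (alt_vertex_fraction <= 0 || alt_vertex_fraction > 1)
    stop("'alt_vertex_fraction' must be in (0, 1]")
  seeds <- c(derive_seed(seed, "agm_jitter"), derive_seed(seed, "agm_rot"))
  if (sensor_jitter_sd_mm > 0) {
    jit <- with_seed(seeds[1],
                     matrix(stats::rnorm(length(array$positions), 0, sensor_jitter_sd_mm),
                            ncol = 3))
    array$positions <- array$positions + jit
    array$axes <- reorthonormalize_axes(array$axes)
    array$radial <- array$axes[, , 1]
  }
  if (abs(alt_vertex_fraction - recon_vertex_fraction) > 1e-12) {
    v <- space$white$vertices
    f <- space$white$faces
    edge <- row_norms(v[f[, 2], ] - v[f[, 1], ])
    theta <- 0.5 * mean(edge) / mean(row_norms(v))
    ax <- with_seed(seeds[2], unit(stats::rnorm(3)))
    R <- rotation_about_axis(ax, theta)
    tf <- structure(list(rotation = R, translation = c(0, 0, 0)),
                    class = "rigid_transform")
    for (nm in c("white", "pial", "mid")) {
      space[[nm]]$vertices <- apply_rigid(space[[nm]]$vertices, tf)
      space[[nm]]$normals <- rotate_only(space[[nm]]$normals, tf)
    }
  }
  list(space = space, array = array)
}

reorthonormalize_axes <- function(axes) {
  k <- dim(axes)[3]
  a1 <- normalize_rows(axes[, , 1])
  axes[, , 1] <- a1
  if (k >= 2) {
    a2 <- axes[, , 2] - rowSums(axes[, , 2] * a1) * a1
    a2 <- normalize_rows(a2)
    axes[, , 2] <- a2
    if (k >= 3) axes[, , 3] <- cross_rows(a1, a2)
  }
  axes
}

rotation_about_axis <- function(axis, theta) {
  u <- unit(axis)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
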
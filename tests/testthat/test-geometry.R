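# Synthetic head geometry, sensor packing, channel axes, offsets and
# co-registration error model.

test_that("icosphere layers have the expected vertex counts and radii", {
  geo <- make_head_geometry(subdivisions = 3, bump_amplitude_mm = 0, seed = 1)
  expect_equal(geo$space$n_vertices, 10 * 4^3 + 2)   # 642
  expect_equal(nrow(geo$space$white$vertices), 642)
  # exact sphere when the bump is off
  expect_lt(max(abs(sqrt(rowSums(geo$space$pial$vertices^2)) - 72)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(geo$space$white$vertices^2)) - 70)), 1e-9)
})

test_that("bump perturbation preserves the per-vertex layer separation", {
  geo <- make_head_geometry(subdivisions = 3, bump_amplitude_mm = 6, seed = 7)
  rp <- sqrt(rowSums(geo$space$pial$vertices^2))
  rw <- sqrt(rowSums(geo$space$white$vertices^2))
  rm <- sqrt(rowSums(geo$space$mid$vertices^2))
  expect_lt(max(abs(rp - rw - 2)), 1e-9)             # bump cancels
  expect_true(all(rm > rw & rm < rp))                # mid between layers
  expect_gt(max(abs(rp - 72)), 1)                    # actually non-spherical
  # normals are unit length and outward
  for (s in c("white", "pial", "mid")) {
    n <- geo$space[[s]]$normals
    expect_lt(max(abs(sqrt(rowSums(n^2)) - 1)), 1e-9)
    expect_true(all(rowSums(n * geo$space[[s]]$vertices) > 0))
  }
})

test_that("invalid geometry arguments are rejected", {
  expect_error(make_head_geometry(white_radius_mm = 80, pial_radius_mm = 72),
               "radii")
  expect_error(make_head_geometry(subdivisions = 0), "subdivisions")
})

test_that("sensor packing respects the minimum distance and is maximal", {
  geo <- tiny_head()
  for (dmin in c(25, 55)) {
    arr <- pack_sensors(geo$scalp, dmin, seed = 3)
    p <- arr$positions
    dm <- as.matrix(dist(p))
    diag(dm) <- Inf
    expect_true(all(dm >= dmin))                     # O(n^2) oracle
    # maximality: every unchosen scalp vertex is within dmin of a sensor
    v <- geo$scalp$vertices
    mind <- apply(v, 1, function(x) min(sqrt(colSums((t(p) - x)^2))))
    expect_true(all(mind < dmin))
  }
})

test_that("halving the packing distance never decreases the sensor count", {
  geo <- tiny_head()
  for (dmin in c(60, 40, 30)) {
    n1 <- nrow(pack_sensors(geo$scalp, dmin, seed = 5)$positions)
    n2 <- nrow(pack_sensors(geo$scalp, dmin / 2, seed = 5)$positions)
    expect_gte(n2, n1)
  }
  # a distance beyond the scalp diameter leaves a single sensor
  arr1 <- pack_sensors(geo$scalp, 1000, seed = 5)
  expect_equal(nrow(arr1$positions), 1)
})

test_that("packing is deterministic given the seed", {
  geo <- tiny_head()
  a <- pack_sensors(geo$scalp, 35, seed = 9)
  b <- pack_sensors(geo$scalp, 35, seed = 9)
  expect_identical(a$positions, b$positions)
})

test_that("tangential channel axes follow the [y, -x, 0] construction", {
  fid <- rbind(c(0, 80, 20), c(-80, 0, 0), c(80, 0, 0))
  mk <- function(radial) {
    opmlaminar:::new_sensor_array(positions = matrix(radial * 100, 1),
                                  radial = matrix(radial, 1),
                                  anchors = matrix(radial * 100, 1),
                                  fiducials = fid)
  }
  arr <- build_channel_axes(mk(c(1, 0, 0)), 3)
  expect_equal(as.numeric(arr$axes[1, , 2]), c(0, -1, 0), tolerance = 1e-12)
  expect_equal(as.numeric(arr$axes[1, , 3]), c(0, 0, -1), tolerance = 1e-12)
  # degenerate case: radial along z falls back to an orthonormal tangent pair
  arr <- build_channel_axes(mk(c(0, 0, 1)), 3)
  G <- t(arr$axes[1, , ]) %*% arr$axes[1, , ]
  expect_lt(max(abs(G - diag(3))), 1e-9)
})

test_that("channel axes are orthonormal across a whole packed array", {
  for (k in 1:3) {
    arr <- tiny_array(n_axes = k)
    for (i in seq_len(nrow(arr$positions))) {
      A <- matrix(arr$axes[i, , ], nrow = 3)
      G <- t(A) %*% A
      expect_lt(max(abs(G - diag(k))), 1e-9)
      if (k >= 2)
        expect_lt(abs(sum(arr$axes[i, , 1] * arr$axes[i, , 2])), 1e-12)
    }
  }
  expect_error(build_channel_axes(tiny_array(), 4), "n_axes")
})

test_that("offsetting moves sensors to the requested along-axis scalp distance", {
  geo <- tiny_head()
  arr <- tiny_array(offset = 6.5)
  # identity when the target equals the current offset
  arr2 <- offset_sensors(arr, geo$scalp, 6.5)
  expect_lt(max(abs(arr2$positions - arr$positions)), 1e-9)
  # offsets used in the off-scalp sweeps, checked by a ray-sphere oracle on
  # the exact-sphere scalp (radius 85): the along-axis distance from the
  # sensor to the sphere must equal the target offset
  for (target in c(6.5, 20, 30, 40)) {
    a3 <- offset_sensors(arr, geo$scalp, target)
    for (i in seq_len(nrow(a3$positions))) {
      p <- a3$positions[i, ]; u <- a3$radial[i, ]
      # smallest positive t with |p - t u| = 85
      tt <- polyroot(c(sum(p^2) - 85^2, -2 * sum(p * u), 1))
      tt <- Re(tt[abs(Im(tt)) < 1e-9])
      tt <- min(tt[tt > 0])
      expect_lt(abs(tt - target), 1e-6)
    }
  }
})

test_that("zero fiducial error is an exact no-op on the array", {
  arr <- tiny_array(n_axes = 2)
  out <- perturb_fiducials(arr, sd_mm = 0, seed = 4)
  expect_lt(max(abs(out$array$positions - arr$positions)), 1e-9)
  expect_lt(max(abs(out$array$axes - arr$axes)), 1e-9)
  expect_lt(max(abs(out$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(out$transform$translation)), 1e-9)
})

test_that("fiducial displacement statistics match the chi-squared expectation", {
  # each fiducial moves by iid N(0, sd^2) per coordinate, so the expected
  # squared displacement per fiducial is 3 sd^2
  arr <- tiny_array()
  sd_mm <- 2
  n <- 10000
  msd <- 0
  for (s in seq_len(n)) {
    out <- perturb_fiducials(arr, sd_mm, seed = s)
    msd <- msd + mean(rowSums((out$displaced_fiducials - arr$fiducials)^2))
  }
  msd <- msd / n
  expect_lt(abs(msd / (3 * sd_mm^2) - 1), 0.02)
  # and the rotation is always proper
  out <- perturb_fiducials(arr, 4, seed = 99)
  expect_lt(abs(det(out$transform$rotation) - 1), 1e-9)
})

test_that("fiducial errors of 1-4 mm displace the array increasingly", {
  arr <- tiny_array()
  shift <- vapply(1:4, function(sd_mm) {
    mean(vapply(1:20, function(s) {
      out <- perturb_fiducials(arr, sd_mm, seed = s)
      mean(sqrt(rowSums((out$array$positions - arr$positions)^2)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(shift) > 0))
})

test_that("alternative generative model geometry perturbs as configured", {
  geo <- tiny_head()
  arr <- tiny_array(n_axes = 3)
  # no jitter, matching vertex fractions: exact identity
  same <- make_alternative_geometry(geo$space, arr, sensor_jitter_sd_mm = 0,
                                    alt_vertex_fraction = 0.10,
                                    recon_vertex_fraction = 0.10, seed = 2)
  expect_identical(same$space$pial$vertices, geo$space$pial$vertices)
  expect_identical(same$array$positions, arr$positions)
  # 1 mm jitter: per-coordinate displacement std within 5% over 100 seeds
  disp <- unlist(lapply(1:100, function(s) {
    agm <- make_alternative_geometry(geo$space, arr, sensor_jitter_sd_mm = 1,
                                     seed = s)
    agm$array$positions - arr$positions
  }))
  expect_lt(abs(sd(disp) - 1), 0.05)
  # differing fractions: simulation vertices no longer coincide with the
  # reconstruction source space
  agm <- make_alternative_geometry(geo$space, arr, seed = 2)
  d <- sqrt(rowSums((agm$space$pial$vertices - geo$space$pial$vertices)^2))
  expect_true(all(d > 0.1))
  # axes remain orthonormal after jitter
  G <- t(agm$array$axes[1, , ]) %*% agm$array$axes[1, , ]
  expect_lt(max(abs(G - diag(3))), 1e-9)
  expect_error(make_alternative_geometry(geo$space, arr,
                                         alt_vertex_fraction = 1.5), "fraction")
})
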
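# Analytic forward model: magnetic field of a current dipole in a
# homogeneous spherically symmetric conductor (Sarvas closed form), projected
# onto each sensor's measurement axes.
#
# Conventions: positions in mm, dipole moments in nAm, fields in fT. In a
# spherical conductor the field outside is independent of the conductivity
# profile, and radial dipoles produce no external field.

#' Spherically symmetric volume conductor
#'
#' @param centre conductor centre (mm, length-3).
#' @param radius_mm conductor radius (mm, > 0); sources must be strictly
#'   inside and field points strictly outside.
#' @return object of class `head_conductor`.
#' @export
head_conductor <- function(centre = c(0, 0, 0), radius_mm = 80) {
  stopifnot_scalar(radius_mm, "radius_mm", lower = 1e-9)
  structure(list(centre = as.numeric(centre), radius = radius_mm),
            class = "head_conductor")
}

MU0_OVER_4PI <- 1e-7  # T m / A

# Vectorised Sarvas field. rs: n x 3 field points (mm, relative coordinates
# handled internally), r0: dipole position (mm), q: dipole moment (nAm).
# Returns n x 3 field in fT.
sarvas_field <- function(rs, r0, q, centre) {
  rs <- sweep(matrix(rs, ncol = 3), 2, centre) * 1e-3   # m
  r0 <- (r0 - centre) * 1e-3                            # m
  qm <- q * 1e-9                                        # A m
  a_vec <- rs - matrix(r0, nrow(rs), 3, byrow = TRUE)
  a <- row_norms(a_vec)
  r <- row_norms(rs)
  if (any(a < 1e-12)) stop("field point coincides with the dipole")
  ar <- rowSums(a_vec * rs)       # a . r
  r0r <- as.numeric(rs %*% r0)    # r0 . r
  F_ <- a * (r * a + r^2 - r0r)
  gradF <- (a^2 / r + ar / a + 2 * a + 2 * r) * rs -
    (a + 2 * r + ar / a) * matrix(r0, nrow(rs), 3, byrow = TRUE)
  qxr0 <- cross3(qm, r0)
  qxr0_dot_r <- as.numeric(rs %*% qxr0)
  B <- (MU0_OVER_4PI / F_^2) *
    (F_ * matrix(qxr0, nrow(rs), 3, byrow = TRUE) - qxr0_dot_r * gradF)
  B * 1e15                                              # fT
}

#' Magnetic field of a current dipole in a conducting sphere
#'
#' Sarvas closed-form field of a current dipole inside a homogeneous
#' spherically symmetric conductor, evaluated at external field points.
#' Radial dipoles and dipoles at the conductor centre produce exactly zero
#' external field.
#'
#' @param conductor a `head_conductor`.
#' @param dipole_pos dipole position (mm, strictly inside the conductor).
#' @param dipole_moment dipole moment vector (nAm).
#' @param field_points n x 3 matrix (or length-3 vector) of field points
#'   (mm, strictly outside the conductor).
#' @return n x 3 matrix of magnetic field vectors (fT).
#' @export
dipole_field <- function(conductor, dipole_pos, dipole_moment, field_points) {
  field_points <- matrix(field_points, ncol = 3)
  rel_src <- sqrt(sum((dipole_pos - conductor$centre)^2))
  if (rel_src >= conductor$radius)
    stop("dipole must be strictly inside the conductor")
  rel_fp <- row_norms(sweep(field_points, 2, conductor$centre))
  if (any(rel_fp <= conductor$radius))
    stop("field points must be strictly outside the conductor")
  sarvas_field(field_points, dipole_pos, dipole_moment, conductor$centre)
}

#' Assemble the lead-field (gain) matrix for oriented cortical sources
#'
#' Entry (c, s) is the field of a unit dipole (1 nAm) at source s, oriented
#' along its surface normal, dotted with channel c's unit measurement axis.
#' Channels are ordered sensor-major (all axes of sensor 1, then sensor 2,
#' ...). Units: fT per nAm.
#'
#' @param sources either a `surface_mesh` or a list with `vertices` and
#'   `normals` matrices (positions mm, unit orientation vectors).
#' @param array a `sensor_array`.
#' @param conductor a `head_conductor`; all sources must be strictly inside
#'   and all sensors strictly outside.
#' @return object of class `lead_field`: list with `gain`
#'   (n_channels x n_sources), `channels` (data.frame: channel, sensor,
#'   axis), `sources` (positions and orientations), and `forward = "sphere"`.
#' @export
assemble_leadfield <- function(sources, array, conductor) {
  pos <- sources$vertices
  ori <- sources$normals
  rel_src <- row_norms(sweep(pos, 2, conductor$centre))
  if (any(rel_src >= conductor$radius))
    stop("all sources must be strictly inside the conductor")
  rel_sen <- row_norms(sweep(array$positions, 2, conductor$centre))
  bad <- which(rel_sen <= conductor$radius)
  if (length(bad))
    stop(sprintf("sensor(s) inside the conductor: %s",
                 paste(bad, collapse = ", ")))
  ns <- nrow(array$positions)
  ka <- array$n_axes
  nsrc <- nrow(pos)
  gain <- matrix(0, ns * ka, nsrc)
  # axis matrix aligned with sensor-major channel ordering
  ax <- matrix(0, ns * ka, 3)
  for (k in seq_len(ka))
    ax[seq(k, by = ka, length.out = ns), ] <- array$axes[, , k]
  sen <- array$positions[rep(seq_len(ns), each = ka), , drop = FALSE]
  for (s in seq_len(nsrc)) {
    B <- sarvas_field(sen, pos[s, ], ori[s, ], conductor$centre)
    gain[, s] <- rowSums(B * ax)
  }
  channels <- data.frame(
    channel = paste0("S", formatC(rep(seq_len(ns), each = ka), width = 3, flag = "0"),
                     "_ax", rep(seq_len(ka), ns)),
    sensor = rep(seq_len(ns), each = ka),
    axis = rep(seq_len(ka), ns))
  structure(list(gain = gain, channels = channels,
                 sources = list(positions = pos, orientations = ori),
                 forward = "sphere"),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d channels x %d sources (fT/nAm, %s conductor)\n",
              nrow(x$gain), ncol(x$gain), x$forward))
  invisible(x)
}
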
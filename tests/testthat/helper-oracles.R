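# independent oracles and fixture builders used across the suite

# Brute-force dihedral oracle: the dihedral of x1-x2-x3-x4 is the angle by
# which x4's azimuth about the x2->x3 axis differs from x1's, measured
# clockwise when viewing from x2 towards x3.  Built here from explicit
# projections, independent of the package's two-plane construction.
oracle_dihedral <- function(p1, p2, p3, p4) {
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  proj <- function(p, origin) {
    v <- p - origin
    v - sum(v * axis) * axis
  }
  u <- proj(p1, p2)
  w <- proj(p4, p3)
  cross <- c(u[2] * w[3] - u[3] * w[2],
             u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])
  -atan2(sum(cross * axis), sum(u * w)) * 180 / pi
}

# rotate a point about a unit axis through the origin (Rodrigues)
rotate_about <- function(p, axis, angle_deg) {
  a <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  p * cos(a) + c(axis[2] * p[3] - axis[3] * p[2],
                 axis[3] * p[1] - axis[1] * p[3],
                 axis[1] * p[2] - axis[2] * p[1]) * sin(a) +
    axis * sum(axis * p) * (1 - cos(a))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}

# build a trajectory directly from prescribed twist/wag series
angle_trajectory <- function(id, alpha, beta, times = seq_along(alpha) - 1,
                             states = NULL, hops = NULL) {
  trajectory(id, embed_xyz(alpha, beta), times, states, hops = hops,
             meta = list(atom_labels = c("C", "C", "C", "C", "H", "H")))
}

# minimal decay-record tibble for the statistics operations
make_records <- function(dtau, reactive, hop_time = seq_along(dtau) * 10) {
  out <- tibble::tibble(
    traj_id = sprintf("t%02d", seq_along(dtau)),
    hop_time = hop_time,
    dtau_decay = dtau,
    outcome = ifelse(reactive, "reactive", "unreactive"),
    velocity_defined = TRUE
  )
  attr(out, "n_total") <- nrow(out)
  out
}
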
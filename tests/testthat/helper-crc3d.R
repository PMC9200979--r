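# shared fixtures and small utilities for the test suite

# deterministic uniform random rotation matrices
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3)
}

# wrap a standalone mesh as a root segment for the measurement operations
as_segment <- function(mesh, attachment = NULL) {
  structure(list(mesh = mesh, volume = abs(signed_volume(mesh, check = FALSE)),
                 attachment_point = attachment, fused = FALSE),
            class = "root_segment")
}

# a small separated-root crown specification used by the dissection tests:
# five storage roots at 72 degree spacing, moderate taper
separated_crown_spec <- function(seed, curvature = 0) {
  crown_spec(n_roots = 5, curvature = curvature,
             basal_radius = 2.5, tip_radius = 1,
             length = c(22, 26, 30, 24, 28),
             inclination = c(25, 35, 45, 30, 40), seed = seed)
}

# match dissected segments to generator roots by tip proximity
match_segments_to_truth <- function(segs, crown) {
  spec <- crown$spec
  tips <- t(vapply(seq_len(spec$n_roots), function(i) {
    cl <- crc3d:::root_centerline(spec$azimuth[i], spec$inclination[i],
                                  spec$length[i], spec$curvature[i],
                                  spec$mesh_resolution,
                                  start = c(0, 0, -max(0, spec$hub_radius - 1)))
    cl[nrow(cl), ]
  }, numeric(3)))
  seg_tips <- t(vapply(segs, function(s) {
    v <- s$mesh$vertices
    v[which.max(v[, 1]^2 + v[, 2]^2), ]
  }, numeric(3)))
  apply(seg_tips, 1L, function(p) which.min(colSums((t(tips) - p)^2)))
}
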
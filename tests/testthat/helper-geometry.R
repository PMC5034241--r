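# shared geometric utilities for the tests

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(coords, rot, shift) {
  sweep(coords %*% t(rot), 2, -shift)
}

# straight chain of n points along a unit direction, given bond length
straight_chain <- function(n, bond = 3.8, origin = c(0, 0, 0),
                           dir = c(1, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  t(sapply(seq_len(n) - 1, function(i) origin + i * bond * dir))
}

# compact helical toy chain (protein-like spacing, no clashes)
helix_chain <- function(n, bond = 3.8, origin = c(0, 0, 0)) {
  # rise and radius chosen so consecutive points are `bond` apart
  radius <- 2.3
  turn <- 100 * pi / 180
  rise <- sqrt(bond^2 - (2 * radius * sin(turn / 2))^2)
  t(sapply(seq_len(n) - 1, function(i) {
    origin + c(radius * cos(i * turn), radius * sin(i * turn), i * rise)
  }))
}

gauss_closed_value <- function(a, b) {
  gauss_double_sum(to_segments(a, closed = TRUE),
                   to_segments(b, closed = TRUE))$value
}
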
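# Independent numerical oracles shared across test files.

# hierarchical search over Euler-angle rotations with optimal (centroid)
# translation at each candidate: an exhaustive-grid stand-in for the
# closed-form Kabsch solution
grid_rmsd_oracle <- function(P, Q, levels = 6) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  euler_R <- function(a, b, c) {
    rotation_about_axis(c(0, 0, 1), a) %*%
      rotation_about_axis(c(0, 1, 0), b) %*%
      rotation_about_axis(c(1, 0, 0), c)
  }
  center <- c(0, 0, 0)
  width <- 180
  best <- Inf
  for (lev in seq_len(levels)) {
    grid <- seq(-width, width, length.out = 7)
    best_angles <- center
    for (a in center[1] + grid) for (b in center[2] + grid / 2)
      for (c in center[3] + grid) {
        R <- euler_R(a, b, c)
        r <- sqrt(mean(rowSums((Qc %*% t(R) - Pc)^2)))
        if (r < best) { best <- r; best_angles <- c(a, b, c) }
      }
    center <- best_angles
    width <- width / 3
  }
  best
}

# closed-form exposed solvent-sphere areas of two intersecting spheres
two_sphere_exposed <- function(R1, R2, d) {
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * max(0, h1),
    4 * pi * R2^2 - 2 * pi * R2 * max(0, h2))
}
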
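# Independent analytic / brute-force oracles used across the suite.
# These deliberately avoid the package's own estimator code paths.

# Closed-form volume of the lens-shaped intersection of two spheres.
lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
}

sphere_volume <- function(r) 4 / 3 * pi * r^3

# Rotation matrix about an arbitrary axis (Rodrigues), independent of the
# package's internal helper.
axis_rotation <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  axis_rotation(stats::rnorm(3), stats::runif(1, 0, pi))
}

# Closed-form overlap integral of two spherical Gaussians with amplitude p
# and exponents chosen so each integrates to its hard-sphere volume;
# evaluated symbolically for a single atom pair at distance d.
single_pair_gaussian_overlap <- function(r1, r2, d, p = 2.7) {
  a1 <- pi * (3 * p / (4 * pi * r1^3))^(2 / 3)
  a2 <- pi * (3 * p / (4 * pi * r2^3))^(2 / 3)
  p^2 * exp(-a1 * a2 / (a1 + a2) * d^2) * (pi / (a1 + a2))^1.5
}

# Exhaustive 10-degree ZYZ Euler grid search over proper rotations with
# centroids superposed; the brute-force oracle for chiral alignment.
so3_grid_best_overlap <- function(ref, probe, step = pi / 18) {
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  A <- sweep(ref$xyz, 2, colMeans(ref$xyz))
  B <- sweep(probe$xyz, 2, colMeans(probe$xyz))
  ga <- poseoverlap:::gauss_overlap_xyz
  best <- -Inf
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step, by = step)) {
        v <- ga(A, ref$radius, B %*% t(Rz(a) %*% Ry(b) %*% Rz(g)), probe$radius)
        if (v > best) best <- v
      }
  best
}

# Small single-sphere pose at a given center.
sphere_pose <- function(id, r, center = c(0, 0, 0)) {
  molecule_pose(id, "X", matrix(center, 1, 3), radius = r)
}

# A seeded random multi-atom pose with radii assigned directly.
random_pose <- function(id, n = 10, seed = 1, sd = 2,
                        radii = c(1.2, 1.52, 1.55, 1.7, 2.05)) {
  withr::with_seed(seed, {
    molecule_pose(id, sample(c("C", "N", "O", "H"), n, replace = TRUE),
                  matrix(stats::rnorm(3 * n, sd = sd), n, 3),
                  radius = sample(radii, n, replace = TRUE))
  })
}
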
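# Independent geometric oracles and small fixture builders used across the
# suite. Everything here is derived from first principles (Rodrigues
# formula, direct objective minimisation) so it cannot inherit a defect
# from the package's own closed-form implementations.

# Rodrigues rotation matrix about a (unit) axis.
rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rot_axis_angle(ax, stats::runif(1, 0, pi))
}

# Sum-of-squares registration objective for a candidate (R, t).
rigid_objective <- function(src, dst, R, t) {
  pred <- src %*% t(R) + matrix(t, nrow(src), 3, byrow = TRUE)
  sum((dst - pred)^2)
}

# Brute-force numeric minimiser over axis-angle + translation, multi-start
# Nelder-Mead refined by BFGS. Independent check of the closed-form SVD
# solution.
brute_force_rigid <- function(src, dst) {
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    R <- if (th < 1e-12) diag(3) else rot_axis_angle(par[1:3] / th, th)
    rigid_objective(src, dst, R, par[4:6])
  }
  t0 <- colMeans(dst) - colMeans(src)
  starts <- list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0), c(0, 0, pi / 2),
                 c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi),
                 c(pi / 2, pi / 2, 0), c(0, pi / 2, pi / 2))
  best <- Inf
  for (s in starts) {
    o <- stats::optim(c(s, t0), obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
    if (o$value < best) best <- o$value
  }
  best
}

# A generic non-degenerate 4-point cloud (mm scale of a marker cluster).
cloud4 <- function() {
  rbind(c(0, 0, 0), c(100, 10, -5), c(20, 90, 15), c(-10, 25, 110))
}

# Noiseless rigid cluster motion: 4 local points swept through a smooth
# rotation + translation, as a mocap_traj.
rigid_cluster_motion <- function(n = 100, frame_rate = 100) {
  local <- cloud4()
  pos <- array(NA_real_, dim = c(n, 4, 3))
  for (f in seq_len(n)) {
    ang <- 0.8 * sin(2 * pi * (f - 1) / n)
    R <- rot_axis_angle(c(0.2, 1, 0.4), ang)
    t <- c(5 * (f - 1) / n * 100, 300 + 50 * sin(2 * pi * (f - 1) / n), -40)
    pos[f, , ] <- local %*% t(R) + matrix(t, 4, 3, byrow = TRUE)
  }
  mocap_traj(pos, labels = paste0("M", 1:4), frame_rate = frame_rate)
}

# RMS difference between two equal-length vectors.
rmse <- function(x, y) sqrt(mean((x - y)^2))

# Angle RMSE of a pipeline run against the generator's ground truth,
# restricted to valid frames; returns per-angle values in degrees.
angle_rmse <- function(result, truth) {
  ok <- result$angles$valid
  c(alpha = rmse(result$angles$alpha_deg[ok], truth$alpha_deg[ok]),
    beta  = rmse(result$angles$beta_deg[ok], truth$beta_deg[ok]),
    gamma = rmse(result$angles$gamma_deg[ok], truth$gamma_deg[ok]))
}
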
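# Shared fixtures and independent oracles, built in code.

# Simple test camera: 1000 px focal, principal point at (500, 500).
test_camera <- function(id = "C1", R = diag(3), t = c(0, 0, 0),
                        fx = 1000, fy = 1000, cx = 500, cy = 500,
                        width = 1000, height = 1000,
                        k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  camera(id,
         intrinsics(fx, fy, cx, cy, width, height, k1, k2, k3, p1, p2),
         pose(R, t))
}

# Random proper rotation from a random axis and angle.
random_rotation <- function() {
  axis <- normalize_vec(stats::rnorm(3))
  theta <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

normalize_vec <- function(v) v / sqrt(sum(v^2))

# Independent brute-force oracle for the ray least-squares problem:
# zooming grid search on the sum of squared point-to-ray distances,
# refined down to a 5e-6 step. Shares no code with triangulate_rays().
grid_triangulate <- function(rays, start = c(0, 0, 0)) {
  cost <- function(P) {  # P: n x 3 candidate points
    tot <- numeric(nrow(P))
    for (r in rays) {
      V <- sweep(P, 2, r$origin)
      tot <- tot + rowSums(V^2) - as.numeric(V %*% r$direction)^2
    }
    tot
  }
  best <- start
  for (step in c(0.1, 0.02, 4e-3, 1e-3, 2e-4, 4e-5, 1e-5, 5e-6)) {
    g <- seq(-10, 10) * step
    cand <- as.matrix(expand.grid(x = best[1] + g, y = best[2] + g,
                                  z = best[3] + g))
    best <- cand[which.min(cost(cand)), ]
  }
  unname(best)
}

# Perpendicular distance from a point to a ray (rejection form: stable
# when the point lies almost exactly on the ray).
point_ray_distance <- function(point, r) {
  v <- point - r$origin
  sqrt(sum((v - sum(v * r$direction) * r$direction)^2))
}

# Apply one rigid world transform X' = R0 X + t0 to every camera pose:
# the new world-to-camera maps are R' = R R0', t' = t - R R0' t0.
transform_project_poses <- function(project, R0, t0) {
  project$cameras <- lapply(project$cameras, function(cm) {
    Rn <- cm$pose$R %*% t(R0)
    cm$pose <- pose(Rn, cm$pose$t - as.numeric(Rn %*% t0))
    cm
  })
  project
}
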
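# shared fixtures and independent oracles

# Rodrigues rotation written independently of the package internals
rot_axis_angle_test <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

sem_vec_test <- function(sd_t1, icc) sd_t1 * sqrt(1 - icc)

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

R0_neutral <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)

neutral_pose <- function(origin = c(0, 0, 0)) segment_pose(R0_neutral, origin)

# a hand-built equilibrium system (no reaction columns) for solver tests:
# rows x columns of moment arms, one unknown per muscle
toy_system <- function(arms, b, f_max) {
  arms <- rbind(arms)
  list(A = arms, b = b,
       column_map = data.frame(
         name = paste0("m", seq_len(ncol(arms))),
         type = "muscle", f_max = f_max, group = "other",
         stringsAsFactors = FALSE))
}

# brute-force grid-refinement minimizer of sum((y/u)^3) s.t. A y = b,
# 0 <= y <= u: grid over the first n-p coordinates, solve the remaining
# p x p block exactly, keep feasible points, refine around the incumbent
brute_force_cost <- function(A, b, u, levels = 5, grid_n = 13) {
  A <- rbind(A)
  p <- nrow(A)
  n <- ncol(A)
  free <- seq_len(n - p)
  dep <- (n - p + 1):n
  Ad <- A[, dep, drop = FALSE]
  stopifnot(abs(det(Ad)) > 1e-12)
  lo <- rep(0, length(free)); hi <- u[free]
  best <- Inf; best_y <- NULL
  for (lev in seq_len(levels)) {
    grids <- lapply(seq_along(free), function(i) {
      seq(lo[i], hi[i], length.out = grid_n)
    })
    pts <- as.matrix(expand.grid(grids))
    for (r in seq_len(nrow(pts))) {
      yf <- pts[r, ]
      yd <- solve(Ad, b - A[, free, drop = FALSE] %*% yf)
      if (any(yd < -1e-9) || any(yd > u[dep] + 1e-9)) next
      y <- numeric(n); y[free] <- yf; y[dep] <- yd
      cost <- sum((y / u)^3)
      if (cost < best) { best <- cost; best_y <- y }
    }
    if (is.null(best_y)) break
    span <- (hi - lo) / (grid_n - 1)
    lo <- pmax(0, best_y[free] - 2 * span)
    hi <- pmin(u[free], best_y[free] + 2 * span)
  }
  list(cost = best, y = best_y)
}

# quick full-chain solve of one synthetic trial (used by several suites)
solve_one_trial <- function(task = "gait", seed = 42, mass = 72, height = 175,
                            ...) {
  geom <- load_geometry()
  prof <- subject_profile(mass = mass, height = height)
  tr <- generate_trial(prof, task, seed = seed, ...)
  solve_study_trial(tr, geom, study_config())
}
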
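zero_kin <- function() list(a_com = c(0, 0, 0), omega = c(0, 0, 0),
                            alpha = c(0, 0, 0))

standing_state <- function(geom, mass = 70, load_force = NULL,
                           gravity = 9.81, kin = NULL, knee_angle = 5) {
  lengths <- list(pelvis = 0.20, thigh = 0.42, shank = 0.42, foot = 0.25,
                  patella = 0.04)
  poses <- list(
    foot = neutral_pose(c(0, 0, 0)),
    shank = neutral_pose(c(0, 0, 0.42)),
    thigh = neutral_pose(c(0, 0, 0.84)),
    pelvis = neutral_pose(c(0, 0.09, 0.90)),
    patella = patella_pose(neutral_pose(c(0, 0, 0.84)), knee_angle,
                           default_patella_model(ref_local = c(0, -0.42, 0)))
  )
  inertia <- segment_inertia(geom, mass, lengths)
  if (is.null(load_force)) load_force <- c(0, 0, mass * 9.81)
  if (is.null(kin)) kin <- list(foot = zero_kin(), shank = zero_kin(),
                                thigh = zero_kin())
  frame_state(poses, kin, inertia,
              load = list(force = load_force, cop = c(0.02, 0, 0),
                          free_moment_z = 0),
              knee_angle = knee_angle, gravity = gravity)
}

test_that("Newton-Euler right-hand side vanishes without gravity, load or motion", {
  geom <- load_geometry()
  st <- standing_state(geom, load_force = c(0, 0, 0), gravity = 0)
  expect_equal(unname(newton_euler_rhs(st)), rep(0, 22))
})

test_that("static standing right-hand side reduces to weight terms", {
  geom <- load_geometry()
  mass <- 70
  st <- standing_state(geom, mass = mass)
  b <- newton_euler_rhs(st)
  # force rows: m_k * (0 - g) - S0 (foot row only)
  m_foot <- st$inertia$foot$mass
  expect_equal(unname(b["F_foot_z"]), m_foot * 9.81 - mass * 9.81)
  expect_equal(unname(b["F_shank_z"]), st$inertia$shank$mass * 9.81)
  expect_equal(unname(b["F_thigh_z"]), st$inertia$thigh$mass * 9.81)
  # patella and coupling rows are identically zero
  expect_equal(unname(b[19:22]), rep(0, 4))
})

test_that("shank pendulum moment row matches the analytic Euler equation", {
  geom <- load_geometry()
  # shank swinging about the knee: theta(t) about the global Y axis
  theta <- 0.35; theta_dot <- 1.4; theta_ddot <- -2.2
  lengths <- list(pelvis = 0.20, thigh = 0.42, shank = 0.42, foot = 0.25,
                  patella = 0.04)
  inertia <- segment_inertia(geom, 70, lengths)
  Rsh <- rot_axis_angle_test(c(0, 1, 0), theta) %*% R0_neutral
  knee <- c(0, 0, 0.84)
  # CoM kinematics of a pendulum: r(t) = knee + R(t) c_local
  c_loc <- inertia$shank$com_local
  r_rel <- as.numeric(Rsh %*% c_loc)
  om <- c(0, theta_dot, 0); al <- c(0, theta_ddot, 0)
  a_com <- cross3_test(al, r_rel) +
    cross3_test(om, cross3_test(om, r_rel))
  poses <- list(foot = neutral_pose(c(0, 0, 0)),
                shank = segment_pose(Rsh, knee),
                thigh = neutral_pose(c(0, 0, 0.84)),
                pelvis = neutral_pose(c(0, 0.09, 0.90)),
                patella = patella_pose(neutral_pose(c(0, 0, 0.84)), 5,
                                       default_patella_model(
                                         ref_local = c(0, -0.42, 0))))
  st <- frame_state(poses,
                    kin = list(foot = zero_kin(),
                               shank = list(a_com = a_com, omega = om,
                                            alpha = al),
                               thigh = zero_kin()),
                    inertia = inertia,
                    load = list(force = c(0, 0, 0), cop = c(0, 0, 0),
                                free_moment_z = 0),
                    knee_angle = 5)
  b <- newton_euler_rhs(st)
  # independent oracle: I_pivot * theta_ddot + m g d sin(theta) about Y
  m <- inertia$shank$mass
  d <- abs(c_loc[2])
  I_com_y <- inertia$shank$inertia[3, 3]  # local Z maps to global Y at theta=0
  # rotate inertia: pendulum swings about global Y = local Z axis; the
  # relevant principal moment is invariant under the swing rotation
  I_pivot <- I_com_y + m * d^2
  oracle <- I_pivot * theta_ddot + m * 9.81 * d * sin(theta)
  expect_equal(unname(b["M_shank_y"]), oracle, tolerance = 1e-8)
})

test_that("assembled system has the documented block structure", {
  geom <- load_geometry()
  st <- standing_state(geom)
  sys <- assemble_system(st, geom)
  expect_equal(dim(sys$A), c(22L, length(geom$muscles) + 1 +
                               length(geom$ligaments) + 15))
  expect_true(all(is.finite(sys$A)))

  cm <- sys$column_map
  # a muscle that does not insert on a segment has zero entries in its rows:
  # gastrocnemius spans the shank without attaching to it
  i_gas <- which(cm$name == "gastrocnemius_medialis")
  expect_equal(unname(sys$A[4:6, i_gas]), rep(0, 3))
  expect_equal(unname(sys$A[13:15, i_gas]), rep(0, 3))
  # rectus femoris runs pelvis -> patella: only patella force rows
  i_rf <- which(cm$name == "rectus_femoris")
  expect_equal(max(abs(sys$A[1:18, i_rf])), 0)
  expect_gt(max(abs(sys$A[19:21, i_rf])), 0)

  # reaction sign convention: ankle reaction -I on foot, +I on shank
  i_ank <- which(cm$name == "R_ankle_x")
  expect_equal(unname(sys$A[1:3, i_ank + 0:2]), -diag(3))
  expect_equal(unname(sys$A[4:6, i_ank + 0:2]), diag(3))
  # patellofemoral: -I on patella, +I on thigh
  i_pfj <- which(cm$name == "R_pfj_x")
  expect_equal(unname(sys$A[19:21, i_pfj + 0:2]), -diag(3))
  expect_equal(unname(sys$A[7:9, i_pfj + 0:2]), diag(3))

  # rho coupling row: rho on quadriceps columns, -1 on the patellar tendon
  quad <- which(cm$group %in% "quadriceps")
  rho <- rho_at(geom, st$knee_angle)
  expect_equal(unname(sys$A[22, quad]), rep(rho, length(quad)))
  expect_equal(unname(sys$A[22, cm$type == "pt"]), -1)
  expect_equal(sum(abs(sys$A[22, -c(quad, which(cm$type == "pt"))])), 0)
})

test_that("the system matrix is invariant to rigid translation and to F_max", {
  geom <- load_geometry()
  st <- standing_state(geom)
  sys <- assemble_system(st, geom)

  shift <- c(1.3, -0.4, 0.2)
  st2 <- st
  for (s in names(st2$poses)) {
    st2$poses[[s]] <- segment_pose(st2$poses[[s]]$rotation,
                                   st2$poses[[s]]$origin + shift)
  }
  st2$load$cop <- st2$load$cop + shift
  sys2 <- assemble_system(st2, geom)
  expect_equal(sys2$A, sys$A, tolerance = 1e-9)
  expect_equal(sys2$b, sys$b, tolerance = 1e-9)

  geom2 <- geom
  for (i in seq_along(geom2$muscles)) {
    geom2$muscles[[i]]$f_max <- geom2$muscles[[i]]$f_max * 2
  }
  sys3 <- assemble_system(st, geom2)
  expect_equal(sys3$A, sys$A)
})

test_that("residual measures the max-norm equation error", {
  sys <- list(A = matrix(c(1, 0, 0, 2), 2, 2), b = c(0, 0),
              column_map = data.frame(name = c("a", "b"), type = "muscle",
                                      f_max = 1, group = "other"))
  expect_equal(residual(sys, c(0, 0)), 0)
  expect_equal(residual(sys, c(1, -1)), 2)
  expect_error(residual(sys, c(1, 2, 3)), "dimension")
})

test_that("whole-limb statics balance for a solved standing frame", {
  geom <- load_geometry()
  mass <- 70
  st <- standing_state(geom, mass = mass)
  sys <- assemble_system(st, geom)
  sol <- solve_frame(sys)
  expect_true(sol$converged)
  expect_lt(sol$residual, 1e-6 * (1 + max(abs(sys$b))))
  # ankle reaction carries the load minus the foot weight (plus any
  # vertical components of muscles crossing the ankle)
  seg_w <- sum(vapply(c("foot", "shank", "thigh"),
                      function(s) st$inertia[[s]]$mass, numeric(1)))
  # summing the three force-row blocks of A x = b gives limb-level balance
  lhs <- as.numeric(sys$A[1:3, ] %*% sol$x + sys$A[4:6, ] %*% sol$x +
                      sys$A[7:9, ] %*% sol$x)
  rhs <- as.numeric(sys$b[1:3] + sys$b[4:6] + sys$b[7:9])
  expect_equal(lhs, rhs, tolerance = 1e-6)
  expect_equal(rhs[3], seg_w * 9.81 - mass * 9.81, tolerance = 1e-9)
})
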
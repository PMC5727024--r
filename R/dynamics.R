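#' Segment inertial parameters from geometry ratios and subject anthropometry
#'
#' Segment mass is a fixed fraction of body mass, the centre of mass lies at
#' a fixed fraction of segment length from the proximal joint along the
#' segment axis, and the inertia tensor about the CoM is diagonal in the
#' local frame with radii of gyration proportional to segment length
#' (file order: [sagittal, transverse, longitudinal]).
#'
#' @param geometry an `msk_geometry`
#' @param mass body mass (kg)
#' @param lengths named list of segment lengths (m)
#' @return named list per segment: `mass`, `com_local`, `inertia` (3x3 about
#'   the CoM, local frame)
#' @export
segment_inertia <- function(geometry, mass, lengths) {
  if (mass <= 0) stop("body mass must be positive")
  out <- list()
  for (s in names(geometry$segments)) {
    gs <- geometry$segments[[s]]
    L <- lengths[[s]] %||% gs$reference_length
    m <- mass * gs$mass_fraction
    gy <- unlist(gs$gyration)
    Ident <- diag(c((gy[1] * L)^2, (gy[3] * L)^2, (gy[2] * L)^2)) * m
    out[[s]] <- list(mass = m,
                     com_local = c(0, -gs$com_fraction * L, 0),
                     inertia = Ident)
  }
  out
}

# ordered equilibrium segments: 1 = foot (carries the ground wrench),
# 2 = shank (knee contacts), 3 = thigh (hip reaction); the patella
# contributes force rows only (quasi-static, massless) and the pelvis
# supplies hip-centre kinematics but no equilibrium rows.
EQ_SEGMENTS <- c("foot", "shank", "thigh")

row_names_system <- function() {
  c(paste0("F_foot_", c("x", "y", "z")),
    paste0("F_shank_", c("x", "y", "z")),
    paste0("F_thigh_", c("x", "y", "z")),
    paste0("M_foot_", c("x", "y", "z")),
    paste0("M_shank_", c("x", "y", "z")),
    paste0("M_thigh_", c("x", "y", "z")),
    paste0("F_patella_", c("x", "y", "z")),
    "rho_coupling")
}

#' Per-frame state for equilibrium assembly
#'
#' @param poses named list of [segment_pose()] for pelvis, thigh, shank,
#'   foot and patella
#' @param kin named list (foot/shank/thigh) of `a_com`, `omega`, `alpha`
#'   3-vectors for this frame
#' @param inertia output of [segment_inertia()]
#' @param load list `force`, `cop`, `free_moment_z`: the ground wrench on
#'   the foot for this frame (global)
#' @param knee_angle knee flexion (degrees), used for the rho lookup
#' @param gravity gravitational acceleration magnitude (m/s^2; default 9.81)
#' @return list of class `frame_state`
#' @export
frame_state <- function(poses, kin, inertia, load, knee_angle,
                        gravity = GRAVITY) {
  need <- c("foot", "shank", "thigh", "patella")
  if (!all(need %in% names(poses))) {
    stop("poses must include ", paste(need, collapse = ", "))
  }
  if (!all(EQ_SEGMENTS %in% names(kin))) {
    stop("kinematics must cover foot, shank and thigh")
  }
  structure(list(poses = poses, kin = kin, inertia = inertia,
                 load = load, knee_angle = knee_angle, gravity = gravity),
            class = "frame_state")
}

#' Newton-Euler right-hand side of the equilibrium system
#'
#' Force rows are \eqn{m_k(a_k - g)} (the foot row minus the ground force);
#' moment rows, taken about each segment's proximal joint centre, are
#' \eqn{m_k c_k \times (a_k - g) + I_k \alpha_k + \omega_k \times I_k
#' \omega_k} (the foot row minus the ground wrench moment about the ankle).
#' Patella and coupling rows are zero.
#'
#' @param state a [frame_state()]
#' @return named numeric vector (22 rows)
#' @export
newton_euler_rhs <- function(state) {
  g <- c(0, 0, -(state$gravity %||% GRAVITY))
  b <- numeric(22)
  names(b) <- row_names_system()
  for (k in seq_along(EQ_SEGMENTS)) {
    s <- EQ_SEGMENTS[k]
    pose <- state$poses[[s]]
    ine <- state$inertia[[s]]
    kin <- state$kin[[s]]
    if (is.null(pose) || is.null(ine) || is.null(kin)) {
      stop("missing pose/inertia/kinematics for segment ", s)
    }
    m <- ine$mass
    a_g <- kin$a_com - g
    com_g <- pose_transform(pose, ine$com_local)
    c_vec <- com_g - pose$origin
    Ig <- pose$rotation %*% ine$inertia %*% t(pose$rotation)
    b[(3 * k - 2):(3 * k)] <- m * a_g
    b[(9 + 3 * k - 2):(9 + 3 * k)] <-
      m * cross3(c_vec, a_g) +
      as.numeric(Ig %*% kin$alpha) +
      cross3(kin$omega, as.numeric(Ig %*% kin$omega))
  }
  # external ground wrench on the foot
  s0 <- state$load$force
  ankle <- state$poses$foot$origin
  m_ext <- cross3(state$load$cop - ankle, s0) +
    c(0, 0, state$load$free_moment_z %||% 0)
  b[1:3] <- b[1:3] - s0
  b[10:12] <- b[10:12] - m_ext
  b
}

#' Assemble the per-frame indeterminate equilibrium system
#'
#' Builds the linear system `A x = b` whose unknowns are the muscle forces,
#' the patellar tendon force, the ligament forces, and the joint reaction
#' vectors (ankle, medial and lateral tibiofemoral, hip, patellofemoral).
#' Rows are force and moment equilibrium of foot, shank and thigh, force
#' equilibrium of the (massless) patella, and one coupling row enforcing
#' that the patellar tendon force equals the rho-weighted sum of the
#' quadriceps forces. Reactions carry +I on the segment distal to the joint
#' and -I on the proximal one; tibiofemoral contact levers are taken from
#' the knee centre (shank rows) and from the hip centre (thigh rows), the
#' patellofemoral lever from the hip centre.
#'
#' @param state a [frame_state()]
#' @param geometry an `msk_geometry` (scaled to the subject)
#' @return list of class `equilibrium_system`: `A`, `b`, `column_map`
#'   (data.frame: name, type in muscle/pt/ligament/reaction, f_max, group)
#' @export
assemble_system <- function(state, geometry) {
  poses <- state$poses
  knee <- poses$shank$origin
  hip <- poses$thigh$origin

  n_mus <- length(geometry$muscles)
  n_lig <- length(geometry$ligaments)
  ncol_total <- n_mus + 1 + n_lig + 15
  A <- matrix(0, 22, ncol_total)
  rownames(A) <- row_names_system()

  seg_force_rows <- function(s) {
    k <- match(s, EQ_SEGMENTS)
    if (is.na(k)) NULL else (3 * k - 2):(3 * k)
  }
  add_path <- function(col, attachments) {
    contribs <- line_of_action(attachments, poses)
    for (ct in contribs) {
      if (ct$segment %in% EQ_SEGMENTS) {
        fr <- seg_force_rows(ct$segment)
        A[fr, col] <<- A[fr, col] + ct$p_hat
        A[fr + 9, col] <<- A[fr + 9, col] + cross3(ct$r_vec, ct$p_hat)
      } else if (ct$segment == "patella") {
        A[19:21, col] <<- A[19:21, col] + ct$p_hat
      }
    }
  }

  cn <- character(ncol_total)
  types <- character(ncol_total)
  fmax <- rep(NA_real_, ncol_total)
  grp <- rep(NA_character_, ncol_total)

  for (i in seq_len(n_mus)) {
    m <- geometry$muscles[[i]]
    add_path(i, m$attachments)
    cn[i] <- m$name; types[i] <- "muscle"; fmax[i] <- m$f_max; grp[i] <- m$group
  }
  ipt <- n_mus + 1
  add_path(ipt, geometry$patellar_tendon$attachments)
  cn[ipt] <- "patellar_tendon"; types[ipt] <- "pt"
  for (j in seq_len(n_lig)) {
    l <- geometry$ligaments[[j]]
    add_path(ipt + j, l$attachments)
    cn[ipt + j] <- l$name; types[ipt + j] <- "ligament"; fmax[ipt + j] <- l$l_max
  }

  # contact point positions in the global frame
  cgl <- function(cp) {
    p <- geometry$contacts[[cp]]
    pose_transform(poses[[p$segment]], unlist(p$xyz))
  }
  med <- cgl("medial"); lat <- cgl("lateral"); pf <- cgl("patellofemoral")
  ankle <- poses$foot$origin

  rcol <- ipt + n_lig
  rnames <- c("R_ankle", "R_med_tfj", "R_lat_tfj", "R_hip", "R_pfj")
  for (r in seq_along(rnames)) {
    idx <- rcol + (3 * r - 2):(3 * r)
    cn[idx] <- paste0(rnames[r], "_", c("x", "y", "z"))
    types[idx] <- "reaction"
  }
  blk <- function(rows, cols, M) A[rows, cols] <<- A[rows, cols] + M
  i3 <- diag(3)
  c_ank <- rcol + 1:3; c_med <- rcol + 4:6; c_lat <- rcol + 7:9
  c_hip <- rcol + 10:12; c_pfj <- rcol + 13:15
  # ankle reaction: -I on foot, +I on shank distal end with lever knee->ankle
  blk(1:3, c_ank, -i3)
  blk(4:6, c_ank, i3)
  blk(13:15, c_ank, skew(ankle - knee))
  # tibiofemoral contacts: -I on shank (femur pushes tibia), +I on thigh
  blk(4:6, c_med, -i3); blk(13:15, c_med, -skew(med - knee))
  blk(7:9, c_med, i3); blk(16:18, c_med, skew(med - hip))
  blk(4:6, c_lat, -i3); blk(13:15, c_lat, -skew(lat - knee))
  blk(7:9, c_lat, i3); blk(16:18, c_lat, skew(lat - hip))
  # hip reaction: -I on thigh, zero lever about the hip
  blk(7:9, c_hip, -i3)
  # patellofemoral: -I on patella, +I on thigh with lever hip->contact
  blk(19:21, c_pfj, -i3)
  blk(7:9, c_pfj, i3); blk(16:18, c_pfj, skew(pf - hip))

  # rho coupling: F_pt = sum over quadriceps of rho_i F_i
  rho <- rho_at(geometry, state$knee_angle)
  quad <- which(grp == "quadriceps" & types == "muscle")
  A[22, quad] <- rho
  A[22, ipt] <- -1

  b <- newton_euler_rhs(state)
  structure(list(
    A = A, b = b,
    column_map = data.frame(name = cn, type = types, f_max = fmax,
                            group = grp, stringsAsFactors = FALSE)
  ), class = "equilibrium_system")
}

#' @export
print.equilibrium_system <- function(x, ...) {
  cat("<equilibrium_system>", nrow(x$A), "rows x", ncol(x$A), "columns (",
      sum(x$column_map$type == "muscle"), "muscles,",
      sum(x$column_map$type == "ligament"), "ligaments, 5 reactions )\n")
  invisible(x)
}

#' Equilibrium residual of a candidate solution
#'
#' @param system an `equilibrium_system` (or any list with `A`, `b`)
#' @param x solution vector in system column order
#' @return max-norm of `A x - b` (N / N m)
#' @export
residual <- function(system, x) {
  if (length(x) != ncol(system$A)) stop("dimension mismatch: system has ",
                                        ncol(system$A), " columns, x has ",
                                        length(x))
  max(abs(system$A %*% x - system$b))
}
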
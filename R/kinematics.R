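#' Segment pose
#'
#' A rigid-body pose: the rotation maps segment-local coordinates to the
#' global frame and the origin is the segment's proximal joint centre
#' expressed globally. Local frames are ISB-like for a right limb: X
#' anterior, Y up along the segment, Z mediolateral (to the right).
#'
#' @param rotation 3x3 proper orthonormal matrix (local -> global)
#' @param origin global position of the proximal joint centre (m)
#' @return object of class `segment_pose`
#' @export
segment_pose <- function(rotation, origin) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(origin) == 3)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6) stop("rotation is not orthonormal (max deviation ", err, ")")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, origin = as.numeric(origin)),
            class = "segment_pose")
}

#' Map segment-local points to the global frame
#' @param pose a [segment_pose()]
#' @param pts n x 3 matrix (or length-3 vector) of local coordinates (m)
#' @return global coordinates, same shape
#' @export
pose_transform <- function(pose, pts) {
  if (is.null(dim(pts))) {
    return(as.numeric(pose$rotation %*% pts + pose$origin))
  }
  t(pose$rotation %*% t(pts)) + matrix(pose$origin, nrow(pts), 3, byrow = TRUE)
}

#' Least-squares rigid pose from markers (orthogonal Procrustes / Kabsch)
#'
#' Finds the rotation and translation that map a segment's local marker
#' template onto the observed global marker positions with minimal sum of
#' squared residuals; a proper rotation is enforced via the sign of the
#' smallest singular value.
#'
#' @param template n x 3 matrix of local marker coordinates (n >= 3,
#'   non-collinear)
#' @param observed n x 3 matrix of the same markers observed globally
#' @return a [segment_pose()] with attribute `"rms"` (marker residual RMS, m).
#'   Note the returned origin is the image of the local origin, i.e. the
#'   proximal joint centre if the template is expressed about it.
#' @export
fit_segment_pose <- function(template, observed) {
  template <- as.matrix(template); observed <- as.matrix(observed)
  stopifnot(nrow(template) == nrow(observed), ncol(template) == 3)
  if (nrow(template) < 3) stop("need at least 3 markers")
  ct <- colMeans(template); co <- colMeans(observed)
  A <- sweep(template, 2, ct); B <- sweep(observed, 2, co)
  # collinearity check: second principal moment of the template cloud
  sv_t <- svd(A)$d
  if (sv_t[2] < 1e-9) stop("marker template is collinear or degenerate")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  origin <- co - as.numeric(R %*% ct)
  res <- observed - (t(R %*% t(template)) +
                       matrix(origin, nrow(template), 3, byrow = TRUE))
  pose <- segment_pose(R, origin)
  attr(pose, "rms") <- sqrt(mean(rowSums(res^2)))
  pose
}

#' Knee flexion angle from thigh and shank poses
#'
#' The signed angle between the thigh and shank long axes (local +Y) about
#' the knee mediolateral axis (the thigh's local +Z): 0 at full extension,
#' positive in flexion (shank rotating posteriorly relative to the thigh)
#' for a right limb.
#'
#' @param thigh,shank [segment_pose()] objects
#' @return flexion angle in degrees
#' @export
knee_flexion <- function(thigh, shank) {
  ml <- thigh$rotation[, 3]                 # mediolateral (right) axis
  yt <- thigh$rotation[, 2]; ys <- shank$rotation[, 2]
  # project long axes onto the plane normal to the ML axis
  pt <- unitize(yt - sum(yt * ml) * ml)
  ps <- unitize(ys - sum(ys * ml) * ml)
  ang <- atan2(sum(cross3(ps, pt) * ml), sum(ps * pt))
  # flexion rotates the (downward-pointing) shank about -ML relative to the
  # thigh; with long axes pointing proximally the signed angle above is
  # positive in flexion
  ang * 180 / pi
}

#' Patella pose from the thigh pose and knee flexion angle
#'
#' The patella has zero degrees of freedom: its pose is a deterministic
#' function of the thigh pose and the knee flexion angle. The patella
#' centre sits at a fixed radius from a femoral reference point (the knee
#' centre in the thigh frame), rotated about the femoral mediolateral axis
#' by a monotone angle beta(knee_angle); its orientation is the thigh frame
#' rotated by the same beta. The default placement (beta = 0.7 x flexion,
#' 4.5 cm radius anterior to the femoral axis) is a configurable stand-in
#' for cadaver-derived patellar tracking data.
#'
#' @param thigh [segment_pose()] of the thigh
#' @param knee_angle knee flexion in degrees (must lie in the lookup range)
#' @param model list: `beta` function degrees -> degrees (monotone),
#'   `radius` m, `ref_local` the femoral reference point in thigh-local
#'   coordinates, `range` allowed knee-angle interval
#' @return a [segment_pose()] for the patella (origin = patella centre)
#' @export
patella_pose <- function(thigh, knee_angle, model = default_patella_model()) {
  rng <- model$range %||% c(-10, 150)
  if (knee_angle < rng[1] || knee_angle > rng[2]) {
    stop("knee angle ", knee_angle, " deg outside patella model range [",
         rng[1], ", ", rng[2], "]")
  }
  beta <- model$beta(knee_angle) * pi / 180
  # rotate about the femoral ML axis, expressed in the thigh local frame
  Rb <- rot_axis_angle(c(0, 0, 1), -beta)   # flexion sense about local +Z
  offset_local <- as.numeric(Rb %*% c(model$radius, 0, 0))  # anterior at 0 deg
  centre <- pose_transform(thigh, model$ref_local + offset_local)
  segment_pose(thigh$rotation %*% Rb, centre)
}

#' Default patella placement model
#' @param beta_scale patellar rotation per degree of knee flexion
#' @param radius distance of the patella centre from the femoral reference (m)
#' @param ref_local femoral reference point in thigh-local coordinates (m)
#' @return model list accepted by [patella_pose()]
#' @export
default_patella_model <- function(beta_scale = 0.7, radius = 0.045,
                                  ref_local = c(0, -0.40, 0)) {
  list(beta = function(a) beta_scale * a,
       radius = radius, ref_local = ref_local, range = c(-10, 150))
}

#' Differentiate a pose sequence into segment kinematics
#'
#' Angular velocity is extracted from the skew-symmetric part of
#' \eqn{\dot R R^T} with \eqn{\dot R} by central differences of the rotation
#' matrices; angular acceleration and the centre-of-mass linear acceleration
#' are central differences as well (one-sided at the endpoints).
#'
#' @param poses list of [segment_pose()] (>= 5 frames)
#' @param sample_rate Hz
#' @param com_local centre of mass in segment-local coordinates (m)
#' @return list with `omega`, `alpha` (n x 3, rad/s and rad/s^2), `a_com`
#'   (n x 3, m/s^2) and `com` (n x 3, m, global CoM positions)
#' @export
differentiate_kinematics <- function(poses, sample_rate,
                                     com_local = c(0, 0, 0)) {
  n <- length(poses)
  if (n < 5) stop("need at least 5 frames to differentiate")
  h <- 1 / sample_rate
  Rs <- lapply(poses, `[[`, "rotation")
  com <- t(vapply(poses, function(p) pose_transform(p, com_local),
                  numeric(3)))

  ddt <- function(M) {           # central differences over rows, one-sided ends
    D <- M
    D[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / (2 * h)
    D[1, ] <- (M[2, ] - M[1, ]) / h
    D[n, ] <- (M[n, ] - M[n - 1, ]) / h
    D
  }
  omega <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (i == 1) Rdot <- (Rs[[2]] - Rs[[1]]) / h
    else if (i == n) Rdot <- (Rs[[n]] - Rs[[n - 1]]) / h
    else Rdot <- (Rs[[i + 1]] - Rs[[i - 1]]) / (2 * h)
    W <- Rdot %*% t(Rs[[i]])
    W <- (W - t(W)) / 2
    omega[i, ] <- c(W[3, 2], W[1, 3], W[2, 1])
  }
  alpha <- ddt(omega)
  vel <- ddt(com)
  a_com <- ddt(vel)
  list(omega = omega, alpha = alpha, a_com = a_com, com = com)
}
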
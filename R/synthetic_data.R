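#' Study design for a synthetic test-retest experiment
#'
#' Defaults emulate the reliability study design: 9 subjects, 2 sessions
#' 24 h apart, 3 trials per session, two tasks (level gait and stair
#' ascent).
#'
#' @param n_subjects,n_sessions,n_trials_per_session counts (>= 1)
#' @param tasks character subset of `c("gait", "stair")`
#' @param seed integer seed controlling all generator randomness
#' @return list of class `study_design`
#' @export
study_design <- function(n_subjects = 9, n_sessions = 2,
                         n_trials_per_session = 3,
                         tasks = c("gait", "stair"), seed = 1L) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, n_trials_per_session >= 1)
  if (!all(tasks %in% c("gait", "stair"))) stop("unknown task label")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_trials_per_session = as.integer(n_trials_per_session),
                 tasks = tasks, seed = as.integer(seed)),
            class = "study_design")
}

#' Variance structure for synthetic peak-value datasets
#'
#' Peak values are generated as grand mean + subject effect +
#' subject-session effect + trial noise, with the three SDs given here; the
#' implied true intraclass correlation is
#' \eqn{\sigma^2_b / (\sigma^2_b + \sigma^2_w + \sigma^2_s)}.
#'
#' @param between_subject_sd,within_subject_sd positive SDs
#' @param session_shift_sd nonnegative SD of the session-by-subject shift
#' @return list of class `variance_spec`
#' @export
variance_spec <- function(between_subject_sd, within_subject_sd,
                          session_shift_sd = 0) {
  if (any(c(between_subject_sd, within_subject_sd, session_shift_sd) < 0)) {
    stop("SDs must be nonnegative")
  }
  structure(list(between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 session_shift_sd = session_shift_sd),
            class = "variance_spec")
}

#' True intraclass correlation implied by a variance spec
#' @param spec a [variance_spec()]
#' @return ICC in [0, 1]
#' @export
true_icc <- function(spec) {
  vb <- spec$between_subject_sd^2
  vw <- spec$within_subject_sd^2
  vs <- spec$session_shift_sd^2
  tot <- vb + vw + vs
  if (tot == 0) stop("all variance components are zero: ICC undefined")
  vb / tot
}

#' Subject anthropometry and movement scaling
#'
#' @param mass body mass (kg, > 0)
#' @param height stature (cm, > 0)
#' @param gait_speed_scale dimensionless pace multiplier
#' @param knee_peak_gait,knee_peak_stair subject-mean peak knee flexion (deg)
#' @return list of class `subject_profile`
#' @export
subject_profile <- function(mass, height, gait_speed_scale = 1,
                            knee_peak_gait = 17, knee_peak_stair = 60) {
  if (mass <= 0) stop("mass must be positive")
  if (height <= 0) stop("height must be positive")
  structure(list(mass = mass, height = height,
                 gait_speed_scale = gait_speed_scale,
                 knee_peak_gait = knee_peak_gait,
                 knee_peak_stair = knee_peak_stair),
            class = "subject_profile")
}

#' Segment lengths from stature
#'
#' Standard proportional anthropometry: thigh 24.5%, shank 24.6% and foot
#' 15.2% of stature.
#' @param profile a [subject_profile()]
#' @return named list of segment lengths (m)
#' @export
segment_lengths <- function(profile) {
  h <- profile$height / 100
  list(pelvis = 0.12 * h, thigh = 0.245 * h, shank = 0.246 * h,
       foot = 0.152 * h, patella = 0.04)
}

#' Sample a cohort of subject profiles
#'
#' Heights are drawn uniformly over 152-185 cm and masses from a body-mass
#' index of 19-31 kg/m^2 at that height, matching a healthy older-adult
#' cohort (about 44-91 kg); subject-mean peak knee flexion varies between
#' subjects (gait: SD 5 deg about 17 deg).
#'
#' @param n number of subjects
#' @param seed integer seed
#' @return list of [subject_profile()]
#' @export
sample_subjects <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    height <- stats::runif(1, 152, 185)
    bmi <- stats::runif(1, 19, 31)
    subject_profile(
      mass = bmi * (height / 100)^2,
      height = height,
      gait_speed_scale = stats::runif(1, 0.9, 1.1),
      knee_peak_gait = stats::rnorm(1, 17, 5),
      knee_peak_stair = stats::rnorm(1, 60, 6)
    )
  })
}

#' Marker manifest: names, segments and local template coordinates
#'
#' Eighteen markers over pelvis (4), thigh (5, incl. femoral epicondyles),
#' shank (5, incl. malleoli) and foot (4), with template coordinates in the
#' segment-local frames (origin at the proximal joint centre). Also carries
#' the hip-centre offset in the pelvis frame used for joint-centre
#' regression.
#'
#' @param lengths output of [segment_lengths()]
#' @return list: `segments` (named list of marker-name -> local xyz
#'   matrices), `hip_local`
#' @export
marker_manifest <- function(lengths) {
  lt <- lengths$thigh; ls <- lengths$shank
  m <- list(
    pelvis = rbind(
      RASI = c(0.080, 0.020, 0.120),
      LASI = c(0.080, 0.020, -0.120),
      RPSI = c(-0.100, 0.030, 0.050),
      LPSI = c(-0.100, 0.030, -0.050)
    ),
    thigh = rbind(
      THI1 = c(0.050, -0.40 * lt, 0.030),
      THI2 = c(0.020, -0.60 * lt, 0.060),
      THI3 = c(0.060, -0.70 * lt, -0.020),
      KNEM = c(0.000, -lt, -0.050),
      KNEL = c(0.000, -lt, 0.050)
    ),
    shank = rbind(
      TIB1 = c(0.040, -0.30 * ls, 0.020),
      TIB2 = c(0.020, -0.55 * ls, 0.050),
      TIB3 = c(0.050, -0.65 * ls, -0.030),
      ANKM = c(0.000, -ls, -0.040),
      ANKL = c(0.000, -ls, 0.040)
    ),
    foot = rbind(
      HEEL = c(-0.060, -0.060, 0.000),
      TOE = c(0.160, -0.070, 0.010),
      MT1 = c(0.100, -0.060, -0.040),
      MT5 = c(0.100, -0.060, 0.050)
    )
  )
  list(segments = m, hip_local = c(0.000, -0.060, 0.090))
}

#' Session-level marker re-application offsets
#'
#' Systematic per-marker offsets (constant within a session) emulating
#' marker re-application error between sessions.
#'
#' @param manifest a [marker_manifest()]
#' @param sd offset SD in m (default 0.003)
#' @param seed integer seed
#' @return named list of per-marker 3-vectors (m)
#' @export
session_perturbation <- function(manifest, sd = 0.003, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (s in names(manifest$segments)) {
    for (nm in rownames(manifest$segments[[s]])) {
      out[[nm]] <- stats::rnorm(3, 0, sd)
    }
  }
  out
}

# prescribed joint-angle and GRF profiles over normalized stance time tau
gait_profiles <- function(task, profile, jitter = list()) {
  kp <- (if (task == "gait") profile$knee_peak_gait else profile$knee_peak_stair) +
    (jitter$knee_peak %||% 0)
  if (task == "gait") {
    list(
      knee = function(tau) {
        2 + (kp - 4.5) * exp(-((tau - 0.24) / 0.14)^2) +
          0.75 * (kp - 4.5) * exp(-((tau - 1.05) / 0.25)^2)
      },
      shank_tilt = function(tau) -15 + 35 * tau,
      # two-peak vertical GRF, unit mean over stance
      grf_shape = function(tau) {
        raw <- sin(pi * tau) + 0.4 * sin(3 * pi * tau)
        raw / (2 / pi + 0.4 * 2 / (3 * pi))
      },
      ap_shape = function(tau) -0.12 * sin(2 * pi * tau)
    )
  } else {
    # stair ascent: deep knee flexion at contact extending through stance,
    # shank tilted forward throughout so the hip travels over the foot
    list(
      knee = function(tau) 10 + (kp - 10) * (1 + cos(pi * tau)) / 2,
      shank_tilt = function(tau) 18 + 4 * tau,
      # single early-stance peak, normalized to a 1.05 BW peak (stair stance
      # overlaps double support, so the stance impulse is below BW x time)
      grf_shape = function(tau) {
        raw <- sin(pi * tau) + 0.3 * sin(2 * pi * tau)
        1.05 * raw / 1.136
      },
      ap_shape = function(tau) 0.05 - 0.12 * sin(2 * pi * tau)
    )
  }
}

#' Generate one synthetic motion-capture trial
#'
#' Builds a kinematically consistent planar-dominant right limb over the
#' stance phase of gait or stair ascent: the foot is planted (flat on the
#' plate, or on the instrumented box for stairs), shank and thigh tilts
#' follow prescribed smooth angle profiles (knee flexion peaking near 24%
#' of stance for gait), the pelvis rides on the hip, and 18 markers are
#' generated from rigid segment templates. The vertical ground reaction is
#' a smooth one- (stair) or two-peak (gait) curve normalized to mean body
#' weight over stance (impulse tolerance ~2% after discretization), with a
#' heel-to-toe centre-of-pressure progression. Gaussian marker noise and
#' systematic per-session marker offsets are applied after the ideal
#' kinematics; 0.15 s of unloaded lead-in/out frames surround stance.
#'
#' @param profile a [subject_profile()]
#' @param task `"gait"` or `"stair"`
#' @param perturbation optional [session_perturbation()] offsets
#' @param seed integer seed for noise and trial jitter
#' @param stance_duration stance time in s (default 1.0)
#' @param marker_noise_sd marker noise SD in m (default 0.001)
#' @param trial_jitter logical: add small within-subject trial-to-trial
#'   variation in movement amplitude (default TRUE)
#' @param sample_rate Hz (default 200)
#' @return list of class `motion_trial`: `time`, `markers` (named list of
#'   n x 3 matrices), `wrench` (`force`, `cop`, `free_moment_z`; plate
#'   level), `box` (stair only), `manifest`, `task`, `mass`, `truth`
#'   (noise-free stance interval, knee-angle function, poses)
#' @export
generate_trial <- function(profile, task, perturbation = NULL, seed = 1L,
                           stance_duration = 1.0, marker_noise_sd = 0.001,
                           trial_jitter = TRUE, sample_rate = 200) {
  if (!task %in% c("gait", "stair")) stop("unknown task label: ", task)
  if (profile$mass <= 0) stop("mass must be positive")
  set.seed(seed)
  jitter <- if (trial_jitter) {
    list(knee_peak = stats::rnorm(1, 0, 1), grf_amp = stats::rnorm(1, 0, 0.02))
  } else list(knee_peak = 0, grf_amp = 0)

  lengths <- segment_lengths(profile)
  manifest <- marker_manifest(lengths)
  prof <- gait_profiles(task, profile, jitter)
  bw <- profile$mass * GRAVITY

  lead <- 0.15
  dt <- 1 / sample_rate
  t_all <- seq(0, stance_duration + 2 * lead, by = dt)
  n <- length(t_all)
  tau_raw <- (t_all - lead) / stance_duration
  in_stance <- tau_raw >= 0 & tau_raw <= 1
  tau <- pmin(pmax(tau_raw, 0), 1)

  box <- if (task == "stair") {
    list(mass = 5, top_height = 0.18, com = c(0, 0, 0.09))
  } else NULL
  ground_z <- if (is.null(box)) 0 else box$top_height
  ankle0 <- c(0, 0, ground_z + 0.08)
  if (!is.null(box)) box$com <- c(ankle0[1] + 0.05, 0, box$top_height / 2)

  R0 <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)  # cols: X,Z,-Y
  rot_tilt <- function(phi_deg, oop_deg = 0) {
    rot_axis_angle(c(1, 0, 0), oop_deg * pi / 180) %*%
      rot_axis_angle(c(0, 1, 0), phi_deg * pi / 180) %*% R0
  }

  poses <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- tau[i]
    th_k <- prof$knee(tt)
    phi_s <- prof$shank_tilt(tt)
    phi_t <- phi_s - th_k
    oop <- 1 * sin(pi * tt)            # small out-of-plane component (deg)
    Rs <- rot_tilt(phi_s, oop)
    Rt <- rot_tilt(phi_t, oop * 0.6)
    Rf <- R0
    knee <- ankle0 + lengths$shank *
      c(sin(phi_s * pi / 180), -sin(oop * pi / 180) * 0.1, cos(phi_s * pi / 180))
    hip <- knee + lengths$thigh *
      c(sin(phi_t * pi / 180), -sin(oop * 0.6 * pi / 180) * 0.1,
        cos(phi_t * pi / 180))
    Rp <- R0
    pelvis_origin <- hip - as.numeric(Rp %*% manifest$hip_local)
    poses[[i]] <- list(
      foot = segment_pose(Rf, ankle0),
      shank = segment_pose(Rs, knee),
      thigh = segment_pose(Rt, hip),
      pelvis = segment_pose(Rp, pelvis_origin)
    )
  }

  markers <- list()
  for (s in names(manifest$segments)) {
    tmpl <- manifest$segments[[s]]
    for (nm in rownames(tmpl)) {
      M <- t(vapply(poses, function(p) pose_transform(p[[s]], tmpl[nm, ]),
                    numeric(3)))
      off <- perturbation[[nm]] %||% c(0, 0, 0)
      M <- M + matrix(off, n, 3, byrow = TRUE)
      if (marker_noise_sd > 0) {
        M <- M + matrix(stats::rnorm(3 * n, 0, marker_noise_sd), n, 3)
      }
      markers[[nm]] <- M
    }
  }

  # foot-level ground wrench over stance
  amp <- 1 + jitter$grf_amp
  fz <- ifelse(in_stance, amp * bw * prof$grf_shape(tau), 0)
  fx <- ifelse(in_stance, amp * bw * prof$ap_shape(tau), 0)
  fy <- ifelse(in_stance, -0.01 * bw * sin(pi * tau), 0)
  force_foot <- cbind(fx, fy, fz)
  # CoP progression on the support surface: heel to toe for gait,
  # forefoot contact throughout for stair ascent
  if (task == "gait") {
    heel <- ankle0 + c(-0.05, 0, -0.08)
    toe <- ankle0 + c(0.15, 0, -0.08)
  } else {
    heel <- ankle0 + c(0.04, 0, -0.08)
    toe <- ankle0 + c(0.14, 0, -0.08)
  }
  cop_foot <- cbind(heel[1] + (toe[1] - heel[1]) * tau,
                    heel[2] + 0 * tau,
                    rep(ground_z, n))
  # axial free moment chosen so the net axial (vertical) moment of the
  # ground wrench about the ankle is zero: the reduced muscle set has
  # little axial capacity at the ankle, mirroring how the deep rotators
  # absorbed by a full muscle set are not modelled
  rel <- sweep(cop_foot, 2, ankle0)
  tz_foot <- ifelse(in_stance, -(rel[, 1] * fy - rel[, 2] * fx), 0)

  if (is.null(box)) {
    wrench <- list(force = force_foot, cop = cop_foot, free_moment_z = tz_foot)
  } else {
    # push the foot wrench down through the quasi-static box to plate level
    w <- c(0, 0, box$mass * GRAVITY)
    force_plate <- sweep(force_foot, 2, w, `+`)
    cop_plate <- matrix(0, n, 3)
    tz_plate <- numeric(n)
    for (i in seq_len(n)) {
      Fp <- force_plate[i, ]
      if (!in_stance[i] || Fp[3] <= w[3] + 1e-9) {
        cop_plate[i, ] <- c(box$com[1], box$com[2], 0)
        tz_plate[i] <- 0
        next
      }
      G <- -force_foot[i, ]
      m0 <- -cross3(cop_foot[i, ] - box$com, G)  # required (r_p-com) x Fp
      dzp <- 0 - box$com[3]
      dxp <- (dzp * Fp[1] + m0[2]) / Fp[3]
      dyp <- (dzp * Fp[2] - m0[1]) / Fp[3]
      cop_plate[i, ] <- box$com + c(dxp, dyp, dzp)
      tz_plate[i] <- m0[3] - (dxp * Fp[2] - dyp * Fp[1])
    }
    wrench <- list(force = force_plate, cop = cop_plate,
                   free_moment_z = tz_plate)
  }

  structure(list(
    time = t_all, sample_rate = sample_rate, task = task,
    mass = profile$mass, markers = markers, wrench = wrench, box = box,
    manifest = manifest, lengths = lengths,
    truth = list(stance = range(which(in_stance)), tau = tau,
                 knee_angle = prof$knee, poses = poses,
                 grf_mean_target = amp * bw)
  ), class = "motion_trial")
}

#' @export
print.motion_trial <- function(x, ...) {
  cat("<motion_trial>", x$task, "task,", length(x$time), "frames @",
      x$sample_rate, "Hz,", length(x$markers), "markers, mass",
      round(x$mass, 1), "kg\n")
  invisible(x)
}

#' Generate a synthetic peak-value test-retest dataset
#'
#' Direct generation of peak values (no solver) with a known variance
#' structure: value = grand mean + subject effect + subject-session shift +
#' trial noise, all normal.
#'
#' @param design a [study_design()]
#' @param spec a [variance_spec()]
#' @param grand_means named numeric vector of per-variable grand means
#' @return data.frame: subject, session, trial, variable, value
#' @export
generate_peak_dataset <- function(design, spec, grand_means = c(peak = 0)) {
  set.seed(design$seed)
  vars <- names(grand_means)
  if (is.null(vars)) stop("grand_means must be named")
  res <- list()
  for (v in seq_along(vars)) {
    sb <- stats::rnorm(design$n_subjects, 0, spec$between_subject_sd)
    sh <- matrix(stats::rnorm(design$n_subjects * design$n_sessions, 0,
                              spec$session_shift_sd),
                 design$n_subjects, design$n_sessions)
    for (s in seq_len(design$n_subjects)) {
      for (se in seq_len(design$n_sessions)) {
        eps <- stats::rnorm(design$n_trials_per_session, 0,
                            spec$within_subject_sd)
        res[[length(res) + 1]] <- data.frame(
          subject = s, session = se,
          trial = seq_len(design$n_trials_per_session),
          variable = vars[v],
          value = grand_means[[v]] + sb[s] + sh[s, se] + eps
        )
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
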
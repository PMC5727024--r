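#' Study processing configuration
#'
#' @param cutoff_kinetic,cutoff_kinematic low-pass cutoffs in Hz for force
#'   and marker channels (defaults 15 and 6)
#' @param filter_order effective Butterworth order (default 4)
#' @param stance_threshold vertical-force contact threshold in N
#' @param solver a [solver_config()]
#' @param icc_form `"ICC21"` or `"ICC31"`
#' @param mdc_convention `"session_mean"` or `"t1_only"`
#' @param marker_noise_sd,session_offset_sd generator noise levels (m)
#' @param stance_duration generated stance time (s)
#' @return list of class `study_config`
#' @export
study_config <- function(cutoff_kinetic = 15, cutoff_kinematic = 6,
                         filter_order = 4, stance_threshold = 20,
                         solver = solver_config(), icc_form = "ICC21",
                         mdc_convention = "session_mean",
                         marker_noise_sd = 0.001, session_offset_sd = 0.003,
                         stance_duration = 1.0) {
  structure(list(cutoff_kinetic = cutoff_kinetic,
                 cutoff_kinematic = cutoff_kinematic,
                 filter_order = filter_order,
                 stance_threshold = stance_threshold,
                 solver = solver, icc_form = icc_form,
                 mdc_convention = mdc_convention,
                 marker_noise_sd = marker_noise_sd,
                 session_offset_sd = session_offset_sd,
                 stance_duration = stance_duration),
            class = "study_config")
}

#' Low-pass filter a trial's marker and kinetic channels
#'
#' Marker trajectories are filtered at the kinematic cutoff (6 Hz), force,
#' centre-of-pressure and free-moment channels at the kinetic cutoff
#' (15 Hz), all zero-phase.
#'
#' @param trial a `motion_trial`
#' @param config a [study_config()]
#' @return the trial with filtered channels
#' @export
preprocess_trial <- function(trial, config = study_config()) {
  sr <- trial$sample_rate
  for (nm in names(trial$markers)) {
    trial$markers[[nm]] <- lowpass_filter(trial$markers[[nm]], sr,
                                          config$cutoff_kinematic,
                                          config$filter_order)
  }
  trial$wrench$force <- lowpass_filter(trial$wrench$force, sr,
                                       config$cutoff_kinetic,
                                       config$filter_order)
  trial$wrench$cop <- lowpass_filter(trial$wrench$cop, sr,
                                     config$cutoff_kinetic,
                                     config$filter_order)
  trial$wrench$free_moment_z <- lowpass_filter(trial$wrench$free_moment_z, sr,
                                               config$cutoff_kinetic,
                                               config$filter_order)
  trial
}

# fit the four marker-cluster segment poses for one frame
fit_frame_poses <- function(trial, frame) {
  manifest <- trial$manifest
  poses <- list()
  for (s in names(manifest$segments)) {
    tmpl <- manifest$segments[[s]]
    obs <- t(vapply(rownames(tmpl),
                    function(nm) trial$markers[[nm]][frame, ], numeric(3)))
    poses[[s]] <- fit_segment_pose(tmpl, obs)
  }
  poses
}

#' Process one trial through the full solver chain
#'
#' Filters the trial, detects stance (for stair trials the box weight is
#' removed before thresholding and the foot wrench recovered through the
#' box), fits segment poses per stance frame, differentiates the segment
#' kinematics, assembles and solves the per-frame equilibrium systems, and
#' returns outcome waveforms and peaks.
#'
#' @param trial a `motion_trial`
#' @param geometry an `msk_geometry` (unscaled; scaled internally to the
#'   trial's segment lengths)
#' @param config a [study_config()]
#' @return list: `waveforms` ([knee_waveforms()]), `peaks`, `stance`
#'   (frame interval), `n_failed`, `usable`, `max_residual`,
#'   `solution` (the `trial_solution`)
#' @export
solve_study_trial <- function(trial, geometry, config = study_config()) {
  trial <- preprocess_trial(trial, config)
  fz <- trial$wrench$force[, 3]
  box_w <- if (!is.null(trial$box)) trial$box$mass * GRAVITY else 0
  st <- detect_stance(fz - box_w, config$stance_threshold)
  frames <- seq(st[1], st[2] - 1)
  if (length(frames) < 5) stop("stance too short to process")

  if (is.null(trial$box)) {
    load_frames <- lapply(frames, function(i) {
      list(force = trial$wrench$force[i, ], cop = trial$wrench$cop[i, ],
           free_moment_z = trial$wrench$free_moment_z[i])
    })
  } else {
    load_frames <- lapply(frames, function(i) {
      bc <- box_cop(trial$wrench$force[i, ], trial$wrench$cop[i, ], trial$box)
      # plate free moment transfers through the quasi-static box
      bc$free_moment_z <- bc$free_moment_z + trial$wrench$free_moment_z[i]
      bc
    })
  }

  poses_seq <- lapply(frames, function(i) fit_frame_poses(trial, i))
  knee_angle <- vapply(poses_seq,
                       function(p) knee_flexion(p$thigh, p$shank), numeric(1))
  patella_model <- default_patella_model(
    ref_local = c(0, -trial$lengths$thigh, 0))
  for (i in seq_along(poses_seq)) {
    poses_seq[[i]]$patella <- patella_pose(poses_seq[[i]]$thigh,
                                           min(max(knee_angle[i], -10), 150),
                                           patella_model)
  }

  geom <- scale_geometry(geometry, trial$lengths, mass = trial$mass)
  inertia <- segment_inertia(geom, trial$mass, trial$lengths)
  kin <- list()
  for (s in EQ_SEGMENTS) {
    kin[[s]] <- differentiate_kinematics(lapply(poses_seq, `[[`, s),
                                         trial$sample_rate,
                                         com_local = inertia[[s]]$com_local)
  }

  systems <- lapply(seq_along(frames), function(i) {
    state <- frame_state(
      poses = poses_seq[[i]],
      kin = lapply(kin, function(kk) list(a_com = kk$a_com[i, ],
                                          omega = kk$omega[i, ],
                                          alpha = kk$alpha[i, ])),
      inertia = inertia, load = load_frames[[i]],
      knee_angle = knee_angle[i]
    )
    assemble_system(state, geom)
  })
  sol <- solve_trial(systems, config$solver)
  max_res <- suppressWarnings(max(vapply(sol$solutions, function(s) {
    if (isTRUE(s$converged)) s$residual else -Inf
  }, numeric(1))))

  wf <- knee_waveforms(sol, trial$mass, knee_angle)
  list(waveforms = wf, peaks = extract_peaks(wf), stance = st,
       n_failed = sol$n_failed, usable = sol$usable,
       max_residual = max_res, solution = sol)
}

trial_seed <- function(base, subject, session, trial, task_idx) {
  (base %% 1000000L) + 1000003L * task_idx + 10007L * subject +
    101L * session + 7L * trial
}

#' Run a full synthetic test-retest study
#'
#' Generates the cohort and all trials for the design, solves every trial,
#' and computes the reliability analysis: per-trial peak values, waveform
#' agreement within session 1, inter-session agreement of session-mean
#' waveforms, group mean confidence bands, and per-task reliability tables
#' (ICC, SEM, MDC, MDC%). Trials whose solver fails on too many frames are
#' excluded and counted. Fully deterministic for a fixed design seed.
#'
#' @param design a [study_design()]
#' @param geometry an `msk_geometry`
#' @param config a [study_config()]
#' @param agreement_variable variable used for the waveform-agreement
#'   summaries (default `"total_tfj"`; peak tables always cover all
#'   variables)
#' @param progress print per-trial progress lines
#' @return list of class `study_report`: `peaks` (long data.frame),
#'   `tables` (per task [build_reliability_table()] outputs), `agreement`
#'   (intra- and inter-session summaries), `group_mean` (per task/session
#'   mean waveform + CI), `exclusions`, `subjects`, `max_residual`
#' @export
run_study <- function(design = study_design(), geometry = load_geometry(),
                      config = study_config(), agreement_variable = "total_tfj",
                      progress = FALSE) {
  subjects <- sample_subjects(design$n_subjects, design$seed)
  peaks <- list(); excl <- list()
  wf_store <- list()
  max_res <- 0
  for (si in seq_len(design$n_subjects)) {
    prof <- subjects[[si]]
    for (se in seq_len(design$n_sessions)) {
      pert <- session_perturbation(
        marker_manifest(segment_lengths(prof)),
        sd = config$session_offset_sd,
        seed = trial_seed(design$seed, si, se, 0L, 9L))
      for (ti in seq_len(design$n_trials_per_session)) {
        for (tk in seq_along(design$tasks)) {
          task <- design$tasks[tk]
          tr <- generate_trial(
            prof, task, perturbation = pert,
            seed = trial_seed(design$seed, si, se, ti, tk),
            stance_duration = config$stance_duration,
            marker_noise_sd = config$marker_noise_sd)
          res <- tryCatch(solve_study_trial(tr, geometry, config),
                          error = function(e) e)
          tag <- sprintf("S%02d T%d trial %d %s", si, se, ti, task)
          if (inherits(res, "error") || !res$usable) {
            excl[[length(excl) + 1]] <- data.frame(
              subject = si, session = se, trial = ti, task = task,
              reason = if (inherits(res, "error")) conditionMessage(res)
                       else sprintf("%d/%d frames failed", res$n_failed,
                                    diff(res$stance)))
            if (progress) message(tag, " EXCLUDED")
            next
          }
          if (is.finite(res$max_residual)) {
            max_res <- max(max_res, res$max_residual)
          }
          pk <- res$peaks
          peaks[[length(peaks) + 1]] <- data.frame(
            subject = si, session = se, trial = ti, task = task,
            variable = pk$variable, value = pk$peak,
            pct_stance = pk$pct_stance)
          wf_store[[paste(si, se, ti, task, sep = "_")]] <- res$waveforms
          if (progress) message(tag, " ok (", res$n_failed, " failed frames)")
        }
      }
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    stop("no usable trials in study")
  exclusions <- if (length(excl)) do.call(rbind, excl) else NULL

  tables <- list()
  for (task in design$tasks) {
    tables[[task]] <- build_reliability_table(
      peaks[peaks$task == task, ],
      icc_form = config$icc_form, mdc_convention = config$mdc_convention)
  }

  get_wf <- function(si, se, ti, task) {
    wf_store[[paste(si, se, ti, task, sep = "_")]]
  }
  agreement <- list(); group_mean <- list()
  for (task in design$tasks) {
    intra <- list(); inter <- list()
    sess_means <- list()
    for (si in seq_len(design$n_subjects)) {
      t1 <- Filter(Negate(is.null),
                   lapply(seq_len(design$n_trials_per_session),
                          function(ti) get_wf(si, 1, ti, task)))
      if (length(t1) >= 2) {
        a <- intra_session_agreement(
          lapply(t1, `[[`, agreement_variable))
        intra[[length(intra) + 1]] <- data.frame(subject = si, r = a$r,
                                                 rms = a$rms)
      }
      if (design$n_sessions >= 2) {
        means <- lapply(1:2, function(se) {
          tw <- Filter(Negate(is.null),
                       lapply(seq_len(design$n_trials_per_session),
                              function(ti) get_wf(si, se, ti, task)))
          if (length(tw)) mean_waveform(lapply(tw, `[[`, agreement_variable))
        })
        if (!any(vapply(means, is.null, logical(1)))) {
          a <- waveform_agreement(means[[1]], means[[2]])
          inter[[length(inter) + 1]] <- data.frame(subject = si, r = a$r,
                                                   rms = a$rms)
          sess_means[[length(sess_means) + 1]] <- means
        }
      }
    }
    agreement[[task]] <- list(
      intra_session = if (length(intra)) do.call(rbind, intra) else NULL,
      inter_session = if (length(inter)) do.call(rbind, inter) else NULL)
    if (length(sess_means) >= 2) {
      group_mean[[task]] <- lapply(1:2, function(se) {
        group_mean_ci(lapply(sess_means, `[[`, se))
      })
    }
  }

  structure(list(design = design, peaks = peaks, tables = tables,
                 agreement = agreement, group_mean = group_mean,
                 exclusions = exclusions, subjects = subjects,
                 max_residual = max_res),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  n_excl <- if (is.null(x$exclusions)) 0 else nrow(x$exclusions)
  cat("<study_report>", x$design$n_subjects, "subjects x",
      x$design$n_sessions, "sessions x", x$design$n_trials_per_session,
      "trials x {", paste(x$design$tasks, collapse = ", "), "}\n")
  cat("  usable trial-peaks rows:", nrow(x$peaks), "; excluded trials:",
      n_excl, "\n")
  for (task in names(x$tables)) {
    cat("  --", task, "reliability table (rounded):\n")
    print(format_reliability_table(x$tables[[task]]), row.names = FALSE)
  }
  invisible(x)
}

#' Write a trial to the interchange CSV schema
#'
#' One row per frame; columns `time_s`, `<marker>_{x,y,z}_m` for each
#' marker, `grf_{x,y,z}_N`, `cop_{x,y}_m`, `free_moment_z_Nm`.
#'
#' @param trial a `motion_trial`
#' @param path output file
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(time_s = trial$time)
  for (nm in names(trial$markers)) {
    M <- trial$markers[[nm]]
    df[[paste0(nm, "_x_m")]] <- M[, 1]
    df[[paste0(nm, "_y_m")]] <- M[, 2]
    df[[paste0(nm, "_z_m")]] <- M[, 3]
  }
  df$grf_x_N <- trial$wrench$force[, 1]
  df$grf_y_N <- trial$wrench$force[, 2]
  df$grf_z_N <- trial$wrench$force[, 3]
  df$cop_x_m <- trial$wrench$cop[, 1]
  df$cop_y_m <- trial$wrench$cop[, 2]
  df$free_moment_z_Nm <- trial$wrench$free_moment_z
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial from the interchange CSV schema
#'
#' @param path CSV written by [write_trial_csv()]
#' @param mass subject body mass (kg), not stored in the CSV
#' @param task task label
#' @param sample_rate Hz (default inferred from `time_s`)
#' @return a `motion_trial` (without generator truth; marker templates must
#'   be supplied separately for pose fitting)
#' @export
read_trial_csv <- function(path, mass, task = "gait", sample_rate = NULL) {
  df <- utils::read.csv(path)
  if (is.null(sample_rate)) {
    sample_rate <- round(1 / stats::median(diff(df$time_s)))
  }
  mcols <- grep("_x_m$", names(df), value = TRUE)
  mnames <- setdiff(sub("_x_m$", "", mcols), "cop")
  markers <- lapply(mnames, function(nm) {
    as.matrix(df[, paste0(nm, c("_x_m", "_y_m", "_z_m"))])
  })
  names(markers) <- mnames
  cop_z <- if ("cop_z_m" %in% names(df)) df$cop_z_m else 0
  structure(list(
    time = df$time_s, sample_rate = sample_rate, task = task, mass = mass,
    markers = markers,
    wrench = list(force = as.matrix(df[, c("grf_x_N", "grf_y_N", "grf_z_N")]),
                  cop = cbind(df$cop_x_m, df$cop_y_m, cop_z),
                  free_moment_z = df$free_moment_z_Nm),
    box = NULL, manifest = NULL, lengths = NULL, truth = NULL
  ), class = "motion_trial")
}

#' Write a study manifest as JSON
#'
#' @param report a `study_report` (or compatible list with design/subjects)
#' @param path output JSON file
#' @param trial_paths optional data.frame (subject, session, trial, task,
#'   path) mapping trials to files
#' @export
write_study_manifest <- function(report, path, trial_paths = NULL) {
  subj <- lapply(seq_along(report$subjects), function(i) {
    p <- report$subjects[[i]]
    list(id = i, mass = p$mass, height = p$height)
  })
  jsonlite::write_json(list(design = unclass(report$design), subjects = subj,
                            trials = trial_paths),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
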
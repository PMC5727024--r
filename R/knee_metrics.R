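#' Outcome waveforms from a solved trial
#'
#' Converts per-frame force solutions into the outcome variables: medial,
#' lateral and total tibiofemoral contact force (TFJ), medial TFJ share,
#' patellofemoral contact force (PFJ), summed quadriceps (vastus medialis +
#' intermedialis + lateralis) and hamstrings (biceps femoris long head +
#' semitendinosus + semimembranosus) forces, and knee flexion. Forces are
#' magnitudes of the corresponding reaction vectors normalized by body
#' weight (mass x 9.81); everything is spline-resampled to 100 points of
#' percent stance. Total TFJ is the arithmetic sum of the medial and
#' lateral magnitudes, so the two compartment shares sum to 100%. Share
#' values where total TFJ falls below `share_floor` (xBW) are flagged NA to
#' avoid 0/0. Failed frames are filled by linear interpolation across
#' neighbouring converged frames before resampling.
#'
#' @param trial_sol a `trial_solution` over the stance frames
#' @param mass body mass (kg)
#' @param knee_angle_deg numeric vector of knee flexion (deg) per stance frame
#' @param share_floor minimum total TFJ (xBW) for share computation
#' @return list of class `knee_waveforms`: stance waveforms plus
#'   `body_weight` (N)
#' @export
knee_waveforms <- function(trial_sol, mass, knee_angle_deg,
                           share_floor = 0.05) {
  if (mass <= 0) stop("mass must be positive")
  sols <- trial_sol$solutions
  conv <- trial_sol$converged
  if (!any(conv)) stop("no converged frames in trial")
  n <- length(sols)
  bw <- mass * GRAVITY

  series <- function(getter) {
    v <- rep(NA_real_, n)
    for (i in which(conv)) v[i] <- getter(sols[[i]])
    if (anyNA(v)) {
      idx <- which(!is.na(v))
      v <- stats::approx(idx, v[idx], xout = seq_len(n), rule = 2)$y
    }
    v
  }
  mag <- function(s, r) sqrt(sum(s$reactions[[r]]^2))
  med <- series(function(s) mag(s, "R_med_tfj")) / bw
  lat <- series(function(s) mag(s, "R_lat_tfj")) / bw
  pfj <- series(function(s) mag(s, "R_pfj")) / bw
  musc_sum <- function(names) {
    series(function(s) sum(s$forces[names], na.rm = TRUE))
  }
  quad <- musc_sum(c("vastus_medialis", "vastus_intermedialis",
                     "vastus_lateralis")) / bw
  ham <- musc_sum(c("biceps_femoris_long_head", "semitendinosus",
                    "semimembranosus")) / bw

  w_med <- resample_stance(med, "xBW")
  w_lat <- resample_stance(lat, "xBW")
  total_v <- abs(w_med$values) + abs(w_lat$values)
  w_tot <- stance_waveform(total_v, "xBW")
  share_v <- ifelse(total_v >= share_floor,
                    100 * abs(w_med$values) / total_v, NA_real_)
  w_share <- stance_waveform(share_v, "%")

  structure(list(
    medial_tfj = w_med, lateral_tfj = w_lat, total_tfj = w_tot,
    medial_share = w_share,
    pfj = resample_stance(pfj, "xBW"),
    quadriceps = resample_stance(quad, "xBW"),
    hamstrings = resample_stance(ham, "xBW"),
    knee_flexion = resample_stance(knee_angle_deg, "deg"),
    body_weight = bw
  ), class = "knee_waveforms")
}

# the reportable variables of a knee_waveforms object, in table order
KNEE_VARIABLES <- c("total_tfj", "lateral_tfj", "medial_tfj", "medial_share",
                    "pfj", "quadriceps", "hamstrings", "knee_flexion")

#' Peak values and their percent-of-stance locations
#'
#' The peak of each outcome waveform over the 100-point stance grid, with
#' the grid location of the (earliest, in case of ties) maximum. NA points
#' (e.g. flagged share values) are ignored.
#'
#' @param w a [knee_waveforms()]
#' @return data.frame: variable, peak, pct_stance, units
#' @export
extract_peaks <- function(w) {
  rows <- lapply(KNEE_VARIABLES, function(v) {
    wf <- w[[v]]
    vals <- wf$values
    if (all(is.na(vals))) stop("variable ", v, " has no usable points")
    i <- which(vals == max(vals, na.rm = TRUE))[1]
    data.frame(variable = v, peak = vals[i], pct_stance = wf$grid[i],
               units = wf$units, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
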
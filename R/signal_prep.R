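#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a low-pass Butterworth filter forward and backward so the net
#' phase response is zero (stance timing must not shift). The requested
#' `order` is the *effective* order: a filter of order `order/2` is designed
#' and applied twice, which squares its magnitude response. Endpoints are
#' handled by odd reflection padding of at least three filter lengths so the
#' filter state is warmed up before it reaches the data.
#'
#' Marker trajectories are conventionally filtered at 6 Hz and force-plate
#' channels at 15 Hz before musculoskeletal modelling; see
#' [preprocess_trial()].
#'
#' @param x numeric vector, or a matrix whose columns are channels
#' @param sample_rate sampling frequency in Hz
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist frequency
#' @param order effective filter order (even; default 4)
#' @return filtered data with the same shape as `x`
#' @export
lowpass_filter <- function(x, sample_rate, cutoff, order = 4) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    return(apply(x, 2, lowpass_filter,
                 sample_rate = sample_rate, cutoff = cutoff, order = order))
  }
  nyq <- sample_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         nyq, " Hz)")
  }
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even number")
  half <- order / 2
  bf <- signal::butter(half, cutoff / nyq, type = "low")
  # padding: several cutoff periods (>= 3 filter lengths) so the filter
  # state settles inside the pad, capped by the data length
  npad <- max(3 * (order + 1), ceiling(3 * sample_rate / cutoff))
  n <- length(x)
  if (n < 4) stop("series too short to filter (need >= 4 samples)")
  npad <- min(npad, n - 1)
  # odd (point-symmetric) reflection about the endpoints
  head_pad <- 2 * x[1] - x[seq(npad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xp <- c(head_pad, x, tail_pad)
  # filter about the endpoint level so the zero-state transient vanishes
  # identically for constant signals
  y <- as.numeric(signal::filter(bf, xp - xp[1])) + xp[1]
  y <- rev(y)
  y <- as.numeric(signal::filter(bf, y - y[1])) + y[1]
  y <- rev(y)
  y[seq(npad + 1, npad + n)]
}

#' Detect the stance phase from the vertical ground reaction force
#'
#' The stance phase is taken as the longest contiguous run of frames whose
#' vertical ground reaction force exceeds `threshold`.
#'
#' @param fz numeric vector of vertical force (N), one value per frame
#' @param threshold contact threshold in N (default 20)
#' @return integer vector `c(start, end)`: a half-open frame interval
#'   `[start, end)` in 1-based indexing, i.e. frames `start ... end - 1`
#'   are in contact
#' @export
detect_stance <- function(fz, threshold = 20) {
  above <- fz > threshold
  if (!any(above)) stop("no frame exceeds the contact threshold of ",
                        threshold, " N")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  best <- on[which.max(r$lengths[on])]
  c(start = starts[best], end = ends[best] + 1L)
}

#' Construct a percent-of-stance waveform
#' @param values numeric length-100
#' @param units unit label ("xBW", "%", "deg", "N", ...)
#' @return object of class `stance_waveform`
#' @export
stance_waveform <- function(values, units = "") {
  values <- as.numeric(values)
  if (length(values) != 100) stop("a stance waveform has exactly 100 points")
  structure(list(values = values,
                 grid = seq(0, 100, length.out = 100),
                 units = units),
            class = "stance_waveform")
}

#' @export
print.stance_waveform <- function(x, ...) {
  cat("<stance_waveform> 100 points, units:",
      if (nzchar(x$units)) x$units else "(none)", "\n")
  cat("  range:", signif(min(x$values), 4), "to", signif(max(x$values), 4), "\n")
  invisible(x)
}

#' Time-normalize a stance-phase signal to 100 points
#'
#' Fits a cubic spline through the stance-phase samples and evaluates it at
#' 100 evenly spaced points spanning 0-100% of stance inclusive (step
#' 100/99). The spline interpolates the original samples exactly, so a
#' signal already on the 100-point grid is returned unchanged.
#'
#' @param x numeric vector of samples covering the stance phase (>= 4)
#' @param units unit label carried into the result
#' @return a [stance_waveform()]
#' @export
resample_stance <- function(x, units = "") {
  n <- length(x)
  if (n < 4) stop("need at least 4 stance frames to spline-fit")
  pct_in <- seq(0, 100, length.out = n)
  grid <- seq(0, 100, length.out = 100)
  out <- stats::spline(pct_in, x, xout = grid, method = "fmm")$y
  stance_waveform(out, units = units)
}

#' Transfer a force-plate wrench through a box step to the foot
#'
#' During stair ascent the instrumented step is a rigid box resting on the
#' force plate. Treating the box as quasi-static, the sum of forces and of
#' moments acting on it is zero, which determines both the force the foot
#' applies to its top surface and the centre of pressure of that contact:
#' the foot-ground reaction is the plate force minus the supported box
#' weight, and the foot CoP is located on the top surface so that the net
#' moment on the box about its centre of mass vanishes (the plate force
#' acting through the plate CoP). Any residual axial couple is returned as a
#' vertical free moment at the foot contact.
#'
#' @param plate_force plate-on-box force (N, 3-vector or n x 3 matrix)
#' @param plate_cop plate centre of pressure (m, same shape)
#' @param box list with `mass` (kg), `com` (m 3-vector, global),
#'   `top_height` (m)
#' @return list with `force` (foot-ground reaction), `cop` (on the top
#'   surface, z = top_height) and `free_moment_z` (N m)
#' @export
box_cop <- function(plate_force, plate_cop, box) {
  if (is.matrix(plate_force)) {
    out <- lapply(seq_len(nrow(plate_force)), function(i) {
      box_cop(plate_force[i, ], plate_cop[i, ], box)
    })
    return(list(
      force = do.call(rbind, lapply(out, `[[`, "force")),
      cop = do.call(rbind, lapply(out, `[[`, "cop")),
      free_moment_z = vapply(out, `[[`, numeric(1), "free_moment_z")
    ))
  }
  if (box$mass < 0) stop("box mass must be nonnegative")
  plate_force <- as.numeric(plate_force)
  plate_cop <- as.numeric(plate_cop)
  w <- c(0, 0, box$mass * GRAVITY)
  grf <- plate_force - w            # foot-ground reaction transmitted by box
  if (grf[3] <= 0) {
    if (max(abs(grf)) < 1e-6) {
      # unloaded box: the plate carries exactly the box weight
      return(list(force = c(0, 0, 0),
                  cop = c(box$com[1], box$com[2], box$top_height),
                  free_moment_z = 0))
    }
    stop("vertical foot force is not positive: no foot contact")
  }
  # foot-on-box force G = -grf; moment balance about the box CoM:
  #   (r_p - com) x F_plate + (r_c - com) x G + Tz ez = 0, r_c on top surface
  m0 <- cross3(plate_cop - box$com, plate_force)
  G <- -grf
  dz <- box$top_height - box$com[3]
  dx <- (dz * G[1] + m0[2]) / G[3]
  dy <- (dz * G[2] - m0[1]) / G[3]
  cop <- box$com + c(dx, dy, dz)
  tz <- -(m0[3] + dx * G[2] - dy * G[1])
  list(force = grf, cop = cop, free_moment_z = tz)
}
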
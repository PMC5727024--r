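#' Waveform agreement: Pearson correlation and RMS difference
#'
#' @param w1,w2 [stance_waveform()] objects (same units)
#' @return list `r` (Pearson correlation over the 100 paired points; NA with
#'   a warning if either waveform has zero variance) and `rms` (root mean
#'   squared pointwise difference)
#' @export
waveform_agreement <- function(w1, w2) {
  v1 <- w1$values; v2 <- w2$values
  ok <- !is.na(v1) & !is.na(v2)
  v1 <- v1[ok]; v2 <- v2[ok]
  rms <- sqrt(mean((v1 - v2)^2))
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero-variance waveform: correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(v1, v2)
  }
  list(r = r, rms = rms)
}

#' Mean within-session agreement over all trial pairs
#'
#' Compares every unordered pair of a subject-session's trials (1v2, 1v3,
#' 2v3 for three trials; the single pair for two) and averages the
#' correlation and RMS.
#'
#' @param trials list of >= 2 [stance_waveform()]s
#' @return list `r`, `rms` (means over pairs) and `n_pairs`
#' @export
intra_session_agreement <- function(trials) {
  m <- length(trials)
  if (m < 2) stop("need at least 2 trials for intra-session agreement")
  rs <- c(); rmss <- c()
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    a <- waveform_agreement(trials[[i]], trials[[j]])
    rs <- c(rs, a$r); rmss <- c(rmss, a$rms)
  }
  list(r = mean(rs), rms = mean(rmss), n_pairs = length(rs))
}

#' Pointwise mean waveform over trials
#' @param trials list of [stance_waveform()]s (>= 1)
#' @return a [stance_waveform()]
#' @export
mean_waveform <- function(trials) {
  if (!length(trials)) stop("no trials to average")
  V <- vapply(trials, function(w) w$values, numeric(100))
  stance_waveform(rowMeans(as.matrix(V), na.rm = TRUE),
                  units = trials[[1]]$units)
}

#' Group mean waveform with pointwise normal confidence band
#'
#' @param subject_means list of per-subject [stance_waveform()]s (>= 2)
#' @param level confidence level (default 0.95)
#' @return list of stance waveforms: `mean`, `lower`, `upper`
#'   (mean +/- z * SD/sqrt(n))
#' @export
group_mean_ci <- function(subject_means, level = 0.95) {
  n <- length(subject_means)
  if (n < 2) stop("need at least 2 subjects for a confidence band")
  V <- vapply(subject_means, function(w) w$values, numeric(100))
  mu <- rowMeans(V)
  half <- stats::qnorm(1 - (1 - level) / 2) * apply(V, 1, stats::sd) / sqrt(n)
  units <- subject_means[[1]]$units
  list(mean = stance_waveform(mu, units),
       lower = stance_waveform(mu - half, units),
       upper = stance_waveform(mu + half, units))
}

#' Intraclass correlation from a subjects x sessions matrix
#'
#' Two-way ANOVA decomposition. The default form is the two-way random,
#' absolute-agreement, single-measures coefficient
#' \deqn{ICC(2,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n)}
#' with the consistency form ICC(3,1) selectable.
#'
#' @param values numeric matrix, rows = subjects (n >= 2), columns =
#'   sessions (k >= 2), complete
#' @param form `"ICC21"` (absolute agreement) or `"ICC31"` (consistency)
#' @return scalar ICC
#' @export
icc <- function(values, form = c("ICC21", "ICC31")) {
  form <- match.arg(form)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 sessions")
  if (anyNA(values)) stop("incomplete subjects x sessions matrix")
  grand <- mean(values)
  rm_ <- rowMeans(values); cm_ <- colMeans(values)
  if (sum((values - grand)^2) == 0) stop("zero total variance: ICC undefined")
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  mse <- sum((values - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + grand)^2) / ((n - 1) * (k - 1))
  if (form == "ICC21") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Standard error of measurement
#'
#' \eqn{SEM = SD \sqrt{1 - ICC}}, with SD the between-subject standard
#' deviation of the first test session.
#'
#' @param sd_t1 session-1 between-subject SD (>= 0)
#' @param icc intraclass correlation in [0, 1]
#' @return SEM in the units of `sd_t1`
#' @export
sem <- function(sd_t1, icc) {
  if (sd_t1 < 0) stop("sd must be nonnegative")
  if (icc < 0 || icc > 1) stop("icc must lie in [0, 1]")
  sd_t1 * sqrt(1 - icc)
}

#' Minimal detectable change at 95% confidence
#'
#' \eqn{MDC = SEM \times 1.96 \times \sqrt{2}}; the \eqn{\sqrt 2} accounts
#' for the error of two measurements being compared.
#'
#' @param sem SEM (>= 0)
#' @return MDC in the units of `sem`
#' @export
mdc <- function(sem) {
  if (any(sem < 0)) stop("sem must be nonnegative")
  sem * 1.96 * sqrt(2)
}

#' MDC as a percentage of the mean peak value
#'
#' @param mdc MDC value
#' @param mean_t1,mean_t2 session group means
#' @param convention `"session_mean"` (default; denominator is the mean of
#'   the two session means) or `"t1_only"`
#' @return percentage
#' @export
mdc_percent <- function(mdc, mean_t1, mean_t2 = mean_t1,
                        convention = c("session_mean", "t1_only")) {
  convention <- match.arg(convention)
  den <- if (convention == "session_mean") (mean_t1 + mean_t2) / 2 else mean_t1
  if (den <= 0) stop("denominator must be positive")
  100 * mdc / den
}

#' Test-retest reliability table from a peak-value dataset
#'
#' For each variable: subject-session means over usable trials, session
#' group mean and between-subject SD, the ICC across sessions, SEM (from
#' the session-1 SD), MDC and MDC%. Subjects missing an entire session for
#' a variable are dropped from that variable's ICC with a warning. All
#' values are kept at full precision; round at report time with
#' [format_reliability_table()].
#'
#' @param peaks data.frame with columns subject, session, trial, variable,
#'   value (e.g. long format of per-trial peak values)
#' @param icc_form passed to [icc()]
#' @param mdc_convention passed to [mdc_percent()]
#' @return data.frame of class `reliability_table`: variable, t1_mean,
#'   t1_sd, t2_mean, t2_sd, icc, sem, mdc, mdc_pct, n_subjects
#' @export
build_reliability_table <- function(peaks, icc_form = "ICC21",
                                    mdc_convention = "session_mean") {
  need <- c("subject", "session", "variable", "value")
  if (!all(need %in% names(peaks))) {
    stop("peaks must have columns ", paste(need, collapse = ", "))
  }
  sessions <- sort(unique(peaks$session))
  if (length(sessions) < 2) stop("need >= 2 sessions")
  out <- list()
  for (v in unique(peaks$variable)) {
    pv <- peaks[peaks$variable == v & !is.na(peaks$value), ]
    agg <- stats::aggregate(value ~ subject + session, data = pv, FUN = mean)
    M <- stats::reshape(agg, idvar = "subject", timevar = "session",
                        direction = "wide")
    mat <- as.matrix(M[, -1, drop = FALSE])
    complete <- stats::complete.cases(mat)
    if (sum(complete) < nrow(mat)) {
      warning(v, ": dropping ", sum(!complete),
              " subject(s) missing a session")
    }
    mat <- mat[complete, , drop = FALSE]
    if (nrow(mat) < 2) stop(v, ": fewer than 2 complete subjects")
    icc_v <- icc(mat, form = icc_form)
    t1 <- mat[, 1]; t2 <- mat[, 2]
    icc_cl <- min(max(icc_v, 0), 1)   # Eq. SEM needs ICC in [0,1]
    sem_v <- sem(stats::sd(t1), icc_cl)
    mdc_v <- mdc(sem_v)
    out[[length(out) + 1]] <- data.frame(
      variable = v,
      t1_mean = mean(t1), t1_sd = stats::sd(t1),
      t2_mean = mean(t2), t2_sd = stats::sd(t2),
      icc = icc_v, sem = sem_v, mdc = mdc_v,
      mdc_pct = mdc_percent(mdc_v, mean(t1), mean(t2),
                            convention = mdc_convention),
      n_subjects = nrow(mat),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("reliability_table", "data.frame")
  res
}

#' Round a reliability table at report precision
#'
#' Half-up rounding at the conventional printed precision: 2 decimals for
#' xBW-scale values, 1 for percentages and degrees; ICC at 2 decimals.
#'
#' @param tbl a [build_reliability_table()] result
#' @param digits named vector variable -> decimal places (default 2; use 1
#'   for share/angle variables)
#' @return rounded data.frame
#' @export
format_reliability_table <- function(tbl, digits = NULL) {
  if (is.null(digits)) {
    digits <- ifelse(tbl$variable %in% c("medial_share", "knee_flexion"), 1, 2)
  }
  out <- tbl
  for (col in c("t1_mean", "t1_sd", "t2_mean", "t2_sd", "sem", "mdc")) {
    out[[col]] <- round_half_up(tbl[[col]], digits)
  }
  out$icc <- round_half_up(tbl$icc, 2)
  out$mdc_pct <- round_half_up(tbl$mdc_pct, 0)
  out
}
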
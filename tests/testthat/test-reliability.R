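wf <- function(v, units = "xBW") stance_waveform(v, units)

test_that("waveform agreement computes Pearson r and pointwise RMS", {
  x <- sin(seq(0, 2 * pi, length.out = 100))
  a <- waveform_agreement(wf(x), wf(x))
  expect_equal(a$r, 1)
  expect_equal(a$rms, 0)

  b <- waveform_agreement(wf(x), wf(x + 0.5))
  expect_equal(b$r, 1)
  expect_equal(b$rms, 0.5)

  expect_equal(waveform_agreement(wf(x), wf(-x))$r, -1)
  expect_warning(waveform_agreement(wf(rep(1, 100)), wf(x)), "zero-variance")
})

test_that("intra-session agreement averages all unordered trial pairs", {
  x <- seq(0, 1, length.out = 100)
  t1 <- wf(x); t2 <- wf(x + 0.2); t3 <- wf(2 * x)
  same <- intra_session_agreement(list(t1, wf(x), wf(x)))
  expect_equal(same$r, 1)
  expect_equal(same$rms, 0)
  expect_equal(same$n_pairs, 3)

  two <- intra_session_agreement(list(t1, t2))
  expect_equal(two$n_pairs, 1)
  expect_equal(two$rms, 0.2)

  three <- intra_session_agreement(list(t1, t2, t3))
  hand <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    ws <- list(t1, t2, t3)
    c(cor(ws[[pr[1]]]$values, ws[[pr[2]]]$values),
      sqrt(mean((ws[[pr[1]]]$values - ws[[pr[2]]]$values)^2)))
  })
  expect_equal(three$r, mean(hand[1, ]))
  expect_equal(three$rms, mean(hand[2, ]))
  expect_error(intra_session_agreement(list(t1)), "at least 2")
})

test_that("mean waveforms and group confidence bands are pointwise", {
  x <- seq(0, 1, length.out = 100)
  expect_equal(mean_waveform(list(wf(x)))$values, x)
  expect_equal(mean_waveform(list(wf(x), wf(-x)))$values, rep(0, 100))
  hand <- (x + 2 * x + 4 * x) / 3
  expect_equal(mean_waveform(list(wf(x), wf(2 * x), wf(4 * x)))$values, hand)

  same <- group_mean_ci(list(wf(x), wf(x), wf(x)))
  expect_equal(same$lower$values, same$upper$values)

  # n = 4 subjects with pointwise SD exactly 2 -> half-width 1.96 x 2 / 2
  offs <- c(-3, -1, 1, 3) * (2 / sd(c(-3, -1, 1, 3)))
  subj <- lapply(offs, function(o) wf(x + o))
  ci <- group_mean_ci(subj)
  expect_equal(ci$mean$values, x, tolerance = 1e-12)
  expect_equal(ci$upper$values - ci$mean$values, rep(1.96, 100),
               tolerance = 1e-4)
  expect_error(group_mean_ci(list(wf(x))), "at least 2")
})

test_that("ICC matches an independent two-way ANOVA oracle", {
  M <- rbind(c(1, 2), c(2, 3), c(3, 4))
  # oracle: mean squares from stats::aov on the long two-way layout
  long <- data.frame(y = as.vector(M),
                     subj = factor(rep(1:3, 2)),
                     sess = factor(rep(1:2, each = 3)))
  av <- summary(stats::aov(y ~ subj + sess, data = long))[[1]]
  msr <- av["subj", "Mean Sq"]; msc <- av["sess", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  n <- 3; k <- 2
  oracle21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  oracle31 <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(icc(M, "ICC21"), oracle21, tolerance = 1e-12)
  expect_equal(icc(M, "ICC31"), oracle31, tolerance = 1e-12)

  # identical sessions with subject variance -> perfect agreement
  expect_equal(icc(cbind(1:5, 1:5)), 1)
  # exchangeability over subjects
  expect_equal(icc(M[c(3, 1, 2), ]), icc(M))
  # invariance to adding a constant
  expect_equal(icc(M + 100), icc(M), tolerance = 1e-9)
  expect_error(icc(matrix(1, 3, 2)), "zero total variance")
  expect_error(icc(rbind(c(1, NA), c(2, 3))), "incomplete")
})

test_that("SEM and MDC reproduce the published worked examples", {
  expect_equal(round_half_up(sem(1.75, 0.96), 2), 0.35)
  expect_equal(round_half_up(sem(4.2, 0.87), 1), 1.5)
  expect_equal(sem(3, 1), 0)
  expect_error(sem(1, 1.2), "\\[0, 1\\]")

  expect_equal(round_half_up(mdc(sem(1.75, 0.96)), 2), 0.97)
  expect_equal(round_half_up(mdc(2.1), 1), 5.8)
  expect_equal(mdc(0), 0)
  expect_error(mdc(-1), "nonnegative")

  # MDC / SEM is the fixed factor 1.96 sqrt(2)
  s <- runif(20)
  expect_equal(mdc(s) / s, rep(1.96 * sqrt(2), 20))
  # monotone: higher ICC never increases SEM
  iccs <- seq(0, 1, 0.1)
  expect_true(all(diff(sapply(iccs, sem, sd_t1 = 2)) <= 0))
})

test_that("MDC percentages reproduce the published worked examples", {
  mdc_tot <- mdc(sem(1.75, 0.96))
  expect_equal(round_half_up(mdc_percent(mdc_tot, 5.43, 5.47), 0), 18)
  expect_equal(round_half_up(mdc_percent(1.93, 3.80, 4.04), 0), 49)
  expect_equal(mdc_percent(0.4, 2, 2, "session_mean"),
               mdc_percent(0.4, 2, 2, "t1_only"))
  expect_error(mdc_percent(1, 0, 0), "positive")
})

test_that("reliability tables match a hand computation", {
  # 3 subjects x 2 sessions x 2 trials, one variable
  vals <- data.frame(
    subject = rep(1:3, each = 4),
    session = rep(rep(1:2, each = 2), 3),
    trial = rep(1:2, 6),
    variable = "peak",
    value = c(4.0, 4.2, 4.3, 4.5,
              5.6, 5.4, 5.9, 6.1,
              3.1, 3.3, 3.0, 2.8)
  )
  tbl <- build_reliability_table(vals)
  # hand computation (spreadsheet style)
  m <- rbind(c(mean(c(4.0, 4.2)), mean(c(4.3, 4.5))),
             c(mean(c(5.6, 5.4)), mean(c(5.9, 6.1))),
             c(mean(c(3.1, 3.3)), mean(c(3.0, 2.8))))
  expect_equal(tbl$t1_mean, mean(m[, 1]))
  expect_equal(tbl$t1_sd, sd(m[, 1]))
  expect_equal(tbl$t2_mean, mean(m[, 2]))
  expect_equal(tbl$icc, icc(m))
  expect_equal(tbl$sem, sd(m[, 1]) * sqrt(1 - icc(m)))
  expect_equal(tbl$mdc, tbl$sem * 1.96 * sqrt(2))
  expect_equal(tbl$mdc_pct, 100 * tbl$mdc / ((tbl$t1_mean + tbl$t2_mean) / 2))

  # identical sessions: perfect reliability
  v2 <- vals; v2$value <- rep(c(4, 5, 3), each = 4)
  tbl2 <- build_reliability_table(v2)
  expect_equal(tbl2$icc, 1)
  expect_equal(tbl2$sem, 0)
  expect_equal(tbl2$mdc, 0)
})

test_that("reliability recovery from a synthetic peak dataset", {
  # one trial per session so the table's subject-session means carry the
  # full trial-level variance (ICC estimand = the spec'd 0.9)
  des <- study_design(n_subjects = 200, n_trials_per_session = 1,
                      seed = 31, tasks = "gait")
  d <- generate_peak_dataset(des, variance_spec(3, 1, 0), c(peak = 5))
  tbl <- build_reliability_table(d)
  expect_lt(abs(tbl$icc - 0.9), 0.05)

  # averaging 3 trials per session shrinks the trial-noise share: the
  # estimand becomes vb / (vb + vw/3)
  des3 <- study_design(n_subjects = 200, n_trials_per_session = 3,
                       seed = 32, tasks = "gait")
  d3 <- generate_peak_dataset(des3, variance_spec(3, 1, 0), c(peak = 5))
  expect_lt(abs(build_reliability_table(d3)$icc - 9 / (9 + 1 / 3)), 0.05)
})

test_that("report rounding is half-up at printed precision", {
  expect_equal(round_half_up(0.345, 2), 0.35)
  expect_equal(round_half_up(4.15, 1), 4.2)
  expect_equal(round_half_up(-0.345, 2), -0.35)
  tbl <- data.frame(variable = "medial_share", t1_mean = 86.94, t1_sd = 4.24,
                    t2_mean = 87.01, t2_sd = 4.16, icc = 0.874, sem = 1.507,
                    mdc = 4.178, mdc_pct = 17.8, n_subjects = 9)
  out <- format_reliability_table(tbl)
  expect_equal(out$t1_mean, 86.9)
  expect_equal(out$sem, 1.5)
  expect_equal(out$mdc_pct, 18)
})
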
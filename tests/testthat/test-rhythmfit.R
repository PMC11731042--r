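t120 <- seq(0, 119.5, by = 0.5)

test_that("detrending removes the trend it models", {
  df <- tibble::tibble(time_h = t120, s1 = rep(5, length(t120)))
  for (m in c("linear", "poly3", "movavg")) {
    out <- detrend_series(df, method = m)
    expect_true(all(abs(out$s1) < 1e-9), info = m)
  }

  y <- 2 * t120 + cos(2 * pi * t120 / 24)
  res <- detrend_series(tibble::tibble(time_h = t120, s = y), "linear")$s
  expect_gt(cor(res, cos(2 * pi * t120 / 24)), 0.99)

  # moving average over one full period barely touches the oscillation
  y2 <- cos(2 * pi * t120 / 24.5)
  res2 <- detrend_series(tibble::tibble(time_h = t120, s = y2), "movavg",
                         window_h = 24.5)$s
  interior <- t120 > 13 & t120 < 107
  expect_lt(max(abs(res2[interior] - y2[interior])), 0.05)

  expect_error(detrend_series(df[1:10, ], "movavg", window_h = 24.5), "window")
})

test_that("FFT-NLLS recovers noise-free damped cosines precisely", {
  for (Tp in c(22, 24, 24.5, 26)) {
    df <- tibble::tibble(time_h = t120,
                         s = 5 * cos(2 * pi * (t120 - 6) / Tp))
    fit <- fit_rhythms(df)
    expect_lt(abs(fit$period_h - Tp), 0.1)
    expect_lt(abs(fit$phase_h - 6), 0.25)
    expect_lt(abs(fit$amplitude - 5) / 5, 0.05)
    expect_lt(fit$rae, 0.1)
    expect_true(fit$circadian)
  }
  # damping is recovered too
  fd <- scnphase:::fit_fftnlls(t120, 5 * exp(-0.01 * t120) *
                                 cos(2 * pi * (t120 - 6) / 24))
  expect_lt(abs(fd$period_h - 24), 0.1)
  expect_lt(abs(fd$damping - 0.01), 0.005)
})

test_that("RAE grows with noise and white noise is called non-circadian", {
  withr::with_seed(10, {
    mean_rae <- vapply(c(0.5, 2.5, 5), function(s) {
      mean(replicate(15, {
        y <- 5 * cos(2 * pi * (t120 - 6) / 24) + rnorm(length(t120), 0, s)
        scnphase:::fit_fftnlls(t120, y)$rae
      }))
    }, numeric(1))
  })
  expect_true(all(diff(mean_rae) > 0))
  expect_lt(mean_rae[1], 0.1)

  withr::with_seed(11, {
    raes <- replicate(30, scnphase:::fit_fftnlls(t120, rnorm(length(t120)))$rae)
  })
  expect_gte(mean(raes == 1), 0.95)
})

test_that("moderate noise leaves the mean period nearly unbiased", {
  withr::with_seed(12, {
    periods <- replicate(40, {
      y <- 5 * cos(2 * pi * (t120 - 6) / 24) + rnorm(length(t120), 0, 2.5)
      scnphase:::fit_fftnlls(t120, y)$period_h
    })
  })
  expect_lt(abs(mean(periods) - 24), 0.3)
})

test_that("fits are amplitude- and time-shift-equivariant", {
  y <- 4 * cos(2 * pi * (t120 - 5) / 24.5)
  f1 <- scnphase:::fit_fftnlls(t120, y)
  f2 <- scnphase:::fit_fftnlls(t120, 3 * y)
  expect_equal(f2$amplitude / f1$amplitude, 3, tolerance = 1e-3)
  expect_equal(f2$period_h, f1$period_h, tolerance = 1e-3)
  expect_equal(f2$phase_h, f1$phase_h, tolerance = 1e-3)
  expect_equal(f2$rae, f1$rae, tolerance = 1e-3)

  yshift <- 4 * cos(2 * pi * (t120 - 8) / 24.5)  # shifted by 3 h
  f3 <- scnphase:::fit_fftnlls(t120, yshift)
  expect_equal((f3$phase_h - f1$phase_h) %% f1$period_h, 3, tolerance = 0.05)
})

test_that("averaged-peaks phase handles symmetric and flat-topped waveforms", {
  # trough at 2 h, period 24 -> midpoint rule gives 14 h
  y_tr <- -cos(2 * pi * (t120 - 2) / 24)
  expect_equal(phase_from_peaks(t120, y_tr, 24, flat_peak = TRUE), 14,
               tolerance = 0.5)

  # symmetric cosine: both estimators agree within one sample
  y <- cos(2 * pi * (t120 - 7) / 24)
  expect_lt(abs(phase_from_peaks(t120, y, 24) -
                phase_from_peaks(t120, y, 24, flat_peak = TRUE)), 0.5)

  # flat-topped waveform (sharp trough, broad plateau): the midpoint rule
  # finds the plateau center while direct peak-picking wanders across it
  withr::with_seed(13, {
    err_flat <- err_default <- numeric(12)
    for (i in 1:12) {
      yf <- ((1 + cos(2 * pi * (t120 - 8) / 24)) / 2)^0.3 +
        rnorm(length(t120), 0, 0.08)
      ef <- phase_from_peaks(t120, yf, 24, flat_peak = TRUE) - 8
      ed <- phase_from_peaks(t120, yf, 24) - 8
      err_flat[i] <- abs(((ef + 12) %% 24) - 12)
      err_default[i] <- abs(((ed + 12) %% 24) - 12)
    }
  })
  expect_lt(mean(err_flat), mean(err_default))
  expect_lt(mean(err_flat), 0.5)
  expect_error(phase_from_peaks(t120[1:20], cos(2 * pi * t120[1:20] / 24), 24),
               "2 peaks")
})

test_that("CT calibration follows the reference convention", {
  expect_equal(calibrate_ct(10, 10), 12)
  expect_equal(calibrate_ct(17, 10), 19)  # 7 h after a CT12 reference
  expect_equal(calibrate_ct(4, 10), 6)    # 6 h before
  expect_equal(calibrate_ct(2, 20), 18)   # wraps
})

test_that("first-cycle relative amplitude is a self-ratio", {
  y <- cos(2 * pi * t120 / 24)
  expect_equal(first_cycle_amplitude(t120, y, 60, detrend = FALSE), 1,
               tolerance = 0.05)
  yh <- ifelse(t120 < 60, 1, 0.5) * cos(2 * pi * t120 / 24)
  expect_equal(first_cycle_amplitude(t120, yh, 60, detrend = FALSE), 0.5,
               tolerance = 0.05)
})

test_that("signal slope is the OLS slope of the raw signal", {
  expect_equal(signal_slope(t120, 3 * t120), 3, tolerance = 1e-9)
  y <- cos(2 * pi * t120 / 24)
  expect_lt(abs(signal_slope(t120, y, c(0, 96 - 0.5))), 0.005)
  expect_error(signal_slope(t120, t120, c(0, 0.5)), "fewer")
})

test_that("first-peak alignment recovers known offsets and tightens replicates", {
  df <- tibble::tibble(time_h = t120,
                       a = cos(2 * pi * (t120 - 14) / 24),
                       b = cos(2 * pi * (t120 - 17) / 24),
                       c = cos(2 * pi * (t120 - 21) / 24))
  al <- align_first_peak(df)
  offs <- al$offsets$offset_h
  expect_equal(offs - offs[1], c(0, 3, 7), tolerance = 0.1)
  m <- as.matrix(al$aligned[, -1])
  expect_lt(max(apply(m, 1, function(r) diff(range(r)))), 0.05)

  withr::with_seed(14, {
    noisy <- tibble::tibble(time_h = t120)
    true_pk <- 14 + rnorm(6, 0, 1.5)
    for (i in 1:6)
      noisy[[paste0("r", i)]] <- cos(2 * pi * (t120 - true_pk[i]) / 24) +
        rnorm(length(t120), 0, 0.2)
  })
  al2 <- align_first_peak(noisy)
  expect_lt(sd(al2$offsets$offset_h - true_pk), sd(true_pk))
})

test_that("tidy and glance summarize rhythm fits", {
  df <- tibble::tibble(time_h = t120, s1 = 5 * cos(2 * pi * (t120 - 6) / 24),
                       s2 = 2 * cos(2 * pi * (t120 - 1) / 25))
  fit <- fit_rhythms(df)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "rhythm_fit"))
  gl <- glance(fit)
  expect_equal(gl$n_series, 2)
  expect_equal(gl$n_circadian, 2)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
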
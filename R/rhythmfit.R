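#' Detrend time series
#'
#' Removes slow trends before rhythm analysis. `linear` and `poly3` subtract
#' a least-squares polynomial fit; `movavg` subtracts a centered moving mean
#' whose window defaults to 24.5 h (one full circadian cycle, so the
#' oscillation itself is untouched), shrinking at the edges.
#'
#' @param data wide data frame: time column (hours) + one column per series.
#' @param method `"linear"`, `"poly3"` or `"movavg"`.
#' @param window_h moving-average window in hours (movavg only).
#' @param time_col time column name; default the first column.
#' @return Tibble of the same shape with detrended series.
#' @export
detrend_series <- function(data, method = c("linear", "poly3", "movavg"),
                           window_h = 24.5, time_col = NULL) {
  method <- match.arg(method)
  ser <- series_matrix(data, time_col)
  out <- apply(ser$y, 2, function(y)
    detrend_vec(ser$t_h, y, method, window_h))
  res <- tibble::as_tibble(out, .name_repair = "minimal")
  names(res) <- colnames(ser$y)
  dplyr::bind_cols(tibble::tibble(time_h = ser$t_h), res)
}

detrend_vec <- function(t, y, method = "linear", window_h = 24.5) {
  n <- length(y)
  switch(method,
    linear = {
      if (n < 3) abort("series too short for linear detrend")
      y - stats::fitted(lm(y ~ t))
    },
    poly3 = {
      if (n < 5) abort("series too short for poly3 detrend")
      y - stats::fitted(lm(y ~ poly(t, 3)))
    },
    movavg = {
      dt <- t[2] - t[1]
      half <- window_h / 2
      if (window_h >= (n - 1) * dt + dt)
        abort("moving-average window longer than the series")
      ma <- vapply(seq_len(n), function(i) {
        idx <- which(t >= t[i] - half & t <= t[i] + half)
        mean(y[idx])
      }, numeric(1))
      y - ma
    },
    abort(sprintf("unknown detrend method '%s'", method))
  )
}

#' Fit circadian rhythms by FFT-seeded nonlinear least squares (FFT-NLLS)
#'
#' For each series, spectral peaks of the FFT seed candidate components
#' (period, phase, amplitude); components are added one at a time and fitted
#' jointly as a sum of exponentially damped cosines
#' \eqn{\sum_i A_i e^{-d_i t} \cos(2\pi (t - \phi_i)/T_i)} by
#' Levenberg-Marquardt least squares, stopping when the newest component's
#' amplitude confidence interval (Bonferroni-corrected over the number of
#' candidate frequencies) includes zero. The component whose period lies in
#' `period_window` is reported; its relative amplitude error (RAE) is the
#' half-width of the amplitude's 95% confidence interval divided by the
#' amplitude, clipped to \[0, 1\]. RAE 0 means a perfectly determined
#' rhythm; series with no significant circadian component get RAE 1 and an
#' undefined period.
#'
#' Phases are absolute peak times in hours on \[0, period), not scaled by
#' the estimated period.
#'
#' @param data wide data frame: time (hours) + one column per detrended
#'   series.
#' @param period_window circadian search window in hours, default (18, 34).
#' @param time_col time column name; default the first column.
#' @param max_components maximum number of damped-cosine components.
#' @return A `rhythm_fit` tibble, one row per series: `series`, `period_h`,
#'   `phase_h`, `amplitude`, `damping`, `rae`, `circadian` (a component in
#'   the window was significant), `n_components`. Fitted curves are kept in
#'   `attr(, "curves")` for plotting.
#' @export
fit_rhythms <- function(data, period_window = c(18, 34), time_col = NULL,
                        max_components = 3L) {
  ser <- series_matrix(data, time_col)
  rows <- list(); curves <- list()
  for (j in seq_len(ncol(ser$y))) {
    f <- fit_fftnlls(ser$t_h, ser$y[, j], period_window, max_components)
    rows[[j]] <- tibble::tibble(series = colnames(ser$y)[j],
                                period_h = f$period_h, phase_h = f$phase_h,
                                amplitude = f$amplitude, damping = f$damping,
                                rae = f$rae, circadian = f$circadian,
                                n_components = f$n_components)
    curves[[j]] <- tibble::tibble(series = colnames(ser$y)[j], time_h = ser$t_h,
                                  observed = ser$y[, j], fitted = f$fitted)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- dplyr::bind_rows(curves)
  class(out) <- c("rhythm_fit", class(out))
  out
}

# Single-series FFT-NLLS engine.
fit_fftnlls <- function(t, y, period_window = c(18, 34), max_components = 3L) {
  n <- length(y)
  dt <- t[2] - t[1]
  dur <- t[n] - t[1]
  y0 <- y - mean(y)
  # spectral candidates: local maxima of the periodogram
  sp <- Mod(fft(y0))[2:floor(n / 2)]
  ph_sp <- Arg(fft(y0))[2:floor(n / 2)]
  freq <- (1:(floor(n / 2) - 1)) / (n * dt)
  is_pk <- sp >= c(-Inf, head(sp, -1)) & sp >= c(tail(sp, -1), -Inf)
  cand <- order(sp * is_pk, decreasing = TRUE)
  cand <- cand[sp[cand] > 0 & is_pk[cand]]
  n_cand <- max(1L, length(cand))
  seed_from <- function(k) {
    Tk <- 1 / freq[k]
    list(A = 2 * sp[k] / n, T = Tk,
         phi = wrap_phase(-ph_sp[k] / (2 * pi) * Tk, Tk), d = 0.01)
  }
  model_resid <- function(par) {
    m <- numeric(n)
    nc <- length(par) / 4
    for (i in seq_len(nc)) {
      p <- par[(4 * i - 3):(4 * i)]
      m <- m + p[1] * exp(-p[4] * t) * cos(2 * pi * (t - p[3]) / p[2])
    }
    y0 - m
  }
  fit_pars <- function(start) {
    nc <- length(start) / 4
    lower <- rep(c(0, 2 * dt, -Inf, 0), nc)
    upper <- rep(c(Inf, 3 * dur, Inf, 0.5), nc)
    ctl <- minpack.lm::nls.lm.control(maxiter = 200)
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = model_resid, control = ctl)
  }
  amp_ci <- function(fit, level_q) {
    par <- fit$par
    res <- model_resid(par)
    p <- length(par)
    dof <- max(n - p, 1)
    s2 <- sum(res^2) / dof
    J <- num_jacobian(model_resid, par)
    JtJ <- crossprod(J)
    cv <- try(solve(JtJ), silent = TRUE)
    if (inherits(cv, "try-error")) cv <- MASS_ginv(JtJ)
    se <- sqrt(pmax(0, diag(cv)) * s2)
    nc <- p / 4
    a_idx <- 4 * seq_len(nc) - 3
    list(A = par[a_idx], half = stats::qt(level_q, dof) * se[a_idx])
  }
  # add components while the newest is significant
  kept <- numeric(0)
  used <- integer(0)
  bonf_q <- 1 - 0.025 / n_cand
  fit <- NULL
  for (k in cand) {
    if (length(kept) / 4 >= max_components) break
    s <- seed_from(k)
    trial <- fit_pars(c(kept, s$A, s$T, s$phi, s$d))
    ci <- amp_ci(trial, bonf_q)
    nc <- length(trial$par) / 4
    if (ci$A[nc] - ci$half[nc] > 0) {
      kept <- trial$par
      used <- c(used, k)
      fit <- trial
    } else break
  }
  in_window <- function(par) {
    nc <- length(par) / 4
    Ts <- par[4 * seq_len(nc) - 2]
    which(Ts >= period_window[1] & Ts <= period_window[2])
  }
  # if nothing in the window yet, try the strongest in-window candidate
  if (length(kept) && length(in_window(kept)) == 0L ||
      length(kept) == 0L) {
    win_cand <- cand[freq[cand] >= 1 / period_window[2] &
                     freq[cand] <= 1 / period_window[1]]
    win_cand <- setdiff(win_cand, used)
    if (length(win_cand)) {
      s <- seed_from(win_cand[1])
      trial <- fit_pars(c(kept, s$A, s$T, s$phi, s$d))
      ci <- amp_ci(trial, bonf_q)
      nc <- length(trial$par) / 4
      if (ci$A[nc] - ci$half[nc] > 0) {
        kept <- trial$par
        fit <- trial
      }
    }
  }
  empty <- list(period_h = NA_real_, phase_h = NA_real_, amplitude = NA_real_,
                damping = NA_real_, rae = 1, circadian = FALSE,
                n_components = 0L, fitted = rep(mean(y), n))
  if (length(kept) == 0L) return(empty)
  wi <- in_window(kept)
  nc <- length(kept) / 4
  if (length(wi) == 0L) {
    empty$n_components <- nc
    empty$fitted <- y - model_resid(kept)
    return(empty)
  }
  ci95 <- amp_ci(fit, 0.975)
  comp <- wi[which.max(ci95$A[wi])]
  p <- kept[(4 * comp - 3):(4 * comp)]
  rae <- min(1, max(0, ci95$half[comp] / ci95$A[comp]))
  list(period_h = p[2], phase_h = wrap_phase(p[3], p[2]),
       amplitude = p[1], damping = p[4], rae = rae, circadian = TRUE,
       n_components = nc,
       fitted = y - model_resid(kept))
}

num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- eps * max(1, abs(par[i]))
    p2 <- par; p2[i] <- p2[i] + h
    J[, i] <- (fn(p2) - f0) / h
  }
  -J  # fn returns residuals y - m; Jacobian of the model
}

# small pseudo-inverse helper (avoids importing MASS for one call)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf("<rhythm_fit> %d series, %d circadian\n", nrow(x), sum(x$circadian)))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy rhythm_fit
#' @export
tidy.rhythm_fit <- function(x, ...) {
  out <- x
  attr(out, "curves") <- NULL
  class(out) <- setdiff(class(out), "rhythm_fit")
  out
}

#' @method glance rhythm_fit
#' @export
glance.rhythm_fit <- function(x, ...) {
  circ <- x[x$circadian, ]
  tibble::tibble(
    n_series = nrow(x), n_circadian = sum(x$circadian),
    mean_period_h = mean(circ$period_h),
    mean_rae = mean(circ$rae),
    mean_amplitude = mean(circ$amplitude))
}

#' Estimate phase from averaged peak times
#'
#' The default phase estimate: peak times are found on a lightly smoothed
#' copy of the series (Savitzky-Golay, ~5 h window) with parabolic
#' refinement, and the per-cycle peak phases are averaged circularly. For
#' flat-peaked waveforms the midpoint rule is used instead: the trough phase
#' is estimated on the inverted series and the phase is
#' `(trough + period/2) mod period`.
#'
#' @param t,y time (hours) and signal vectors.
#' @param period_h known/estimated period in hours.
#' @param flat_peak use the trough-midpoint rule?
#' @param smooth_h smoothing window in hours.
#' @return Phase in hours on \[0, period_h).
#' @export
phase_from_peaks <- function(t, y, period_h, flat_peak = FALSE, smooth_h = 5) {
  if (flat_peak) {
    trough <- phase_from_peaks(t, -y, period_h, flat_peak = FALSE,
                               smooth_h = smooth_h)
    return(wrap_phase(trough + period_h / 2, period_h))
  }
  pk <- find_peaks(t, y, period_h, smooth_h)
  if (length(pk) < 2)
    abort("fewer than 2 peaks detected; cannot average peak phases")
  ph <- hours_to_rad(pk, period_h)
  rad_to_hours(circ_mean(ph)$mean, period_h)
}

# peak times via smoothed local maxima + parabolic refinement,
# enforcing >= half a period separation
find_peaks <- function(t, y, period_h, smooth_h = 5) {
  n <- length(y)
  dt <- t[2] - t[1]
  w <- max(5L, 2L * floor(smooth_h / dt / 2) + 1L)
  w <- min(w, 2L * floor((n - 1) / 2) - 1L)
  ys <- signal::sgolayfilt(y, p = 2, n = w)
  loc <- which(ys > c(-Inf, head(ys, -1)) & ys >= c(tail(ys, -1), -Inf))
  edge <- (w - 1) %/% 2  # smoother edge effects can fake maxima
  loc <- loc[loc > max(1, edge) & loc < n - max(0, edge - 1)]
  # ignore ripples in flat regions: demand a quarter of the dynamic range
  loc <- loc[ys[loc] >= min(ys) + 0.25 * (max(ys) - min(ys))]
  if (!length(loc)) return(numeric(0))
  loc <- loc[order(ys[loc], decreasing = TRUE)]
  keep <- integer(0)
  for (i in loc) {
    if (!length(keep) || all(abs(t[i] - t[keep]) >= 0.7 * period_h))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  vapply(keep, function(i) {
    # parabolic 3-point refinement
    a <- ys[i - 1]; b <- ys[i]; cc <- ys[i + 1]
    den <- a - 2 * b + cc
    off <- if (abs(den) > 1e-12) 0.5 * (a - cc) / den else 0
    t[i] + max(-1, min(1, off)) * dt
  }, numeric(1))
}

#' Calibrate phase to circadian time (CT)
#'
#' Expresses a reporter's phase on the CT scale given a co-detected
#' reference whose CT is known (conventionally the PER2::LUC peak defines
#' CT12): `phase_ct = (phase_h - reference_phase_h + reference_ct) mod T`.
#'
#' @param phase_h reporter phase(s) in hours.
#' @param reference_phase_h reference reporter's phase in hours.
#' @param reference_ct CT of the reference peak (default 12).
#' @param period_h cycle length.
#' @return Phase(s) on the CT scale, in \[0, period_h).
#' @export
calibrate_ct <- function(phase_h, reference_phase_h, reference_ct = 12,
                         period_h = 24) {
  wrap_phase(phase_h - reference_phase_h + reference_ct, period_h)
}

#' Relative amplitude of the first cycle after an event
#'
#' Ratio of the post-event first-cycle amplitude to the pre-event one: the
#' (max - min)/2 of the linearly detrended series over `window_h` after the
#' event, divided by the same quantity over the window immediately before.
#'
#' @param t,y time (hours) and raw signal.
#' @param event_h event time in hours.
#' @param window_h cycle window (default 30 h).
#' @param detrend detrend linearly before measuring? (default TRUE)
#' @return Relative amplitude (1 = unchanged).
#' @export
first_cycle_amplitude <- function(t, y, event_h, window_h = 30, detrend = TRUE) {
  if (detrend) y <- detrend_vec(t, y, "linear")
  post <- y[t >= event_h & t < event_h + window_h]
  pre <- y[t >= event_h - window_h & t < event_h]
  if (length(post) < 4 || length(pre) < 4)
    abort("windows around the event are too short")
  ((max(post) - min(post)) / 2) / ((max(pre) - min(pre)) / 2)
}

#' Linear slope of the raw signal over a window
#'
#' Ordinary least-squares slope of the undetrended signal, used to quantify
#' slow drifts in reporter baseline (intensity/h).
#'
#' @param t,y time (hours) and raw signal.
#' @param window `c(t0, t1)` in hours; default the full series.
#' @return Slope in intensity/h.
#' @export
signal_slope <- function(t, y, window = range(t)) {
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 3) abort("window contains fewer than 3 points")
  unname(coef(lm(y[sel] ~ t[sel]))[2])
}

#' Align series on their first peak
#'
#' Shifts each series so its first detected peak after a burn-in sits at
#' t = 0, then interpolates all series onto the common overlapping time
#' grid. Used to average replicate slices without phase smearing.
#'
#' @param data wide data frame: time (hours) + one column per series.
#' @param period_h approximate period for peak separation.
#' @param burn_in_h ignore peaks before this time (default 12 h).
#' @param time_col time column name; default the first column.
#' @return List: `aligned` (wide tibble on the common grid, time from the
#'   aligned peak) and `offsets` (tibble `series`, `offset_h`).
#' @export
align_first_peak <- function(data, period_h = 24, burn_in_h = 12,
                             time_col = NULL) {
  ser <- series_matrix(data, time_col)
  offs <- vapply(seq_len(ncol(ser$y)), function(j) {
    pk <- find_peaks(ser$t_h, ser$y[, j], period_h)
    pk <- pk[pk >= burn_in_h]
    if (!length(pk)) abort(sprintf("no peak after burn-in in series '%s'",
                                   colnames(ser$y)[j]))
    pk[1]
  }, numeric(1))
  dt <- ser$dt_h
  lo <- max(ser$t_h[1] - offs)
  hi <- min(ser$t_h[length(ser$t_h)] - offs)
  grid <- seq(ceiling(lo / dt) * dt, floor(hi / dt) * dt, by = dt)
  aligned <- vapply(seq_len(ncol(ser$y)), function(j) {
    approx(ser$t_h - offs[j], ser$y[, j], xout = grid)$y
  }, numeric(length(grid)))
  aligned <- tibble::as_tibble(aligned, .name_repair = "minimal")
  names(aligned) <- colnames(ser$y)
  list(aligned = dplyr::bind_cols(tibble::tibble(time_h = grid), aligned),
       offsets = tibble::tibble(series = colnames(ser$y), offset_h = offs))
}
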
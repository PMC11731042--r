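#' Cluster ROI time series with Lloyd k-means
#'
#' Partitions the slice's ROI time series into `k` spatiotemporal clusters.
#' Each ROI series is linearly detrended and z-score normalized, then
#' clustered with the classical EM-style Lloyd algorithm (`n_init` random
#' restarts, best within-cluster sum of squares kept). Clusters are
#' renumbered by their spatial center of mass (row-major) so labels are
#' stable across runs with identical input.
#'
#' @param rois a `roi_set` from [grid_rois()] (or any object with `centers`,
#'   `series`, `dt_h`, `dim`).
#' @param k number of clusters (default 5).
#' @param seed RNG seed for initialization.
#' @param n_init number of random restarts.
#' @return An object of class `cluster_map`: `labels` (per-ROI cluster id),
#'   `centers` (ROI centroids + label), `mean_series` (k x T, means of the
#'   normalized member series), `k`, `dt_h`, `dim`, `label_image`,
#'   `channel`.
#' @export
cluster_rois <- function(rois, k = 5, seed = 1L, n_init = 10L) {
  if (nrow(rois$centers) < k)
    abort(sprintf("fewer ROIs (%d) than clusters (%d)", nrow(rois$centers), k))
  t_h <- (seq_len(ncol(rois$series)) - 1) * rois$dt_h
  z <- t(apply(rois$series, 1, function(y) {
    yd <- detrend_vec(t_h, y, "linear")
    s <- stats::sd(yd)
    if (!is.finite(s) || s < 1e-12) rep(0, length(yd)) else yd / s
  }))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  km <- withCallingHandlers(
    kmeans(z, centers = k, algorithm = "Lloyd", nstart = n_init,
           iter.max = 200L),
    warning = function(w) {
      # random restarts make occasional empty-cluster proposals; harmless
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  # stable relabeling by spatial center of mass
  com <- vapply(seq_len(k), function(c_) {
    sel <- km$cluster == c_
    c(mean(rois$centers$row[sel]), mean(rois$centers$col[sel]))
  }, numeric(2))
  ord <- order(com[1, ], com[2, ])
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  mean_series <- t(vapply(seq_len(k), function(c_)
    colMeans(z[labels == c_, , drop = FALSE]), numeric(ncol(z))))
  centers <- rois$centers
  centers$cluster <- labels
  li <- matrix(NA_integer_, rois$dim[1], rois$dim[2])
  half <- (rois$roi_size - 1) / 2
  for (i in seq_len(nrow(centers))) {
    rr <- (centers$row[i] - half):(centers$row[i] + half)
    cc <- (centers$col[i] - half):(centers$col[i] + half)
    li[rr, cc] <- labels[i]
  }
  structure(list(labels = labels, centers = centers,
                 mean_series = mean_series, k = k, dt_h = rois$dt_h,
                 dim = rois$dim, label_image = li, channel = rois$channel,
                 normalized = z),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> '%s': k = %d over %d ROIs", x$channel, x$k,
              length(x$labels)))
  if (!is.null(x$summary))
    cat(sprintf("; %d rhythmic, dispersal V = %.3f",
                sum(x$summary$rhythmic), x$dispersal_V))
  cat("\n")
  invisible(x)
}

#' Fit and test each cluster's mean series
#'
#' Runs the rhythmicity test and phase estimation on every cluster's mean
#' series: non-rhythmic clusters are flagged NR; rhythmic clusters get an
#' absolute phase (averaged-peaks estimate at the slice-common period, with
#' the flat-peak midpoint rule when requested). The slice-common period
#' comes from an FFT-NLLS fit of the mean of all cluster series, so
#' per-cluster period noise does not leak into phase comparisons. The
#' inter-cluster phase dispersal V (circular variance of rhythmic cluster
#' phases) is attached.
#'
#' @param cm a `cluster_map` from [cluster_rois()].
#' @param alpha rhythmicity threshold on the empirical p.
#' @param n_null null-sample count for the empirical p (default resolves
#'   `alpha`).
#' @param flat_peak use the trough-midpoint phase rule (flat-topped
#'   reporters)?
#' @param period_window FFT-NLLS search window for the common period.
#' @param seed seed for the null distribution.
#' @param refs optional pre-built `reference_set` (speeds up batch runs).
#' @return The `cluster_map` with `summary` (tibble: cluster, n_roi, tau,
#'   p_empirical, rhythmic, phase_h), `common_period_h`, `dispersal_V`
#'   (NA when < 2 rhythmic clusters).
#' @export
summarize_clusters <- function(cm, alpha = 1e-4, n_null = NULL,
                               flat_peak = FALSE, period_window = c(18, 34),
                               seed = 1L, refs = NULL) {
  t_h <- (seq_len(ncol(cm$mean_series)) - 1) * cm$dt_h
  df <- tibble::as_tibble(t(cm$mean_series), .name_repair = "minimal")
  names(df) <- paste0("cluster_", seq_len(cm$k))
  df <- dplyr::bind_cols(tibble::tibble(time_h = t_h), df)
  calls <- test_rhythm(df, period_h = 24, alpha = alpha, n_null = n_null,
                       seed = seed, refs = refs)
  # slice-common period from the grand mean of cluster series
  grand <- colMeans(cm$mean_series)
  gfit <- fit_fftnlls(t_h, grand, period_window)
  common_T <- if (gfit$circadian) gfit$period_h else 24
  # absolute phase per cluster: the FFT-NLLS fitted phase (peak time of the
  # circadian component); any waveform-shape bias is shared across clusters
  # and cancels in dispersal/vector statistics. Flat-peaked channels use the
  # trough-midpoint rule instead; peak averaging is the fallback.
  phases <- rep(NA_real_, cm$k)
  for (c_ in seq_len(cm$k)) {
    if (!calls$rhythmic[c_]) next
    ph <- NA_real_
    if (!flat_peak) {
      f <- try(fit_fftnlls(t_h, cm$mean_series[c_, ], period_window),
               silent = TRUE)
      if (!inherits(f, "try-error") && f$circadian)
        ph <- wrap_phase(f$phase_h, common_T)
    }
    if (!is.finite(ph)) {
      pk <- try(phase_from_peaks(t_h, cm$mean_series[c_, ], common_T,
                                 flat_peak = flat_peak), silent = TRUE)
      if (!inherits(pk, "try-error")) ph <- pk
    }
    phases[c_] <- ph
  }
  rhythmic <- calls$rhythmic & !is.na(phases)
  cm$summary <- tibble::tibble(
    cluster = seq_len(cm$k),
    n_roi = as.integer(table(factor(cm$labels, levels = seq_len(cm$k)))),
    tau = calls$tau, p_empirical = calls$p_empirical,
    rhythmic = rhythmic, phase_h = phases)
  cm$common_period_h <- common_T
  cm$dispersal_V <- if (sum(rhythmic) >= 2)
    phase_dispersal(phases[rhythmic], common_T) else NA_real_
  cm
}

#' Inter-cluster phase dispersal (circular variance of phases)
#'
#' Converts phases in hours to angles \eqn{x = 2\pi (\phi \bmod T)/T} and
#' evaluates \eqn{V = 1 - \sqrt{(\sum\sin x)^2 + (\sum\cos x)^2}/n}: 0 for a
#' fully synchronized slice, 1 for complete dispersal. This is the
#' circuit-level synchrony metric of the phase-mapping analysis.
#'
#' @param phases_h phases in hours (>= 2 required).
#' @param period_h common period in hours.
#' @return V in \[0, 1\].
#' @export
phase_dispersal <- function(phases_h, period_h) {
  phases_h <- phases_h[is.finite(phases_h)]
  if (length(phases_h) < 2)
    abort("phase dispersal needs at least 2 phases")
  circ_var(hours_to_rad(phases_h, period_h))
}

#' Phase-wave direction vector
#'
#' Quantifies the spatial progression of the phase map: each rhythmic
#' cluster's spatial center of mass is regressed (row and column
#' separately) on its phase; the vector `(d col/d phase, d row/d phase)`
#' gives the direction and speed (px/h) of phase progression. The vector is
#' flagged undefined when fewer than 3 rhythmic clusters exist, the phase
#' range is below `2 * dt`, or the mean regression R-squared falls below
#' `r2_threshold` (e.g. in uniformly phased slices, where direction is
#' meaningless).
#'
#' @param cm a summarized `cluster_map`.
#' @param r2_threshold minimum mean R-squared for a defined vector.
#' @return One-row tibble: `angle_deg` (ccw from +col), `speed_px_per_h`,
#'   `r2`, `defined`, `n_clusters`.
#' @export
wave_vector <- function(cm, r2_threshold = 0.5) {
  if (is.null(cm$summary)) abort("run summarize_clusters() first")
  s <- cm$summary[cm$summary$rhythmic, ]
  undef <- tibble::tibble(angle_deg = NA_real_, speed_px_per_h = NA_real_,
                          r2 = NA_real_, defined = FALSE,
                          n_clusters = nrow(s))
  if (nrow(s) < 3) return(undef)
  com <- t(vapply(s$cluster, function(c_) {
    sel <- cm$labels == c_
    c(row = mean(cm$centers$row[sel]), col = mean(cm$centers$col[sel]))
  }, numeric(2)))
  # unwrap phases around their circular mean so regression sees no seam
  ph <- s$phase_h
  Tc <- cm$common_period_h
  ph <- phase_distance(ph, Tc,
                       reference_h = rad_to_hours(circ_mean(hours_to_rad(ph, Tc))$mean, Tc))
  if (diff(range(ph)) < 2 * cm$dt_h) return(undef)
  fr <- lm(com[, "row"] ~ ph)
  fc <- lm(com[, "col"] ~ ph)
  drow <- coef(fr)[2]; dcol <- coef(fc)[2]
  # fit quality along the recovered direction (an axis-aligned wave has no
  # variance in the orthogonal coordinate, so per-axis R2 would mislead)
  u <- c(drow, dcol) / sqrt(drow^2 + dcol^2)
  proj <- com %*% u
  r2 <- suppressWarnings(summary(lm(proj ~ ph))$r.squared)
  tibble::tibble(
    angle_deg = (atan2(drow, dcol) * 180 / pi) %% 360,
    speed_px_per_h = sqrt(drow^2 + dcol^2),
    r2 = r2,
    defined = is.finite(r2) && r2 >= r2_threshold,
    n_clusters = nrow(s))
}

#' SD-across-clusters profile
#'
#' At each timepoint, the standard deviation across the k cluster mean
#' series. Synchronized slices (uniform phase) give flat, low profiles;
#' phase-waved slices give larger, oscillating profiles.
#'
#' @param cm a `cluster_map`.
#' @return Tibble: `time_h`, `sd_across_clusters`.
#' @export
cluster_sd_profile <- function(cm) {
  tibble::tibble(
    time_h = (seq_len(ncol(cm$mean_series)) - 1) * cm$dt_h,
    sd_across_clusters = apply(cm$mean_series, 2, stats::sd))
}

#' Circular histogram of wave-vector directions + Rayleigh test
#'
#' Bins the angles of defined wave vectors from many slices and tests them
#' for uniformity (Rayleigh). Undefined vectors are excluded from the test
#' but counted.
#'
#' @param vectors tibble of [wave_vector()] rows (one per slice).
#' @param bin_width_deg histogram bin width in degrees.
#' @return List: `histogram` (tibble `bin_mid_deg`, `count`), `rayleigh`
#'   (one-row tibble or NULL when no defined vectors), `n_defined`,
#'   `n_undefined`.
#' @export
direction_histogram <- function(vectors, bin_width_deg = 30) {
  def <- vectors[which(vectors$defined), , drop = FALSE]
  breaks <- seq(0, 360, by = bin_width_deg)
  hist_tbl <- tibble::tibble(
    bin_mid_deg = head(breaks, -1) + bin_width_deg / 2,
    count = as.integer(table(cut(def$angle_deg %% 360, breaks,
                                 include.lowest = TRUE))))
  ray <- if (nrow(def) > 0)
    rayleigh_test(def$angle_deg * pi / 180) else NULL
  if (is.null(ray))
    rlang::inform("all wave vectors undefined; uniformity test skipped")
  list(histogram = hist_tbl, rayleigh = ray,
       n_defined = nrow(def), n_undefined = sum(!vectors$defined))
}

#' @method tidy cluster_map
#' @export
tidy.cluster_map <- function(x, ...) {
  if (is.null(x$summary)) abort("run summarize_clusters() first")
  out <- x$summary
  out$channel <- x$channel
  out
}

#' @method glance cluster_map
#' @export
glance.cluster_map <- function(x, ...) {
  if (is.null(x$summary)) abort("run summarize_clusters() first")
  tibble::tibble(channel = x$channel, k = x$k,
                 n_roi = length(x$labels),
                 n_rhythmic = sum(x$summary$rhythmic),
                 common_period_h = x$common_period_h,
                 dispersal_V = x$dispersal_V)
}
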
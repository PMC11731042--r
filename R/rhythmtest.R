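#' Build a reference-waveform set for rhythmicity testing
#'
#' Constructs the family of phase- and asymmetry-shifted reference waveforms
#' used by the empirical JTK_CYCLE-style test. Each template is a piecewise
#' ("asymmetric") cosine with peak at its phase offset, falling to the trough
#' over `(1 - a) * T` and rising back over `a * T`, where `a` is the
#' asymmetry (peak fraction). `a = 0.5` recovers a standard cosine.
#'
#' @param period_h template period in hours.
#' @param dt_h sampling interval in hours.
#' @param n_time number of timepoints the tested series have.
#' @param phase_step_h phase-grid step; default `dt_h`.
#' @param asymmetries vector of peak-fraction values in (0, 1).
#' @return An object of class `reference_set`: template matrix plus a
#'   metadata tibble (`phase_h`, `asymmetry`) and precomputed rank structures
#'   for fast Kendall correlation.
#' @export
build_references <- function(period_h, dt_h, n_time,
                             phase_step_h = dt_h,
                             asymmetries = seq(0.1, 0.9, by = 0.1)) {
  stopifnot_scalar(period_h, "period_h", positive = TRUE)
  stopifnot_scalar(dt_h, "dt_h", positive = TRUE)
  if (phase_step_h > dt_h + 1e-9)
    warn("phase grid step exceeds sampling interval; phase resolution is limited by the grid")
  if (any(asymmetries <= 0 | asymmetries >= 1))
    abort("`asymmetries` must lie strictly in (0, 1)")
  t_h <- (seq_len(n_time) - 1) * dt_h
  phases <- seq(0, period_h - phase_step_h / 2, by = phase_step_h)
  meta <- tidyr::expand_grid(phase_h = phases, asymmetry = asymmetries)
  templates <- mapply(function(ph, a) {
    asym_cosine(t_h, period_h, ph, a)
  }, meta$phase_h, meta$asymmetry)
  templates <- sweep(templates, 2, colMeans(templates))  # zero-mean contract
  ord <- apply(templates, 2, order) - 1L
  grp <- apply(templates, 2, function(v) {
    sv <- v[order(v)]
    cumsum(c(1L, as.integer(diff(sv) != 0)))
  })
  n1 <- apply(grp, 2, function(g) {
    tt <- tabulate(g)
    sum(tt * (tt - 1) / 2)
  })
  structure(list(
    period_h = period_h, dt_h = dt_h, n_time = n_time,
    meta = meta, templates = templates,
    ord = ord, grp = grp, n1 = as.numeric(n1)
  ), class = "reference_set")
}

# Asymmetric cosine, peak at t = phase_h, rise fraction a of the cycle.
asym_cosine <- function(t_h, period_h, phase_h, a) {
  u <- ((t_h - phase_h) / period_h) %% 1
  fall <- 1 - a  # peak -> trough over (1-a)T
  ifelse(u < fall,
         cos(pi * u / fall),            # 1 at u=0 down to -1 at u=fall
         -cos(pi * (u - fall) / a))     # back up to 1 at u=1
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set> period %.3g h, %d timepoints @ %.3g h, %d templates (%d phases x %d asymmetries)\n",
    x$period_h, x$n_time, x$dt_h, ncol(x$templates),
    length(unique(x$meta$phase_h)), length(unique(x$meta$asymmetry))))
  invisible(x)
}

#' Best Kendall correlation against a reference set
#'
#' Computes the exact tie-corrected Kendall \eqn{\tau} (tau-b) between a
#' series and every template in a [build_references()] set and returns the
#' maximum with its phase and asymmetry. Because the phase grid covers a full
#' period, anti-phase signals are absorbed into the phase search and
#' \eqn{\tau} is reported on \[0, 1\] for non-degenerate input.
#'
#' @param y numeric series (detrended), sampled as the reference set expects.
#' @param refs a `reference_set`.
#' @return One-row tibble: `tau`, `best_phase_h`, `best_asymmetry`,
#'   `degenerate` (TRUE for constant input, where `tau` is set to 0).
#' @export
best_tau <- function(y, refs) {
  if (!inherits(refs, "reference_set")) abort("`refs` must be a reference_set")
  y <- as.numeric(y)
  if (length(y) != refs$n_time)
    abort(sprintf("series length %d does not match reference set (%d)", length(y), refs$n_time))
  if (anyNA(y)) abort("series contains NA")
  if (max(y) == min(y)) {
    return(tibble::tibble(tau = 0, best_phase_h = NA_real_,
                          best_asymmetry = NA_real_, degenerate = TRUE))
  }
  taus <- kendall_tau_templates(y, refs$ord, refs$grp, refs$n1)
  i <- which.max(taus)
  tibble::tibble(tau = taus[i], best_phase_h = refs$meta$phase_h[i],
                 best_asymmetry = refs$meta$asymmetry[i], degenerate = FALSE)
}

# In-session cache of null tau distributions, keyed by grid geometry.
.null_cache <- new.env(parent = emptyenv())

#' Null distribution of the best tau under white noise
#'
#' Draws `n_null` Gaussian white-noise series of the same length and grid and
#' records each one's best tau over the reference set. The distribution is
#' cached in-session per (reference geometry, n_null, seed), so repeated
#' tests on series of identical shape reuse it.
#'
#' @param refs a `reference_set`.
#' @param n_null number of null series.
#' @param seed RNG seed for the null draws.
#' @return Numeric vector of `n_null` best-tau values (sorted).
#' @export
null_tau_distribution <- function(refs, n_null = 9999L, seed = 1L) {
  key <- paste(refs$period_h, refs$dt_h, refs$n_time, ncol(refs$templates),
               n_null, seed, sep = "_")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- vapply(seq_len(n_null), function(i) {
    yn <- rnorm(refs$n_time)
    max(kendall_tau_templates(yn, refs$ord, refs$grp, refs$n1))
  }, numeric(1))
  out <- sort(out)
  .null_cache[[key]] <- out
  out
}

#' Empirical p-value for an observed best tau
#'
#' \eqn{p = (1 + \#\{\tau_{null} \ge \tau_{obs}\}) / (n_{null} + 1)}, the
#' standard add-one empirical p against the white-noise null.
#'
#' @param tau_obs observed best tau.
#' @param null_taus vector from [null_tau_distribution()].
#' @param alpha significance threshold the caller intends to apply; a warning
#'   is raised when the null is too small to resolve it.
#' @return Empirical p-value in (0, 1\].
#' @export
empirical_p <- function(tau_obs, null_taus, alpha = 1e-4) {
  n_null <- length(null_taus)
  if (n_null < 1 / alpha - 1)
    warn(sprintf("n_null = %d cannot resolve alpha = %g (min attainable p = %.3g)",
                 n_null, alpha, 1 / (n_null + 1)))
  (1 + sum(null_taus >= tau_obs)) / (n_null + 1)
}

#' Empirical JTK_CYCLE-style rhythmicity test
#'
#' Full rhythmicity call for one or more series: best Kendall tau over an
#' asymmetric-cosine reference family, empirical p against a Gaussian
#' white-noise null, and the rhythmic call at `alpha`. Operates on a wide
#' data frame (time column + one column per series) and returns one row per
#' series.
#'
#' @param data data frame; first column (or `time_col`) is time in hours,
#'   remaining columns are series.
#' @param period_h reference period in hours.
#' @param time_col name of the time column; default the first column.
#' @param alpha rhythmicity threshold on the empirical p (default 1e-4, the
#'   most stringent threshold used for these recordings).
#' @param n_null null-sample count; defaults to the smallest size resolving
#'   `alpha`.
#' @param seed seed for the null draws.
#' @param refs optional pre-built `reference_set` (overrides `period_h`).
#' @param asymmetries,phase_step_h forwarded to [build_references()].
#' @return Tibble with columns `series`, `tau`, `best_phase_h`,
#'   `best_asymmetry`, `p_empirical`, `rhythmic`.
#' @export
test_rhythm <- function(data, period_h = 24, time_col = NULL, alpha = 1e-4,
                        n_null = NULL, seed = 1L, refs = NULL,
                        asymmetries = seq(0.1, 0.9, by = 0.1),
                        phase_step_h = NULL) {
  ser <- series_matrix(data, time_col)
  dt_h <- ser$dt_h
  if (is.null(n_null)) n_null <- as.integer(ceiling(1 / alpha)) - 1L
  if (is.null(refs)) {
    refs <- build_references(period_h, dt_h, nrow(ser$y),
                             phase_step_h = phase_step_h %||% dt_h,
                             asymmetries = asymmetries)
  }
  nulls <- null_tau_distribution(refs, n_null = n_null, seed = seed)
  purrr::map_dfr(seq_len(ncol(ser$y)), function(j) {
    bt <- best_tau(ser$y[, j], refs)
    p <- empirical_p(bt$tau, nulls, alpha = alpha)
    tibble::tibble(series = colnames(ser$y)[j], tau = bt$tau,
                   best_phase_h = bt$best_phase_h,
                   best_asymmetry = bt$best_asymmetry,
                   p_empirical = p, rhythmic = !bt$degenerate & p <= alpha)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector of p-values.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

# Coerce a wide data frame (time + series columns) to a sampled matrix.
series_matrix <- function(data, time_col = NULL) {
  if (is.matrix(data)) abort("`data` must be a data frame with a time column")
  data <- tibble::as_tibble(data)
  if (is.null(time_col)) time_col <- names(data)[1]
  t_h <- data[[time_col]]
  if (is.null(t_h)) abort(sprintf("time column `%s` not found", time_col))
  y <- as.matrix(data[setdiff(names(data), time_col)])
  if (ncol(y) == 0L) abort("no series columns found")
  storage.mode(y) <- "double"
  dts <- diff(t_h)
  if (length(dts) < 1L) abort("need at least 2 timepoints")
  if (max(abs(dts - dts[1])) > 1e-6 * max(abs(dts)))
    abort("time column must be uniformly sampled")
  list(t_h = as.numeric(t_h), y = y, dt_h = as.numeric(dts[1]))
}
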
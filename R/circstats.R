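#' Circular mean and resultant length
#'
#' Computes the mean direction and mean resultant length \eqn{R} of a sample
#' of angles, optionally weighted. \eqn{R} ranges from 0 (complete dispersal)
#' to 1 (all angles identical); the circular variance is \eqn{V = 1 - R}.
#'
#' @param theta numeric vector of angles in radians.
#' @param weights optional nonnegative weights, one per angle.
#' @return A list with `mean` (mean angle in \[0, 2pi), `NA` when the
#'   resultant is numerically zero), `R` (mean resultant length), and `n`.
#' @examples
#' circ_mean(c(0, pi / 2))  # mean pi/4, R = sqrt(2)/2
#' @export
circ_mean <- function(theta, weights = NULL) {
  theta <- as.numeric(theta)
  if (length(theta) == 0L) abort("`theta` must be non-empty")
  if (any(!is.finite(theta))) abort("`theta` must be finite")
  if (is.null(weights)) weights <- rep(1, length(theta))
  if (any(weights < 0)) abort("`weights` must be nonnegative")
  w <- weights / sum(weights)
  S <- sum(w * sin(theta))
  C <- sum(w * cos(theta))
  R <- sqrt(S^2 + C^2)
  mean_angle <- if (R < 1e-12) NA_real_ else atan2(S, C) %% (2 * pi)
  list(mean = mean_angle, R = R, n = length(theta))
}

#' Circular variance
#'
#' The synchrony metric used throughout the package:
#' \deqn{V = 1 - \sqrt{(\sum \sin x)^2 + (\sum \cos x)^2} / n}
#' where \eqn{x} are angles in radians. \eqn{V = 0} for perfect synchrony and
#' \eqn{V = 1} for complete phase dispersal. Identical to `1 - circ_mean()$R`.
#'
#' @inheritParams circ_mean
#' @return Circular variance in \[0, 1\].
#' @examples
#' circ_var(c(0, pi / 2, pi))  # 1 - 1/3
#' @export
circ_var <- function(theta, weights = NULL) {
  1 - circ_mean(theta, weights)$R
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative, using the mean resultant length.
#' The p-value uses the standard finite-n corrected approximation
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - n Z)} - (1 + 2n))} with
#' \eqn{Z = n R^2}. For very small samples an exact Monte-Carlo p-value can
#' be requested instead.
#'
#' @inheritParams circ_mean
#' @param monte_carlo if `TRUE`, estimate p by simulation from the uniform
#'   null instead of the approximation (recommended for n < 10).
#' @param n_sim number of Monte-Carlo null samples.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return One-row tibble with `n`, `R`, `statistic` (\eqn{Z = nR^2}) and
#'   `p_value`.
#' @export
rayleigh_test <- function(theta, monte_carlo = FALSE, n_sim = 1e5, seed = 1L) {
  cm <- circ_mean(theta)
  n <- cm$n
  R <- cm$R
  Z <- n * R^2
  if (monte_carlo) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    null_R <- vapply(seq_len(n_sim), function(i) {
      circ_mean(runif(n, 0, 2 * pi))$R
    }, numeric(1))
    p <- (1 + sum(null_R >= R)) / (n_sim + 1)
  } else {
    p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Z * n)) - (1 + 2 * n))
    p <- min(max(p, 0), 1)
  }
  tibble::tibble(n = n, R = R, statistic = Z, p_value = p)
}

# Save/restore global RNG state so seeded helpers don't disturb the caller.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Signed circular phase distance
#'
#' Shortest signed distance (in hours) from each phase to a reference phase
#' around the circadian cycle: \eqn{d = ((\phi - ref + T/2) \bmod T) - T/2},
#' so distances lie in \[-T/2, T/2). The reference defaults to the circular
#' mean of the sample, matching the per-slice "phase distance from the mean
#' SCN phase" analysis.
#'
#' @param phase_h numeric vector of phases in hours.
#' @param period_h cycle length in hours.
#' @param reference_h reference phase in hours; default the circular mean of
#'   `phase_h`.
#' @return Numeric vector of signed distances in hours.
#' @export
phase_distance <- function(phase_h, period_h, reference_h = NULL) {
  stopifnot_scalar(period_h, "period_h", positive = TRUE)
  if (is.null(reference_h)) {
    cm <- circ_mean(hours_to_rad(phase_h, period_h))
    if (is.na(cm$mean)) abort("circular mean undefined for this sample; supply `reference_h`")
    reference_h <- rad_to_hours(cm$mean, period_h)
  }
  ((phase_h - reference_h + period_h / 2) %% period_h) - period_h / 2
}

#' Kernel density curve (optionally wrapped/circular)
#'
#' Gaussian kernel density estimate over a fixed support grid. With
#' `wrapped = TRUE` the kernel is wrapped on a circle of circumference
#' `period` (used for phase-distance distributions, where linear KDE would
#' leak mass past the \eqn{\pm T/2} edges).
#'
#' @param values numeric sample.
#' @param bandwidth kernel SD; default Scott's rule
#'   \eqn{\hat\sigma n^{-1/5}}.
#' @param wrapped wrap the kernel on a circle?
#' @param period circle circumference when `wrapped` (support becomes
#'   \[-period/2, period/2)).
#' @param n_grid number of support points.
#' @param from,to support range for the unwrapped case; defaults pad the data
#'   range by 3 bandwidths.
#' @return Tibble with `support` and `density`; the trapezoidal integral of
#'   `density` is 1.
#' @export
density_curve <- function(values, bandwidth = NULL, wrapped = FALSE,
                          period = NULL, n_grid = 512L, from = NULL, to = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) abort("`values` must contain finite data")
  if (is.null(bandwidth)) {
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) s <- max(abs(values), 1e-3) * 0.1
    bandwidth <- s * n^(-1 / 5)
  }
  if (wrapped) {
    if (is.null(period)) abort("`period` required when wrapped = TRUE")
    support <- seq(-period / 2, period / 2, length.out = n_grid)
    # wrap the Gaussian kernel: sum over a few replicas is ample for bw << period
    dens <- rowSums(vapply(-3:3, function(k) {
      rowMeans(outer(support, values, function(g, v)
        stats::dnorm(g - v + k * period, sd = bandwidth)))
    }, numeric(length(support))))
  } else {
    if (is.null(from)) from <- min(values) - 3 * bandwidth
    if (is.null(to)) to <- max(values) + 3 * bandwidth
    support <- seq(from, to, length.out = n_grid)
    dens <- rowMeans(outer(support, values, function(g, v)
      stats::dnorm(g - v, sd = bandwidth)))
  }
  # renormalize the trapezoidal integral to 1 (finite support truncation)
  integ <- sum(diff(support) * (head(dens, -1) + tail(dens, -1)) / 2)
  tibble::tibble(support = support, density = dens / integ)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Exact statistic \eqn{D = \sup_x |ECDF_a(x) - ECDF_b(x)|} computed by a
#' joint ECDF sweep, with the asymptotic Kolmogorov p-value.
#'
#' @param a,b numeric samples.
#' @return One-row tibble with `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_2samp <- function(a, b) {
  a <- sort(a[is.finite(a)]); b <- sort(b[is.finite(b)])
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0L || n_b == 0L) abort("both samples must be non-empty")
  grid <- sort(unique(c(a, b)))
  ecdf_a <- findInterval(grid, a) / n_a
  ecdf_b <- findInterval(grid, b) / n_b
  D <- max(abs(ecdf_a - ecdf_b))
  n_eff <- n_a * n_b / (n_a + n_b)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  if (lambda < 0.2) {
    p <- 1  # Kolmogorov series is numerically useless near zero
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  tibble::tibble(statistic = D, p_value = p, n_a = n_a, n_b = n_b)
}

# circular SD in hours: sqrt(-2 log R) scaled to the period
circ_sd_h <- function(phase_h, period_h) {
  R <- circ_mean(hours_to_rad(phase_h, period_h))$R
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) * period_h / (2 * pi)
}
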
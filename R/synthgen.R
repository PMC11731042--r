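#' Per-channel specification for the synthetic SCN generator
#'
#' Describes one reporter channel of a simulated slice: how cell phases are
#' laid out in space (a linear phase wave, as for neuronal reporters, or a
#' uniform shared phase, as for astrocytic ones), a fixed phase offset
#' relative to the shared clock (anti-phasic co-detection is
#' `phase_offset_h = period/2`), waveform sharpness, and an optional
#' perturbation.
#'
#' @param name channel label (used for file naming and result tables).
#' @param phase_mode `"wave"` (linear spatial phase gradient) or `"uniform"`.
#' @param wave_span_h total phase span in hours across the tissue along the
#'   wave direction (the neuronal phase wave in these slices spans ~3 h).
#' @param wave_direction_deg direction of phase progression, degrees
#'   counterclockwise from the +column axis (rows increase downward).
#' @param phase_jitter_h per-cell Gaussian SD added to the phase field.
#' @param phase_offset_h fixed offset added to every cell's phase.
#' @param base_phase_h phase of the uniform field (and of the wave's earliest
#'   cell) before offset/jitter.
#' @param waveform_power sharpness exponent `p` of the rectified cosine;
#'   `NULL` inherits the config default. `p < 1` gives flat-topped waveforms,
#'   large `p` gives peaked ones.
#' @param perturbation a [perturbation_spec()] or `NULL`.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name = "ch1",
                         phase_mode = c("wave", "uniform"),
                         wave_span_h = 3, wave_direction_deg = 0,
                         phase_jitter_h = 0, phase_offset_h = 0,
                         base_phase_h = 0, waveform_power = NULL,
                         perturbation = NULL) {
  phase_mode <- match.arg(phase_mode)
  if (wave_span_h < 0) abort("`wave_span_h` must be >= 0")
  if (phase_jitter_h < 0) abort("`phase_jitter_h` must be >= 0")
  if (!is.null(perturbation) && !inherits(perturbation, "perturbation_spec"))
    abort("`perturbation` must come from perturbation_spec()")
  structure(list(name = name, phase_mode = phase_mode,
                 wave_span_h = wave_span_h,
                 wave_direction_deg = wave_direction_deg,
                 phase_jitter_h = phase_jitter_h,
                 phase_offset_h = phase_offset_h,
                 base_phase_h = base_phase_h,
                 waveform_power = waveform_power,
                 perturbation = perturbation),
            class = "channel_spec")
}

#' Perturbation specification
#'
#' Models the three classes of manipulation the pipeline is designed to
#' quantify: `telc_like` (progressive desynchronization: per-cell phase
#' random walk plus exponential per-cycle amplitude decay from onset, as when
#' synaptic vesicle release is blocked), `a37_like` (transient amplitude
#' suppression of one channel plus a sustained baseline-slope increase,
#' as under GABA-transaminase inhibition), and `selegiline_like` (rhythm
#' abolished outright from onset).
#'
#' @param kind one of `"telc_like"`, `"a37_like"`, `"selegiline_like"`,
#'   `"none"`.
#' @param onset_h time of application, hours from recording start.
#' @param phase_diffusion_sd_h_per_cycle telc_like: SD (h) of the per-cycle
#'   random-walk step added to each cell's phase after onset.
#' @param amplitude_decay_factor telc_like: fractional amplitude loss per
#'   cycle after onset, in \[0, 1\].
#' @param suppression_duration_h a37_like: length of the amplitude
#'   suppression window.
#' @param suppression_factor a37_like: amplitude multiplier during the
#'   window, in \[0, 1\].
#' @param slope_increase a37_like: baseline slope (intensity/h) added from
#'   onset.
#' @param abolish_rhythm selegiline_like: zero the oscillatory component
#'   after onset.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(kind = c("none", "telc_like", "a37_like", "selegiline_like"),
                              onset_h = 48,
                              phase_diffusion_sd_h_per_cycle = 0,
                              amplitude_decay_factor = 0,
                              suppression_duration_h = 30,
                              suppression_factor = 1,
                              slope_increase = 0,
                              abolish_rhythm = kind == "selegiline_like") {
  kind <- match.arg(kind)
  if (amplitude_decay_factor < 0 || amplitude_decay_factor > 1)
    abort("`amplitude_decay_factor` must be in [0, 1]")
  if (suppression_factor < 0 || suppression_factor > 1)
    abort("`suppression_factor` must be in [0, 1]")
  if (phase_diffusion_sd_h_per_cycle < 0)
    abort("`phase_diffusion_sd_h_per_cycle` must be >= 0")
  structure(list(kind = kind, onset_h = onset_h,
                 phase_diffusion_sd_h_per_cycle = phase_diffusion_sd_h_per_cycle,
                 amplitude_decay_factor = amplitude_decay_factor,
                 suppression_duration_h = suppression_duration_h,
                 suppression_factor = suppression_factor,
                 slope_increase = slope_increase,
                 abolish_rhythm = abolish_rhythm),
            class = "perturbation_spec")
}

#' Full generative specification of a synthetic SCN slice
#'
#' Defines the geometry, cell population, oscillator parameters, noise and
#' channels of a simulated slice recording. Defaults emulate the recordings
#' this pipeline targets: ~24 h damped oscillations sampled every 30 min
#' over 5 days, with per-cell amplitude/baseline heterogeneity. The same
#' config (same seed) always reproduces identical output.
#'
#' @param shape `c(height_px, width_px)` of the frame.
#' @param mask optional logical H x W tissue mask; default an inscribed
#'   ellipse with semi-axes 0.4 x each dimension.
#' @param n_cells number of cells to place inside the mask.
#' @param cell_radius_px cell radius in pixels (blob sigma is half this).
#' @param period_h,dt_h,duration_h oscillator period, sampling interval and
#'   recording length (hours); `duration_h` must cover >= 3 cycles.
#' @param amplitude_mean,amplitude_sd per-cell oscillation amplitude
#'   distribution (intensity units; truncated at 10% of the mean).
#' @param baseline_mean,baseline_sd per-cell baseline distribution.
#' @param damping_rate fractional amplitude decay per hour.
#' @param trend_slope shared linear trend, intensity/h.
#' @param noise_sd Gaussian noise SD (per pixel per frame in movies; per
#'   cell-series sample in table output).
#' @param waveform_power default sharpness exponent of the rectified cosine
#'   waveform (can be overridden per channel).
#' @param channels list of [channel_spec()]s sharing this geometry.
#' @param seed integer RNG seed; full determinism contract.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(shape = c(96, 128), mask = NULL,
                         n_cells = 110, cell_radius_px = 4,
                         period_h = 24, dt_h = 0.5, duration_h = 120,
                         amplitude_mean = 100, amplitude_sd = 20,
                         baseline_mean = 200, baseline_sd = 30,
                         damping_rate = 0.005, trend_slope = 0,
                         noise_sd = 10, waveform_power = 1,
                         channels = list(channel_spec()), seed = 1L) {
  stopifnot_scalar(dt_h, "dt_h", positive = TRUE)
  stopifnot_scalar(period_h, "period_h", positive = TRUE)
  if (duration_h < 3 * period_h)
    abort("`duration_h` must cover at least 3 cycles (>= 3 * period_h)")
  if (length(shape) != 2L || any(shape < 8))
    abort("`shape` must be c(height, width), each >= 8 px")
  if (is.null(mask)) mask <- ellipse_mask(shape)
  if (!is.logical(mask) || !identical(dim(mask), as.integer(shape)))
    abort("`mask` must be a logical matrix matching `shape`")
  if (!any(mask)) abort("mask is empty")
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  if (!length(channels) || !all(vapply(channels, inherits, TRUE, "channel_spec")))
    abort("`channels` must be a list of channel_spec objects")
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nm)) abort("channel names must be unique")
  for (ch in channels) {
    p <- ch$perturbation
    if (!is.null(p) && p$kind != "none" &&
        (p$onset_h < 0 || p$onset_h > duration_h))
      abort("perturbation onset must lie within the recording")
  }
  structure(list(shape = as.integer(shape), mask = mask, n_cells = n_cells,
                 cell_radius_px = cell_radius_px, period_h = period_h,
                 dt_h = dt_h, duration_h = duration_h,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 damping_rate = damping_rate, trend_slope = trend_slope,
                 noise_sd = noise_sd, waveform_power = waveform_power,
                 channels = channels, seed = as.integer(seed)),
            class = "synth_config")
}

ellipse_mask <- function(shape, center = shape / 2,
                         semi_axes = 0.4 * shape) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((rr - center[1]) / semi_axes[1])^2 + ((cc - center[2]) / semi_axes[2])^2 <= 1
}

# Rejection-sample cell centers inside the mask, min spacing 1.5 * radius.
place_cells <- function(config) {
  ok <- which(config$mask)
  H <- config$shape[1]
  min_d2 <- (1.5 * config$cell_radius_px)^2
  rows <- numeric(0); cols <- numeric(0)
  attempts <- 0L
  while (length(rows) < config$n_cells) {
    attempts <- attempts + 1L
    if (attempts > 200L * config$n_cells)
      abort("could not place all cells; mask too small for n_cells at this spacing")
    i <- ok[sample.int(length(ok), 1L)]
    r <- ((i - 1L) %% H) + 1L
    cl <- ((i - 1L) %/% H) + 1L
    if (length(rows) == 0L || all((rows - r)^2 + (cols - cl)^2 > min_d2)) {
      rows <- c(rows, r); cols <- c(cols, cl)
    }
  }
  tibble::tibble(cell = seq_len(config$n_cells), row = rows, col = cols)
}

#' Assign per-cell phases from a spatial phase field
#'
#' Wave mode plants a linear phase gradient: each cell's phase is
#' `span * s + base + jitter`, where `s` is its centroid's projection onto
#' the wave direction, min-max normalized to \[0, 1\] across cells. Uniform
#' mode gives every cell the same base phase plus jitter. Phases are wrapped
#' to \[0, period).
#'
#' @param config a [synth_config()].
#' @param centroids tibble with `cell`, `row`, `col`; default places cells
#'   from the config seed.
#' @param channel which channel's field to evaluate (index or name).
#' @return `centroids` with a `phase_h` column added.
#' @export
make_phase_field <- function(config, centroids = NULL, channel = 1L) {
  ch <- resolve_channel(config, channel)
  if (is.null(centroids)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed)
    centroids <- place_cells(config)
  }
  if (ch$phase_mode == "wave") {
    th <- ch$wave_direction_deg * pi / 180
    proj <- centroids$col * cos(th) + centroids$row * sin(th)
    rng <- range(proj)
    if (diff(rng) < 1e-9)
      abort("degenerate geometry: all cells project to one point along the wave direction")
    s <- (proj - rng[1]) / diff(rng)
    phase <- ch$wave_span_h * s + ch$base_phase_h
  } else {
    phase <- rep(ch$base_phase_h, nrow(centroids))
  }
  phase <- phase + ch$phase_offset_h
  if (ch$phase_jitter_h > 0)
    phase <- phase + rnorm(nrow(centroids), 0, ch$phase_jitter_h)
  centroids$phase_h <- wrap_phase(phase, config$period_h)
  centroids
}

resolve_channel <- function(config, channel) {
  if (is.character(channel)) {
    i <- match(channel, vapply(config$channels, `[[`, "", "name"))
    if (is.na(i)) abort(sprintf("no channel named '%s'", channel))
    config$channels[[i]]
  } else config$channels[[channel]]
}

# Noise-free per-cell waveform matrix (n_cells x T) for one channel.
# Perturbation randomness (telc phase walk) must already be in `walk`
# (n_cells x n_cycles cumulative offsets) when applicable.
cell_series_matrix <- function(config, ch, truth, t_h, walk = NULL) {
  p <- ch$waveform_power %||% config$waveform_power
  pert <- ch$perturbation %||% perturbation_spec("none")
  Tn <- length(t_h)
  out <- matrix(0, nrow(truth), Tn)
  for (i in seq_len(nrow(truth))) {
    A <- rep(truth$amplitude[i], Tn)
    phase <- rep(truth$phase_h[i], Tn)
    extra <- numeric(Tn)
    if (pert$kind == "telc_like") {
      m <- pmax(0, floor((t_h - pert$onset_h) / config$period_h) + 1)
      m[t_h < pert$onset_h] <- 0
      A <- A * (1 - pert$amplitude_decay_factor)^m
      if (!is.null(walk) && ncol(walk) > 0) {
        idx <- pmin(m, ncol(walk))
        off <- ifelse(idx > 0, walk[i, pmax(idx, 1)], 0)
        phase <- phase + off
      }
    } else if (pert$kind == "a37_like") {
      inwin <- t_h >= pert$onset_h & t_h <= pert$onset_h + pert$suppression_duration_h
      A[inwin] <- A[inwin] * pert$suppression_factor
      extra <- extra + pert$slope_increase * pmax(0, t_h - pert$onset_h)
    } else if (pert$kind == "selegiline_like" && pert$abolish_rhythm) {
      A[t_h >= pert$onset_h] <- 0
    }
    osc <- pmax(0, cos(2 * pi * (t_h - phase) / config$period_h))^p
    out[i, ] <- truth$baseline[i] + config$trend_slope * t_h + extra +
      A * exp(-config$damping_rate * t_h) * osc
  }
  out
}

# Draw the telc phase random walk: n_cells x n_cycles cumulative offsets (h).
draw_phase_walk <- function(config, pert, n_cells) {
  n_cyc <- max(0L, floor((config$duration_h - pert$onset_h) / config$period_h) + 1L)
  sd <- pert$phase_diffusion_sd_h_per_cycle
  if (n_cyc == 0L || sd == 0) return(matrix(0, n_cells, n_cyc))
  steps <- matrix(rnorm(n_cells * n_cyc, 0, sd), n_cells, n_cyc)
  t(apply(steps, 1, cumsum))
}

#' Simulate per-cell time-series tables (no image rendering)
#'
#' Generates the planted ground truth and the per-cell reporter series for
#' every channel of a config, with Gaussian observation noise of
#' `noise_sd`. This is the fast path for statistics-level validation; use
#' [simulate_movie()] when pixel data are needed.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_cells`: `t_h`, `truth` (one row per cell:
#'   centroid, per-channel planted phase columns `phase_<name>_h`, period,
#'   amplitude, baseline), `series` (named list per channel of wide tibbles
#'   `time_h` + one column per cell), `config`.
#' @export
simulate_cells <- function(config) {
  sim <- simulate_cells_noiseless(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2027L)  # series noise stream, separate from geometry
  n <- nrow(sim$truth)
  series <- list()
  for (nm in names(sim$clean)) {
    noisy <- sim$clean[[nm]] + if (config$noise_sd > 0)
      matrix(rnorm(length(sim$clean[[nm]]), 0, config$noise_sd), n) else 0
    df <- tibble::as_tibble(t(noisy), .name_repair = "minimal")
    names(df) <- paste0("cell_", seq_len(n))
    series[[nm]] <- dplyr::bind_cols(tibble::tibble(time_h = sim$t_h), df)
  }
  structure(list(t_h = sim$t_h, truth = sim$truth, series = series,
                 config = config),
            class = "synth_cells")
}

#' Simulate a full multi-channel SCN movie with ground truth
#'
#' Renders every cell as a 2-D Gaussian blob (sigma = half the cell radius,
#' truncated at 3 sigma) whose brightness follows the cell's damped,
#' rectified-cosine waveform, adds per-pixel Gaussian noise, and returns one
#' [movie_stack()] per channel alongside the planted truth. Channels share
#' geometry and cell placement but have independent phase fields.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_movie`: `stacks` (named list of
#'   `movie_stack`), `truth`, `config`.
#' @export
simulate_movie <- function(config) {
  sim <- simulate_cells_noiseless(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1013L)  # movie noise stream, distinct from geometry
  H <- config$shape[1]; W <- config$shape[2]
  sigma <- config$cell_radius_px / 2
  win <- ceiling(3 * sigma)
  n <- nrow(sim$truth)
  # sparse-ish blob weights: P x n, built per cell over a local window
  Wmat <- matrix(0, H * W, n)
  for (i in seq_len(n)) {
    r0 <- sim$truth$row[i]; c0 <- sim$truth$col[i]
    rr <- max(1, r0 - win):min(H, r0 + win)
    cc <- max(1, c0 - win):min(W, c0 + win)
    g <- exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sigma^2))
    Wmat[as.vector(outer(rr, (cc - 1) * H, "+")), i] <- as.vector(g)
  }
  # analysis mask: reporter-covered tissue (within ~2 sigma of some cell)
  cover <- matrix(rowSums(Wmat), H, W) > exp(-2)
  out_mask <- config$mask & cover
  stacks <- list()
  for (ch in config$channels) {
    px <- Wmat %*% sim$clean[[ch$name]]      # P x T
    if (config$noise_sd > 0)
      px <- px + matrix(rnorm(length(px), 0, config$noise_sd), nrow(px))
    arr <- array(px, dim = c(H, W, ncol(px)))
    stacks[[ch$name]] <- movie_stack(arr, dt_h = config$dt_h,
                                     channel = ch$name, mask = out_mask)
  }
  structure(list(stacks = stacks, truth = sim$truth, config = config),
            class = "synth_movie")
}

# shared core: noise-free clean matrices per channel + truth (same RNG
# consumption pattern as simulate_cells so geometry/truth match exactly)
simulate_cells_noiseless <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  cells <- place_cells(config)
  n <- nrow(cells)
  amp <- pmax(0.1 * config$amplitude_mean,
              rnorm(n, config$amplitude_mean, config$amplitude_sd))
  base <- pmax(0, rnorm(n, config$baseline_mean, config$baseline_sd))
  t_h <- seq(0, config$duration_h - config$dt_h, by = config$dt_h)
  truth <- cells
  truth$period_h <- config$period_h
  truth$amplitude <- amp
  truth$baseline <- base
  clean <- list()
  for (ch in config$channels) {
    pf <- make_phase_field(config, cells, ch$name)
    truth[[paste0("phase_", ch$name, "_h")]] <- pf$phase_h
    tr <- truth; tr$phase_h <- pf$phase_h
    pert <- ch$perturbation %||% perturbation_spec("none")
    walk <- if (pert$kind == "telc_like") draw_phase_walk(config, pert, n) else NULL
    clean[[ch$name]] <- cell_series_matrix(config, ch, tr, t_h, walk)
  }
  list(t_h = t_h, truth = truth, clean = clean)
}

#' Write a simulation run to disk
#'
#' Writes `<dir>/<channel>.tif` (multi-page 16-bit TIFF, frame order =
#' time), `<dir>/truth.csv` (one row per cell) and `<dir>/config.json`.
#'
#' @param sim result of [simulate_movie()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(sim, dir) {
  if (!inherits(sim, "synth_movie")) abort("`sim` must come from simulate_movie()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$stacks)) {
    st <- sim$stacks[[nm]]
    hi <- max(st$data, 1e-9)
    lo <- min(st$data, 0)
    frames <- lapply(seq_len(dim(st$data)[3]), function(i) {
      f <- (st$data[, , i] - lo) / (hi - lo)
      round(f * 65535) / 65535  # quantize to the 16-bit grid deterministically
    })
    tiff::writeTIFF(frames, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  }
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  cfg <- sim$config
  cfg$mask <- NULL  # geometry is implied by shape + ellipse default
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
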
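test_that("uniform phase fields share one phase; wave fields are linear in space", {
  cfg <- synth_config(n_cells = 50, channels = list(
    channel_spec("u", phase_mode = "uniform", base_phase_h = 4, phase_jitter_h = 0)))
  pf <- make_phase_field(cfg)
  expect_equal(nrow(pf), 50)
  expect_true(all(pf$phase_h == 4))

  cfgw <- synth_config(n_cells = 50, channels = list(
    channel_spec("w", phase_mode = "wave", wave_span_h = 3,
                 wave_direction_deg = 0, phase_jitter_h = 0)))
  pfw <- make_phase_field(cfgw)
  expect_equal(pfw$phase_h[which.min(pfw$col)], 0)
  expect_equal(pfw$phase_h[which.max(pfw$col)], 3)
  # exactly linear in the column coordinate
  fit <- lm(phase_h ~ col, data = pfw)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999999)
})

test_that("planted wave phases give the circular variance the formula predicts", {
  cfg <- synth_config(n_cells = 60, channels = list(
    channel_spec("w", phase_mode = "wave", wave_span_h = 3,
                 wave_direction_deg = 90, phase_jitter_h = 0)))
  pf <- make_phase_field(cfg)
  x <- 2 * pi * (pf$phase_h %% 24) / 24
  brute <- 1 - sqrt(sum(sin(x))^2 + sum(cos(x))^2) / length(x)
  expect_equal(circ_var(x), brute, tolerance = 1e-12)
  expect_equal(phase_dispersal(pf$phase_h, 24), brute, tolerance = 1e-12)
})

test_that("degenerate wave geometry is rejected", {
  cfg <- synth_config(n_cells = 5, channels = list(
    channel_spec("w", phase_mode = "wave")))
  cells <- tibble::tibble(cell = 1:5, row = 1:5, col = rep(10, 5))
  expect_error(make_phase_field(cfg, cells, "w"), "degenerate")
})

test_that("noise-free single cell reproduces the closed-form waveform at its center", {
  mask <- matrix(TRUE, 32, 32)
  cfg <- synth_config(shape = c(32, 32), mask = mask, n_cells = 1,
                      cell_radius_px = 4, noise_sd = 0, damping_rate = 0.01,
                      trend_slope = 0.5, duration_h = 72,
                      amplitude_sd = 0, baseline_sd = 0,
                      channels = list(channel_spec("x", phase_mode = "uniform",
                                                   base_phase_h = 6)))
  sim <- simulate_movie(cfg)
  tr <- sim$truth
  t_h <- seq(0, 71.5, by = 0.5)
  expected <- tr$baseline + 0.5 * t_h +
    tr$amplitude * exp(-0.01 * t_h) * pmax(0, cos(2 * pi * (t_h - 6) / 24))
  center <- sim$stacks$x$data[tr$row, tr$col, ]
  # center pixel carries blob weight 1 exactly
  expect_equal(center, expected, tolerance = 1e-10)
})

test_that("identical configs reproduce identical output (seed determinism)", {
  cfg <- synth_config(shape = c(48, 64), n_cells = 20, duration_h = 72,
                      channels = list(channel_spec("w", phase_mode = "wave",
                                                   phase_jitter_h = 0.2)),
                      seed = 123)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stacks$w$data, b$stacks$w$data)
  sa <- simulate_cells(cfg)
  sb <- simulate_cells(cfg)
  expect_identical(sa$series$w, sb$series$w)
  # movie and series routes agree on the planted truth
  expect_identical(a$truth, sa$truth)
})

test_that("all non-noise intensity lies within the dilated tissue mask", {
  cfg <- synth_config(shape = c(48, 64), n_cells = 15, noise_sd = 0,
                      duration_h = 72,
                      channels = list(channel_spec("x", phase_mode = "uniform")))
  sim <- simulate_movie(cfg)
  r <- 3 * cfg$cell_radius_px
  dil <- EBImage::dilate(cfg$mask * 1, EBImage::makeBrush(2L * r + 1L, "disc")) > 0
  outside <- sweep(sim$stacks$x$data, c(1, 2), dil * 1, "*") - sim$stacks$x$data
  expect_equal(sum(abs(outside)), 0)
})

test_that("null perturbation leaves the simulation unchanged", {
  base <- list(channel_spec("x", phase_mode = "uniform", base_phase_h = 6))
  null_p <- list(channel_spec("x", phase_mode = "uniform", base_phase_h = 6,
    perturbation = perturbation_spec("telc_like", onset_h = 48,
                                     phase_diffusion_sd_h_per_cycle = 0,
                                     amplitude_decay_factor = 0)))
  a <- simulate_cells(synth_config(n_cells = 20, channels = base, seed = 4))
  b <- simulate_cells(synth_config(n_cells = 20, channels = null_p, seed = 4))
  expect_equal(as.matrix(a$series$x), as.matrix(b$series$x), tolerance = 1e-12)
})

test_that("telc-like phase diffusion spreads phases like sqrt(cycles) * sigma", {
  sigma <- 0.5
  cfg <- synth_config(n_cells = 150, cell_radius_px = 2, noise_sd = 0,
                      duration_h = 168, damping_rate = 0,
                      amplitude_sd = 0, baseline_sd = 0,
                      channels = list(channel_spec("x", phase_mode = "uniform",
                        base_phase_h = 6,
                        perturbation = perturbation_spec("telc_like", onset_h = 24,
                          phase_diffusion_sd_h_per_cycle = sigma,
                          amplitude_decay_factor = 0))),
                      seed = 21)
  sim <- simulate_cells(cfg)
  t_h <- sim$t_h
  # per-cell peak times, assigned to post-onset cycles
  sds <- matrix(NA_real_, 150, 5)
  for (j in 1:150) {
    y <- as.matrix(sim$series$x[, -1])[, j]
    pk <- scnphase:::find_peaks(t_h, y, 24)
    pk <- pk[pk >= 24]
    k <- floor((pk - 24) / 24) + 1
    sds[j, k[k <= 5]] <- (pk[k <= 5] - (24 * k[k <= 5] + 6))
  }
  per_cycle_sd <- apply(sds, 2, sd, na.rm = TRUE)
  expected <- sigma * sqrt(1:5)
  # monotone growth and within 20% of the random-walk prediction
  expect_true(all(diff(per_cycle_sd) > -0.05))
  expect_true(all(abs(per_cycle_sd - expected) / expected < 0.2))
})

test_that("a37-like perturbation suppresses amplitude and adds slope as configured", {
  cfg <- synth_config(n_cells = 60, cell_radius_px = 2, channels = list(
    channel_spec("gaba", base_phase_h = 6,
      perturbation = perturbation_spec("a37_like", onset_h = 60,
        suppression_duration_h = 30, suppression_factor = 0.3)),
    channel_spec("neuro", base_phase_h = 6,
      perturbation = perturbation_spec("a37_like", onset_h = 60,
        suppression_factor = 1, slope_increase = 2))), seed = 5)
  sim <- simulate_cells(cfg)
  t <- sim$t_h
  gmean <- rowMeans(as.matrix(sim$series$gaba[, -1]))
  rel <- first_cycle_amplitude(t, gmean, 60)
  expect_lt(abs(rel - 0.3) / 0.3, 0.2)
  nmean <- rowMeans(as.matrix(sim$series$neuro[, -1]))
  dslope <- signal_slope(t, nmean, c(60, 120)) - signal_slope(t, nmean, c(0, 60))
  expect_lt(abs(dslope - 2) / 2, 0.2)
})

test_that("selegiline-like perturbation abolishes the rhythm after onset", {
  cfg <- synth_config(n_cells = 10, cell_radius_px = 2, noise_sd = 0,
                      channels = list(channel_spec("x", base_phase_h = 6,
                        perturbation = perturbation_spec("selegiline_like",
                                                         onset_h = 60))),
                      seed = 2)
  sim <- simulate_cells(cfg)
  y <- rowMeans(as.matrix(sim$series$x[, -1]))
  post <- y[sim$t_h >= 60]
  expect_lt(diff(range(post)), 1e-9)  # flat baseline, no oscillation
})

test_that("simulation runs are written as TIFF + truth CSV + config JSON", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(shape = c(48, 64), n_cells = 15, duration_h = 72,
                      channels = list(channel_spec("ch1"), channel_spec("ch2",
                        phase_mode = "uniform")), seed = 3)
  run_simulate(cfg, dir)
  expect_true(file.exists(file.path(dir, "ch1.tif")))
  expect_true(file.exists(file.path(dir, "ch2.tif")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  tr <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_equal(nrow(tr), 15)
  st <- read_movie_tiff(file.path(dir, "ch1.tif"), dt_h = 0.5)
  expect_equal(dim(st$data), c(48, 64, 144))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(duration_h = 40), "3 cycles")
  expect_error(synth_config(dt_h = 0), "dt_h")
  expect_error(synth_config(channels = list()), "channel_spec")
  expect_error(channel_spec(wave_span_h = -1), "wave_span_h")
  expect_error(perturbation_spec("telc_like", amplitude_decay_factor = 1.5),
               "amplitude_decay_factor")
  expect_error(synth_config(channels = list(channel_spec("x",
    perturbation = perturbation_spec("telc_like", onset_h = 500)))),
    "onset")
})
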
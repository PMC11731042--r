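# lightweight roi_set construction for clustering tests
fake_rois <- function(series, rows, cols, dt_h = 0.5, dim = c(30, 30)) {
  structure(list(
    centers = tibble::tibble(roi = seq_len(nrow(series)), row = rows, col = cols),
    series = series, dt_h = dt_h, roi_size = 3, dim = dim, channel = "x",
    mask = matrix(TRUE, dim[1], dim[2])), class = "roi_set")
}

test_that("phase dispersal evaluates the circular-variance formula exactly", {
  expect_equal(phase_dispersal(c(0, 6, 12), 24), 2 / 3, tolerance = 1e-12)
  expect_equal(phase_dispersal(rep(5, 8), 24), 0, tolerance = 1e-12)
  expect_equal(phase_dispersal(c(0, 12), 24), 1, tolerance = 1e-12)
  expect_error(phase_dispersal(3, 24), "2 phases")

  brute <- function(ph, T) {
    x <- 2 * pi * (ph %% T) / T
    1 - sqrt(sum(sin(x))^2 + sum(cos(x))^2) / length(x)
  }
  withr::with_seed(30, {
    for (i in 1:1000) {
      ph <- runif(sample(2:12, 1), 0, 30)
      expect_equal(phase_dispersal(ph, 24), brute(ph, 24), tolerance = 1e-12)
    }
  })
  # permutation invariance
  ph <- c(1, 5, 9, 13)
  expect_identical(phase_dispersal(ph, 24), phase_dispersal(rev(ph), 24))
})

test_that("k-means clustering handles edge cases and honors k", {
  t_h <- (0:119) * 0.5
  withr::with_seed(31, {
    series <- t(sapply(runif(20, 0, 3), function(ph)
      cos(2 * pi * (t_h - ph) / 24) + rnorm(120, 0, 0.1)))
  })
  rois <- fake_rois(series, rows = rep(1:4, 5) * 3, cols = rep(1:5, each = 4) * 3)
  cm1 <- cluster_rois(rois, k = 1)
  expect_true(all(cm1$labels == 1))
  expect_error(cluster_rois(rois, k = 25), "fewer ROIs")

  # duplicated series always co-cluster
  rois2 <- fake_rois(rbind(series, series),
                     rows = rep(rep(1:4, 5) * 3, 2),
                     cols = rep(rep(1:5, each = 4) * 3, 2))
  cm <- cluster_rois(rois2, k = 4, seed = 2)
  expect_identical(cm$labels[1:20], cm$labels[21:40])
})

test_that("clustering recovers discrete planted phase bands almost perfectly", {
  t_h <- (0:119) * 0.5
  bands <- rep(0:4, each = 30)  # 5 bands at 0..4 h
  withr::with_seed(32, {
    series <- t(sapply(bands, function(ph)
      cos(2 * pi * (t_h - ph) / 24) + rnorm(120, 0, 0.02)))
  })
  rois <- fake_rois(series, rows = rep(1:10, 15)[1:150] * 2,
                    cols = rep(1:15, each = 10)[1:150] * 2, dim = c(24, 34))
  cm <- cluster_rois(rois, k = 5, seed = 1)
  # every planted band maps to exactly one cluster
  agreement <- mean(vapply(0:4, function(b) {
    tab <- table(cm$labels[bands == b])
    max(tab) / sum(tab)
  }, numeric(1)))
  expect_gte(agreement, 0.95)
})

test_that("cluster summaries flag noise as NR and phase rhythmic clusters", {
  t_h <- (0:119) * 0.5
  withr::with_seed(33, {
    noise <- matrix(rnorm(40 * 120), 40)
  })
  rois <- fake_rois(noise, rows = rep(1:8, 5) * 3, cols = rep(1:5, each = 8) * 3)
  cm <- cluster_rois(rois, k = 3, seed = 1)
  cm <- summarize_clusters(cm, alpha = 0.005, n_null = 199, seed = 1)
  expect_true(all(!cm$summary$rhythmic))
  expect_true(is.na(cm$dispersal_V))
  expect_false(wave_vector(cm)$defined)
})

test_that("wave vectors point along the planted gradient; uniform is undefined", {
  t_h <- (0:239) * 0.5
  grid <- expand.grid(row = (1:10) * 3, col = (1:12) * 3)
  # wave along +col over 3 h
  ph_wave <- 3 * (grid$col - min(grid$col)) / diff(range(grid$col))
  withr::with_seed(34, {
    wave <- t(sapply(ph_wave, function(ph)
      cos(2 * pi * (t_h - ph) / 24) + rnorm(240, 0, 0.05)))
  })
  rois <- fake_rois(wave, grid$row, grid$col, dim = c(36, 40))
  cm <- summarize_clusters(cluster_rois(rois, seed = 3), alpha = 0.005,
                           n_null = 199, seed = 3)
  wv <- wave_vector(cm)
  expect_true(wv$defined)
  expect_lt(ang_diff_deg(wv$angle_deg, 0), 10)
  # speed ~ spatial extent / span
  expect_lt(abs(wv$speed_px_per_h - diff(range(grid$col)) / 3) / (33 / 3), 0.35)
  span <- diff(range(unwrap_h(cm$summary$phase_h[cm$summary$rhythmic], 1.5)))
  expect_gt(span, 2); expect_lt(span, 3.5)

  # diagonal wave at 45 degrees (square grid: the center-of-mass path of
  # diagonal bands follows the mask diagonal, so the mask must be isotropic)
  sq <- expand.grid(row = (1:12) * 3, col = (1:12) * 3)
  proj <- (sq$col + sq$row)
  ph_diag <- 3 * (proj - min(proj)) / diff(range(proj))
  withr::with_seed(35, {
    diag_s <- t(sapply(ph_diag, function(ph)
      cos(2 * pi * (t_h - ph) / 24) + rnorm(240, 0, 0.05)))
  })
  cmd <- summarize_clusters(cluster_rois(fake_rois(diag_s, sq$row, sq$col,
                                                   dim = c(40, 40)), seed = 3),
                            alpha = 0.005, n_null = 199, seed = 3)
  wvd <- wave_vector(cmd)
  expect_true(wvd$defined)
  expect_lt(ang_diff_deg(wvd$angle_deg, 45), 10)

  # uniform phase: vector undefined
  withr::with_seed(36, {
    unif <- t(sapply(rnorm(nrow(grid), 0, 0.1), function(ph)
      cos(2 * pi * (t_h - ph) / 24) + rnorm(240, 0, 0.05)))
  })
  cmu <- summarize_clusters(cluster_rois(fake_rois(unif, grid$row, grid$col,
                                                   dim = c(36, 40)), seed = 3),
                            alpha = 0.005, n_null = 199, seed = 3)
  expect_false(wave_vector(cmu)$defined)
})

test_that("SD-across-clusters profiles reflect synchrony", {
  t_h <- (0:99) * 0.5
  same <- matrix(rep(cos(2 * pi * t_h / 24), 4), 4, byrow = TRUE)
  cm_same <- structure(list(mean_series = same, dt_h = 0.5, k = 4),
                       class = "cluster_map")
  expect_true(all(cluster_sd_profile(cm_same)$sd_across_clusters < 1e-12))

  # two anti-phase clusters of amplitude A oscillate with max ~ A * sqrt(2)
  A <- 2
  anti <- rbind(A * cos(2 * pi * t_h / 24), -A * cos(2 * pi * t_h / 24))
  cm_anti <- structure(list(mean_series = anti, dt_h = 0.5, k = 2),
                       class = "cluster_map")
  prof <- cluster_sd_profile(cm_anti)$sd_across_clusters
  expect_equal(max(prof), A * sqrt(2), tolerance = 1e-9)
  expect_lt(min(prof), 1e-9)
})

test_that("direction histograms feed the Rayleigh test and count undefined vectors", {
  withr::with_seed(37, {
    shared <- tibble::tibble(angle_deg = rnorm(20, 90, 5), defined = TRUE)
  })
  dh <- direction_histogram(shared)
  expect_lt(dh$rayleigh$p_value, 0.01)
  expect_equal(dh$n_defined, 20)

  withr::with_seed(38, {
    hits <- replicate(20, {
      v <- tibble::tibble(angle_deg = runif(20, 0, 360), defined = TRUE)
      direction_histogram(v)$rayleigh$p_value > 0.05
    })
  })
  expect_gte(mean(hits), 0.9)

  undef <- tibble::tibble(angle_deg = NA_real_, defined = FALSE)
  expect_message(dhu <- direction_histogram(undef), "undefined")
  expect_null(dhu$rayleigh)
  expect_equal(dhu$n_undefined, 1)
})
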
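# Shared fixtures, built in code.

# noise SD giving a target RMS signal-to-noise ratio for the rectified
# cosine waveform (RMS of the oscillatory component is A*sqrt(1/4 - 1/pi^2))
snr_noise_sd <- function(amplitude, snr) {
  amplitude * sqrt(0.25 - 1 / pi^2) / snr
}

# small two-channel slice config: neuronal-like 3 h wave + astrocyte-like
# uniform phase, shared geometry
paired_slice_config <- function(seed, span_h = 3, jitter_h = 0.25,
                                direction_deg = 0, ...) {
  synth_config(channels = list(
    channel_spec("wave", phase_mode = "wave", wave_span_h = span_h,
                 wave_direction_deg = direction_deg),
    channel_spec("unif", phase_mode = "uniform", phase_jitter_h = jitter_h)
  ), seed = seed, ...)
}

# quick wide tibble of cosine series
cosine_tbl <- function(t, phases_h, period_h = 24, amplitude = 1, noise_sd = 0) {
  df <- tibble::tibble(time_h = t)
  for (i in seq_along(phases_h)) {
    df[[paste0("s", i)]] <- amplitude * cos(2 * pi * (t - phases_h[i]) / period_h) +
      rnorm(length(t), 0, noise_sd)
  }
  df
}

# unwrap phases (hours) around a center for linear comparison
unwrap_h <- function(x, center, period = 24) {
  ((x - center + period / 2) %% period) - period / 2 + center
}

# circular absolute difference in degrees
ang_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
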
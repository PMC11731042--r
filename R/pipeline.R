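#' Simulate a slice and write it to a run directory
#'
#' End-to-end "simulate" stage: builds the movie for every channel of the
#' config and writes `<channel>.tif`, `truth.csv` and `config.json` to
#' `out_dir`.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  sim <- simulate_movie(config)
  write_run(sim, out_dir)
}

#' Full spatiotemporal phase-map analysis of one or more channels
#'
#' Chains the slice-level pipeline per channel: ROI grid extraction ->
#' linear detrend + z-score -> Lloyd k-means -> per-cluster rhythm calls
#' and absolute phases -> inter-cluster phase dispersal V, wave vector and
#' SD-across-clusters profile. Writes `cluster_summary.csv`,
#' `wave_vectors.csv`, `sd_profiles.csv`, `dispersal.csv` and per-channel
#' label-image CSVs to `out_dir` when given.
#'
#' @param stacks named list of [movie_stack()]s (e.g. `simulate_movie()$stacks`).
#' @param k,roi_size,n_init clustering parameters.
#' @param alpha,n_null rhythmicity-test parameters.
#' @param flat_peak_channels channel names analyzed with the trough-midpoint
#'   phase rule.
#' @param seed global seed (clustering restarts + null distribution).
#' @param out_dir optional output directory; when given, all result tables
#'   are written as CSV.
#' @return List: `cluster_maps` (named list of summarized `cluster_map`s),
#'   `summary` (per-channel tibble with dispersal V and wave vector),
#'   `cluster_summary`, `sd_profiles` (long tibbles).
#' @export
run_phasemap <- function(stacks, k = 5, roi_size = 3, n_init = 10L,
                         alpha = 1e-4, n_null = NULL,
                         flat_peak_channels = character(),
                         seed = 1L, out_dir = NULL) {
  if (inherits(stacks, "movie_stack")) stacks <- list(stacks)
  if (is.null(names(stacks)) || any(names(stacks) == ""))
    names(stacks) <- vapply(stacks, `[[`, "", "channel")
  refs <- NULL
  maps <- list(); summaries <- list(); profiles <- list(); clusters <- list()
  for (nm in names(stacks)) {
    rois <- grid_rois(stacks[[nm]], roi_size = roi_size)
    if (is.null(refs))
      refs <- build_references(24, rois$dt_h, ncol(rois$series))
    cm <- cluster_rois(rois, k = k, seed = seed, n_init = n_init)
    cm <- summarize_clusters(cm, alpha = alpha, n_null = n_null,
                             flat_peak = nm %in% flat_peak_channels,
                             seed = seed, refs = refs)
    wv <- wave_vector(cm)
    maps[[nm]] <- cm
    clusters[[nm]] <- dplyr::mutate(tidy(cm), channel = nm, .before = 1)
    summaries[[nm]] <- dplyr::bind_cols(glance(cm), wv[, c("angle_deg",
                                                           "speed_px_per_h",
                                                           "r2", "defined")])
    pr <- cluster_sd_profile(cm)
    pr$channel <- nm
    profiles[[nm]] <- pr
  }
  out <- list(cluster_maps = maps,
              summary = dplyr::bind_rows(summaries),
              cluster_summary = dplyr::bind_rows(clusters),
              sd_profiles = dplyr::bind_rows(profiles))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$summary, file.path(out_dir, "dispersal.csv"))
    readr::write_csv(out$cluster_summary,
                     file.path(out_dir, "cluster_summary.csv"))
    readr::write_csv(out$sd_profiles, file.path(out_dir, "sd_profiles.csv"))
    for (nm in names(maps)) {
      li <- maps[[nm]]$label_image
      readr::write_csv(tibble::as_tibble(li, .name_repair = "unique_quiet"),
                       file.path(out_dir, paste0("labels_", nm, ".csv")))
    }
    snapshot <- list(k = k, roi_size = roi_size, n_init = n_init,
                     alpha = alpha, n_null = n_null,
                     flat_peak_channels = flat_peak_channels, seed = seed,
                     package_version = as.character(utils::packageVersion("scnphase")))
    jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Single-cell analysis of one channel
#'
#' Detects cells (or accepts a pre-extracted series table), summarizes every
#' cell's rhythm, and — when `onset_h` is given — repeats the analysis on
#' pre- and post-onset windows and compares the phase-distance
#' distributions. Writes `cell_table.csv`, `slice_summary.csv` and (when
#' applicable) `comparison.csv` to `out_dir`.
#'
#' @param x a [movie_stack()] (cells detected first), `cell_set`, or wide
#'   series data frame.
#' @param onset_h optional perturbation onset splitting the recording into
#'   pre/post windows.
#' @param alpha,n_null rhythmicity-test parameters.
#' @param flat_peak use the trough-midpoint phase rule?
#' @param log_sigma_px,threshold cell-detection parameters (stack input).
#' @param seed seed for the null distribution.
#' @param out_dir optional output directory.
#' @return List: `cells` (full-window `cell_rhythm_table`), `slice`
#'   (glance tibble), and with `onset_h`: `pre`, `post`, `comparison`.
#' @export
run_cells <- function(x, onset_h = NULL, alpha = 1e-4, n_null = NULL,
                      flat_peak = FALSE, log_sigma_px = 2, threshold = NULL,
                      seed = 1L, out_dir = NULL) {
  df <- if (inherits(x, "movie_stack")) {
    cs <- detect_cells(x, log_sigma_px = log_sigma_px, threshold = threshold)
    if (nrow(cs$cells) == 0L) abort("no cells detected")
    cell_series_tbl(cs)
  } else if (inherits(x, "cell_set")) cell_series_tbl(x)
  else tibble::as_tibble(x)
  tbl <- summarize_cells(df, alpha = alpha, n_null = n_null,
                         flat_peak = flat_peak, seed = seed)
  out <- list(cells = tbl, slice = glance(tbl))
  if (!is.null(onset_h)) {
    t_all <- df[[1]]
    out$pre <- summarize_cells(df, alpha = alpha, n_null = n_null,
                               flat_peak = flat_peak, seed = seed,
                               window = c(min(t_all), onset_h))
    out$post <- summarize_cells(df, alpha = alpha, n_null = n_null,
                                flat_peak = flat_peak, seed = seed,
                                window = c(onset_h, max(t_all)))
    out$comparison <- compare_distributions(out$pre, out$post)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy_cell_table(tbl), file.path(out_dir, "cell_table.csv"))
    readr::write_csv(out$slice, file.path(out_dir, "slice_summary.csv"))
    if (!is.null(out$comparison))
      readr::write_csv(out$comparison, file.path(out_dir, "comparison.csv"))
  }
  out
}

tidy_cell_table <- function(tbl) {
  out <- tbl
  attr(out, "slice") <- NULL
  class(out) <- setdiff(class(out), "cell_rhythm_table")
  out
}
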
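#' Movie stack container
#'
#' A registered image time series for one reporter channel: an H x W x T
#' intensity array with its sampling interval, channel label and a logical
#' tissue mask. All spatial analysis starts from this container.
#'
#' @param data numeric H x W x T array (frame index = time).
#' @param dt_h hours per frame.
#' @param channel channel label.
#' @param mask logical H x W tissue mask; default all-TRUE.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(data, dt_h, channel = "ch1", mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be an H x W x T array")
  if (anyNA(data)) abort("stack contains NA frames")
  stopifnot_scalar(dt_h, "dt_h", positive = TRUE)
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  if (!is.logical(mask) || !identical(dim(mask), dim(data)[1:2]))
    abort("`mask` must be a logical H x W matrix")
  if (!any(mask)) abort("mask is empty")
  structure(list(data = data, dt_h = dt_h, channel = channel, mask = mask),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> '%s': %d x %d px, %d frames @ %.3g h (%.1f h), %d mask px\n",
              x$channel, d[1], d[2], d[3], x$dt_h, d[3] * x$dt_h, sum(x$mask)))
  invisible(x)
}

#' Read a multi-page TIFF as a movie stack
#'
#' @param path TIFF path (one page per timepoint).
#' @param dt_h hours per frame.
#' @param channel channel label; default the file name.
#' @param mask logical matrix, or path to a mask image (nonzero = tissue).
#' @return A [movie_stack()].
#' @export
read_movie_tiff <- function(path, dt_h, channel = NULL, mask = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(unlist(frames), dim = c(dim(frames[[1]])[1:2], length(frames)))
  if (is.character(mask)) mask <- tiff::readTIFF(mask) > 0
  movie_stack(arr, dt_h = dt_h,
              channel = channel %||% sub("\\.[^.]+$", "", basename(path)),
              mask = mask)
}

#' Preprocess a bioluminescence stack
#'
#' Per-frame artifact removal mirroring the standard bioluminescence cleanup:
#' a 3 x 3 median filter (despeckle), replacement of outlier pixels (cosmic
#' rays) that deviate from the local median by more than a threshold, and
#' unsharp masking (subtract a weighted Gaussian-blurred copy, then
#' renormalize) to sharpen cell outlines.
#'
#' @param stack a [movie_stack()].
#' @param median_k median filter kernel width in px (odd; 3 = despeckle).
#' @param outlier_thresh absolute deviation from the local median above which
#'   a pixel is replaced by it; default 3 SD of each frame.
#' @param unsharp_radius Gaussian sigma (px) of the blurred copy.
#' @param unsharp_weight weight of the subtracted blur, in \[0, 1).
#' @return A preprocessed `movie_stack` of the same shape.
#' @export
preprocess_biolum <- function(stack, median_k = 3, outlier_thresh = NULL,
                              unsharp_radius = 4, unsharp_weight = 0.6) {
  if (!inherits(stack, "movie_stack")) abort("`stack` must be a movie_stack")
  if (median_k < 1 || unsharp_radius <= 0) abort("filter sizes must be positive")
  if (unsharp_weight < 0 || unsharp_weight >= 1)
    abort("`unsharp_weight` must be in [0, 1)")
  r <- (median_k - 1) %/% 2
  out <- stack$data
  for (i in seq_len(dim(out)[3])) {
    f <- out[, , i]
    f1 <- frame_median(f, r)        # despeckle
    thr <- outlier_thresh %||% (3 * stats::sd(f))
    med <- frame_median(f1, r)      # cosmic-ray rule vs the local median
    dev <- abs(f1 - med) > thr
    f2 <- f1
    f2[dev] <- med[dev]
    # unsharp: subtract weighted blur, renormalize so flat fields pass through
    br <- 2L * as.integer(ceiling(3 * unsharp_radius)) + 1L
    brmax <- 2L * ((min(dim(f2)) - 1L) %/% 2L) - 1L
    bl <- EBImage::gblur(f2, sigma = unsharp_radius, radius = min(br, brmax))
    out[, , i] <- (f2 - unsharp_weight * bl) / (1 - unsharp_weight)
  }
  movie_stack(out, dt_h = stack$dt_h, channel = stack$channel, mask = stack$mask)
}

# median filter with EBImage (which expects [0,1]); robust to flat frames
frame_median <- function(f, r) {
  if (r < 1) return(f)
  lo <- min(f); hi <- max(f)
  if (hi - lo < 1e-12) return(f)
  g <- EBImage::medianFilter((f - lo) / (hi - lo), r)
  g * (hi - lo) + lo
}

#' Tile the mask into square ROIs and extract mean time series
#'
#' Lays a non-overlapping grid of `roi_size` x `roi_size` tiles aligned to
#' the mask bounding box, keeps tiles that lie fully inside the image and
#' overlap the tissue mask by more than 50%, and extracts each tile's
#' per-frame mean intensity.
#'
#' @param stack a [movie_stack()].
#' @param roi_size tile side in px (default 3).
#' @return An object of class `roi_set`: `centers` tibble (`roi`, `row`,
#'   `col`), `series` matrix (n_roi x T), `dt_h`, `roi_size`, `dim`,
#'   `channel`, `mask`.
#' @export
grid_rois <- function(stack, roi_size = 3) {
  if (!inherits(stack, "movie_stack")) abort("`stack` must be a movie_stack")
  if (roi_size < 1) abort("`roi_size` must be >= 1")
  d <- dim(stack$data)
  mrows <- range(which(rowSums(stack$mask) > 0))
  mcols <- range(which(colSums(stack$mask) > 0))
  if (diff(mrows) + 1 < roi_size || diff(mcols) + 1 < roi_size)
    abort("mask smaller than one ROI tile")
  r_starts <- seq(mrows[1], mrows[2] - roi_size + 1, by = roi_size)
  c_starts <- seq(mcols[1], mcols[2] - roi_size + 1, by = roi_size)
  tiles <- tidyr::expand_grid(r0 = r_starts, c0 = c_starts)
  keep <- vapply(seq_len(nrow(tiles)), function(i) {
    rr <- tiles$r0[i]:(tiles$r0[i] + roi_size - 1)
    cc <- tiles$c0[i]:(tiles$c0[i] + roi_size - 1)
    mean(stack$mask[rr, cc]) > 0.5
  }, logical(1))
  tiles <- tiles[keep, , drop = FALSE]
  if (nrow(tiles) == 0L) abort("no ROI overlaps the mask by more than 50%")
  Tn <- d[3]
  flat <- matrix(stack$data, d[1] * d[2], Tn)
  series <- matrix(0, nrow(tiles), Tn)
  for (i in seq_len(nrow(tiles))) {
    rr <- tiles$r0[i]:(tiles$r0[i] + roi_size - 1)
    cc <- tiles$c0[i]:(tiles$c0[i] + roi_size - 1)
    idx <- as.vector(outer(rr, (cc - 1) * d[1], "+"))
    series[i, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  centers <- tibble::tibble(roi = seq_len(nrow(tiles)),
                            row = tiles$r0 + (roi_size - 1) / 2,
                            col = tiles$c0 + (roi_size - 1) / 2)
  structure(list(centers = centers, series = series, dt_h = stack$dt_h,
                 roi_size = roi_size, dim = d[1:2], channel = stack$channel,
                 mask = stack$mask),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> '%s': %d ROIs of %d x %d px, %d frames @ %.3g h\n",
              x$channel, nrow(x$centers), x$roi_size, x$roi_size,
              ncol(x$series), x$dt_h))
  invisible(x)
}

#' ROI series as a wide tibble
#'
#' @param rois a `roi_set`.
#' @return Tibble: `time_h` + one column per ROI (`roi_<i>`).
#' @export
roi_series_tbl <- function(rois) {
  df <- tibble::as_tibble(t(rois$series), .name_repair = "minimal")
  names(df) <- paste0("roi_", rois$centers$roi)
  dplyr::bind_cols(
    tibble::tibble(time_h = (seq_len(ncol(rois$series)) - 1) * rois$dt_h), df)
}

#' Detect single cells on the temporal-average image
#'
#' Averages the stack over time, computes the (negative) Laplacian-of-
#' Gaussian response at the expected cell scale, and keeps local maxima
#' above threshold inside the mask with a minimum separation of
#' `2 * log_sigma_px`. Each detected cell's series is the mean over a disc
#' of radius `log_sigma_px` around its centroid.
#'
#' @param stack a [movie_stack()] (preprocess bioluminescence first).
#' @param log_sigma_px blob scale in px (roughly cell radius / sqrt(2)).
#' @param threshold minimum LoG response; default 20% of the maximum
#'   response (calibrated on synthetic data).
#' @return An object of class `cell_set`: `cells` tibble (`cell`, `row`,
#'   `col`, `response`), `series` matrix (n_cell x T), `dt_h`, `radius_px`,
#'   `channel`. Zero detections yield an empty (0-row) set, not an error.
#' @export
detect_cells <- function(stack, log_sigma_px = 2, threshold = NULL) {
  if (!inherits(stack, "movie_stack")) abort("`stack` must be a movie_stack")
  d <- dim(stack$data)
  avg <- apply(stack$data, c(1, 2), mean)
  resp <- -log_filter(avg, log_sigma_px)   # bright blobs -> positive response
  resp[!stack$mask] <- -Inf
  if (is.null(threshold)) {
    mx <- max(resp[is.finite(resp)])
    threshold <- if (mx > 0) 0.2 * mx else Inf
  }
  rad <- max(1L, ceiling(2 * log_sigma_px))
  mx_f <- max_filter(resp, rad)
  is_peak <- resp >= mx_f - 1e-9 & resp > threshold & is.finite(resp)
  pk <- which(is_peak, arr.ind = TRUE)
  if (nrow(pk) > 1L) {  # enforce min separation, strongest first
    ord <- order(resp[pk], decreasing = TRUE)
    pk <- pk[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))[-1]) {
      prev <- pk[seq_len(i - 1)[keep[seq_len(i - 1)]], , drop = FALSE]
      if (nrow(prev) &&
          any((prev[, 1] - pk[i, 1])^2 + (prev[, 2] - pk[i, 2])^2 < (2 * log_sigma_px)^2))
        keep[i] <- FALSE
    }
    pk <- pk[keep, , drop = FALSE]
  }
  n <- nrow(pk)
  Tn <- d[3]
  series <- matrix(0, n, Tn)
  if (n > 0L) {
    flat <- matrix(stack$data, d[1] * d[2], Tn)
    rdisc <- max(1L, round(log_sigma_px))
    for (i in seq_len(n)) {
      rr <- max(1, pk[i, 1] - rdisc):min(d[1], pk[i, 1] + rdisc)
      cc <- max(1, pk[i, 2] - rdisc):min(d[2], pk[i, 2] + rdisc)
      grid2 <- expand.grid(r = rr, c = cc)
      inside <- (grid2$r - pk[i, 1])^2 + (grid2$c - pk[i, 2])^2 <= rdisc^2
      idx <- grid2$r[inside] + (grid2$c[inside] - 1) * d[1]
      series[i, ] <- colMeans(flat[idx, , drop = FALSE])
    }
  }
  cells <- tibble::tibble(cell = seq_len(n),
                          row = if (n) as.numeric(pk[, 1]) else numeric(0),
                          col = if (n) as.numeric(pk[, 2]) else numeric(0),
                          response = if (n) resp[pk] else numeric(0))
  structure(list(cells = cells, series = series, dt_h = stack$dt_h,
                 radius_px = log_sigma_px, channel = stack$channel),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> '%s': %d cells, %d frames @ %.3g h\n",
              x$channel, nrow(x$cells), ncol(x$series), x$dt_h))
  invisible(x)
}

#' Cell series as a wide tibble
#'
#' @param cells a `cell_set` (or `synth_cells` channel via [simulate_cells()]).
#' @return Tibble: `time_h` + one column per cell (`cell_<i>`).
#' @export
cell_series_tbl <- function(cells) {
  df <- tibble::as_tibble(t(cells$series), .name_repair = "minimal")
  names(df) <- paste0("cell_", cells$cells$cell)
  dplyr::bind_cols(
    tibble::tibble(time_h = (seq_len(ncol(cells$series)) - 1) * cells$dt_h), df)
}

# Laplacian-of-Gaussian filter response (scale-normalized)
log_filter <- function(img, sigma) {
  k <- ceiling(4 * sigma)
  xs <- -k:k
  g2 <- outer(xs, xs, function(x, y) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  g2 <- g2 - mean(g2)  # zero response to flat background
  EBImage::filter2(img, g2 * sigma^2)
}

# greyscale max filter over a disc of radius r (via EBImage dilation)
max_filter <- function(img, r) {
  img[!is.finite(img)] <- min(img[is.finite(img)]) - 1
  EBImage::dilate(img, EBImage::makeBrush(2L * r + 1L, shape = "disc"))
}
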
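#' Construct a bioluminescence image stack
#'
#' @param frames 3-D numeric array (rows x cols x frames), intensities >= 0.
#' @param pixel_size_um pixel edge length (micrometres).
#' @param frame_interval_min minutes between frame midpoints (default 25;
#'   each frame is treated as an instantaneous sample at its midpoint).
#' @param exposure_min exposure per frame (metadata only).
#' @param t0_hr hour of the first frame midpoint.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_min = 25,
                        exposure_min = 10, t0_hr = 0) {
  stopifnot(length(dim(frames)) == 3, all(frames >= 0))
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 exposure_min = exposure_min, t0_hr = t0_hr),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px (%g um/px), %d frames at %g min (%.1f days)\n",
              d[1], d[2], x$pixel_size_um, d[3], x$frame_interval_min,
              d[3] * x$frame_interval_min / 60 / 24))
  invisible(x)
}

#' Frame midpoint times (hours) of a stack
#' @param stack an \code{image_stack}.
#' @export
stack_time_hr <- function(stack) {
  stack$t0_hr + (seq_len(dim(stack$frames)[3]) - 1) *
    stack$frame_interval_min / 60
}

#' Read a multi-frame TIFF stack with a JSON sidecar
#'
#' @param path TIFF path.
#' @param sidecar optional sidecar path (default: same name, \code{.json})
#'   supplying \code{pixel_size_um}, \code{frame_interval_min},
#'   \code{exposure_min}, \code{t0_hr}.
#' @param scale multiply intensities (e.g. 65535 to undo 16-bit
#'   normalization applied by the TIFF reader).
#' @return An \code{image_stack}.
#' @export
read_image_stack <- function(path, sidecar = NULL, scale = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  sidecar <- sidecar %||% sub("\\.[^.]*$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  image_stack(arr * scale, pixel_size_um = meta$pixel_size_um %||% 4,
              frame_interval_min = meta$frame_interval_min %||% 25,
              exposure_min = meta$exposure_min %||% 10,
              t0_hr = meta$t0_hr %||% 0)
}

#' Quantify an image stack on a square grid
#'
#' Tiles the field with non-overlapping squares of \code{grid_size_um} per
#' side (trailing partial rows/columns are dropped, never padded) and sums
#' pixel intensities within each square per frame. Total retained intensity
#' is conserved exactly.
#'
#' @param stack an \code{image_stack}.
#' @param grid_size_um grid edge length (micrometres, default 40); must be a
#'   whole number of pixels.
#' @return A \code{grid_series} object: list with \code{series} (matrix,
#'   grids x frames), \code{info} (data frame \code{grid_row},
#'   \code{grid_col}, \code{total}), \code{time_hr}, and grid geometry.
#' @export
quantify_grids <- function(stack, grid_size_um = 40) {
  g <- grid_size_um / stack$pixel_size_um
  if (abs(g - round(g)) > 1e-9 || g < 1)
    stop("grid size must be a whole number of pixels >= 1; with ",
         stack$pixel_size_um, " um pixels try grid sizes ",
         paste(stack$pixel_size_um * c(ceiling(g), floor(max(g, 1))),
               collapse = " or "), " um")
  g <- round(g)
  d <- dim(stack$frames)
  nr <- floor(d[1] / g)
  nc <- floor(d[2] / g)
  if (nr < 1 || nc < 1) stop("field smaller than one grid square")
  sub <- stack$frames[seq_len(nr * g), seq_len(nc * g), , drop = FALSE]
  ## grid id for each retained pixel (row-major over grid squares)
  gid <- matrix(rep(rep(seq_len(nr), each = g), nc * g), nrow = nr * g) +
    (matrix(rep(rep(seq_len(nc), each = g), each = nr * g), nrow = nr * g) - 1) * nr
  flat <- matrix(sub, nrow = nr * g * nc * g)
  series <- rowsum(flat, group = as.vector(gid))
  info <- data.frame(grid_row = rep(seq_len(nr), nc),
                     grid_col = rep(seq_len(nc), each = nr),
                     total = rowSums(series))
  structure(list(series = series, info = info,
                 time_hr = stack_time_hr(stack), grid_px = g,
                 grid_size_um = grid_size_um, n_rows = nr, n_cols = nc),
            class = "grid_series")
}

#' @export
print.grid_series <- function(x, ...) {
  cat(sprintf("<grid_series> %d grids (%d x %d of %g um), %d frames\n",
              nrow(x$series), x$n_rows, x$n_cols, x$grid_size_um,
              ncol(x$series)))
  invisible(x)
}

#' Select the brightest grid series
#'
#' Orders grids by decreasing total summed intensity (the ranking statistic
#' for "strongest signals"), breaking ties deterministically by (row, col),
#' and keeps the top \code{n}.
#'
#' @param grids a \code{grid_series}.
#' @param n number of grids to keep.
#' @param rank_key \code{"total"} (default), \code{"peak"} or \code{"mean"}.
#' @return A \code{grid_series} restricted to the selection, in rank order.
#' @export
select_top <- function(grids, n, rank_key = c("total", "peak", "mean")) {
  rank_key <- match.arg(rank_key)
  if (n > nrow(grids$series)) stop("n exceeds the number of grids")
  key <- switch(rank_key,
                total = rowSums(grids$series),
                peak = apply(grids$series, 1, max),
                mean = rowMeans(grids$series))
  ord <- order(-key, grids$info$grid_row, grids$info$grid_col)[seq_len(n)]
  out <- grids
  out$series <- grids$series[ord, , drop = FALSE]
  out$info <- grids$info[ord, , drop = FALSE]
  rownames(out$info) <- NULL
  out
}

#' Row-normalized heat-map matrix of grid series
#'
#' Each selected grid series is detrended by a 24-hr running average and
#' min-max scaled to [0, 1]; rows are in rank order. Constant rows are set
#' to zero and flagged.
#'
#' @param grids a (typically top-ranked) \code{grid_series}.
#' @param window_hr detrend window (hr).
#' @return Matrix (grids x frames of the detrended support) with attribute
#'   \code{flagged_rows}.
#' @export
heatmap_matrix <- function(grids, window_hr = 24) {
  if (nrow(grids$series) == 0) stop("empty grid selection")
  tt <- grids$time_hr
  flagged <- integer(0)
  rows <- lapply(seq_len(nrow(grids$series)), function(i) {
    s <- detrend_running_average(
      data.frame(time_hr = tt, value = grids$series[i, ]), window_hr)
    v <- s$value
    rng <- range(v)
    if (diff(rng) == 0) { flagged <<- c(flagged, i); return(rep(0, length(v))) }
    (v - rng[1]) / diff(rng)
  })
  m <- do.call(rbind, rows)
  attr(m, "flagged_rows") <- flagged
  m
}

#' Fit rhythms to the top-ranked grid series
#'
#' Detrends each selected grid series (24-hr running average), fits the
#' damped-cosine FFT-NLLS model, computes the relative amplitude against the
#' raw grid series over the amplitude window, and converts the fitted peak
#' time to a period-normalized phase angle
#' \code{2 pi (peak mod tau) / tau}. Grids failing quality control are
#' excluded and, by default, replaced by the next-ranked grid.
#'
#' @param grids a \code{grid_series} (ordered, e.g. from
#'   \code{\link{select_top}}).
#' @param top_n number of retained fits (default 50).
#' @param substitute replace QC-failing grids by next-ranked ones (default
#'   \code{TRUE}).
#' @param trim_start_hr initial hours discarded before fitting (default 0:
#'   imaging stacks are not trimmed like explant luminometry unless
#'   configured).
#' @param amplitude_window_hr window for relative amplitude (default
#'   \code{c(36, 60)}).
#' @param ... passed to \code{\link{fft_nlls}}.
#' @return Data frame with one row per retained grid: \code{grid_row},
#'   \code{grid_col}, \code{rank}, \code{period_hr}, \code{peak_hr},
#'   \code{rel_amplitude}, \code{rae}, \code{norm_phase_rad}; attribute
#'   \code{excluded} lists QC failures.
#' @export
fit_grids <- function(grids, top_n = 50, substitute = TRUE,
                      trim_start_hr = 0, amplitude_window_hr = c(36, 60),
                      ...) {
  if (top_n > nrow(grids$series)) stop("top_n exceeds the selection size")
  tt <- grids$time_hr
  rows <- list()
  excluded <- list()
  i <- 0L
  limit <- if (substitute) nrow(grids$series) else top_n
  while (length(rows) < top_n && i < limit) {
    i <- i + 1L
    raw <- data.frame(time_hr = tt, value = grids$series[i, ])
    raw <- raw[raw$time_hr >= trim_start_hr, , drop = FALSE]
    det <- detrend_running_average(raw)
    fit <- fft_nlls(det, ...)
    qc <- qc_filter(fit)
    if (!qc$retained) {
      excluded[[length(excluded) + 1]] <- data.frame(
        rank = i, grid_row = grids$info$grid_row[i],
        grid_col = grids$info$grid_col[i], reason = qc$reason)
      next
    }
    ra <- relative_amplitude(fit, raw, amplitude_window_hr)
    rows[[length(rows) + 1]] <- data.frame(
      grid_row = grids$info$grid_row[i], grid_col = grids$info$grid_col[i],
      rank = i, period_hr = fit$period_hr, peak_hr = fit$phase_hr,
      rel_amplitude = as.numeric(ra), rae = fit$rae,
      norm_phase_rad = 2 * pi * (fit$phase_hr %% fit$period_hr) / fit$period_hr)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(grid_row = integer(0), grid_col = integer(0),
                      rank = integer(0), period_hr = numeric(0),
                      peak_hr = numeric(0), rel_amplitude = numeric(0),
                      rae = numeric(0), norm_phase_rad = numeric(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else NULL
  out
}
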
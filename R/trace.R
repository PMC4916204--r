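#' Contraction trace
#'
#' A uniformly sampled scalar signal representing cardiac contraction: the
#' software analog of the output channel of a video edge detector that
#' compares an active pixel region over the heart with a static reference
#' region. Values are in arbitrary intensity units.
#'
#' @param values numeric vector of samples (finite).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param exclusions optional two-column `start`, `end` matrix/data frame of
#'   half-open artifact intervals in seconds, normalised on construction.
#' @return an object of class `contraction_trace` with fields `values`,
#'   `sample_rate`, `t0` and `exclusions`.
#' @export
contraction_trace <- function(values, sample_rate, t0 = 0, exclusions = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop_param("trace must contain at least one sample")
  if (any(!is.finite(values))) stop_param("trace values must be finite")
  check_scalar_num(sample_rate, "sample_rate")
  if (sample_rate <= 0) stop_param("'sample_rate' must be > 0")
  check_scalar_num(t0, "t0")
  structure(
    list(values = values, sample_rate = sample_rate, t0 = t0,
         exclusions = normalize_exclusions(exclusions)),
    class = "contraction_trace")
}

#' Sample times of a contraction trace
#' @param trace a [contraction_trace()].
#' @return numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1L) / trace$sample_rate
}

#' @export
print.contraction_trace <- function(x, ...) {
  dur <- length(x$values) / x$sample_rate
  cat(sprintf("<contraction_trace> %d samples @ %g Hz (%.1f s from t0 = %g s)\n",
              length(x$values), x$sample_rate, dur, x$t0))
  cat(sprintf("  range [%.4g, %.4g], %d exclusion interval(s)\n",
              min(x$values), max(x$values), nrow(x$exclusions)))
  invisible(x)
}

#' @export
plot.contraction_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = "intensity (a.u.)", ...)
  if (nrow(x$exclusions))
    graphics::rect(x$exclusions[, 1], graphics::par("usr")[3],
                   x$exclusions[, 2], graphics::par("usr")[4],
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  invisible(x)
}

#' Frame sequence
#'
#' An ordered stack of video frames with a fixed frame rate. Frames are
#' numeric arrays, either `H x W` (grayscale) or `H x W x 3` (RGB), all of
#' identical shape, with intensities on any common scale.
#'
#' @param frames list of frame arrays.
#' @param frame_rate frames per second (> 0).
#' @param t0 time of the first frame, seconds.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate, t0 = 0) {
  if (!is.list(frames) || length(frames) == 0L)
    stop_param("'frames' must be a non-empty list of arrays")
  d <- dim(frames[[1L]])
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop_param("frames must be 2-D or 2-D x 3 arrays")
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop_param("all frames must have identical shape")
  check_scalar_num(frame_rate, "frame_rate")
  if (frame_rate <= 0) stop_param("'frame_rate' must be > 0")
  structure(list(frames = frames, frame_rate = frame_rate, t0 = t0),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence> %d frames of %s @ %g fps (%.2f s)\n",
              length(x$frames), paste(d, collapse = "x"), x$frame_rate,
              length(x$frames) / x$frame_rate))
  invisible(x)
}

#' Region-of-interest specification
#'
#' Disc regions for the active point (over the heart) and the reference
#' point (a stationary area outside the animal), in 0-based row-major pixel
#' coordinates, plus the colour-to-scalar projection weights.
#'
#' @param active,reference numeric `c(row, col, radius)` in pixels.
#' @param channel_weights length-3 weights projecting RGB to a scalar;
#'   default is rec.601 luma. Ignored for grayscale frames.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(active, reference,
                     channel_weights = c(0.299, 0.587, 0.114)) {
  for (nm in c("active", "reference")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 3L || r[3L] < 0)
      stop_param(sprintf("'%s' must be c(row, col, radius) with radius >= 0", nm))
  }
  if (!is.numeric(channel_weights) || length(channel_weights) != 3L)
    stop_param("'channel_weights' must have length 3")
  structure(list(active = as.numeric(active), reference = as.numeric(reference),
                 channel_weights = as.numeric(channel_weights)),
            class = "roi_spec")
}

# logical mask of pixels within a disc; region = c(row0, col0, radius), 0-based
disc_mask <- function(region, nrow, ncol) {
  r <- outer(0:(nrow - 1L) - region[1L], rep(1, ncol))
  c_ <- outer(rep(1, nrow), 0:(ncol - 1L) - region[2L])
  r * r + c_ * c_ <= region[3L]^2
}

#' Extract a contraction trace from video frames
#'
#' Emulates the edge-detector comparison of pixel colour at an active point
#' over the heart with a reference point outside the animal: each sample is
#' the mean intensity over the active disc minus the mean over the
#' reference disc, after projecting colour frames to a scalar with the ROI's
#' channel weights. One sample per frame; the trace inherits the frame rate.
#'
#' @param frames a [frame_sequence()].
#' @param roi an [roi_spec()]; both discs must lie within the frame and be
#'   disjoint.
#' @return a [contraction_trace()] with no exclusions set.
#' @export
extract_trace <- function(frames, roi) {
  if (!inherits(frames, "frame_sequence")) stop_param("'frames' must be a frame_sequence")
  if (!inherits(roi, "roi_spec")) stop_param("'roi' must be an roi_spec")
  d <- dim(frames$frames[[1L]])
  h <- d[1L]; w <- d[2L]
  for (nm in c("active", "reference")) {
    r <- roi[[nm]]
    if (r[1L] - r[3L] < 0 || r[1L] + r[3L] > h - 1 ||
        r[2L] - r[3L] < 0 || r[2L] + r[3L] > w - 1)
      stop_param(sprintf("ROI '%s' extends outside the %dx%d frame", nm, h, w))
  }
  ma <- disc_mask(roi$active, h, w)
  mr <- disc_mask(roi$reference, h, w)
  if (any(ma & mr)) stop_param("active and reference regions must be disjoint")

  wts <- roi$channel_weights
  project <- function(f) {
    if (length(dim(f)) == 3L)
      f[, , 1L] * wts[1L] + f[, , 2L] * wts[2L] + f[, , 3L] * wts[3L]
    else f
  }
  vals <- vapply(frames$frames, function(f) {
    g <- project(f)
    mean(g[ma]) - mean(g[mr])
  }, numeric(1))
  contraction_trace(vals, frames$frame_rate, t0 = frames$t0)
}

#' Read video frames from disk
#'
#' Supported containers: a directory of numbered PNG frames (sorted by file
#' name) or a multi-page TIFF. Intensities are returned on the `[0, 1]`
#' scale used by the PNG/TIFF readers.
#'
#' @param path directory of `.png` files, or a `.tif`/`.tiff` file.
#' @param frame_rate frames per second of the recording.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, frame_rate) {
  drop_alpha <- function(f) {
    if (length(dim(f)) == 3L && dim(f)[3L] >= 3L) f[, , 1:3, drop = FALSE]
    else f
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop_param("no .png frames found in ", path)
    frames <- lapply(files, function(f) drop_alpha(png::readPNG(f)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, drop_alpha)
  } else {
    stop_param("unsupported frame container: ", path,
               " (expected a PNG directory or a multi-page TIFF)")
  }
  frame_sequence(frames, frame_rate)
}

#' Write video frames to disk
#'
#' @param frames a [frame_sequence()] with intensities in `[0, 1]`.
#' @param path output: a directory (PNG frames `frame_000001.png`, ...) or a
#'   `.tif`/`.tiff` path (multi-page TIFF).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  if (!inherits(frames, "frame_sequence")) stop_param("'frames' must be a frame_sequence")
  fr <- lapply(frames$frames, function(f) pmin(pmax(f, 0), 1))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(fr, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(fr))
      png::writePNG(fr[[i]], file.path(path, sprintf("frame_%06d.png", i)))
  }
  invisible(path)
}

#' Read an ROI specification from a YAML config
#'
#' Expected keys: `active` and `reference`, each with `row`, `col`,
#' `radius` (0-based pixels); optional `channel_weights` (length 3).
#'
#' @param path YAML file path.
#' @return an [roi_spec()].
#' @export
load_roi <- function(path) {
  cfg <- yaml::read_yaml(path)
  reg <- function(key) {
    r <- cfg[[key]]
    if (is.null(r) || !all(c("row", "col", "radius") %in% names(r)))
      stop_param(sprintf("ROI config must define %s: {row, col, radius}", key))
    c(r$row, r$col, r$radius)
  }
  w <- cfg$channel_weights
  if (is.null(w)) w <- c(0.299, 0.587, 0.114)
  roi_spec(reg("active"), reg("reference"), unlist(w))
}

#' Read a contraction trace from CSV
#'
#' The CSV dialect is a `time_s,value` header with strictly increasing,
#' uniformly spaced times (relative tolerance 1e-6 on the spacing).
#'
#' @param path CSV file path.
#' @return a [contraction_trace()].
#' @export
load_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop_param("trace CSV must have columns 'time_s' and 'value'")
  t <- df$time_s
  if (length(t) < 2L) stop_param("trace CSV must contain at least 2 rows")
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop_param(sprintf("trace times must be strictly increasing (row %d)", bad))
  }
  if (any(abs(dt - dt[1L]) > 1e-6 * dt[1L])) {
    bad <- which(abs(dt - dt[1L]) > 1e-6 * dt[1L])[1L] + 1L
    stop_param(sprintf("trace times must be uniformly spaced (row %d)", bad))
  }
  # pooled spacing estimate; snap near-integer rates distorted by decimal
  # printing (e.g. 60 fps written as 0.0166666666666667 s steps)
  rate <- (length(t) - 1L) / (t[length(t)] - t[1L])
  if (abs(rate - round(rate)) < 1e-6 * rate) rate <- round(rate)
  contraction_trace(df$value, sample_rate = rate, t0 = t[1L])
}

#' Write a contraction trace to CSV
#'
#' Inverse of [load_trace()]: `load_trace(save_trace(x))` reproduces the
#' values and sample rate.
#'
#' @param trace a [contraction_trace()].
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
save_trace <- function(trace, path) {
  if (!inherits(trace, "contraction_trace")) stop_param("'trace' must be a contraction_trace")
  df <- data.frame(time_s = trace_times(trace), value = trace$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
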
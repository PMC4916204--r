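#' Synthetic video scene description
#'
#' Geometry and photometry of a rendered trans-illuminated spat: a dark
#' shell ellipse on a bright background with a pulsating heart disc inside
#' it. Intensities are on the `[0, 1]` scale; the default scene is
#' 128 x 128 px RGB at 60 fps, matching a desk-scale version of the
#' capture geometry.
#'
#' @param frame_size `c(height, width)` in pixels.
#' @param frame_rate frames per second.
#' @param heart_center `c(row, col)` of the heart disc, 0-based.
#' @param heart_radius heart disc radius, px.
#' @param shell_center,shell_axes ellipse centre `c(row, col)` and
#'   semi-axes `c(a_row, a_col)` in px; the heart must lie strictly inside.
#' @param contraction_color_delta peak intensity change of heart pixels at
#'   a contraction (darkening), intensity units.
#' @param background_noise_sd per-pixel Gaussian noise SD, intensity units.
#' @param active_point,reference_point `c(row, col)` suggested ROI centres;
#'   the reference point must lie strictly outside the shell.
#' @return an object of class `video_scene`.
#' @export
video_scene <- function(frame_size = c(128, 128), frame_rate = 60,
                        heart_center = c(64, 56), heart_radius = 10,
                        shell_center = c(64, 64), shell_axes = c(44, 36),
                        contraction_color_delta = 0.25,
                        background_noise_sd = 0.02,
                        active_point = heart_center,
                        reference_point = c(10, 118)) {
  check_scalar_num(frame_rate, "frame_rate")
  check_scalar_num(heart_radius, "heart_radius", min = 0)
  check_scalar_num(contraction_color_delta, "contraction_color_delta", min = 0)
  check_scalar_num(background_noise_sd, "background_noise_sd", min = 0)
  scene <- structure(
    list(frame_size = as.integer(frame_size), frame_rate = frame_rate,
         heart_center = heart_center, heart_radius = heart_radius,
         shell_center = shell_center, shell_axes = shell_axes,
         contraction_color_delta = contraction_color_delta,
         background_noise_sd = background_noise_sd,
         active_point = active_point, reference_point = reference_point),
    class = "video_scene")
  # heart strictly inside the shell ellipse; reference strictly outside
  in_ellipse <- function(p, margin = 0) {
    d <- (p - scene$shell_center) / (scene$shell_axes)
    sum(d^2) < (1 - margin)^2
  }
  corners <- rbind(heart_center + c(heart_radius, 0),
                   heart_center - c(heart_radius, 0),
                   heart_center + c(0, heart_radius),
                   heart_center - c(0, heart_radius))
  if (!all(apply(corners, 1L, in_ellipse)))
    stop_param("heart region must lie strictly inside the shell ellipse")
  if (in_ellipse(reference_point))
    stop_param("reference point must lie strictly outside the shell")
  scene
}

# gamma-shaped contraction pulse: fast rise (peak at t_peak), slower decay,
# asymmetric like a contraction's leading edge; unit peak amplitude
pulse_kernel <- function(u, t_peak = 0.06, shape = 2) {
  k <- numeric(length(u))
  pos <- u >= 0
  x <- u[pos] / t_peak
  k[pos] <- x^shape * exp(shape * (1 - x))
  k
}

#' Render a synthetic beating-heart video
#'
#' Renders RGB frames of the scene in which heart-disc pixels brighten by a
#' gamma-shaped pulse (rise to peak within 100 ms, decayed within ~300 ms)
#' triggered at each beat time — the contracting heart thins and passes
#' more of the trans-illumination — with stationary Gaussian pixel noise
#' everywhere. The reference point region contains no signal, so an
#' active-minus-reference trace isolates the cardiac pulsation with a
#' rising leading edge at each contraction onset.
#'
#' @param beats a [beat_series()] of ground-truth contraction times (s).
#' @param scene a [video_scene()].
#' @param duration_s video duration; must cover all beat times.
#' @param seed optional integer seed.
#' @return a list of class `synthetic_video`: `frames` (a
#'   [frame_sequence()]), `beat_times` (ground truth), `scene`, `roi` (an
#'   [roi_spec()] matching the scene's active/reference points), `seed`.
#' @export
make_video <- function(beats, scene = video_scene(), duration_s, seed = NULL) {
  if (!inherits(beats, "beat_series")) stop_param("'beats' must be a beat_series")
  if (!inherits(scene, "video_scene")) stop_param("'scene' must be a video_scene")
  check_scalar_num(duration_s, "duration_s", min = 0)
  if (length(beats$event_times) && max(beats$event_times) > duration_s)
    stop_param("'duration_s' must cover all beat times")
  h <- scene$frame_size[1L]; w <- scene$frame_size[2L]

  rows <- outer(0:(h - 1L), rep(1, w))
  cols <- outer(rep(1, h), 0:(w - 1L))
  er <- (rows - scene$shell_center[1L]) / scene$shell_axes[1L]
  ec <- (cols - scene$shell_center[2L]) / scene$shell_axes[2L]
  shell <- er * er + ec * ec <= 1
  heart <- (rows - scene$heart_center[1L])^2 +
           (cols - scene$heart_center[2L])^2 <= scene$heart_radius^2

  # base colours: bright trans-illuminated background, darker shell,
  # reddish heart at rest
  base <- array(0, dim = c(h, w, 3L))
  base[, , 1L] <- 0.85; base[, , 2L] <- 0.82; base[, , 3L] <- 0.78
  for (ch in 1:3) {
    plane <- base[, , ch]
    plane[shell] <- plane[shell] - 0.18
    base[, , ch] <- plane
  }
  r <- base[, , 1L]; r[heart] <- r[heart] + 0.05; base[, , 1L] <- r
  g <- base[, , 2L]; g[heart] <- g[heart] - 0.05; base[, , 2L] <- g

  n_frames <- max(1L, floor(duration_s * scene$frame_rate))
  ft <- (seq_len(n_frames) - 1L) / scene$frame_rate
  # pulse amplitude per frame: sum of kernels of recent beats
  amp <- numeric(n_frames)
  for (tb in beats$event_times) {
    lo <- max(1L, floor(tb * scene$frame_rate))
    hi <- min(n_frames, ceiling((tb + 0.4) * scene$frame_rate) + 1L)
    if (hi >= lo) {
      k <- lo:hi
      amp[k] <- amp[k] + pulse_kernel(ft[k] - tb)
    }
  }
  hidx <- which(heart)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    f <- base
    for (ch in 1:3) {
      plane <- f[, , ch]
      plane[hidx] <- plane[hidx] + scene$contraction_color_delta * amp[i]
      f[, , ch] <- plane
    }
    if (scene$background_noise_sd > 0)
      f <- f + stats::rnorm(length(f), 0, scene$background_noise_sd)
    pmin(pmax(f, 0), 1)
  }))
  roi <- roi_spec(active = c(scene$active_point, max(2, scene$heart_radius / 2)),
                  reference = c(scene$reference_point, 3))
  structure(list(frames = frame_sequence(frames, scene$frame_rate),
                 beat_times = beats$event_times, scene = scene, roi = roi,
                 seed = seed),
            class = "synthetic_video")
}

#' Write a generated artifact's provenance sidecar
#'
#' Every generated fixture written to disk gets a JSON sidecar recording
#' the seed and generator parameters, so an artifact can be regenerated
#' byte-identically.
#'
#' @param path path of the artifact the sidecar describes.
#' @param seed integer seed used.
#' @param params named list of generator parameters.
#' @return sidecar path, invisibly.
#' @export
write_seed_sidecar <- function(path, seed, params = list()) {
  side <- paste0(path, ".json")
  jsonlite::write_json(list(seed = seed, params = params), side,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}
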
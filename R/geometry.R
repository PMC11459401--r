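#' Screen and viewing geometry
#'
#' Describes the stimulus display and the observer's position, everything
#' needed to convert pixel displacements into visual angle. Defaults match a
#' 23.8-inch 16:9 panel at 1920 x 1080 viewed from 70 cm, sampled at 90 Hz.
#'
#' @param width_px,height_px panel resolution in pixels.
#' @param diagonal_cm physical panel diagonal in centimetres.
#' @param viewing_distance_cm eye-to-screen distance in centimetres.
#' @param sampling_rate_hz gaze sampling rate in Hz.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' pixels_to_degrees(100, 0, geom)
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            diagonal_cm = 23.8 * 2.54,
                            viewing_distance_cm = 70,
                            sampling_rate_hz = 90) {
  vals <- c(width_px, height_px, diagonal_cm, viewing_distance_cm, sampling_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be strictly positive and finite")
  }
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      diagonal_cm = diagonal_cm,
      viewing_distance_cm = viewing_distance_cm,
      sampling_rate_hz = sampling_rate_hz
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, %.1f cm diagonal, %.0f cm viewing distance, %.0f Hz\n",
    x$width_px, x$height_px, x$diagonal_cm, x$viewing_distance_cm, x$sampling_rate_hz
  ))
  invisible(x)
}

#' Physical size of one pixel
#'
#' Pixel pitch in cm derived from the panel diagonal and pixel dimensions
#' (square pixels assumed).
#'
#' @param geometry a [screen_geometry()].
#' @return pitch in cm per pixel.
#' @export
pixel_pitch_cm <- function(geometry) {
  geometry$diagonal_cm / sqrt(geometry$width_px^2 + geometry$height_px^2)
}

#' Convert pixel displacements to visual angle
#'
#' Small-angle-free conversion: each axis displacement is converted to a
#' physical length via the pixel pitch and then to an angle with `atan`; the
#' vectorial magnitude is the Euclidean norm of the two per-axis angles.
#'
#' @param dx,dy displacement in pixels (vectorised).
#' @param geometry a [screen_geometry()].
#' @return A data frame with columns `h_deg`, `v_deg` (signed per-axis angles)
#'   and `deg` (vectorial magnitude).
#' @export
pixels_to_degrees <- function(dx, dy, geometry) {
  if (geometry$viewing_distance_cm <= 0) stop("viewing distance must be positive")
  pitch <- pixel_pitch_cm(geometry)
  h <- atan(dx * pitch / geometry$viewing_distance_cm) * 180 / pi
  v <- atan(dy * pitch / geometry$viewing_distance_cm) * 180 / pi
  data.frame(h_deg = h, v_deg = v, deg = sqrt(h^2 + v^2))
}

# Angular gaze position about the screen centre, in degrees.
# Returns an n x 2 matrix (columns theta_x, theta_y) for a sample data frame.
angular_position <- function(x_px, y_px, geometry) {
  pitch <- pixel_pitch_cm(geometry)
  d <- geometry$viewing_distance_cm
  cbind(
    atan((x_px - geometry$width_px / 2) * pitch / d) * 180 / pi,
    atan((y_px - geometry$height_px / 2) * pitch / d) * 180 / pi
  )
}

#' Stimulus presentation protocol
#'
#' The trial structure of the emotional-face viewing task: a fixed number of
#' combined-face images, each shown for a fixed duration, with a 1 s central
#' cross between images so every trial starts with gaze at the screen centre.
#'
#' @param n_trials number of stimulus images per session.
#' @param trial_duration_s presentation time per image, seconds.
#' @param inter_trial_cross logical; whether a central cross precedes each
#'   trial (fixes the initial gaze position at the screen centre).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_trials = 10L, trial_duration_s = 5,
                              inter_trial_cross = TRUE) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (trial_duration_s <= 0) stop("trial_duration_s must be positive")
  structure(
    list(
      n_trials = as.integer(n_trials),
      trial_duration_s = trial_duration_s,
      inter_trial_cross = isTRUE(inter_trial_cross)
    ),
    class = "stimulus_protocol"
  )
}
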
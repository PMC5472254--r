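#' Flag low-intensity LED samples as missing
#'
#' When an LED leaves the camera's view, the brightest pixel in the weighted
#' image is noise somewhere in the arena; such frames are identified by a
#' minimum-intensity threshold on the distribution of per-frame maxima and
#' marked missing. The threshold defaults to a low percentile of the observed
#' intensity distribution (pooled over both LEDs).
#'
#' @param stream data frame with columns `t_s`, `ant_x_px`, `ant_y_px`,
#'   `ant_int`, `post_x_px`, `post_y_px`, `post_int` (one row per video frame).
#' @param min_intensity absolute intensity threshold; if `NULL`, taken as the
#'   `percentile` quantile of the pooled intensity maxima.
#' @param percentile percentile (in \[0, 1\]) used when `min_intensity` is `NULL`.
#' @return the stream with coordinates of sub-threshold samples set to `NA`.
#' @export
flag_missing <- function(stream, min_intensity = NULL, percentile = 0.01) {
  if (nrow(stream) == 0) stop("empty LED stream", call. = FALSE)
  if (is.null(min_intensity)) {
    min_intensity <- stats::quantile(c(stream$ant_int, stream$post_int),
                                     probs = percentile, na.rm = TRUE,
                                     names = FALSE)
  }
  for (led in c("ant", "post")) {
    bad <- !is.na(stream[[paste0(led, "_int")]]) &
      stream[[paste0(led, "_int")]] < min_intensity
    stream[bad, paste0(led, "_x_px")] <- NA_real_
    stream[bad, paste0(led, "_y_px")] <- NA_real_
  }
  attr(stream, "min_intensity") <- min_intensity
  stream
}

# Fill NA runs of length <= max_gap by cubic spline through valid neighbors.
# Boundary runs are left missing (no extrapolation).
fill_gaps_spline <- function(v, t, max_gap) {
  miss <- is.na(v)
  if (!any(miss)) return(v)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(!miss)
  if (length(ok) < 2) return(v)
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    if (r$lengths[j] > max_gap) next
    if (starts[j] == 1 || ends[j] == length(v)) next  # boundary: leave missing
    idx <- starts[j]:ends[j]
    v[idx] <- stats::spline(t[ok], v[ok], xout = t[idx], method = "natural")$y
  }
  v
}

#' Interpolate short runs of missing LED samples
#'
#' Missing runs of up to `max_gap_frames` frames (333 ms at 30 fps for the
#' default of 10) are filled by cubic spline interpolation through the
#' neighboring valid samples; longer runs and runs touching the stream
#' boundary remain missing and are discarded downstream.
#'
#' @param stream LED stream as in [flag_missing()], with missing samples `NA`.
#' @param max_gap_frames longest missing run (frames) that may be filled.
#' @return the stream with fillable gaps interpolated.
#' @export
interpolate_gaps <- function(stream, max_gap_frames = 10) {
  for (col in c("ant_x_px", "ant_y_px", "post_x_px", "post_y_px")) {
    stream[[col]] <- fill_gaps_spline(stream[[col]], stream$t_s, max_gap_frames)
  }
  stream
}

#' Estimate the image-to-arena rigid calibration
#'
#' Least-squares rigid transform (proper rotation + translation) mapping image
#' points to matched arena points, estimated from the singular value
#' decomposition of the cross-covariance of the centered point sets; a
#' reflection in the SVD solution is corrected to a proper rotation
#' (determinant +1).
#'
#' @param image_points n x 2 matrix of calibration points in image pixels.
#' @param arena_points n x 2 matrix of the same points in arena mm.
#' @return object of class `calibration_transform` with fields `R` (2 x 2
#'   rotation) and `T` (length-2 translation, mm), applied as `N = T + R %*% M`.
#' @export
estimate_calibration <- function(image_points, arena_points) {
  image_points <- as.matrix(image_points)
  arena_points <- as.matrix(arena_points)
  if (nrow(image_points) < 3 || nrow(image_points) != nrow(arena_points)) {
    stop("need >= 3 matched point pairs", call. = FALSE)
  }
  cm <- colMeans(image_points)
  cn <- colMeans(arena_points)
  M <- sweep(image_points, 2, cm)
  N <- sweep(arena_points, 2, cn)
  H <- t(M) %*% N
  s <- svd(H)
  if (min(s$d) < 1e-9 * max(s$d, 1e-300)) {
    stop("calibration points are collinear or degenerate", call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  T <- as.numeric(cn - R %*% cm)
  structure(list(R = R, T = T), class = "calibration_transform")
}

#' @export
print.calibration_transform <- function(x, ...) {
  ang <- atan2(x$R[2, 1], x$R[1, 1]) * 180 / pi
  cat(sprintf("<calibration_transform> rotation %.2f deg, translation (%.1f, %.1f) mm\n",
              ang, x$T[1], x$T[2]))
  invisible(x)
}

# Apply N = T + R M to an n x 2 matrix of points (rows).
apply_calibration <- function(calib, pts) {
  sweep(as.matrix(pts) %*% t(calib$R), 2, calib$T, `+`)
}

#' Pose time series from a calibrated LED stream
#'
#' Maps both LED positions into the arena frame via `N = T + R M`, then takes
#' head position as the midpoint between the LEDs and head direction as the
#' atan2 angle of the posterior-to-anterior vector (the head midline). Frames
#' with a missing or coincident LED pair yield a missing pose.
#'
#' @param stream interpolated LED stream (see [interpolate_gaps()]).
#' @param calib a `calibration_transform`.
#' @return data frame (`t_s`, `x_mm`, `y_mm`, `dir_deg`) with `NA` rows where
#'   the pose could not be reconstructed.
#' @export
pose_timeseries <- function(stream, calib) {
  stopifnot(inherits(calib, "calibration_transform"))
  ant <- apply_calibration(calib, cbind(stream$ant_x_px, stream$ant_y_px))
  post <- apply_calibration(calib, cbind(stream$post_x_px, stream$post_y_px))
  dx <- ant[, 1] - post[, 1]
  dy <- ant[, 2] - post[, 2]
  coincident <- !is.na(dx) & !is.na(dy) & dx == 0 & dy == 0
  dir <- ifelse(coincident, NA_real_, atan2(dy, dx) * 180 / pi)
  dir[!is.na(dir)] <- wrap_angle(dir[!is.na(dir)])
  data.frame(
    t_s = stream$t_s,
    x_mm = (ant[, 1] + post[, 1]) / 2,
    y_mm = (ant[, 2] + post[, 2]) / 2,
    dir_deg = dir
  )
}

#' Render a pose series to a synthetic LED stream
#'
#' Inverse of [pose_timeseries()]: places anterior/posterior LEDs on the head
#' midline at `led_sep_mm / 2` either side of the head origin, then maps them
#' into image coordinates with the inverse of `calib`. Used to build
#' round-trip fixtures for the tracking pipeline.
#'
#' @param poses data frame (`t_s`, `x_mm`, `y_mm`, `dir_deg`).
#' @param calib a `calibration_transform` (arena -> image applied inversely).
#' @param led_sep_mm distance between the two LEDs along the midline, mm.
#' @param intensity constant intensity written for both LEDs.
#' @return an LED stream data frame as accepted by [flag_missing()].
#' @export
render_led_stream <- function(poses, calib, led_sep_mm = 20, intensity = 100) {
  stopifnot(inherits(calib, "calibration_transform"))
  u <- cbind(cos(poses$dir_deg * pi / 180), sin(poses$dir_deg * pi / 180))
  ant <- cbind(poses$x_mm, poses$y_mm) + u * led_sep_mm / 2
  post <- cbind(poses$x_mm, poses$y_mm) - u * led_sep_mm / 2
  Rinv <- t(calib$R)
  to_img <- function(p) sweep(p, 2, calib$T) %*% t(Rinv)
  ai <- to_img(ant)
  pi_ <- to_img(post)
  data.frame(
    t_s = poses$t_s,
    ant_x_px = ai[, 1], ant_y_px = ai[, 2], ant_int = intensity,
    post_x_px = pi_[, 1], post_y_px = pi_[, 2], post_int = intensity
  )
}
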
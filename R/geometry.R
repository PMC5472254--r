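#' Wrap angles into the canonical interval (-180, 180]
#'
#' All angular quantities in the package (head direction, stimulus angle in
#' either coordinate frame) live on the half-open interval (-180, 180] degrees,
#' counter-clockwise positive (right-hand rule about the z axis, matching
#' `atan2`). By convention -180 maps to +180.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in (-180, 180] and
#'   congruent to the input modulo 360.
#' @examples
#' wrap_angle(c(190, -180, 720))  # -170, 180, 0
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wrap_angle: angles must be finite numeric values", call. = FALSE)
  }
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Construct an arena model
#'
#' Describes the testing arena: speaker positions on a ring, the arena bounds,
#' and the sound-level calibration at the arena center. The arena coordinate
#' frame has its origin at the arena center and its "front" (the direction the
#' speaker at 0 degrees lies in, and the line of symmetry of the D-shaped
#' arena) along the +x axis; angles are measured counter-clockwise from +x, so
#' positive world angles are to the left of the front when facing forward.
#'
#' The default arena is a D-shape: a 350 x 300 mm rectangle (behind the
#' center) joined to a semicircle of radius 175 mm (in front), with 7 speakers
#' at 30 degree intervals between -90 and +90 degrees, 260 mm from the center.
#' Click level is calibrated to 60 dB SPL (0.02 Pa) at the center.
#'
#' @param speaker_angles_deg speaker angles on the ring, degrees, strictly
#'   increasing, 0 = arena front.
#' @param speaker_radius_mm distance from arena origin to every speaker, mm.
#' @param shape `"d"` for the default D-shaped bounds, `"disc"` for a circular
#'   arena of radius `speaker_radius_mm` (used for simulated speaker rings).
#' @param rect_width_mm,rect_length_mm,semi_radius_mm D-shape dimensions, mm.
#' @param cal_pressure_pa reference RMS pressure at the arena center, Pa.
#' @param cal_level_db sound level corresponding to `cal_pressure_pa`, dB SPL.
#' @return an object of class `arena_model`.
#' @examples
#' arena <- make_arena()
#' speaker_positions(arena)
#' @export
make_arena <- function(speaker_angles_deg = seq(-90, 90, by = 30),
                       speaker_radius_mm = 260,
                       shape = c("d", "disc"),
                       rect_width_mm = 350, rect_length_mm = 300,
                       semi_radius_mm = 175,
                       cal_pressure_pa = 0.02, cal_level_db = 60) {
  shape <- match.arg(shape)
  if (any(diff(speaker_angles_deg) <= 0)) {
    stop("speaker angles must be strictly increasing", call. = FALSE)
  }
  if (speaker_radius_mm <= 0) stop("speaker radius must be positive", call. = FALSE)
  structure(
    list(
      speaker_angles_deg = wrap_angle(speaker_angles_deg),
      speaker_radius_mm = speaker_radius_mm,
      shape = shape,
      rect_width_mm = rect_width_mm,
      rect_length_mm = rect_length_mm,
      semi_radius_mm = semi_radius_mm,
      cal_pressure_pa = cal_pressure_pa,
      cal_level_db = cal_level_db
    ),
    class = "arena_model"
  )
}

#' Speaker ring arena for deterministic receptive-field simulations
#'
#' A circular arena whose speakers form a full or partial ring; the classic
#' simulation setup uses 36 speakers at 10 degree intervals, 1000 mm from the
#' origin.
#'
#' @param n_speakers number of equally spaced speakers.
#' @param radius_mm ring radius, mm.
#' @param span_deg total angular span covered; 360 gives a full ring.
#' @param ... passed to [make_arena()].
#' @return an `arena_model`.
#' @export
make_ring_arena <- function(n_speakers = 36, radius_mm = 1000,
                            span_deg = 360, ...) {
  if (span_deg >= 360) {
    ang <- seq(-180, 180, length.out = n_speakers + 1)[-1]
  } else {
    ang <- seq(-span_deg / 2, span_deg / 2, length.out = n_speakers)
  }
  make_arena(speaker_angles_deg = sort(ang), speaker_radius_mm = radius_mm,
             shape = "disc", ...)
}

#' @export
print.arena_model <- function(x, ...) {
  cat(sprintf("<arena_model> %d speakers at %.0f mm (%s shape), %g dB SPL at center\n",
              length(x$speaker_angles_deg), x$speaker_radius_mm, x$shape,
              x$cal_level_db))
  invisible(x)
}

#' Cartesian positions of the arena speakers
#'
#' @param arena an `arena_model`.
#' @return data frame with columns `speaker_id`, `angle_deg`, `x_mm`, `y_mm`.
#' @export
speaker_positions <- function(arena) {
  stopifnot(inherits(arena, "arena_model"))
  th <- arena$speaker_angles_deg * pi / 180
  data.frame(
    speaker_id = seq_along(th),
    angle_deg = arena$speaker_angles_deg,
    x_mm = arena$speaker_radius_mm * cos(th),
    y_mm = arena$speaker_radius_mm * sin(th)
  )
}

#' Is a point inside the arena bounds?
#'
#' For the D-shape: the semicircular half occupies x >= 0 (radius
#' `semi_radius_mm`), the rectangular half x in [-rect_length, 0] with
#' |y| <= rect_width / 2.
#'
#' @param arena an `arena_model`.
#' @param x_mm,y_mm coordinates, mm (vectorized).
#' @return logical vector.
#' @export
in_arena <- function(arena, x_mm, y_mm) {
  stopifnot(inherits(arena, "arena_model"))
  if (arena$shape == "disc") {
    return(x_mm^2 + y_mm^2 <= arena$speaker_radius_mm^2)
  }
  half_w <- arena$rect_width_mm / 2
  in_rect <- x_mm <= 0 & x_mm >= -arena$rect_length_mm & abs(y_mm) <= half_w
  in_semi <- x_mm > 0 & (x_mm^2 + y_mm^2) <= arena$semi_radius_mm^2
  in_rect | in_semi
}

#' Stimulus geometry relative to a head pose
#'
#' Computes, for each (head pose, source position) pair, the stimulus angle
#' relative to the head midline, the stimulus angle in the world frame, the
#' head-to-source distance, and the sound level at the head. The head-relative
#' angle subtracts the head direction from the atan2 angle of the head-to-source
#' vector; the level assumes spherical spreading from the source calibrated at
#' the arena center, i.e. pressure at the head is the center-calibrated
#' pressure scaled by (origin-to-source distance) / (head-to-source distance).
#'
#' @param head_x_mm,head_y_mm,head_dir_deg head position (mm, arena frame) and
#'   direction (degrees, CCW from +x); vectorized.
#' @param src_x_mm,src_y_mm source position, mm (vectorized or scalar).
#' @param arena an `arena_model` supplying the level calibration.
#' @param nominal_level_db nominal click level at the calibration point, dB SPL
#'   (defaults to the arena calibration level; vectorized to handle level rove).
#' @return data frame with columns `theta_hs_deg` (head frame), `theta_ws_deg`
#'   (world frame), `hs_distance_mm`, `level_at_head_db`.
#' @export
stimulus_geometry <- function(head_x_mm, head_y_mm, head_dir_deg,
                              src_x_mm, src_y_mm, arena,
                              nominal_level_db = arena$cal_level_db) {
  stopifnot(inherits(arena, "arena_model"))
  dx <- src_x_mm - head_x_mm
  dy <- src_y_mm - head_y_mm
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0)) {
    stop("degenerate geometry: head coincides with source", call. = FALSE)
  }
  as_dist <- sqrt(src_x_mm^2 + src_y_mm^2)
  theta_hs <- wrap_angle(atan2(dy, dx) * 180 / pi - head_dir_deg)
  theta_ws <- wrap_angle(atan2(src_y_mm, src_x_mm) * 180 / pi)
  # level: p_head = p_cal * |AS| / |HS|; L = 20 log10(p_head / 20 uPa)
  level <- nominal_level_db + 20 * log10(as_dist / d)
  data.frame(
    theta_hs_deg = theta_hs,
    theta_ws_deg = theta_ws,
    hs_distance_mm = d,
    level_at_head_db = level
  )
}

#' Head speed from a position time series
#'
#' Frame-to-frame displacement of the head origin divided by the inter-frame
#' interval, smoothed with a unit-sum 9-point Hann window. Boundary frames use
#' a truncated, renormalized window; the first frame duplicates the first
#' backward difference so the output has the same length as the input.
#'
#' @param x_mm,y_mm head position series, mm.
#' @param t_s frame times, seconds, strictly increasing.
#' @param window_len Hann window length in frames (odd).
#' @return numeric vector of speeds, cm/s, same length as the input.
#' @export
head_speed <- function(x_mm, y_mm, t_s, window_len = 9) {
  n <- length(t_s)
  if (length(x_mm) != n || length(y_mm) != n) {
    stop("position and time series must have equal length", call. = FALSE)
  }
  if (n < window_len) stop("need at least ", window_len, " samples", call. = FALSE)
  dt <- diff(t_s)
  if (any(dt <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  step_cm <- sqrt(diff(x_mm)^2 + diff(y_mm)^2) / 10
  raw <- c(step_cm[1] / dt[1], step_cm / dt)
  smooth_hann(raw, window_len)
}

# Unit-sum Hann smoothing with truncated renormalized boundary windows.
smooth_hann <- function(x, window_len = 9) {
  k <- 0:(window_len - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (window_len - 1)))
  w <- w / sum(w)
  half <- (window_len - 1) %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    wi <- w[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(x[lo:hi] * wi) / sum(wi)
  }
  out
}

#' Serialize / read an arena description as YAML
#'
#' @param arena an `arena_model`.
#' @param path file path for the YAML document.
#' @return `read_arena_yaml` returns an `arena_model`; `write_arena_yaml`
#'   returns `path` invisibly.
#' @export
write_arena_yaml <- function(arena, path) {
  stopifnot(inherits(arena, "arena_model"))
  yaml::write_yaml(unclass(arena), path)
  invisible(path)
}

#' @rdname write_arena_yaml
#' @export
read_arena_yaml <- function(path) {
  a <- yaml::read_yaml(path)
  make_arena(
    speaker_angles_deg = as.numeric(a$speaker_angles_deg),
    speaker_radius_mm = a$speaker_radius_mm,
    shape = a$shape,
    rect_width_mm = a$rect_width_mm,
    rect_length_mm = a$rect_length_mm,
    semi_radius_mm = a$semi_radius_mm,
    cal_pressure_pa = a$cal_pressure_pa,
    cal_level_db = a$cal_level_db
  )
}
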
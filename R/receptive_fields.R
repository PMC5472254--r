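#' Egocentric (head-centered) receptive field
#'
#' Spike probability as a circular Gaussian of the sound angle relative to the
#' head midline: `P(theta) = a * exp(-(theta - b)^2 / (2 c^2))`, with the
#' angular difference wrapped to (-180, 180].
#'
#' @param a peak spike probability (> 0, dimensionless).
#' @param b preferred head-relative angle, degrees in (-180, 180].
#' @param c_deg Gaussian width, degrees (> 0).
#' @return object of class `c("ego_field", "receptive_field")`.
#' @examples
#' f <- ego_field()            # the canonical matched field
#' ego_response(f, 0)          # 1.044
#' @export
ego_field <- function(a = 1.044, b = 0, c_deg = 75.7) {
  if (a <= 0 || c_deg <= 0) stop("a and c must be positive", call. = FALSE)
  structure(list(a = a, b = wrap_angle(b), c_deg = c_deg),
            class = c("ego_field", "receptive_field"))
}

#' Allocentric (world-centered) receptive field
#'
#' Spike probability as a separable product of one-dimensional probability
#' densities over arena x and y: `P(x, y) = f(x) * f(y)`. Each axis density
#' may be logistic, gaussian, laplace, or uniform (the uniform family uses a
#' half-width convention: support `mu +/- s`).
#'
#' The default parameters are the canonical matched field (logistic on both
#' axes, `mu_x = 1000`, `s_x = 400`, `mu_y = 0`, `s_y = 1000` mm) whose tuning
#' over a speaker ring matches the canonical egocentric field in the aligned
#' condition.
#'
#' @param family_x,family_y axis density family.
#' @param mu_x,s_x,mu_y,s_y location and scale per axis, mm (`s` > 0).
#' @return object of class `c("allo_field", "receptive_field")`.
#' @export
allo_field <- function(family_x = "logistic", mu_x = 1000, s_x = 400,
                       family_y = "logistic", mu_y = 0, s_y = 1000) {
  fams <- c("logistic", "gaussian", "laplace", "uniform")
  family_x <- match.arg(family_x, fams)
  family_y <- match.arg(family_y, fams)
  if (s_x <= 0 || s_y <= 0) stop("axis scales must be positive", call. = FALSE)
  structure(list(family_x = family_x, mu_x = mu_x, s_x = s_x,
                 family_y = family_y, mu_y = mu_y, s_y = s_y),
            class = c("allo_field", "receptive_field"))
}

#' @export
print.ego_field <- function(x, ...) {
  cat(sprintf("<ego_field> a = %g, b = %g deg, c = %g deg\n", x$a, x$b, x$c_deg))
  invisible(x)
}

#' @export
print.allo_field <- function(x, ...) {
  cat(sprintf("<allo_field> x: %s(mu = %g, s = %g) mm; y: %s(mu = %g, s = %g) mm\n",
              x$family_x, x$mu_x, x$s_x, x$family_y, x$mu_y, x$s_y))
  invisible(x)
}

#' Egocentric field response
#'
#' @param field an `ego_field`.
#' @param theta_hs_deg sound angle relative to the head midline, degrees
#'   (vectorized).
#' @return spike probabilities.
#' @export
ego_response <- function(field, theta_hs_deg) {
  stopifnot(inherits(field, "ego_field"))
  d <- wrap_angle(theta_hs_deg - field$b)
  field$a * exp(-d^2 / (2 * field$c_deg^2))
}

#' One-dimensional axis probability density
#'
#' @param family one of `"logistic"`, `"gaussian"`, `"laplace"`, `"uniform"`.
#' @param mu location, mm.
#' @param s scale, mm (> 0); for `"uniform"`, the half-width of the support.
#' @param u evaluation points, mm (vectorized).
#' @return densities, 1/mm.
#' @export
axis_pdf <- function(family, mu, s, u) {
  if (s <= 0) stop("scale must be positive", call. = FALSE)
  switch(family,
    logistic = stats::dlogis(u, location = mu, scale = s),
    gaussian = stats::dnorm(u, mean = mu, sd = s),
    laplace = exp(-abs(u - mu) / s) / (2 * s),
    uniform = stats::dunif(u, min = mu - s, max = mu + s),
    stop("unsupported axis family: ", family, call. = FALSE)
  )
}

#' Allocentric field response
#'
#' @param field an `allo_field`.
#' @param x_mm,y_mm source position in the arena frame, mm (vectorized).
#' @return spike probabilities (product of the axis densities).
#' @export
allo_response <- function(field, x_mm, y_mm) {
  stopifnot(inherits(field, "allo_field"))
  axis_pdf(field$family_x, field$mu_x, field$s_x, x_mm) *
    axis_pdf(field$family_y, field$mu_y, field$s_y, y_mm)
}

#' Deterministic field response over stimulus epochs
#'
#' Evaluates a receptive field on a table of stimulus epochs: egocentric
#' fields depend only on the head-relative angle, allocentric fields only on
#' the source position in the world.
#'
#' @param field a `receptive_field`.
#' @param epochs data frame with columns `theta_hs_deg`, `src_x_mm`, `src_y_mm`.
#' @return numeric vector of spike probabilities, one per epoch.
#' @export
field_response <- function(field, epochs) {
  if (inherits(field, "ego_field")) {
    ego_response(field, epochs$theta_hs_deg)
  } else if (inherits(field, "allo_field")) {
    allo_response(field, epochs$src_x_mm, epochs$src_y_mm)
  } else {
    stop("not a receptive field", call. = FALSE)
  }
}

#' Expected (noise-free) tuning of a simulated field under given behavior
#'
#' Averages the deterministic field response within angular bins of the
#' requested coordinate frame over a table of stimulus epochs (each epoch a
#' head pose paired with one source presentation). Optionally conditions on a
#' subset of head directions before binning, which is how head-direction-
#' conditioned tuning curves are produced.
#'
#' @param field a `receptive_field`.
#' @param epochs data frame with columns `theta_hs_deg`, `theta_ws_deg`,
#'   `src_x_mm`, `src_y_mm`, and (if conditioning) `head_dir_deg`.
#' @param frame `"head"` or `"world"`: which angle defines the bins.
#' @param bin_width_deg angular bin width, degrees.
#' @param range_deg half-range: bins cover `(-range, range]` via centers at
#'   multiples of `bin_width_deg`; use 180 for a full circle.
#' @param head_dir_range optional length-2 vector (degrees): keep only epochs
#'   whose wrapped head direction lies within the interval.
#' @return a `tuning_curve` object (see [tuning_curve()]) whose `mean_rate`
#'   column holds mean spike probabilities; empty bins are dropped and counted
#'   in `attr(, "n_empty_bins")`.
#' @export
expected_tuning <- function(field, epochs, frame = c("head", "world"),
                            bin_width_deg = 30, range_deg = 180,
                            head_dir_range = NULL) {
  frame <- match.arg(frame)
  if (!is.null(head_dir_range)) {
    keep <- in_angle_interval(epochs$head_dir_deg, head_dir_range)
    epochs <- epochs[keep, , drop = FALSE]
  }
  theta <- if (frame == "head") epochs$theta_hs_deg else epochs$theta_ws_deg
  p <- field_response(field, epochs)
  bin_average(theta, p, bin_width_deg, range_deg, frame = frame)
}

# TRUE where wrap_angle(x) falls inside [lo, hi] interpreted circularly.
in_angle_interval <- function(x, range) {
  lo <- range[1]; hi <- range[2]
  x <- wrap_angle(x)
  if (lo <= hi) x >= lo & x <= hi else x >= lo | x <= hi
}

# Shared circular binning: centers at integer multiples of bin_width within
# [-range, range]; the center at -180*sign collapses onto +180 (wrap).
# Returns a tuning_curve data frame (mean, sem, n per bin).
bin_average <- function(theta, value, bin_width_deg, range_deg, frame = "head") {
  idx <- round(wrap_angle(theta) / bin_width_deg)
  centers <- wrap_angle(idx * bin_width_deg)
  keep <- abs(centers) <= range_deg + 1e-9
  centers <- centers[keep]
  value <- value[keep]
  if (length(value) == 0) stop("no epochs fall in the requested range", call. = FALSE)
  grid <- sort(unique(centers))
  m <- tapply(value, factor(centers, levels = grid), mean)
  s <- tapply(value, factor(centers, levels = grid), stats::sd)
  n <- tapply(value, factor(centers, levels = grid), length)
  full_grid <- wrap_angle(seq(-range_deg, range_deg, by = bin_width_deg))
  full_grid <- sort(unique(full_grid[abs(full_grid) <= range_deg + 1e-9]))
  out <- data.frame(
    frame = frame,
    bin_center_deg = grid,
    mean_rate = as.numeric(m),
    sem = as.numeric(s) / sqrt(as.numeric(n)),
    n = as.numeric(n),
    bin_width_deg = bin_width_deg
  )
  attr(out, "n_empty_bins") <- length(setdiff(full_grid, grid))
  class(out) <- c("tuning_curve", "data.frame")
  out
}

#' Build stimulus epochs from a trajectory and an arena
#'
#' Pairs every trajectory step with every speaker (the deterministic
#' presentation schedule used for noise-free simulations) or with a supplied
#' per-step speaker assignment, and computes the stimulus geometry for each
#' pairing.
#'
#' @param traj trajectory data frame (`t_s`, `x_mm`, `y_mm`, `dir_deg`).
#' @param arena an `arena_model`.
#' @param speaker_ids optional integer vector (length `nrow(traj)`): one
#'   speaker per step; default pairs each step with all speakers.
#' @return data frame of epochs with pose, source position and geometry
#'   columns (`theta_hs_deg`, `theta_ws_deg`, `hs_distance_mm`,
#'   `level_at_head_db`, `src_x_mm`, `src_y_mm`, `head_dir_deg`, `speaker_id`).
#' @export
stimulus_epochs <- function(traj, arena, speaker_ids = NULL) {
  sp <- speaker_positions(arena)
  if (is.null(speaker_ids)) {
    i <- rep(seq_len(nrow(traj)), times = nrow(sp))
    j <- rep(seq_len(nrow(sp)), each = nrow(traj))
  } else {
    stopifnot(length(speaker_ids) == nrow(traj))
    i <- seq_len(nrow(traj))
    j <- speaker_ids
  }
  g <- stimulus_geometry(traj$x_mm[i], traj$y_mm[i], traj$dir_deg[i],
                         sp$x_mm[j], sp$y_mm[j], arena)
  cbind(
    g,
    data.frame(
      src_x_mm = sp$x_mm[j], src_y_mm = sp$y_mm[j],
      head_dir_deg = traj$dir_deg[i], speaker_id = sp$speaker_id[j],
      t_s = traj$t_s[i]
    )
  )
}
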
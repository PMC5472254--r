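#' Waveform distances between a test session and comparison sets
#'
#' Euclidean distances from a test session's mean waveform to the mean
#' waveforms of every other session at the same recording site (`d_test`) and
#' to every session at spatially separated control sites (`d_control`).
#' Control sites are assumed to satisfy the spatial separation criterion
#' (> 50 um in depth or > 500 um laterally) that guarantees distinct units.
#'
#' @param test numeric vector: the test session's mean waveform (e.g. 128
#'   interpolated amplitude samples).
#' @param same_site matrix (sessions x samples) of same-site mean waveforms.
#' @param other_sites matrix (sessions x samples) of control-site waveforms.
#' @return list with `d_test` and `d_control` distance vectors.
#' @export
waveform_distances <- function(test, same_site, other_sites) {
  same_site <- as.matrix(same_site)
  other_sites <- as.matrix(other_sites)
  if (ncol(same_site) != length(test) || ncol(other_sites) != length(test)) {
    stop("waveform lengths differ", call. = FALSE)
  }
  dist_to <- function(m) unname(sqrt(rowSums(sweep(m, 2, test)^2)))
  list(d_test = dist_to(same_site), d_control = dist_to(other_sites))
}

#' Test unit identity across sessions at a recording site
#'
#' For each same-site session, tests whether its waveform distance to the
#' test session is smaller than expected under the control distribution of
#' distances between known-distinct units. The default treats each same-site
#' distance as a single new observation from the control population
#' (prediction-style one-sided t test, df = n_control - 1); `method =
#' "pooled"` instead runs one two-sample Welch t test of all same-site
#' distances against the controls and assigns its p to every session.
#' P values are compared against `alpha` Bonferroni-corrected by the number
#' of sessions conducted at the site; the tracked run is the longest
#' contiguous run of significant sessions.
#'
#' @param d_test same-site distances (one per comparison session).
#' @param d_control control distances (>= 3).
#' @param n_sessions_at_site Bonferroni divisor (defaults to
#'   `length(d_test) + 1`, the number of sessions at the site).
#' @param alpha nominal significance level.
#' @param method `"per_session"` or `"pooled"`.
#' @return list with `p` (per session), `significant`, `run_start`,
#'   `run_end`, `run_length`.
#' @export
identity_test <- function(d_test, d_control,
                          n_sessions_at_site = length(d_test) + 1,
                          alpha = 0.05,
                          method = c("per_session", "pooled")) {
  method <- match.arg(method)
  if (length(d_control) < 3) stop("need >= 3 control distances", call. = FALSE)
  s <- stats::sd(d_control)
  if (s == 0) stop("zero-variance control distances", call. = FALSE)
  m <- length(d_control)
  p <- if (method == "per_session") {
    tstat <- (d_test - mean(d_control)) / (s * sqrt(1 + 1 / m))
    stats::pt(tstat, df = m - 1)  # one-sided: smaller than control
  } else {
    rep(stats::t.test(d_test, d_control, alternative = "less")$p.value,
        length(d_test))
  }
  sig <- p < alpha / n_sessions_at_site
  run <- longest_run(sig)
  list(p = p, significant = sig,
       run_start = run$start, run_end = run$end, run_length = run$length)
}

longest_run <- function(flags) {
  if (!any(flags)) return(list(start = NA_integer_, end = NA_integer_, length = 0L))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)[which.max(r$lengths[r$values])]
  list(start = starts[i], end = ends[i], length = r$lengths[i])
}

#' Single-unit flag from inter-spike intervals
#'
#' A cluster is treated as a well-isolated single unit when strictly less
#' than 1% of its inter-spike intervals are shorter than the refractory
#' period (1 ms).
#'
#' @param isi_s inter-spike intervals, seconds (non-empty).
#' @param refractory_s refractory period, seconds.
#' @param max_violation maximum tolerated violation fraction (exclusive).
#' @return list with `single_unit`, `violation_fraction`, `n_isi`.
#' @export
single_unit_flag <- function(isi_s, refractory_s = 0.001,
                             max_violation = 0.01) {
  if (length(isi_s) == 0) stop("empty ISI list", call. = FALSE)
  if (length(isi_s) < 100) warning("fewer than 100 ISIs: flag is unreliable")
  frac <- mean(isi_s < refractory_s)
  list(single_unit = frac < max_violation, violation_fraction = frac,
       n_isi = length(isi_s))
}
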
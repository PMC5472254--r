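#' Write a session bundle to a directory of plain-text files
#'
#' Emits `poses.csv`, `clicks.csv`, `spikes.csv` (long format: `unit_id`,
#' `t_s`), `arena.yaml` and `config.yaml` (provenance metadata).
#'
#' @param bundle a `session_bundle` (see [simulate_session()]).
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$poses, file.path(path, "poses.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$clicks, file.path(path, "clicks.csv"),
                   row.names = FALSE)
  spk <- do.call(rbind, lapply(names(bundle$spikes), function(u) {
    data.frame(unit_id = u, t_s = bundle$spikes[[u]])
  }))
  if (is.null(spk)) spk <- data.frame(unit_id = character(0), t_s = numeric(0))
  utils::write.csv(spk, file.path(path, "spikes.csv"), row.names = FALSE)
  write_arena_yaml(bundle$arena, file.path(path, "arena.yaml"))
  yaml::write_yaml(bundle$meta, file.path(path, "config.yaml"))
  invisible(path)
}

#' Read and validate a session bundle
#'
#' Loads a directory written by [write_session()] (or assembled by hand in
#' the same layout) into a typed in-memory bundle. All schema violations
#' found are reported together rather than silently fixed.
#'
#' @param path session directory.
#' @return a `session_bundle`.
#' @export
read_session <- function(path) {
  files <- c(poses = "poses.csv", clicks = "clicks.csv", spikes = "spikes.csv",
             arena = "arena.yaml")
  missing_files <- files[!file.exists(file.path(path, files))]
  if (length(missing_files)) {
    stop("session bundle is missing file(s): ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  poses <- utils::read.csv(file.path(path, "poses.csv"))
  clicks <- utils::read.csv(file.path(path, "clicks.csv"))
  spk <- utils::read.csv(file.path(path, "spikes.csv"))
  arena <- read_arena_yaml(file.path(path, "arena.yaml"))
  meta <- if (file.exists(file.path(path, "config.yaml"))) {
    yaml::read_yaml(file.path(path, "config.yaml"))
  } else list(source = "unknown")

  problems <- character(0)
  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      problems <<- c(problems, paste0(name, " lacks column(s): ",
                                      paste(miss, collapse = ", ")))
    }
  }
  need(poses, c("t_s", "x_mm", "y_mm", "dir_deg"), "poses.csv")
  need(clicks, c("t_s", "speaker_id"), "clicks.csv")
  need(spk, c("unit_id", "t_s"), "spikes.csv")
  if (!length(problems)) {
    if (is.unsorted(poses$t_s)) problems <- c(problems, "pose times not sorted")
    if (is.unsorted(clicks$t_s)) problems <- c(problems, "click times not sorted")
    bad_sp <- !clicks$speaker_id %in% seq_along(arena$speaker_angles_deg)
    if (any(bad_sp)) {
      problems <- c(problems, sprintf("%d clicks reference unknown speakers",
                                      sum(bad_sp)))
    }
    dirs <- poses$dir_deg[!is.na(poses$dir_deg)]
    if (any(dirs <= -180 | dirs > 180)) {
      problems <- c(problems, "pose directions outside (-180, 180]")
    }
  }
  if (length(problems)) {
    stop("invalid session bundle:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  spikes <- split(spk$t_s, spk$unit_id)
  structure(list(arena = arena, poses = poses, clicks = clicks,
                 spikes = spikes, meta = meta),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle> %s: %.1f min, %d clicks, %d pose frames, %d unit(s)\n",
    if (!is.null(x$meta$source)) x$meta$source else "?",
    diff(range(x$poses$t_s)) / 60, nrow(x$clicks), nrow(x$poses),
    length(x$spikes)))
  invisible(x)
}

#' Run the coordinate-frame analysis pipeline on a session bundle
#'
#' Orders the full workflow for every unit in a session: responsiveness
#' screen, aligned-condition tuning screen, free-movement tuning curves and
#' modulation depths in both frames, residual-modulation classification
#' (when residual regression models are supplied), and GLM/AIC
#' classification. Deterministic given the session contents.
#'
#' @param bundle a `session_bundle`.
#' @param stages character subset of
#'   `c("screen", "tuning", "classify_md", "classify_glm")`.
#' @param residual_models optional list with elements `head` and `world`
#'   (`residual_regression` objects) enabling the `classify_md` stage.
#' @param n_tests Bonferroni divisor for the modulation-depth test.
#' @param out_dir optional directory: per-stage CSV outputs and a YAML
#'   manifest are written there.
#' @return list with a per-unit results data frame `units`, the per-unit
#'   tuning curves, and the run `manifest`.
#' @export
run_pipeline <- function(bundle,
                         stages = c("screen", "tuning", "classify_md",
                                    "classify_glm"),
                         residual_models = NULL, n_tests = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(bundle, "session_bundle"))
  stages <- match.arg(stages, several.ok = TRUE)
  bs <- behavior_summary(bundle$poses, bundle$clicks, bundle$arena)
  units <- names(bundle$spikes)
  if (is.null(n_tests)) n_tests <- length(units)
  curves <- list()
  rows <- lapply(units, function(u) {
    tr <- trial_responses(bundle$spikes[[u]], bundle$clicks, bundle$poses,
                          bundle$arena)
    row <- data.frame(unit_id = u, n_trials = nrow(tr))
    if ("screen" %in% stages) {
      scr <- screen_sound_responsive(tr)
      al <- aligned_subset(tr)
      tun <- if (nrow(al) > 0) screen_spatial_tuning(al)
             else list(testable = FALSE, p = NA_real_, tuned = NA)
      row$responsive_p <- scr$p
      row$responsive <- scr$responsive
      row$aligned_n <- nrow(al)
      row$tuning_testable <- tun$testable
      row$tuning_p <- tun$p
      row$tuned <- tun$tuned
    }
    if (any(c("tuning", "classify_md", "classify_glm") %in% stages)) {
      ch <- tuning_curve(tr, "head")
      cw <- tuning_curve(tr, "world")
      curves[[u]] <<- list(head = ch, world = cw)
      row$md_head_pct <- modulation_depth(ch)
      row$md_world_pct <- modulation_depth(cw)
    }
    if ("classify_md" %in% stages && !is.null(residual_models)) {
      cls <- classify_modulation(row$md_head_pct, row$md_world_pct,
                                 bs$sigma_dir_deg,
                                 model_head = residual_models$head,
                                 model_world = residual_models$world,
                                 n_tests = n_tests)
      row$significant_head <- cls$significant_head
      row$significant_world <- cls$significant_world
      row$dominant_frame <- cls$dominant_frame
    }
    if ("classify_glm" %in% stages) {
      fits <- fit_glm_set(tr)
      sc <- model_scores(fits)
      lab <- classify_aic(fits)
      row$fit_head_pct <- sc$fit_head_pct
      row$fit_world_pct <- sc$fit_world_pct
      row$preference_pct <- sc$preference_pct
      row$aic_label <- lab$label
    }
    row
  })
  res <- do.call(rbind, rows)
  manifest <- list(
    package_version = as.character(utils::packageVersion("soundframes")),
    stages = stages,
    session = bundle$meta,
    sigma_dir_deg = bs$sigma_dir_deg,
    r2_head_world = bs$r2_head_world,
    n_units = length(units),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "units.csv"), row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(units = res, curves = curves, behavior = bs, manifest = manifest)
}
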
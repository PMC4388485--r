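# File interfaces: plain CSV (comma separator, '.' decimal, header row, LF
# endings, fixed column order), JSON run manifests, and one-increment-per-line
# noise scripts for deterministic fixtures.

#' Write and read batch trajectories as CSV
#'
#' The trajectory file has one row per trajectory sample with columns
#' `trial_id, step, t, x, y, z, z_eff` in deterministic row order.
#'
#' @param batch A recorded `batch_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(batch, path) {
  stopifnot(inherits(batch, "batch_result"))
  if (is.null(batch$trials))
    stop("batch was not recorded; rerun with `record = TRUE`")
  rows <- lapply(seq_along(batch$trials), function(i) {
    m <- batch$trials[[i]]$trajectory
    data.frame(trial_id = i, step = seq_len(nrow(m)) - 1L,
               t = m[, "t"], x = m[, "x"], y = m[, "y"],
               z = m[, "z"], z_eff = m[, "z_eff"])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param choices Optional character vector giving each trial's choice
#'   (`"target1"`/`"target2"`); if omitted it is inferred from the last
#'   sample's proximity to the targets.
#' @param geom Geometry used for choice inference on read.
#' @return For the reader: a list of `trial_result` objects.
#' @export
read_trajectory_csv <- function(path, choices = NULL,
                                geom = task_geometry()) {
  df <- utils::read.csv(path)
  need <- c("trial_id", "t", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("trajectory file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$z)) df$z <- NA_real_
  if (is.null(df$z_eff)) df$z_eff <- NA_real_
  ids <- unique(df$trial_id)
  out <- lapply(seq_along(ids), function(k) {
    d <- df[df$trial_id == ids[k], , drop = FALSE]
    d <- d[order(d$t), , drop = FALSE]
    m <- as.matrix(d[, c("t", "x", "y", "z", "z_eff")])
    colnames(m) <- c("t", "x", "y", "z", "z_eff")
    last <- m[nrow(m), c("x", "y")]
    ch <- if (!is.null(choices)) choices[k] else {
      d1 <- sum((last - geom$target1)^2)
      d2 <- sum((last - geom$target2)^2)
      if (d1 <= d2) "target1" else "target2"
    }
    structure(list(choice = ch, correct = ch == "target1",
                   rt = m[nrow(m), "t"], t_dec = NA_real_,
                   n_focus_switches = NA_integer_, trajectory = m,
                   model = "external", seed = NA_integer_),
              class = "trial_result")
  })
  out
}

#' Read external tabular trajectories with affine normalization
#'
#' Maps externally recorded 2AFC trajectories (columns `trial_id, t, x, y`)
#' into the default arena: the supplied start point goes to the arena
#' start and the chosen target to the corresponding arena target, via a
#' per-axis affine map. Metrics then apply identically to external and
#' simulated trajectories.
#'
#' @param path CSV file with columns `trial_id, t, x, y`.
#' @param start `(x, y)` of the recording's start location.
#' @param target1,target2 `(x, y)` of the recording's two targets.
#' @param geom Arena to normalise into (default [task_geometry()]).
#' @return A list of `trial_result` objects in arena coordinates.
#' @export
read_trajectories <- function(path, start, target1, target2,
                              geom = task_geometry()) {
  trs <- read_trajectory_csv(path, geom = geom)
  sx <- (geom$target2[1] - geom$target1[1]) / (target2[1] - target1[1])
  sy <- (geom$target1[2] - geom$start[2]) / (target1[2] - start[2])
  lapply(trs, function(tr) {
    m <- tr$trajectory
    m[, "x"] <- geom$start[1] + (m[, "x"] - start[1]) * sx
    m[, "y"] <- geom$start[2] + (m[, "y"] - start[2]) * sy
    last <- m[nrow(m), c("x", "y")]
    d1 <- sum((last - geom$target1)^2)
    d2 <- sum((last - geom$target2)^2)
    tr$choice <- if (d1 <= d2) "target1" else "target2"
    tr$correct <- tr$choice == "target1"
    tr$trajectory <- m
    tr
  })
}

#' Write the per-trial index of a batch as CSV
#'
#' Columns: `trial_id, choice, correct, rt, n_focus_switches`.
#'
#' @inheritParams write_trajectory_csv
#' @export
write_trial_index_csv <- function(batch, path) {
  stopifnot(inherits(batch, "batch_result"))
  df <- data.frame(trial_id = seq_along(batch$rt),
                   choice = batch$choice,
                   correct = batch$correct,
                   rt = batch$rt,
                   n_focus_switches = batch$n_focus_switches)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a sweep curve as CSV
#'
#' @param curve A [sweep_boundaries()] result.
#' @param path Output file path.
#' @export
write_sweep_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a metrics report as CSV
#'
#' @param metrics One or more rows from [trajectory_metrics()].
#' @param path Output file path.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Embeds the resolved configuration, seed and package version next to
#' every emitted artifact so a run can be replayed exactly.
#'
#' @param config Named list of resolved configuration values.
#' @param path Output file path.
#' @export
write_run_manifest <- function(config, path) {
  config$package <- "driftact"
  config$version <- as.character(utils::packageVersion("driftact"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Noise scripts: deterministic evidence increments
#'
#' A noise script is a plain-text file with one evidence increment per
#' line; fed to [run_trial()] via `increments` it replaces the stochastic
#' draws exactly, one increment per step.
#'
#' @param increments Numeric vector of increments.
#' @param path File path.
#' @export
write_noise_script <- function(increments, path) {
  writeLines(formatC(increments, format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname write_noise_script
#' @export
read_noise_script <- function(path) {
  as.numeric(readLines(path))
}

#' Generate the deterministic fixture bundle
#'
#' Writes the small plain-text fixtures backing deterministic tests and
#' examples: a zero-noise ramp script, a single-switch script driving the
#' evidence to `+b` then `-b`, a straight-line serial-model trajectory CSV,
#' and a mirrored pair of trajectories for symmetry checks.
#'
#' @param dir Output directory (created if absent).
#' @param seed Seed for the trajectory fixtures.
#' @param b Bound assumed by the switch script.
#' @return Named character vector of the files written.
#' @export
generate_fixtures <- function(dir, seed = 1, b = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(ramp = file.path(dir, "noise_ramp_sigma0.txt"),
         switch = file.path(dir, "noise_single_switch.txt"),
         m1 = file.path(dir, "trajectories_m1.csv"),
         mirror = file.path(dir, "trajectories_mirror_pair.csv"))
  # sigma = 0 ramp: constant drift increments
  write_noise_script(rep(1 / 3, 200), f["ramp"])
  # drive z to +b, then to -b two steps later, then hold past arrival
  write_noise_script(c(b, 0, -2 * b, rep(0, 200)), f["switch"])
  spec <- model_spec("m1", bound_b = b)
  batch <- run_batch(spec, 12, master_seed = seed, record = TRUE)
  write_trajectory_csv(batch, f["m1"])
  # mirrored pair about the midline, both ending at target 1
  spec0 <- model_spec("m2", bound_b = b)
  up <- run_trial(spec0, increments = c(b, rep(0, 200)))
  m <- up$trajectory
  mirrored <- m
  mirrored[, "x"] <- -mirrored[, "x"]
  df <- rbind(
    data.frame(trial_id = 1, step = seq_len(nrow(m)) - 1L, t = m[, "t"],
               x = m[, "x"], y = m[, "y"], z = m[, "z"],
               z_eff = m[, "z_eff"]),
    data.frame(trial_id = 2, step = seq_len(nrow(mirrored)) - 1L,
               t = mirrored[, "t"], x = mirrored[, "x"],
               y = mirrored[, "y"], z = -mirrored[, "z"],
               z_eff = -mirrored[, "z_eff"]))
  utils::write.csv(df, f["mirror"], row.names = FALSE, quote = FALSE,
                   eol = "\n")
  f
}
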
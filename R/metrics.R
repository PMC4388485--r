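# Trajectory analytics: every metric integrates over y (the axis from start
# to the target line), exploiting that y is non-decreasing along simulated
# trajectories (all foci lie on the target line). Segments with zero y-extent
# (stationary pre-decision phases; horizontal travel along the target line)
# contribute nothing to y-integrals by construction.

traj_matrix <- function(traj) {
  if (inherits(traj, "trial_result")) traj$trajectory else as.matrix(traj)
}

chosen_target_xy <- function(traj, geom) {
  stopifnot(inherits(traj, "trial_result"))
  if (traj$choice == "target1") geom$target1 else geom$target2
}

# collapse duplicate y values, keeping the last sample at each y, so that
# x(y) is single-valued for interpolation
collapse_by_y <- function(m) {
  y <- m[, "y"]
  keep <- c(y[-1] != y[-length(y)], TRUE)
  m[keep, , drop = FALSE]
}

#' Area between a trajectory and the chosen-target line
#'
#' The deviation measure for change-of-mind behaviour: the integral
#' `int |x(y) - x_chosen| dy` over the y-range from start to target, where
#' `x_chosen` is the chosen target's x-coordinate. Larger areas mean the
#' trajectory deviated more from heading straight down from (up to) its
#' final choice. Computed by trapezoidal integration on the native samples;
#' segments with no y-extent contribute zero.
#'
#' @param traj A `trial_result` whose trajectory ends at a target.
#' @param geom The [task_geometry()] the trajectory was simulated under.
#' @return The area in arena units squared.
#' @examples
#' spec <- model_spec("m1", evidence = evidence_params(noise_sigma = 0))
#' trajectory_area(run_trial(spec), spec$geometry) # straight line: 0.75
#' @export
trajectory_area <- function(traj, geom) {
  stopifnot(inherits(geom, "task_geometry"))
  m <- traj_matrix(traj)
  tgt <- chosen_target_xy(traj, geom)
  if (sqrt(sum((m[nrow(m), c("x", "y")] - tgt)^2)) > 1e-9)
    stop("trajectory does not terminate at the chosen target")
  dev <- abs(m[, "x"] - tgt[1])
  dy <- diff(m[, "y"])
  if (any(dy < -1e-12)) stop("trajectory y must be non-decreasing")
  sum((dev[-1] + dev[-length(dev)]) / 2 * dy)
}

#' Area-under-curve curvature of a trajectory
#'
#' The standard mouse-tracking deviation measure: the area between the
#' trajectory and the straight chord from its first to its last sample,
#' both reparameterised by y, `int |x(y) - x_chord(y)| dy`. Zero for a
#' straight path.
#'
#' @param traj A `trial_result`.
#' @return The area in arena units squared.
#' @export
auc_curvature <- function(traj) {
  m <- traj_matrix(traj)
  n <- nrow(m)
  y0 <- m[1, "y"]; y1 <- m[n, "y"]
  x0 <- m[1, "x"]; x1 <- m[n, "x"]
  if (y1 == y0) return(0)
  chord_x <- x0 + (x1 - x0) * (m[, "y"] - y0) / (y1 - y0)
  dev <- abs(m[, "x"] - chord_x)
  dy <- diff(m[, "y"])
  if (any(dy < -1e-12)) stop("trajectory y must be non-decreasing")
  sum((dev[-1] + dev[-length(dev)]) / 2 * dy)
}

#' Mean trajectory computed parallel to the x-axis
#'
#' Averages a set of same-choice trajectories over a common y-grid: each
#' trajectory is reparameterised as a single-valued function x(y) (duplicate
#' y-samples collapsed to the last sample at that y) and linearly
#' interpolated at the grid heights; the mean is taken per height. The
#' averaging axis is space (y), not normalised time.
#'
#' @param trajs A list of `trial_result` objects (or a recorded
#'   `batch_result`), all ending at the same target.
#' @param y_grid Strictly increasing grid of heights; defaults to 101
#'   uniform points spanning start y to target y.
#' @param geom Geometry used for the default grid; defaults to
#'   [task_geometry()].
#' @return An object of class `mean_trajectory`: list with `y_grid`,
#'   `mean_x` and `n_trajectories`.
#' @export
mean_trajectory <- function(trajs, y_grid = NULL, geom = task_geometry()) {
  if (inherits(trajs, "batch_result")) trajs <- trajs$trials
  if (length(trajs) == 0) stop("no trajectories supplied")
  choices <- vapply(trajs, function(tr) tr$choice, character(1))
  if (length(unique(choices)) != 1L)
    stop("all trajectories must end at the same target")
  if (is.null(y_grid)) {
    tgt <- if (choices[1] == "target1") geom$target1 else geom$target2
    y_grid <- seq(geom$start[2], tgt[2], length.out = 101)
  }
  if (any(diff(y_grid) <= 0)) stop("y_grid must be strictly increasing")
  xs <- vapply(trajs, function(tr) {
    m <- collapse_by_y(traj_matrix(tr))
    stats::approx(m[, "y"], m[, "x"], xout = y_grid, rule = 2)$y
  }, numeric(length(y_grid)))
  structure(list(y_grid = y_grid, mean_x = rowMeans(xs),
                 n_trajectories = length(trajs)),
            class = "mean_trajectory")
}

#' Angle from vertical of a mean-trajectory segment
#'
#' Fits a least-squares line of x on y over the first (or last) `fraction`
#' of the y-range of a mean trajectory and returns `atan(|dx/dy|)` in
#' degrees: 0 is vertical movement (no lateral drift), 90 horizontal.
#'
#' @param mt A [mean_trajectory()].
#' @param segment `"initial"` or `"final"`.
#' @param fraction Fraction of the y-range used, in `(0, 0.5]`; default 0.1.
#' @return The angle in degrees, in `[0, 90]`.
#' @export
angle_from_vertical <- function(mt, segment = c("initial", "final"),
                                fraction = 0.1) {
  segment <- match.arg(segment)
  stopifnot(inherits(mt, "mean_trajectory"),
            fraction > 0, fraction <= 0.5)
  y <- mt$y_grid; x <- mt$mean_x
  span <- diff(range(y))
  keep <- if (segment == "initial") y <= min(y) + fraction * span
          else y >= max(y) - fraction * span
  if (sum(keep) < 2) stop("fewer than 2 grid points in the segment")
  ys <- y[keep]; xs <- x[keep]
  slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((ys - mean(ys))^2)
  atan(abs(slope)) * 180 / pi
}

#' Study-style trajectory metrics for a batch
#'
#' Convenience wrapper: selects the first `k` trajectories ending at
#' `target`, computes the mean per-trajectory area to the chosen-target
#' line, the mean per-trajectory AUC curvature, and the initial and final
#' angles of the mean trajectory.
#'
#' @param batch A recorded `batch_result`.
#' @param target Target whose finishers are analysed (default `"target1"`,
#'   the direction of positive drift).
#' @param k Number of trajectories (default 150).
#' @param fraction Segment fraction for the angle fits.
#' @return A one-row `data.frame` with columns `model_id`,
#'   `n_trajectories`, `mean_area`, `initial_angle_deg`, `final_angle_deg`,
#'   `mean_auc`, `sigma`, `bound_b`, `seed`.
#' @export
trajectory_metrics <- function(batch, target = "target1", k = 150,
                               fraction = 0.1) {
  stopifnot(inherits(batch, "batch_result"))
  geom <- batch$spec$geometry
  sel <- select_trajectories(batch, target = target, k = k)
  mt <- mean_trajectory(sel, geom = geom)
  data.frame(
    model_id = batch$model,
    n_trajectories = k,
    mean_area = mean(vapply(sel, trajectory_area, numeric(1), geom = geom)),
    initial_angle_deg = angle_from_vertical(mt, "initial", fraction),
    final_angle_deg = angle_from_vertical(mt, "final", fraction),
    mean_auc = mean(vapply(sel, auc_curvature, numeric(1))),
    sigma = batch$spec$evidence$noise_sigma,
    bound_b = batch$spec$bound_b,
    seed = batch$summary$seed,
    stringsAsFactors = FALSE
  )
}
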
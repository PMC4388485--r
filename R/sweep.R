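#' Decision-boundary grid
#'
#' The default sweep grid: `n` geometrically spaced bounds spanning three
#' decades. Geometric spacing resolves the small-b end of the range that a
#' linear grid would skip over.
#'
#' @param n Number of grid points (default 31).
#' @param lower,upper Grid range (defaults 0.01 and 10).
#' @return A strictly increasing numeric vector.
#' @export
boundary_grid <- function(n = 31, lower = 0.01, upper = 10) {
  stopifnot(n >= 1, lower > 0, upper >= lower)
  if (n == 1) return(lower)
  exp(seq(log(lower), log(upper), length.out = n))
}

# independent master seed for grid point j of a sweep run from `seed`
point_seed <- function(seed, j) trial_seed(seed, 1000003 + j)

#' Speed-accuracy frontier over a boundary sweep
#'
#' Runs one [run_batch()] per bound in `b_grid` (independent seed
#' substreams per point) and collects the mean response time and mean error
#' at each, tracing the model's speed-accuracy frontier. For `m4` the
#' commitment gain tracks the grid as `g = 4 b` unless `gain_g` is given.
#'
#' @param model One of `"baseline"`, `"m1"`, `"m2"`, `"m3"`, `"m4"`.
#' @param b_grid Ascending vector of bounds (default [boundary_grid()]).
#' @param n_trials Trials per grid point.
#' @param seed Master seed for the sweep; point `j` uses a substream derived
#'   from `(seed, j)`, so sweeps of different models at the same seed share
#'   per-trial noise.
#' @param evidence,geometry Shared model configuration.
#' @param gain_g Optional fixed commitment gain for `m4`.
#' @return A `data.frame` of class `sweep_curve` with columns `model_id`,
#'   `b`, `g`, `n_trials`, `mean_rt`, `mean_error`, `seed`.
#' @examples
#' sweep_boundaries("baseline", b_grid = c(0.5, 1), n_trials = 200, seed = 1)
#' @export
sweep_boundaries <- function(model, b_grid = boundary_grid(),
                             n_trials = 1e4, seed = 1,
                             evidence = evidence_params(),
                             geometry = task_geometry(), gain_g = NULL) {
  if (length(b_grid) == 0) stop("empty boundary grid")
  if (any(diff(b_grid) <= 0)) stop("boundary grid must be strictly ascending")
  rows <- lapply(seq_along(b_grid), function(j) {
    b <- b_grid[j]
    spec <- model_spec(model, bound_b = b, evidence = evidence,
                       geometry = geometry, gain_g = gain_g)
    s <- run_batch(spec, n_trials, master_seed = point_seed(seed, j))$summary
    data.frame(model_id = model, b = b, g = spec$gain_g,
               n_trials = n_trials, mean_rt = s$mean_rt,
               mean_error = s$mean_error, seed = seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_curve", class(out))
  out
}

#' Interpolate a frontier's error at matched mean response times
#'
#' Piecewise-linear interpolation of a sweep curve's mean error as a
#' function of mean response time, for comparing models at matched speed.
#' Extrapolation is refused (`NA` outside the curve's RT range), since the
#' RT ranges of different architectures genuinely differ.
#'
#' @param curve A [sweep_boundaries()] result.
#' @param rt Response times at which to evaluate.
#' @return Mean errors at `rt`, `NA` where outside the observed range.
#' @export
frontier_error_at <- function(curve, rt) {
  ord <- order(curve$mean_rt)
  stats::approx(curve$mean_rt[ord], curve$mean_error[ord], xout = rt,
                ties = mean, rule = 1)$y
}

#' Calibrate the decision bound to a target mean response time
#'
#' Evaluates the mean response time on a coarse geometric grid of bounds
#' (common random numbers: every evaluation re-simulates with the same
#' master seed), locates a grid interval bracketing the target, and bisects
#' within it until the achieved mean RT is within `tol` of the target. The
#' bracketing step makes calibration robust for architectures whose mean RT
#' is not monotone in `b` (the commitment model's RT first falls then
#' flattens as the gain `g = 4b` grows with the bound).
#'
#' @param model Model identifier (as in [sweep_boundaries()]).
#' @param target_mean_rt Target mean response time in seconds.
#' @param tol Tolerance on the achieved mean RT (default 0.02 s).
#' @param n_trials Trials per bisection iterate (default 1e4).
#' @param seed Master seed shared by all iterates.
#' @param b_range Search interval for the bound.
#' @param evidence,geometry,gain_g Model configuration (see
#'   [sweep_boundaries()]).
#' @param max_iter Bisection iteration cap.
#' @return An object of class `calibration_result`: list with `b_star`,
#'   `achieved_mean_rt`, `target_mean_rt`, `tolerance`, `n_trials`, `seed`
#'   and `model`.
#' @examples
#' calibrate_boundary("baseline", target_mean_rt = 0.15, tol = 1e-9,
#'                    n_trials = 10, seed = 1,
#'                    evidence = evidence_params(noise_sigma = 0))
#' @export
calibrate_boundary <- function(model, target_mean_rt, tol = 0.02,
                               n_trials = 1e4, seed = 1,
                               b_range = c(0.01, 10),
                               evidence = evidence_params(),
                               geometry = task_geometry(), gain_g = NULL,
                               max_iter = 60) {
  mean_rt_at <- function(b) {
    spec <- model_spec(model, bound_b = b, evidence = evidence,
                       geometry = geometry, gain_g = gain_g)
    run_batch(spec, n_trials, master_seed = seed)$summary$mean_rt
  }
  grid <- boundary_grid(9, b_range[1], b_range[2])
  f <- vapply(grid, mean_rt_at, numeric(1))
  if (target_mean_rt < min(f) - tol)
    stop(sprintf(
      "target mean RT %.3f s is below the attainable minimum %.3f s for %s",
      target_mean_rt, min(f), model))
  if (target_mean_rt > max(f) + tol)
    stop(sprintf(
      "target mean RT %.3f s is above the attainable maximum %.3f s for %s",
      target_mean_rt, max(f), model))
  # convention: the smallest bound achieving the target, so the solution is
  # unique even when the RT curve dips and re-attains the target at larger b
  hit <- which(abs(f - target_mean_rt) <= tol)[1]
  br <- which((f[-length(f)] - target_mean_rt) *
                (f[-1] - target_mean_rt) <= 0)[1]
  if (!is.na(hit) && (is.na(br) || hit <= br)) {
    b_star <- grid[hit]; achieved <- f[hit]
  } else if (!is.na(br)) {
    # bisect the first (smallest-b) grid interval straddling the target
    lo <- grid[br]; hi <- grid[br + 1]; f_lo <- f[br]
    closer <- which.min(abs(f[c(br, br + 1)] - target_mean_rt))
    b_star <- grid[br + closer - 1L]
    achieved <- f[br + closer - 1L]
    for (it in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)  # bisect in log space, matching the grid scale
      f_mid <- mean_rt_at(mid)
      if (abs(f_mid - target_mean_rt) < abs(achieved - target_mean_rt)) {
        b_star <- mid; achieved <- f_mid
      }
      if (abs(f_mid - target_mean_rt) <= tol) break
      if ((f_lo > target_mean_rt) == (f_mid > target_mean_rt)) {
        lo <- mid; f_lo <- f_mid
      } else {
        hi <- mid
      }
    }
  } else {
    k <- which.min(abs(f - target_mean_rt))
    b_star <- grid[k]; achieved <- f[k]
  }
  if (abs(achieved - target_mean_rt) > tol)
    warning(sprintf(
      "calibration stopped at |achieved - target| = %.4f s > tol = %.4f s",
      abs(achieved - target_mean_rt), tol))
  structure(list(b_star = b_star, achieved_mean_rt = achieved,
                 target_mean_rt = target_mean_rt, tolerance = tol,
                 n_trials = n_trials, seed = seed, model = model),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %s: b* = %.5f (mean RT %.4f s, target %.4f +/- %.3f s, n = %d)\n",
    x$model, x$b_star, x$achieved_mean_rt, x$target_mean_rt, x$tolerance,
    as.integer(x$n_trials)))
  invisible(x)
}
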
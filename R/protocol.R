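#' Trajectory metrics at a calibrated bound
#'
#' The standard trajectory-analysis protocol: calibrate the decision bound
#' to a target mean response time ([calibrate_boundary()]), simulate a
#' recorded batch at the calibrated bound with the same master seed, select
#' the first `k` trials ending at `target`, and compute the batch metrics
#' ([trajectory_metrics()]).
#'
#' @inheritParams calibrate_boundary
#' @param n_trials_batch Recorded trials simulated for trajectory selection
#'   (their seed substreams are shared with the calibration batches, so
#'   they are a prefix of the calibration run).
#' @param target,k Selection passed to [trajectory_metrics()].
#' @return A one-row `data.frame`: the [trajectory_metrics()] columns plus
#'   `b_star`, `achieved_mean_rt` and `target_mean_rt`.
#' @examples
#' \donttest{
#' calibrated_metrics("m3", target_mean_rt = 1.5, seed = 1,
#'                    n_trials = 2000, n_trials_batch = 400, k = 100)
#' }
#' @export
calibrated_metrics <- function(model, target_mean_rt, seed, n_trials = 1e4,
                               n_trials_batch = 600, k = 150, tol = 0.02,
                               evidence = evidence_params(),
                               geometry = task_geometry(), gain_g = NULL,
                               target = "target1") {
  cal <- calibrate_boundary(model, target_mean_rt, tol = tol,
                            n_trials = n_trials, seed = seed,
                            evidence = evidence, geometry = geometry,
                            gain_g = gain_g)
  spec <- model_spec(model, bound_b = cal$b_star, evidence = evidence,
                     geometry = geometry, gain_g = gain_g)
  batch <- run_batch(spec, n_trials_batch, master_seed = seed, record = TRUE)
  out <- trajectory_metrics(batch, target = target, k = k)
  out$b_star <- cal$b_star
  out$achieved_mean_rt <- cal$achieved_mean_rt
  out$target_mean_rt <- target_mean_rt
  out
}
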
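#' Per-trial seed substream
#'
#' Derives the seed for trial `i` of a batch as a pure function of the
#' master seed and the trial index, so batches are reproducible and
#' independent of execution order or batch splitting.
#'
#' @param master_seed Integer master seed.
#' @param i Trial index (1-based), vectorised.
#' @return Integer seed(s) in `[1, 2^31 - 1)`.
#' @export
trial_seed <- function(master_seed, i) {
  m <- 2147483647
  s <- as.numeric(master_seed) %% m
  as.integer(1 + ((s * 48271) %% m + (as.numeric(i) %% m) * 69621) %% m)
}

#' Simulate a single decision-action trial
#'
#' Runs one trial of the model in `spec`: the evidence accumulator and the
#' constant-speed action system advance on a shared clock, the action focus
#' for each interval being computed from the evidence state at the start of
#' that interval. The baseline terminates at bound crossing; models `m1`-`m4`
#' terminate when the agent reaches a target, with the terminal step
#' shortened so that straight-line travel takes exactly `distance / v`.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed applied before the trial; `NULL` uses
#'   the current RNG state.
#' @param increments Optional numeric vector of scripted evidence increments
#'   replacing the stochastic draws (one per step, for deterministic
#'   fixtures); an error is raised if the script runs out.
#' @param record If `TRUE` (default) the full time-stamped trajectory with
#'   evidence traces is returned.
#' @param max_steps Hard step cap; exhaustion signals a non-terminating
#'   configuration.
#' @return An object of class `trial_result`: a list with `choice`
#'   (`"target1"`/`"target2"`), `correct` (choice of target 1, the direction
#'   of positive drift), `rt` (s), `t_dec` (first bound-crossing time, `NA`
#'   if none), `n_focus_switches` (midline crossings of the focus), and
#'   `trajectory`, a matrix with columns `t, x, y, z, z_eff`.
#' @examples
#' spec <- model_spec("m1", bound_b = 1, evidence = evidence_params(noise_sigma = 0))
#' tr <- run_trial(spec)
#' tr$rt # 0.15 + sqrt(3.25)/2
#' @export
run_trial <- function(spec, seed = NULL, increments = NULL, record = TRUE,
                      max_steps = 1e6) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  g <- spec$geometry
  res <- sim_trial_cpp(
    model_code(spec$model),
    spec$evidence$drift_mu, spec$evidence$noise_sigma, spec$evidence$dt,
    spec$bound_b, spec$gain_g, g$speed_v,
    g$start[1], g$start[2], g$target1[1], g$target1[2],
    g$target2[1], g$target2[2],
    as.integer(max_steps), record, increments)
  structure(list(
    choice = c("target1", "target2")[res$choice],
    correct = res$choice == 1L,
    rt = res$rt,
    t_dec = res$t_dec,
    n_focus_switches = res$n_focus_switches,
    trajectory = res$trajectory,
    model = spec$model,
    seed = if (is.null(seed)) NA_integer_ else seed
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s: %s (%s), rt = %.4f s, %d focus switch(es)\n",
              x$model, x$choice, if (x$correct) "correct" else "error",
              x$rt, x$n_focus_switches))
  invisible(x)
}

#' Simulate a reproducible batch of trials
#'
#' Trial `i` runs on the seed substream [trial_seed()]`(master_seed, i)`, so
#' the same master seed always yields bitwise-identical results regardless
#' of how the batch is split.
#'
#' @param spec A [model_spec()].
#' @param n_trials Number of trials (>= 1).
#' @param master_seed Integer master seed.
#' @param record If `TRUE`, keep every trial's full trajectory (memory
#'   scales with trials x steps); summaries alone need `FALSE`.
#' @param max_steps Per-trial step cap.
#' @return An object of class `batch_result`: vectors `rt`, `correct`,
#'   `choice`, `n_focus_switches` over trials; `trials`, a list of
#'   [run_trial()] results when `record = TRUE` (else `NULL`); and `summary`
#'   with `n_trials`, `mean_rt`, `mean_error` (fraction incorrect) and
#'   `seed`.
#' @examples
#' b <- run_batch(model_spec("baseline"), 100, master_seed = 7)
#' b$summary
#' @export
run_batch <- function(spec, n_trials, master_seed, record = FALSE,
                      max_steps = 1e6) {
  stopifnot(inherits(spec, "model_spec"), n_trials >= 1)
  n_trials <- as.integer(n_trials)
  rt <- numeric(n_trials)
  correct <- logical(n_trials)
  nsw <- integer(n_trials)
  trials <- if (record) vector("list", n_trials) else NULL
  for (i in seq_len(n_trials)) {
    tr <- run_trial(spec, seed = trial_seed(master_seed, i),
                    record = record, max_steps = max_steps)
    rt[i] <- tr$rt
    correct[i] <- tr$correct
    nsw[i] <- tr$n_focus_switches
    if (record) trials[[i]] <- tr
  }
  structure(list(
    model = spec$model,
    spec = spec,
    rt = rt,
    correct = correct,
    choice = ifelse(correct, "target1", "target2"),
    n_focus_switches = nsw,
    trials = trials,
    summary = list(n_trials = n_trials, mean_rt = mean(rt),
                   mean_error = mean(!correct), seed = master_seed)
  ), class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<batch_result> %s: %d trials (seed %s)\n  mean RT %.4f s, mean error %.4f\n",
    x$model, s$n_trials, format(s$seed), s$mean_rt, s$mean_error))
  invisible(x)
}

#' Select recorded trajectories ending at a given target
#'
#' Returns the first `k` trials (in trial-index order) whose choice equals
#' `target`. No mirror reflection is applied.
#'
#' @param results A `batch_result` recorded with `record = TRUE`, or a list
#'   of `trial_result` objects.
#' @param target `"target1"` or `"target2"`.
#' @param k Number of trajectories requested; an error is raised if fewer
#'   qualify.
#' @return A list of `trial_result` objects of length `k`.
#' @export
select_trajectories <- function(results, target = c("target1", "target2"),
                                k) {
  target <- match.arg(target)
  trials <- if (inherits(results, "batch_result")) results$trials else results
  if (is.null(trials))
    stop("batch was not recorded; rerun with `record = TRUE`")
  stopifnot(k >= 0)
  hits <- Filter(function(tr) tr$choice == target, trials)
  if (length(hits) < k)
    stop(sprintf("only %d of %d trials end at %s (requested %d)",
                 length(hits), length(trials), target, k))
  hits[seq_len(k)]
}
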
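#' Evidence accumulator state
#'
#' A snapshot of the accumulator: evidence `z`, elapsed time `t`, and the
#' step index. Accumulation always starts unbiased at `z = 0`.
#'
#' @param z Accumulated evidence.
#' @param t Elapsed time in seconds.
#' @param step_index Integer number of steps taken.
#' @return An object of class `evidence_state`.
#' @export
evidence_state <- function(z = 0, t = 0, step_index = 0L) {
  structure(list(z = z, t = t, step_index = as.integer(step_index)),
            class = "evidence_state")
}

#' Advance the accumulator by one step
#'
#' Draws one increment from Normal(`drift_mu`, `noise_sigma`^2) using the
#' current R random number stream and returns the advanced state; the input
#' state is unmodified. With `noise_sigma = 0` the update is the
#' deterministic drift `drift_mu`.
#'
#' @param state An [evidence_state()].
#' @param params An [evidence_params()].
#' @return The new `evidence_state` with `z` incremented, `t` advanced by
#'   `dt` and `step_index` by one.
#' @examples
#' set.seed(1)
#' s <- accumulate_step(evidence_state(), evidence_params())
#' s$t # 0.05
#' @export
accumulate_step <- function(state, params) {
  stopifnot(inherits(state, "evidence_state"),
            inherits(params, "evidence_params"))
  dz <- stats::rnorm(1L, params$drift_mu, params$noise_sigma)
  evidence_state(z = state$z + dz, t = state$t + params$dt,
                 step_index = state$step_index + 1L)
}

#' Bound-crossing status of an evidence value
#'
#' Crossing is inclusive: `z >= b` reports `"upper_crossed"`, `z <= -b`
#' reports `"lower_crossed"`, anything in between `"undecided"`. The upper
#' bound takes precedence (only reachable in the degenerate limit).
#'
#' @param z Evidence value.
#' @param b Positive decision bound.
#' @return One of `"upper_crossed"`, `"lower_crossed"`, `"undecided"`.
#' @export
bound_status <- function(z, b) {
  b <- bound(b)
  if (z >= b) "upper_crossed"
  else if (z <= -b) "lower_crossed"
  else "undecided"
}

#' Run one baseline (no-action) accumulator trial
#'
#' Iterates [accumulate_step()] until a bound is crossed. The upper bound
#' (the direction of positive drift) is the correct response. This is a
#' deliberately plain scalar loop over the exported single-step operations;
#' the batch engine in [run_batch()] uses a compiled path, and the two must
#' agree draw-for-draw under the same seed.
#'
#' @param params An [evidence_params()].
#' @param b Positive decision bound.
#' @param max_steps Hard step cap guarding non-terminating configurations.
#' @return A list with `decision` (`"correct"` or `"error"`) and `rt`, the
#'   first-crossing time in seconds.
#' @examples
#' run_baseline_trial(evidence_params(noise_sigma = 0), b = 1)
#' # 3 deterministic steps of 1/3: rt = 0.15
#' @export
run_baseline_trial <- function(params, b, max_steps = 1e6) {
  stopifnot(inherits(params, "evidence_params"))
  b <- bound(b)
  state <- evidence_state()
  repeat {
    state <- accumulate_step(state, params)
    status <- bound_status(state$z, b)
    if (status == "upper_crossed")
      return(list(decision = "correct", rt = state$t))
    if (status == "lower_crossed")
      return(list(decision = "error", rt = state$t))
    if (state$step_index >= max_steps)
      stop("step cap exhausted: non-terminating configuration")
  }
}
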
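#' Evidence accumulator parameters
#'
#' Parameters of the discrete-time drift-diffusion accumulator: per-step
#' increments are drawn from Normal(`drift_mu`, `noise_sigma`^2) every `dt`
#' seconds. The defaults (`drift_mu = 1/3`, `noise_sigma = 1`, `dt = 0.05`)
#' are the standard task configuration used throughout the package.
#'
#' @param drift_mu Mean evidence increment per step (dimensionless). Positive
#'   drift favours target 1.
#' @param noise_sigma Standard deviation of the per-step increment; `0` is
#'   legal and yields deterministic linear accumulation.
#' @param dt Step size in seconds.
#' @return An object of class `evidence_params`.
#' @examples
#' evidence_params()
#' evidence_params(noise_sigma = 4) # a harder (noisier) stimulus
#' @export
evidence_params <- function(drift_mu = 1 / 3, noise_sigma = 1, dt = 0.05) {
  stopifnot(is.numeric(drift_mu), length(drift_mu) == 1L, is.finite(drift_mu))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0)
    stop("`noise_sigma` must be a single non-negative number")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number")
  structure(list(drift_mu = drift_mu, noise_sigma = noise_sigma, dt = dt),
            class = "evidence_params")
}

#' Decision bound
#'
#' Symmetric evidence thresholds at +/- `b`. Crossing is inclusive: `z >= b`
#' counts as reaching the upper bound, so zero-noise configurations terminate
#' at exact multiples of `dt`.
#'
#' @param b Evidence threshold, a single positive number.
#' @return The validated numeric bound.
#' @export
bound <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("decision bound `b` must be a single positive finite number")
  b
}

#' Task geometry of the two-target arena
#'
#' The arena in which the action unfolds: a start point, two choice targets,
#' a constant movement speed, and the time step shared with the accumulator.
#' The default geometry places the start at the origin with targets at
#' (-1, 1.5) and (+1, 1.5) and speed 2 arena units/s, so the straight-line
#' travel time to either target is sqrt(3.25)/2 ~= 0.9014 s.
#'
#' @param start,target1,target2 Numeric length-2 points `(x, y)`.
#' @param speed_v Movement speed in arena units per second.
#' @param dt Time step in seconds (must match the accumulator's).
#' @return An object of class `task_geometry` with a precomputed `t_target`,
#'   the straight-line time from start to target 1.
#' @examples
#' geom <- task_geometry()
#' geom$t_target # ~0.9014 s
#' @export
task_geometry <- function(start = c(0, 0), target1 = c(-1, 1.5),
                          target2 = c(1, 1.5), speed_v = 2, dt = 0.05) {
  pt <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)))
      stop(sprintf("`%s` must be a finite numeric (x, y) pair", nm))
    as.numeric(p)
  }
  start <- pt(start, "start")
  target1 <- pt(target1, "target1")
  target2 <- pt(target2, "target2")
  if (!is.numeric(speed_v) || length(speed_v) != 1L || speed_v <= 0)
    stop("`speed_v` must be a single positive number")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number")
  if (all(target1 == target2)) stop("targets must be distinct points")
  structure(list(
    start = start, target1 = target1, target2 = target2,
    speed_v = speed_v, dt = dt,
    t_target = sqrt(sum((target1 - start)^2)) / speed_v
  ), class = "task_geometry")
}

#' Commitment gain
#'
#' Gain of the position-dependent commitment term added to the effective
#' evidence in the fully embodied model (`m4`). The convention used across
#' the package is `g = 4 b` unless an explicit gain is supplied.
#'
#' @param gain_g Non-negative gain in evidence units.
#' @return An object of class `commitment_spec`.
#' @export
commitment_spec <- function(gain_g) {
  if (!is.numeric(gain_g) || length(gain_g) != 1L || gain_g < 0)
    stop("`gain_g` must be a single non-negative number")
  structure(list(gain_g = gain_g), class = "commitment_spec")
}

#' Full model specification
#'
#' Bundles the model identity, decision bound, evidence parameters, arena
#' geometry and (for `m4`) commitment gain into a single validated object
#' consumed by [run_trial()] and [run_batch()].
#'
#' The five architectures are:
#' \describe{
#'   \item{`baseline`}{pure accumulator, decision at bound crossing, no
#'     action (instantaneous response).}
#'   \item{`m1`}{serial: straight-line movement to the chosen target starts
#'     only after the bound is crossed.}
#'   \item{`m2`}{changes of mind: movement starts at the first crossing and
#'     is redirected whenever the opposing bound is crossed; the choice is
#'     the target actually reached.}
#'   \item{`m3`}{action preparation: movement from time zero toward a focus
#'     interpolated between the targets according to the current evidence.}
#'   \item{`m4`}{preparation plus commitment: as `m3`, with a
#'     position-dependent term added to the effective evidence so that an
#'     ongoing approach to a target is harder to revise.}
#' }
#'
#' @param model One of `"baseline"`, `"m1"`, `"m2"`, `"m3"`, `"m4"`.
#' @param bound_b Decision bound (see [bound()]).
#' @param evidence An [evidence_params()] object.
#' @param geometry A [task_geometry()] object; its `dt` must equal the
#'   accumulator's, since a single clock drives both systems.
#' @param gain_g Commitment gain for `m4`; `NULL` applies the default
#'   `g = 4 * bound_b`. Ignored by the other models.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec("m3", bound_b = 2)
#' spec
#' @export
model_spec <- function(model = c("baseline", "m1", "m2", "m3", "m4"),
                       bound_b = 1, evidence = evidence_params(),
                       geometry = task_geometry(), gain_g = NULL) {
  model <- match.arg(model)
  bound_b <- bound(bound_b)
  stopifnot(inherits(evidence, "evidence_params"),
            inherits(geometry, "task_geometry"))
  if (!isTRUE(all.equal(evidence$dt, geometry$dt)))
    stop("evidence dt and geometry dt must be equal (one clock drives both)")
  if (model == "m4") {
    if (is.null(gain_g)) gain_g <- 4 * bound_b
    gain_g <- commitment_spec(gain_g)$gain_g
  } else {
    gain_g <- 0
  }
  structure(list(model = model, bound_b = bound_b, evidence = evidence,
                 geometry = geometry, gain_g = gain_g),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: b = %g", x$model, x$bound_b))
  if (x$model == "m4") cat(sprintf(", g = %g", x$gain_g))
  cat(sprintf("\n  evidence: mu = %g, sigma = %g, dt = %g s\n",
              x$evidence$drift_mu, x$evidence$noise_sigma, x$evidence$dt))
  cat(sprintf("  arena: start (%g, %g), targets (%g, %g) / (%g, %g), v = %g\n",
              x$geometry$start[1], x$geometry$start[2],
              x$geometry$target1[1], x$geometry$target1[2],
              x$geometry$target2[1], x$geometry$target2[2],
              x$geometry$speed_v))
  invisible(x)
}

# internal: numeric model code used by the compiled engine
model_code <- function(model) {
  match(model, c("baseline", "m1", "m2", "m3", "m4")) - 1L
}
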
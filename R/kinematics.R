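#' Action focus
#'
#' The spatial point the agent currently steers toward. In the serial and
#' change-of-mind models the focus is undefined until the first bound
#' crossing (the agent cannot move); in the preparation models it is always
#' defined and lies on the segment joining the two targets.
#'
#' @param focus Numeric `(x, y)` point, or `c(NA, NA)` when undefined.
#' @param defined Logical flag.
#' @return An object of class `focus_point`.
#' @export
focus_point <- function(focus = c(NA_real_, NA_real_), defined = FALSE) {
  structure(list(focus = as.numeric(focus), defined = isTRUE(defined)),
            class = "focus_point")
}

#' Move one step toward the action focus
#'
#' Constant-speed kinematics: the agent advances `v * dt` along the unit
#' vector toward the focus. If the focus is within one step the move is
#' shortened to land exactly on it; a zero-distance focus leaves the
#' position unchanged.
#'
#' @param pos Numeric `(x, y)` current position.
#' @param focus A defined [focus_point()] (or a bare `(x, y)` point).
#' @param geom A [task_geometry()].
#' @return The new `(x, y)` position.
#' @examples
#' g <- task_geometry()
#' move_step(c(0, 0), focus_point(g$target1, TRUE), g)
#' @export
move_step <- function(pos, focus, geom) {
  stopifnot(inherits(geom, "task_geometry"))
  if (inherits(focus, "focus_point")) {
    if (!focus$defined) stop("cannot move toward an undefined focus")
    focus <- focus$focus
  }
  pos <- as.numeric(pos)
  d <- sqrt(sum((focus - pos)^2))
  if (d == 0) return(pos)
  if (d <= geom$speed_v * geom$dt) return(focus)  # land exactly on the focus
  new_pos <- pos + (focus - pos) / d * (geom$speed_v * geom$dt)
  # each coordinate moves monotonically toward the focus; clamp 1-ulp overshoot
  pmin(pmax(new_pos, pmin(pos, focus)), pmax(pos, focus))
}

#' Serial action focus (decide, then act)
#'
#' Undefined until the decision is made; thereafter permanently the chosen
#' target: target 1 for a decision at the upper bound (`z >= b`), target 2
#' at the lower. Never re-evaluated, so post-decision trajectories are
#' straight segments.
#'
#' @param z_at_decision Evidence at decision time (ignored until `decided`).
#' @param decided Logical: has the bound been crossed?
#' @param b Positive decision bound.
#' @param geom A [task_geometry()].
#' @return A [focus_point()].
#' @export
focus_serial <- function(z_at_decision, decided, b, geom) {
  b <- bound(b)
  stopifnot(inherits(geom, "task_geometry"))
  if (!decided) return(focus_point())
  if (abs(z_at_decision) < b)
    stop("decided with |z| < b violates the serial-model contract")
  if (z_at_decision >= b) focus_point(geom$target1, TRUE)
  else focus_point(geom$target2, TRUE)
}

#' Switching action focus (changes of mind)
#'
#' Undefined until the first bound crossing; thereafter the currently
#' instructed target: target 1 whenever `z >= b`, target 2 whenever
#' `z <= -b`, and held at its last value while the evidence sits between the
#' bounds. Movement toward the last-instructed target therefore continues
#' until the opposing bound is crossed, which is the change-of-mind
#' mechanism.
#'
#' @param z Current evidence.
#' @param current_focus The [focus_point()] from the previous step.
#' @param b Positive decision bound.
#' @param geom A [task_geometry()].
#' @return A [focus_point()].
#' @export
focus_switching <- function(z, current_focus, b, geom) {
  b <- bound(b)
  stopifnot(inherits(geom, "task_geometry"),
            inherits(current_focus, "focus_point"))
  if (z >= b) focus_point(geom$target1, TRUE)
  else if (z <= -b) focus_point(geom$target2, TRUE)
  else current_focus
}

#' Interpolated action focus (action preparation)
#'
#' Always defined, so movement starts at time zero. For evidence between the
#' bounds the focus lies on the segment joining the targets,
#' `((b + z) * target1 + (b - z) * target2) / (2 b)`, moving continuously
#' from the midpoint toward the currently favoured target; it clamps to
#' target 1 for `z >= b` and target 2 for `z <= -b`.
#'
#' @param z_eff Effective evidence (the raw accumulator, or the
#'   commitment-augmented value in the embodied model).
#' @param b Positive decision bound.
#' @param geom A [task_geometry()].
#' @return A defined [focus_point()].
#' @examples
#' focus_interpolated(0, 1, task_geometry())$focus # midpoint (0, 1.5)
#' @export
focus_interpolated <- function(z_eff, b, geom) {
  b <- bound(b)
  stopifnot(inherits(geom, "task_geometry"))
  if (z_eff >= b) return(focus_point(geom$target1, TRUE))
  if (z_eff <= -b) return(focus_point(geom$target2, TRUE))
  w1 <- (b + z_eff) / (2 * b)
  # parameterised from target2 so the focus sits exactly on the segment
  focus_point(geom$target2 + w1 * (geom$target1 - geom$target2), TRUE)
}

#' Position-dependent commitment term
#'
#' The feedback from action to decision in the embodied model: with `d1`,
#' `d2` the Euclidean distances from the current position to the two
#' targets, returns `g * (d2 - d1) / (d1 + d2)`. Proximity to a target adds
#' effective evidence for that target; the term is zero on the perpendicular
#' bisector and bounded in `[-g, +g]`.
#'
#' @param pos Numeric `(x, y)` position.
#' @param geom A [task_geometry()].
#' @param gain_g Non-negative commitment gain.
#' @return The commitment contribution to the effective evidence.
#' @examples
#' commitment_term(c(0, 0), task_geometry(), gain_g = 4) # 0 (equidistant)
#' @export
commitment_term <- function(pos, geom, gain_g) {
  stopifnot(inherits(geom, "task_geometry"))
  gain_g <- commitment_spec(gain_g)$gain_g
  pos <- as.numeric(pos)
  d1 <- sqrt(sum((pos - geom$target1)^2))
  d2 <- sqrt(sum((pos - geom$target2)^2))
  if (d1 + d2 == 0) stop("position coincides with both targets")
  gain_g * (d2 - d1) / (d1 + d2)
}

#' Effective evidence seen by the focus computation
#'
#' Identity for the baseline and models 1-3. In the embodied model (`m4`)
#' the commitment term is added to the raw accumulator. The combination is
#' recomputed from `z` and the position each step (non-recursive): the raw
#' accumulator is never modified by position, so removing the agent from the
#' arena recovers `z` exactly.
#'
#' @param z Raw accumulated evidence.
#' @param pos Numeric `(x, y)` position.
#' @param spec A [model_spec()].
#' @return The effective evidence.
#' @export
effective_evidence <- function(z, pos, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model != "m4") return(z)
  z + commitment_term(pos, spec$geometry, spec$gain_g)
}
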
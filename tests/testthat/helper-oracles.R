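# Independent oracles and fixture builders used across the suite.

t_target_default <- sqrt(1^2 + 1.5^2) / 2

# Vectorized brute-force baseline random walk: a code path independent of the
# package's engines (no per-trial substreams, no step loop per trial).
brute_force_baseline <- function(n, mu = 1 / 3, sigma = 1, b = 1, dt = 0.05,
                                 seed = 1) {
  set.seed(seed)
  z <- numeric(n)
  done <- logical(n)
  err <- logical(n)
  steps <- integer(n)
  k <- 0L
  while (any(!done)) {
    k <- k + 1L
    idx <- which(!done)
    z[idx] <- z[idx] + stats::rnorm(length(idx), mu, sigma)
    crossed <- idx[abs(z[idx]) >= b]
    err[crossed] <- z[crossed] <= -b
    steps[crossed] <- k
    done[crossed] <- TRUE
    if (k > 1e6) stop("brute-force step cap")
  }
  list(err = err, rt = steps * dt,
       mean_error = mean(err), mean_rt = mean(steps) * dt)
}

# Pure-R reference trial built from the exported single-step operations,
# mirroring the documented interval semantics: focus and movement for an
# interval come from the evidence state at its start; the increment lands at
# its end. Scripted increments only (no RNG), so agreement with the compiled
# engine can be asserted exactly.
r_reference_trial <- function(spec, increments, max_steps = 1e5) {
  geom <- spec$geometry
  b <- spec$bound_b
  z <- 0
  pos <- geom$start
  t <- 0
  fp <- focus_point()
  decided <- FALSE
  rows <- list(c(t = 0, x = pos[1], y = pos[2], z = 0,
                 z_eff = effective_evidence(0, pos, spec)))
  for (step in seq_len(max_steps)) {
    z_eff <- effective_evidence(z, pos, spec)
    if (spec$model == "m1" && !decided && abs(z) >= b) decided <- TRUE
    fp <- switch(spec$model,
      baseline = focus_point(),
      m1 = if (decided) focus_serial(z, TRUE, b, geom) else focus_point(),
      m2 = focus_switching(z, fp, b, geom),
      m3 = focus_interpolated(z_eff, b, geom),
      m4 = focus_interpolated(z_eff, b, geom))
    if (fp$defined) {
      d <- sqrt(sum((fp$focus - pos)^2))
      at_target <- isTRUE(all.equal(fp$focus, geom$target1)) ||
        isTRUE(all.equal(fp$focus, geom$target2))
      if (at_target && d <= geom$speed_v * geom$dt) {
        rt <- t + d / geom$speed_v
        pos <- fp$focus
        choice <- if (isTRUE(all.equal(fp$focus, geom$target1)))
          "target1" else "target2"
        rows[[length(rows) + 1]] <- c(rt, pos[1], pos[2], z, z_eff)
        traj <- do.call(rbind, rows)
        colnames(traj) <- c("t", "x", "y", "z", "z_eff")
        return(list(choice = choice, rt = rt, trajectory = traj))
      }
      pos <- move_step(pos, fp, geom)
    }
    if (step > length(increments)) stop("reference script exhausted")
    if (!(spec$model == "m1" && decided)) z <- z + increments[step]
    t <- t + spec$evidence$dt
    rows[[length(rows) + 1]] <-
      c(t, pos[1], pos[2], z, effective_evidence(z, pos, spec))
    if (spec$model == "baseline" && abs(z) >= b) {
      traj <- do.call(rbind, rows)
      colnames(traj) <- c("t", "x", "y", "z", "z_eff")
      return(list(choice = if (z >= b) "target1" else "target2", rt = t,
                  trajectory = traj))
    }
  }
  stop("reference step cap")
}

# Synthetic trial_result from a bare path matrix, for metric unit tests.
make_traj <- function(xy, choice = "target1") {
  m <- cbind(t = seq_len(nrow(xy)) - 1, x = xy[, 1], y = xy[, 2],
             z = 0, z_eff = 0)
  colnames(m) <- c("t", "x", "y", "z", "z_eff")
  structure(list(choice = choice, correct = choice == "target1",
                 rt = m[nrow(m), "t"], t_dec = NA_real_,
                 n_focus_switches = 0L, trajectory = m, model = "synthetic",
                 seed = NA_integer_),
            class = "trial_result")
}

# Mirror a trial about the arena midline (x -> -x), flipping its choice.
mirror_trial <- function(tr) {
  m <- tr$trajectory
  m[, "x"] <- -m[, "x"]
  m[, "z"] <- -m[, "z"]
  m[, "z_eff"] <- -m[, "z_eff"]
  tr$trajectory <- m
  tr$choice <- if (tr$choice == "target1") "target2" else "target1"
  tr$correct <- tr$choice == "target1"
  tr
}
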
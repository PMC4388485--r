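test_that("serial model with zero noise: decide at 0.15 s, arrive after straight travel", {
  spec <- model_spec("m1", bound_b = 1,
                     evidence = evidence_params(noise_sigma = 0))
  tr <- run_trial(spec)
  expect_equal(tr$t_dec, 0.15)
  expect_equal(tr$rt, 0.15 + t_target_default, tolerance = 1e-12)
  expect_identical(tr$choice, "target1")
  expect_identical(tr$n_focus_switches, 0L)
  # post-decision samples are collinear with start -> target 1
  m <- tr$trajectory
  moving <- m[m[, "y"] > 0, , drop = FALSE]
  expect_true(all(abs(moving[, "x"] * 1.5 - moving[, "y"] * (-1)) < 1e-9))
  # trajectory ends exactly on the target; rt is the last sample's time
  expect_equal(unname(m[nrow(m), c("x", "y")]), c(-1, 1.5), tolerance = 1e-9)
  expect_equal(unname(m[nrow(m), "t"]), tr$rt)
})

test_that("preparation model with zero noise curves monotonically to target 1", {
  spec <- model_spec("m3", bound_b = 1,
                     evidence = evidence_params(noise_sigma = 0))
  tr <- run_trial(spec)
  expect_identical(tr$choice, "target1")
  m <- tr$trajectory
  expect_true(all(diff(m[, "y"]) >= -1e-12))
  expect_true(all(m[, "x"] <= 1e-12))       # never pulled toward target 2
  expect_true(all(diff(m[, "x"]) <= 1e-12)) # monotone drift toward target 1
  # movement starts at time zero
  expect_gt(m[2, "y"], 0)
})

test_that("a scripted double crossing produces exactly one change of mind", {
  spec <- model_spec("m2", bound_b = 1)
  tr <- run_trial(spec, increments = c(1, 0, -2, rep(0, 200)))
  expect_identical(tr$n_focus_switches, 1L)
  expect_identical(tr$choice, "target2")  # final choice = target reached
  # single kink: x first decreases (toward T1), then increases (toward T2)
  dx <- diff(tr$trajectory[, "x"])
  dx <- dx[dx != 0]
  expect_identical(rle(sign(dx))$lengths |> length(), 2L)
})

test_that("compiled engine matches the R reference composition exactly", {
  scripts <- list(
    c(1, 0, -2, rep(0, 200)),                 # change of mind
    c(rep(1 / 3, 300)),                       # deterministic ramp
    c(0.4, -0.9, 1.6, -0.2, rep(0.25, 300)),  # wandering then commit
    c(rep(-0.5, 300)))                        # straight to target 2
  for (model in c("baseline", "m1", "m2", "m3", "m4")) {
    spec <- model_spec(model, bound_b = 1)
    for (s in scripts) {
      got <- run_trial(spec, increments = s)
      ref <- r_reference_trial(spec, s)
      expect_identical(got$choice, ref$choice)
      expect_equal(got$rt, ref$rt, tolerance = 1e-12)
      expect_equal(got$trajectory, ref$trajectory, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("batches are reproducible and splitting-invariant", {
  spec <- model_spec("m3", bound_b = 2)
  b1 <- run_batch(spec, 60, master_seed = 99)
  b2 <- run_batch(spec, 60, master_seed = 99)
  expect_identical(b1$rt, b2$rt)
  expect_identical(b1$correct, b2$correct)
  b3 <- run_batch(spec, 30, master_seed = 99)
  expect_identical(b3$rt, b1$rt[1:30])
})

test_that("the serial model is the baseline shifted by the travel time", {
  n <- 2000
  base <- run_batch(model_spec("baseline", bound_b = 1.5), n, master_seed = 4)
  m1 <- run_batch(model_spec("m1", bound_b = 1.5), n, master_seed = 4)
  expect_identical(base$correct, m1$correct)
  expect_equal(m1$rt, base$rt + t_target_default, tolerance = 1e-9)
  # whole RT distribution shifts: KS distance of the aligned samples is 0
  # (RTs are atoms at multiples of dt; round away float fuzz so ties align)
  ks <- suppressWarnings(
    stats::ks.test(round(m1$rt - t_target_default, 9), round(base$rt, 9)))
  expect_equal(unname(ks$statistic), 0)
})

test_that("y never decreases along any model's trajectory", {
  for (model in c("m1", "m2", "m3", "m4")) {
    batch <- run_batch(model_spec(model, bound_b = 1.2), 25,
                       master_seed = 13, record = TRUE)
    for (tr in batch$trials)
      expect_true(all(diff(tr$trajectory[, "y"]) >= -1e-12))
  }
})

test_that("changes of mind do not hurt accuracy at equal bound and seeds", {
  n <- 4000
  e1 <- run_batch(model_spec("m1", bound_b = 1), n, master_seed = 31)
  e2 <- run_batch(model_spec("m2", bound_b = 1), n, master_seed = 31)
  p <- e1$summary$mean_error
  se <- sqrt(p * (1 - p) / n) * sqrt(2)
  expect_lte(e2$summary$mean_error, p + 3 * se)
})

test_that("raising the commitment gain never adds midline crossings (scripted)", {
  script <- c(0.6, -1.1, 0.9, -0.8, 1.2, rep(0.3, 300))
  crossings <- vapply(c(0, 1, 2, 4), function(g) {
    spec <- model_spec("m4", bound_b = 1, gain_g = g)
    run_trial(spec, increments = script)$n_focus_switches
  }, integer(1))
  expect_true(all(diff(crossings) <= 0L))
})

test_that("select_trajectories returns the first k finishers in trial order", {
  batch <- run_batch(model_spec("m2", bound_b = 1), 60, master_seed = 2,
                     record = TRUE)
  k <- 10
  sel <- select_trajectories(batch, "target1", k)
  expect_length(sel, k)
  idx <- which(batch$choice == "target1")[seq_len(k)]
  expect_identical(vapply(sel, function(tr) tr$rt, numeric(1)),
                   batch$rt[idx])
  expect_length(select_trajectories(batch, "target1", 0), 0)
  expect_error(select_trajectories(batch, "target2", 1e5), "only")
  expect_error(select_trajectories(run_batch(model_spec("m2"), 5,
                                             master_seed = 1), "target1", 1),
               "record")
})

test_that("the step cap is enforced for non-terminating configurations", {
  spec <- model_spec("baseline", bound_b = 5,
                     evidence = evidence_params(drift_mu = 0,
                                                noise_sigma = 0))
  expect_error(run_trial(spec, max_steps = 1000), "step cap")
})
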
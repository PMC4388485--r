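geom <- task_geometry()

test_that("move_step follows the constant-speed update and snaps to the focus", {
  # hand evaluation with |focus - pos| = sqrt(3.25)
  p <- move_step(c(0, 0), focus_point(c(-1, 1.5), TRUE), geom)
  expect_equal(p, c(-1, 1.5) / sqrt(3.25) * 0.1, tolerance = 1e-12)
  expect_equal(p, c(-0.05547002, 0.08320503), tolerance = 1e-7)

  expect_equal(move_step(c(-1, 1.5), focus_point(c(-1, 1.5), TRUE), geom),
               c(-1, 1.5))
  expect_equal(move_step(c(-0.95, 1.5), focus_point(c(-1, 1.5), TRUE), geom),
               c(-1, 1.5))
  expect_error(move_step(c(0, 0), focus_point(), geom), "undefined")
})

test_that("move_step preserves speed except on the shortened terminal step", {
  set.seed(8)
  for (i in 1:50) {
    pos <- c(stats::runif(1, -1, 1), stats::runif(1, 0, 1.4))
    fp <- focus_point(c(stats::runif(1, -1, 1), 1.5), TRUE)
    d <- sqrt(sum((fp$focus - pos)^2))
    p2 <- move_step(pos, fp, geom)
    step_len <- sqrt(sum((p2 - pos)^2))
    if (d >= geom$speed_v * geom$dt) {
      expect_equal(step_len, geom$speed_v * geom$dt, tolerance = 1e-12)
    } else {
      expect_equal(p2, fp$focus)
    }
  }
})

test_that("serial focus is undefined pre-decision, then frozen at the chosen target", {
  expect_false(focus_serial(0, FALSE, 1, geom)$defined)
  expect_equal(focus_serial(1, TRUE, 1, geom)$focus, geom$target1)
  expect_equal(focus_serial(-1, TRUE, 1, geom)$focus, geom$target2)
  expect_error(focus_serial(0.5, TRUE, 1, geom), "contract")
})

test_that("switching focus holds its last target between the bounds", {
  fp <- focus_point()
  zs <- c(0.5, 1, 0.2, -0.9, -1, 0.3)
  want_defined <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  want_x <- c(NA, -1, -1, -1, 1, 1)
  for (i in seq_along(zs)) {
    fp <- focus_switching(zs[i], fp, 1, geom)
    expect_identical(fp$defined, want_defined[i])
    if (fp$defined) expect_equal(fp$focus[1], want_x[i])
  }
  # never crossing leaves the focus undefined forever
  fp <- focus_point()
  for (z in c(0.3, -0.6, 0.9)) fp <- focus_switching(z, fp, 1, geom)
  expect_false(fp$defined)
})

test_that("interpolated focus: midpoint at 0, clamps at the bounds, linear between", {
  expect_equal(focus_interpolated(0, 1, geom)$focus, c(0, 1.5))
  expect_equal(focus_interpolated(1, 1, geom)$focus, geom$target1)
  expect_equal(focus_interpolated(2.5, 1, geom)$focus, geom$target1)
  expect_equal(focus_interpolated(-1, 1, geom)$focus, geom$target2)
  expect_equal(focus_interpolated(-0.5, 1, geom)$focus, c(0.5, 1.5))
  expect_error(focus_interpolated(0, 0, geom), "positive")
})

test_that("interpolated focus is continuous, monotone and midline-antisymmetric", {
  b <- 2
  zs <- seq(-2.5, 2.5, by = 0.05)
  xs <- vapply(zs, function(z) focus_interpolated(z, b, geom)$focus[1],
               numeric(1))
  expect_true(all(diff(xs) <= 1e-12))          # monotone toward target 1
  expect_lt(max(abs(diff(xs))), 0.05 / (2 * b) * 2 + 1e-9)  # no jumps
  for (z in seq(0, 2.5, by = 0.25)) {
    expect_equal(focus_interpolated(-z, b, geom)$focus[1],
                 -focus_interpolated(z, b, geom)$focus[1])
  }
})

test_that("commitment term: zero at start, +/-g at the targets, hand value", {
  expect_equal(commitment_term(c(0, 0), geom, 4), 0)
  expect_equal(commitment_term(geom$target1, geom, 4), 4)
  expect_equal(commitment_term(geom$target2, geom, 4), -4)
  expect_equal(commitment_term(c(-0.5, 1.5), geom, 4), 2)
})

test_that("commitment term is bounded by g and antisymmetric under reflection", {
  set.seed(21)
  g <- 3
  for (i in 1:100) {
    pos <- c(stats::runif(1, -1, 1), stats::runif(1, 0, 1.5))
    v <- commitment_term(pos, geom, g)
    expect_lte(abs(v), g)
    expect_equal(commitment_term(c(-pos[1], pos[2]), geom, g), -v,
                 tolerance = 1e-12)
  }
})

test_that("effective evidence is the identity except under commitment", {
  m3 <- model_spec("m3", bound_b = 1)
  m4 <- model_spec("m4", bound_b = 1, gain_g = 4)
  expect_identical(effective_evidence(0.37, c(-0.8, 1.2), m3), 0.37)
  expect_equal(effective_evidence(0.3, c(0, 0), m4), 0.3)
  expect_equal(effective_evidence(0.3, c(-0.5, 1.5), m4), 2.3)
})

test_that("commitment pulls the focus toward the approached target", {
  m3 <- model_spec("m3", bound_b = 2)
  m4 <- model_spec("m4", bound_b = 2, gain_g = 8)
  for (z in c(-1, 0, 0.5, 1.5)) {
    for (pos in list(c(-0.4, 0.8), c(-0.1, 1.2))) {  # strictly closer to T1
      f3 <- focus_interpolated(effective_evidence(z, pos, m3), 2, geom)
      f4 <- focus_interpolated(effective_evidence(z, pos, m4), 2, geom)
      d3 <- sum((f3$focus - geom$target1)^2)
      d4 <- sum((f4$focus - geom$target1)^2)
      expect_lt(d4, d3 + 1e-12)
    }
  }
})
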
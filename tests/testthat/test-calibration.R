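test_that("secant update reproduces its closed form", {
  # exact on an affine residual in one update
  f <- function(x) 3 * x - 12
  x2 <- secant_update(0, 1, f(0), f(1))
  expect_equal(x2, 4)
  expect_equal(f(x2), 0)
  # midpoint of an antisymmetric pair
  expect_equal(secant_update(0, 1, -10, 10), 0.5)
  # superlinear shrinkage on a quadratic residual
  g <- function(x) x^2 - 2
  xs <- c(1, 2)
  for (i in 1:4) xs <- c(xs, secant_update(xs[length(xs) - 1],
                                           xs[length(xs)],
                                           g(xs[length(xs) - 1]),
                                           g(xs[length(xs)])))
  err <- abs(g(xs))
  expect_true(all(diff(err[3:6]) < 0))
  expect_lt(err[6], 1e-4)
  # degenerate (flat) residual falls back to a perturbation
  xd <- secant_update(1, 2, 5, 5)
  expect_true(isTRUE(attr(xd, "degenerate")))
  expect_equal(as.numeric(xd), 2.02)
})

test_that("single-screw response is linear and yields an exact initial guess", {
  a <- single_assembly()
  for (m in c("ISO", "ORT", "FOR")) {
    resp <- single_screw_response(a, m, F_P = 200)
    x0 <- 200 / resp$slope
    plan <- build_plan(m, a)
    res <- run_pretension_step(a, plan, 200, controls = x0)
    ind <- free_zone_force(a, res$pretension, 1)
    expect_equal(ind, 200, tolerance = 0.05)
    # controls have the physical sign: contraction strains are negative,
    # force pairs positive
    if (m == "FOR") expect_gt(x0, 0) else expect_lt(x0, 0)
  }
  # zero target needs no control
  expect_equal(single_screw_initial_guess(a, "ISO", 0), 0)
})

test_that("an isolated screw calibrates within a few iterations", {
  a <- single_assembly()
  cal <- calibrate_assembly(a, "ORT", targets = 250)
  expect_true(cal$converged)
  expect_lte(cal$iterations, 5)
  expect_lt(max(cal$errors), 5)
  # the trace records one row per full-model solve
  expect_equal(nrow(cal$trace), cal$iterations)
  expect_true(all(cal$trace$max_err >= cal$trace$mean_err))
})

test_that("coupled three-screw calibration converges below the 5% criterion
           for every iterative method", {
  cmp <- three_comparison()
  for (m in c("ISO", "ORT", "FOR")) {
    cal <- cmp$calibrations[[m]]
    expect_true(cal$converged)
    expect_lt(max(cal$errors), 5)
    expect_lte(mean(cal$errors), max(cal$errors))
    expect_lte(cal$iterations, 50)
  }
})

test_that("calibration is deterministic", {
  a <- single_assembly()
  c1 <- calibrate_assembly(a, "FOR", targets = 250)
  c2 <- calibrate_assembly(a, "FOR", targets = 250)
  expect_identical(c1$trace, c2$trace)
  expect_identical(c1$controls, c2$controls)
})
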
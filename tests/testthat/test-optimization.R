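test_that("objective value matches its definition and an independent oracle", {
  spec <- objective_spec(list(objective_term("t", "uniform", 20, 1)))
  expect_equal(objective_value(list(t = rep(20, 7)), spec), 0)
  spec_min <- objective_spec(list(objective_term("t", "min", 10, 1)))
  expect_equal(objective_value(list(t = 9), spec_min), 1)  # (1 Gy)^2, n = 1
  set.seed(3)
  for (i in 1:20) {
    spec_r <- objective_spec(list(
      objective_term("a", "min", runif(1, 5, 15), runif(1, 0.5, 5)),
      objective_term("a", "max", runif(1, 16, 30), runif(1, 0.5, 5)),
      objective_term("b", "uniform", runif(1, 5, 25), runif(1, 0.5, 5))))
    doses <- list(a = runif(13, 0, 30), b = runif(9, 0, 30))
    expect_equal(objective_value(doses, spec_r),
                 objective_oracle(doses, spec_r), tolerance = 1e-10)
  }
  expect_error(objective_value(list(a = 1), spec), "missing structure")
})

test_that("objective specifications are validated", {
  expect_error(objective_spec(list(objective_term("t", "max", 10, 1))),
               "target")
  expect_error(objective_spec(list(
    objective_term("t", "min", 20, 1),
    objective_term("t", "max", 10, 1))), "infeasible")
  expect_error(objective_term("t", "min", -1), ">= 0")
})

test_that("single-field optimization recovers the closed-form least squares solution", {
  A <- matrix(c(1, 0.1, 0.3, 0.8), 2, 2)
  w_star <- solve(A, rep(33, 2))   # nonnegative exact solution
  spec <- objective_spec(list(objective_term("target", "uniform", 33, 1)))
  pl <- optimize_sfo(list(list(target = A)), spec,
                     beams = list(beam(180)),
                     spots = list(data.frame(a = c(0, 5), b = 0,
                                             range = c(50, 55), layer = 1:2)),
                     control = opt_control(maxit = 3000, tol = 1e-13))
  expect_equal(pl$weights[[1]], w_star, tolerance = 1e-4)
  # descent contract: history non-increasing, final below the start
  h <- pl$history[[1]]
  expect_true(all(diff(h) <= 1e-12))
  expect_lt(h[length(h)], h[1])
  expect_true(all(pl$weights[[1]] >= 0))
})

test_that("weights stay nonnegative under conflicting objectives", {
  set.seed(8)
  A <- matrix(runif(60, 0, 1), 10, 6)
  # conflicting min on one structure, max on another sharing the spots
  spec <- objective_spec(list(
    objective_term("target", "min", 30, 10),
    objective_term("oar", "max", 5, 10)))
  pl <- optimize_sfo(list(list(target = A, oar = A[1:4, ])), spec,
                     beams = list(beam(180)),
                     spots = list(data.frame(a = 1:6, b = 0, range = 50,
                                             layer = 1)),
                     control = opt_control(maxit = 300))
  expect_true(all(pl$weights[[1]] >= 0))
  expect_true(all(diff(pl$history[[1]]) <= 1e-12))
})

test_that("robust optimization with only the nominal scenario equals SFO", {
  set.seed(21)
  A <- matrix(runif(40, 0, 1), 8, 5)
  spec <- objective_spec(list(objective_term("target", "uniform", 33, 1)))
  ctl <- opt_control(maxit = 800, inner_maxit = 800, tol = 1e-10)
  beams <- list(beam(180))
  spots <- list(data.frame(a = 1:5, b = 0, range = 50, layer = 1))
  p_sfo <- optimize_sfo(list(list(target = A)), spec, beams, spots,
                        control = ctl)
  p_ro <- optimize_robust(list(list(list(target = A))), spec, beams, spots,
                          scenarios = list(scenario()), control = ctl)
  expect_equal(p_ro$weights[[1]], p_sfo$weights[[1]], tolerance = 1e-5)
})

test_that("minimax balances conflicting scenario demands", {
  # same influence, min-dose 20 on one structure and max-dose 10 on another:
  # optimum at the midpoint 15 of the conflicting single-spot demands
  spec <- objective_spec(list(
    objective_term("lo", "min", 20, 1),
    objective_term("hi", "max", 10, 1)))
  mats <- list(lo = matrix(1, 1, 1), hi = matrix(1, 1, 1))
  p <- optimize_robust(list(list(mats, mats)), spec,
                       beams = list(beam(180)),
                       spots = list(data.frame(a = 0, b = 0, range = 50,
                                               layer = 1)),
                       scenarios = list(scenario(), scenario(scale = 1.035,
                                                            label = "s2")),
                       control = opt_control(maxit = 2000,
                                             inner_maxit = 2000,
                                             tol = 1e-12))
  expect_equal(p$weights[[1]], 15, tolerance = 1e-3)
  # two scenarios demanding uniform single-spot doses 12 and 6:
  # minimax of (w-12)^2 vs (2w-12)^2 is at w = 8 (equalized objectives)
  spec_u <- objective_spec(list(objective_term("target", "uniform", 12, 1)))
  p2 <- optimize_robust(
    list(list(list(target = matrix(1, 1, 1)),
              list(target = matrix(2, 1, 1)))),
    spec_u, beams = list(beam(180)),
    spots = list(data.frame(a = 0, b = 0, range = 50, layer = 1)),
    scenarios = list(scenario(), scenario(scale = 1.035, label = "s2")),
    control = opt_control(maxit = 4000, inner_maxit = 4000, tol = 1e-13))
  expect_equal(p2$weights[[1]], 8, tolerance = 1e-2)
  expect_error(optimize_robust(list(list()), spec_u, list(beam(180)),
                               list(), scenarios = list()), "empty")
})

test_that("robust worst-case objective trace is monotone non-increasing", {
  set.seed(13)
  A1 <- matrix(runif(40, 0, 1), 8, 5)
  A2 <- A1 * matrix(runif(40, 0.7, 1.3), 8, 5)
  A3 <- A1 * matrix(runif(40, 0.7, 1.3), 8, 5)
  spec <- objective_spec(list(objective_term("target", "min", 30, 1),
                              objective_term("target", "max", 33, 1)))
  p <- optimize_robust(
    list(list(list(target = A1), list(target = A2), list(target = A3))),
    spec, beams = list(beam(180)),
    spots = list(data.frame(a = 1:5, b = 0, range = 50, layer = 1)),
    scenarios = list(scenario(),
                     scenario(c(0, 2, 0), 1, "p"),
                     scenario(c(0, -2, 0), 1, "a")),
    control = opt_control())
  expect_true(all(diff(p$worst_history[[1]]) <= 1e-12))
  expect_true(all(p$weights[[1]] >= 0))
})
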
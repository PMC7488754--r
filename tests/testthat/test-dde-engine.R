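test_that("constant histories evaluate exactly and respect their domain", {
  h <- make_history(2.5, 0.5, 5, horizon = 15)
  expect_equal(h(0), c(x = 2.5, y = 0.5, z = 5))
  expect_equal(h(-15), c(x = 2.5, y = 0.5, z = 5))
  expect_equal(h(-7.3), c(x = 2.5, y = 0.5, z = 5))
  expect_error(h(-16), "outside")
  expect_error(h(1), "outside")
  expect_error(make_history(-1, 0, 0, 1), "nonnegative")
  h0 <- make_history(0, 0, 0, 1)
  expect_equal(unname(h0(-0.5)), c(0, 0, 0))
})

test_that("pure decay follows the closed-form exponential", {
  p <- decay_params()
  d <- delay_params(1, 2, 3, 5)
  tr <- integrate_dde(p, d, c(1, 0, 0), short_settings(t_end = 5))
  expect_equal(tail(tr$x, 1), exp(-5), tolerance = 1e-9)
  # the whole curve, not just the endpoint
  expect_equal(tr$x, exp(-tr$t), tolerance = 1e-8)
})

test_that("delay-zero integration matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  set.seed(31)
  d0 <- delay_params(0, 0, 0, 0)
  for (i in 1:10) {
    p <- random_smooth_params()
    s0 <- c(x = runif(1, 0.1, 3), y = runif(1, 0, 1), z = runif(1, 0.1, 5))
    tr <- integrate_dde(p, d0, s0, short_settings(t_end = 100))
    ode_rhs <- function(t, s, parms) {
      list(unname(model_rhs(c(x = s[1], y = s[2], z = s[3]),
                            s[1], s[1], s[2], s[3], p)))
    }
    ref <- deSolve::ode(unname(s0), c(0, 100), ode_rhs, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-12)
    got <- unlist(tail(tr, 1)[, c("x", "y", "z")])
    want <- ref[2, 2:4]
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-8)), 1e-6)
  }
})

test_that("step halving shows fourth-order convergence", {
  # moderate rates so the whole step triplet sits inside the explicit
  # scheme's stability region (the basic set's k_b ~ 200 needs h <= 0.01)
  p <- suppressWarnings(model_params(k_b = 10, h_b = 4, k_x = 10, h_x = 2,
                                     k_rz = 0.25, k_dz = 0.75))
  run <- function(d, h, hist) {
    integrate_dde(p, d, hist, integration_settings(h = h, t_end = 50))
  }
  sup_ratio <- function(d, hist) {
    sol <- lapply(c(0.02, 0.01, 0.005), function(h) run(d, h, hist))
    common <- function(tr, step) tr$x[seq(1, nrow(tr), by = round(0.02 / step))]
    x1 <- common(sol[[1]], 0.02)
    x2 <- common(sol[[2]], 0.01)
    x3 <- common(sol[[3]], 0.005)
    max(abs(x1 - x3)) / max(abs(x2 - x3))
  }
  # smooth setting (no delays, so no history-induced derivative kinks):
  # clean fourth order, sup-norm differences shrink ~16x per halving
  expect_gt(sup_ratio(delay_params(0, 0, 0, 0), c(2.5, 0.5, 5)), 12)
  # delayed Cauchy problem: derivative discontinuities propagating from the
  # constant history shave the observed order; still far above order 2
  expect_gt(sup_ratio(delay_params(1, 2, 3, 5), standard_history()), 6)
})

test_that("trajectories stay in the orthant and below the FMRP capacity", {
  set.seed(41)
  for (i in 1:5) {
    p <- random_smooth_params()
    d <- delay_params(1, 2, 3, 5)
    s0 <- c(x = runif(1, 0, 3), y = runif(1, 0, 1), z = runif(1, 0, 5))
    tr <- integrate_dde(p, d, s0, short_settings(t_end = 100))
    expect_true(all(tr$x >= -1e-9 & tr$y >= -1e-9 & tr$z >= -1e-9))
    expect_true(all(tr$y <= p$y0 + 1e-9))
  }
})

test_that("dense evaluation reproduces nodes and interpolates the decay", {
  p <- decay_params()
  tr <- integrate_dde(p, delay_params(1, 2, 3, 5), c(1, 0, 0),
                      short_settings(t_end = 5))
  # exact at grid nodes, including the range end
  nodes <- tr$t[c(1, 124, nrow(tr))]
  expect_equal(dense_eval(tr, nodes)$x, tr$x[c(1, 124, nrow(tr))])
  # off-grid values against the closed form
  tm <- c(0.005, 1.2345, 4.9999)
  expect_equal(dense_eval(tr, tm)$x, exp(-tm), tolerance = 1e-8)
  expect_error(dense_eval(tr, 5.1), "outside")
})

test_that("twin integration reflects linearity in the decay system", {
  p <- decay_params()
  d <- delay_params(1, 2, 3, 5)
  pair <- integrate_twin(p, d, c(1, 0, 0), short_settings(t_end = 10),
                         epsilon = 1e-6)
  dx <- pair$base$x - pair$shifted$x
  # |x1 - x2| = epsilon * exp(-t): monotone contraction
  expect_lt(max(abs(abs(dx) - 1e-6 * exp(-pair$base$t))), 1e-12)
  div <- sensitivity_divergence(pair)
  expect_false(attr(div, "sensitive"))
  # epsilon = 0 gives bitwise-identical twins
  pair0 <- integrate_twin(p, d, c(1, 0, 0), short_settings(t_end = 5),
                          epsilon = 0)
  expect_identical(pair0$base$x, pair0$shifted$x)
})

test_that("z can be ignored when recycling is off", {
  p <- suppressWarnings(set_params(basic_params(), k_rz = 0))
  d <- delay_params(1, 2, 3, 5)
  tr1 <- integrate_dde(p, d, c(2.5, 0.5, 5), short_settings(t_end = 100))
  tr2 <- integrate_dde(p, d, c(2.5, 0.5, 0.1), short_settings(t_end = 100))
  expect_equal(tr1$x, tr2$x, tolerance = 1e-12)
  expect_equal(tr1$y, tr2$y, tolerance = 1e-12)
})

test_that("integration reports the time when leaving the orthant", {
  # force a violation with an (invalid) negative constitutive rate by
  # bypassing validation: k_a0 < 0 drives y below zero
  p <- suppressWarnings(model_params(k_x = 0, k_x0 = 0, k_rz = 0))
  p$k_a0 <- -5
  expect_error(
    integrate_dde(p, delay_params(1, 2, 3, 5), c(1, 0.5, 1),
                  short_settings(t_end = 50), validate = FALSE),
    "nonnegative orthant at t ="
  )
})

test_that("trajectory TSV round-trips with its provenance", {
  p <- with_recycling(basic_params(), 0.25)
  d <- delay_params(1, 2, 3, 5)
  tr <- integrate_dde(p, d, settings = short_settings(t_end = 10))
  path <- tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_equal(unclass(attr(back, "params")), unclass(p))
  expect_equal(unclass(attr(back, "delays")), unclass(d))
  expect_equal(attr(back, "step"), attr(tr, "step"))
})
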
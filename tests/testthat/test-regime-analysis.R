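# Manufactured trajectory helper: builds a tibble that quacks like a
# trajectory record so crossing detection can be checked against analytic
# crossing times.
fake_traj <- function(t, x, y = NULL, z = NULL) {
  tibble::tibble(t = t, x = x,
                 y = if (is.null(y)) rep(0, length(t)) else y,
                 z = if (is.null(z)) rep(0, length(t)) else z)
}

test_that("crossing detection finds analytic crossings with O(h^2) error", {
  for (h in c(0.02, 0.01)) {
    t <- seq(0, 50, h)
    tr <- fake_traj(t, x = 2 + sin(t), y = cos(t))
    cr <- poincare_crossings(tr, poincare_section("x", 2, "both"),
                             t_transient = 0)
    expected <- pi * (seq_len(nrow(cr)) - 1)  # includes the t = 0 crossing
    expect_equal(cr$t, expected, tolerance = 10 * h^2)
    err <- max(abs(cr$t - expected))
    # quadratic shrinkage of the refinement error
    if (h == 0.02) err_coarse <- err else {
      expect_lt(err, err_coarse / 2.5)
    }
  }
})

test_that("crossing direction filters and empty sections behave", {
  t <- seq(0, 40, 0.01)
  tr <- fake_traj(t, x = 2 + sin(t))
  up <- poincare_crossings(tr, poincare_section("x", 2, "increasing"), 0)
  down <- poincare_crossings(tr, poincare_section("x", 2, "decreasing"), 0)
  both <- poincare_crossings(tr, poincare_section("x", 2, "both"), 0)
  expect_equal(nrow(up), 7)    # t = 0, 2pi, ..., 12pi
  expect_equal(nrow(down), 6)  # t = pi, 3pi, ..., 11pi
  expect_equal(nrow(both), 13)
  # crossings at even multiples of pi are increasing
  expect_equal(up$t[2], 2 * pi, tolerance = 1e-3)
  # plane never reached -> empty set, no error
  none <- poincare_crossings(tr, poincare_section("x", 5), 0)
  expect_equal(nrow(none), 0)
})

test_that("regime labels match constructed dynamics", {
  # constant positive trajectory -> STATIONARY
  t <- seq(0, 100, 0.01)
  lab <- classify_regime(fake_traj(t, x = rep(1.5, length(t))))
  expect_equal(lab$category, "STATIONARY")
  # decay to the origin -> ZERO
  p <- decay_params()
  tr <- integrate_dde(p, delay_params(1, 2, 3, 5), c(1, 0.5, 1),
                      short_settings(t_end = 100))
  cr <- poincare_crossings(tr, poincare_section("x", 2), 50)
  expect_equal(classify_regime(tr, cr)$category, "ZERO")
  # clean limit cycle -> PERIODIC with one crossing cluster
  tcyc <- seq(0, 900, 0.01)
  cyc <- fake_traj(tcyc, x = 2 + sin(tcyc), y = 0.5 + 0.3 * cos(tcyc))
  crc <- poincare_crossings(cyc, poincare_section("x", 2, "increasing"), 200)
  labc <- classify_regime(cyc, crc)
  expect_equal(labc$category, "PERIODIC")
  expect_equal(labc$multiplicity, 1L)
  # period-2 structure: alternate ordinates -> two clusters, still cyclic
  y2 <- 0.5 + 0.3 * cos(tcyc / 2)
  cyc2 <- fake_traj(tcyc, x = 2 + sin(tcyc), y = y2)
  crc2 <- poincare_crossings(cyc2, poincare_section("x", 2, "increasing"),
                             200)
  labc2 <- classify_regime(cyc2, crc2)
  expect_equal(labc2$category, "PERIODIC")
  expect_equal(labc2$multiplicity, 2L)
})

test_that("chaotic reference setting is sensitive and labeled chaotic", {
  p <- with_recycling(basic_params(), 0.25)
  d <- delay_params(1, 2, 3, 5)
  lab <- classify_setting(p, d, settings = integration_settings(t_end = 2000))
  expect_equal(lab$category, "CHAOTIC")
  expect_true(lab$diagnostics$sensitive)
  # the twin divergence reaches the oscillation scale
  pair <- integrate_twin(p, d, settings = integration_settings(t_end = 2000))
  div <- sensitivity_divergence(pair)
  expect_true(attr(div, "sensitive"))
  expect_gt(attr(div, "max_divergence"), 0.1 * attr(div, "amplitude"))
})

test_that("single-cycle reference setting is periodic with one cluster", {
  p <- with_recycling(basic_params(), 1)
  d <- delay_params(1, 2, 3, 5)
  lab <- classify_setting(p, d, settings = integration_settings(t_end = 4000))
  expect_equal(lab$category, "PERIODIC")
  expect_equal(lab$multiplicity, 1L)
  # empirical return period times cluster count matches the full pattern
  cr <- lab$diagnostics$crossings
  expect_gt(nrow(cr), 50)
  gaps <- diff(cr$t)
  expect_lt(stats::sd(gaps) / mean(gaps), 0.01)
})

test_that("classification is stable under finer steps and longer runs", {
  p <- with_recycling(basic_params(), 0.25)
  d <- delay_params(1, 2, 3, 5)
  base <- classify_setting(p, d,
                           settings = integration_settings(t_end = 2000))
  finer <- classify_setting(p, d,
                            settings = integration_settings(h = 0.005,
                                                            t_end = 2000))
  longer <- classify_setting(p, d,
                             settings = integration_settings(t_end = 4000))
  expect_equal(base$category, "CHAOTIC")
  expect_equal(finer$category, base$category)
  expect_equal(longer$category, base$category)
})

test_that("census finds the single global attractor of the decay system", {
  p <- decay_params()
  d <- delay_params(1, 2, 3, 5)
  cen <- attractor_census(p, d, n_starts = 6, seed = 0,
                          settings = short_settings(t_end = 150))
  expect_equal(nrow(cen), 1)
  expect_equal(cen$category, "ZERO")
  expect_equal(cen$n_basin, 6L)
  expect_equal(glance(cen)$symbol, "0")
})

test_that("census output is invariant to the seed at generous start counts", {
  d <- delay_params(1, 2, 3, 5)
  run <- function(p, seed, t_end) {
    attractor_census(p, d, n_starts = 20, seed = seed,
                     settings = integration_settings(t_end = t_end))
  }
  # decay system: always exactly the origin
  counts <- sapply(c(0, 1), function(s) nrow(run(decay_params(), s, 150)))
  expect_equal(counts, c(1, 1))
  # single-cycle setting: same count and signature across seeds
  p1 <- with_recycling(basic_params(), 1)
  c1 <- run(p1, 0, 4000); c2 <- run(p1, 1, 4000)
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(c1$amplitude, c2$amplitude, tolerance = 0.05)
})

test_that("two coexisting cycles are reachable from their basins", {
  # strong-suppression setting with full recycling: a large-basin cycle and
  # a second cycle with a small basin near the upper equilibrium shell
  p <- with_recycling(suppressWarnings(max_set(h_b = 20)), 1)
  d <- delay_params(1, 2, 3, 3)
  s <- integration_settings(t_end = 3000)
  lab1 <- classify_setting(p, d, standard_history(), s)
  lab2 <- classify_setting(p, d, c(x = 4.5, y = 0.05, z = 1.8), s)
  expect_equal(lab1$category, "PERIODIC")
  expect_equal(lab2$category, "PERIODIC")
  # distinct attractors: amplitudes differ beyond the merge tolerance
  expect_gt(abs(lab1$diagnostics$amplitude - lab2$diagnostics$amplitude),
            0.05)
  # both miss the x = 2 plane and were classified on the fallback section
  expect_true(lab1$diagnostics$section_missed)
  expect_true(lab2$diagnostics$section_missed)
})

test_that("zero label agrees with the equilibrium solver", {
  p <- with_recycling(suppressWarnings(max_set(h_b = 20)), 0)
  d <- delay_params(1, 2, 3, 3)
  lab <- classify_setting(p, d, settings = integration_settings(t_end = 2000))
  expect_equal(lab$category, "ZERO")
  eq <- find_equilibria(p)
  origin <- eq[eq$x == 0, ]
  expect_equal(nrow(origin), 1)
  expect_lt(max(abs(lab$diagnostics$final_state -
                      unlist(origin[, c("x", "y", "z")]))), 1e-6)
})

test_that("tidy and glance methods summarize results", {
  p <- with_recycling(basic_params(), 1)
  d <- delay_params(1, 2, 3, 5)
  lab <- classify_setting(p, d, settings = integration_settings(t_end = 4000))
  td <- tidy(lab)
  expect_equal(td$category, "PERIODIC")
  expect_equal(td$n_clusters, 1L)
  cen <- attractor_census(p, d, n_starts = 4, seed = 0,
                          settings = integration_settings(t_end = 4000))
  expect_equal(glance(cen)$symbol, "P")
  expect_true("ordinate" %in% names(tidy(cen)))
})
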
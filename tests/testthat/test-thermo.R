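test_that("folded fraction maps anchors to 0/1 and the hand-evaluated midpoint", {
  tr <- list(temperatures = c(25, 50, 75, 97),
             mre = c(-3000, -6000, -7000, -5000))
  fr <- folded_fraction(tr, y0 = -3000, ymax = -7000)
  expect_equal(fr$f_raw[1], 0)
  expect_equal(fr$f_raw[3], 1)
  expect_equal(fr$f[1], 1e-6)        # clip bound
  expect_equal(fr$f[3], 1 - 1e-6)
  expect_equal(fr$f_raw[2], 0.75)    # (-6000+3000)/(-7000+3000)
  expect_error(folded_fraction(tr, y0 = -5, ymax = -5), "degenerate")
  # auto anchors: min-|y| and max-|y| signals
  fr2 <- folded_fraction(tr)
  expect_equal(fr2$y0, -3000)
  expect_equal(fr2$ymax, -7000)
})

test_that("equilibrium constant and free energy follow the two-state closed forms", {
  expect_equal(equilibrium_constant(0.5), 1)
  expect_equal(equilibrium_constant(0.75), 3)
  expect_equal(equilibrium_constant(0.25), 1 / equilibrium_constant(0.75))
  expect_error(equilibrium_constant(1), "inside")
  expect_equal(free_energy(1, 37), 0)
  expect_equal(free_energy(3, 25), -8.314 * 298.15 * log(3) / 1000,
               tolerance = 1e-12)
  expect_equal(round(free_energy(3, 25), 3), -2.723)
  expect_equal(free_energy(4, 60), -free_energy(1 / 4, 60))
  # dG = 0 exactly where f = 0.5, on any temperature grid
  for (tg in list(seq(0, 100, 7), c(25, 37, 85)))
    expect_equal(free_energy(equilibrium_constant(rep(0.5, length(tg))), tg),
                 rep(0, length(tg)))
})

test_that("composition agrees with brute-force re-evaluation over random fractions", {
  set.seed(42)
  f <- runif(1e4, 1e-6, 1 - 1e-6)
  tc <- runif(1e4, 0, 100)
  got <- free_energy(equilibrium_constant(f), tc)
  # independent scalar-loop evaluation of -RT ln(f/(1-f))
  exp_dg <- vapply(seq_along(f), function(i)
    -8.314 * (tc[i] + 273.15) * (log(f[i]) - log(1 - f[i])) / 1000,
    numeric(1))
  expect_equal(got, exp_dg, tolerance = 1e-12)
})

test_that("transition fit recovers an exact line and its thermodynamic identity", {
  tt <- seq(60, 80, 1)
  ft <- fit_transition(list(temperatures = tt, dG = -(tt - 70)))
  expect_equal(ft$tm, 70, tolerance = 1e-9)
  expect_equal(ft$dS, 1000, tolerance = 1e-9)
  expect_equal(ft$dH, 70, tolerance = 1e-9)
  # internal identity holds exactly on outputs
  expect_equal(ft$dH, ft$tm * ft$dS / 1000)
  expect_equal(ft$dH_kelvin, (ft$tm + 273.15) * ft$dS / 1000)
  # window restricted to |dG| < 5: only points within the band are used
  expect_true(all(abs(-(seq(ft$window[1], ft$window[2]) - 70)) < 5 + 1e-9))
  expect_error(fit_transition(list(temperatures = c(60, 80),
                                   dG = c(-10, 10))), ">= 3")
  expect_warning(fit_transition(list(temperatures = tt, dG = (tt - 70) / 10)),
                 "non-cooperative")
})

test_that("Celsius-axis convention reproduces printed melt-table enthalpies", {
  # slope -0.530 kJ/mol/degC crossing zero at 63.2 degC
  tt <- seq(53, 73, 1)
  ft <- fit_transition(list(temperatures = tt, dG = -0.530 * (tt - 63.2)))
  expect_equal(ft$dS, 530, tolerance = 1e-6)
  expect_equal(ft$dH, 33.5, tolerance = 1e-2)
  # slope -1.370 crossing at 69.8 -> dH rounds to 96
  tt <- seq(63, 77, 1)
  ft2 <- fit_transition(list(temperatures = tt, dG = -1.370 * (tt - 69.8)))
  expect_equal(round(ft2$dH), 96)
})

test_that("segmentation selects the constructed number of transitions", {
  tt <- seq(25, 97, 2)
  # single logistic centered at 70
  f1 <- folded_fraction(list(temperatures = tt,
                             mre = 1 / (1 + exp(-(tt - 70) / 3))),
                        y0 = 0, ymax = 1)
  r1 <- segment_transitions(f1)
  expect_identical(attr(r1, "k"), 1L)
  expect_equal(r1[[1]]$t_lo, min(tt))
  expect_equal(r1[[1]]$t_hi, max(tt))
  # three logistics (centers 53, 67, 86), mirroring a stored-water pattern
  y3 <- 1 / (1 + exp(-(tt - 53) / 2)) + 1 / (1 + exp(-(tt - 67) / 2)) +
    1 / (1 + exp(-(tt - 86) / 2))
  r3 <- segment_transitions(folded_fraction(list(temperatures = tt,
                                                 mre = y3),
                                            y0 = 0, ymax = 3))
  expect_identical(attr(r3, "k"), 3L)
  expect_error(segment_transitions(folded_fraction(
    list(temperatures = tt[1:6], mre = y3[1:6]), y0 = 0, ymax = 3)),
    "12 temperature points")
})

test_that("two-logistic split point matches an exhaustive grid-search oracle", {
  tt <- seq(25, 97, 2)
  ff <- 0.5 / (1 + exp(-(tt - 63) / 2.5)) + 0.5 / (1 + exp(-(tt - 78) / 2.5))
  fr <- folded_fraction(list(temperatures = tt, mre = ff), y0 = 0, ymax = 1)
  regs <- segment_transitions(fr)
  expect_identical(attr(regs, "k"), 2L)
  # the inter-region cut sits at the midpoint of the fitted centers
  split <- mean(c(regs[[1]]$center, regs[[2]]$center))
  oracle <- grid_search_split(tt, ff, seq(55, 86, 0.5))
  expect_lt(abs(split - 70.5), 1)
  expect_lt(abs(oracle - 70.5), 1)
  expect_lt(abs(split - oracle), 2)
})

test_that("noiseless van't Hoff melts recover Tm and dS in the closed-form limit", {
  sp <- melt_spec(transitions = list(list(tm = 70, dh_vanthoff = 300,
                                          amplitude = 4000, sign = -1)),
                  baseline = -3000, noise_sigma = 0)
  res <- analyze_melt(generate_melt(sp)$trace)
  expect_identical(attr(res$regions, "k"), 1L)
  tr <- res$transitions[[1]]
  expect_lt(abs(tr$tm - 70), 0.01)
  ds_expected <- 300e3 / (70 + 273.15)    # dH_gen / Tm_K, J/K/mol
  expect_lt(abs(tr$dS / ds_expected - 1), 0.001)
  # dG(T) is exactly linear for two-state data: near-perfect line fit
  expect_gt(tr$r_squared, 1 - 1e-6)
})
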
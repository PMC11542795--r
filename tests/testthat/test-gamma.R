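flat_1d <- function(dose = 2, n = 41, pitch = 1) {
  dose_grid(seq(0, by = pitch, length.out = n), rep(dose, n))
}

flat_2d <- function(dose = 2, n = 15, pitch = 2) {
  ax <- seq(0, by = pitch, length.out = n)
  dose_grid(list(ax, ax), matrix(dose, n, n))
}

test_that("gamma closed forms: identity, and uniform offsets on flat fields", {
  for (ref in list(flat_1d(), flat_2d())) {
    g0 <- gamma_index(ref, ref, gamma_criteria(3, 2))
    expect_equal(g0$passing_rate, 100)
    expect_true(all(g0$gamma[!is.na(g0$gamma)] == 0))

    # flat fields: the spatial search cannot compensate a uniform dose
    # offset, so gamma equals offset / tolerance exactly
    ev1 <- ref; ev1$dose <- ref$dose * 1.03
    g1 <- gamma_index(ref, ev1, gamma_criteria(3, 2))
    expect_equal(unique(round(as.numeric(g1$gamma), 9)), 1)
    expect_equal(g1$passing_rate, 100)  # gamma <= 1 passes

    ev2 <- ref; ev2$dose <- ref$dose * 1.015
    g2 <- gamma_index(ref, ev2, gamma_criteria(3, 2))
    expect_equal(unique(round(as.numeric(g2$gamma), 9)), 0.5)

    ev3 <- ref; ev3$dose <- ref$dose * 1.05
    g3 <- gamma_index(ref, ev3, gamma_criteria(3, 2))
    expect_equal(g3$passing_rate, 0)
  }
})

test_that("gamma passing rate is anti-monotone in the criteria", {
  # a sloped 1D field with a small local perturbation
  x <- seq(0, 60, by = 1)
  ref <- dose_grid(x, 2 + 0.01 * x)
  ev <- ref
  ev$dose <- ev$dose * (1 + 0.025 * exp(-((x - 30) / 4)^2))
  rates <- vapply(list(c(2, 1), c(2, 2), c(3, 2), c(3, 3)), function(cr) {
    gamma_index(ref, ev, gamma_criteria(cr[1L], cr[2L]))$passing_rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("gamma result is stable under interpolation refinement", {
  x <- seq(0, 60, by = 1)
  ref <- dose_grid(x, 2 + 0.3 * sin(x / 8))
  ev <- dose_grid(x, 2 + 0.3 * sin((x - 1.2) / 8))  # small spatial shift
  cr <- gamma_criteria(3, 2)
  r1 <- gamma_index(ref, ev, cr, interp_step = cr$dta / 10)$passing_rate
  r2 <- gamma_index(ref, ev, cr, interp_step = cr$dta / 20)$passing_rate
  expect_lt(abs(r1 - r2), 0.5)
})

test_that("gamma respects the low-dose cutoff and the fixed reference role", {
  x <- seq(0, 40, by = 1)
  ref <- dose_grid(x, c(rep(0.05, 10), rep(2, 21), rep(0.05, 10)))
  ev <- ref; ev$dose <- ev$dose * 1.5
  g <- gamma_index(ref, ev, gamma_criteria(3, 2, low_dose_cutoff = 10))
  expect_lt(g$points_evaluated, length(x))

  # asymmetry: a single hot spike fails when evaluated against a flat
  # reference, but a flat evaluation finds agreement next to the spike
  flat <- dose_grid(x, rep(2, length(x)))
  spike <- flat; spike$dose[21] <- 2.6
  a <- gamma_index(flat, spike, gamma_criteria(3, 2))$passing_rate
  b <- gamma_index(spike, flat, gamma_criteria(3, 2))$passing_rate
  expect_lt(a, 100)
  expect_equal(b, 100)

  expect_error(gamma_index(ref, dose_grid(x + 1000, ref$dose),
                           gamma_criteria(3, 2)), "overlap")
})

test_that("profile differences use the reference/evaluated - 1 convention", {
  x <- seq(0, 30, by = 1)
  ref <- dose_grid(x, 2 + 0.02 * x)
  same <- profile_difference(ref, ref)
  expect_true(all(same$diff_pct == 0))
  expect_equal(same$median_diff_pct, 0)

  hot <- ref; hot$dose <- ref$dose * 1.04
  d_hot <- profile_difference(ref, hot)
  expect_equal(d_hot$median_diff_pct, 100 * (1 / 1.04 - 1), tolerance = 1e-9)

  cold <- ref; cold$dose <- ref$dose * 0.96
  d_cold <- profile_difference(ref, cold)
  expect_equal(d_cold$median_diff_pct, 100 * (1 / 0.96 - 1), tolerance = 1e-9)

  zero <- ref; zero$dose[3] <- 0
  expect_error(profile_difference(ref, zero), "positive")
})

test_that("resolution degradation subsamples without averaging", {
  x <- seq(0, 60, by = 1)
  ref <- dose_grid(x, 2 + 0.2 * sin(x / 3))
  expect_equal(degrade_resolution(ref, 1)$dose, ref$dose)
  coarse <- degrade_resolution(ref, 5)
  expect_equal(mean(diff(coarse$coords[[1L]])), 5)
  expect_true(all(coarse$dose %in% ref$dose))
  expect_error(degrade_resolution(coarse, 1), "finer")

  # a 2 mm dose feature is caught at 1 mm pitch but missed at 5 mm
  ev <- ref
  bump <- which(x >= 31 & x <= 33)        # off the 5 mm sampling comb
  ev$dose[bump] <- ev$dose[bump] * 1.10
  cr <- gamma_criteria(3, 1)
  fine <- gamma_index(ref, ev, cr)
  expect_lt(fine$passing_rate, 100)
  coarse_rate <- gamma_index(degrade_resolution(ref, 5),
                             degrade_resolution(ev, 5), cr)$passing_rate
  expect_equal(coarse_rate, 100)

  # smooth fields: degrading then 3%/3mm leaves the rate within 1%
  sm_ref <- dose_grid(x, 2 + 0.05 * sin(x / 15))
  sm_ev <- dose_grid(x, (2 + 0.05 * sin(x / 15)) * 1.02)
  r_fine <- gamma_index(sm_ref, sm_ev, gamma_criteria(3, 3))$passing_rate
  r_coarse <- gamma_index(degrade_resolution(sm_ref, 5),
                          degrade_resolution(sm_ev, 5),
                          gamma_criteria(3, 3))$passing_rate
  expect_lt(abs(r_fine - r_coarse), 1)
})

test_that("dose grids round-trip through TSV in 1D and 2D", {
  path <- withr::local_tempfile(fileext = ".tsv")
  x <- seq(0, 20, by = 2)
  g1 <- dose_grid(x, 1 + 0.1 * x)
  write_dose_grid(g1, path)
  b1 <- read_dose_grid(path)
  expect_equal(b1$coords[[1L]], g1$coords[[1L]])
  expect_equal(as.numeric(b1$dose), as.numeric(g1$dose))

  g2 <- dose_grid(list(x, x), outer(x, x, function(a, b) 2 + 0.01 * a * b))
  write_dose_grid(g2, path)
  b2 <- read_dose_grid(path)
  expect_equal(b2$coords[[2L]], g2$coords[[2L]])
  expect_equal(b2$dose, g2$dose, tolerance = 1e-9)

  expect_error(dose_grid(c(0, 1, 1.5), c(1, 1, 1)), "uniformly spaced")
  expect_error(dose_grid(x, -(1 + x)), "non-negative")
})
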
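test_that("slope distribution matches analytic derivatives", {
  ramp <- ramp_curve(span = 36)
  sd_ramp <- slope_distribution(ramp)
  expect_equal(sd_ramp$median_slope, -100 / 36, tolerance = 1e-9)
  expect_equal(sd_ramp$rms_slope, 100 / 36, tolerance = 1e-9)

  # brute-force oracle: analytic dV/dD of the logistic DVH on the same
  # support; median agrees within one bin's discretisation error
  k <- 3; span <- 36; bin <- 0.02
  sig <- sigmoid_curve(span = span, k = k, bin = bin)
  dist <- slope_distribution(sig)
  dgrid <- seq(dist$support[1L], dist$support[2L], by = bin)
  analytic <- -100 / k * plogis((span / 2 - dgrid) / k) *
    (1 - plogis((span / 2 - dgrid) / k))
  expect_lt(abs(dist$median_slope - median(analytic)), abs(median(analytic)) * 0.01)
  # median magnitude below the inflection-point magnitude
  expect_lt(abs(dist$median_slope), 100 / (4 * k))

  # a cliff steeper than the cap has no finite-difference slope
  expect_error(slope_distribution(step_curve()), "cap")
})

test_that("linear fit recovers exact lines and respects symmetry", {
  ramp <- ramp_curve(span = 36)
  fit <- suppressWarnings(fit_linear(ramp))
  expect_equal(fit$fit_slope, -100 / 36, tolerance = 1e-9)
  expect_equal(fit$intercept, 100, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # symmetric logistic on its symmetric support: fitted line passes
  # through (midpoint dose, 50%)
  sig <- sigmoid_curve(span = 36, k = 3)
  f <- fit_linear(sig, support = c(6, 30))
  expect_equal(f$fit_slope * 18 + f$intercept, 50, tolerance = 1e-6)

  tiny <- dvh_curve(c(0, 1, 2), c(100, 50, 0))
  expect_error(fit_linear(tiny, support = c(0, 0.5)), "fewer than 3")
})

test_that("per-arc linear coefficient reproduces reported clinical values", {
  # conventional-technique arc: R^2 0.94, median -2.10, fit -3.85
  expect_equal(round(f_lin_from_summary(0.94, -2.10, -3.85), 2), 0.51)
  # staggered-technique arc: R^2 0.99, median -2.80, fit -2.78
  expect_equal(round(f_lin_from_summary(0.99, -2.80, -2.78), 2), 1.00)
  expect_equal(f_lin_from_summary(1, -2.5, -2.5), 1)

  # object interface agrees with the summary interface
  ramp <- ramp_curve()
  fit <- suppressWarnings(fit_linear(ramp))
  dist <- slope_distribution(ramp)
  expect_equal(f_lin_arc(fit, dist),
               f_lin_from_summary(fit$r_squared, dist$median_slope, fit$fit_slope))

  # rising DVH is rejected
  bad_fit <- fit; bad_fit$fit_slope <- 2.5
  expect_error(f_lin_arc(bad_fit, dist), "rising")
})

test_that("overlap linear coefficient is the mean of the per-arc values", {
  ov <- overlap_spec(ramp_curve(arc = "U"), ramp_curve(arc = "M"), h = 9)
  expect_equal(f_lin(ov), 1, tolerance = 1e-9)
  expect_equal(mean(c(f_lin_from_summary(0.94, -2.10, -3.85),
                      f_lin_from_summary(0.94, -2.10, -3.81))),
               0.515, tolerance = 1e-3)
  expect_equal(mean(c(1, 0.5)), 0.75)  # documented averaging convention
})

test_that("gradient coefficient follows its closed form", {
  # arcs whose D2% - D98% equals the prescription exactly: linear over
  # [0, 37.5] so that 0.96 * 37.5 = 36
  arc <- ramp_curve(span = 37.5, dpr = 36)
  ov9 <- overlap_spec(arc, arc, h = 9, prescription_gy = 36)
  expect_equal(f_grad(ov9), 1, tolerance = 1e-9)        # (9*36/18) * (2/36)
  ov45 <- overlap_spec(arc, arc, h = 4.5, prescription_gy = 36)
  expect_equal(f_grad(ov45), 0.5, tolerance = 1e-9)     # linear in h

  # doubling both spans halves f_grad
  wide <- ramp_curve(span = 75, dpr = 36)
  ov_wide <- overlap_spec(wide, wide, h = 9, prescription_gy = 36)
  expect_equal(f_grad(ov_wide), f_grad(ov9) * 36 / (0.96 * 75), tolerance = 1e-9)

  # degenerate cliff DVH: the D2-D98 span collapses to one bin and the
  # gradient coefficient blows up (flagged by the normalisation warning)
  stp <- step_curve(at = 10)
  ov_cliff <- overlap_spec(stp, stp, h = 6, prescription_gy = 36)
  expect_warning(fg <- f_grad(ov_cliff), "not normalised")
  expect_gt(fg, 10)
})

test_that("ORI equals f_lin x f_grad and matches the expanded single formula", {
  set.seed(7)
  for (i in 1:5) {
    k <- runif(1, 2, 3.5)
    h <- runif(1, 3, 9)
    ov <- overlap_spec(sigmoid_curve(k = k), sigmoid_curve(k = k + 0.5),
                       h = h, prescription_gy = 36)
    res <- suppressWarnings(compute_ori(ov))
    expect_equal(res$ori, res$f_lin * res$f_grad, tolerance = 1e-12)
    # expanded form: h * Dpr / 36 * sum(f_lin_i) * sum(1 / (D2 - D98))
    spans <- vapply(res$per_arc, function(a) a$d2 - a$d98, numeric(1))
    flins <- vapply(res$per_arc, `[[`, numeric(1), "f_lin_i")
    expanded <- (h * 36 / 36) * sum(flins) * sum(1 / spans)
    expect_equal(res$ori, expanded, tolerance = 1e-9)
  }
})

test_that("ORI is invariant under absolute vs relative dose units", {
  sig_abs <- sigmoid_curve(k = 3.5, dpr = 36)
  ov_abs <- overlap_spec(sig_abs, sig_abs, h = 6, prescription_gy = 36)
  sig_rel <- to_relative(sig_abs)
  ov_rel <- overlap_spec(sig_rel, sig_rel, h = 6, prescription_gy = 36)
  res_abs <- compute_ori(ov_abs)
  res_rel <- compute_ori(ov_rel)
  expect_equal(res_rel$ori, res_abs$ori, tolerance = 1e-9)
  expect_equal(res_rel$f_lin, res_abs$f_lin, tolerance = 1e-9)
  expect_equal(res_rel$f_grad, res_abs$f_grad, tolerance = 1e-9)
})

test_that("ORI grows with overlap length at fixed DVH shape", {
  oris <- vapply(c(3, 5, 7, 9), function(h) {
    ov <- overlap_spec(sigmoid_curve(k = 3), sigmoid_curve(k = 3),
                       h = h, prescription_gy = 36)
    suppressWarnings(compute_ori(ov))$ori
  }, numeric(1))
  expect_true(all(diff(oris) > 0))
})

test_that("ideal ramp pair yields the f_lin ideal and warns beyond the reference", {
  ov <- overlap_spec(ramp_curve(), ramp_curve(), h = 9, prescription_gy = 36)
  res <- suppressWarnings(compute_ori(ov))
  expect_equal(res$f_lin, 1, tolerance = 1e-9)
  # full-range ramps read D2-D98 = 0.96 span, so f_grad is 25/24
  expect_equal(res$f_grad, 25 / 24, tolerance = 1e-9)
  expect_warning(f_grad(ov), "not normalised")
})
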
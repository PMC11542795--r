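test_that("junction construction is deterministic and conserves dose", {
  for (tech in c("static", "staggered")) {
    m1 <- make_junction(tech, h = 6, noise_sd = 0.05, seed = 42)
    m2 <- make_junction(tech, h = 6, noise_sd = 0.05, seed = 42)
    expect_identical(m1, m2)
    m3 <- make_junction(tech, h = 6, noise_sd = 0.05, seed = 43)
    expect_false(identical(m1$dose_upper, m3$dose_upper))

    # zero shift, zero noise: total equals the prescription in the
    # overlap interior to well within 1%
    m0 <- make_junction(tech, h = 6, noise_sd = 0)
    inside <- m0$z > 0.1 & m0$z < m0$h - 0.1
    total <- m0$dose_upper[inside] + m0$dose_lower[inside]
    expect_lt(max(abs(total - m0$prescription_gy)), 0.01 * m0$prescription_gy)
    expect_true(all(m0$dose_upper >= 0 & m0$dose_upper <= m0$prescription_gy + 1e-9))
  }
  expect_error(make_junction("staggered", h = 6, n_steps = 5), "3, 4 or 6")
  expect_error(make_junction("static", h = -1), "positive")
})

test_that("staggered profiles approach a linear ramp as steps refine", {
  dev_from_ramp <- function(n) {
    m <- make_junction("staggered", h = 6, n_steps = n,
                       step_weight_jitter = 0, noise_sd = 0)
    sel <- m$z >= 0.5 & m$z <= 5.5
    ramp <- m$prescription_gy * (1 - m$z[sel] / 6)
    max(abs(m$dose_upper[sel] - ramp))
  }
  devs <- vapply(c(3L, 4L, 6L), dev_from_ramp, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3L], 0.05 * 36)
})

test_that("profiles map to DVHs by exact length fraction", {
  # linear ramp profile -> exactly linear DVH
  rj <- ramp_junction(h = 6)
  dvh <- profile_to_dvh(rj, "upper")
  expect_dvh_valid(dvh)
  mid <- dvh$dose > 1 & dvh$dose < 35
  expect_equal(dvh$volume[mid], 100 * (1 - dvh$dose[mid] / 36), tolerance = 1e-6)

  # uniform region -> step DVH
  stp <- profile_to_dvh(rj, "upper", region = c(-2.5, -0.5))
  expect_true(all(stp$volume %in% c(0, 100)))
  expect_lte(abs(dose_at_volume(stp, 2) - 36), 0.05 + 1e-9)

  # near-staircase profile -> plateaus at the expected volume levels
  n <- 4L
  sj <- make_junction("staggered", h = 6, n_steps = n, penumbra_width = 0.05,
                      step_weight_jitter = 0, noise_sd = 0)
  sd_dvh <- profile_to_dvh(sj, "upper")
  for (j in seq_len(n)) {
    d_mid <- 36 * (j - 0.5) / n
    v_expect <- 100 * (n - j + 0.5) / n
    idx <- which.min(abs(sd_dvh$dose - d_mid))
    expect_equal(sd_dvh$volume[idx], v_expect, tolerance = 0.75)
  }

  expect_error(profile_to_dvh(rj, "total", region = c(20, 30)), "empty region")
})

test_that("shifting one arc translates its profile and keeps the other fixed", {
  m <- make_junction("static", h = 6)
  expect_identical(apply_shift(m, 0), m)

  s <- apply_shift(m, 3, "lower")
  expect_identical(s$dose_upper, m$dose_upper)
  # exact grid translation: 3 mm = 30 grid steps of 0.1 mm
  k <- 30L
  n <- length(m$z)
  expect_equal(s$dose_lower[(k + 1L):n], m$dose_lower[1L:(n - k)],
               tolerance = 1e-9)

  # complementary ideal ramps: the shift changes the interior total by
  # a spatially uniform delta/h * Dpr
  rj <- ramp_junction(h = 6)
  rs <- apply_shift(rj, 3, "lower")
  sel <- rs$z > 0.4 & rs$z < 5.6
  total <- rs$dose_upper[sel] + rs$dose_lower[sel]
  expect_lt(max(total) - min(total), 1e-9)
  expect_equal(total[1L], 36 * (1 - 0.3 / 6), tolerance = 1e-9)

  # zero-penumbra step junction: a delta-wide cold band appears
  sj <- step_junction(h = 6)
  ss <- apply_shift(sj, 2, "lower")
  tot <- ss$dose_upper + ss$dose_lower
  cold <- ss$z > 0 & ss$z < 6 & tot < 1e-9
  expect_equal(sum(cold) * ss$grid_step, 0.2, tolerance = 0.02)

  small <- make_junction("static", h = 4)
  expect_warning(apply_shift(small, 25), "half the overlap")
  expect_error(apply_shift(m, 400), "margin")
})

test_that("inhomogeneity ratio is 1 at zero shift and ranks techniques", {
  ms <- make_junction("static", h = 6, noise_sd = 0)
  ir0 <- inhomogeneity_ratio(ms, delta_mm = 0)
  expect_equal(ir0$ir_plus, 1)
  expect_equal(ir0$ir_minus, 1)
  expect_equal(ir0$ir_worst, 1)

  # all D2/D98 ratios are >= 1 by construction
  ir3 <- inhomogeneity_ratio(ms, delta_mm = 3)
  expect_true(all(c(ir3$ratio_unshifted, ir3$ratio_plus, ir3$ratio_minus) >= 1))

  # ramp-like staggered junction is more robust than the conventional
  # junction on matched geometry
  md <- make_junction("staggered", h = 6, step_weight_jitter = 0, noise_sd = 0)
  ird <- inhomogeneity_ratio(md, delta_mm = 3)
  expect_lt(ird$ir_worst, ir3$ir_worst)

  # static degradation grows monotonically with the shift magnitude
  irs <- vapply(c(1, 2, 3, 4, 5),
                function(d) inhomogeneity_ratio(ms, delta_mm = d)$ir_worst,
                numeric(1))
  expect_true(all(diff(irs) > 0))
})

test_that("cohort generation is reproducible and shows the built-in contrast", {
  co1 <- suppressWarnings(cohort_generate(n_patients = 2, seed = 5))
  co2 <- suppressWarnings(cohort_generate(n_patients = 2, seed = 5))
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 2 * 2 * 2)

  # ramp-like cohort: high ORI, IR near 1; conventional: lower ORI, higher IR
  stag <- co1[co1$technique == "staggered", ]
  stat <- co1[co1$technique == "static", ]
  expect_gt(median(stag$ori), median(stat$ori))
  expect_lt(median(stag$ir), median(stat$ir))
  expect_lt(max(stag$ir), 1.15)
  expect_error(cohort_generate(n_patients = 1), "at least 2")
})

test_that("cohort statistics compute rank, paired and normality summaries", {
  co <- suppressWarnings(cohort_generate(n_patients = 3, seed = 2))
  cs <- cohort_statistics(co)
  expect_lt(cs$spearman_r, 0)
  expect_true(all(cs$wilcoxon_p >= 0 & cs$wilcoxon_p <= 1, na.rm = TRUE))
  expect_true(all(cs$normality_p >= 0 & cs$normality_p <= 1))
  expect_equal(cs$n_pairs, 6)

  # perfectly anti-monotone pairs give Spearman -1
  toy <- data.frame(
    patient = rep(1:4, each = 2), overlap = 1,
    technique = rep(c("a", "b"), 4),
    ori = c(8, 7, 6, 5, 4, 3, 2, 1), ir = c(1, 2, 3, 4, 5, 6, 7, 8))
  cs_toy <- cohort_statistics(toy)
  expect_equal(cs_toy$spearman_r, -1)

  # identical paired samples: all-zero differences are flagged, not tested
  same <- toy
  same$ori <- rep(c(4, 3, 2, 1), each = 2)
  same$ir <- rep(c(1, 2, 3, 4), each = 2)
  cs_same <- cohort_statistics(same)
  expect_true(all(is.na(cs_same$wilcoxon_p)))

  expect_error(cohort_statistics(toy[-1, ]), "paired")
})
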
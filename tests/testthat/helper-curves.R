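# analytic curves used across tests

# exact linear ramp DVH: V(D) = 100 * (1 - D / span)
ramp_curve <- function(span = 36, bin = 0.05, dpr = span, arc = "ramp") {
  d <- seq(0, span, by = bin)
  dvh_curve(d, pmax(0, 100 * (1 - d / span)),
            arc_set = arc, prescription_gy = dpr)
}

# step DVH of a uniform dose: 100% up to `at`, 0 beyond
step_curve <- function(at = 10, top = 12, bin = 0.05, dpr = 36) {
  d <- seq(0, top, by = bin)
  dvh_curve(d, ifelse(d <= at, 100, 0), prescription_gy = dpr)
}

# logistic (sigmoid-in-dose) DVH centred at span/2 with scale k
sigmoid_curve <- function(span = 36, k = 3, bin = 0.05, dpr = span) {
  d <- seq(0, span, by = bin)
  dvh_curve(d, 100 * plogis((span / 2 - d) / k), prescription_gy = dpr)
}

# minimal hand-built junction model (exact complementary ramps)
ramp_junction <- function(h = 6, dpr = 36, grid_step = 0.01, margin = 3) {
  z <- seq(-margin, h + margin, by = grid_step)
  upper <- dpr * pmin(pmax(1 - z / h, 0), 1)
  structure(
    list(technique = "staggered", h = h, prescription_gy = dpr,
         penumbra_width = NA_real_, sigmoid_width = NA_real_,
         n_steps = NA_integer_, step_weight_jitter = NA_real_,
         grid_step = grid_step, noise_sd = 0, seed = 1L,
         z = z, dose_upper = upper, dose_lower = dpr - upper,
         shift_mm = 0, shifted_arc = NA_character_),
    class = "junction_model")
}

# step-edge junction (zero-width penumbra at mid-overlap)
step_junction <- function(h = 6, dpr = 36, grid_step = 0.01, margin = 3) {
  m <- ramp_junction(h, dpr, grid_step, margin)
  m$dose_upper <- dpr * as.numeric(m$z < h / 2)
  m$dose_lower <- dpr - m$dose_upper
  m
}

expect_dvh_valid <- function(curve) {
  expect_s3_class(curve, "dvh_curve")
  expect_true(all(diff(curve$dose) > 0))
  expect_true(all(curve$volume >= 0 & curve$volume <= 100))
  expect_true(all(diff(curve$volume) <= 1e-12))
}
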
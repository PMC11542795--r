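#' Deterministic synthetic DVH fixtures
#'
#' Generates cumulative DVH curves with the shapes the analysis
#' distinguishes: exact linear ramps (the robustness ideal), logistic
#' sigmoids (conventional fixed-overlap junctions, mixing shallow and
#' steep slope regions) and staircases (idealised staggered sub-field
#' plateaus). Optional noise is applied before monotonisation so every
#' generated curve is a valid cumulative DVH; the same `seed` always
#' reproduces the same curve.
#'
#' @param family `"ramp"`, `"sigmoid"` or `"staircase"`.
#' @param span Dose span in Gy: the ramp reaches zero volume at `span`;
#'   sigmoid and staircase falloffs are centred at `span / 2`.
#' @param width Sigmoid 80--20\% dose width in Gy (sigmoid family).
#' @param n_steps Number of equal plateaus (staircase family).
#' @param bin_width Dose grid bin, Gy.
#' @param noise_sd Gaussian volume noise (\% points) added before
#'   monotonisation. Default 0.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param structure,arc_set Labels stamped on the curve.
#' @return A [dvh_curve()] in absolute Gy with `prescription_gy = span`.
#' @export
#' @examples
#' make_dvh_fixture("ramp", span = 36)
make_dvh_fixture <- function(family = c("ramp", "sigmoid", "staircase"),
                             span = 36, width = 4, n_steps = 4L,
                             bin_width = 0.05, noise_sd = 0, seed = 1L,
                             structure = "PTV_overlap", arc_set = family) {
  family <- match.arg(family)
  stopifnot(span > 0, bin_width > 0)
  d <- seq(0, span, by = bin_width)
  if (d[length(d)] < span) d <- c(d, span)
  v <- switch(family,
    ramp = pmin(pmax(100 * (1 - d / span), 0), 100),
    sigmoid = {
      if (width <= 0) stop("`width` must be positive", call. = FALSE)
      k <- width / (2 * log(4))
      100 * stats::plogis((span / 2 - d) / k)
    },
    staircase = {
      n <- as.integer(n_steps)
      if (n < 2L) stop("`n_steps` must be at least 2", call. = FALSE)
      # n equal-width volume plateaus stepping down across the span
      100 * (1 - pmin(floor(d / span * n), n) / n)
    }
  )
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    v <- v + stats::rnorm(length(v), 0, noise_sd)
    v <- cummin(pmin(pmax(v, 0), 100))
  }
  dvh_curve(d, v, structure = structure, arc_set = arc_set[1L],
            dose_units = "absolute_gy", prescription_gy = span)
}

#' Benchmark overlap pair: conventional-like vs staggered-like
#'
#' Builds two ready-made [overlap_spec()] objects representing the two
#' junction regimes on matched geometry: a conventional fixed-overlap
#' junction whose arc-set DVHs are sigmoid-like in dose (linear
#' coefficient in the 0.4--0.6 range, the regime of clinical
#' fixed-overlap plans) and a staggered junction whose arc-set DVHs are
#' ideal ramps (linear coefficient at 1). Both share the same overlap
#' length and prescription, so the resulting robustness indices isolate
#' the effect of DVH shape.
#'
#' @param h Overlap length, cm. Default 4 (a typical cranial-spinal
#'   junction).
#' @param prescription_gy Prescription dose, Gy. Default 36.
#' @param sigmoid_width 80--20\% dose width of the conventional-like
#'   sigmoid DVH, Gy. Default 10: clinical fixed-overlap arc sets still
#'   spread their D98\%--D2\% span over most of the prescription range,
#'   but with slope concentrated at mid doses.
#' @return Named list `static` / `dynamic` of [overlap_spec()] objects.
#' @export
make_benchmark_pair <- function(h = 4, prescription_gy = 36,
                                sigmoid_width = 10) {
  sig <- function(arc) make_dvh_fixture("sigmoid", span = prescription_gy,
                                        width = sigmoid_width, arc_set = arc)
  rmp <- function(arc) make_dvh_fixture("ramp", span = prescription_gy,
                                        arc_set = arc)
  list(
    static = overlap_spec(sig("US"), sig("MS"), h = h,
                          prescription_gy = prescription_gy,
                          label = "benchmark_static"),
    dynamic = overlap_spec(rmp("UD"), rmp("MD"), h = h,
                           prescription_gy = prescription_gy,
                           label = "benchmark_dynamic")
  )
}
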
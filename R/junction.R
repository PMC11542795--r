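#' Parametric longitudinal two-arc junction dose model
#'
#' Models the dose along the patient's cranial-caudal (z) axis in the
#' overlap region where two adjacent VMAT arc sets are joined. The
#' overlap occupies `z` in `[0, h]`; the upper arc set delivers the full
#' prescription on `z < 0` and falls off across the overlap, the lower
#' arc set mirrors it, and at zero shift and zero noise the two always
#' sum exactly to the prescription dose.
#'
#' Two junction techniques are modelled:
#' \describe{
#'   \item{static}{a conventional fixed overlap: both arc sets cover
#'     the whole overlap and the optimiser shapes complementary
#'     falloffs across it. The delivered per-arc falloff is a
#'     logit-in-position curve spanning the overlap — steep near the
#'     overlap boundaries, shallow at mid-overlap — whose cumulative
#'     DVH is sigmoid in dose with an 80--20\% dose width of
#'     `sigmoid_width` Gy, mixing shallow and steep DVH slope regions
#'     as observed for clinical fixed-overlap plans.}
#'   \item{staggered}{field edges staggered in `n_steps` equal
#'     sub-steps of the overlap length, each sub-field contributing
#'     `Dpr / n_steps` through its own logistic penumbra. The
#'     superposed profile approaches a linear ramp across the overlap
#'     as `n_steps` grows, spreading the gradient evenly over the whole
#'     junction.}
#' }
#'
#' @param technique `"static"` or `"staggered"`.
#' @param h Overlap length, cm.
#' @param prescription_gy Prescription dose, Gy.
#' @param penumbra_width 80--20\% penumbra width of one staggered
#'   sub-field edge, cm. Default 0.8, a typical 6 MV longitudinal
#'   penumbra scale.
#' @param sigmoid_width 80--20\% dose width (Gy) of the static arc-set
#'   DVH sigmoid. Default 10: conventional plans still spread the
#'   D98\%--D2\% span over most of the prescription range while
#'   concentrating slope at mid doses.
#' @param n_steps Number of staggered sub-steps (3, 4 or 6). Default
#'   follows overlap length: 3 for `h <= 4`, 4 for `4 < h <= 6`, 6 for
#'   `h > 6` (shorter sub-steps for longer overlaps).
#' @param step_weight_jitter Relative spread of the staggered sub-field
#'   dose contributions (optimised plans do not deliver exactly
#'   `Dpr / n_steps` per sub-field). Weights are drawn once per model
#'   from the seed and renormalised to sum to the prescription. Default
#'   0.15; set 0 for ideal equal-weight sub-fields.
#' @param grid_step Longitudinal grid step, cm. Default 0.01 (0.1 mm)
#'   so millimetre shifts are exact grid translations.
#' @param margin Modelled margin beyond the overlap on each side, cm.
#' @param noise_sd Additive Gaussian noise per arc profile, Gy
#'   (clipped to `[0, 2 Dpr]`). Default 0.
#' @param seed Integer seed for the noise; ignored when `noise_sd = 0`.
#' @return A `junction_model`: `z` grid plus `dose_upper`, `dose_lower`
#'   per-arc dose vectors (Gy) and the generating parameters.
#' @seealso [apply_shift()], [profile_to_dvh()], [inhomogeneity_ratio()]
#' @export
make_junction <- function(technique = c("static", "staggered"),
                          h, prescription_gy = 36,
                          penumbra_width = 0.8, sigmoid_width = 10,
                          n_steps = NULL, step_weight_jitter = 0.15,
                          grid_step = 0.01, margin = 3,
                          noise_sd = 0, seed = 1L) {
  technique <- match.arg(technique)
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("`h` must be a single positive overlap length in cm", call. = FALSE)
  }
  if (grid_step <= 0 || grid_step > 0.05) {
    stop("`grid_step` must be positive and at most 0.05 cm", call. = FALSE)
  }
  if (penumbra_width <= 0) stop("`penumbra_width` must be positive", call. = FALSE)
  if (sigmoid_width <= 0) stop("`sigmoid_width` must be positive", call. = FALSE)
  if (is.null(n_steps)) {
    n_steps <- if (h <= 4) 3L else if (h <= 6) 4L else 6L
  }
  if (technique == "staggered" && !n_steps %in% c(3L, 4L, 6L)) {
    stop("`n_steps` must be 3, 4 or 6", call. = FALSE)
  }
  dpr <- prescription_gy
  z <- seq(-margin, h + margin, by = grid_step)
  needs_rng <- noise_sd > 0 ||
    (technique == "staggered" && step_weight_jitter > 0)
  if (needs_rng) set.seed(as.integer(seed))
  # logistic scale giving an 80-20% distance equal to the stated width
  k <- penumbra_width / (2 * log(4))
  if (technique == "staggered") {
    edge <- function(z, centre) stats::plogis((centre - z) / k)
    centres <- h * (seq_len(n_steps) - 0.5) / n_steps
    w <- rep(1, n_steps)
    if (step_weight_jitter > 0) {
      w <- pmax(1 + stats::rnorm(n_steps, 0, step_weight_jitter), 0.2)
    }
    w <- dpr * w / sum(w)
    upper <- rowSums(vapply(seq_len(n_steps), function(j) w[j] * edge(z, centres[j]),
                            numeric(length(z))))
  } else {
    # conventional overlap: logit-in-z falloff spanning the overlap
    # (dose fraction 1/2 - s * logit(z/h), clamped). This is the
    # delivered composite of the optimised arc segments, so it is
    # parameterised directly in dose: its cumulative DVH over the
    # overlap is logistic in dose with 80-20% width `sigmoid_width`.
    ks <- sigmoid_width / (2 * log(4))
    s <- ks / dpr
    u <- pmin(pmax(z / h, 1e-12), 1 - 1e-12)
    frac <- pmin(pmax(0.5 - s * log(u / (1 - u)), 0), 1)
    frac[z <= 0] <- 1
    frac[z >= h] <- 0
    upper <- dpr * frac
  }
  lower <- dpr - upper
  if (noise_sd > 0) {
    # independent noise per arc; summation to Dpr then only holds in mean
    upper <- pmin(pmax(upper + stats::rnorm(length(z), 0, noise_sd), 0), 2 * dpr)
    lower <- pmin(pmax(lower + stats::rnorm(length(z), 0, noise_sd), 0), 2 * dpr)
  }
  structure(
    list(technique = technique, h = h, prescription_gy = dpr,
         penumbra_width = penumbra_width,
         sigmoid_width = if (technique == "static") sigmoid_width else NA_real_,
         n_steps = if (technique == "staggered") as.integer(n_steps) else NA_integer_,
         step_weight_jitter = if (technique == "staggered") step_weight_jitter else NA_real_,
         grid_step = grid_step, noise_sd = noise_sd, seed = as.integer(seed),
         z = z, dose_upper = upper, dose_lower = lower,
         shift_mm = 0, shifted_arc = NA_character_),
    class = "junction_model"
  )
}

#' @export
print.junction_model <- function(x, ...) {
  cat(sprintf("<junction_model> %s junction, h = %g cm, %g Gy\n",
              x$technique, x$h, x$prescription_gy))
  if (x$technique == "staggered") {
    cat(sprintf("  %d sub-steps, penumbra %g cm\n", x$n_steps, x$penumbra_width))
  } else {
    cat(sprintf("  DVH sigmoid width %g Gy, penumbra %g cm\n",
                x$sigmoid_width, x$penumbra_width))
  }
  cat(sprintf("  grid %g mm over z in [%g, %g] cm; noise sd %g Gy\n",
              10 * x$grid_step, min(x$z), max(x$z), x$noise_sd))
  if (x$shift_mm != 0) {
    cat(sprintf("  applied shift: %+g mm on %s arc\n", x$shift_mm, x$shifted_arc))
  }
  invisible(x)
}

#' Shift one arc set of a junction model longitudinally
#'
#' Emulates a setup error of one isocenter along the cranial-caudal
#' axis: the chosen arc's dose profile is translated by `delta_mm`
#' (positive toward caudal / larger z) while the other arc and the
#' overlap region stay fixed in the patient frame. The shifted profile
#' is resampled onto the common grid by linear interpolation with
#' constant extension at its plateau ends.
#'
#' @param model A [make_junction()] model.
#' @param delta_mm Signed shift in millimetres.
#' @param shifted_arc `"upper"` or `"lower"` (`"lower"` corresponds to
#'   shifting the mid isocenter of a cranial junction).
#' @return A `junction_model` with the shift applied.
#' @export
apply_shift <- function(model, delta_mm, shifted_arc = c("lower", "upper")) {
  stopifnot(inherits(model, "junction_model"))
  shifted_arc <- match.arg(shifted_arc)
  if (!is.numeric(delta_mm) || length(delta_mm) != 1L || is.na(delta_mm)) {
    stop("`delta_mm` must be a single number", call. = FALSE)
  }
  delta_cm <- delta_mm / 10
  if (abs(delta_cm) >= (max(model$z) - model$h)) {
    stop("shift exceeds the modelled margin beyond the overlap", call. = FALSE)
  }
  if (abs(delta_cm) > model$h / 2) {
    warning("shift exceeds half the overlap length; junction integrity is lost",
            call. = FALSE)
  }
  if (delta_mm == 0) return(model)
  field <- paste0("dose_", shifted_arc)
  prof <- model[[field]]
  shifted <- stats::approx(model$z + delta_cm, prof, xout = model$z,
                           method = "linear", rule = 2)$y
  model[[field]] <- shifted
  model$shift_mm <- model$shift_mm + delta_mm
  model$shifted_arc <- shifted_arc
  model
}

#' Cumulative DVH of a junction profile over a z-interval
#'
#' The overlap is modelled as a cylinder of uniform cross-section, so
#' the volume fraction receiving at least a dose equals the length
#' fraction of the region where the profile reaches that dose. The
#' length fraction is computed exactly for the piecewise-linear profile
#' (crossing positions interpolated within grid cells), so the DVH is
#' free of grid-counting quantisation and an exact ramp profile yields
#' an exactly linear DVH.
#'
#' @param model A [make_junction()] model.
#' @param arc `"upper"`, `"lower"` or `"total"` (sum of both).
#' @param region z-interval `c(lo, hi)` in cm; defaults to the overlap
#'   `[0, h]`.
#' @param bin_width DVH dose bin width, Gy.
#' @param structure Structure label stamped on the curve.
#' @return A [dvh_curve()] in absolute Gy.
#' @export
profile_to_dvh <- function(model, arc = c("total", "upper", "lower"),
                           region = NULL, bin_width = 0.05,
                           structure = "PTV_overlap") {
  stopifnot(inherits(model, "junction_model"))
  arc <- match.arg(arc)
  if (is.null(region)) region <- c(0, model$h)
  stopifnot(length(region) == 2L, region[1L] < region[2L])
  sel <- model$z >= region[1L] & model$z <= region[2L]
  if (!any(sel)) stop("empty region: no grid points inside it", call. = FALSE)
  dose <- switch(arc,
    upper = model$dose_upper[sel],
    lower = model$dose_lower[sel],
    total = model$dose_upper[sel] + model$dose_lower[sel]
  )
  top <- max(dose)
  grid <- seq(0, top + bin_width, by = bin_width)
  # exact length fraction at or above each threshold for the
  # piecewise-linear profile: per grid cell, the covered sub-length is
  # clamp((max - d) / |slope span|, 0, 1); flat cells count 0 or 1
  a <- dose[-length(dose)]
  b <- dose[-1L]
  hi <- pmax(a, b)
  span <- abs(b - a)
  flat <- span < .Machine$double.eps
  vol <- vapply(grid, function(d) {
    frac <- ifelse(flat, as.numeric(hi >= d),
                   pmin(pmax((hi - d) / ifelse(flat, 1, span), 0), 1))
    100 * mean(frac)
  }, numeric(1))
  dvh_curve(grid, vol,
            structure = structure,
            arc_set = paste0(arc, if (model$shift_mm != 0)
              sprintf("_%+gmm", model$shift_mm) else ""),
            dose_units = "absolute_gy",
            prescription_gy = model$prescription_gy)
}

#' Inhomogeneity Ratio of a junction under a longitudinal shift
#'
#' Quantifies how much a setup error of `delta_mm` degrades dose
#' homogeneity in the overlap: the D2\%/D98\% ratio of the total
#' junction dose is computed without shift and with the designated arc
#' shifted by plus and minus `delta_mm` (convergence and divergence of
#' the isocenters), and each shifted ratio is divided by the unshifted
#' one. A value of 1 means the junction is insensitive to the shift.
#'
#' @param model A [make_junction()] model (unshifted).
#' @param delta_mm Shift magnitude in millimetres. Default 3, a
#'   realistic couch-sag / intrafraction-motion setup error.
#' @param region z-interval evaluated; defaults to the overlap.
#' @param shifted_arc Which arc moves, see [apply_shift()].
#' @param bin_width DVH dose bin width, Gy.
#' @return An `ir_result`: `ratio_unshifted`, `ratio_plus`,
#'   `ratio_minus` (D2\%/D98\% at 0, +delta, -delta), `ir_plus`,
#'   `ir_minus`, and `ir_worst = max(ir_plus, ir_minus)`.
#' @export
inhomogeneity_ratio <- function(model, delta_mm = 3, region = NULL,
                                shifted_arc = "lower", bin_width = 0.05) {
  stopifnot(inherits(model, "junction_model"))
  if (delta_mm < 0) stop("`delta_mm` is a magnitude; use a non-negative value",
                         call. = FALSE)
  ratio_of <- function(m) {
    dvh <- profile_to_dvh(m, "total", region, bin_width)
    d98 <- dose_at_volume(dvh, 98)
    if (d98 <= 0) stop("D98% is zero in the evaluated region", call. = FALSE)
    dose_at_volume(dvh, 2) / d98
  }
  r0 <- ratio_of(model)
  rp <- ratio_of(apply_shift(model, delta_mm, shifted_arc))
  rm <- ratio_of(apply_shift(model, -delta_mm, shifted_arc))
  structure(
    list(delta_mm = delta_mm,
         ratio_unshifted = r0, ratio_plus = rp, ratio_minus = rm,
         ir_plus = rp / r0, ir_minus = rm / r0,
         ir_worst = max(rp, rm) / r0),
    class = "ir_result"
  )
}

#' @export
print.ir_result <- function(x, ...) {
  cat(sprintf("<ir_result> +/-%g mm shift\n", x$delta_mm))
  cat(sprintf("  D2/D98: unshifted %.4f, +shift %.4f, -shift %.4f\n",
              x$ratio_unshifted, x$ratio_plus, x$ratio_minus))
  cat(sprintf("  IR: + %.4f, - %.4f, worst %.4f\n",
              x$ir_plus, x$ir_minus, x$ir_worst))
  invisible(x)
}

#' Generate a synthetic cohort of junction overlaps with paired ORI and IR
#'
#' Emulates a clinical cohort in which each patient has an upper and a
#' lower junction, each planned with both the conventional (static
#' fixed-overlap) and the staggered technique. Overlap lengths are
#' drawn per junction from `h_range`; penumbra widths vary per patient
#' around the nominal beam penumbra; staggered step counts follow the
#' overlap-length rule of [make_junction()]. For every overlap the ORI
#' is computed from the two per-arc DVHs and the IR from a simulated
#' `delta_mm` shift of the shared isocenter.
#'
#' @param n_patients Number of patients. Default 5.
#' @param techniques Techniques generated per overlap.
#' @param overlaps_per_patient Junctions per patient. Default 2.
#' @param h_range Overlap-length range, cm. Default `c(3, 9)`.
#' @param prescription_gy Prescription dose, Gy.
#' @param penumbra_range Per-patient 80--20\% penumbra width range, cm.
#' @param sigmoid_width_range Per-overlap range of the static DVH
#'   sigmoid width, Gy (plan-to-plan variation in how well the
#'   conventional optimisation spreads the junction gradient).
#' @param noise_sd Profile noise, Gy.
#' @param delta_mm Simulated shift magnitude, mm.
#' @param seed Integer seed controlling every random draw.
#' @return A data frame with one row per patient x overlap x technique:
#'   `patient`, `overlap`, `technique`, `h`, `penumbra`, `n_steps`,
#'   `f_lin`, `f_grad`, `ori`, `ir` (worst-case of the two shift
#'   signs), `ir_plus`, `ir_minus`.
#' @export
cohort_generate <- function(n_patients = 5,
                            techniques = c("static", "staggered"),
                            overlaps_per_patient = 2,
                            h_range = c(3, 9),
                            prescription_gy = 36,
                            penumbra_range = c(0.6, 1.0),
                            sigmoid_width_range = c(8, 12),
                            noise_sd = 0.05,
                            delta_mm = 3,
                            seed = 1L) {
  if (n_patients < 2) stop("`n_patients` must be at least 2", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  for (p in seq_len(n_patients)) {
    penumbra <- stats::runif(1, penumbra_range[1L], penumbra_range[2L])
    for (ov in seq_len(overlaps_per_patient)) {
      h <- stats::runif(1, h_range[1L], h_range[2L])
      sw <- stats::runif(1, sigmoid_width_range[1L], sigmoid_width_range[2L])
      for (tech in techniques) {
        mseed <- as.integer((seed * 1009L + p * 97L + ov * 13L +
                               match(tech, techniques)) %% .Machine$integer.max)
        model <- make_junction(tech, h = h, prescription_gy = prescription_gy,
                               penumbra_width = penumbra, sigmoid_width = sw,
                               noise_sd = noise_sd, seed = mseed)
        ov_spec <- overlap_spec(
          profile_to_dvh(model, "upper"),
          profile_to_dvh(model, "lower"),
          h = h, prescription_gy = prescription_gy,
          label = sprintf("P%02d_ov%d_%s", p, ov, tech)
        )
        ores <- compute_ori(ov_spec)
        ires <- inhomogeneity_ratio(model, delta_mm = delta_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          patient = p, overlap = ov, technique = tech,
          h = h, penumbra = penumbra,
          n_steps = ifelse(is.na(model$n_steps), NA_integer_, model$n_steps),
          f_lin = ores$f_lin, f_grad = ores$f_grad, ori = ores$ori,
          ir = ires$ir_worst, ir_plus = ires$ir_plus, ir_minus = ires$ir_minus,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
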
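#' Pair two adjacent arc-set DVHs into an overlap specification
#'
#' An overlap (field junction) of a multi-isocenter VMAT plan is
#' irradiated by exactly two adjacent arc sets. The robustness index is
#' computed from their cumulative DVHs inside the overlap structure,
#' together with the overlap length `h` and the prescription dose.
#'
#' The overlap volume is treated as a cylinder of radius `r` and length
#' `h`; the cross-section cancels between the evaluated and the
#' reference overlap, so no radius is required.
#'
#' @param upper,lower [dvh_curve()] objects of the two adjacent arc
#'   sets (cranial and caudal contributors to the junction).
#' @param h Overlap length in cm.
#' @param prescription_gy Prescription dose in Gy. Defaults to the dose
#'   recorded on the curves when they agree.
#' @param label Overlap label, e.g. `"PTV_upperOverlap"`.
#' @param reference_length Length in cm of the ideal reference overlap
#'   against which the dose gradient is normalised. Default 9, a typical
#'   extended overlap in clinical use. ORI values are only comparable
#'   between plans evaluated at the same reference length.
#' @return An `overlap_spec` object.
#' @export
overlap_spec <- function(upper, lower, h, prescription_gy = NULL,
                         label = "overlap", reference_length = 9) {
  stopifnot(inherits(upper, "dvh_curve"), inherits(lower, "dvh_curve"))
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("`h` (overlap length, cm) must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(reference_length) || length(reference_length) != 1L ||
      reference_length <= 0) {
    stop("`reference_length` must be a single positive number", call. = FALSE)
  }
  if (is.null(prescription_gy)) {
    cand <- stats::na.omit(c(upper$prescription_gy, lower$prescription_gy))
    if (!length(cand)) {
      stop("prescription dose unknown; supply `prescription_gy`", call. = FALSE)
    }
    if (length(unique(cand)) > 1L) {
      stop("the two curves record different prescription doses; supply `prescription_gy`",
           call. = FALSE)
    }
    prescription_gy <- cand[1L]
  }
  if (prescription_gy <= 0) stop("`prescription_gy` must be positive", call. = FALSE)
  structure(
    list(label = as.character(label)[1L],
         h = as.numeric(h),
         prescription_gy = as.numeric(prescription_gy),
         reference_length = as.numeric(reference_length),
         arcs = list(upper = upper, lower = lower)),
    class = "overlap_spec"
  )
}

#' @export
print.overlap_spec <- function(x, ...) {
  cat(sprintf("<overlap_spec> %s: h = %g cm, prescription %g Gy (reference %g cm)\n",
              x$label, x$h, x$prescription_gy, x$reference_length))
  cat(sprintf("  arc sets: %s, %s\n", x$arcs$upper$arc_set, x$arcs$lower$arc_set))
  invisible(x)
}

# Bin indices over which slopes and fits are taken.
# "falling" excludes the 100% plateau and the zero tail, which would
# otherwise bias the fitted slope toward zero; "full" keeps every bin.
support_bins <- function(curve, support = c("falling", "full"), range = NULL) {
  if (is.numeric(support) || !is.null(range)) {
    rng <- if (!is.null(range)) range else support
    stopifnot(length(rng) == 2L, rng[1L] < rng[2L])
    idx <- which(curve$dose >= rng[1L] & curve$dose <= rng[2L])
  } else {
    support <- match.arg(support)
    idx <- switch(support,
      full = seq_along(curve$dose),
      falling = which(curve$volume > 0.1 & curve$volume < 99.9)
    )
    # keep one flanking bin on each side so the branch endpoints are
    # represented and central differences exist at the edges; a cliff
    # that never samples the open interval falls back to the full curve
    if (length(idx)) {
      idx <- seq(max(1L, min(idx) - 1L), min(length(curve$dose), max(idx) + 1L))
    } else {
      idx <- seq_along(curve$dose)
    }
  }
  if (length(idx) < 3L) {
    stop("support contains fewer than 3 bins", call. = FALSE)
  }
  idx
}

#' Distribution of the DVH slope over a dose range
#'
#' Central finite differences of cumulative volume with respect to dose
#' on a uniform grid, summarised by their median and root-mean-square.
#' Slopes are negative on the falling branch of a valid cumulative DVH
#' and are kept signed.
#'
#' @param curve A [dvh_curve()] on a uniform dose grid (see
#'   [resample_dvh()]); non-uniform grids are resampled first.
#' @param support `"falling"` (default: bins with 0.1\% < V < 99.9\%),
#'   `"full"`, or a numeric `c(lo, hi)` dose range.
#' @param bin_width Resampling bin width when the input grid is not
#'   uniform.
#' @param max_drop Largest tolerated volume drop (\% points) between
#'   adjacent bins. A cliff steeper than this (e.g. a step DVH of a
#'   uniform dose) has no meaningful finite-difference slope and raises
#'   an error. Default 50.
#' @return A `slope_distribution` object: per-bin `slopes` (\%/Gy),
#'   `median_slope`, `rms_slope`, and the `support` dose range used.
#' @export
slope_distribution <- function(curve, support = "falling",
                               bin_width = 0.05, max_drop = 50) {
  stopifnot(inherits(curve, "dvh_curve"))
  steps <- diff(curve$dose)
  if (max(steps) - min(steps) > 1e-8 * max(steps)) {
    curve <- resample_dvh(curve, bin_width)
  }
  idx <- support_bins(curve, support)
  d <- curve$dose[idx]
  v <- curve$volume[idx]
  drops <- -diff(v)
  if (any(drops > max_drop)) {
    stop(sprintf(
      "volume drops by %.3g%% within one bin (cap %g%%): slope is not resolved at this bin width",
      max(drops), max_drop), call. = FALSE)
  }
  n <- length(d)
  slopes <- numeric(n)
  slopes[1L] <- (v[2L] - v[1L]) / (d[2L] - d[1L])
  slopes[n] <- (v[n] - v[n - 1L]) / (d[n] - d[n - 1L])
  mid <- 2:(n - 1L)
  slopes[mid] <- (v[mid + 1L] - v[mid - 1L]) / (d[mid + 1L] - d[mid - 1L])
  structure(
    list(slopes = slopes,
         median_slope = stats::median(slopes),
         rms_slope = sqrt(mean(slopes^2)),
         support = range(d)),
    class = "slope_distribution"
  )
}

#' @export
print.slope_distribution <- function(x, ...) {
  cat(sprintf("<slope_distribution> %d bins on dose [%.3g, %.3g]\n",
              length(x$slopes), x$support[1L], x$support[2L]))
  cat(sprintf("  median = %.4g %%/Gy, RMS = %.4g %%/Gy\n",
              x$median_slope, x$rms_slope))
  invisible(x)
}

#' Straight-line fit to a cumulative DVH
#'
#' Ordinary least squares of \%volume on dose over the chosen support:
#' `V(D) = slope * D + b`. An ideal ramp-like arc-set DVH is exactly
#' linear; the fit slope, its coefficient of determination and the
#' median finite-difference slope together quantify how far a real
#' curve departs from that ideal.
#'
#' @inheritParams slope_distribution
#' @return A `linear_fit_result`: `fit_slope` (\%/Gy), `intercept`
#'   (\%), `r_squared`, 95\% confidence intervals `ci95_slope`,
#'   `ci95_intercept`, and the `support` dose range.
#' @export
fit_linear <- function(curve, support = "falling", bin_width = 0.05) {
  stopifnot(inherits(curve, "dvh_curve"))
  steps <- diff(curve$dose)
  if (max(steps) - min(steps) > 1e-8 * max(steps)) {
    curve <- resample_dvh(curve, bin_width)
  }
  idx <- support_bins(curve, support)
  d <- curve$dose[idx]
  v <- curve$volume[idx]
  if (stats::sd(d) == 0) stop("degenerate support: constant dose", call. = FALSE)
  fit <- stats::lm(v ~ d)
  # exact ramps fit perfectly; summary()'s reliability warning does not
  # apply to the slope/R^2 read-outs used here
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  r2 <- sm$r.squared
  structure(
    list(fit_slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         ci95_slope = unname(ci[2L, ]),
         ci95_intercept = unname(ci[1L, ]),
         support = range(d)),
    class = "linear_fit_result"
  )
}

#' @export
print.linear_fit_result <- function(x, ...) {
  cat(sprintf("<linear_fit_result> V = %.4g * D + %.4g on dose [%.3g, %.3g]\n",
              x$fit_slope, x$intercept, x$support[1L], x$support[2L]))
  cat(sprintf("  R^2 = %.4f; slope 95%% CI (%.4g, %.4g)\n",
              x$r_squared, x$ci95_slope[1L], x$ci95_slope[2L]))
  invisible(x)
}

#' Per-arc linear coefficient
#'
#' `f_lin_i = R^2 * median_slope / fit_slope`: the coefficient of
#' determination of the straight-line DVH fit, weighted by the ratio of
#' the median finite-difference slope to the fitted slope. Equal to 1
#' for a perfectly linear ramp-like DVH; below 1 when shallow- and
#' steep-sloped DVH regions coexist (sigmoid-like curves of
#' conventional fixed-overlap junctions).
#'
#' @param fit A `linear_fit_result` from [fit_linear()].
#' @param dist A `slope_distribution` from [slope_distribution()].
#' @return The per-arc linear coefficient (positive scalar).
#' @export
f_lin_arc <- function(fit, dist) {
  stopifnot(inherits(fit, "linear_fit_result"),
            inherits(dist, "slope_distribution"))
  if (fit$fit_slope == 0) stop("zero fitted slope", call. = FALSE)
  if (fit$fit_slope > 0 || dist$median_slope > 0) {
    stop("rising DVH branch: fitted and median slopes must both be negative",
         call. = FALSE)
  }
  fit$r_squared * dist$median_slope / fit$fit_slope
}

#' Per-arc linear coefficient from reported fit summaries
#'
#' Same quantity as [f_lin_arc()] computed from the three scalar
#' summaries directly, for re-evaluating published per-arc results
#' (fit slope, median DVH slope, coefficient of determination) without
#' access to the underlying curves.
#'
#' @param r_squared Coefficient of determination of the straight-line
#'   DVH fit, in \[0, 1\].
#' @param median_slope Median DVH slope, \%/Gy (negative).
#' @param fit_slope Fitted DVH slope, \%/Gy (negative).
#' @return The per-arc linear coefficient.
#' @export
#' @examples
#' f_lin_from_summary(0.94, -2.10, -3.85)  # ~0.51
f_lin_from_summary <- function(r_squared, median_slope, fit_slope) {
  stopifnot(r_squared >= 0, r_squared <= 1)
  if (fit_slope == 0) stop("zero fitted slope", call. = FALSE)
  if (fit_slope > 0 || median_slope > 0) {
    stop("rising DVH branch: fitted and median slopes must both be negative",
         call. = FALSE)
  }
  r_squared * median_slope / fit_slope
}

#' Linear coefficient of an overlap
#'
#' Arithmetic mean of the per-arc coefficients [f_lin_arc()] of the two
#' adjacent arc sets.
#'
#' @param overlap An [overlap_spec()].
#' @param support,bin_width Passed to [fit_linear()] and
#'   [slope_distribution()].
#' @return The overlap linear coefficient `f_lin`.
#' @export
f_lin <- function(overlap, support = "falling", bin_width = 0.05) {
  stopifnot(inherits(overlap, "overlap_spec"))
  mean(vapply(overlap$arcs, function(curve) {
    f_lin_arc(fit_linear(curve, support, bin_width),
              slope_distribution(curve, support, bin_width))
  }, numeric(1)))
}

#' Gradient coefficient of an overlap
#'
#' Ratio of the average DVH slope of the two adjacent arc sets over the
#' evaluated overlap of length `h` to the theoretical slope of an arc
#' set forming an ideal `reference_length` (default 9 cm) overlap with
#' a perfect linear-ramp DVH spanning zero to the prescription dose.
#' With the overlap treated as a cylinder the cross-section cancels,
#' leaving
#' \deqn{f_{grad} = \frac{h \, D_{pr}}{2 L_{ref}} \sum_{i=1}^{2}
#'   \frac{1}{D2\%_i - D98\%_i}}
#' which is 1 for two full-range ramps over a 9 cm overlap, grows
#' linearly with `h`, and shrinks as the per-arc D2\%-D98\% span widens.
#' Values above 1 are possible for `h` above the reference length; they
#' are reported as-is with a warning (the index is not normalised to 1).
#'
#' @param overlap An [overlap_spec()].
#' @return The gradient coefficient `f_grad`.
#' @export
f_grad <- function(overlap) {
  stopifnot(inherits(overlap, "overlap_spec"))
  dpr <- overlap$prescription_gy
  spans <- vapply(overlap$arcs, function(curve) {
    m_dpr <- if (curve$dose_units == "relative_pct") 100 else dpr
    d2 <- dose_at_volume(curve, 2)
    d98 <- dose_at_volume(curve, 98)
    if (d2 <= d98) {
      stop(sprintf("arc set %s: D2%% <= D98%% (non-falling DVH)", curve$arc_set),
           call. = FALSE)
    }
    # span expressed as a fraction of the prescription so mixed unit
    # systems cancel identically
    (d2 - d98) / m_dpr
  }, numeric(1))
  out <- overlap$h / (2 * overlap$reference_length) * sum(1 / spans)
  if (out > 1) {
    warning("f_grad exceeds 1 (overlap longer than the reference length); ",
            "the index is not normalised to 1", call. = FALSE)
  }
  out
}

#' Overlap Robustness Index
#'
#' The ORI of a field junction is the product of the linear coefficient
#' [f_lin()] (how ramp-like the two adjacent arc-set DVHs are) and the
#' gradient coefficient [f_grad()] (the junction dose gradient
#' normalised to an ideal 9 cm overlap). Two exact full-range ramp DVHs
#' over a 9 cm overlap give ORI = 1; steep or sigmoid-like junction
#' falloffs give values well below 1 and mark plans vulnerable to
#' longitudinal setup errors.
#'
#' @param overlap An [overlap_spec()].
#' @param support,bin_width Fit and slope support, see [fit_linear()].
#' @return An `ori_result`: per-arc fits, slope distributions, linear
#'   coefficients and D2\%/D98\% values, plus `f_lin`, `f_grad` and
#'   `ori`.
#' @export
#' @examples
#' d <- seq(0, 36, by = 0.05)
#' ramp <- dvh_curve(d, pmax(0, 100 * (1 - d / 36)), prescription_gy = 36)
#' ov <- overlap_spec(ramp, ramp, h = 9, label = "ideal")
#' compute_ori(ov)$ori   # 1
compute_ori <- function(overlap, support = "falling", bin_width = 0.05) {
  stopifnot(inherits(overlap, "overlap_spec"))
  per_arc <- lapply(overlap$arcs, function(curve) {
    fit <- fit_linear(curve, support, bin_width)
    dist <- slope_distribution(curve, support, bin_width)
    m_dpr <- if (curve$dose_units == "relative_pct") 100 else overlap$prescription_gy
    list(arc_set = curve$arc_set,
         linear_fit = fit,
         slope_dist = dist,
         f_lin_i = f_lin_arc(fit, dist),
         d2 = dose_at_volume(curve, 2),
         d98 = dose_at_volume(curve, 98),
         span_frac = (dose_at_volume(curve, 2) - dose_at_volume(curve, 98)) / m_dpr)
  })
  flin <- mean(vapply(per_arc, `[[`, numeric(1), "f_lin_i"))
  fgrad <- f_grad(overlap)
  structure(
    list(label = overlap$label,
         h = overlap$h,
         prescription_gy = overlap$prescription_gy,
         reference_length = overlap$reference_length,
         per_arc = per_arc,
         f_lin = flin,
         f_grad = fgrad,
         ori = flin * fgrad),
    class = "ori_result"
  )
}

#' @export
print.ori_result <- function(x, ...) {
  cat(sprintf("<ori_result> %s (h = %g cm, %g Gy)\n",
              x$label, x$h, x$prescription_gy))
  for (pa in x$per_arc) {
    cat(sprintf("  arc %-4s fit %7.3f %%/Gy  R^2 %.3f  median %7.3f  f_lin_i %.3f  D2 %.2f  D98 %.2f\n",
                pa$arc_set, pa$linear_fit$fit_slope, pa$linear_fit$r_squared,
                pa$slope_dist$median_slope, pa$f_lin_i, pa$d2, pa$d98))
  }
  cat(sprintf("  f_lin = %.3f   f_grad = %.3f   ORI = %.3f\n",
              x$f_lin, x$f_grad, x$ori))
  invisible(x)
}
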
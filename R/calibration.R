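#' Inhomogeneity Ratio thresholds from dose-ratio tolerances
#'
#' Converts hot/cold dose-percentage tolerances on the shifted
#' D2\%/D98\% ratio into Inhomogeneity Ratio thresholds by dividing
#' each shifted ratio by the nominal (unshifted) one. With the nominal
#' ratio 105\%/95\%, a tolerated shifted ratio of 110\%/90\% (the
#' accepted 5\% delivery accuracy of external beam radiotherapy) gives
#' an IR tolerance limit of 1.11, and an action ratio of 125\%/90\%
#' (the spinal-cord D2\% tolerance at the 125\% relative isodose) gives
#' an IR action limit of 1.26.
#'
#' @param nominal Hot/cold percentages of the unshifted D2\%/D98\%
#'   ratio, default `c(105, 95)`.
#' @param tolerance Hot/cold percentages tolerated after the shift,
#'   default `c(110, 90)`.
#' @param action Hot/cold percentages triggering action, default
#'   `c(125, 90)`.
#' @return A list with `ir_tolerance` and `ir_action`.
#' @export
#' @examples
#' ir_thresholds()  # 1.11 and 1.26 at two decimals
ir_thresholds <- function(nominal = c(105, 95),
                          tolerance = c(110, 90),
                          action = c(125, 90)) {
  ratio <- function(p) {
    if (any(p <= 0)) stop("percentages must be positive", call. = FALSE)
    p[1L] / p[2L]
  }
  nom <- ratio(nominal)
  list(ir_tolerance = ratio(tolerance) / nom,
       ir_action = ratio(action) / nom)
}

#' Fit the power relationship between ORI and IR
#'
#' Fits `ori = a * ir^b` to paired (IR, ORI) observations by
#' untransformed nonlinear least squares, initialised from the log-log
#' straight-line fit. A decreasing relationship (`b < 0`) is expected:
#' junctions whose homogeneity degrades more under a setup shift carry
#' lower robustness indices.
#'
#' @param ir,ori Numeric vectors of paired positive observations, or a
#'   data frame with columns `ir` and `ori` passed as the first
#'   argument.
#' @param objective `"natural"` (default) minimises untransformed
#'   residuals; `"log"` minimises log-scale residuals (equivalent to
#'   the log-log linear fit).
#' @return A `limit_calibration`: `a`, `b`, standard errors `a_se`,
#'   `b_se`, `r_squared` (natural scale), the fitted points, and slots
#'   for thresholds/limits filled by [ori_limit()].
#' @export
fit_power <- function(ir, ori = NULL, objective = c("natural", "log")) {
  objective <- match.arg(objective)
  if (is.data.frame(ir)) {
    if (!all(c("ir", "ori") %in% names(ir))) {
      stop("data frame input needs columns `ir` and `ori`", call. = FALSE)
    }
    ori <- ir$ori
    ir <- ir$ir
  }
  if (length(ir) != length(ori)) stop("`ir` and `ori` lengths differ", call. = FALSE)
  keep <- stats::complete.cases(ir, ori)
  ir <- ir[keep]; ori <- ori[keep]
  if (length(ir) < 3L) stop("at least 3 points are required", call. = FALSE)
  if (any(ir <= 0) || any(ori <= 0)) {
    stop("all IR and ORI values must be positive", call. = FALSE)
  }
  loglog <- stats::lm(log(ori) ~ log(ir))
  start <- list(a = exp(unname(stats::coef(loglog)[1L])),
                b = unname(stats::coef(loglog)[2L]))
  if (objective == "log") {
    sm <- summary(loglog)
    a <- start$a; b <- start$b
    a_se <- a * sm$coefficients[1L, 2L]  # delta method on exp(intercept)
    b_se <- sm$coefficients[2L, 2L]
  } else {
    fit <- minpack.lm::nlsLM(ori ~ a * ir^b, start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- summary(fit)$coefficients
    a <- cf["a", "Estimate"]; b <- cf["b", "Estimate"]
    a_se <- cf["a", "Std. Error"]; b_se <- cf["b", "Std. Error"]
  }
  pred <- a * ir^b
  r2 <- 1 - sum((ori - pred)^2) / sum((ori - mean(ori))^2)
  structure(
    list(a = a, b = b, a_se = a_se, b_se = b_se,
         r_squared = r2, objective = objective,
         points = data.frame(ir = ir, ori = ori),
         ir_tolerance = NA_real_, ir_action = NA_real_,
         ori_tolerance = NA_real_, ori_action = NA_real_),
    class = "limit_calibration"
  )
}

#' Build a calibration directly from known power-law parameters
#'
#' Useful for evaluating published fit parameters without refitting.
#'
#' @param a,b Power-law parameters of `ori = a * ir^b`.
#' @return A `limit_calibration` with empty point set.
#' @export
power_calibration <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  structure(
    list(a = a, b = b, a_se = NA_real_, b_se = NA_real_,
         r_squared = NA_real_, objective = "given",
         points = data.frame(ir = numeric(0), ori = numeric(0)),
         ir_tolerance = NA_real_, ir_action = NA_real_,
         ori_tolerance = NA_real_, ori_action = NA_real_),
    class = "limit_calibration"
  )
}

round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' ORI limit corresponding to an IR threshold
#'
#' Evaluates the fitted power relationship at an IR threshold and
#' rounds to one decimal (half away from zero), the reporting precision
#' of QA limits. With `b < 0` the limit decreases as the IR threshold
#' grows, so the tolerance limit always exceeds the action limit.
#'
#' @param cal A `limit_calibration` from [fit_power()] or
#'   [power_calibration()].
#' @param ir_threshold IR threshold (e.g. from [ir_thresholds()]).
#' @param digits Reported decimals, default 1.
#' @return The rounded ORI limit.
#' @export
#' @examples
#' cal <- power_calibration(a = 1.45, b = -6.02)
#' ori_limit(cal, 1.11)  # 0.8
#' ori_limit(cal, 1.26)  # 0.4
ori_limit <- function(cal, ir_threshold, digits = 1L) {
  stopifnot(inherits(cal, "limit_calibration"))
  if (is.na(cal$a) || is.na(cal$b)) stop("calibration is not fitted", call. = FALSE)
  if (ir_threshold <= 0) stop("`ir_threshold` must be positive", call. = FALSE)
  round_half_away(cal$a * ir_threshold^cal$b, digits)
}

#' Derive both ORI limits for a calibration
#'
#' Convenience wrapper: computes the IR thresholds from dose-ratio
#' tolerances and fills the `ori_tolerance` / `ori_action` slots of the
#' calibration.
#'
#' @param cal A `limit_calibration`.
#' @param thresholds Output of [ir_thresholds()] (or a compatible
#'   list).
#' @return The calibration with all four threshold/limit slots filled.
#' @export
calibrate_limits <- function(cal, thresholds = ir_thresholds()) {
  stopifnot(inherits(cal, "limit_calibration"))
  cal$ir_tolerance <- thresholds$ir_tolerance
  cal$ir_action <- thresholds$ir_action
  cal$ori_tolerance <- ori_limit(cal, thresholds$ir_tolerance)
  cal$ori_action <- ori_limit(cal, thresholds$ir_action)
  cal
}

#' @export
print.limit_calibration <- function(x, ...) {
  cat("<limit_calibration> ori = a * ir^b\n")
  cat(sprintf("  a = %.4g (se %.3g), b = %.4g (se %.3g)",
              x$a, x$a_se, x$b, x$b_se))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 = %.3f", x$r_squared))
  cat(sprintf("\n  %d points; objective: %s\n", nrow(x$points), x$objective))
  if (!is.na(x$ori_tolerance)) {
    cat(sprintf("  IR tolerance %.2f -> ORI tolerance %.1f\n",
                x$ir_tolerance, x$ori_tolerance))
    cat(sprintf("  IR action    %.2f -> ORI action    %.1f\n",
                x$ir_action, x$ori_action))
  }
  invisible(x)
}

#' Rank and paired statistics of a junction cohort
#'
#' Summarises a paired cohort of overlaps evaluated with two junction
#' techniques: Spearman rank correlation between ORI and IR across all
#' observations; a paired two-sided Wilcoxon signed-rank test per
#' metric between the techniques (exact distribution for n <= 25,
#' zero differences dropped); a Kolmogorov-Smirnov-type normality test
#' per metric (Lilliefors correction, since mean and sd are estimated);
#' and median/min/max per technique.
#'
#' @param cohort Data frame with columns `patient`, `overlap`,
#'   `technique`, `ori`, `ir` (as returned by [cohort_generate()]).
#' @param metrics Metric columns summarised and tested. Default
#'   `c("ori", "ir")`.
#' @param normality `"lilliefors"` (default) or `"ks"` (plain KS on
#'   standardised values).
#' @return A `cohort_stats` object.
#' @export
cohort_statistics <- function(cohort, metrics = c("ori", "ir"),
                              normality = c("lilliefors", "ks")) {
  normality <- match.arg(normality)
  need <- c("patient", "overlap", "technique", metrics)
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  techs <- sort(unique(cohort$technique))
  if (length(techs) != 2L) {
    stop("exactly two techniques are required for paired tests", call. = FALSE)
  }
  key <- interaction(cohort$patient, cohort$overlap, drop = TRUE)
  sp <- suppressWarnings(
    stats::cor.test(cohort$ori, cohort$ir, method = "spearman", exact = FALSE))
  norm_test <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)  # degenerate: all tied
    if (normality == "lilliefors") nortest::lillie.test(x)$p.value
    else suppressWarnings(stats::ks.test(scale(x), "pnorm")$p.value)
  }
  wilcox_p <- normality_p <- stats::setNames(numeric(length(metrics)), metrics)
  summaries <- list()
  for (m in metrics) {
    a <- cohort[[m]][cohort$technique == techs[1L]]
    b <- cohort[[m]][cohort$technique == techs[2L]]
    ka <- key[cohort$technique == techs[1L]]
    kb <- key[cohort$technique == techs[2L]]
    if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb)) {
      stop("observations are not paired one-to-one across techniques", call. = FALSE)
    }
    b <- b[match(ka, kb)]
    d <- a - b
    if (all(d == 0)) {
      wilcox_p[m] <- NA_real_  # all-zero differences: no-difference outcome
    } else {
      wilcox_p[m] <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE,
                           exact = length(d[d != 0]) <= 25))$p.value
    }
    normality_p[m] <- norm_test(cohort[[m]])
    summaries[[m]] <- do.call(rbind, lapply(techs, function(tt) {
      x <- cohort[[m]][cohort$technique == tt]
      data.frame(technique = tt, median = stats::median(x),
                 min = min(x), max = max(x))
    }))
  }
  structure(
    list(spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
         wilcoxon_p = wilcox_p, normality_p = normality_p,
         normality_test = normality,
         summaries = summaries, techniques = techs,
         n_pairs = length(unique(key))),
    class = "cohort_stats"
  )
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats> %d paired overlaps, techniques: %s\n",
              x$n_pairs, paste(x$techniques, collapse = " vs ")))
  cat(sprintf("  Spearman(ORI, IR): r = %.3f, p = %.3g\n",
              x$spearman_r, x$spearman_p))
  for (m in names(x$wilcoxon_p)) {
    cat(sprintf("  %s: Wilcoxon p = %.3g, normality (%s) p = %.3g\n",
                m, x$wilcoxon_p[m], x$normality_test, x$normality_p[m]))
    s <- x$summaries[[m]]
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-10s median %.3f  range [%.3f, %.3f]\n",
                  s$technique[i], s$median[i], s$min[i], s$max[i]))
    }
  }
  invisible(x)
}
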
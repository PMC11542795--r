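#' Cumulative dose-volume histogram for one structure and one arc set
#'
#' Constructs and validates a cumulative DVH: the percentage of a
#' structure's volume receiving at least each dose. Cumulative (not
#' differential) curves are the canonical representation throughout the
#' package, because the linear coefficient of the robustness index is
#' defined by a straight-line fit of \%volume against dose.
#'
#' Small monotonicity violations of the volume column (typical of
#' text exports that round to a fixed number of decimals) are repaired by
#' cumulative-max enforcement when they do not exceed `repair_tol`;
#' larger violations are treated as corrupt input and raise an error.
#'
#' @param dose Numeric vector of dose grid values, strictly increasing,
#'   non-negative. Units per `dose_units`.
#' @param volume Numeric vector of cumulative volume (\% of structure
#'   volume), same length as `dose`, values in \[0, 100\].
#' @param structure Structure label (e.g. `"PTV_upperOverlap"`).
#' @param arc_set Arc-set label (e.g. `"US"`, `"MS"`, `"UD"`, `"MD"`).
#' @param dose_units `"absolute_gy"` or `"relative_pct"` (\% of the
#'   prescription dose).
#' @param prescription_gy Prescription dose in Gy. Required when
#'   `dose_units = "relative_pct"`; optional otherwise.
#' @param repair_tol Largest volume increase (\% points) repaired
#'   silently by cumulative-max enforcement. Default 0.01.
#'
#' @return An object of class `dvh_curve`.
#' @seealso [read_dvh()], [dvh_metrics()], [dose_at_volume()]
#' @export
#' @examples
#' ramp <- dvh_curve(seq(0, 36, by = 0.5), pmax(0, 100 * (1 - seq(0, 36, by = 0.5) / 36)),
#'                   structure = "PTV_overlap", arc_set = "US")
#' dvh_metrics(ramp)
dvh_curve <- function(dose, volume,
                      structure = "structure", arc_set = "arc",
                      dose_units = c("absolute_gy", "relative_pct"),
                      prescription_gy = NULL,
                      repair_tol = 0.01) {
  dose_units <- match.arg(dose_units)
  if (!is.numeric(dose) || !is.numeric(volume)) {
    stop("`dose` and `volume` must be numeric vectors", call. = FALSE)
  }
  if (length(dose) != length(volume)) {
    stop("`dose` and `volume` must have the same length", call. = FALSE)
  }
  if (length(dose) < 2L) {
    stop("a DVH needs at least two dose bins", call. = FALSE)
  }
  if (anyNA(dose) || anyNA(volume)) {
    stop("DVH columns must not contain missing values", call. = FALSE)
  }
  if (any(dose < 0)) stop("dose grid must be non-negative", call. = FALSE)
  if (any(diff(dose) <= 0)) {
    stop("dose grid must be strictly increasing", call. = FALSE)
  }
  if (any(volume < -repair_tol) || any(volume > 100 + repair_tol)) {
    stop("volume values outside [0, 100] beyond tolerance", call. = FALSE)
  }
  volume <- pmin(pmax(volume, 0), 100)
  inc <- diff(volume)
  if (any(inc > repair_tol)) {
    stop(sprintf(
      "volume increases by up to %.4g%% along the dose axis (tolerance %g); not a cumulative DVH",
      max(inc), repair_tol), call. = FALSE)
  }
  # repair sub-tolerance wiggles: running minimum keeps the curve cumulative
  volume <- cummin(volume)
  if (identical(dose_units, "relative_pct") && is.null(prescription_gy)) {
    stop("`prescription_gy` is required for relative-dose DVHs", call. = FALSE)
  }
  if (!is.null(prescription_gy) &&
      (!is.numeric(prescription_gy) || length(prescription_gy) != 1L ||
       prescription_gy <= 0)) {
    stop("`prescription_gy` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      structure = as.character(structure)[1L],
      arc_set = as.character(arc_set)[1L],
      dose = as.numeric(dose),
      volume = as.numeric(volume),
      dose_units = dose_units,
      prescription_gy = if (is.null(prescription_gy)) NA_real_ else as.numeric(prescription_gy)
    ),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  unit <- if (x$dose_units == "absolute_gy") "Gy" else "% of prescription"
  cat(sprintf("<dvh_curve> %s / arc set %s\n", x$structure, x$arc_set))
  cat(sprintf("  %d bins, dose %.4g-%.4g %s, volume %.4g-%.4g %%\n",
              length(x$dose), min(x$dose), max(x$dose), unit,
              min(x$volume), max(x$volume)))
  if (!is.na(x$prescription_gy)) {
    cat(sprintf("  prescription: %.4g Gy\n", x$prescription_gy))
  }
  invisible(x)
}

#' Read a cumulative DVH from a self-describing TSV file
#'
#' The expected dialect is plain text with `#`-prefixed header lines
#' declaring `structure`, `arc_set`, `dose_units` and (for relative-dose
#' curves) `prescription_gy`, followed by a two-column table `dose`,
#' `volume_pct`. [write_dvh()] produces this dialect, so round-tripping
#' is lossless. Vendor DVH exports can be converted by prepending the
#' header lines.
#'
#' @param path Path to the DVH text file.
#' @param repair_tol Monotonicity repair tolerance, see [dvh_curve()].
#' @return A validated [dvh_curve()].
#' @export
#' @examples
#' # synthetic example curve shipped with the package
#' f <- system.file("extdata", "synthetic_sigmoid_US.tsv", package = "oriqa")
#' dvh_metrics(read_dvh(f))
read_dvh <- function(path, repair_tol = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^\\s*#", lines)
  hdr <- lines[hdr_idx]
  keys <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", h))[[1L]]
    if (length(m) == 3L) keys[[m[2L]]] <- m[3L]
  }
  required <- c("structure", "arc_set", "dose_units")
  missing_keys <- setdiff(required, names(keys))
  if (length(missing_keys)) {
    stop("DVH header is missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.table(text = body, header = TRUE,
                           colClasses = "numeric", sep = "")
  if (!all(c("dose", "volume_pct") %in% names(tab))) {
    stop("DVH table must have columns `dose` and `volume_pct`", call. = FALSE)
  }
  dvh_curve(
    dose = tab$dose, volume = tab$volume_pct,
    structure = keys$structure, arc_set = keys$arc_set,
    dose_units = keys$dose_units,
    prescription_gy = if (!is.null(keys$prescription_gy)) as.numeric(keys$prescription_gy),
    repair_tol = repair_tol
  )
}

#' Write a cumulative DVH in the package's TSV dialect
#'
#' @param curve A [dvh_curve()].
#' @param path Output file path.
#' @param digits Decimal places written for both columns (fixed-notation
#'   output keeps generated fixtures byte-identical across platforms).
#' @return `path`, invisibly.
#' @export
write_dvh <- function(curve, path, digits = 6L) {
  stopifnot(inherits(curve, "dvh_curve"))
  hdr <- c(
    paste0("# structure: ", curve$structure),
    paste0("# arc_set: ", curve$arc_set),
    paste0("# dose_units: ", curve$dose_units),
    if (!is.na(curve$prescription_gy))
      paste0("# prescription_gy: ", formatC(curve$prescription_gy, format = "f", digits = 4L))
  )
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  body <- paste(fmt(curve$dose), fmt(curve$volume), sep = "\t")
  writeLines(c(hdr, "dose\tvolume_pct", body), path)
  invisible(path)
}

#' Dose received by at least a given percentage of the volume
#'
#' Reads Dx\% metrics (the minimum dose received by the hottest `v`\% of
#' the structure) off a cumulative DVH. Dose is linearly interpolated as
#' a function of cumulative volume on the falling segment bracketing
#' `v`. When `v` coincides with a volume plateau the highest dose of the
#' plateau is returned, which is the conservative choice for D2-type
#' hot-spot metrics.
#'
#' @param curve A [dvh_curve()].
#' @param v Target cumulative volume in percent, within the volume range
#'   attained by the curve.
#' @return Dose in the curve's dose units.
#' @export
#' @examples
#' d <- seq(0, 36, by = 0.1)
#' ramp <- dvh_curve(d, pmax(0, 100 * (1 - d / 36)))
#' dose_at_volume(ramp, 2)   # 35.28
dose_at_volume <- function(curve, v) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
    stop("`v` must be a single volume percentage", call. = FALSE)
  }
  vol <- curve$volume
  dose <- curve$dose
  if (v > max(vol) || v < min(vol)) {
    stop(sprintf("volume level %g%% outside the curve's attained range [%g, %g]",
                 v, min(vol), max(vol)), call. = FALSE)
  }
  eps <- 1e-9
  on_plateau <- abs(vol - v) <= eps
  if (any(on_plateau)) {
    return(max(dose[on_plateau]))
  }
  # last bin with volume above v starts the falling segment that crosses it
  j <- max(which(vol > v))
  d0 <- dose[j]; d1 <- dose[j + 1L]
  v0 <- vol[j]; v1 <- vol[j + 1L]
  d0 + (v0 - v) / (v0 - v1) * (d1 - d0)
}

#' Coverage and homogeneity metrics of a cumulative DVH
#'
#' Computes D2\%, D98\%, D5\%, D95\%, the maximum dose, and the
#' Heterogeneity Index HI = D5\%/D95\% (unity for a perfectly
#' homogeneous dose). A volume level the curve does not attain (a
#' truncated export) yields `NA` for that metric; when D95\% is zero or
#' unattained the HI is undefined and returned as `NA` with
#' `hi_defined = FALSE`.
#'
#' @param curve A [dvh_curve()].
#' @return A `dvh_metrics` object (list with `d2`, `d98`, `d5`, `d95`,
#'   `dmax`, `hi`, `hi_defined`).
#' @export
dvh_metrics <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  dv <- function(v) tryCatch(dose_at_volume(curve, v),
                             error = function(e) NA_real_)
  d2 <- dv(2)
  d98 <- dv(98)
  d5 <- dv(5)
  d95 <- dv(95)
  dmax <- max(curve$dose[curve$volume > 0])
  hi_defined <- !is.na(d5) && !is.na(d95) && d95 > 0
  out <- list(
    structure = curve$structure, arc_set = curve$arc_set,
    d2 = d2, d98 = d98, d5 = d5, d95 = d95, dmax = dmax,
    hi = if (hi_defined) d5 / d95 else NA_real_,
    hi_defined = hi_defined
  )
  class(out) <- "dvh_metrics"
  out
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("<dvh_metrics> %s / %s\n", x$structure, x$arc_set))
  cat(sprintf("  D2%%=%.3f  D98%%=%.3f  D5%%=%.3f  D95%%=%.3f  Dmax=%.3f\n",
              x$d2, x$d98, x$d5, x$d95, x$dmax))
  cat(if (x$hi_defined) sprintf("  HI (D5%%/D95%%) = %.3f\n", x$hi)
      else "  HI undefined (D95% = 0)\n")
  invisible(x)
}

#' Resample a DVH onto a uniform dose grid
#'
#' Linear interpolation of cumulative volume onto an equally spaced dose
#' grid spanning the curve. Uniform bins are a precondition of the slope
#' distribution used by the robustness index, whose finite differences
#' assume constant bin width.
#'
#' @param curve A [dvh_curve()].
#' @param bin_width Bin width in the curve's dose units. Default 0.05
#'   (Gy), finer than any gradient feature the junction simulator
#'   produces.
#' @return A [dvh_curve()] on the uniform grid.
#' @export
resample_dvh <- function(curve, bin_width = 0.05) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a single positive number", call. = FALSE)
  }
  span <- max(curve$dose) - min(curve$dose)
  if (bin_width > span) {
    stop("`bin_width` exceeds the dose span of the curve", call. = FALSE)
  }
  grid <- seq(min(curve$dose), max(curve$dose), by = bin_width)
  if (grid[length(grid)] < max(curve$dose)) grid <- c(grid, max(curve$dose))
  vol <- stats::approx(curve$dose, curve$volume, xout = grid,
                       method = "linear", rule = 2)$y
  dvh_curve(grid, vol,
            structure = curve$structure, arc_set = curve$arc_set,
            dose_units = curve$dose_units,
            prescription_gy = if (is.na(curve$prescription_gy)) NULL else curve$prescription_gy)
}

#' Convert between absolute (Gy) and relative (\% of prescription) dose axes
#'
#' The robustness index is invariant under this rescaling because the
#' prescription dose and the D2\%-D98\% spans rescale together; the
#' conversions exist so curves from either convention can be mixed.
#'
#' @param curve A [dvh_curve()].
#' @param prescription_gy Prescription dose in Gy; defaults to the one
#'   recorded on the curve.
#' @return A [dvh_curve()] in the other unit system.
#' @export
to_relative <- function(curve, prescription_gy = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  dpr <- prescription_gy %||% curve$prescription_gy
  if (is.null(dpr) || is.na(dpr)) {
    stop("prescription dose unknown; supply `prescription_gy`", call. = FALSE)
  }
  if (curve$dose_units == "relative_pct") return(curve)
  dvh_curve(curve$dose / dpr * 100, curve$volume,
            structure = curve$structure, arc_set = curve$arc_set,
            dose_units = "relative_pct", prescription_gy = dpr)
}

#' @rdname to_relative
#' @export
to_absolute <- function(curve, prescription_gy = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  dpr <- prescription_gy %||% curve$prescription_gy
  if (is.null(dpr) || is.na(dpr)) {
    stop("prescription dose unknown; supply `prescription_gy`", call. = FALSE)
  }
  if (curve$dose_units == "absolute_gy") return(curve)
  dvh_curve(curve$dose * dpr / 100, curve$volume,
            structure = curve$structure, arc_set = curve$arc_set,
            dose_units = "absolute_gy", prescription_gy = dpr)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
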
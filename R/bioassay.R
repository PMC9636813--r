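#' DPPH radical scavenging capacity
#'
#' Computes `1 - (A2 - A0) / A1` from 517 nm absorbances, where `A0` is the
#' blank (no DPPH), `A1` the negative control and `A2` the test sample. The
#' result is a fraction (1 = complete scavenging, 0 = none); multiply by 100
#' at the reporting layer for percent. Returning fractions from the core
#' avoids silent x100 bugs even though assay protocols label the same
#' formula "(%)".
#'
#' The value is strictly decreasing in `A2`. It is invariant to scaling all
#' three absorbances by a common positive constant only when `A0 = 0`
#' (otherwise the blank offset breaks the homogeneity).
#'
#' @param A0 blank absorbance (without DPPH).
#' @param A1 negative-control absorbance; must be `> 0`.
#' @param A2 test-sample absorbance.
#' @return Scavenging fraction in `(-Inf, 1]`; vectorized.
#' @examples
#' dpph_scavenging(0.05, 0.80, 0.45)  # 0.5
#' @export
dpph_scavenging <- function(A0, A1, A2) {
  if (any(!is.finite(A0) | !is.finite(A1) | !is.finite(A2)) ||
      any(A0 < 0) || any(A2 < 0))
    stop("dpph_scavenging: absorbances must be finite and >= 0", call. = FALSE)
  if (any(A1 <= 0))
    stop("dpph_scavenging: negative-control absorbance A1 must be > 0", call. = FALSE)
  1 - (A2 - A0) / A1
}

#' Fit a FRAP calibration line
#'
#' Ordinary least squares of 593 nm absorbance on ferrous sulfate standard
#' concentration (umol/L). Warns when r-squared falls below `r2_floor`.
#'
#' @param concs standard concentrations, strictly increasing, `>= 3` points.
#' @param abs_values standard absorbances.
#' @param r2_floor warn if the calibration r-squared is below this
#'   (default 0.99).
#' @return Object of class `frap_calibration` with `slope`, `intercept`,
#'   `r_squared` and the standards.
#' @export
fit_frap_calibration <- function(concs, abs_values, r2_floor = 0.99) {
  if (length(concs) < 3)
    stop("fit_frap_calibration: need at least 3 calibration points", call. = FALSE)
  if (length(abs_values) != length(concs))
    stop("fit_frap_calibration: concs and abs_values lengths differ", call. = FALSE)
  if (any(diff(concs) <= 0))
    stop("fit_frap_calibration: concentrations must be strictly increasing", call. = FALSE)
  if (stats::sd(abs_values) == 0)
    stop("fit_frap_calibration: constant absorbances, singular fit", call. = FALSE)
  fit <- stats::lm(abs_values ~ concs)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((abs_values - mean(abs_values))^2)
  if (r2 < r2_floor)
    warning(sprintf("FRAP calibration r-squared %.4f below floor %.4f", r2, r2_floor))
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    warning("FRAP calibration slope is not positive; check standards")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, standard_concentrations = concs,
                 standard_absorbances = abs_values, fit = fit),
            class = "frap_calibration")
}

#' @export
print.frap_calibration <- function(x, ...) {
  cat(sprintf("FRAP calibration: abs = %.6g + %.6g * conc (r2 = %.4f, %d standards)\n",
              x$intercept, x$slope, x$r_squared,
              length(x$standard_concentrations)))
  invisible(x)
}

#' FRAP ferrous-equivalent value of a sample
#'
#' Inverts the calibration line and scales to umol Fe(II) per gram:
#' `((abs - intercept) / slope) * dilution / mass_g`, where `dilution`
#' converts the cuvette concentration (umol/L) to umol in the extract (i.e.
#' it is the litre-equivalent extract volume times any dilution factor).
#' A below-blank absorbance yields a negative value, returned with a warning
#' and attribute `below_blank = TRUE` rather than being censored.
#'
#' @param sample_abs sample absorbance at 593 nm.
#' @param cal a [fit_frap_calibration()] result.
#' @param mass_g sample mass in grams, `> 0`.
#' @param dilution litre-equivalent dilution factor.
#' @return umol Fe(II)/g.
#' @export
frap_value <- function(sample_abs, cal, mass_g, dilution = 1) {
  stopifnot(inherits(cal, "frap_calibration"))
  if (mass_g <= 0) stop("frap_value: mass_g must be > 0", call. = FALSE)
  val <- ((sample_abs - cal$intercept) / cal$slope) * dilution / mass_g
  if (any(val < 0)) {
    warning("frap_value: absorbance below calibration blank; negative value flagged")
    attr(val, "below_blank") <- val < 0
  }
  val
}

#' Trolox-equivalent antioxidant capacity
#'
#' Converts a sample readout into reference-standard equivalents as the
#' ratio of calibration slopes: the sample's concentration-equivalent on the
#' reference standard's calibration divided by sample mass. This
#' slope-ratio convention is an assumption of this package; protocols rarely
#' print the conversion arithmetic.
#'
#' @param sample_abs sample absorbance.
#' @param sample_cal calibration for the assay chromophore.
#' @param reference_cal calibration of the reference standard (e.g. Trolox)
#'   in the same assay.
#' @param mass_g sample mass in grams.
#' @return Reference-standard equivalents per gram (units follow the
#'   reference calibration's concentration units).
#' @export
trolox_equivalent <- function(sample_abs, sample_cal, reference_cal, mass_g) {
  stopifnot(inherits(reference_cal, "frap_calibration"))
  if (mass_g <= 0) stop("trolox_equivalent: mass_g must be > 0", call. = FALSE)
  ((sample_abs - reference_cal$intercept) / reference_cal$slope) / mass_g
}

#' NO-production inhibition rate
#'
#' `(stimulated - treated) / (stimulated - unstimulated)`: 1 when treatment
#' returns NO to the unstimulated baseline, 0 when it does nothing. Values
#' outside `[0, 1]` are clipped and flagged via attribute `clipped`.
#'
#' @param treated NO level (uM) with stimulus + treatment.
#' @param stimulated NO level with stimulus alone; must exceed
#'   `unstimulated`.
#' @param unstimulated baseline NO level.
#' @return Inhibition fraction in `[0, 1]`; vectorized over `treated`.
#' @examples
#' inhibition_rate(22.2, stimulated = 43.72, unstimulated = 0.67)
#' @export
inhibition_rate <- function(treated, stimulated, unstimulated) {
  if (stimulated <= unstimulated)
    stop("inhibition_rate: stimulus did not raise NO above baseline", call. = FALSE)
  raw <- (stimulated - treated) / (stimulated - unstimulated)
  out <- pmin(pmax(raw, 0), 1)
  if (any(raw < 0 | raw > 1)) attr(out, "clipped") <- raw < 0 | raw > 1
  out
}

#' Estimate IC50 from a dose-response curve
#'
#' Fits a four-parameter logistic (4PL),
#' `r(c) = lower + (upper - lower) / (1 + (ic50 / c)^hill)`, to inhibition
#' fractions by nonlinear least squares ([minpack.lm::nlsLM()]). If the fit
#' fails to converge, falls back to log-linear interpolation between the two
#' doses bracketing 50% and sets the `interpolated` flag. When the responses
#' never bracket 0.5 the result is censored (`"> max dose"` / `"< min
#' dose"`), mirroring the conventional `IC50 > highest tested` style of
#' reporting.
#'
#' IC50 is equivariant under dose-unit changes: scaling all concentrations
#' by `c` scales the estimate by `c`.
#'
#' @param concs dose levels (ug/mL or uM), `>= 4` values, positive.
#' @param responses inhibition fractions (not percent), same length.
#' @param method `"auto"` (4PL with interpolation fallback) or
#'   `"interpolation"` (log-linear bracketing only).
#' @return Object of class `dose_response` with `ic50` (NA when censored),
#'   `censored` (`"none"`, `"above_max"`, `"below_min"`), `fit_params`
#'   (lower, upper, hill, ic50) or `interpolated = TRUE`.
#' @examples
#' cc <- c(12.5, 25, 50, 100, 200, 400)
#' estimate_ic50(cc, 1 / (1 + (50 / cc)))
#' @export
estimate_ic50 <- function(concs, responses, method = c("auto", "interpolation")) {
  method <- match.arg(method)
  if (length(concs) < 4)
    stop("estimate_ic50: need at least 4 dose levels", call. = FALSE)
  if (length(responses) != length(concs))
    stop("estimate_ic50: concs and responses lengths differ", call. = FALSE)
  if (any(concs <= 0)) stop("estimate_ic50: doses must be positive", call. = FALSE)
  if (any(!is.finite(responses)))
    stop("estimate_ic50: responses must be finite", call. = FALSE)
  ord <- order(concs)
  concs <- concs[ord]; responses <- responses[ord]

  censored <- "none"
  if (max(responses) < 0.5) censored <- "above_max"
  if (min(responses) > 0.5) censored <- "below_min"
  if (censored != "none") {
    return(structure(list(concentrations = concs, responses = responses,
                          ic50 = NA_real_, censored = censored,
                          fit_params = NULL, interpolated = FALSE),
                     class = "dose_response"))
  }

  fit_params <- NULL; interpolated <- FALSE; ic50 <- NA_real_
  start <- list(lower = max(0, min(responses)), upper = min(1, max(responses)),
                hill = 1, ic50 = exp(stats::approx(responses, log(concs),
                                                   xout = 0.5, ties = mean)$y))
  fit <- if (method == "interpolation") NULL else tryCatch(
    minpack.lm::nlsLM(responses ~ lower + (upper - lower) / (1 + (ic50 / concs)^hill),
                      start = start,
                      lower = c(-0.5, 0.2, -20, min(concs) / 100),
                      upper = c(0.5, 1.5, 20, max(concs) * 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    fit_params <- as.list(cf)
    ic50 <- unname(cf[["ic50"]])
  }
  if (is.null(fit) || !is.finite(ic50) || ic50 < min(concs) / 10 ||
      ic50 > max(concs) * 10) {
    # log-linear interpolation between the doses bracketing 0.5
    above <- which(responses >= 0.5)[1]
    below <- max(which(responses[seq_len(above)] < 0.5), 0)
    if (below == 0) {
      ic50 <- concs[above]
    } else {
      r1 <- responses[below]; r2 <- responses[above]
      l1 <- log(concs[below]); l2 <- log(concs[above])
      ic50 <- exp(l1 + (0.5 - r1) / (r2 - r1) * (l2 - l1))
    }
    interpolated <- TRUE
    fit_params <- NULL
  }
  structure(list(concentrations = concs, responses = responses, ic50 = ic50,
                 censored = "none", fit_params = fit_params,
                 interpolated = interpolated),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  if (x$censored == "above_max") {
    cat(sprintf("IC50 > %g (max tested dose; 50%% inhibition not reached)\n",
                max(x$concentrations)))
  } else if (x$censored == "below_min") {
    cat(sprintf("IC50 < %g (min tested dose)\n", min(x$concentrations)))
  } else {
    cat(sprintf("IC50 = %.4g%s\n", x$ic50,
                if (x$interpolated) " (log-linear interpolation)" else " (4PL fit)"))
  }
  invisible(x)
}
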
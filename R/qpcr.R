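#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(known quantity), from
#' calibration mixtures at known ratios. Zero-quantity points and
#' no-amplification wells (`NA` Ct) cannot enter a log-linear fit; they
#' are excluded and counted. The amplification efficiency is
#' `10^(-1/slope) - 1` (a slope of -3.3219 cycles per decade is 100%).
#'
#' @param calibration Data frame with columns `known_quantity` and `Ct`
#'   (`NA` = no amplification).
#' @return An object of class `"standard_curve"`: `intercept` (cycles at
#'   quantity 1), `slope` (cycles per decade), `r_squared`, `n_points`,
#'   `n_excluded`, `amplification_efficiency`, and the underlying `fit`.
#'   A non-negative slope attaches a warning flag.
#' @examples
#' cal <- data.frame(known_quantity = c(0.01, 0.1, 1),
#'                   Ct = 30 - 3.3219 * log10(c(0.01, 0.1, 1)))
#' fit_standard_curve(cal)
#' @export
fit_standard_curve <- function(calibration) {
  calibration <- as.data.frame(calibration)
  if (!all(c("known_quantity", "Ct") %in% names(calibration))) {
    stop("'calibration' needs columns 'known_quantity' and 'Ct'")
  }
  usable <- is.finite(calibration$Ct) & is.finite(calibration$known_quantity) &
    calibration$known_quantity > 0
  n_excluded <- sum(!usable)
  cal <- calibration[usable, , drop = FALSE]
  if (nrow(cal) < 2L) {
    stop(sprintf("need at least 2 usable calibration points, have %d",
                 nrow(cal)))
  }
  fit <- lm(Ct ~ log10(known_quantity), data = cal)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  r2 <- summary(fit)$r.squared
  warn <- NULL
  if (!is.finite(slope) || slope >= 0) {
    warn <- "non-negative slope: curve is not a valid dilution series"
    warning(warn, call. = FALSE)
  }
  structure(
    list(intercept = intercept, slope = slope, r_squared = r2,
         n_points = nrow(cal), n_excluded = n_excluded,
         amplification_efficiency = 10^(-1 / slope) - 1,
         warning = warn, fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: Ct = %.4f %+.4f * log10(q)  (r^2 = %.4f, n = %d, efficiency %.1f%%)\n",
    x$intercept, x$slope, x$r_squared, x$n_points,
    100 * x$amplification_efficiency
  ))
  if (x$n_excluded > 0L) {
    cat(sprintf("  %d point(s) excluded (zero quantity or no amplification)\n",
                x$n_excluded))
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
#' @param object A `"standard_curve"`.
#' @param newdata Optional data frame with a `Ct` column (or numeric Ct
#'   vector) to invert.
#' @param ... Unused.
#' @rdname fit_standard_curve
predict.standard_curve <- function(object, newdata, ...) {
  ct <- if (is.data.frame(newdata)) newdata$Ct else as.numeric(newdata)
  quantity_from_ct(ct, object)
}

#' Invert a Ct value through a standard curve
#'
#' quantity = 10^((Ct - intercept) / slope). A no-amplification marker
#' (`NA` Ct) maps to quantity 0, flagged in the `no_amplification`
#' attribute.
#'
#' @param Ct Numeric Ct values; `NA` = no amplification.
#' @param curve A [fit_standard_curve()] result with negative slope.
#' @return Numeric quantities, with attribute `no_amplification`.
#' @export
quantity_from_ct <- function(Ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope >= 0) {
    stop("curve slope must be negative to invert Ct values")
  }
  ct <- as.numeric(Ct)
  q <- ifelse(is.na(ct), 0, 10^((ct - curve$intercept) / curve$slope))
  attr(q, "no_amplification") <- is.na(ct)
  q
}

#' Excision fraction from paired qPCR assays
#'
#' Estimates the fraction of DNA template molecules whose floxed region
#' was excised, N_Lox / N_Total: the edited-target assay and the
#' total-template (normalisation) assay are each inverted through their
#' own standard curve. Replicate Ct values are averaged (arithmetic mean
#' of Ct) before inversion; all-missing replicates count as no
#' amplification (quantity 0). A fraction above 1 is flagged, not
#' clipped, since both quantities carry measurement error.
#'
#' @param sample_ct_lox Ct replicate(s) of the edited-target assay
#'   (`NA` = no amplification).
#' @param curve_lox Standard curve of the edited-target assay.
#' @param sample_ct_total Ct replicate(s) of the total-template assay.
#' @param curve_total Standard curve of the total-template assay.
#' @return An object of class `"excision_estimate"`: `n_lox`, `n_total`,
#'   `fraction`, `flagged` (fraction > 1), `lox_no_amplification`.
#' @export
excision_fraction <- function(sample_ct_lox, curve_lox,
                              sample_ct_total, curve_total) {
  stopifnot(inherits(curve_lox, "standard_curve"),
            inherits(curve_total, "standard_curve"))
  mean_ct <- function(ct) {
    ct <- as.numeric(ct)
    if (all(is.na(ct))) NA_real_ else mean(ct[!is.na(ct)])
  }
  n_lox <- as.numeric(quantity_from_ct(mean_ct(sample_ct_lox), curve_lox))
  n_total <- as.numeric(quantity_from_ct(mean_ct(sample_ct_total),
                                         curve_total))
  if (n_total == 0) stop("total-template quantity is zero")
  fraction <- n_lox / n_total
  structure(
    list(n_lox = n_lox, n_total = n_total, fraction = fraction,
         flagged = fraction > 1,
         lox_no_amplification = all(is.na(as.numeric(sample_ct_lox)))),
    class = "excision_estimate"
  )
}

#' @export
print.excision_estimate <- function(x, ...) {
  cat(sprintf("Excision fraction N_Lox/N_Total = %.4f%s\n", x$fraction,
              if (x$flagged) " (flagged: > 1)" else ""))
  invisible(x)
}
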
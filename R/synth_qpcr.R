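#' Specification of a synthetic qPCR experiment
#'
#' Emulates a calibration series of mixtures of edited and non-edited
#' genomic DNA at known ratios, plus replicate measurements of a sample
#' with a known true edited fraction. Ct values follow
#' Ct = intercept + slope * log10(fraction) + N(0, noise_sd); a zero
#' fraction does not amplify and is emitted as `NA`.
#'
#' @param true_fraction True edited fraction of the sample, in `[0, 1]`.
#' @param calibration_fractions Known mixture ratios; the default ladder
#'   is 0, 0.005, 0.01, 0.05, 0.10, 0.50, 0.70, 0.90, 1.
#' @param intercept_Ct Ct at fraction 1. Default 30 cycles.
#' @param slope Cycles per decade, negative. Default -3.3219 (100%
#'   efficiency).
#' @param noise_sd Gaussian Ct noise, cycles. Default 0.2.
#' @param replicates Replicate wells per point. Default 3.
#' @param seed RNG seed.
#' @return An object of class `"qpcr_spec"`.
#' @export
qpcr_spec <- function(true_fraction = 0.3,
                      calibration_fractions = c(0, 0.005, 0.01, 0.05, 0.1,
                                                0.5, 0.7, 0.9, 1),
                      intercept_Ct = 30, slope = -3.3219, noise_sd = 0.2,
                      replicates = 3L, seed = 1L) {
  stop_if_not_scalar(true_fraction, "true_fraction")
  if (true_fraction < 0 || true_fraction > 1) {
    stop("'true_fraction' must lie in [0, 1]")
  }
  if (!is.numeric(calibration_fractions) ||
      any(calibration_fractions < 0 | calibration_fractions > 1)) {
    stop("'calibration_fractions' must lie in [0, 1]")
  }
  if (!any(calibration_fractions > 0)) {
    stop("at least one calibration fraction must be positive")
  }
  stop_if_not_scalar(slope, "slope")
  if (slope >= 0) stop("'slope' must be negative")
  stop_if_not_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  stop_if_not_scalar(replicates, "replicates", positive = TRUE)
  structure(
    list(true_fraction = true_fraction,
         calibration_fractions = as.numeric(calibration_fractions),
         intercept_Ct = intercept_Ct, slope = slope, noise_sd = noise_sd,
         replicates = as.integer(replicates), seed = seed),
    class = "qpcr_spec"
  )
}

#' Simulate qPCR calibration and sample measurements
#'
#' @param spec A [qpcr_spec()].
#' @return List with `calibration` (data frame: `known_quantity`,
#'   `replicate`, `Ct`, with `NA` Ct marking no amplification at zero
#'   quantity) and `sample` (data frame: `replicate`, `Ct` at the true
#'   fraction). Deterministic in the seed.
#' @export
simulate_qpcr <- function(spec = qpcr_spec()) {
  stopifnot(inherits(spec, "qpcr_spec"))
  with_seed(spec$seed, {
    ct_of <- function(fraction, n) {
      if (fraction <= 0) return(rep(NA_real_, n))
      spec$intercept_Ct + spec$slope * log10(fraction) +
        if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
    }
    cal <- do.call(rbind, lapply(spec$calibration_fractions, function(fr) {
      data.frame(known_quantity = fr, replicate = seq_len(spec$replicates),
                 Ct = ct_of(fr, spec$replicates))
    }))
    smp <- data.frame(replicate = seq_len(spec$replicates),
                      Ct = ct_of(spec$true_fraction, spec$replicates))
    list(calibration = cal, sample = smp)
  })
}
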
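test_that("noiseless calibrations give exact curves and round trips", {
  q <- c(0.005, 0.01, 0.05, 0.1, 0.5, 0.7, 0.9, 1)
  cal <- data.frame(known_quantity = q, Ct = 30 - 3.3219 * log10(q))
  curve <- suppressWarnings(fit_standard_curve(cal))
  expect_equal(curve$intercept, 30, tolerance = 1e-9)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  # slope -3.3219 corresponds to a doubling per cycle: 100% efficiency
  expect_equal(curve$amplification_efficiency, 1, tolerance = 1e-4)
  # Ct at the intercept inverts to quantity one
  expect_equal(as.numeric(quantity_from_ct(30, curve)), 1, tolerance = 1e-12)
  # exact round trip at arbitrary quantities
  for (qq in c(0.003, 0.3, 0.72)) {
    ct <- 30 - 3.3219 * log10(qq)
    expect_equal(as.numeric(quantity_from_ct(ct, curve)), qq,
                 tolerance = 1e-10)
  }
})

test_that("zero-quantity calibration points are filtered, not imputed", {
  q <- c(0, 0.005, 0.01, 0.05, 0.1, 0.5, 0.7, 0.9, 1)
  cal <- data.frame(known_quantity = q,
                    Ct = ifelse(q > 0, 31 - 3.1 * log10(q), NA))
  curve <- suppressWarnings(fit_standard_curve(cal))
  expect_equal(curve$n_points, 8L)
  expect_equal(curve$n_excluded, 1L)
  # dropping the zero row beforehand changes nothing
  curve2 <- suppressWarnings(fit_standard_curve(cal[cal$known_quantity > 0, ]))
  expect_equal(coef(curve), coef(curve2), tolerance = 1e-12)
  expect_error(fit_standard_curve(cal[1, ]), "at least 2")
})

test_that("the default calibration ladder amplifies 8 of its 9 mixtures", {
  sim <- simulate_qpcr(qpcr_spec(noise_sd = 0, replicates = 1, seed = 5))
  expect_equal(nrow(sim$calibration), 9L)
  expect_equal(sum(is.na(sim$calibration$Ct)), 1L)
  expect_equal(sim$calibration$known_quantity[is.na(sim$calibration$Ct)], 0)
  # noiseless points are exactly collinear in (log10 fraction, Ct)
  ok <- !is.na(sim$calibration$Ct)
  fit <- lm(Ct ~ log10(known_quantity), data = sim$calibration[ok, ])
  expect_lt(max(abs(residuals(fit))), 1e-12)
  # a fully edited sample sits at the intercept
  s1 <- simulate_qpcr(qpcr_spec(true_fraction = 1, noise_sd = 0, seed = 5))
  expect_equal(s1$sample$Ct, rep(30, 3))
  expect_identical(simulate_qpcr(qpcr_spec(seed = 3)),
                   simulate_qpcr(qpcr_spec(seed = 3)))
})

test_that("excision estimates divide the two assay quantities", {
  q <- c(0.01, 0.1, 1)
  curve <- suppressWarnings(fit_standard_curve(
    data.frame(known_quantity = q, Ct = 28 - 3.2 * log10(q))
  ))
  # identical Ct and identical curves: fraction one
  est <- excision_fraction(25, curve, 25, curve)
  expect_equal(est$fraction, 1, tolerance = 1e-12)
  # no amplification of the edited target: fraction zero
  est0 <- excision_fraction(NA, curve, 28, curve)
  expect_equal(est0$fraction, 0)
  expect_true(est0$lox_no_amplification)
  # zero-noise simulated sample at fraction 0.30 recovers exactly
  sim <- simulate_qpcr(qpcr_spec(true_fraction = 0.3, noise_sd = 0,
                                 seed = 21))
  cv <- suppressWarnings(fit_standard_curve(sim$calibration))
  est3 <- excision_fraction(sim$sample$Ct, cv, cv$intercept, cv)
  expect_equal(est3$fraction, 0.3, tolerance = 1e-10)
  # fractions above one are flagged, never clipped
  hi <- excision_fraction(24, curve, 25, curve)
  expect_gt(hi$fraction, 1)
  expect_true(hi$flagged)
  expect_error(excision_fraction(25, curve, NA, curve), "zero")
})

test_that("zero-noise round trips are exact across fractions and curves", {
  for (fr in c(0.004, 0.05, 0.5, 1)) {
    for (par in list(c(30, -3.3219), c(26.5, -3.6))) {
      sim <- simulate_qpcr(qpcr_spec(true_fraction = fr, noise_sd = 0,
                                     intercept_Ct = par[1], slope = par[2],
                                     seed = 2))
      cv <- suppressWarnings(fit_standard_curve(sim$calibration))
      expect_equal(as.numeric(quantity_from_ct(mean(sim$sample$Ct), cv)),
                   fr, tolerance = 1e-9)
    }
  }
})

test_that("noisy estimation is nearly median-unbiased and tightens with replicates", {
  est_with <- function(reps, seed) {
    sim <- simulate_qpcr(qpcr_spec(true_fraction = 0.3, noise_sd = 0.2,
                                   replicates = reps, seed = seed))
    cv <- fit_standard_curve(sim$calibration)
    as.numeric(quantity_from_ct(mean(sim$sample$Ct), cv))
  }
  e3 <- vapply(1:40, function(s) est_with(3, s), numeric(1))
  expect_lt(abs(median(e3) / 0.3 - 1), 0.05)
  # dispersion shrinks roughly like 1/sqrt(replicates)
  e12 <- vapply(1:40, function(s) est_with(12, 1000 + s), numeric(1))
  expect_lt(mad(log(e12)), mad(log(e3)))
})
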
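th310 <- thermo()

test_that("the analysis grid reproduces the canonical binning", {
  g <- make_grid(3.75, 10.25, 13)
  expect_equal(g$width, 0.5)
  expect_equal(g$centers, seq(4, 10, by = 0.5))
  g1 <- make_grid(0, 1, 1)
  expect_equal(g1$centers, 0.5)
  g26 <- make_grid(3.75, 10.25, 26)
  expect_equal(g26$width, 0.25)
  expect_equal(g26$centers[1], 3.875)
  expect_error(make_grid(5, 5, 10), "upper")
})

test_that("blocking discards equilibration and drops partial blocks", {
  mk <- function(total_ns, dt = 0.01) {
    umbrella_window(5, 20, rnorm(round(total_ns / dt), 5, 0.2), dt)
  }
  set.seed(1)
  expect_length(split_blocks(mk(30)), 5)
  expect_length(split_blocks(mk(10)), 1)
  expect_length(split_blocks(mk(31)), 5) # trailing 1 ns dropped
  expect_error(split_blocks(mk(9)), "too short")
  # blocks partition the post-equilibration samples in order
  w <- mk(30)
  blk <- split_blocks(w)
  expect_identical(unlist(lapply(blk, `[[`, "series"))[1:100],
                   w$series[501:600])
})

test_that("bias energy uses the one-half prefactor convention", {
  w <- umbrella_window(5, 20, c(5), dt_ns = 1)
  expect_equal(bias_energy(w, 5), 0)
  expect_equal(bias_energy(w, 6), 10)   # 1/2 * 20 * 1^2
  expect_equal(bias_energy(w, 4.5), 2.5) # 1/2 * 20 * 0.25
})

test_that("a single unbiased window returns its normalized histogram", {
  grid <- make_grid(0, 5, 5)
  set.seed(7)
  x <- runif(5000, 0, 5)
  w <- umbrella_window(2.5, 0, x, dt_ns = 0.01)
  bd <- wham_solve(list(w), grid, th310, tolerance = 1e-10)
  expect_equal(bd$p, grid_histogram(x, grid) / length(x), tolerance = 1e-12)
})

test_that("WHAM matches the brute-force fixed point on small exact instances", {
  grid <- make_grid(0, 2.5, 5)
  set.seed(3)
  windows <- lapply(c(0.7, 1.2, 1.8), function(c0) {
    umbrella_window(c0, 2, rnorm(4000, c0, 0.5), dt_ns = 0.01)
  })
  bd <- wham_solve(windows, grid, th310, tolerance = 1e-10, sub_bins = 1)
  counts <- t(vapply(windows, function(w) grid_histogram(w$series, grid),
                     numeric(5)))
  bias <- t(vapply(windows, function(w) bias_energy(w, grid$centers),
                   numeric(5)))
  oracle <- brute_force_wham(counts, bias, th310$beta, th310$kT)
  expect_lt(max(abs(bd$f - oracle$f)), 1e-6)
  expect_lt(max(abs(-th310$kT * log(bd$p) + th310$kT * log(oracle$p))),
            1e-6)
})

test_that("WHAM recovers a flat landscape from overlapping biased draws", {
  grid <- make_grid(0, 2, 4)
  flat <- potential_1d(poly_term(0))
  k <- 2
  n <- 8000
  reps <- 30
  set.seed(5)
  P <- replicate(reps, {
    windows <- lapply(c(0.6, 1.4), function(c0) {
      umbrella_window(c0, k,
                      sample_biased_boltzmann(n, flat, c0, k, th310, -3, 5),
                      dt_ns = 0.01)
    })
    bd <- wham_solve(windows, grid, th310, tolerance = 1e-8)
    expect_equal(sum(bd$p), 1, tolerance = 1e-10)
    bd$p
  })
  # mean over replicates vs truth, on the empirical SE of that mean
  se <- apply(P, 1, sd) / sqrt(reps)
  expect_true(all(abs(rowMeans(P) - 0.25) < 3 * se))
})

test_that("WHAM agrees with likelihood optimisation and the analytic Gaussian", {
  kappa <- 4
  pot <- potential_1d(poly_term(c(0, 0, kappa / 2)))
  grid <- make_grid(-1.25, 1.25, 5)
  k <- 3
  set.seed(9)
  n <- 30000
  windows <- lapply(c(-0.6, 0, 0.6), function(c0) {
    umbrella_window(c0, k,
                    sample_biased_boltzmann(n, pot, c0, k, th310, -4, 4),
                    dt_ns = 0.01)
  })
  bd <- wham_solve(windows, grid, th310, tolerance = 1e-9, sub_bins = 1)
  counts <- t(vapply(windows, function(w) grid_histogram(w$series, grid),
                     numeric(5)))
  bias <- t(vapply(windows, function(w) bias_energy(w, grid$centers),
                   numeric(5)))
  ora <- likelihood_wham(counts, bias, th310$beta, th310$kT)
  expect_lt(max(abs(-th310$kT * log(bd$p) + th310$kT * log(ora$p))), 1e-3)
  expect_lt(max(abs(bd$f - ora$f)), 1e-3)
})

test_that("WHAM recovers the discretized analytic Gaussian on a harmonic well", {
  kappa <- 4
  pot <- potential_1d(poly_term(c(0, 0, kappa / 2)))
  grid <- make_grid(-1.25, 1.25, 5)
  k <- 3
  n <- 8000
  reps <- 8
  set.seed(13)
  P <- replicate(reps, {
    windows <- lapply(c(-0.6, 0, 0.6), function(c0) {
      umbrella_window(c0, k,
                      sample_biased_boltzmann(n, pot, c0, k, th310, -4, 4),
                      dt_ns = 0.01)
    })
    wham_solve(windows, grid, th310, tolerance = 1e-8)$p
  })
  s <- sqrt(th310$kT / kappa)
  p_true <- diff(pnorm(grid$edges, 0, s))
  p_true <- p_true / sum(p_true)
  se <- apply(P, 1, sd) / sqrt(reps)
  expect_true(all(abs(rowMeans(P) - p_true) < 3 * se + 1e-4))
})

test_that("block averaging applies the stated free-energy and error formulas", {
  grid2 <- make_grid(0, 2, 2)
  # identical blocks: zero error everywhere
  blocks <- lapply(1:5, function(i) fake_block(c(0.8, 0.2), grid2))
  prof <- pmf_from_blocks(blocks, grid2, th310)
  expect_equal(prof$sigma_F, c(0, 0))
  # two-bin mean (0.8, 0.2) at 310 K: delta F = kT ln 4
  kT <- 0.0019872041 * 310
  expect_equal(prof$F[2] - prof$F[1], kT * log(4), tolerance = 1e-10)
  expect_equal(prof$F[2] - prof$F[1], 0.854, tolerance = 1e-3)
  # uniform probabilities: flat profile
  grid4 <- make_grid(0, 4, 4)
  flatp <- lapply(1:3, function(i) fake_block(rep(0.25, 4), grid4))
  expect_equal(pmf_from_blocks(flatp, grid4, th310)$F, rep(0, 4))
  # sigma uses twice the SEM with the sample standard deviation
  varied <- lapply(c(0.7, 0.8, 0.9), function(q) {
    fake_block(c(q, 1 - q), grid2)
  })
  pv <- pmf_from_blocks(varied, grid2, th310)
  sem1 <- sd(c(0.7, 0.8, 0.9)) / sqrt(3)
  expect_equal(pv$sigma_F[1], th310$kT * 2 * sem1 / 0.8, tolerance = 1e-12)
  # a single block leaves the error undefined but the profile intact
  one <- pmf_from_blocks(list(fake_block(c(0.5, 0.5), grid2)), grid2, th310)
  expect_true(all(is.na(one$sigma_F)))
  expect_equal(one$F, c(0, 0))
  # empty bins stay undefined and are ignored by the zero offset
  zb <- lapply(1:3, function(i) fake_block(c(0.9, 0.1, 0), make_grid(0, 3, 3)))
  pz <- pmf_from_blocks(zb, make_grid(0, 3, 3), th310)
  expect_true(is.na(pz$F[3]))
  expect_false(pz$defined[3])
  expect_equal(min(pz$F, na.rm = TRUE), 0)
})

test_that("block probabilities always sum to one", {
  pot <- double_well_potential()
  sims <- simulate_umbrella(pot, umbrella_ladder(),
                            langevin_spec(seed = 4), th310)
  prof <- estimate_pmf(sims)
  for (b in prof$blocks) {
    expect_equal(sum(b$p), 1, tolerance = 1e-10)
  }
  expect_equal(prof$n_blocks, 5L)
})

test_that("the estimated PMF is gauge invariant under constant energy shifts", {
  base <- double_well_potential()
  shifted <- potential_1d(poly_term(base$terms[[1]]$coefficients +
                                      c(7.3, rep(0, 4))))
  spec <- langevin_spec(n_steps = 6000, seed = 17)
  p1 <- estimate_pmf(simulate_umbrella(base, umbrella_ladder(), spec, th310),
                     equilibration_ns = 2, block_ns = 2)
  p2 <- estimate_pmf(simulate_umbrella(shifted, umbrella_ladder(), spec,
                                       th310),
                     equilibration_ns = 2, block_ns = 2)
  expect_equal(p1$F, p2$F, tolerance = 1e-10)
  a1 <- analytic_pmf(base, make_grid(), th310)
  a2 <- analytic_pmf(shifted, make_grid(), th310)
  expect_equal(a1$F, a2$F, tolerance = 1e-8)
})

test_that("more sampling per block shrinks the error bars", {
  pot <- double_well_potential()
  mean_sigma <- function(n_steps) {
    sims <- simulate_umbrella(pot, umbrella_ladder(),
                              langevin_spec(n_steps = n_steps, seed = 31),
                              th310)
    total_ns <- n_steps * 0.002
    prof <- estimate_pmf(sims, equilibration_ns = total_ns / 6,
                         block_ns = total_ns / 6)
    mean(prof$sigma_F[prof$defined])
  }
  expect_lt(mean_sigma(30000), mean_sigma(7500))
})

test_that("windows losing most samples outside the grid are rejected", {
  grid <- make_grid(0, 1, 2)
  w_out <- umbrella_window(5, 0, rnorm(1000, 5, 0.1), dt_ns = 0.01)
  expect_error(wham_solve(list(w_out), grid, th310), "outside the grid")
})
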
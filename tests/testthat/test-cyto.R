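test_that("the density gate encloses exactly the target fraction", {
  ev <- simulate_cytometry(cytometry_spec(n_events = 2000,
                                          debris_fraction = 0, seed = 8))
  g <- kde_gate(ev, target_fraction = 0.4)
  expect_equal(g$n_gated, ceiling(0.4 * 2000))
  expect_equal(sum(g$in_gate), 800)
  # smallest admissible target gates exactly the single densest event
  g1 <- kde_gate(ev, target_fraction = 1 / 2000)
  expect_equal(g1$n_gated, 1L)
  expect_equal(which(g1$in_gate), which.max(g1$density))
})

test_that("compiled density evaluation matches the brute-force KDE", {
  set.seed(2)
  x <- rnorm(400, 10, 2); y <- rnorm(400, 5, 1)
  hx <- bw.nrd0(x); hy <- bw.nrd0(y)
  ref <- brute_force_kde(x, y, x, y, hx, hy)
  got <- loxquant:::.kde2d_at(x, y, x, y, hx, hy)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("gating a sparse-plus-dense mixture keeps only the dense blob", {
  set.seed(4)
  dense <- cbind(rnorm(1800, 100, 3), rnorm(1800, 100, 3))
  sparse <- cbind(rnorm(200, 500, 60), rnorm(200, 500, 60))
  ev <- data.frame(rbind(dense, sparse), fl = 1)
  names(ev) <- c("FSC-H", "SSC-H", "FL")
  g <- kde_gate(ev, target_fraction = 0.4)
  expect_true(all(which(g$in_gate) <= 1800))
  # ranking agrees with a brute-force density computation
  ref <- brute_force_kde(ev[["FSC-H"]], ev[["SSC-H"]],
                         ev[["FSC-H"]], ev[["SSC-H"]],
                         g$bandwidth[1], g$bandwidth[2])
  expect_equal(order(g$density, decreasing = TRUE)[1:800],
               order(ref, decreasing = TRUE)[1:800])
})

test_that("degenerate scatter is rejected", {
  ev <- data.frame(a = rep(1, 100), b = rnorm(100), fl = 1)
  names(ev) <- c("FSC-H", "SSC-H", "FL")
  expect_error(kde_gate(ev), "degenerate scatter")
})

test_that("row permutation changes nothing but boundary tie-breaks", {
  ev <- simulate_cytometry(cytometry_spec(n_events = 1000, seed = 12))
  perm <- sample(seq_len(nrow(ev)))
  ev2 <- ev[perm, ]
  g1 <- kde_gate(ev)
  g2 <- kde_gate(ev2)
  expect_equal(g2$density, g1$density[perm], tolerance = 1e-12)
  expect_equal(g1$n_gated, g2$n_gated)
  expect_equal(g1$centroid, g2$centroid, tolerance = 1e-9)
})

test_that("outlier screening flags only clearly shifted gates", {
  mk <- function(fsc, ssc, id) fake_gate(rep(TRUE, 10), c(fsc = fsc, ssc = ssc), id)
  # identical centroids: nothing flagged
  same <- lapply(1:4, function(i) mk(100, 100, paste0("s", i)))
  expect_false(any(flag_outlier_samples(same)))
  # one sample shifted far beyond the inter-sample spread
  shifted <- list(mk(100, 100, "a"), mk(101, 99, "b"), mk(99, 101, "c"),
                  mk(100.5, 100.2, "d"), mk(180, 100, "e"))
  fl <- flag_outlier_samples(shifted)
  expect_identical(unname(fl), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_named(fl, c("a", "b", "c", "d", "e"))
  expect_error(flag_outlier_samples(shifted[1:2]), "at least 3")
})

test_that("the negative-control threshold is the interpolated percentile", {
  ev <- data.frame(f = rnorm(4000, 100, 5), s = rnorm(4000, 100, 5),
                   fl = as.numeric(1:4000))
  names(ev) <- c("FSC-H", "SSC-H", "FL")
  gate <- fake_gate(rep(TRUE, 4000))
  thr <- negative_threshold(ev, gate)
  expect_gte(thr, 3996)
  expect_lte(thr, 3997)
  expect_equal(100 * mean(ev$FL <= thr), 99.9)
  # oracle: quantile of the sorted list by direct interpolation (type 6)
  h <- (4000 + 1) * 0.999
  expect_equal(thr, floor(h) + (h - floor(h)) * 1, tolerance = 1e-9)
  # all-equal values collapse to that value
  ev$FL <- 7
  expect_equal(negative_threshold(ev, gate), 7)
})

test_that("fraction_on counts strictly-above-threshold gated events", {
  ev <- simulate_cytometry(cytometry_spec(n_events = 1000, on_fraction = 0.5,
                                          seed = 3))
  g <- kde_gate(ev)
  expect_equal(fraction_on(ev, g, min(ev$FL) - 1)$fraction_on, 1)
  expect_equal(fraction_on(ev, g, max(ev$FL))$fraction_on, 0)
  r <- fraction_on(ev, g, 40) # midway between OFF (median 5) and ON (500)
  expect_lt(abs(r$fraction_on - 0.5), 3 * sqrt(0.25 / r$n_gated) + 0.01)
})

test_that("group summaries report mean, sem and n as in the figures", {
  s <- summarize_groups(list(a = c(0.2, 0.2, 0.2), b = c(0.1, 0.2, 0.3),
                             c = 0.5))
  expect_equal(s$mean, c(0.2, 0.2, 0.5))
  expect_equal(s$sem[1], 0)
  expect_equal(s$sem[2], 0.1 / sqrt(3), tolerance = 1e-12)
  expect_true(is.na(s$sem[3]))
  expect_equal(s$n, c(3L, 3L, 1L))
  expect_error(summarize_groups(list(a = numeric(0))), "empty")
})

test_that("condition comparisons follow the Welch and rank-sum conventions", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3), "t_test")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # exact two-sided rank-sum for fully separated triplets
  w <- compare_conditions(c(1, 2, 3), c(4, 5, 6), "wilcoxon")
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)
  # oracle: enumerate all C(6,3) rank assignments
  ranks <- combn(6, 3)
  stat <- apply(ranks, 2, sum)
  p_enum <- 2 * mean(stat <= sum(1:3))
  expect_equal(w$p_value, p_enum, tolerance = 1e-12)
  # a 10-SD shift is overwhelming for the t-test
  set.seed(6)
  a <- rnorm(4); b <- rnorm(4) + 10 * sd(c(rnorm(100)))
  big <- compare_conditions(a, b + 10, "t_test")
  expect_lt(big$p_value, 1e-3)
  # equal constant groups: p = 1 by convention
  cc <- compare_conditions(c(2, 2), c(2, 2), "t_test")
  expect_equal(cc$p_value, 1)
})
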
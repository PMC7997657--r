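# Independent oracles and fixture builders used across the suite.

# Textbook WHAM fixed point on coarse bins, iterated to machine-level
# self-consistency. Independent of loxquant::wham_solve: written against
# histogram counts and a bias matrix directly.
brute_force_wham <- function(counts, bias, beta, kT, delta = 1e-12,
                             max_iter = 5e5) {
  nw <- nrow(counts)
  Nw <- rowSums(counts)
  ntot <- colSums(counts)
  f <- rep(0, nw)
  for (it in seq_len(max_iter)) {
    denom <- colSums(Nw * exp(-beta * sweep(bias, 1, f)))
    p <- ntot / denom
    p <- p / sum(p)
    f_new <- -kT * log(as.numeric(exp(-beta * bias) %*% p))
    if (max(abs(f_new - f)) < delta) {
      return(list(p = p, f = f_new - f_new[1], iterations = it))
    }
    f <- f_new
  }
  stop("brute-force WHAM did not converge")
}

# Second independent route: minimise the closed-form WHAM objective over
# window free energies with a quasi-Newton optimiser (gauge: g[1] = 0).
likelihood_wham <- function(counts, bias, beta, kT) {
  nw <- nrow(counts)
  Nw <- rowSums(counts)
  ntot <- colSums(counts)
  cwi <- exp(-beta * bias)
  obj <- function(g_free) {
    g <- c(0, g_free)
    -sum(Nw * g) + sum(ntot * log(colSums(Nw * exp(g) * cwi)))
  }
  opt <- stats::optim(rep(0, nw - 1), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  g <- c(0, opt$par)
  p <- ntot / colSums(Nw * exp(g) * cwi)
  # stationarity gives exp(-g_w) = sum_i p_i c_wi, i.e. f_w = kT g_w
  list(p = p / sum(p), f = kT * (g - g[1]))
}

# Exact O(n^2) product-Gaussian KDE, vectorised with outer(); the
# reference for the compiled density evaluation.
brute_force_kde <- function(x, y, qx, qy, hx, hy) {
  n <- length(x)
  gx <- outer(qx, x, function(a, b) stats::dnorm((a - b) / hx))
  gy <- outer(qy, y, function(a, b) stats::dnorm((a - b) / hy))
  rowSums(gx * gy) / (n * hx * hy)
}

# Histogram counts on a wham_grid (samples outside the grid dropped).
grid_histogram <- function(x, grid) {
  x <- x[x >= grid$lower & x <= grid$upper]
  idx <- pmin(pmax(findInterval(x, grid$edges, rightmost.closed = TRUE), 1L),
              grid$n_bins)
  tabulate(idx, nbins = grid$n_bins)
}

# Minimal gate_region for functions that only consume the gate fields.
fake_gate <- function(in_gate, centroid = c(fsc = 0, ssc = 0),
                      sample_id = NULL) {
  structure(
    list(in_gate = in_gate, density = rep(1, length(in_gate)),
         threshold_density = 1,
         centroid = centroid, n_gated = sum(in_gate),
         target_fraction = mean(in_gate), bandwidth = c(1, 1),
         polygon = NULL, sample_id = sample_id),
    class = "gate_region"
  )
}

# Minimal block_distribution on a given grid.
fake_block <- function(p, grid) {
  structure(
    list(p = p, f = 0, n_iterations = 0L,
         counts = matrix(p, nrow = 1), n_dropped = 0L, grid = grid,
         sub_bins = 1L, p_sub = p),
    class = "block_distribution"
  )
}

# Direct Monte-Carlo draw from the biased Boltzmann density of a window
# on a potential, via inverse-CDF sampling on a fine grid.
sample_biased_boltzmann <- function(n, potential, center, k, thermo,
                                    lower, upper) {
  xs <- seq(lower, upper, length.out = 20001L)
  u <- potential_energy(potential, xs) + 0.5 * k * (xs - center)^2
  w <- exp(-thermo$beta * (u - min(u)))
  cdf <- cumsum(w) / sum(w)
  xs[findInterval(runif(n), cdf) + 1L]
}
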
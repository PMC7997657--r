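#' Analysis grid for WHAM
#'
#' Equal-width bins over the reaction coordinate. The canonical grid has
#' 13 bins between 3.75 and 10.25 Angstrom, giving 0.5 A bins centered on
#' the 13 window centers 4, 4.5, ..., 10.
#'
#' @param lower,upper Grid boundaries (Angstrom), `upper > lower`.
#' @param n_bins Number of equal-width bins (>= 1).
#' @return An object of class `"wham_grid"` with fields `lower`, `upper`,
#'   `n_bins`, `width`, `edges` (length `n_bins + 1`) and `centers`.
#' @examples
#' make_grid(3.75, 10.25, 13)$centers
#' @export
make_grid <- function(lower = 3.75, upper = 10.25, n_bins = 13L) {
  stop_if_not_scalar(lower, "lower"); stop_if_not_scalar(upper, "upper")
  stop_if_not_scalar(n_bins, "n_bins", positive = TRUE)
  if (upper <= lower) stop("'upper' must be > 'lower'")
  n_bins <- as.integer(n_bins)
  width <- (upper - lower) / n_bins
  if (width <= 0) stop("bin width must be positive")
  edges <- lower + width * (0:n_bins)
  structure(
    list(lower = lower, upper = upper, n_bins = n_bins, width = width,
         edges = edges, centers = lower + width * (seq_len(n_bins) - 0.5)),
    class = "wham_grid"
  )
}

#' @export
print.wham_grid <- function(x, ...) {
  cat(sprintf("WHAM grid: %d bins of %g A over [%g, %g] A\n",
              x$n_bins, x$width, x$lower, x$upper))
  invisible(x)
}

#' Split a window series into analysis blocks
#'
#' Discards an initial equilibration phase and cuts the remainder into
#' consecutive non-overlapping blocks; a trailing partial block is
#' dropped (equal block weights keep the block SEM unbiased).
#'
#' @param window An [umbrella_window()], or a numeric series (then
#'   `dt_ns` must be given).
#' @param equilibration_ns Equilibration to discard (ns). Default 5.
#' @param block_ns Block length (ns). Default 5.
#' @param dt_ns Sampling interval, only for bare numeric series.
#' @return A list of blocks; `umbrella_window` input gives
#'   `umbrella_window` blocks sharing the bias parameters, numeric input
#'   gives numeric blocks.
#' @examples
#' w <- umbrella_window(5, 20, rnorm(3000, 5, 0.2), dt_ns = 0.01)
#' length(split_blocks(w)) # 30 ns -> 5 blocks of 5 ns after 5 ns equilibration
#' @export
split_blocks <- function(window, equilibration_ns = 5, block_ns = 5,
                         dt_ns = NULL) {
  if (inherits(window, "umbrella_window")) {
    series <- window$series
    dt_ns <- window$dt_ns
  } else {
    series <- as.numeric(window)
    if (is.null(dt_ns)) stop("'dt_ns' required for a bare numeric series")
  }
  stop_if_not_scalar(block_ns, "block_ns", positive = TRUE)
  stop_if_not_scalar(equilibration_ns, "equilibration_ns")
  if (equilibration_ns < 0) stop("'equilibration_ns' must be >= 0")
  n_eq <- as.integer(round(equilibration_ns / dt_ns))
  n_blk <- as.integer(round(block_ns / dt_ns))
  if (n_blk < 1L) stop("block length is shorter than one sampling interval")
  n_rest <- length(series) - n_eq
  if (n_rest < n_blk) {
    stop(sprintf(
      "series too short: %d samples remain after equilibration, one block needs %d",
      max(n_rest, 0L), n_blk
    ), call. = FALSE)
  }
  n_blocks <- n_rest %/% n_blk
  lapply(seq_len(n_blocks), function(b) {
    sub <- series[(n_eq + (b - 1L) * n_blk + 1L):(n_eq + b * n_blk)]
    if (inherits(window, "umbrella_window")) {
      umbrella_window(window$center, window$spring_constant, sub, dt_ns)
    } else {
      sub
    }
  })
}

#' Harmonic bias energy of a window
#'
#' One-half prefactor convention: b(x) = (1/2) k (x - center)^2.
#'
#' @param window An [umbrella_window()].
#' @param x Positions (Angstrom).
#' @return Bias energy in kcal mol^-1.
#' @export
bias_energy <- function(window, x) {
  stopifnot(inherits(window, "umbrella_window"), all(is.finite(x)))
  0.5 * window$spring_constant * (x - window$center)^2
}

#' Solve the WHAM equations on one block
#'
#' Self-consistent weighted-histogram solution combining the biased
#' histograms of all windows into one unbiased bin-probability vector:
#'
#'   p_i = (sum_w n_wi) / (sum_w N_w exp(-beta (b_w(center_i) - f_w)))
#'   f_w = -kT ln sum_i p_i exp(-beta b_w(center_i))
#'
#' iterated from f_w = 0 (no damping) until max_w |delta f_w| drops below
#' `tolerance`. Samples falling outside the grid are dropped and
#' counted; losing more than half of a window's samples is an error.
#'
#' The bias is evaluated at bin centers. Because a stiff bias varies by
#' more than kT across a wide bin (here: biased sampling width ~0.18 A
#' inside 0.5 A bins), evaluating it at the centers of the *reporting*
#' bins carries a large systematic error; the iteration therefore runs
#' on an internal equal-width subdivision of each reporting bin (bias at
#' sub-bin centers, where the approximation is accurate) and the
#' converged sub-bin probabilities are summed back onto the reporting
#' grid. `sub_bins = 1` recovers the textbook coarse-bin fixed point.
#'
#' @param windows List of [umbrella_window()] restricted to one block.
#' @param grid A [make_grid()] grid.
#' @param thermo A [thermo()] state.
#' @param tolerance Convergence tolerance on the window free energies,
#'   kcal mol^-1. Default 0.01.
#' @param max_iterations Iteration cap. Default 1e5.
#' @param sub_bins Internal subdivisions per reporting bin; `NULL`
#'   (default) picks the smallest subdivision whose sub-bin width is at
#'   most half the narrowest biased-sampling width sqrt(kT / k_max)
#'   (capped at 20).
#' @return An object of class `"block_distribution"`: `p` (per-bin
#'   unbiased probabilities, summing to 1), `f` (window free energies,
#'   kcal mol^-1, relative to the first window), `n_iterations`, `counts`
#'   (window-by-bin histogram) and `n_dropped` (out-of-grid samples per
#'   window).
#' @export
wham_solve <- function(windows, grid, thermo = loxquant::thermo(),
                       tolerance = 0.01, max_iterations = 1e5,
                       sub_bins = NULL) {
  stopifnot(is.list(windows), length(windows) >= 1L,
            inherits(grid, "wham_grid"), inherits(thermo, "thermo"))
  stop_if_not_scalar(tolerance, "tolerance", positive = TRUE)
  nw <- length(windows)
  nb <- grid$n_bins
  if (is.null(sub_bins)) {
    k_max <- max(vapply(windows, `[[`, numeric(1), "spring_constant"))
    sub_bins <- if (k_max > 0) {
      min(20L, max(1L, as.integer(ceiling(
        grid$width / (0.5 * sqrt(thermo$kT / k_max))
      ))))
    } else {
      1L
    }
  }
  sub_bins <- as.integer(sub_bins)
  stopifnot(sub_bins >= 1L)
  ns <- nb * sub_bins
  sub_edges <- seq(grid$lower, grid$upper, length.out = ns + 1L)
  sub_centers <- (sub_edges[-1L] + sub_edges[-(ns + 1L)]) / 2

  counts <- matrix(0, nrow = nw, ncol = ns)
  n_dropped <- integer(nw)
  for (w in seq_len(nw)) {
    x <- windows[[w]]$series
    inside <- x >= grid$lower & x <= grid$upper
    n_dropped[w] <- sum(!inside)
    if (n_dropped[w] > length(x) / 2) {
      stop(sprintf(
        "window %d (center %g A) lost %d of %d samples outside the grid",
        w, windows[[w]]$center, n_dropped[w], length(x)
      ), call. = FALSE)
    }
    xi <- x[inside]
    if (length(xi) == 0L) {
      stop(sprintf("window %d contributes no samples inside the grid", w),
           call. = FALSE)
    }
    idx <- pmin(pmax(findInterval(xi, sub_edges, rightmost.closed = TRUE),
                     1L), ns)
    counts[w, ] <- tabulate(idx, nbins = ns)
  }

  beta <- thermo$beta
  kT <- thermo$kT
  # bias of window w at (sub-)bin center i
  b <- t(vapply(windows, function(win) bias_energy(win, sub_centers),
                numeric(ns)))
  if (nw == 1L) b <- matrix(b, nrow = 1L)
  Nw <- rowSums(counts)
  n_tot <- colSums(counts)

  f <- numeric(nw)
  eb <- exp(-beta * b) # window-by-bin Boltzmann factor of the bias
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # denom_i = sum_w N_w exp(-beta (b_wi - f_w)); exponents stay moderate
    denom <- colSums(Nw * eb * exp(beta * f))
    p <- ifelse(denom > 0, n_tot / denom, 0)
    p <- p / sum(p)
    f_new <- -kT * log(as.numeric(eb %*% p))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance) break
    if (iter >= max_iterations) {
      stop(sprintf(
        "WHAM did not converge in %d iterations (last residual %.3g kcal/mol)",
        as.integer(max_iterations), delta
      ), call. = FALSE)
    }
  }

  p_report <- if (sub_bins > 1L) {
    colSums(matrix(p, nrow = sub_bins))
  } else {
    as.numeric(p)
  }
  structure(
    list(p = p_report, f = as.numeric(f - f[1L]), n_iterations = iter,
         counts = counts, n_dropped = n_dropped, grid = grid,
         sub_bins = sub_bins, p_sub = as.numeric(p)),
    class = "block_distribution"
  )
}

#' @export
print.block_distribution <- function(x, ...) {
  cat(sprintf(
    "WHAM block distribution: %d bins, %d windows, %d iterations, %d dropped sample(s)\n",
    length(x$p), nrow(x$counts), x$n_iterations, sum(x$n_dropped)
  ))
  invisible(x)
}

new_pmf_profile <- function(bin_centers, F, sigma_F, n_blocks, thermo,
                            source = "wham", blocks = NULL,
                            diagnostics = NULL) {
  structure(
    list(bin_centers = bin_centers, F = F, sigma_F = sigma_F,
         defined = !is.na(F), n_blocks = n_blocks, thermo = thermo,
         source = source, blocks = blocks, diagnostics = diagnostics),
    class = "pmf_profile"
  )
}

#' Average block distributions into a PMF with error bars
#'
#' For each bin, the mean probability over blocks gives the free energy
#' Fi = -kT ln(p_bar_i); the error is sigma_Fi = kT sigma_pbar_i / p_bar_i
#' with sigma_pbar_i twice the standard error of the mean over blocks
#' (sample standard deviation, n - 1). The profile is shifted so its
#' lowest defined value is zero. Bins with zero mean probability are
#' marked undefined (`NA`), never given a fabricated value; a single
#' block leaves `sigma_F` undefined.
#'
#' @param blocks List of `"block_distribution"` objects on one grid.
#' @param grid The shared [make_grid()] grid.
#' @param thermo A [thermo()] state.
#' @return An object of class `"pmf_profile"`: `bin_centers`, `F`,
#'   `sigma_F` (kcal mol^-1), `defined`, `n_blocks`.
#' @export
pmf_from_blocks <- function(blocks, grid, thermo = loxquant::thermo()) {
  stopifnot(is.list(blocks), length(blocks) >= 1L,
            inherits(grid, "wham_grid"), inherits(thermo, "thermo"))
  for (b in blocks) {
    if (!inherits(b, "block_distribution")) {
      stop("'blocks' must be block_distribution objects")
    }
    if (length(b$p) != grid$n_bins ||
        !isTRUE(all.equal(b$grid$edges, grid$edges, tolerance = 1e-12))) {
      stop("all blocks must share the analysis grid")
    }
  }
  P <- vapply(blocks, function(b) b$p, numeric(grid$n_bins))
  if (grid$n_bins == 1L) P <- matrix(P, nrow = 1L)
  nbk <- length(blocks)
  p_bar <- rowMeans(P)
  kT <- thermo$kT
  F <- ifelse(p_bar > 0, -kT * log(p_bar), NA_real_)
  if (nbk >= 2L) {
    sigma_p <- 2 * apply(P, 1L, sd) / sqrt(nbk)
    sigma_F <- ifelse(p_bar > 0, kT * sigma_p / p_bar, NA_real_)
  } else {
    sigma_F <- rep(NA_real_, grid$n_bins)
  }
  if (all(is.na(F))) stop("no bin has positive mean probability")
  F <- F - min(F, na.rm = TRUE)
  new_pmf_profile(grid$centers, F, sigma_F, nbk, thermo, source = "wham",
                  blocks = blocks)
}

#' Estimate a PMF from umbrella windows
#'
#' End-to-end estimator: each window's series is split into blocks
#' ([split_blocks()]), WHAM is solved independently on each block (block
#' b combines block b of every window; [wham_solve()]), and the block
#' distributions are averaged into a profile with block-based error bars
#' ([pmf_from_blocks()]).
#'
#' @param windows List of [umbrella_window()] objects.
#' @param grid A [make_grid()] grid (default: 13 bins, 3.75-10.25 A).
#' @param thermo A [thermo()] state (default 310 K).
#' @param equilibration_ns,block_ns Blocking scheme in ns (defaults 5/5).
#' @param tolerance WHAM convergence tolerance, kcal mol^-1 (default 0.01).
#' @param max_iterations WHAM iteration cap.
#' @return A `"pmf_profile"`; `$diagnostics` records per-block iteration
#'   counts and dropped-sample totals.
#' @examples
#' pot <- double_well_potential()
#' sims <- simulate_umbrella(pot, umbrella_ladder(),
#'   langevin_spec(n_steps = 15000, seed = 42), thermo())
#' pmf <- estimate_pmf(sims)
#' pmf
#' @export
estimate_pmf <- function(windows, grid = make_grid(),
                         thermo = loxquant::thermo(),
                         equilibration_ns = 5, block_ns = 5,
                         tolerance = 0.01, max_iterations = 1e5) {
  stopifnot(is.list(windows), length(windows) >= 1L)
  split <- lapply(windows, split_blocks, equilibration_ns = equilibration_ns,
                  block_ns = block_ns)
  n_blocks <- min(vapply(split, length, integer(1)))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    wham_solve(lapply(split, `[[`, b), grid, thermo, tolerance,
               max_iterations)
  })
  prof <- pmf_from_blocks(blocks, grid, thermo)
  prof$diagnostics <- list(
    n_iterations = vapply(blocks, `[[`, integer(1), "n_iterations"),
    n_dropped = vapply(blocks, function(b) sum(b$n_dropped), integer(1)),
    tolerance = tolerance, equilibration_ns = equilibration_ns,
    block_ns = block_ns
  )
  prof
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("Potential of mean force (%s), %d bins", x$source,
              length(x$bin_centers)))
  if (x$n_blocks > 0L) cat(sprintf(", %d block(s)", x$n_blocks))
  cat("\n")
  df <- as.data.frame(x)
  df$F_kcal_mol <- signif(df$F_kcal_mol, 4)
  df$sigma_F_kcal_mol <- signif(df$sigma_F_kcal_mol, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.pmf_profile <- function(object, ...) {
  def <- object$defined
  cat(sprintf("PMF over %d bins (%d defined)\n", length(def), sum(def)))
  if (any(def)) {
    cat(sprintf("  barrier (max defined F): %.3f kcal/mol at %g A\n",
                max(object$F[def]),
                object$bin_centers[def][which.max(object$F[def])]))
    if (object$n_blocks >= 2L) {
      cat(sprintf("  mean sigma_F: %.3f kcal/mol over %d blocks\n",
                  mean(object$sigma_F[def]), object$n_blocks))
    }
  }
  invisible(object)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(
    bin_center_A = x$bin_centers,
    F_kcal_mol = x$F,
    sigma_F_kcal_mol = x$sigma_F,
    defined = x$defined
  )
}

#' @export
plot.pmf_profile <- function(x, ..., xlab = "reaction coordinate (Å)",
                             ylab = "PMF (kcal/mol)") {
  def <- x$defined
  graphics::plot(x$bin_centers[def], x$F[def], type = "b", pch = 19,
                 xlab = xlab, ylab = ylab, ...)
  if (any(def & !is.na(x$sigma_F))) {
    graphics::arrows(x$bin_centers[def], x$F[def] - x$sigma_F[def],
                     x$bin_centers[def], x$F[def] + x$sigma_F[def],
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
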
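#' Specification for overdamped Langevin (Brownian) dynamics
#'
#' Desk-scale surrogate for the all-atom restrained simulations: the
#' reaction coordinate is propagated on U0 + bias with the
#' Euler--Maruyama update
#' x <- x - beta * D * dU/dx * dt + sqrt(2 D dt) * xi,   xi ~ N(0, 1).
#'
#' @param diffusion_coefficient D in Angstrom^2 ns^-1.
#' @param timestep Integration step dt in ns. Stability requires
#'   dt < (beta * D * max|U''|)^-1; the defaults satisfy it by a wide
#'   margin for the default double well plus a 20 kcal/mol/A^2 bias.
#' @param n_steps Number of integration steps.
#' @param sampling_interval Save every this-many steps (default 1).
#' @param x_init Starting position in Angstrom, or `NULL` to start each
#'   window at its bias center.
#' @param seed Integer RNG seed; the simulation is a pure function of
#'   the spec including this seed.
#' @return An object of class `"langevin_spec"`.
#' @export
langevin_spec <- function(diffusion_coefficient = 0.5, timestep = 0.002,
                          n_steps = 15000L, sampling_interval = 1L,
                          x_init = NULL, seed = 1L) {
  stop_if_not_scalar(diffusion_coefficient, "diffusion_coefficient",
                     positive = TRUE)
  stop_if_not_scalar(timestep, "timestep", positive = TRUE)
  stop_if_not_scalar(n_steps, "n_steps", positive = TRUE)
  stop_if_not_scalar(sampling_interval, "sampling_interval", positive = TRUE)
  if (n_steps < sampling_interval) {
    stop("'n_steps' must be >= 'sampling_interval'")
  }
  if (!is.null(x_init)) stop_if_not_scalar(x_init, "x_init")
  structure(
    list(diffusion_coefficient = diffusion_coefficient, timestep = timestep,
         n_steps = as.integer(n_steps),
         sampling_interval = as.integer(sampling_interval),
         x_init = x_init, seed = seed),
    class = "langevin_spec"
  )
}

#' One umbrella window
#'
#' A biased simulation: harmonic bias (1/2) k (x - center)^2 (one-half
#' prefactor convention) and the sampled reaction-coordinate series.
#'
#' @param center Bias center in Angstrom.
#' @param spring_constant Bias spring constant k in kcal mol^-1 A^-2.
#' @param series Numeric vector of reaction-coordinate values (Angstrom).
#' @param dt_ns Sampling interval of `series` in ns.
#' @return An object of class `"umbrella_window"`.
#' @export
umbrella_window <- function(center, spring_constant, series, dt_ns) {
  stop_if_not_scalar(center, "center")
  stop_if_not_scalar(spring_constant, "spring_constant")
  if (spring_constant < 0) stop("'spring_constant' must be >= 0")
  if (length(series) == 0L || any(!is.finite(series))) {
    stop("'series' must be non-empty and finite")
  }
  stop_if_not_scalar(dt_ns, "dt_ns", positive = TRUE)
  structure(
    list(center = center, spring_constant = spring_constant,
         series = as.numeric(series), dt_ns = dt_ns),
    class = "umbrella_window"
  )
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "Umbrella window: center %g A, k %g kcal/mol/A^2, %d samples every %g ns (%g ns total)\n",
    x$center, x$spring_constant, length(x$series), x$dt_ns,
    length(x$series) * x$dt_ns
  ))
  invisible(x)
}

#' Simulate umbrella-sampling windows by Brownian dynamics
#'
#' Runs one overdamped Langevin trajectory per window on
#' U0 + (1/2) k (x - center)^2 and returns the sampled
#' reaction-coordinate series. Replaces the molecular-dynamics engine of
#' a real umbrella-sampling study; identical specs (including the seed)
#' give bitwise-identical output.
#'
#' @param potential Ground-truth potential, a [potential_1d()].
#' @param windows Data frame with columns `center` and `spring_constant`
#'   (one row per window), or a list of such pairs.
#' @param spec A [langevin_spec()].
#' @param thermo A [thermo()] state.
#' @return A list of [umbrella_window()] objects, one per row of
#'   `windows`, in order.
#' @examples
#' pot <- double_well_potential()
#' win <- umbrella_ladder()
#' sims <- simulate_umbrella(pot, win[1:2, ],
#'   langevin_spec(n_steps = 500, seed = 7), thermo())
#' @export
simulate_umbrella <- function(potential, windows, spec = langevin_spec(),
                              thermo = loxquant::thermo()) {
  stopifnot(inherits(potential, "potential_1d"),
            inherits(spec, "langevin_spec"), inherits(thermo, "thermo"))
  windows <- as.data.frame(windows)
  if (nrow(windows) == 0L) stop("'windows' must be non-empty")
  if (!all(c("center", "spring_constant") %in% names(windows))) {
    stop("'windows' needs columns 'center' and 'spring_constant'")
  }
  centers <- as.numeric(windows$center)
  ks <- as.numeric(windows$spring_constant)
  if (any(ks < 0)) stop("spring constants must be >= 0")
  nw <- length(centers)
  D <- spec$diffusion_coefficient
  dt <- spec$timestep
  beta <- thermo$beta
  amp <- sqrt(2 * D * dt)
  keep <- spec$sampling_interval
  n_save <- spec$n_steps %/% keep
  out <- matrix(NA_real_, nrow = n_save, ncol = nw)

  with_seed(spec$seed, {
    x <- if (is.null(spec$x_init)) centers else rep(spec$x_init, nw)
    for (step in seq_len(spec$n_steps)) {
      g <- potential_gradient(potential, x) + ks * (x - centers)
      x <- x - beta * D * g * dt + amp * rnorm(nw)
      if (any(!is.finite(x)) ||
          any(!is.finite(potential_energy(potential, x)))) {
        bad <- which(!is.finite(x) |
                       !is.finite(potential_energy(potential, x)))[1L]
        stop(sprintf(
          "non-finite energy at integration step %d in window %d (center %g A)",
          step, bad, centers[bad]
        ), call. = FALSE)
      }
      if (step %% keep == 0L) out[step %/% keep, ] <- x
    }
  })

  lapply(seq_len(nw), function(w) {
    umbrella_window(centers[w], ks[w], out[, w], dt_ns = dt * keep)
  })
}

#' Default umbrella-window ladder
#'
#' Thirteen windows with centers equally spaced from 4 to 10 Angstrom and
#' spring constant 20 kcal mol^-1 A^-2 (one-half prefactor convention),
#' the standard ladder for the 3.75--10.25 Angstrom analysis grid.
#'
#' @param centers Window centers (Angstrom).
#' @param spring_constant Shared spring constant (kcal mol^-1 A^-2).
#' @return Data frame with columns `center`, `spring_constant`.
#' @export
umbrella_ladder <- function(centers = seq(4, 10, by = 0.5),
                            spring_constant = 20) {
  data.frame(center = centers, spring_constant = spring_constant)
}

#' Analytic (ground-truth) PMF of a known potential
#'
#' Bin-integrated Boltzmann reference: Fi = -kT ln Int_bin exp(-beta U0),
#' offset so the smallest Fi is zero, with zero error bars. Serves as the
#' oracle for parameter-recovery tests of the WHAM estimator.
#'
#' @param potential A [potential_1d()].
#' @param grid A [make_grid()] analysis grid.
#' @param thermo A [thermo()] state.
#' @return A `"pmf_profile"` (see [pmf_from_blocks()]) with `sigma_F = 0`.
#' @export
analytic_pmf <- function(potential, grid, thermo = loxquant::thermo()) {
  stopifnot(inherits(potential, "potential_1d"), inherits(grid, "wham_grid"),
            inherits(thermo, "thermo"))
  beta <- thermo$beta
  # subtract the minimum over the grid before exponentiating to avoid underflow
  probe <- seq(grid$lower, grid$upper, length.out = 2048L)
  u_min <- min(potential_energy(potential, probe))
  ints <- vapply(seq_len(grid$n_bins), function(i) {
    integrate(function(x) exp(-beta * (potential_energy(potential, x) - u_min)),
              lower = grid$edges[i], upper = grid$edges[i + 1L],
              rel.tol = 1e-10, abs.tol = 0)$value
  }, numeric(1))
  if (all(ints == 0)) stop("Boltzmann weight underflows in every bin")
  F <- ifelse(ints > 0, -thermo$kT * log(ints), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  new_pmf_profile(
    bin_centers = grid$centers, F = F,
    sigma_F = ifelse(is.na(F), NA_real_, 0), n_blocks = 0L,
    thermo = thermo, source = "analytic"
  )
}
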
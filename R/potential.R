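#' One-dimensional potentials
#'
#' A `potential_1d` is a sum of terms, each either a polynomial in the
#' reaction coordinate x (coefficients of increasing powers, in
#' kcal mol^-1 Angstrom^-n) or a Gaussian well of given depth, center and
#' width. These stand in for the molecular force field in the synthetic
#' umbrella-sampling generator and carry the ground truth for
#' parameter-recovery tests.
#'
#' @param ... One or more terms created by [poly_term()] or
#'   [gaussian_well_term()].
#' @return An object of class `"potential_1d"`.
#' @seealso [potential_energy()], [potential_gradient()],
#'   [double_well_potential()]
#' @examples
#' # harmonic well of stiffness 2 centered at 1: U = (x - 1)^2
#' pot <- potential_1d(poly_term(c(1, -2, 1)))
#' potential_energy(pot, c(0, 1, 2))
#' @export
potential_1d <- function(...) {
  terms <- list(...)
  if (length(terms) == 0L) stop("a potential needs at least one term")
  ok <- vapply(terms, function(t) inherits(t, "potential_term"), logical(1))
  if (!all(ok)) stop("all terms must be poly_term() or gaussian_well_term()")
  structure(list(terms = terms), class = "potential_1d")
}

#' @rdname potential_1d
#' @param coefficients Numeric vector `c(c0, c1, ...)`:
#'   U(x) = c0 + c1 x + c2 x^2 + ...
#' @export
poly_term <- function(coefficients) {
  if (!is.numeric(coefficients) || length(coefficients) == 0L ||
      any(!is.finite(coefficients))) {
    stop("'coefficients' must be a finite numeric vector")
  }
  structure(list(kind = "polynomial", coefficients = as.numeric(coefficients)),
            class = "potential_term")
}

#' @rdname potential_1d
#' @param depth Well depth in kcal mol^-1 (positive = attractive well).
#' @param center Well center in Angstrom.
#' @param width Gaussian width in Angstrom.
#' @export
gaussian_well_term <- function(depth, center, width) {
  stop_if_not_scalar(depth, "depth")
  stop_if_not_scalar(center, "center")
  stop_if_not_scalar(width, "width", positive = TRUE)
  structure(list(kind = "gaussian_well", depth = depth, center = center,
                 width = width),
            class = "potential_term")
}

#' Symmetric quartic double well
#'
#' Convenience constructor for U0(x) = a (x - c1)^2 (x - c2)^2 with the
#' prefactor `a` chosen so the barrier at the midpoint equals `barrier`.
#' The default (minima at 5 and 9 Angstrom, 3 kcal/mol barrier) exercises
#' multi-window overlap across a 4-10 Angstrom umbrella ladder.
#'
#' @param c1,c2 Positions of the two minima (Angstrom).
#' @param barrier Barrier height at the midpoint (kcal mol^-1).
#' @return A `potential_1d` with one polynomial term.
#' @export
double_well_potential <- function(c1 = 5, c2 = 9, barrier = 3) {
  stop_if_not_scalar(c1, "c1"); stop_if_not_scalar(c2, "c2")
  stop_if_not_scalar(barrier, "barrier", positive = TRUE)
  if (c1 == c2) stop("'c1' and 'c2' must differ")
  m <- (c1 + c2) / 2
  a <- barrier / ((m - c1)^2 * (m - c2)^2)
  # expand a (x-c1)^2 (x-c2)^2 into polynomial coefficients
  p1 <- c(c1^2, -2 * c1, 1)
  p2 <- c(c2^2, -2 * c2, 1)
  conv <- function(u, v) {
    out <- numeric(length(u) + length(v) - 1L)
    for (i in seq_along(u)) {
      out[i:(i + length(v) - 1L)] <- out[i:(i + length(v) - 1L)] + u[i] * v
    }
    out
  }
  potential_1d(poly_term(a * conv(p1, p2)))
}

#' Evaluate a potential or its gradient
#'
#' @param potential A [potential_1d()] object.
#' @param x Numeric vector of positions (Angstrom).
#' @return `potential_energy` returns U(x) in kcal mol^-1;
#'   `potential_gradient` returns dU/dx in kcal mol^-1 Angstrom^-1.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "potential_1d"))
  u <- numeric(length(x))
  for (term in potential$terms) {
    if (term$kind == "polynomial") {
      cf <- term$coefficients
      acc <- rep(cf[length(cf)], length(x))
      if (length(cf) > 1L) {
        for (j in rev(seq_len(length(cf) - 1L))) acc <- acc * x + cf[j]
      }
      u <- u + acc
    } else {
      u <- u - term$depth * exp(-(x - term$center)^2 / (2 * term$width^2))
    }
  }
  u
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "potential_1d"))
  g <- numeric(length(x))
  for (term in potential$terms) {
    if (term$kind == "polynomial") {
      cf <- term$coefficients
      if (length(cf) > 1L) {
        dcf <- cf[-1L] * seq_len(length(cf) - 1L)
        acc <- rep(dcf[length(dcf)], length(x))
        if (length(dcf) > 1L) {
          for (j in rev(seq_len(length(dcf) - 1L))) acc <- acc * x + dcf[j]
        }
        g <- g + acc
      }
    } else {
      g <- g + term$depth * (x - term$center) / term$width^2 *
        exp(-(x - term$center)^2 / (2 * term$width^2))
    }
  }
  g
}

#' @export
print.potential_1d <- function(x, ...) {
  cat(sprintf("1-D potential with %d term(s):\n", length(x$terms)))
  for (t in x$terms) {
    if (t$kind == "polynomial") {
      cat("  polynomial, coefficients:", paste(signif(t$coefficients, 6),
                                               collapse = ", "), "\n")
    } else {
      cat(sprintf("  gaussian well: depth %g, center %g, width %g\n",
                  t$depth, t$center, t$width))
    }
  }
  invisible(x)
}
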
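#' Specification of a synthetic microscopy image
#'
#' Round cells of known intensity on a uniform background with optional
#' Gaussian pixel noise, plus the matching label mask — a controlled
#' stand-in for a segmented fluorescence micrograph.
#'
#' @param image_shape Integer length-2 (rows, cols). Default 256 x 256.
#' @param n_cells Number of cells. Default 20.
#' @param cell_radius Cell radius in pixels. Default 8.
#' @param cell_intensities Above-background gray value per cell
#'   (recycled). Default 150.
#' @param background_level Background gray value. Default 100.
#' @param noise_sd Gaussian pixel noise (gray values). Default 2.
#' @param seed RNG seed.
#' @return An object of class `"microscopy_spec"`.
#' @export
microscopy_spec <- function(image_shape = c(256L, 256L), n_cells = 20L,
                            cell_radius = 8L, cell_intensities = 150,
                            background_level = 100, noise_sd = 2,
                            seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8))
  stop_if_not_scalar(n_cells, "n_cells")
  if (n_cells < 0) stop("'n_cells' must be >= 0")
  stop_if_not_scalar(cell_radius, "cell_radius", positive = TRUE)
  if (any(cell_intensities < 0) || background_level < 0) {
    stop("intensities must be >= 0")
  }
  stop_if_not_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(
    list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
         cell_radius = as.integer(cell_radius),
         cell_intensities = rep_len(as.numeric(cell_intensities),
                                    max(n_cells, 1L))[seq_len(n_cells)],
         background_level = background_level, noise_sd = noise_sd,
         seed = seed),
    class = "microscopy_spec"
  )
}

#' Simulate a labeled microscopy image
#'
#' Places `n_cells` non-overlapping disks (with a 2-pixel background
#' margin between cells and to the border), adds the background level
#' and optional Gaussian noise, clips at zero, and labels cells 1..n in
#' the mask. Deterministic under the seed; impossible placement after a
#' bounded number of retries is an error.
#'
#' @param spec A [microscopy_spec()].
#' @param max_tries Placement retry bound per image.
#' @return A [labeled_image()]; `$truth` carries the spec.
#' @export
simulate_microscopy <- function(spec = microscopy_spec(),
                                max_tries = 10000L) {
  stopifnot(inherits(spec, "microscopy_spec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  r <- spec$cell_radius
  margin <- 2L
  mask <- matrix(0L, nr, nc)
  img <- matrix(spec$background_level, nr, nc)

  with_seed(spec$seed, {
    if (spec$n_cells > 0L) {
      centers <- matrix(NA_real_, spec$n_cells, 2L)
      placed <- 0L
      tries <- 0L
      lim <- r + margin
      while (placed < spec$n_cells) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop(sprintf(
            "could not place %d cells of radius %d in a %d x %d image",
            spec$n_cells, r, nr, nc
          ), call. = FALSE)
        }
        ci <- runif(1, lim + 1, nr - lim)
        cj <- runif(1, lim + 1, nc - lim)
        if (placed > 0L) {
          d2 <- (centers[seq_len(placed), 1L] - ci)^2 +
            (centers[seq_len(placed), 2L] - cj)^2
          if (any(d2 < (2 * r + margin)^2)) next
        }
        placed <- placed + 1L
        centers[placed, ] <- c(ci, cj)
      }
      row_idx <- matrix(seq_len(nr), nr, nc)
      col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (k in seq_len(spec$n_cells)) {
        disk <- (row_idx - centers[k, 1L])^2 +
          (col_idx - centers[k, 2L])^2 <= r^2
        mask[disk] <- k
        img[disk] <- img[disk] + spec$cell_intensities[k]
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    img <- pmax(img, 0)
  })

  li <- labeled_image(img, mask)
  li$truth <- spec
  li
}
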
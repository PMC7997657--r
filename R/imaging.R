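#' Labeled microscopy image
#'
#' An image plus its segmentation: a grayscale matrix and a same-shape
#' integer label mask (0 = background, 1..n = cells). Segmentation is an
#' input, not a responsibility of this package.
#'
#' @param image Numeric matrix of gray values.
#' @param mask Integer matrix of labels, same shape.
#' @param bit_depth Pixel bit depth metadata (default 16).
#' @return An object of class `"labeled_image"`.
#' @export
labeled_image <- function(image, mask, bit_depth = 16L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a numeric matrix")
  }
  if (!is.matrix(mask) || !all(dim(mask) == dim(image))) {
    stop("'mask' must be a matrix with the same shape as 'image'")
  }
  mk <- as.integer(mask)
  if (any(is.na(mk)) || any(mk < 0)) {
    stop("'mask' labels must be non-negative integers")
  }
  labels <- sort(unique(mk[mk > 0L]))
  structure(
    list(image = image,
         mask = matrix(mk, nrow = nrow(mask)),
         labels = labels, bit_depth = as.integer(bit_depth)),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("Labeled image: %d x %d px, %d cell(s), %d-bit\n",
              nrow(x$image), ncol(x$image), length(x$labels), x$bit_depth))
  invisible(x)
}

#' Per-cell mean fluorescence
#'
#' Mean gray value of the pixels in each segmented area.
#'
#' @param li A [labeled_image()].
#' @return Data frame with columns `label`, `area`, `mean_intensity`
#'   (one row per label; empty when the mask has no cells).
#' @export
cell_mean_fluorescence <- function(li) {
  stopifnot(inherits(li, "labeled_image"))
  if (length(li$labels) == 0L) {
    return(data.frame(label = integer(0), area = integer(0),
                      mean_intensity = numeric(0)))
  }
  inside <- li$mask > 0L
  sums <- tapply(li$image[inside], li$mask[inside], sum)
  areas <- tapply(li$image[inside], li$mask[inside], length)
  lab <- as.integer(names(sums))
  data.frame(label = lab, area = as.integer(areas),
             mean_intensity = as.numeric(sums) / as.numeric(areas),
             row.names = NULL)
}

# Sample n_regions non-overlapping disks entirely outside all labels and
# return pooled pixel sum/count. Region placement depends only on the
# mask and the seed, never on pixel values.
background_regions <- function(li, n_regions = 8L, region_area = NULL,
                               seed = 1L, max_tries = 10000L) {
  stopifnot(inherits(li, "labeled_image"))
  stop_if_not_scalar(n_regions, "n_regions", positive = TRUE)
  nr <- nrow(li$mask); nc <- ncol(li$mask)
  if (is.null(region_area)) {
    if (length(li$labels) == 0L) {
      stop("'region_area' must be given when the mask has no cells")
    }
    region_area <- median(tabulate(li$mask[li$mask > 0L]) [li$labels])
  }
  stop_if_not_scalar(region_area, "region_area", positive = TRUE)
  radius <- max(1, round(sqrt(region_area / pi)))
  occupied <- li$mask > 0L
  taken <- matrix(FALSE, nr, nc)
  dx <- outer(-radius:radius, rep(1, 2 * radius + 1))
  dy <- t(dx)
  disk <- which(dx^2 + dy^2 <= radius^2, arr.ind = TRUE)
  disk <- cbind(disk[, 1L] - (radius + 1L), disk[, 2L] - (radius + 1L))

  with_seed(seed, {
    regions <- vector("list", n_regions)
    placed <- 0L
    tries <- 0L
    while (placed < n_regions) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(
          "could not place %d background regions of area %d (%d free background pixels)",
          n_regions, as.integer(region_area), sum(!occupied & !taken)
        ), call. = FALSE)
      }
      ci <- sample.int(nr - 2L * radius, 1L) + radius
      cj <- sample.int(nc - 2L * radius, 1L) + radius
      px <- cbind(ci + disk[, 1L], cj + disk[, 2L])
      idx <- px[, 1L] + (px[, 2L] - 1L) * nr
      if (any(occupied[idx]) || any(taken[idx])) next
      taken[idx] <- TRUE
      placed <- placed + 1L
      regions[[placed]] <- idx
    }
    regions
  })
}

#' Image background level from random cell-free regions
#'
#' Estimates the background fluorescence from `n_regions` (default 8)
#' random, non-overlapping disk regions placed entirely outside all
#' segmented cells, each with area similar to a single cell (default:
#' the median cell area). Returns the mean gray value over the pooled
#' region pixels; deterministic under the seed.
#'
#' @param li A [labeled_image()].
#' @param n_regions Number of regions. Default 8.
#' @param region_area Region area in pixels; default median cell area.
#' @param seed RNG seed for region placement.
#' @param max_tries Placement retry bound.
#' @return Background gray value, with attribute `regions` (list of
#'   pixel index vectors, one per region).
#' @export
background_level <- function(li, n_regions = 8L, region_area = NULL,
                             seed = 1L, max_tries = 10000L) {
  regions <- background_regions(li, n_regions, region_area, seed, max_tries)
  px <- unlist(regions)
  structure(sum(li$image[px]) / length(px), regions = regions)
}

#' Background-corrected per-cell intensities
#'
#' Combines [cell_mean_fluorescence()] with one shared
#' [background_level()] per image: corrected = cell mean - background.
#' Internally the subtraction is carried out on pooled pixel sums with a
#' common denominator, which cancels any uniform offset exactly (adding
#' a constant to the whole image leaves every corrected intensity
#' bit-identical). Corrected values may be negative under noise and are
#' never clipped.
#'
#' @inheritParams background_level
#' @return Data frame with columns `label`, `area`, `mean_intensity`,
#'   `background`, `corrected_intensity`.
#' @examples
#' li <- simulate_microscopy(microscopy_spec(n_cells = 4, noise_sd = 0,
#'                                           seed = 2))
#' corrected_intensities(li, seed = 3)
#' @export
corrected_intensities <- function(li, n_regions = 8L, region_area = NULL,
                                  seed = 1L, max_tries = 10000L) {
  cells <- cell_mean_fluorescence(li)
  regions <- background_regions(li, n_regions, region_area, seed, max_tries)
  px <- unlist(regions)
  s_b <- sum(li$image[px])
  n_b <- length(px)
  inside <- li$mask > 0L
  s_c <- as.numeric(tapply(li$image[inside], li$mask[inside], sum))
  n_c <- as.numeric(cells$area)
  cells$background <- s_b / n_b
  # (S_c n_b - S_b n_c) / (n_c n_b): exact cancellation of uniform offsets
  cells$corrected_intensity <- (s_c * n_b - s_b * n_c) / (n_c * n_b)
  cells
}
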
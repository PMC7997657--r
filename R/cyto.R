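#' Default cytometry channel map
#'
#' Maps the logical roles used by the gating functions onto column names
#' of an event table. The canonical CSV dialect uses `FSC-H`, `SSC-H`
#' and `FL`.
#'
#' @param fsc,ssc,fl Column names for forward scatter, side scatter and
#'   the fluorescence channel.
#' @return Named character vector with entries `fsc`, `ssc`, `fl`.
#' @export
channel_map <- function(fsc = "FSC-H", ssc = "SSC-H", fl = "FL") {
  c(fsc = fsc, ssc = ssc, fl = fl)
}

chan <- function(events, map, which) {
  col <- map[[which]]
  if (is.null(col) || !col %in% names(events)) {
    stop(sprintf("channel '%s' (%s) not found in event table", which, col),
         call. = FALSE)
  }
  v <- events[[col]]
  if (!all(is.finite(v))) stop("event values must be finite", call. = FALSE)
  v
}

#' Automatic density gate on scatter channels
#'
#' Estimates a product-Gaussian kernel density over (FSC-H, SSC-H),
#' evaluated exactly at every event, and gates the
#' `ceiling(target_fraction * n)` densest events: the density threshold
#' d* is the per-event density quantile that encloses exactly the target
#' fraction, with ties broken by input order. This reproduces an
#' automatic perimeter containing a fixed fraction (default 40%) of the
#' events; the raster contour polygon is attached for display only.
#'
#' @param events Data frame of events (see [channel_map()]).
#' @param target_fraction Fraction of events to enclose, in (0, 1).
#'   Default 0.4.
#' @param bandwidth Optional numeric length-2 bandwidth (FSC, SSC);
#'   default is Silverman's rule of thumb per axis ([stats::bw.nrd0()]).
#' @param grid_resolution Raster size for the display polygon only.
#' @param map Channel map.
#' @param polygon Compute the display contour? Default `FALSE` (it costs
#'   an extra grid evaluation and affects no downstream quantity).
#' @return An object of class `"gate_region"`: logical `in_gate`,
#'   per-event `density`, `threshold_density` (d*), `centroid` (mean
#'   gated FSC/SSC), `n_gated`, `bandwidth`, and optionally `polygon`
#'   (list of x/y contour paths).
#' @examples
#' ev <- simulate_cytometry(cytometry_spec(n_events = 500, seed = 1))
#' g <- kde_gate(ev)
#' g$n_gated / nrow(ev) # exactly 0.4
#' @export
kde_gate <- function(events, target_fraction = 0.4, bandwidth = NULL,
                     grid_resolution = 64L, map = channel_map(),
                     polygon = FALSE) {
  events <- as.data.frame(events)
  n <- nrow(events)
  if (n < 10L) stop("need at least 10 events to gate")
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1) {
    stop("'target_fraction' must lie strictly between 0 and 1")
  }
  x <- chan(events, map, "fsc")
  y <- chan(events, map, "ssc")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate scatter: zero variance on an axis")
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(bw.nrd0(x), bw.nrd0(y))
  }
  stopifnot(length(bandwidth) == 2L, all(bandwidth > 0))
  dens <- .kde2d_at(x, y, x, y, bandwidth[1L], bandwidth[2L])
  m <- as.integer(ceiling(target_fraction * n))
  ord <- order(dens, decreasing = TRUE) # stable: ties keep input order
  sel <- ord[seq_len(m)]
  in_gate <- logical(n)
  in_gate[sel] <- TRUE
  dstar <- dens[ord[m]]

  poly <- NULL
  if (isTRUE(polygon)) {
    gx <- seq(min(x) - 2 * bandwidth[1L], max(x) + 2 * bandwidth[1L],
              length.out = grid_resolution)
    gy <- seq(min(y) - 2 * bandwidth[2L], max(y) + 2 * bandwidth[2L],
              length.out = grid_resolution)
    gz <- matrix(.kde2d_at(x, y, rep(gx, times = grid_resolution),
                           rep(gy, each = grid_resolution),
                           bandwidth[1L], bandwidth[2L]),
                 nrow = grid_resolution)
    poly <- grDevices::contourLines(gx, gy, gz, levels = dstar)
  }

  structure(
    list(in_gate = in_gate, density = dens, threshold_density = dstar,
         centroid = c(fsc = mean(x[in_gate]), ssc = mean(y[in_gate])),
         n_gated = m, target_fraction = target_fraction,
         bandwidth = bandwidth, polygon = poly,
         sample_id = attr(events, "sample_id", exact = TRUE)),
    class = "gate_region"
  )
}

#' @export
print.gate_region <- function(x, ...) {
  cat(sprintf(
    "Density gate: %d events enclosed (target %.1f%%), centroid (%.1f, %.1f)\n",
    x$n_gated, 100 * x$target_fraction, x$centroid[["fsc"]],
    x$centroid[["ssc"]]
  ))
  invisible(x)
}

#' Flag samples whose gate drifted from the rest of an experiment
#'
#' Screens an experiment's gates for shifted cell populations: on each
#' scatter axis the gate centroids are summarised by their median and
#' MAD ([stats::mad()], consistency constant 1.4826), and a sample is
#' flagged when its centroid sits more than `mad_cutoff` MADs from the
#' median on either axis. A zero MAD on an axis flags nothing on that
#' axis. Flagged samples should be excluded from downstream aggregation.
#'
#' @param gates List of [kde_gate()] results from one experiment
#'   (at least 3).
#' @param mad_cutoff Cutoff in MAD units. Default 5.
#' @return Logical vector of flags, named by sample id when available.
#' @export
flag_outlier_samples <- function(gates, mad_cutoff = 5) {
  stopifnot(is.list(gates))
  if (length(gates) < 3L) {
    stop("outlier screening needs at least 3 samples per experiment")
  }
  stop_if_not_scalar(mad_cutoff, "mad_cutoff", positive = TRUE)
  cent <- t(vapply(gates, function(g) {
    stopifnot(inherits(g, "gate_region"))
    g$centroid
  }, numeric(2)))
  flags <- rep(FALSE, nrow(cent))
  for (axis in 1:2) {
    med <- median(cent[, axis])
    m <- mad(cent[, axis])
    if (m > 0) flags <- flags | (abs(cent[, axis] - med) > mad_cutoff * m)
  }
  ids <- vapply(gates, function(g) {
    if (is.null(g$sample_id)) NA_character_ else as.character(g$sample_id)
  }, character(1))
  if (!all(is.na(ids))) names(flags) <- ids
  flags
}

#' ON/OFF threshold from a gated negative control
#'
#' The threshold separating reporter-ON from reporter-OFF cells is the
#' empirical `percentile` (default 99.9) of the gated fluorescence
#' values of the negative-control sample, computed by linear
#' interpolation between the closest order statistics
#' ([stats::quantile()] type 6), so that exactly `percentile`% of the
#' gated negative-control values sit at or below it.
#'
#' @param negative Event table of the negative-control sample.
#' @param gate The [kde_gate()] computed on that same sample.
#' @param percentile Percentile in (0, 100). Default 99.9.
#' @param map Channel map.
#' @return The threshold (numeric scalar).
#' @export
negative_threshold <- function(negative, gate, percentile = 99.9,
                               map = channel_map()) {
  stopifnot(inherits(gate, "gate_region"))
  role <- attr(negative, "role", exact = TRUE)
  if (!is.null(role) && !identical(role, "negative_control")) {
    stop("'negative' must be a negative-control sample")
  }
  if (percentile <= 0 || percentile >= 100) {
    stop("'percentile' must lie strictly between 0 and 100")
  }
  fl <- chan(as.data.frame(negative), map, "fl")
  if (length(fl) != length(gate$in_gate)) {
    stop("gate was computed on a different sample")
  }
  gated <- fl[gate$in_gate]
  if (length(gated) < 100L) {
    stop("need at least 100 gated negative-control events")
  }
  unname(quantile(gated, probs = percentile / 100, type = 6))
}

#' Fraction of gated cells above the ON threshold
#'
#' @param sample Event table.
#' @param gate [kde_gate()] computed on the same sample.
#' @param threshold ON/OFF fluorescence threshold (strictly-greater
#'   comparison: a cell exactly at the threshold is OFF).
#' @param map Channel map.
#' @return An object of class `"switch_result"`: `sample_id`,
#'   `threshold`, `fraction_on`, `n_gated`, `n_on`, `outlier_flag`.
#' @export
fraction_on <- function(sample, gate, threshold, map = channel_map()) {
  stopifnot(inherits(gate, "gate_region"))
  stop_if_not_scalar(threshold, "threshold")
  fl <- chan(as.data.frame(sample), map, "fl")
  if (length(fl) != length(gate$in_gate)) {
    stop("gate was computed on a different sample")
  }
  gated <- fl[gate$in_gate]
  n_on <- sum(gated > threshold)
  structure(
    list(sample_id = attr(sample, "sample_id", exact = TRUE),
         threshold = threshold, fraction_on = n_on / length(gated),
         n_gated = length(gated), n_on = n_on, outlier_flag = FALSE),
    class = "switch_result"
  )
}

#' @export
print.switch_result <- function(x, ...) {
  cat(sprintf("Switch result%s: %.4f ON (%d / %d gated, threshold %.4g)\n",
              if (is.null(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$fraction_on, x$n_on, x$n_gated, x$threshold))
  invisible(x)
}

#' Per-condition summary statistics
#'
#' Mean, standard error of the mean (sd / sqrt(n), sample sd) and n per
#' condition, the form reported in figures as mean +/- s.e.m. A group of
#' one yields an `NA` s.e.m.
#'
#' @param groups Named list of numeric vectors (one per condition), or a
#'   named list of lists of `"switch_result"` objects.
#' @return Data frame with columns `condition`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  vals <- lapply(groups, function(g) {
    if (is.list(g) && all(vapply(g, inherits, logical(1), "switch_result"))) {
      vapply(g, `[[`, numeric(1), "fraction_on")
    } else {
      as.numeric(g)
    }
  })
  if (any(vapply(vals, length, integer(1)) == 0L)) {
    stop("empty group")
  }
  data.frame(
    condition = if (is.null(names(groups))) {
      as.character(seq_along(groups))
    } else {
      names(groups)
    },
    n = vapply(vals, length, integer(1)),
    mean = vapply(vals, mean, numeric(1)),
    sem = vapply(vals, function(v) {
      if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    row.names = NULL
  )
}

#' Two-group comparison
#'
#' The two tests used for condition comparisons: Welch's two-sided
#' two-sample t-test, or the two-sided Wilcoxon rank-sum test (exact for
#' combined n <= 20 without ties, normal approximation with continuity
#' correction above). Two constant groups with equal values give p = 1
#' by convention.
#'
#' @param group_a,group_b Numeric vectors.
#' @param method `"t_test"` or `"wilcoxon"`.
#' @return List with `method`, `statistic`, `p_value`.
#' @examples
#' compare_conditions(c(1, 2, 3), c(4, 5, 6), "wilcoxon")$p_value # 0.1
#' @export
compare_conditions <- function(group_a, group_b,
                               method = c("t_test", "wilcoxon")) {
  method <- match.arg(method)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (method == "t_test") {
    if (length(a) < 2L || length(b) < 2L) {
      stop("t_test needs at least 2 values per group")
    }
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) {
        return(list(method = method, statistic = 0, p_value = 1))
      }
      stop("both groups constant with different means: t statistic undefined")
    }
    ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    list(method = method, statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    if (length(a) < 1L || length(b) < 1L) {
      stop("wilcoxon needs at least 1 value per group")
    }
    exact <- (length(a) + length(b)) <= 20L
    ht <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = exact,
                  correct = !exact)
    )
    list(method = method, statistic = unname(ht$statistic),
         p_value = ht$p.value)
  }
}
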
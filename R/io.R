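# File formats: window CSVs with '# key=value' metadata headers, a
# window manifest, event-table CSVs, PMF CSVs, and 16-bit grayscale
# TIFF images/masks.

#' Write / read umbrella-window CSV files
#'
#' One CSV per window with metadata header lines (`# center=`, `# k=`,
#' `# dt_ns=`) followed by columns `time_ns`, `xi_angstrom`. A panel of
#' windows is described by a manifest CSV listing each file with its
#' bias parameters.
#'
#' @param window An [umbrella_window()].
#' @param path Output file path.
#' @return `write_window_csv` returns `path` invisibly;
#'   `read_window_csv` an [umbrella_window()]; `write_window_panel` the
#'   manifest path; `read_window_panel` a list of windows.
#' @export
write_window_csv <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# center=%s", fmt9(window$center)),
    sprintf("# k=%s", fmt9(window$spring_constant)),
    sprintf("# dt_ns=%s", fmt9(window$dt_ns)),
    "time_ns,xi_angstrom"
  ), con)
  t_ns <- seq_along(window$series) * window$dt_ns
  writeLines(paste(fmt9(t_ns), fmt9(window$series), sep = ","), con)
  invisible(path)
}

#' @rdname write_window_csv
#' @export
read_window_csv <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (length(m) != 1L) stop(sprintf("missing '%s' metadata in %s", key, path))
    as.numeric(sub(sprintf("^#\\s*%s=", key), "", m))
  }
  df <- read.csv(path, comment.char = "#")
  umbrella_window(get_meta("center"), get_meta("k"), df$xi_angstrom,
                  get_meta("dt_ns"))
}

#' @rdname write_window_csv
#' @param windows List of [umbrella_window()] objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @export
write_window_panel <- function(windows, dir, prefix = "window") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(windows))
  for (i in seq_along(windows)) {
    files[i] <- sprintf("%s_%02d.csv", prefix, i)
    write_window_csv(windows[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    file = files,
    center = vapply(windows, `[[`, numeric(1), "center"),
    spring_constant = vapply(windows, `[[`, numeric(1), "spring_constant")
  )
  write_csv9(manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname write_window_csv
#' @param manifest_path Path to a panel manifest CSV.
#' @export
read_window_panel <- function(manifest_path) {
  manifest <- read.csv(manifest_path)
  dir <- dirname(manifest_path)
  lapply(manifest$file, function(f) read_window_csv(file.path(dir, f)))
}

#' Write a PMF profile to CSV
#'
#' Columns: `bin_center_A`, `F_kcal_mol`, `sigma_F_kcal_mol`,
#' `defined_flag`.
#'
#' @param pmf A `"pmf_profile"`.
#' @param path Output path.
#' @export
write_pmf_csv <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  df <- as.data.frame(pmf)
  names(df)[names(df) == "defined"] <- "defined_flag"
  write_csv9(df, path)
  invisible(path)
}

#' Write / read cytometry event tables
#'
#' Canonical CSV dialect with columns `FSC-H`, `SSC-H`, `FL` (plus any
#' extra columns such as the simulation's `population` label). Sample
#' metadata (`sample_id`, `role`) travels as attributes.
#'
#' @param events Event data frame.
#' @param path File path.
#' @export
write_event_csv <- function(events, path) {
  write_csv9(as.data.frame(events), path)
  invisible(path)
}

#' @rdname write_event_csv
#' @param sample_id,role Optional metadata attached to the returned
#'   table.
#' @export
read_event_csv <- function(path, sample_id = NULL, role = NULL) {
  ev <- read.csv(path, check.names = FALSE)
  if (!is.null(sample_id)) attr(ev, "sample_id") <- sample_id
  if (!is.null(role)) attr(ev, "role") <- role
  ev
}

#' Write / read 16-bit grayscale TIFF images and label masks
#'
#' Gray values are stored as 16-bit unsigned integers (0..65535); label
#' masks use the same representation with 0 = background.
#'
#' @param x Numeric matrix (image) or integer matrix (mask).
#' @param path File path.
#' @export
write_image_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  if (any(x < 0) || any(x > 65535)) {
    stop("gray values must lie in [0, 65535] for 16-bit storage")
  }
  tiff::writeTIFF(round(x) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.numeric(img), nrow = nrow(img))
}

#' @rdname write_image_tiff
#' @param image_path,mask_path Paths of the image and mask TIFFs.
#' @export
read_labeled_image <- function(image_path, mask_path) {
  labeled_image(read_image_tiff(image_path),
                matrix(as.integer(read_image_tiff(mask_path)),
                       nrow = nrow(read_image_tiff(mask_path))))
}
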
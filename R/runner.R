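#' Default pipeline configuration
#'
#' A nested list with one block per stage, pre-filled with the canonical
#' analysis constants: 13 bins between 3.75 and 10.25 Angstrom, WHAM
#' tolerance 0.01 kcal/mol, 5 ns equilibration + 5 ns blocks, 310 K, a
#' 40% density gate, the 99.9th-percentile negative-control threshold
#' and 8 background regions. All randomness derives from `seed`.
#'
#' @param out_dir Output directory for [run_pipeline()].
#' @param stages Character vector of stage names, a subset of
#'   `simulate-umbrella`, `pmf`, `simulate-cyto`, `gate`,
#'   `simulate-qpcr`, `qpcr`, `simulate-image`, `imaging`, or `"all"`.
#' @param seed Base RNG seed; per-stage seeds are derived from it.
#' @return A named list (class `"run_config"`).
#' @export
default_config <- function(out_dir = tempfile("loxquant_run_"),
                           stages = "all", seed = 1L) {
  structure(list(
    stages = stages,
    seed = as.integer(seed),
    out_dir = out_dir,
    pmf = list(
      lower = 3.75, upper = 10.25, n_bins = 13L,
      temperature = 310, tolerance = 0.01,
      equilibration_ns = 5, block_ns = 5,
      centers = seq(4, 10, by = 0.5), spring_constant = 20,
      diffusion_coefficient = 0.5, timestep = 0.002, n_steps = 15000L,
      sampling_interval = 1L,
      well_centers = c(5, 9), barrier = 3,
      input_dir = NULL
    ),
    cyto = list(
      target_fraction = 0.4, percentile = 99.9, mad_cutoff = 5,
      n_events = 10000L, on_fractions = c(0.05, 0.25, 0.5),
      debris_fraction = 0.05, sample_sheet = NULL,
      channels = list(fsc = "FSC-H", ssc = "SSC-H", fl = "FL")
    ),
    qpcr = list(
      true_fraction = 0.3,
      calibration_fractions = c(0, 0.005, 0.01, 0.05, 0.1, 0.5, 0.7,
                                0.9, 1),
      intercept_Ct = 30, slope = -3.3219, noise_sd = 0.2, replicates = 3L
    ),
    imaging = list(
      n_regions = 8L, image_shape = c(256L, 256L), n_cells = 20L,
      cell_radius = 8L, cell_intensities = 150, background_level = 100,
      noise_sd = 2
    )
  ), class = "run_config")
}

all_stages <- c("simulate-umbrella", "pmf", "simulate-cyto", "gate",
                "simulate-qpcr", "qpcr", "simulate-image", "imaging")

expand_stages <- function(stages) {
  if (identical(stages, "all") || "all" %in% stages) all_stages else stages
}

finding <- function(field, message, domain = NULL) {
  data.frame(field = field, message = message,
             domain = if (is.null(domain)) "" else domain)
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its documented domain. An empty result
#' means the configuration is runnable; each finding carries the field
#' path, a message, and the allowed domain.
#'
#' @param config A [default_config()]-shaped list.
#' @return Data frame with columns `field`, `message`, `domain`
#'   (zero rows when valid).
#' @examples
#' nrow(validate_config(default_config())) # 0
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(x) f[[length(f) + 1L]] <<- x
  chk <- function(value, field, ok, domain) {
    if (!isTRUE(ok)) add(finding(field, "out of domain", domain))
  }
  stages <- expand_stages(config$stages)
  unknown <- setdiff(stages, all_stages)
  for (s in unknown) add(finding("stages", paste("unknown stage", s),
                                 paste(all_stages, collapse = ", ")))
  p <- config$pmf
  chk(p$n_bins, "pmf.n_bins", is.numeric(p$n_bins) && p$n_bins >= 1,
      ">= 1")
  chk(p$upper, "pmf.upper", is.numeric(p$upper) && p$upper > p$lower,
      "> pmf.lower")
  chk(p$tolerance, "pmf.tolerance",
      is.numeric(p$tolerance) && p$tolerance > 0, "> 0")
  chk(p$temperature, "pmf.temperature",
      is.numeric(p$temperature) && p$temperature > 0, "> 0 K")
  chk(p$block_ns, "pmf.block_ns", is.numeric(p$block_ns) && p$block_ns > 0,
      "> 0 ns")
  chk(p$equilibration_ns, "pmf.equilibration_ns",
      is.numeric(p$equilibration_ns) && p$equilibration_ns >= 0, ">= 0 ns")
  chk(p$spring_constant, "pmf.spring_constant",
      is.numeric(p$spring_constant) && p$spring_constant >= 0,
      ">= 0 kcal/mol/A^2")
  chk(p$timestep, "pmf.timestep", is.numeric(p$timestep) && p$timestep > 0,
      "> 0 ns")
  chk(p$diffusion_coefficient, "pmf.diffusion_coefficient",
      is.numeric(p$diffusion_coefficient) && p$diffusion_coefficient > 0,
      "> 0 A^2/ns")
  cy <- config$cyto
  chk(cy$target_fraction, "cyto.target_fraction",
      is.numeric(cy$target_fraction) && cy$target_fraction > 0 &&
        cy$target_fraction < 1, "(0, 1)")
  chk(cy$percentile, "cyto.percentile",
      is.numeric(cy$percentile) && cy$percentile > 0 && cy$percentile < 100,
      "(0, 100)")
  chk(cy$mad_cutoff, "cyto.mad_cutoff",
      is.numeric(cy$mad_cutoff) && cy$mad_cutoff > 0, "> 0")
  chk(cy$n_events, "cyto.n_events",
      is.numeric(cy$n_events) && cy$n_events >= 10, ">= 10")
  chk(cy$on_fractions, "cyto.on_fractions",
      is.numeric(cy$on_fractions) && all(cy$on_fractions >= 0) &&
        all(cy$on_fractions <= 1), "[0, 1]")
  if ("gate" %in% stages && !"simulate-cyto" %in% stages) {
    sheet <- cy$sample_sheet
    ok <- FALSE
    if (!is.null(sheet) && file.exists(sheet)) {
      ss <- read.csv(sheet)
      if ("role" %in% names(ss)) {
        exps <- unique(ss$experiment)
        missing <- exps[!vapply(exps, function(e) {
          any(ss$role[ss$experiment == e] == "negative_control")
        }, logical(1))]
        if (length(missing) == 0L) {
          ok <- TRUE
        } else {
          for (e in missing) {
            add(finding("cyto.sample_sheet",
                        sprintf("experiment '%s' has no negative control", e),
                        "one role=negative_control row per experiment"))
          }
          ok <- TRUE # the specific findings above already cover it
        }
      }
    }
    if (!ok) {
      add(finding("cyto.sample_sheet",
                  "gate stage without simulate-cyto needs an existing sample sheet with a negative control",
                  "path to CSV with columns sample_id, file, role, condition"))
    }
  }
  q <- config$qpcr
  chk(q$slope, "qpcr.slope", is.numeric(q$slope) && q$slope < 0, "< 0")
  chk(q$replicates, "qpcr.replicates",
      is.numeric(q$replicates) && q$replicates >= 1, ">= 1")
  chk(q$true_fraction, "qpcr.true_fraction",
      is.numeric(q$true_fraction) && q$true_fraction >= 0 &&
        q$true_fraction <= 1, "[0, 1]")
  chk(q$calibration_fractions, "qpcr.calibration_fractions",
      is.numeric(q$calibration_fractions) &&
        all(q$calibration_fractions >= 0 & q$calibration_fractions <= 1) &&
        any(q$calibration_fractions > 0), "[0, 1], at least one > 0")
  im <- config$imaging
  chk(im$n_regions, "imaging.n_regions",
      is.numeric(im$n_regions) && im$n_regions >= 1, ">= 1")
  chk(im$n_cells, "imaging.n_cells",
      is.numeric(im$n_cells) && im$n_cells >= 0, ">= 0")
  chk(config$seed, "seed", is.numeric(config$seed) &&
        is.finite(config$seed), "finite integer")
  if (length(f) == 0L) {
    data.frame(field = character(0), message = character(0),
               domain = character(0))
  } else {
    do.call(rbind, f)
  }
}

#' Run the quantification pipeline
#'
#' Executes the requested stages in dependency order, writing CSV/JSON
#' (and TIFF, for images) outputs under `config$out_dir`. Every stage's
#' randomness is derived from `config$seed`, so an identical
#' configuration reproduces byte-identical CSV outputs.
#'
#' @param config A [default_config()]-shaped list.
#' @return An object of class `"run_record"`: the config snapshot,
#'   package version, per-stage timings (seconds), collected warnings,
#'   and an output manifest with MD5 checksums.
#' @export
run_pipeline <- function(config = default_config()) {
  findings <- validate_config(config)
  if (nrow(findings) > 0L) {
    stop(paste0("invalid configuration:\n", paste(
      sprintf("  %s: %s (allowed: %s)", findings$field, findings$message,
              findings$domain), collapse = "\n")), call. = FALSE)
  }
  stages <- expand_stages(config$stages)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- numeric(0)
  warns <- character(0)
  note_warning <- function(w) warns <<- c(warns, conditionMessage(w))
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note_warning(w)
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
  }
  th <- thermo(temperature = config$pmf$temperature)

  if ("simulate-umbrella" %in% stages) run_stage("simulate-umbrella", function() {
    p <- config$pmf
    pot <- double_well_potential(p$well_centers[1L], p$well_centers[2L],
                                 p$barrier)
    n_steps <- as.integer(round(
      (p$equilibration_ns + 5 * p$block_ns) / p$timestep))
    if (!is.null(p$n_steps)) n_steps <- as.integer(p$n_steps)
    sims <- simulate_umbrella(
      pot, umbrella_ladder(p$centers, p$spring_constant),
      langevin_spec(p$diffusion_coefficient, p$timestep, n_steps,
                    p$sampling_interval, seed = config$seed),
      th
    )
    write_window_panel(sims, file.path(out, "umbrella"))
  })

  if ("pmf" %in% stages) run_stage("pmf", function() {
    p <- config$pmf
    src <- if (is.null(p$input_dir)) file.path(out, "umbrella") else p$input_dir
    windows <- read_window_panel(file.path(src, "manifest.csv"))
    prof <- estimate_pmf(windows, make_grid(p$lower, p$upper, p$n_bins), th,
                         p$equilibration_ns, p$block_ns, p$tolerance)
    write_pmf_csv(prof, file.path(out, "pmf.csv"))
    jsonlite::write_json(
      list(n_blocks = prof$n_blocks,
           iterations_per_block = prof$diagnostics$n_iterations,
           dropped_samples_per_block = prof$diagnostics$n_dropped,
           tolerance = prof$diagnostics$tolerance,
           temperature_K = th$temperature),
      file.path(out, "pmf_summary.json"), auto_unbox = TRUE, digits = NA
    )
  })

  if ("simulate-cyto" %in% stages) run_stage("simulate-cyto", function() {
    cy <- config$cyto
    dir.create(file.path(out, "cyto"), showWarnings = FALSE)
    rows <- list()
    emit <- function(sample_id, role, condition, on_fraction, seed) {
      ev <- simulate_cytometry(cytometry_spec(
        n_events = cy$n_events, on_fraction = on_fraction,
        debris_fraction = cy$debris_fraction, seed = seed
      ))
      file <- sprintf("%s.csv", sample_id)
      write_event_csv(ev, file.path(out, "cyto", file))
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, file = file, role = role,
        condition = condition, experiment = "exp1"
      )
    }
    emit("negctrl", "negative_control", "negative", 0, config$seed + 100L)
    for (i in seq_along(cy$on_fractions)) {
      emit(sprintf("sample_%02d", i), "test",
           sprintf("on_%g", cy$on_fractions[i]), cy$on_fractions[i],
           config$seed + 100L + i)
    }
    write_csv9(do.call(rbind, rows), file.path(out, "cyto",
                                               "sample_sheet.csv"))
  })

  if ("gate" %in% stages) run_stage("gate", function() {
    cy <- config$cyto
    sheet_path <- if (is.null(cy$sample_sheet)) {
      file.path(out, "cyto", "sample_sheet.csv")
    } else {
      cy$sample_sheet
    }
    sheet <- read.csv(sheet_path)
    map <- do.call(channel_map, cy$channels)
    dirn <- dirname(sheet_path)
    samples <- lapply(seq_len(nrow(sheet)), function(i) {
      read_event_csv(file.path(dirn, sheet$file[i]),
                     sample_id = sheet$sample_id[i], role = sheet$role[i])
    })
    gates <- lapply(samples, kde_gate, target_fraction = cy$target_fraction,
                    map = map)
    flags <- flag_outlier_samples(gates, cy$mad_cutoff)
    neg_i <- which(sheet$role == "negative_control")[1L]
    threshold <- negative_threshold(samples[[neg_i]], gates[[neg_i]],
                                    cy$percentile, map)
    res <- lapply(seq_along(samples), function(i) {
      r <- fraction_on(samples[[i]], gates[[i]], threshold, map)
      r$outlier_flag <- unname(flags[i])
      r
    })
    res_df <- data.frame(
      sample_id = sheet$sample_id, condition = sheet$condition,
      role = sheet$role,
      threshold = threshold,
      fraction_on = vapply(res, `[[`, numeric(1), "fraction_on"),
      n_gated = vapply(res, `[[`, integer(1), "n_gated"),
      outlier_flag = vapply(res, `[[`, logical(1), "outlier_flag")
    )
    write_csv9(res_df, file.path(out, "switch_results.csv"))
    keep <- res_df$role == "test" & !res_df$outlier_flag
    groups <- split(res_df$fraction_on[keep], res_df$condition[keep])
    write_csv9(summarize_groups(groups), file.path(out, "cyto_summary.csv"))
  })

  if ("simulate-qpcr" %in% stages) run_stage("simulate-qpcr", function() {
    q <- config$qpcr
    sim <- simulate_qpcr(qpcr_spec(
      true_fraction = q$true_fraction,
      calibration_fractions = q$calibration_fractions,
      intercept_Ct = q$intercept_Ct, slope = q$slope,
      noise_sd = q$noise_sd, replicates = q$replicates,
      seed = config$seed + 200L
    ))
    write_csv9(sim$calibration, file.path(out, "qpcr_calibration.csv"))
    write_csv9(sim$sample, file.path(out, "qpcr_samples.csv"))
  })

  if ("qpcr" %in% stages) run_stage("qpcr", function() {
    cal <- read.csv(file.path(out, "qpcr_calibration.csv"))
    smp <- read.csv(file.path(out, "qpcr_samples.csv"))
    curve <- fit_standard_curve(cal)
    # total-template assay at known unit quantity: Ct at the curve intercept
    est <- excision_fraction(smp$Ct, curve, curve$intercept, curve)
    write_csv9(data.frame(
      assay = "lox", intercept = curve$intercept, slope = curve$slope,
      r_squared = curve$r_squared, n_points = curve$n_points,
      n_excluded = curve$n_excluded,
      amplification_efficiency = curve$amplification_efficiency
    ), file.path(out, "qpcr_curves.csv"))
    write_csv9(data.frame(
      n_lox = est$n_lox, n_total = est$n_total, fraction = est$fraction,
      flagged = est$flagged
    ), file.path(out, "qpcr_excision.csv"))
  })

  if ("simulate-image" %in% stages) run_stage("simulate-image", function() {
    im <- config$imaging
    li <- simulate_microscopy(microscopy_spec(
      image_shape = im$image_shape, n_cells = im$n_cells,
      cell_radius = im$cell_radius, cell_intensities = im$cell_intensities,
      background_level = im$background_level, noise_sd = im$noise_sd,
      seed = config$seed + 300L
    ))
    write_image_tiff(li$image, file.path(out, "image.tiff"))
    write_image_tiff(li$mask, file.path(out, "mask.tiff"))
  })

  if ("imaging" %in% stages) run_stage("imaging", function() {
    li <- read_labeled_image(file.path(out, "image.tiff"),
                             file.path(out, "mask.tiff"))
    cells <- corrected_intensities(li, config$imaging$n_regions,
                                   seed = config$seed + 400L)
    write_csv9(cells, file.path(out, "cell_intensities.csv"))
  })

  files <- setdiff(list.files(out, recursive = TRUE), "run_record.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files)))
  )
  record <- structure(
    list(config = config, version = as.character(packageVersion("loxquant")),
         timings = as.list(timings), warnings = warns, manifest = manifest),
    class = "run_record"
  )
  jsonlite::write_json(
    list(version = record$version, stages = stages,
         timings_s = record$timings, warnings = warns,
         manifest = manifest),
    file.path(out, "run_record.json"), auto_unbox = TRUE, digits = NA
  )
  record
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("Pipeline run (loxquant %s): %d stage(s), %d output file(s)\n",
              x$version, length(x$timings), nrow(x$manifest)))
  for (s in names(x$timings)) {
    cat(sprintf("  %-18s %.2fs\n", s, x$timings[[s]]))
  }
  if (length(x$warnings)) {
    cat("  warnings:", length(x$warnings), "\n")
  }
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; scalar
#' fields override, unknown fields are kept verbatim.
#'
#' @param path YAML file path.
#' @return A `"run_config"` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_lists(unclass(base), user), class = "run_config")
}
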
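#' Serialize / parse a simulation configuration
#'
#' YAML or JSON is chosen from the file extension. Round-tripping a config
#' (write, read, write) is the identity, which keeps validation runs
#' reproducible from their manifest.
#'
#' @param config A [sim_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("muscles", "axes", "shared_fraction", "emg_amplitude_mv",
              "burst_width", "rom_targets_deg", "misalignment_euler_deg"))
    x[[f]] <- unlist(x[[f]])
  do.call(sim_config, x)
}

# deterministic sub-stream seeds keyed by participant/side/stage
substream_seed <- function(base, participant, side, stage) {
  idx <- (participant - 1L) * 2L + (side == "left")
  (as.integer(base) + 104729L * idx +
     7919L * match(stage, c("timeline", "emg", "kin"))) %% 2147483111L
}

#' Simulate one participant-limb and run both pipelines
#'
#' Generates the timeline, the paired EMG recording and the paired kinematic
#' recording for one participant and limb (sub-stream seeds derived from the
#' config seed), then runs the EMG and kinematics chains.
#'
#' @param config A [sim_config()].
#' @param participant Participant index (1-based).
#' @param side `"right"` or `"left"`.
#' @param alignment Alignment mode passed to [run_kinematics_pipeline()].
#' @return List with `annotation`, `emg` (pipeline output per system),
#'   `rom` (kinematics output), `emg_truth`, `kin_truth`, `alignment`.
#' @export
simulate_participant <- function(config, participant, side,
                                 alignment = "procrustes") {
  ann <- generate_timeline(
    config, substream_seed(config$seed, participant, side, "timeline"))
  emg <- generate_emg_pair(
    ann, config, substream_seed(config$seed, participant, side, "emg"),
    side = side)
  kin <- generate_kinematics_pair(
    ann, config, substream_seed(config$seed, participant, side, "kin"),
    side = side)
  emg_dev <- run_emg_pipeline(emg$device, ann, config$adc_bits,
                              config$vref_volts, config$adc_gain)
  emg_ref <- run_emg_pipeline(emg$reference, ann, config$adc_bits,
                              config$vref_volts, config$adc_gain)
  rom_res <- run_kinematics_pipeline(kin$imu_euler, kin$cam, ann,
                                     alignment = alignment)
  emg_dev$system <- "device"; emg_ref$system <- "reference"
  list(annotation = ann, emg = rbind(emg_dev, emg_ref), rom = rom_res,
       emg_truth = emg$truth, kin_truth = kin$truth,
       alignment = attr(rom_res, "alignment"))
}

#' Run the full synthetic validation study
#'
#' Simulates a cohort (default 11 participants x 2 limbs), runs the EMG and
#' kinematics pipelines on every recording pair, and assembles the agreement
#' tables (one row per muscle x limb and per axis x limb). When `outdir` is
#' given, tidy measure tables, agreement tables, Bland-Altman point tables,
#' the config snapshot and a run manifest (seed, package version, file
#' digests, warnings) are written there.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if missing).
#' @param seed Overrides `config$seed` when given.
#' @return (Invisibly) a list with `emg_measures`, `rom_measures`,
#'   `agreement_emg`, `agreement_rom`, `ba_points_emg`, `ba_points_rom`,
#'   `truth` (per participant-limb ground-truth summaries), `config`,
#'   `seed`, and `manifest` (when written).
#' @export
run_full_validation <- function(config = sim_config(), outdir = NULL,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  warnings_log <- character(0)
  emg_rows <- list(); rom_rows <- list(); truth <- list()
  withCallingHandlers(
    for (p in seq_len(config$n_participants)) {
      for (side in c("right", "left")) {
        sim <- tryCatch(
          simulate_participant(config, p, side),
          error = function(e) stop(sprintf(
            "participant %d (%s), stage failure: %s", p, side,
            conditionMessage(e)), call. = FALSE))
        e <- sim$emg
        emg_rows[[length(emg_rows) + 1L]] <- data.frame(
          participant = p, side = side, target = e$muscle,
          system = e$system, repetition = e$repetition, value = e$rms)
        r <- sim$rom
        rom_rows[[length(rom_rows) + 1L]] <- data.frame(
          participant = p, side = side, target = r$axis,
          system = r$system, repetition = r$repetition, value = r$rom_deg)
        truth[[paste(p, side, sep = "_")]] <- list(
          latent_rms = sim$emg_truth$latent_rms,
          true_rom_deg = colMeans(sim$kin_truth$true_rom_deg),
          alignment_error_deg = rotation_angle_deg(
            sim$alignment, t(sim$kin_truth$true_alignment)))
      }
    },
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  emg_measures <- do.call(rbind, emg_rows)
  rom_measures <- do.call(rbind, rom_rows)
  agreement_emg <- build_agreement_table(emg_measures)
  agreement_rom <- build_agreement_table(rom_measures)
  ba_points <- function(measures) {
    head_ <- measures[measures$repetition == 0L, ]
    combos <- unique(head_[c("target", "side")])
    out <- list()
    for (i in seq_len(nrow(combos))) {
      sub <- head_[head_$target == combos$target[i] &
                     head_$side == combos$side[i], ]
      wide <- merge(sub[sub$system == "device", c("participant", "value")],
                    sub[sub$system == "reference", c("participant", "value")],
                    by = "participant", suffixes = c("_d", "_r"))
      pd <- bland_altman_plot_data(wide$value_d, wide$value_r)
      out[[i]] <- data.frame(target = combos$target[i],
                             side = combos$side[i], pd$points,
                             bias = pd$bias, loa_lower = pd$loa_lower,
                             loa_upper = pd$loa_upper)
    }
    do.call(rbind, out)
  }
  res <- list(emg_measures = emg_measures, rom_measures = rom_measures,
              agreement_emg = agreement_emg, agreement_rom = agreement_rom,
              ba_points_emg = ba_points(emg_measures),
              ba_points_rom = ba_points(rom_measures),
              truth = truth, config = config, seed = config$seed,
              warnings = warnings_log)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(rms = "rms.csv", rom = "rom.csv",
               agreement_emg = "agreement_emg.csv",
               agreement_rom = "agreement_rom.csv",
               ba_emg = "bland_altman_points_emg.csv",
               ba_rom = "bland_altman_points_rom.csv",
               config = "config.yaml")
    utils::write.csv(stats::setNames(
      emg_measures, c("participant", "side", "muscle", "system",
                      "repetition", "rms")),
      file.path(outdir, files["rms"]), row.names = FALSE)
    utils::write.csv(stats::setNames(
      rom_measures, c("participant", "side", "axis", "system",
                      "cycle", "rom_deg")),
      file.path(outdir, files["rom"]), row.names = FALSE)
    utils::write.csv(agreement_emg, file.path(outdir, files["agreement_emg"]),
                     row.names = FALSE)
    utils::write.csv(agreement_rom, file.path(outdir, files["agreement_rom"]),
                     row.names = FALSE)
    utils::write.csv(res$ba_points_emg, file.path(outdir, files["ba_emg"]),
                     row.names = FALSE)
    utils::write.csv(res$ba_points_rom, file.path(outdir, files["ba_rom"]),
                     row.names = FALSE)
    write_sim_config(config, file.path(outdir, files["config"]))
    paths <- file.path(outdir, unname(files))
    manifest <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("wearval")),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      config = unclass(config),
      outputs = stats::setNames(
        as.list(unname(tools::md5sum(paths))), basename(paths)),
      warnings = warnings_log)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  invisible(res)
}

fmt2 <- function(x) formatC(x, digits = 2, format = "f")

#' Render a human-readable validation report
#'
#' Markdown tables mirroring the layout of a device-validation report (bias,
#' LOA, Pearson r, between- and intra-device ICC, CV per system), with
#' 2-decimal rounding applied only here, at render time. Accepts either the
#' result list of [run_full_validation()] or a results directory containing
#' its CSV/manifest output.
#'
#' @param results A [run_full_validation()] result or a directory path.
#' @param path Optional file to write the report to.
#' @return Character vector of report lines (invisibly when `path` is given).
#' @export
render_report <- function(results, path = NULL) {
  if (is.character(results)) {
    dir <- results
    need <- file.path(dir, c("agreement_emg.csv", "agreement_rom.csv",
                             "manifest.json"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("missing results file: ", missing[1L], call. = FALSE)
    results <- list(
      agreement_emg = utils::read.csv(need[1L]),
      agreement_rom = utils::read.csv(need[2L]),
      seed = jsonlite::read_json(need[3L])$seed)
  }
  tab <- function(df, target_label) {
    hdr <- c(target_label, "Limb", "Bias", "LOA (Lower-Upper)", "Pearson r",
             "ICC (between)", "ICC (device)", "ICC (reference)",
             "CV% (device)", "CV% (reference)")
    rows <- apply(df, 1L, function(r) {
      x <- as.list(r)
      paste("|", paste(c(
        x$target, x$side, fmt2(as.numeric(x$bias)),
        sprintf("%s to %s", fmt2(as.numeric(x$loa_lower)),
                fmt2(as.numeric(x$loa_upper))),
        fmt2(as.numeric(x$pearson_r)), fmt2(as.numeric(x$icc_between)),
        fmt2(as.numeric(x$icc_intra_device)),
        fmt2(as.numeric(x$icc_intra_reference)),
        fmt2(as.numeric(x$cv_device_pct)),
        fmt2(as.numeric(x$cv_reference_pct))), collapse = " | "), "|")
    })
    c(paste("|", paste(hdr, collapse = " | "), "|"),
      paste("|", paste(rep("---", length(hdr)), collapse = " | "), "|"),
      rows)
  }
  lines <- c(
    "# Wearable validation report",
    "",
    sprintf("Seed: %d", as.integer(results$seed)),
    "",
    "## EMG amplitude agreement (normalized RMS, device vs reference)",
    "",
    tab(results$agreement_emg, "Muscle"),
    "",
    "## Shoulder range-of-motion agreement (degrees, IMU vs camera)",
    "",
    tab(results$agreement_rom, "Axis"))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
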
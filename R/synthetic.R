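#' Simulation configuration for the synthetic paired-sensor study
#'
#' Bundles every constant of the emulated validation study: 11 participants,
#' 2 limbs, 6 shoulder muscles observed by two EMG systems at 1000 Hz, one
#' segment-orientation trajectory observed by an IMU (through a fixed mounting
#' misalignment) and by an optical reference at 100 Hz, five task repetitions
#' separated by 5 s rests. Device and reference observe a shared latent muscle
#' activation; the `shared_fraction` per muscle controls how much of the
#' participant-level activation shape is common to both systems (1 = identical
#' latent, 0 = independent), which is the generator's dial for muscle-dependent
#' agreement.
#'
#' @param n_participants Number of participants in a simulated cohort.
#' @param n_cycles Task repetitions per recording.
#' @param cycle_duration_mean_s,cycle_duration_sd_s Cycle duration mean/SD in
#'   seconds (durations are redrawn until positive).
#' @param rest_s Rest interval between repetitions, seconds.
#' @param emg_rate_hz,imu_rate_hz,cam_rate_hz Sampling rates, samples/s.
#' @param muscles Muscle labels (6 shoulder muscles).
#' @param axes Named axis labels (`axis1` = abduction/adduction, `axis2` =
#'   flexion/extension, `axis3` = lateral/medial rotation).
#' @param shared_fraction Per-muscle shared-latent fraction in `[0, 1]`.
#' @param emg_amplitude_mv Per-muscle peak envelope amplitude, millivolts.
#' @param burst_width Per-muscle activation burst width as a fraction of the
#'   cycle duration (Hann-window support).
#' @param burst_width_participant_sd,burst_width_cycle_sd SDs of the
#'   participant-level and cycle-level burst-width variation (fractions).
#' @param burst_center_sd SD of the burst-center jitter (fraction of cycle).
#' @param device_gain,reference_gain Multiplicative analog gain of each system.
#' @param device_offset_counts,reference_offset_counts Baseline offsets added
#'   to the digitized signal, ADC counts.
#' @param device_noise_sd_counts,reference_noise_sd_counts Additive white
#'   measurement noise SD, ADC counts.
#' @param adc_bits,vref_volts,adc_gain ADC transfer-function constants shared
#'   by both systems (see [counts_to_volts()]).
#' @param ecg_artifact_amplitude_mv Amplitude of the 72 beats/min biphasic
#'   cardiac-artifact spike train added to the left pectoralis major channels
#'   (0 disables it).
#' @param rom_targets_deg Per-axis true range of motion, degrees (must be
#'   < 180 to keep unwrapping unambiguous).
#' @param rom_participant_sd,rom_cycle_sd Fractional SDs of the participant-
#'   and cycle-level ROM variation (shared by both systems: same motion).
#' @param misalignment_euler_deg Fixed IMU-to-segment mounting rotation,
#'   degrees (roll, pitch, yaw).
#' @param orientation_noise_deg Per-frame orientation noise SD of the camera
#'   (small random rotations: axis uniform on the sphere, angle ~
#'   `N(0, sd)`), degrees.
#' @param imu_orientation_noise_deg Per-frame orientation noise SD of the IMU
#'   (same small-random-rotation model, applied to the mounted orientation
#'   before the Euler readout), degrees.
#' @param imu_angle_gain Multiplicative error on the angular excursion sensed
#'   by the IMU (1 = unbiased); used to inject a known inter-device ROM bias.
#' @param seed Integer seed; together with the config it fully determines
#'   every generated output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 11,
                       n_cycles = 5,
                       cycle_duration_mean_s = 10,
                       cycle_duration_sd_s = 1,
                       rest_s = 5,
                       emg_rate_hz = 1000,
                       imu_rate_hz = 100,
                       cam_rate_hz = 100,
                       muscles = c("PM", "AD", "MD", "PD", "UT", "LT"),
                       axes = c(axis1 = "ABD/ADD", axis2 = "F/E",
                                axis3 = "LR/MR"),
                       shared_fraction = c(PM = 0.80, AD = 0.90, MD = 0.85,
                                           PD = 0.50, UT = 0.55, LT = 0.55),
                       emg_amplitude_mv = c(PM = 0.18, AD = 0.28, MD = 0.23,
                                            PD = 0.13, UT = 0.21, LT = 0.12),
                       burst_width = c(PM = 0.35, AD = 0.55, MD = 0.45,
                                       PD = 0.25, UT = 0.50, LT = 0.30),
                       burst_width_participant_sd = 0.06,
                       burst_width_cycle_sd = 0.04,
                       burst_center_sd = 0.03,
                       device_gain = 1.0,
                       reference_gain = 1.0,
                       device_offset_counts = 40,
                       reference_offset_counts = 25,
                       device_noise_sd_counts = 8,
                       reference_noise_sd_counts = 8,
                       adc_bits = 12,
                       vref_volts = 3.3,
                       adc_gain = 1000,
                       ecg_artifact_amplitude_mv = 0.12,
                       rom_targets_deg = c(axis1 = 30, axis2 = 20,
                                           axis3 = 45),
                       rom_participant_sd = 0.15,
                       rom_cycle_sd = 0.08,
                       misalignment_euler_deg = c(roll = 12, pitch = -7,
                                                  yaw = 9),
                       orientation_noise_deg = 1.0,
                       imu_orientation_noise_deg = 1.0,
                       imu_angle_gain = 1.0,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$emg_rate_hz, cfg$imu_rate_hz, cfg$cam_rate_hz)
  if (any(rates <= 0)) stop("sampling rates must be positive", call. = FALSE)
  if (cfg$n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (cfg$cycle_duration_mean_s <= 0 || cfg$cycle_duration_sd_s < 0 ||
      cfg$rest_s < 0)
    stop("cycle duration/rest parameters must be positive", call. = FALSE)
  if (any(cfg$shared_fraction < 0 | cfg$shared_fraction > 1))
    stop("`shared_fraction` must lie in [0, 1]", call. = FALSE)
  if (any(cfg$rom_targets_deg < 0))
    stop("`rom_targets_deg` must be >= 0", call. = FALSE)
  for (f in c("shared_fraction", "emg_amplitude_mv", "burst_width"))
    cfg[[f]] <- expand_per_muscle(cfg[[f]], cfg$muscles, f)
  if (length(cfg$axes) != 3L || length(cfg$rom_targets_deg) != 3L ||
      length(cfg$misalignment_euler_deg) != 3L)
    stop("`axes`, `rom_targets_deg` and `misalignment_euler_deg` must have ",
         "3 elements", call. = FALSE)
  names(cfg$axes) <- names(cfg$rom_targets_deg) <-
    c("axis1", "axis2", "axis3")
  names(cfg$misalignment_euler_deg) <- c("roll", "pitch", "yaw")
  class(cfg) <- "sim_config"
  cfg
}

expand_per_muscle <- function(x, muscles, what) {
  if (length(x) == 1L) x <- stats::setNames(rep(x, length(muscles)), muscles)
  if (is.null(names(x))) names(x) <- muscles
  if (!all(muscles %in% names(x)))
    stop(sprintf("`%s` must be named for every muscle", what), call. = FALSE)
  x[muscles]
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d participants x 2 limbs, %d cycles (%g +/- %g s, ",
    "%g s rest)\nEMG %g Hz (%s), IMU %g Hz, camera %g Hz, seed %d\n"),
    x$n_participants, x$n_cycles, x$cycle_duration_mean_s,
    x$cycle_duration_sd_s, x$rest_s, x$emg_rate_hz,
    paste(x$muscles, collapse = ","), x$imu_rate_hz, x$cam_rate_hz,
    as.integer(x$seed)))
  invisible(x)
}

#' Generate a seeded cycle timeline
#'
#' Draws `n_cycles` durations from the configured mean/SD (redrawn until
#' positive) and lays them out from t = 0 separated by the rest interval.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [cycle_annotation()] with `n_cycles` non-overlapping intervals.
#' @export
generate_timeline <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  dur <- stats::rnorm(config$n_cycles, config$cycle_duration_mean_s,
                      config$cycle_duration_sd_s)
  for (i in seq_len(50)) {
    bad <- dur <= 0
    if (!any(bad)) break
    dur[bad] <- stats::rnorm(sum(bad), config$cycle_duration_mean_s,
                             config$cycle_duration_sd_s)
  }
  if (any(dur <= 0))
    stop("could not draw positive cycle durations; check configuration",
         call. = FALSE)
  starts <- cumsum(c(0, utils::head(dur, -1L) + config$rest_s))
  cycle_annotation(starts, starts + dur, fps = NA_real_, source = "synthetic")
}

# Hann burst evaluated at normalized cycle positions u in [0, 1)
hann_burst <- function(u, center, width) {
  v <- numeric(length(u))
  inside <- abs(u - center) < width / 2
  v[inside] <- 0.5 * (1 + cos(2 * pi * (u[inside] - center) / width))
  v
}

# latent-mixing helper: fraction f of the shared draw, 1 - f system-specific
mix_latent <- function(f, shared, specific) f * shared + (1 - f) * specific

#' Generate a paired EMG recording (device + reference) with known truth
#'
#' Each muscle channel is `gain * (envelope x wideband carrier)` digitized
#' through the configured ADC transfer function, plus a baseline offset and
#' white noise. The activation envelope is a per-cycle Hann burst whose width
#' and center mix a participant-level shared latent with system-specific
#' variation according to the muscle's `shared_fraction`. Both systems observe
#' the same carrier, so with zero noise, equal gains and shared fraction 1 the
#' two recordings are identical up to the baseline offset. For the left limb a
#' 72 beats/min biphasic cardiac-artifact spike train contaminates the
#' pectoralis-major channel of each system (independent phases).
#'
#' @param annotation A [cycle_annotation()] from [generate_timeline()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param side `"left"` or `"right"` (controls the cardiac artifact).
#' @return List with elements `device`, `reference` (both [ts_recording()] in
#'   ADC counts, one column per muscle) and `truth` (latent per-cycle
#'   envelopes on a 1700-point grid and the latent normalized-mean-cycle RMS
#'   per muscle).
#' @export
generate_emg_pair <- function(annotation, config, seed = config$seed,
                              side = c("right", "left")) {
  stopifnot(inherits(annotation, "cycle_annotation"),
            inherits(config, "sim_config"))
  side <- match.arg(side)
  set.seed(seed)
  rate <- config$emg_rate_hz
  span <- max(annotation$end_s) + config$rest_s
  if (min(annotation$start_s) < 0)
    stop("annotation extends before the recording span", call. = FALSE)
  n <- round(span * rate)
  t <- (seq_len(n) - 1L) / rate
  nc <- nrow(annotation)
  muscles <- config$muscles
  full_scale <- 2^config$adc_bits - 1
  mv_to_counts <- function(mv)
    (mv * 1e-3 * config$adc_gain / config$vref_volts) * full_scale

  dev <- matrix(0, n, length(muscles), dimnames = list(NULL, muscles))
  ref <- dev
  # drawn up front (whether used or not) so the RNG stream, and hence every
  # non-PM channel, is identical for the two sides under the same seed
  ecg_phase <- stats::runif(2, 0, 60 / 72)
  grid <- (seq_len(1700) - 0.5) / 1700
  latent_env <- array(0, dim = c(nc, 1700, length(muscles)),
                      dimnames = list(NULL, NULL, muscles))
  latent_rms <- stats::setNames(numeric(length(muscles)), muscles)

  for (m in seq_along(muscles)) {
    mus <- muscles[m]
    f <- config$shared_fraction[[mus]]
    # participant-level burst geometry: shared latent + system-specific parts
    w_base <- config$burst_width[[mus]]
    w_sh <- w_base + stats::rnorm(1, 0, config$burst_width_participant_sd)
    w_dv <- w_base + stats::rnorm(1, 0, config$burst_width_participant_sd)
    w_rf <- w_base + stats::rnorm(1, 0, config$burst_width_participant_sd)
    # per-cycle jitters, mixed the same way so f = 1 collapses the systems
    jw_sh <- stats::rnorm(nc, 0, config$burst_width_cycle_sd)
    jw_dv <- stats::rnorm(nc, 0, config$burst_width_cycle_sd)
    jw_rf <- stats::rnorm(nc, 0, config$burst_width_cycle_sd)
    jc_sh <- stats::rnorm(nc, 0, config$burst_center_sd)
    jc_dv <- stats::rnorm(nc, 0, config$burst_center_sd)
    jc_rf <- stats::rnorm(nc, 0, config$burst_center_sd)
    clampw <- function(w) pmin(0.9, pmax(0.08, w))
    w_dev_c <- clampw(mix_latent(f, w_sh + jw_sh, w_dv + jw_dv))
    w_ref_c <- clampw(mix_latent(f, w_sh + jw_sh, w_rf + jw_rf))
    w_lat_c <- clampw(w_sh + jw_sh)
    c_dev_c <- 0.5 + mix_latent(f, jc_sh, jc_dv)
    c_ref_c <- 0.5 + mix_latent(f, jc_sh, jc_rf)
    c_lat_c <- 0.5 + jc_sh
    # amplitude: participant factor shared, session factor mixed
    a_part <- config$emg_amplitude_mv[[mus]] * exp(stats::rnorm(1, 0, 0.10))
    z_sh <- stats::rnorm(1, 0, 0.05); z_dv <- stats::rnorm(1, 0, 0.05)
    z_rf <- stats::rnorm(1, 0, 0.05)
    a_dev <- a_part * exp(mix_latent(f, z_sh, z_dv))
    a_ref <- a_part * exp(mix_latent(f, z_sh, z_rf))

    env_dev <- numeric(n); env_ref <- numeric(n)
    for (k in seq_len(nc)) {
      s <- annotation$start_s[k]; e <- annotation$end_s[k]
      idx <- which(t >= s & t < e)
      u <- (t[idx] - s) / (e - s)
      env_dev[idx] <- a_dev * hann_burst(u, c_dev_c[k], w_dev_c[k])
      env_ref[idx] <- a_ref * hann_burst(u, c_ref_c[k], w_ref_c[k])
      latent_env[k, , m] <- hann_burst(grid, c_lat_c[k], w_lat_c[k])
    }
    carrier <- stats::rnorm(n)      # shared wideband myoelectric carrier
    sig_dev <- env_dev * carrier * config$device_gain
    sig_ref <- env_ref * carrier * config$reference_gain
    if (side == "left" && mus == "PM" &&
        config$ecg_artifact_amplitude_mv > 0) {
      sig_dev <- sig_dev + ecg_spike_train(
        t, config$ecg_artifact_amplitude_mv * config$device_gain,
        phase = ecg_phase[1L])
      sig_ref <- sig_ref + ecg_spike_train(
        t, config$ecg_artifact_amplitude_mv * config$reference_gain,
        phase = ecg_phase[2L])
    }
    dev[, m] <- mv_to_counts(sig_dev) + 0.5 * full_scale +
      config$device_offset_counts +
      stats::rnorm(n, 0, config$device_noise_sd_counts)
    ref[, m] <- mv_to_counts(sig_ref) + 0.5 * full_scale +
      config$reference_offset_counts +
      stats::rnorm(n, 0, config$reference_noise_sd_counts)
    # latent truth: RMS of the mean of per-cycle 0-1 normalized envelopes
    norm_env <- latent_env[, , m, drop = FALSE][, , 1]
    if (nc == 1L) norm_env <- matrix(norm_env, 1L)
    peaks <- apply(norm_env, 1L, max)
    norm_env <- norm_env / ifelse(peaks > 0, peaks, 1)
    latent_rms[m] <- sqrt(mean(colMeans(norm_env)^2))
  }
  truth <- list(latent_envelopes = latent_env, latent_rms = latent_rms,
                side = side)
  list(device = ts_recording(dev, rate, start_s = 0, units = "counts"),
       reference = ts_recording(ref, rate, start_s = 0, units = "counts"),
       truth = truth)
}

# biphasic (derivative-of-Gaussian) spike train at 72 beats/min
ecg_spike_train <- function(t, amplitude, phase, sigma_s = 0.015) {
  out <- numeric(length(t))
  if (!length(t)) return(out)
  beats <- seq(phase, max(t), by = 60 / 72)
  dt <- t[2] - t[1]
  half <- 5 * sigma_s
  for (b in beats) {
    i0 <- max(1L, ceiling((b - half) / dt) + 1L)
    i1 <- min(length(t), floor((b + half) / dt) + 1L)
    if (i0 > i1) next
    x <- t[i0:i1] - b
    out[i0:i1] <- out[i0:i1] +
      amplitude * (x / sigma_s) * exp(0.5 - x^2 / (2 * sigma_s^2))
  }
  out
}

#' Generate a paired kinematic recording (IMU + camera) with known truth
#'
#' A ground-truth segment orientation `R_true(t)` is built from per-axis
#' smooth quartic-sine bumps whose per-cycle peak-to-peak excursions equal
#' the configured (participant- and cycle-modulated) ROM targets. The camera observes `R_true(t)` perturbed by small random
#' rotations; the IMU is rigidly mounted, so it observes
#' `R_true(t) %*% R_mis` (body-fixed misalignment) reported as Euler angles
#' plus angular noise. `imu_angle_gain` scales the angular excursion the IMU
#' senses, injecting a known multiplicative ROM bias.
#'
#' @inheritParams generate_emg_pair
#' @return List with elements `imu_euler` (a [ts_recording()] with channels
#'   roll/pitch/yaw in degrees), `cam` (a [rotation_trajectory()]) and `truth`
#'   (the mounting rotation, per-axis/cycle true ROM, and the angle traces).
#' @export
generate_kinematics_pair <- function(annotation, config, seed = config$seed,
                                     side = c("right", "left")) {
  stopifnot(inherits(annotation, "cycle_annotation"),
            inherits(config, "sim_config"))
  side <- match.arg(side)
  if (any(config$rom_targets_deg >= 180))
    stop("ROM targets must be < 180 degrees (unwrap ambiguity)",
         call. = FALSE)
  set.seed(seed)
  span <- max(annotation$end_s) + config$rest_s
  nc <- nrow(annotation)
  axes <- names(config$axes)

  fac_p <- 1 + stats::rnorm(3, 0, config$rom_participant_sd)
  fac_c <- matrix(1 + stats::rnorm(3 * nc, 0, config$rom_cycle_sd), nc, 3)
  rom_true <- sweep(fac_c, 2L, pmax(0, fac_p) * config$rom_targets_deg, `*`)
  rom_true <- pmin(pmax(rom_true, 0), 179)
  colnames(rom_true) <- axes

  angle_at <- function(t) {
    th <- matrix(0, length(t), 3L)
    for (k in seq_len(nc)) {
      s <- annotation$start_s[k]; e <- annotation$end_s[k]
      idx <- which(t >= s & t < e)
      # quartic-sine bump: peak-to-peak exactly rom_true, and flat enough at
      # the cycle boundaries that the initial reference window sees rest
      shape <- sin(pi * (t[idx] - s) / (e - s))^4
      for (a in 1:3) th[idx, a] <- rom_true[k, a] * shape
    }
    th
  }

  # camera stream: R_true perturbed by small body-frame noise rotations
  t_cam <- seq(0, span, by = 1 / config$cam_rate_hz)
  t_cam <- t_cam[t_cam < span]
  th_cam <- angle_at(t_cam)
  R_cam <- euler_to_rot9(th_cam[, 1], th_cam[, 2], th_cam[, 3])
  if (config$orientation_noise_deg > 0)
    R_cam <- rot9_compose(
      R_cam, random_rot9(length(t_cam), config$orientation_noise_deg))
  cam <- rotation_trajectory(t_cam, R_cam, side = side, system = "camera",
                             check = FALSE)

  # IMU stream: mounted sensor, Euler readout with angular noise
  R_mis <- euler_to_matrix(config$misalignment_euler_deg[[1]],
                           config$misalignment_euler_deg[[2]],
                           config$misalignment_euler_deg[[3]])
  t_imu <- seq(0, span, by = 1 / config$imu_rate_hz)
  t_imu <- t_imu[t_imu < span]
  th_imu <- angle_at(t_imu) * config$imu_angle_gain
  R_imu <- rot9_rcompose(
    euler_to_rot9(th_imu[, 1], th_imu[, 2], th_imu[, 3]), R_mis)
  if (config$imu_orientation_noise_deg > 0)
    R_imu <- rot9_compose(
      R_imu, random_rot9(length(t_imu), config$imu_orientation_noise_deg))
  eul <- rot9_to_euler(R_imu)
  E <- cbind(roll = eul$roll, pitch = eul$pitch, yaw = eul$yaw)
  imu <- ts_recording(E, config$imu_rate_hz, start_s = 0, units = "deg")

  list(imu_euler = imu, cam = cam,
       truth = list(true_alignment = R_mis, true_rom_deg = rom_true,
                    side = side))
}

# n random rotations with axis uniform on the sphere, angle ~ N(0, sd_deg)
random_rot9 <- function(n, sd_deg) {
  ang <- stats::rnorm(n, 0, sd_deg) * pi / 180
  ax <- matrix(stats::rnorm(3 * n), n, 3L)
  ax <- ax / sqrt(rowSums(ax^2))
  ca <- cos(ang); sa <- sin(ang); omc <- 1 - ca
  x <- ax[, 1]; y <- ax[, 2]; z <- ax[, 3]
  cbind(ca + x * x * omc,      x * y * omc + z * sa,  x * z * omc - y * sa,
        x * y * omc - z * sa,  ca + y * y * omc,      y * z * omc + x * sa,
        x * z * omc + y * sa,  y * z * omc - x * sa,  ca + z * z * omc)
}

#' Inject a synchronization tap into a recording
#'
#' Adds a short half-sine transient (the accelerometer signature of the
#' manual synchronization tap) to one channel; all other samples are
#' unchanged.
#'
#' @param recording A [ts_recording()].
#' @param time_s Tap onset time, seconds; must lie inside the recording.
#' @param amplitude Peak amplitude of the transient, recording units.
#' @param width_s Transient duration, seconds.
#' @param channel Channel label or index to receive the tap.
#' @return The modified [ts_recording()].
#' @export
inject_sync_tap <- function(recording, time_s, amplitude, width_s = 0.01,
                            channel = 1L) {
  stopifnot(inherits(recording, "ts_recording"))
  t <- rec_times(recording)
  if (time_s < t[1L] || time_s >= t[length(t)])
    stop("tap time lies outside the recording span", call. = FALSE)
  idx <- which(t >= time_s & t < time_s + width_s)
  if (length(idx))
    recording$data[idx, channel] <- recording$data[idx, channel] +
      amplitude * sin(pi * (t[idx] - time_s) / width_s)
  recording
}
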
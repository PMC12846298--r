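#' Estimate the rigid IMU-to-segment alignment
#'
#' Finds the fixed rotation `A` minimizing
#' `sum_t || R_cam(t) - R_imu(t) %*% A ||_F^2` over time-matched frame pairs
#' (nearest-neighbor matching within half the coarser sample period): the
#' orthogonal-Procrustes solution `A = U diag(1, 1, det(U V')) V'` from the
#' SVD of `sum_t t(R_imu(t)) %*% R_cam(t)`. For a rigidly mounted sensor this
#' recovers the (inverse of the) unknown mounting rotation.
#'
#' @param imu,cam [rotation_trajectory()] objects for the same limb.
#' @return A 3x3 rotation matrix (orthonormal, det +1), with the number of
#'   matched pairs as attribute `"n_pairs"`.
#' @export
estimate_rigid_alignment <- function(imu, cam) {
  stopifnot(inherits(imu, "rotation_trajectory"),
            inherits(cam, "rotation_trajectory"))
  step_imu <- stats::median(diff(imu$times))
  step_cam <- stats::median(diff(cam$times))
  tol <- max(step_imu, step_cam) / 2
  j <- findInterval(imu$times, cam$times + step_cam / 2) + 1L
  j[j > length(cam$times)] <- length(cam$times)
  ok <- abs(cam$times[j] - imu$times) <= tol
  if (sum(ok) < 3L)
    stop("fewer than 3 time-matched frame pairs for alignment", call. = FALSE)
  Vi <- imu$mats[ok, , drop = FALSE]
  Vc <- cam$mats[j[ok], , drop = FALSE]
  C <- crossprod(Vi, Vc)              # 9 x 9
  M <- matrix(0, 3, 3)
  for (i in 1:3) for (jj in 1:3)
    M[i, jj] <- sum(C[cbind((i - 1L) * 3L + 1:3, (jj - 1L) * 3L + 1:3)])
  s <- svd(M)
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate accumulation: alignment is not identifiable",
         call. = FALSE)
  A <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  attr(A, "n_pairs") <- sum(ok)
  A
}

#' Reference a trajectory to its initial pose
#'
#' Computes the chordal [mean_rotation()] over the first `ref_window_s`
#' seconds and expresses every frame relative to it,
#' `R_rel(t) = t(R0_bar) %*% R(t)`, so the initial pose maps to (near)
#' identity and subsequent analysis concerns relative angular variation only.
#' The relative orientation is returned as an Euler-angle stream.
#'
#' @param traj A [rotation_trajectory()].
#' @param ref_window_s Reference window length, seconds; must lie within the
#'   trajectory.
#' @return A [ts_recording()] with channels `roll`, `pitch`, `yaw` in degrees
#'   (gimbal-locked samples flagged in the `"gimbal_lock"` attribute).
#' @export
reference_to_initial <- function(traj, ref_window_s = 0.3) {
  stopifnot(inherits(traj, "rotation_trajectory"))
  t0 <- traj$times[1L]
  idx <- which(traj$times < t0 + ref_window_s)
  if (length(idx) == length(traj$times))
    stop("reference window spans the whole trajectory", call. = FALSE)
  if (!length(idx)) stop("empty reference window", call. = FALSE)
  R0 <- mean_rotation(traj$mats[idx, , drop = FALSE])
  rel <- rot9_lcompose(t(R0), traj$mats)
  e <- rot9_to_euler(rel)
  rate <- 1 / stats::median(diff(traj$times))
  out <- ts_recording(cbind(roll = e$roll, pitch = e$pitch, yaw = e$yaw),
                      rate_hz = rate, start_s = traj$times[1L], units = "deg")
  attr(out, "gimbal_lock") <- e$lock
  out
}

#' Unwrap a degree-valued angle series
#'
#' Adds multiples of 360 degrees so that consecutive differences lie in
#' (-180, 180], removing artificial +/-180 discontinuities. The first sample
#' is unchanged.
#'
#' @param angles Numeric vector, degrees.
#' @return Unwrapped angles.
#' @export
unwrap_degrees <- function(angles) {
  if (length(angles) < 2L) return(angles)
  d <- diff(angles)
  dw <- ((d + 180) %% 360) - 180
  dw[dw == -180] <- 180
  cumsum(c(angles[1L], dw))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) application of an order-`order` Butterworth
#' design, so the smoothing introduces no lag that would bias per-cycle
#' extrema. The signal is extended by odd reflection about its endpoints
#' before filtering and trimmed afterwards, which removes the startup
#' transients of a direct forward-backward pass (DC gain exactly 1: a
#' constant signal is returned unchanged).
#'
#' @param x Numeric signal.
#' @param order Filter order (4 by default).
#' @param cutoff_hz Cutoff frequency, Hz; must satisfy
#'   `0 < cutoff_hz < rate_hz / 2`.
#' @param rate_hz Sampling rate, samples/s.
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, order = 4, cutoff_hz = 6, rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2)
    stop("`cutoff_hz` must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  n <- length(x)
  if (n <= 3 * (2 * order + 1))
    stop("signal too short for the filter's impulse response", call. = FALSE)
  b <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  # pad long enough for the filter's transient to die out: the slowest pole
  # decayed below 1e-8 (capped by the signal length)
  r <- max(Mod(polyroot(rev(b$a))))
  decay <- if (r < 1) ceiling(log(1e-8) / log(r)) else n - 1L
  np <- min(n - 1L, max(3L * (2L * order + 1L), decay))
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(b, c(pre, x, post))
  y[(np + 1L):(np + n)]
}

#' Resample a series to a fixed length by linear interpolation
#'
#' Interpolates onto `target_len` equally spaced points spanning the first to
#' the last time stamp; endpoints are preserved exactly.
#'
#' @param x Numeric series.
#' @param times Sample times (strictly increasing); defaults to sample index.
#' @param target_len Output length (1700 by default).
#' @return Numeric vector of length `target_len`.
#' @export
resample_linear <- function(x, times = seq_along(x), target_len = 1700) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(times) != length(x) || any(diff(times) <= 0))
    stop("`times` must be strictly increasing and match `x`", call. = FALSE)
  xout <- seq(times[1L], times[length(times)], length.out = target_len)
  stats::approx(times, x, xout = xout)$y
}

#' Range of motion of an angle series
#' @param angles Non-empty numeric vector, degrees.
#' @return `max(angles) - min(angles)` (>= 0), degrees.
#' @export
rom <- function(angles) {
  if (!length(angles)) stop("empty angle series", call. = FALSE)
  max(angles) - min(angles)
}

# Euler-angle recording -> rotation trajectory (same convention throughout)
euler_recording_to_trajectory <- function(rec, side = "right",
                                          system = "imu") {
  stopifnot(inherits(rec, "ts_recording"))
  need <- c("roll", "pitch", "yaw")
  if (!all(need %in% colnames(rec$data)))
    stop("Euler recording needs roll/pitch/yaw channels", call. = FALSE)
  mats <- euler_to_rot9(rec$data[, "roll"], rec$data[, "pitch"],
                        rec$data[, "yaw"])
  rotation_trajectory(rec_times(rec), mats, side = side, system = system,
                      check = FALSE)
}

trim_trajectory <- function(traj, start_s, end_s) {
  keep <- which(traj$times >= start_s & traj$times < end_s)
  if (!length(keep)) stop("trim window outside trajectory", call. = FALSE)
  rotation_trajectory(traj$times[keep] - start_s,
                      traj$mats[keep, , drop = FALSE],
                      side = traj$side, system = traj$system, check = FALSE)
}

#' Run the full kinematics chain on a paired IMU/camera recording
#'
#' Harmonizes the two streams and extracts per-cycle range of motion for each
#' of the three rotational axes: the IMU Euler stream is converted to rotation
#' matrices and rigidly aligned to the camera frame
#' ([estimate_rigid_alignment()], applied as a post-multiplication on the IMU
#' side), both streams are referenced to the mean pose of the initial
#' `ref_window_s` seconds, split into annotated cycles, unwrapped, smoothed
#' with a zero-phase Butterworth filter, resampled to `target_len` points,
#' and reduced to per-cycle max-minus-min per axis. Axis 1/2/3 correspond to
#' the roll/pitch/yaw components of the relative orientation.
#'
#' @param imu_euler A [ts_recording()] with roll/pitch/yaw channels, degrees.
#' @param cam A [rotation_trajectory()] from the optical reference.
#' @param annotation A [cycle_annotation()] covering both streams.
#' @param cutoff_hz Butterworth cutoff, Hz.
#' @param ref_window_s Initial reference window, seconds.
#' @param alignment `"procrustes"` (estimate the mounting rotation per trial)
#'   or `"identity"` (streams assumed already aligned).
#' @param target_len Fixed per-cycle length after resampling.
#' @return A data frame with columns `axis`, `system` (`device` = IMU,
#'   `reference` = camera), `repetition` (0 = mean over cycles), `rom_deg`.
#'   The estimated alignment is attached as attribute `"alignment"`.
#' @export
run_kinematics_pipeline <- function(imu_euler, cam, annotation,
                                    cutoff_hz = 6, ref_window_s = 0.3,
                                    alignment = c("procrustes", "identity"),
                                    target_len = 1700) {
  stopifnot(inherits(imu_euler, "ts_recording"),
            inherits(cam, "rotation_trajectory"),
            inherits(annotation, "cycle_annotation"))
  alignment <- match.arg(alignment)
  task0 <- min(annotation$start_s); task1 <- max(annotation$end_s)
  imu_traj <- euler_recording_to_trajectory(imu_euler, side = cam$side,
                                            system = "imu")
  imu_traj <- trim_trajectory(imu_traj, task0, task1)
  cam_t <- trim_trajectory(cam, task0, task1)
  ann0 <- cycle_annotation(annotation$start_s - task0,
                           annotation$end_s - task0)

  A <- if (alignment == "procrustes")
    estimate_rigid_alignment(imu_traj, cam_t) else diag(3)
  imu_traj$mats <- rot9_rcompose(imu_traj$mats, A)

  streams <- list(device = imu_traj, reference = cam_t)
  nc <- nrow(ann0)
  out <- list()
  for (sys in names(streams)) {
    rel <- reference_to_initial(streams[[sys]], ref_window_s)
    cycles <- split_cycles(rel, ann0)
    romv <- matrix(NA_real_, nc, 3L,
                   dimnames = list(NULL, c("axis1", "axis2", "axis3")))
    for (k in seq_len(nc)) {
      for (a in 1:3) {
        ang <- unwrap_degrees(rec_channel(cycles[[k]], a))
        ang <- butterworth_lowpass(ang, order = 4, cutoff_hz = cutoff_hz,
                                   rate_hz = cycles[[k]]$rate_hz)
        ang <- resample_linear(ang, rec_times(cycles[[k]]), target_len)
        romv[k, a] <- rom(ang)
      }
    }
    out[[sys]] <- data.frame(
      axis = rep(colnames(romv), each = nc + 1L),
      system = sys,
      repetition = rep(c(0L, seq_len(nc)), times = 3L),
      rom_deg = as.vector(rbind(colMeans(romv), romv)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alignment") <- A
  res
}
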
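test_that("Euler conversions follow the intrinsic yaw-pitch-roll convention", {
  expect_equal(euler_to_matrix(0, 0, 0), diag(3))
  # 90 degrees of yaw maps x-hat onto y-hat
  expect_equal(as.numeric(euler_to_matrix(0, 0, 90) %*% c(1, 0, 0)),
               c(0, 1, 0))
  expect_equal(as.numeric(matrix_to_euler(diag(3))), c(0, 0, 0))
  set.seed(31)
  for (i in 1:25) {
    ang <- c(runif(1, -179, 179), runif(1, -88, 88), runif(1, -179, 179))
    back <- matrix_to_euler(euler_to_matrix(ang[1], ang[2], ang[3]))
    expect_equal(as.numeric(back), ang, tolerance = 1e-9)
    expect_false(attr(back, "gimbal_lock"))
  }
  lock <- matrix_to_euler(euler_to_matrix(25, 90, 10))
  expect_true(attr(lock, "gimbal_lock"))
  expect_equal(lock[["roll"]], 0)
  expect_error(matrix_to_euler(matrix(1:9, 3)), "not a valid rotation")
})

test_that("chordal mean rotation handles the symmetric cases", {
  set.seed(32)
  R <- random_rotation()
  expect_equal(mean_rotation(list(R)), R)
  expect_equal(mean_rotation(list(R, R)), R)
  rot_x <- function(th) euler_to_matrix(th, 0, 0)
  expect_equal(mean_rotation(list(rot_x(25), rot_x(-25))), diag(3))
  expect_equal(mean_rotation(list(rot_x(60), rot_x(-60))), diag(3))
})

test_that("Procrustes alignment recovers a constructed mounting rotation", {
  set.seed(33)
  t <- seq(0, 5, by = 0.01)
  th <- cbind(20 * sin(t), 15 * sin(1.3 * t), 30 * sin(0.7 * t))
  mats <- wearval:::euler_to_rot9(th[, 1], th[, 2], th[, 3])
  imu <- rotation_trajectory(t, mats, system = "imu")
  expect_equal(estimate_rigid_alignment(imu, imu), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  A0 <- random_rotation()
  cam <- rotation_trajectory(t, wearval:::rot9_rcompose(mats, A0))
  A <- estimate_rigid_alignment(imu, cam)
  expect_lt(max(abs(A - A0)), 1e-8)
  tiny <- rotation_trajectory(t[1:2], mats[1:2, ], system = "imu")
  expect_error(estimate_rigid_alignment(tiny,
                                        rotation_trajectory(t[1:2] + 100,
                                                            mats[1:2, ])),
               "fewer than 3")
})

test_that("referencing to the initial pose zeroes a static trajectory", {
  set.seed(34)
  R <- random_rotation()
  t <- seq(0, 2, by = 0.01)
  static <- rotation_trajectory(t, matrix(rep(as.vector(R), length(t)),
                                          length(t), 9, byrow = TRUE))
  rel <- reference_to_initial(static)
  expect_equal(max(abs(rel$data)), 0, tolerance = 1e-9)
  # relative angles are invariant to a global pre-rotation of the lab frame
  th <- cbind(25 * sin(t), 10 * sin(2 * t), 35 * sin(1.1 * t))
  mats <- wearval:::euler_to_rot9(th[, 1], th[, 2], th[, 3])
  traj <- rotation_trajectory(t, mats)
  G <- random_rotation()
  rotated <- rotation_trajectory(t, wearval:::rot9_lcompose(G, mats))
  expect_equal(reference_to_initial(rotated)$data,
               reference_to_initial(traj)$data, tolerance = 1e-8)
})

test_that("degree unwrapping removes +/-180 discontinuities", {
  expect_equal(unwrap_degrees(c(179, -179)), c(179, 181))
  smooth <- cumsum(runif(100, -5, 5))
  expect_equal(unwrap_degrees(smooth), smooth)
  set.seed(35)
  for (i in 1:20) {
    walk <- cumsum(runif(300, -170, 170))
    wrapped <- ((walk + 180) %% 360) - 180
    expect_equal(unwrap_degrees(wrapped), arg_unwrap(wrapped),
                 tolerance = 1e-9)
  }
})

test_that("zero-phase Butterworth has unit DC gain and a sharp rolloff", {
  expect_equal(butterworth_lowpass(rep(2.4, 400), cutoff_hz = 6,
                                   rate_hz = 100),
               rep(2.4, 400))
  t <- (0:2000) / 100
  pass <- sin(2 * pi * 0.5 * t)
  expect_lt(max(abs(butterworth_lowpass(pass, cutoff_hz = 6, rate_hz = 100) -
                      pass)), 0.01)
  stop_band <- sin(2 * pi * 40 * t)   # integer periods: zero at both ends
  out <- butterworth_lowpass(stop_band, cutoff_hz = 6, rate_hz = 100)
  expect_lt(max(abs(out[200:1800])), 0.01)
  expect_error(butterworth_lowpass(pass, cutoff_hz = 50, rate_hz = 100),
               "Nyquist")
})

test_that("linear resampling preserves endpoints and length", {
  ramp <- seq(2, 8, length.out = 123)
  out <- resample_linear(ramp, target_len = 1700)
  expect_length(out, 1700)
  expect_equal(out[c(1, 1700)], c(2, 8))
  expect_equal(out, seq(2, 8, length.out = 1700))
  x <- rnorm(1700)
  expect_equal(resample_linear(x, target_len = 1700), x)
  expect_error(resample_linear(1:5, times = c(1, 2, 2, 3, 4)), "increasing")
})

test_that("range of motion is the peak-to-peak excursion", {
  expect_equal(rom(rep(4, 10)), 0)
  th <- 20 * sin(seq(0, 2 * pi, length.out = 5000))
  expect_equal(rom(th), 40, tolerance = 1e-5)
  x <- rnorm(50)
  expect_equal(rom(sample(x)), rom(x))
})

test_that("noiseless paired kinematics agree and recover the target ROM", {
  # identity mounting: IMU and camera streams coincide
  cfg <- noiseless_kin_config(misalignment_euler_deg = c(0, 0, 0),
                              rom_targets_deg = c(axis1 = 30, axis2 = 40,
                                                  axis3 = 45),
                              rom_participant_sd = 0, rom_cycle_sd = 0)
  ann <- generate_timeline(cfg, 41)
  pair <- generate_kinematics_pair(ann, cfg, 41)
  eul_cam <- wearval:::rot9_to_euler(pair$cam$mats)
  expect_equal(cbind(eul_cam$roll, eul_cam$pitch, eul_cam$yaw),
               unname(pair$imu_euler$data), tolerance = 1e-9)
  res <- run_kinematics_pipeline(pair$imu_euler, pair$cam, ann)
  head_ <- res[res$repetition == 0, ]
  expect_equal(head_$rom_deg[head_$system == "device"],
               head_$rom_deg[head_$system == "reference"], tolerance = 0.1)
  expect_equal(head_$rom_deg[head_$system == "device" &
                               head_$axis == "axis2"], 40, tolerance = 0.5)
  expect_true(all(table(res$axis[res$repetition > 0],
                        res$system[res$repetition > 0]) == 5))

  # a mounting misalignment is absorbed by the Procrustes alignment
  cfg2 <- noiseless_kin_config(rom_participant_sd = 0, rom_cycle_sd = 0,
                               misalignment_euler_deg = c(25, -40, 65))
  pair2 <- generate_kinematics_pair(ann, cfg2, 41)
  res2 <- run_kinematics_pipeline(pair2$imu_euler, pair2$cam, ann)
  h2 <- res2[res2$repetition == 0, ]
  expect_equal(h2$rom_deg[h2$system == "device"],
               h2$rom_deg[h2$system == "reference"], tolerance = 0.1)
  expect_equal(attr(res2, "alignment"), t(pair2$truth$true_alignment),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("mirroring the motion negates roll but preserves ROM", {
  cfg <- noiseless_kin_config(misalignment_euler_deg = c(0, 0, 0))
  ann <- generate_timeline(cfg, 42)
  pair <- generate_kinematics_pair(ann, cfg, 42)
  S <- diag(c(1, -1, 1))
  mirrored <- pair$cam
  mirrored$mats <- t(apply(pair$cam$mats, 1L,
                           function(v) as.vector(S %*% matrix(v, 3) %*% S)))
  rel <- reference_to_initial(pair$cam)
  rel_m <- reference_to_initial(mirrored)
  expect_equal(rel_m$data[, "roll"], -rel$data[, "roll"], tolerance = 1e-8)
  expect_equal(rel_m$data[, "pitch"], rel$data[, "pitch"], tolerance = 1e-8)
  expect_equal(rom(rel_m$data[, "yaw"]), rom(rel$data[, "yaw"]),
               tolerance = 1e-8)
})
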
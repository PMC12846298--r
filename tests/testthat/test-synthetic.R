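test_that("timelines follow the protocol layout deterministically", {
  cfg <- sim_config(cycle_duration_sd_s = 0)
  ann <- generate_timeline(cfg, 1)
  expect_equal(ann$start_s, c(0, 15, 30, 45, 60))
  expect_equal(ann$end_s - ann$start_s, rep(10, 5))
  expect_equal(nrow(generate_timeline(sim_config(), 7)), 5)
  expect_identical(generate_timeline(sim_config(), 99),
                   generate_timeline(sim_config(), 99))
  expect_error(sim_config(cycle_duration_mean_s = -1), "positive")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(emg_rate_hz = 0), "rates")
  expect_error(sim_config(shared_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(rom_targets_deg = c(axis1 = -5, axis2 = 1,
                                              axis3 = 1)), ">= 0")
  cfg <- fast_config(rom_targets_deg = c(axis1 = 200, axis2 = 10,
                                         axis3 = 10))
  ann <- generate_timeline(cfg, 1)
  expect_error(generate_kinematics_pair(ann, cfg, 1), "180")
})

test_that("generated recordings honor the configured schema and rates", {
  cfg <- fast_config()
  ann <- generate_timeline(cfg, 61)
  pair <- generate_emg_pair(ann, cfg, 61)
  span <- max(ann$end_s) + cfg$rest_s
  expect_equal(n_samples(pair$device), round(span * 1000))
  expect_equal(colnames(pair$device$data), cfg$muscles)
  expect_equal(colnames(pair$reference$data), cfg$muscles)
  kin <- generate_kinematics_pair(ann, cfg, 61)
  expect_equal(n_samples(kin$imu_euler), length(kin$cam$times))
  expect_lte(abs(n_samples(kin$imu_euler) - span * 100), 1)
  expect_equal(colnames(kin$imu_euler$data), c("roll", "pitch", "yaw"))
  # camera frames stay on SO(3)
  expect_true(all(wearval:::rot9_valid(kin$cam$mats, tol = 1e-8)))
})

test_that("identical config and seed give bitwise-identical outputs", {
  cfg <- fast_config()
  ann <- generate_timeline(cfg, 62)
  expect_identical(generate_emg_pair(ann, cfg, 62),
                   generate_emg_pair(ann, cfg, 62))
  expect_identical(generate_kinematics_pair(ann, cfg, 62),
                   generate_kinematics_pair(ann, cfg, 62))
})

test_that("noiseless equal-gain recordings differ only by the offset", {
  cfg <- noiseless_emg_config()
  ann <- generate_timeline(cfg, 63)
  pair <- generate_emg_pair(ann, cfg, 63, side = "right")
  diffs <- pair$device$data - pair$reference$data
  expect_equal(max(diffs) - min(diffs), 0, tolerance = 1e-9)
  expect_equal(mean(diffs),
               cfg$device_offset_counts - cfg$reference_offset_counts)
})

test_that("the cardiac artifact contaminates only the left pectoralis", {
  cfg <- fast_config(device_noise_sd_counts = 0,
                     reference_noise_sd_counts = 0, shared_fraction = 1,
                     ecg_artifact_amplitude_mv = 0.3)
  ann <- generate_timeline(cfg, 64)
  left <- generate_emg_pair(ann, cfg, 64, side = "left")
  right <- generate_emg_pair(ann, cfg, 64, side = "right")
  # same seed: only the PM channel differs between the sides
  expect_identical(left$device$data[, -1], right$device$data[, -1])
  expect_gt(max(abs(left$device$data[, "PM"] - right$device$data[, "PM"])),
            10)
})

test_that("sync taps are additive, local and zero at amplitude zero", {
  set.seed(65)
  rec <- ts_recording(matrix(rnorm(4000 * 2, sd = 0.1), ncol = 2), 1000)
  expect_equal(inject_sync_tap(rec, 1.5, amplitude = 0), rec)
  tapped <- inject_sync_tap(rec, 2.0, amplitude = 30, width_s = 0.02)
  peak_t <- rec_times(tapped)[which.max(abs(rec_channel(tapped, 1)))]
  expect_lt(abs(peak_t - 2.01), 0.02)
  expect_identical(tapped$data[, 2], rec$data[, 2])
  changed <- which(tapped$data[, 1] != rec$data[, 1])
  expect_true(all(rec_times(rec)[changed] >= 2.0 &
                    rec_times(rec)[changed] < 2.02))
  expect_error(inject_sync_tap(rec, 10, 1), "outside")
})

test_that("between-device correlation rises with the shared-latent fraction", {
  # fixed cycle durations isolate the shared latent activation: with random
  # durations both systems also share the cycle clock, which alone induces
  # a positive RMS correlation and would mask the latent mixing
  r_for <- function(frac, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(muscles = "MD", shared_fraction = frac,
                        cycle_duration_mean_s = 5, cycle_duration_sd_s = 0,
                        rest_s = 1, n_participants = 6)
      vals <- vapply(1:6, function(p) {
        ann <- generate_timeline(cfg, s * 100 + p)
        pair <- generate_emg_pair(ann, cfg, s * 1000 + p)
        c(run_emg_pipeline(pair$device, ann)$rms[1],
          run_emg_pipeline(pair$reference, ann)$rms[1])
      }, numeric(2))
      pearson_r(vals[1, ], vals[2, ])
    }, numeric(1))
  }
  rs <- vapply(c(0, 0.6, 1), function(f) mean(r_for(f, 1:8)), numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.9)
  # fully independent latents: mean correlation indistinguishable from zero
  expect_lt(abs(mean(r_for(0, 1:200))), 0.1)
})
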
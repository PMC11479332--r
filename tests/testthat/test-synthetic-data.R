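test_that("noise-free channel sum conserves total weight plus cardiac term", {
  bed <- bed_model(frame_mass = 60)
  p <- virtual_participant(mass = 70, noise_sd = 0, cardiac_amplitude = 0,
                           seed = 1)
  rec <- simulate_pose(p, bed, tpa = 0, duration = 10, jitter_sd = 0)
  W <- (70 + 60) * bed$gravity
  expect_lt(max(abs(rowSums(rec$force[c("LH", "RH", "LF", "RF")]) - W)) / W,
            1e-9)

  # with a cardiac component the sum equals weight + the cardiac sinusoid
  p2 <- virtual_participant(mass = 70, noise_sd = 0, cardiac_amplitude = 2,
                            cardiac_rate = 1.1, seed = 1)
  rec2 <- simulate_pose(p2, bed, tpa = 0, duration = 10, jitter_sd = 0)
  expected <- W + 2 * sin(2 * pi * 1.1 * rec2$force$time)
  expect_lt(max(abs(rowSums(rec2$force[c("LH", "RH", "LF", "RF")]) -
                      expected)) / W, 1e-9)

  # mean over whole breaths returns the static weight
  p3 <- virtual_participant(mass = 70, noise_sd = 0, cardiac_amplitude = 0,
                            resp_rate = 0.25, seed = 1)
  rec3 <- simulate_pose(p3, bed, tpa = 30, duration = 8, jitter_sd = 0)
  expect_equal(mean(rowSums(rec3$force[c("LH", "RH", "LF", "RF")])), W,
               tolerance = 1e-9)
})

test_that("centred symmetric configuration yields four equal constant channels", {
  bed <- bed_model(frame_mass = 0)
  p <- virtual_participant(mass = 80, com_longitudinal_frac = 0,
                           lateral_shift_coeff = 0,
                           resp_amplitude = 1e-12, noise_sd = 0,
                           cardiac_amplitude = 0, seed = 1)
  rec <- simulate_pose(p, bed, tpa = 0, duration = 5, jitter_sd = 0)
  f <- rec$force
  expect_equal(max(abs(f$LH - f$RH)), 0, tolerance = 1e-9)
  expect_equal(max(abs(f$LH - f$LF)), 0, tolerance = 1e-9)
  expect_equal(f$LH + f$RH + f$LF + f$RF, rep(80 * bed$gravity, nrow(f)),
               tolerance = 1e-9)
})

test_that("configured CoM positions are recovered from the static trace", {
  bed <- bed_model()
  for (tpa in c(-90, -30, 0, 45, 120)) {
    p <- quiet_participant(resp_amplitude = 1e-12)
    rec <- simulate_pose(p, bed, tpa = tpa, duration = 5, jitter_sd = 0)
    com <- compute_com(rec$force, bed)
    m <- p$mass; M <- bed$frame_mass
    x_exp <- p$lateral_shift_coeff * tpa * pi / 180 * m / (m + M)
    y_exp <- p$com_longitudinal_frac * bed$length_l * m / (m + M)
    expect_lt(max(abs(com$CoM_x - x_exp)), 1e-9)
    expect_lt(max(abs(com$CoM_y - y_exp)), 1e-9)
  }
})

test_that("a CoM path leaving the supported footprint is rejected", {
  bed <- bed_model(width_w = 0.3, frame_mass = 0)
  p <- virtual_participant(mass = 70, lateral_shift_coeff = 0.2,
                           noise_sd = 0, seed = 1)
  expect_error(simulate_pose(p, bed, tpa = 90, duration = 5),
               "footprint")
  expect_error(simulate_pose(quiet_participant(), bed_model(), tpa = 0,
                             duration = -1),
               "positive|breath")
})

test_that("phase one protocol has 11 three-minute primaries in fixed order", {
  p <- phase_one_protocol()
  primaries <- p[p$role == "primary", ]
  expect_equal(nrow(primaries), 11L)
  expect_true(all(primaries$duration == 180))
  expect_setequal(primaries$target_tpa,
                  c(0, 15, -15, 30, -30, 45, -45, 60, -60, 90, -90))
  inter <- p[p$role == "intermediate", ]
  expect_true(all(inter$duration == 60))
  expect_true(all(inter$target_tpa %in% c(0, 90, -90)))
  expect_identical(phase_one_protocol(seed = 7), phase_one_protocol(seed = 7))
})

test_that("phase two protocol draws reproducible poses in (-180, 180]", {
  p <- phase_two_protocol(seed = 9)
  expect_equal(nrow(p), 10L)
  expect_true(all(p$target_tpa > -180 & p$target_tpa <= 180))
  expect_true(all(p$duration == 180))
  expect_identical(p, phase_two_protocol(seed = 9))
  expect_false(identical(p$target_tpa, phase_two_protocol(seed = 10)$target_tpa))
  expect_equal(nrow(phase_two_protocol(seed = 1, n_poses = 1)), 1L)
})

test_that("cohort generation is deterministic and respects invariants", {
  expect_error(generate_cohort(1), "at least 2")
  coh <- generate_cohort(2, master_seed = 5, pose_duration = 20,
                         n_phase_two = 2)
  coh2 <- generate_cohort(2, master_seed = 5, pose_duration = 20,
                          n_phase_two = 2)
  expect_identical(coh$recordings$p01$one$force, coh2$recordings$p01$one$force)
  for (id in names(coh$recordings)) {
    for (ph in c("one", "two")) {
      rec <- coh$recordings[[id]][[ph]]
      expect_equal(length(rec$truth_tpa), nrow(rec$force))
      expect_true(all(rec$force[c("LH", "RH", "LF", "RF")] >= 0))
      dt <- diff(rec$force$time)
      expect_lt(max(abs(dt - 1 / rec$rate)), 1e-9)
      # realized TPA stays within 5 degrees of the segment target
      for (s in seq_len(nrow(rec$segments))) {
        idx <- rec$segments$start[s]:rec$segments$end[s]
        expect_lte(max(abs(rec$truth_tpa[idx] - rec$segments$target_tpa[s])),
                   5)
      }
    }
  }
})

test_that("identical seeds produce byte-identical CSV output", {
  rec <- simulate_pose(quiet_participant(), bed_model(), tpa = 15,
                       duration = 5, seed = 77)
  rec2 <- simulate_pose(quiet_participant(), bed_model(), tpa = 15,
                        duration = 5, seed = 77)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_force_csv(rec, f1); write_force_csv(rec2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_force_csv(f1)
  expect_equal(back$LH, rec$force$LH, tolerance = 1e-5)
  unlink(c(f1, f2))
})
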
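# brute-force oracle: solve the torque equilibrium about both bed axes for
# the CoM, independently of the closed-form quotients in compute_com
torque_balance_com <- function(force, bed) {
  w <- bed$width_w; l <- bed$length_l
  t(apply(force[c("LH", "RH", "LF", "RF")], 1, function(f) {
    total <- sum(f)
    # corner coordinates: LH (+w/2, +l/2), RH (-w/2, +l/2),
    # LF (+w/2, -l/2), RF (-w/2, -l/2)
    x <- (f[1] * w / 2 + f[2] * (-w / 2) + f[3] * w / 2 + f[4] * (-w / 2)) /
      total
    y <- (f[1] * l / 2 + f[2] * l / 2 + f[3] * (-l / 2) + f[4] * (-l / 2)) /
      total
    c(x, y)
  }))
}

test_that("compute_com reproduces hand-evaluated and corner-load cases", {
  bed <- bed_model(length_l = 2, width_w = 1)
  f <- data.frame(LH = 100, RH = 100, LF = 100, RF = 100)
  expect_equal(compute_com(f, bed), data.frame(CoM_x = 0, CoM_y = 0))
  f <- data.frame(LH = 400, RH = 0, LF = 0, RF = 0)
  expect_equal(compute_com(f, bed), data.frame(CoM_x = 0.5, CoM_y = 1.0))
  f <- data.frame(LH = 300, RH = 100, LF = 0, RF = 0)
  expect_equal(compute_com(f, bed), data.frame(CoM_x = 0.25, CoM_y = 1.0))
  expect_error(compute_com(data.frame(LH = 0, RH = 0, LF = 0, RF = 0), bed),
               "sample 1")
})

test_that("compute_com matches the torque-balance oracle on random traces", {
  set.seed(101)
  bed <- bed_model(length_l = 1.9, width_w = 0.85)
  for (r in 1:25) {
    f <- as.data.frame(matrix(runif(4 * 40, 10, 500), ncol = 4))
    names(f) <- c("LH", "RH", "LF", "RF")
    com <- compute_com(f, bed)
    oracle <- torque_balance_com(f, bed)
    expect_lt(max(abs(com$CoM_x - oracle[, 1])), 1e-12)
    expect_lt(max(abs(com$CoM_y - oracle[, 2])), 1e-12)
  }
})

test_that("respiration low-pass is zero-phase, DC-passing and idempotent", {
  t <- seq(0, 60 - 0.02, by = 0.02)
  # constant input passes unchanged
  const <- data.frame(CoM_x = rep(0.2, length(t)), CoM_y = rep(-0.1, length(t)))
  out <- isolate_respiration(const, filter_spec(), rate = 50)
  expect_equal(out$CoM_resp_x, const$CoM_x, tolerance = 1e-9)
  expect_equal(out$CoM_resp_y, const$CoM_y, tolerance = 1e-9)

  # zero net phase: cross-correlation of a passband sinusoid peaks at lag 0
  x <- sin(2 * pi * 0.25 * t)
  com <- data.frame(CoM_x = x, CoM_y = x)
  y <- isolate_respiration(com, filter_spec(cutoff = 0.5), rate = 50)$CoM_resp_x
  cc <- stats::ccf(y, x, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # stopband: 5 Hz sinusoid attenuated below 1%
  hx <- sin(2 * pi * 5 * t)
  hy <- isolate_respiration(data.frame(CoM_x = hx, CoM_y = hx),
                            filter_spec(cutoff = 0.5), rate = 50)$CoM_resp_x
  n <- length(t)
  expect_lt(max(abs(hy[500:(n - 500)])), 0.01)

  # idempotence in the passband: second pass changes amplitude < 1%
  spec <- filter_spec(cutoff = 0.75)
  y1 <- isolate_respiration(com, spec, rate = 50)
  y2 <- isolate_respiration(
    data.frame(CoM_x = y1$CoM_resp_x, CoM_y = y1$CoM_resp_y), spec, 50)
  a1 <- diff(range(y1$CoM_resp_x[500:(n - 500)]))
  a2 <- diff(range(y2$CoM_resp_x[500:(n - 500)]))
  expect_lt(abs(a2 - a1) / a1, 0.01)

  expect_error(isolate_respiration(com, filter_spec(cutoff = 30), 50),
               "Nyquist")
})

test_that("personalized filter finds the dominant respiration frequency", {
  t <- seq(0, 120 - 0.02, by = 0.02)
  com <- data.frame(CoM_x = 0.1 + 0.004 * sin(2 * pi * 0.3 * t),
                    CoM_y = 0.2 + 0.001 * sin(2 * pi * 0.3 * t))
  spec <- personalize_filter(com, rate = 50)
  expect_equal(attr(spec, "resp_freq"), 0.3, tolerance = 0.02)
  expect_equal(spec$cutoff, 3 * attr(spec, "resp_freq"))
})

test_that("pulse band-pass rejects DC and respiration, passes the cardiac line", {
  t <- seq(0, 60 - 0.02, by = 0.02)
  n <- length(t)
  mk <- function(x) data.frame(LH = x, RH = x, LF = x, RF = x)
  # constant input -> zero output
  out <- pulse_band_filter(mk(rep(250, n)), band = c(0.8, 2.5), rate = 50)
  expect_lt(max(abs(out$LH)), 1e-9)
  # 1.1 Hz passes within 5%
  cardiac <- sin(2 * pi * 1.1 * t)
  oc <- pulse_band_filter(mk(cardiac), band = c(0.8, 2.5), rate = 50)
  amp <- diff(range(oc$LH[500:(n - 500)])) / 2
  expect_lt(abs(amp - 1), 0.05)
  # 0.25 Hz respiration is rejected below 5%
  resp <- sin(2 * pi * 0.25 * t)
  or <- pulse_band_filter(mk(resp), band = c(0.8, 2.5), rate = 50)
  expect_lt(max(abs(or$LH[500:(n - 500)])), 0.05)
  expect_error(pulse_band_filter(mk(resp), band = c(2.5, 0.8)), "band")
})

test_that("breath extrema detection matches the closed-form sine solution", {
  t <- seq(0, 45, by = 0.02)
  ex <- detect_breath_extrema(sin(2 * pi * 0.25 * t))
  # closed form: 11.25 periods, so 11-12 extrema of each type
  expect_true(length(ex$tmax) %in% 11:12)
  expect_true(length(ex$tmin) %in% 11:12)
  merged <- sort(c(ex$tmax, ex$tmin))
  types <- ifelse(merged %in% ex$tmax, "max", "min")
  expect_true(all(types[-1] != types[-length(types)]))  # alternation
  # same-type extrema spaced one period (4 s = 200 samples) apart
  expect_equal(unique(diff(ex$tmax)), 200, tolerance = 0.01)
  # maxima at sin = +1
  expect_true(all(abs(sin(2 * pi * 0.25 * t[ex$tmax]) - 1) < 1e-4))
})

test_that("degenerate signals yield no or single extrema", {
  expect_equal(detect_breath_extrema(seq(0, 1, by = 0.01)),
               list(tmax = integer(0), tmin = integer(0)))
  tri <- c(seq(0, 1, by = 0.1), seq(0.9, 0, by = -0.1))
  ex <- detect_breath_extrema(tri)
  expect_equal(length(ex$tmax), 1L)
  expect_equal(tri[ex$tmax], 1)
  expect_error(detect_breath_extrema(c(1, 2)), "3 samples")
})

test_that("com_resp_angle evaluates the arctangent with its limit case", {
  resp <- data.frame(CoM_resp_x = c(1, 0), CoM_resp_y = c(1, 0))
  expect_equal(com_resp_angle(resp, 1, 2), 45)
  resp <- data.frame(CoM_resp_x = c(1, 0), CoM_resp_y = c(0.5, 0.5))
  expect_equal(com_resp_angle(resp, 1, 2), 0)
  resp <- data.frame(CoM_resp_x = c(sqrt(3), 0), CoM_resp_y = c(-1, 0))
  expect_equal(com_resp_angle(resp, 1, 2), -30)
  resp <- data.frame(CoM_resp_x = c(0.3, 0.3), CoM_resp_y = c(1, 0))
  expect_equal(com_resp_angle(resp, 1, 2), 90)
  # swapping the roles of the two samples flips both differences: angle
  # unchanged
  resp <- data.frame(CoM_resp_x = c(0.8, 0.1), CoM_resp_y = c(0.4, 0.9))
  expect_equal(com_resp_angle(resp, 1, 2), com_resp_angle(resp, 2, 1))
})

test_that("signal operations preserve length and leave inputs unmodified", {
  t <- seq(0, 30 - 0.02, by = 0.02)
  com <- data.frame(CoM_x = 0.004 * sin(2 * pi * 0.25 * t),
                    CoM_y = 0.002 * sin(2 * pi * 0.25 * t))
  com_copy <- com
  out <- isolate_respiration(com, filter_spec(), 50)
  expect_equal(nrow(out), nrow(com))
  expect_identical(com, com_copy)
  f <- data.frame(LH = 100 + sin(t), RH = 100 - sin(t),
                  LF = 100 + cos(t), RF = 100 - cos(t))
  f_copy <- f
  out2 <- pulse_band_filter(f, rate = 50)
  expect_equal(nrow(out2), nrow(f))
  expect_identical(f, f_copy)
})
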
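fs <- 20
dt <- 1.3
f27 <- fs / 27           # one cycle = exactly one 27-sample analysis window
t10 <- (0:599) / fs

test_that("arm correlation matches the direct windowed-summation oracle", {
  set.seed(41)
  x <- rnorm(1500); y <- 0.4 * x + rnorm(1500)
  expect_equal(as.numeric(arm_correlation(x, y, dt, fs)),
               bf_sliding_correlation(x, y, dt, fs), tolerance = 1e-9)
})

test_that("arm correlation has the perfect-synchronization limits", {
  x <- sin(2 * pi * 0.8 * t10) * 150
  inner <- interior(length(x), dt, fs)
  expect_equal(as.numeric(arm_correlation(x, x, dt, fs))[inner],
               rep(1, sum(inner)))
  expect_equal(as.numeric(arm_correlation(x, -x, dt, fs))[inner],
               rep(-1, sum(inner)))
  # affine invariance with the sign of the slope
  expect_equal(as.numeric(arm_correlation(x, 3 * x + 7, dt, fs))[inner],
               rep(1, sum(inner)), tolerance = 1e-9)
  # orthogonal quadrature signals over an exact window period
  s <- sin(2 * pi * f27 * t10); cq <- cos(2 * pi * f27 * t10)
  expect_lt(max(abs(as.numeric(arm_correlation(s, cq, dt, fs))[inner])), 1e-9)
  # symmetry and zero-variance convention
  expect_equal(as.numeric(arm_correlation(s, cq, dt, fs)),
               as.numeric(arm_correlation(cq, s, dt, fs)))
  expect_equal(as.numeric(arm_correlation(rep(1, 100), rnorm(100), dt, fs)),
               rep(0, 100))
  expect_error(arm_correlation(s, s[-1], dt, fs), "equal length")
})

test_that("arm motion energy equals the analytic sinusoid variance sum", {
  inner <- interior(length(t10), dt, fs)
  zero <- arm_motion(rep(2, 300), rep(-1, 300), dt, fs)
  expect_equal(as.numeric(zero), rep(0, 300))
  A <- 120
  s <- A * sin(2 * pi * f27 * t10)
  am <- as.numeric(arm_motion(s, s, dt, fs))
  expect_equal(am[inner], rep(A^2, sum(inner)), tolerance = 1e-2 * A^2)
  # 150 deg/s arms clear the arm-motion tolerance (22500 > 1e4)
  s150 <- 150 * sin(2 * pi * f27 * t10)
  am150 <- as.numeric(arm_motion(s150, s150, dt, fs))[inner]
  expect_equal(am150, rep(22500, sum(inner)), tolerance = 1e-6)
  expect_true(all(am150 > ski_tolerances()$tol_armMo))
})

test_that("leg angle differences isolate axis and double anti-phase motion", {
  params <- ski_tolerances()
  n <- length(t10)
  A <- 6; f <- 0.8; w <- 2 * pi * f
  # lateral-axis (sagittal) anti-phase angles enter through their rates
  gy_l <- A * w * cos(w * t10)       # d/dt of A sin(wt), deg/s
  gyro_l <- cbind(0, gy_l, 0)
  gyro_r <- cbind(0, -gy_l, 0)
  ad <- leg_angle_differences(gyro_l, gyro_r, params)
  # filter/integration transients decay within ~4 s of the record edges
  inner <- t10 > 4 & t10 < max(t10) - 4
  expect_lt(max(abs(ad$theta[inner] - 2 * A * sin(w * t10)[inner])),
            0.05 * 2 * A)
  # no vertical-axis input -> psi difference negligible
  expect_lt(max(abs(ad$psi)), 0.01 * max(abs(ad$theta)))
  # identical legs cancel exactly
  ad0 <- leg_angle_differences(gyro_l, gyro_l, params)
  expect_equal(ad0$theta, rep(0, n))
  expect_equal(ad0$psi, rep(0, n))
})

test_that("leg motion has the sinusoid closed form and legMoST >= legMoS", {
  th <- 6 * sin(2 * pi * f27 * t10)
  lm <- leg_motion(th, numeric(length(th)), dt, fs)
  inner <- interior(length(th), dt, fs)
  expect_equal(lm$legMoS[inner], rep(18, sum(inner)), tolerance = 1e-9)
  expect_equal(lm$legMoST[inner], lm$legMoS[inner])
  # adding transversal motion only increases legMoST
  ps <- 4 * sin(2 * pi * f27 * t10 + 1)
  lm2 <- leg_motion(th, ps, dt, fs)
  expect_true(all(lm2$legMoST >= lm2$legMoS))
  expect_equal(leg_motion(numeric(100), numeric(100), dt, fs)$legMoS,
               rep(0, 100))
})

test_that("kick rotation is a scale-invariant standard-deviation ratio", {
  th <- 1.5 * sin(2 * pi * f27 * t10)
  ps <- 3 * sin(2 * pi * f27 * t10 + 0.7)
  kr <- kick_rotation(th, ps, dt, fs)
  inner <- interior(length(th), dt, fs)
  # sd ratio 3/1.5 = 2, the kick-rotation tolerance boundary
  expect_equal(kr[inner], rep(2, sum(inner)), tolerance = 1e-6)
  # common positive scaling leaves the ratio unchanged
  expect_equal(kick_rotation(13.7 * th, 13.7 * ps, dt, fs), kr,
               tolerance = 1e-9)
  # equal deviations give 1; vanishing denominator is capped, not infinite
  expect_equal(kick_rotation(th, -th, dt, fs)[inner], rep(1, sum(inner)),
               tolerance = 1e-9)
  kr0 <- kick_rotation(numeric(200), ps[1:200], dt, fs)
  expect_true(all(is.finite(kr0)))
  expect_equal(max(kr0), 1e3)
})

test_that("assembled components separate poling from diagonal sessions", {
  seg_dp <- generate_segment(technique_motif("DP", duration = 30, seed = 5))
  ses_dp <- ski_session(seg_dp$recordings)
  comp_dp <- assemble_components(ses_dp)
  mid <- comp_dp$t > 10 & comp_dp$t < 20
  expect_true(all(comp_dp$armCorr[mid] > 0.9))

  seg_dia <- generate_segment(technique_motif("DIA", duration = 30, seed = 6))
  comp_dia <- assemble_components(ski_session(seg_dia$recordings))
  expect_true(all(comp_dia$armCorr[mid] < -0.5))
  expect_true(all(comp_dia$legMoST >= comp_dia$legMoS - 1e-12))

  expect_error(ski_session(list()), "empty session")
  expect_error(assemble_components(ski_session(seg_dp$recordings["left_arm"],
                                               require_all = FALSE)),
               "missing sensor")
})
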
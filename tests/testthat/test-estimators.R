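test_that("vigor equals the brute-force windowed std everywhere", {
  set.seed(3)
  fs <- 300
  t <- (0:599) / fs
  for (i in 1:5) {
    x <- cumsum(rnorm(600)) * 0.05
    v <- vigor(t, x, vigor_config(0.05))
    expect_equal(v, vigor_oracle(x, 15), tolerance = 1e-12)
  }
  expect_true(all(vigor(t, rep(2.5, 600), vigor_config(0.05)) == 0))
  expect_error(vigor(t[c(1, 20)], c(0, 1), vigor_config(0.05)), "exceeds")
})

test_that("vigor of a sinusoid over full periods is amplitude/sqrt(2)", {
  A <- 0.8
  bt <- generate_bout_trace(20, A, 1, fs = 300, envelope = "rect")
  v <- vigor(bt$t, bt$curvature, vigor_config(0.05))  # 15 samples = 1 period
  plateau <- v[50:250]
  expect_equal(mean(plateau), A / sqrt(2), tolerance = 0.01)
})

test_that("fish_velocity follows the negative-forward convention", {
  cfg <- vigor_config(0.05, vigor_scale = 1, swim_threshold = 0.3)
  expect_equal(fish_velocity(0, cfg), 0)
  expect_equal(fish_velocity(0.3, cfg), -0.3)  # boundary inclusive
  expect_equal(fish_velocity(0.1, cfg), 0)

  # the 'fish_vel < -15' swim test of the usage convention
  cfg2 <- vigor_config(0.05, vigor_scale = 30, swim_threshold = 0.3)
  v <- fish_velocity(20 / 30, cfg2)
  expect_equal(v, -20)
  expect_true(v < -15)
  expect_error(fish_velocity(1, vigor_config(0.05)), "configured")
})

test_that("grating velocity is linear in gain and fish velocity", {
  expect_equal(grating_velocity(10, -7, 0), 10)     # open loop
  expect_equal(grating_velocity(10, -10, 1), 0)
  set.seed(8)
  vf <- -runif(50, 0, 30)
  for (g in c(0.5, 1.0, 1.5)) {
    expect_equal(grating_velocity(10, vf, g), 10 + g * vf)
  }
  # linearity: v(g1) + v(g2) - v_base = v(g1 + g2)
  expect_equal(grating_velocity(10, vf, 0.5) + grating_velocity(10, vf, 1) -
                 10, grating_velocity(10, vf, 1.5))
})

test_that("interbout intervals and the merge rule follow generator timing", {
  fs <- 300
  cfg <- vigor_config(0.05, vigor_scale = 30, swim_threshold = 0.3)
  t <- (0:(3 * fs - 1)) / fs

  expect_length(interbout_intervals(t, numeric(3 * fs), cfg)$intervals, 0)

  # two 300 ms vigor pulses with a 1.2 s gap
  v <- numeric(3 * fs)
  v[t >= 0.3 & t < 0.6] <- 0.6
  v[t >= 1.8 & t < 2.1] <- 0.6
  ib <- interbout_intervals(t, v, cfg)
  expect_equal(nrow(ib$bouts), 2)
  expect_lt(abs(ib$intervals - 1.2), 1.5 / fs + 1e-12)

  # 10 ms gap with min_gap 50 ms merges into one bout
  v2 <- numeric(3 * fs)
  v2[t >= 0.3 & t < 0.5] <- 0.6
  v2[t >= 0.51 & t < 0.7] <- 0.6
  ib2 <- interbout_intervals(t, v2, cfg, min_gap = 0.05)
  expect_equal(nrow(ib2$bouts), 1)
  ib2b <- interbout_intervals(t, v2, cfg, min_gap = 0)
  expect_equal(nrow(ib2b$bouts), 2)
})

test_that("affine calibration recovers exact transforms from 3 points", {
  tri <- rbind(c(10, 10), c(90, 20), c(40, 80))
  id <- compute_calibration(tri, tri)
  expect_equal(id$A, diag(2), tolerance = 1e-12)
  expect_equal(id$b, c(0, 0), tolerance = 1e-12)

  # rotation 30 deg + scale 2 + offset (5, -3)
  phi <- 30 * deg
  A_true <- 2 * matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2,
                       byrow = TRUE)
  b_true <- c(5, -3)
  set.seed(21)
  cam <- matrix(runif(6, 0, 100), 3, 2)
  disp <- t(A_true %*% t(cam) + b_true)
  tf <- compute_calibration(cam, disp)
  expect_equal(tf$A, A_true, tolerance = 1e-9)
  expect_equal(tf$b, b_true, tolerance = 1e-9)
  # anchor-point residuals are zero to machine precision
  expect_lt(max(abs(apply_calibration(tf, cam) - disp)), 1e-9)

  expect_error(compute_calibration(rbind(c(0, 0), c(1, 1), c(2, 2)), tri),
               "collinear")
})

test_that("calibration round trip is exact on random points", {
  set.seed(14)
  cam <- matrix(runif(6, 0, 100), 3, 2)
  disp <- matrix(runif(6, 0, 1920), 3, 2)
  tf <- compute_calibration(cam, disp)
  inv <- invert_calibration(tf)
  pts <- matrix(runif(200, -50, 150), 100, 2)
  back <- apply_calibration(inv, apply_calibration(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("calibration spots are detected to sub-pixel accuracy", {
  ctrs <- rbind(c(20.3, 25.7), c(50.1, 75.9), c(80.6, 30.2))
  gx <- matrix(rep(0:99, each = 100), 100)
  gy <- matrix(rep(0:99, times = 100), 100)
  px <- matrix(10, 100, 100)
  for (i in 1:3) {
    px <- px + 200 * exp(-((gx - ctrs[i, 1])^2 + (gy - ctrs[i, 2])^2) /
                           (2 * 2.5^2))
  }
  pts <- detect_calibration_points(new_frame(px))
  expect_lt(max(abs(pts - ctrs[order(ctrs[, 1]), ])), 0.5)

  # a fourth, dimmer spot is ignored
  px4 <- px + 80 * exp(-((gx - 65)^2 + (gy - 60)^2) / (2 * 2.5^2))
  pts4 <- detect_calibration_points(new_frame(px4))
  expect_equal(pts4, pts, tolerance = 0.05)

  expect_error(detect_calibration_points(new_frame(matrix(7, 50, 50))),
               "maxima")
})

test_that("phototaxis half-field geometry follows the midline", {
  f <- phototaxis_field(c(0, 0), 0, "left")
  expect_true(is_bright(f, c(0, 1)))    # left of an east-heading fish
  expect_false(is_bright(f, c(0, -1)))

  # rotating the fish rotates the boundary identically
  set.seed(6)
  for (h in runif(5, 0, 2 * pi)) {
    fr <- phototaxis_field(c(10, -5), h, "left")
    p_left <- c(10, -5) + c(-sin(h), cos(h))   # unit left of heading
    expect_true(is_bright(fr, p_left))
    expect_false(is_bright(fr, c(10, -5) - c(-sin(h), cos(h))))
  }

  # flipping the bright side inverts every off-line point
  set.seed(16)
  pts <- matrix(runif(40, -10, 10), 20, 2)
  fl <- phototaxis_field(c(1, 1), 0.8, "left")
  frt <- phototaxis_field(c(1, 1), 0.8, "right")
  expect_identical(is_bright(fl, pts), !is_bright(frt, pts))
})
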
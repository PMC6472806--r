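test_that("detect_fish finds nothing in an empty scene", {
  bg <- empty_bg(c(120, 120))
  blank <- new_frame(matrix(200, 120, 120))
  det <- detect_fish(foreground(bg, blank), blank, scene_fish_params())
  expect_equal(nrow(det), 0)
})

test_that("a single rendered fish is localized with pose accuracy", {
  truth <- simulate_swim_trajectory(n_bouts = 0, arena = c(160, 160),
                                    start_heading = 0.7, seed = 3)
  fr <- render_scene(truth, noise_sigma = 2, seed = 11)[[1]]
  bg <- empty_bg(c(160, 160))
  det <- detect_fish(foreground(bg, fr), fr, scene_fish_params())
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x - truth$pose$x[1])^2 + (det$y - truth$pose$y[1])^2), 2)
  expect_lt(circ_err_deg(det$heading, truth$pose$heading[1]), 10)
  expect_false(det$low_confidence)
})

test_that("two well-separated fish give two matched detections", {
  t1 <- simulate_swim_trajectory(n_bouts = 0, arena = c(300, 300),
                                 start_pos = c(70, 70), seed = 1)
  t2 <- simulate_swim_trajectory(n_bouts = 0, arena = c(300, 300),
                                 start_pos = c(230, 230), start_heading = 2,
                                 seed = 2)
  fr <- render_scene(list(t1, t2), noise_sigma = 2, seed = 4)[[1]]
  bg <- empty_bg(c(300, 300))
  det <- detect_fish(foreground(bg, fr), fr, scene_fish_params())
  expect_equal(nrow(det), 2)
  for (tru in list(t1, t2)) {
    d <- sqrt((det$x - tru$pose$x[1])^2 + (det$y - tru$pose$y[1])^2)
    expect_lt(min(d), 2)
  }
})

test_that("initial_tail_direction is equivariant and flags flat input", {
  fp <- scene_fish_params()
  for (h0 in c(0, pi / 2)) {
    truth <- simulate_swim_trajectory(n_bouts = 0, arena = c(160, 160),
                                      start_heading = h0, seed = 5)
    fr <- render_scene(truth, noise_sigma = 0)[[1]]
    bg <- empty_bg(c(160, 160))
    td <- initial_tail_direction(foreground(bg, fr), c(80, 80), fp)
    # tail points opposite the heading
    expect_lt(circ_err_deg(td$angle, h0 + pi), 15)
    expect_false(td$flat)
  }
  flat <- new_frame(matrix(0, 120, 120))
  td <- initial_tail_direction(flat, c(60, 60), fp)
  expect_true(td$flat)
  expect_equal(td$angle, 0)
  expect_error(initial_tail_direction(flat, c(200, 60), fp), "outside")
})

test_that("identity assignment matches greedily and issues new ids", {
  fp <- scene_fish_params()
  prev <- data.frame(id = 1L, x = 50, y = 50, heading = 0)
  det <- data.frame(x = 53, y = 50, heading = 0.05)
  asg <- assign_identities(prev, det, fp)
  expect_equal(asg$pairs$id, 1L)

  prev2 <- data.frame(id = c(1L, 2L), x = c(50, 350), y = c(50, 50),
                      heading = c(0, pi / 2))
  det2 <- data.frame(x = c(352, 54), y = c(51, 49),
                     heading = c(pi / 2 + 0.1, 0.1))
  asg2 <- assign_identities(prev2, det2, fp)
  # exhaustive 2x2 check: det 1 belongs to fish 2, det 2 to fish 1
  expect_equal(asg2$pairs$id[asg2$pairs$det == 1], 2L)
  expect_equal(asg2$pairs$id[asg2$pairs$det == 2], 1L)
  expect_length(asg2$lost_ids, 0)

  det3 <- data.frame(x = 500, y = 500, heading = 0)
  asg3 <- assign_identities(prev, det3, fp, next_id = 7L)
  expect_equal(asg3$pairs$id, 7L)   # beyond max_jump: fresh id
  expect_equal(asg3$lost_ids, 1L)
})

test_that("Kalman smoothing reduces error on jittered measurements", {
  set.seed(7)
  n <- 300
  t <- (0:(n - 1)) / 300
  tru <- data.frame(t = t, x = 50 + 60 * t, y = 80 + 20 * t, heading = 0.3)
  meas <- tru
  meas$x <- meas$x + rnorm(n)
  meas$y <- meas$y + rnorm(n)
  meas$heading <- meas$heading + rnorm(n, 0, 0.05)
  sm <- kalman_smooth(meas)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(c(sm$x, sm$y), c(tru$x, tru$y)),
            rmse(c(meas$x, meas$y), c(tru$x, tru$y)))
  expect_lt(rmse(sm$heading, tru$heading), rmse(meas$heading, tru$heading))

  # stationary fish: smoothed position variance does not exceed raw
  meas2 <- data.frame(t = t, x = 100 + rnorm(n, 0, 0.8),
                      y = 100 + rnorm(n, 0, 0.8), heading = 0)
  sm2 <- kalman_smooth(meas2)
  expect_lte(sd(sm2$x), sd(meas2$x))
  expect_lte(sd(sm2$y), sd(meas2$y))
})

test_that("a fish leaving the field of view is retired", {
  truth <- simulate_swim_trajectory(n_bouts = 0, arena = c(140, 140),
                                    seed = 9, lead_in = 0.1)
  with_fish <- render_scene(truth, noise_sigma = 0)
  blank <- lapply(seq_along(with_fish), function(i) {
    new_frame(matrix(200, 140, 140), t = max(truth$t) + i / 300,
              frame_id = length(with_fish) + i - 1L)
  })
  bg <- empty_bg(c(140, 140))
  log <- track_sequence(c(with_fish, blank), scene_fish_params(), bg = bg)
  expect_true(any(!log$visible))
  lost <- log[!log$visible, ][1, ]
  expect_equal(lost$id, 1L)
  # no rows for id 1 after retirement
  expect_false(any(log$visible[log$t > lost$t]))
})

test_that("bout segmentation recovers kinematics and aligns rigidly", {
  # one bout turning +30 deg
  truth <- simulate_swim_trajectory(n_bouts = 1, turns = 30 * deg,
                                    arena = c(240, 240), seed = 2,
                                    start_heading = 1.1)
  traj <- cbind(t = truth$t, truth$pose)
  bouts <- bout_kinematics(traj, speed_on = 5, speed_off = 2.5)
  expect_length(bouts, 1)
  expect_lt(abs(bouts[[1]]$angle_change - 30 * deg) / deg, 2)
  expect_equal(bouts[[1]]$aligned$x[1], 0)
  expect_equal(bouts[[1]]$aligned$heading[1], 0)

  # realigning an already aligned bout is the identity (exact fixed point)
  al <- bouts[[1]]$aligned
  realign <- function(df) {
    h0 <- df$heading[1]
    dx <- df$x - df$x[1]
    dy <- df$y - df$y[1]
    data.frame(x = cos(-h0) * dx - sin(-h0) * dy,
               y = sin(-h0) * dx + cos(-h0) * dy,
               heading = df$heading - h0)
  }
  expect_identical(realign(al), al)

  # zero-speed trace has no bouts
  still <- data.frame(t = (0:99) / 300, x = 5, y = 5, heading = 0)
  expect_length(bout_kinematics(still, speed_on = 5), 0)

  # two rectangular speed pulses 500 ms apart
  fs <- 300
  tt <- (0:599) / fs
  sp <- numeric(600)
  sp[tt >= 0.2 & tt < 0.4] <- 100
  sp[tt >= 0.9 & tt < 1.1] <- 100
  x <- cumsum(sp) / fs
  traj3 <- data.frame(t = tt, x = x, y = 0, heading = 0)
  b3 <- bout_kinematics(traj3, speed_on = 50, speed_off = 25)
  expect_length(b3, 2)
  ib <- attr(b3, "interbout_intervals")
  expect_lt(abs(ib - 0.5), 1.5 / fs + 1e-9)
})
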
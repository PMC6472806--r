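test_that("pause + flash fires one exact transition at t = 9 s", {
  prot <- protocol_spec("flash", list(pause_stimulus(9), flash_stimulus(1)))
  rec <- run_protocol(prot, sim_clock(60))
  sl <- rec$stimulus_log
  starts <- sl[sl$event == "start", ]
  expect_equal(nrow(starts), 2)
  expect_identical(starts$t[starts$stimulus == "flash"], 9)
  expect_identical(sl$t[sl$event == "end"], 10)
  expect_false(rec$aborted)
  # record duration equals the sum of stimulus durations exactly
  expect_equal(max(sl$t), 9 + 1)
  # updates: 540 pause ticks + 60 flash ticks
  expect_equal(sum(sl$event == "update"), 600)
})

test_that("simulated-clock runs are byte-identical", {
  prot <- protocol_spec("flash", list(pause_stimulus(9), flash_stimulus(1)))
  r1 <- run_protocol(prot, sim_clock(60))
  r2 <- run_protocol(prot, sim_clock(60))
  expect_identical(r1$stimulus_log, r2$stimulus_log)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  data.table::fwrite(r1$stimulus_log, f1)
  data.table::fwrite(r2$stimulus_log, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("stimulus onsets equal cumulative durations on the tick grid", {
  durs <- c(0.5, 1.25, 2, 0.25)
  stims <- lapply(seq_along(durs), function(i) {
    stimulus_spec(paste0("s", i), durs[i])
  })
  rec <- run_protocol(protocol_spec("seq", stims), sim_clock(80))
  starts <- rec$stimulus_log[rec$stimulus_log$event == "start", ]
  expect_equal(starts$t, c(0, cumsum(durs))[1:4])
})

test_that("a dynamic grating logs the closed-loop law sample-wise", {
  fs <- 60
  cfg <- vigor_config(0.05, vigor_scale = 30, swim_threshold = 0.3)
  set.seed(10)
  vig <- abs(cumsum(rnorm(300))) / 10
  est <- function(t) fish_velocity(vig[floor(t * fs) + 1], cfg)
  prot <- protocol_spec("cl", list(grating_stimulus(5, gain = 1.5)))
  rec <- run_protocol(prot, sim_clock(fs), estimator = est)
  upd <- rec$stimulus_log[rec$stimulus_log$event == "update", ]
  # oracle: recompute the law from the same vigor trace
  oracle <- grating_velocity(10, fish_velocity(vig[floor(upd$t * fs) + 1],
                                               cfg), 1.5)
  expect_equal(upd$velocity, oracle)
})

test_that("an exception in the hook aborts with a partial record", {
  prot <- protocol_spec("flash", list(pause_stimulus(1), flash_stimulus(1)))
  rec <- run_protocol(prot, sim_clock(20), update_hook = function(t, ctx) {
    if (t >= 1.5) stop("hardware glitch")
  })
  expect_true(rec$aborted)
  expect_match(rec$metadata$abort_message, "glitch")
  expect_lt(max(rec$stimulus_log$t), 2)
  expect_gt(nrow(rec$stimulus_log), 10)
})

test_that("combining stimuli is identity on singletons, associative on logs", {
  mk <- function(nm, val) {
    stimulus_spec(nm, 1, params = list(level = val),
                  on_update = function(t, tl, ctx) list(value = val + tl))
  }
  a <- mk("a", 1); b <- mk("b", 2); c_ <- mk("c", 3)
  expect_identical(combine_stimuli(list(a)), a)
  expect_error(combine_stimuli(list()), "empty")
  expect_error(combine_stimuli(list(a, stimulus_spec("x", 2))), "duration")

  run <- function(s) {
    run_protocol(protocol_spec("p", list(s)), sim_clock(20))$stimulus_log
  }
  flat <- run(combine_stimuli(list(a, b, c_)))
  nested <- run(combine_stimuli(list(combine_stimuli(list(a, b)), c_)))
  expect_identical(flat[c("a.value", "b.value", "c.value")],
                   nested[c("a.value", "b.value", "c.value")])

  # both member parameter sets are in the composite's static params
  comp <- combine_stimuli(list(a, b))
  expect_identical(comp$params, list(a.level = 1, b.level = 2))
})

test_that("conditional stimuli follow the predicate and need an estimator", {
  dyn <- function(nm) stimulus_spec(nm, 1, on_update = function(t, tl, ctx) {
    list(out = nm)
  })
  cond <- conditional_stimulus(dyn("A"), dyn("B"),
                               predicate = function(s) isTRUE(s > 0))
  prot <- protocol_spec("c", list(cond))
  expect_error(run_protocol(prot, sim_clock(20)), "estimator")

  # always-false predicate runs the else branch every tick
  rec <- run_protocol(prot, sim_clock(20), estimator = function(t) -1)
  upd <- rec$stimulus_log[rec$stimulus_log$event == "update", ]
  expect_true(all(upd$branch == "else"))
  expect_true(all(upd$out == "B"))

  # per-tick flipping predicate alternates branches every tick
  flip <- conditional_stimulus(dyn("A"), dyn("B"),
                               predicate = function(s) s %% 2 == 0)
  rec2 <- run_protocol(protocol_spec("f", list(flip)), sim_clock(20),
                       estimator = function(t) round(t * 20))
  upd2 <- rec2$stimulus_log[rec2$stimulus_log$event == "update", ]
  expect_true(all(upd2$branch == rep(c("if", "else"), 10)))

  # synthetic bout train: switches align with generator windows +- one tick
  fs <- 300
  cfg <- vigor_config(0.05, vigor_scale = 30, swim_threshold = 0.3)
  tt <- (0:(2 * fs - 1)) / fs
  vg <- numeric(2 * fs)
  vg[tt >= 0.5 & tt < 0.8] <- 0.6
  vg[tt >= 1.4 & tt < 1.7] <- 0.6
  swim <- conditional_stimulus(
    dyn("A"), dyn("B"),
    predicate = function(s) isTRUE(s < -15))
  est <- function(t) fish_velocity(vg[round(t * fs) + 1], cfg)
  rec3 <- run_protocol(protocol_spec("s", list(
    conditional_stimulus(dyn("A"), dyn("B"),
                         predicate = function(s) isTRUE(s < -15)))),
    sim_clock(fs), estimator = est)
  upd3 <- rec3$stimulus_log[rec3$stimulus_log$event == "update", ]
  expect_identical(upd3$branch == "if",
                   vg[round(upd3$t * fs) + 1] >= 0.3)
})

test_that("records survive CSV and HDF5 round trips with metadata audit", {
  prot <- protocol_spec("flash", list(pause_stimulus(0.5),
                                      grating_stimulus(0.5, gain = 1)))
  rec <- run_protocol(prot, sim_clock(60), estimator = function(t) -17.3)
  rec$tracking_log <- data.frame(t = seq(0, 1, length.out = 1000),
                                 theta_00 = sin(seq_len(1000) / 7),
                                 total_curvature = rnorm(1000))

  d1 <- file.path(tempdir(), "rec_csv")
  save_record(rec, d1, format = "csv")
  back <- load_record(d1, format = "csv")
  expect_lt(max(abs(back$tracking_log$total_curvature -
                      rec$tracking_log$total_curvature)), 1e-12)
  expect_lt(max(abs(back$stimulus_log$t - rec$stimulus_log$t)), 1e-12)

  d2 <- file.path(tempdir(), "rec_h5")
  save_record(rec, d2, format = "hdf5")
  b2 <- load_record(d2, format = "hdf5")
  # lossless: numeric content identical bit for bit
  expect_identical(b2$tracking_log$total_curvature,
                   rec$tracking_log$total_curvature)
  expect_identical(b2$tracking_log$theta_00, rec$tracking_log$theta_00)
  expect_identical(as.numeric(b2$stimulus_log$t),
                   as.numeric(rec$stimulus_log$t))

  # version string and full parameter audit in the saved metadata
  meta <- jsonlite::read_json(file.path(d2, "metadata.json"),
                              simplifyVector = TRUE)
  expect_identical(meta$version,
                   as.character(utils::packageVersion("fishtrack")))
  expect_true(all(meta$accessed_params %in% names(meta$params)))
  expect_true("clock.fps" %in% meta$accessed_params)

  # unwritable target errors before writing anything
  blocker <- tempfile()
  writeLines("x", blocker)
  expect_error(save_record(rec, file.path(blocker, "sub")), "writable")
})
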
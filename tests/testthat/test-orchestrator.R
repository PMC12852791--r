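test_that("experiment configs validate their controller contracts", {
  expect_error(experiment_config("lexy", duration = 10),
               "exactly one of")
  expect_error(
    experiment_config("lexy", duration = 10,
                      controller = list(gains = pid_gains(1),
                                        schedule = gain_schedule(
                                          c(0.2, 0.8),
                                          list(pid_gains(1), pid_gains(2))))),
    "exactly one of"
  )
  expect_error(
    experiment_config("lexy", duration = 10,
                      controller = list(gains = pid_gains(1),
                                        setpoints = data.frame(frame = 5,
                                                               setpoint = 0.5)))
  )
  expect_error(
    experiment_config("migration", duration = 10, n_cells = 2,
                      paths = circle_path(40, c(80, 80))),
    "one guide path per cell"
  )
})

test_that("a one-frame run produces exactly one row per cell", {
  cfg <- experiment_config("migration", duration = 1, seed = 1, n_cells = 2)
  rec <- run_closed_loop(cfg)
  expect_equal(nrow(rec$rows), 2)
  expect_equal(rec$rows$frame, c(1, 1))
})

test_that("runs are bit-exactly reproducible from config and seed", {
  cfg <- experiment_config("migration", duration = 25, seed = 33)
  r1 <- run_closed_loop(cfg)
  r2 <- run_closed_loop(cfg)
  expect_identical(r1$rows, r2$rows)
  expect_identical(r1$commands, r2$commands)
  expect_identical(r1$events, r2$events)

  d1 <- tempfile()
  d2 <- tempfile()
  save_loop_record(r1, d1)
  save_loop_record(r2, d2)
  expect_identical(readLines(file.path(d1, "tracks.csv")),
                   readLines(file.path(d2, "tracks.csv")))
  expect_identical(readLines(file.path(d1, "commands.csv")),
                   readLines(file.path(d2, "commands.csv")))
})

test_that("without light the cell leaves the path; the closed loop keeps it on", {
  base <- experiment_config("migration", duration = 100, seed = 12,
                            controller = list(irradiance = 0))
  open_loop <- run_closed_loop(base)
  dev_open <- open_loop$rows$deviation
  # the undirected random walk drifts away from the path over time
  fit <- lm(dev_open ~ seq_along(dev_open))
  expect_gt(coef(fit)[2], 0)
  expect_gt(max(dev_open, na.rm = TRUE), 5)

  closed <- run_closed_loop(
    experiment_config("migration", duration = 100, seed = 12)
  )
  expect_lt(mean(closed$rows$deviation, na.rm = TRUE),
            mean(dev_open, na.rm = TRUE) / 3)
})

test_that("run artefacts land on disk with the documented schema", {
  cfg <- experiment_config("migration", duration = 12, seed = 2,
                           record_frames = TRUE)
  rec <- run_closed_loop(cfg)
  d <- tempfile()
  save_loop_record(rec, d)
  expect_true(all(file.exists(file.path(
    d, c("config.yaml", "tracks.csv", "commands.csv", "events.log",
         "summary.csv", "frames.tiff")
  ))))
  tr <- read.csv(file.path(d, "tracks.csv"))
  expect_true(all(c("frame", "cell", "x", "y", "deviation",
                    "irradiance_cmd", "irradiance_eff") %in% names(tr)))
  cfg_back <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_equal(cfg_back$seed, 2)
  expect_equal(cfg_back$frame_interval, 60)
  expect_length(read_frames_tiff(file.path(d, "frames.tiff")), 12)
})

test_that("run summaries equal an independent recomputation from the raw record", {
  cfg <- experiment_config("migration", duration = 60, seed = 21)
  rec <- run_closed_loop(cfg)
  s <- run_summary(rec)
  d <- rec$rows[is.finite(rec$rows$x), ]
  dev_direct <- vapply(seq_len(nrow(d)), function(i) {
    project_to_path(c(d$x[i], d$y[i]), rec$paths[[1]])$deviation
  }, numeric(1))
  expect_equal(s$cells$mean_deviation, mean(dev_direct), tolerance = 1e-9)
  expect_equal(s$cells$max_deviation, max(dev_direct), tolerance = 1e-9)
  # the recorded deviation column agrees with recomputation too
  expect_equal(d$deviation, dev_direct, tolerance = 1e-9)
})

test_that("the tuner rejects insensitive plants and honours its overshoot bound", {
  dead <- lexy_plant(k_on_per_I = 0)
  expect_error(tune_pid(dead), "light sensitivity")

  sched <- tuned_schedule()
  tuning <- attr(sched, "tuning")
  expect_true(all(tuning$overshoot <= 0.05))
  # independent verification: replay the tuned gains at each operating point
  pl <- lexy_plant()
  for (p in seq_along(sched$operating_points)) {
    op <- sched$operating_points[p]
    from <- if (p == 1) 0 else sched$operating_points[p - 1]
    I0 <- lexy_irradiance_for(pl, from)
    ss <- lexy_steady_state(pl, I0)
    p0 <- pl
    p0$A <- ss$A; p0$N <- ss$N; p0$C <- ss$C
    sim <- simulate_lexy_pid(p0, sched$gains[[p]],
                             data.frame(frame = 1, setpoint = op),
                             duration = 120, dt = 15)
    overshoot <- max(sim$measurement - op) / max(op - from, 1e-9)
    expect_lte(overshoot, 0.05 + 1e-6)
    expect_lt(abs(tail(sim$measurement, 1) - op), 0.02)
  }
})

test_that("mid-range gains degrade across the operating range; the schedule does not", {
  pl <- lexy_plant()
  fixed <- tuned_fixed_pid()
  sched <- tuned_schedule()
  stair <- data.frame(frame = seq(1, by = 80, length.out = 5),
                      setpoint = c(0.1, 0.3, 0.5, 0.7, 0.9))
  err_at <- function(ctl) {
    sim <- simulate_lexy_pid(pl, ctl, stair, duration = 400, dt = 15)
    vapply(1:5, function(e) {
      seg <- sim$measurement[sim$frame >= stair$frame[e] &
                             sim$frame < stair$frame[e] + 80]
      steady_state_error(seg, stair$setpoint[e], interval = 15)$mean_abs_error
    }, numeric(1))
  }
  e_fixed <- err_at(fixed)
  e_sched <- err_at(sched)
  expect_lt(mean(e_sched), mean(e_fixed))
  expect_lt(max(e_sched), max(e_fixed))
})

test_that("the PWM multi-cell loop holds several cells at one nucleus setpoint", {
  schedn <- tuned_nucleus_schedule()
  cfg <- experiment_config("multi_lexy", duration = 70, seed = 11, n_cells = 4,
                           controller = list(schedule = schedn,
                                             mode = "nucleus",
                                             setpoints = data.frame(
                                               frame = 1, setpoint = 0.4)))
  rec <- run_closed_loop(cfg)
  s <- run_summary(rec)
  expect_equal(nrow(s), 4)
  expect_true(all(s$settled))
  expect_true(all(s$pct_error < 10))
  # distinct cells need distinct duty cycles (expression heterogeneity)
  late <- rec$commands[rec$commands$frame > 50, ]
  mean_duty <- tapply(late$duty, late$cell, mean)
  expect_gt((max(mean_duty) - min(mean_duty)) / mean(mean_duty), 0.01)
  expect_true(all(rec$commands$duty >= 0 & rec$commands$duty <= 1))
})
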
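test_that("AOI selection illuminates the cell sector facing the target", {
  mask <- disc_mask(c(48, 48), 12)

  # half-disc facing the target; its centroid lies on the centroid->target ray
  aoi <- select_aoi(mask, c(48, 48), c(90, 48), front_fraction = 0.5)
  expect_true(all(aoi[mask == FALSE] == FALSE))
  expect_equal(sum(aoi), ceiling(0.5 * sum(mask)), tolerance = 0.01)
  idx <- which(aoi, arr.ind = TRUE)
  aoi_c <- c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5)
  expect_gt(aoi_c[1], 48)            # ahead of the centroid
  expect_equal(aoi_c[2], 48, tolerance = 0.1) # on the ray

  # front_fraction 1: the whole mask
  expect_equal(select_aoi(mask, c(48, 48), c(90, 48), 1), mask)

  # asymmetric mask: equals the brute-force top-quantile pixel set
  set.seed(13)
  amask <- mask
  amask[sample(which(amask), 150)] <- FALSE
  amask[30:60, 52:70] <- TRUE
  d <- c(60, 60) - c(48, 48)
  u <- d / sqrt(sum(d^2))
  aoi2 <- select_aoi(amask, c(48, 48), c(60, 60), front_fraction = 0.3)
  idx <- which(amask, arr.ind = TRUE)
  proj <- ((idx[, 2] - 0.5) - 48) * u[1] + ((idx[, 1] - 0.5) - 48) * u[2]
  k <- ceiling(0.3 * nrow(idx))
  thr <- sort(proj, decreasing = TRUE)[k]
  oracle <- matrix(FALSE, 96, 96)
  oracle[idx[proj >= thr, , drop = FALSE]] <- TRUE
  expect_identical(aoi2, oracle)

  expect_error(select_aoi(mask, c(48, 48), c(48, 48)), "degenerate")
})

test_that("the trajectory controller corrects toward the path", {
  path <- circle_path(40, c(80, 80))
  mask_on <- disc_mask(c(120, 80), 12, c(160, 160))

  # centroid on the path: the AOI faces the along-path direction
  cmd <- migration_controller_step(c(120, 80), mask_on, path)
  expect_length(cmd$masks, 1)
  aoi_c <- optoloop:::mask_centroid(cmd$masks[[1]])
  # path runs counterclockwise in (x, y): tangent at (120, 80) is +y
  expect_gt(aoi_c[2] - 80, 2)

  # centroid displaced 5 um inside the circle: outward radial correction
  mask_in <- disc_mask(c(115, 80), 12, c(160, 160))
  cmd2 <- migration_controller_step(c(115, 80), mask_in, path)
  aoi_c2 <- optoloop:::mask_centroid(cmd2$masks[[1]])
  expect_gt(aoi_c2[1] - 115, 0.5) # +x is radially outward here

  # lost track: a zero-irradiance (empty) command
  cmd3 <- migration_controller_step(NULL, mask_on, path)
  expect_length(cmd3$masks, 0)
  expect_true(attr(cmd3, "lost"))
})

test_that("closed-loop trajectory correction is contracting without noise", {
  path <- guide_path(rbind(c(0, 50), c(500, 50)))
  cell <- migrating_cell(position = c(20, 60), angle = 0) # 10 um off the path
  dev <- numeric(40)
  for (k in 1:40) {
    pr <- project_to_path(cell$position, path)
    dev[k] <- pr$deviation
    sp <- next_setpoint(pr, path, 10)
    mask <- disc_mask(cell$position, 12, c(120, 520))
    aoi <- select_aoi(mask, cell$position, sp$point)
    cell <- migrate_step(cell, 0.23, optoloop:::mask_centroid(aoi), 60,
                         noise = FALSE)
  }
  # contracts monotonically until it reaches the path, and stays there
  approach <- dev[5:40]
  while_off <- which(approach > 0.5)
  expect_true(all(diff(approach[while_off]) <= 1e-9))
  expect_lt(dev[40], 0.5)
})

test_that("collision detection flags exactly the converging configurations", {
  cfg <- avoidance_config(lookahead_horizon = 5, collision_distance = 30)
  v <- 1.2 # um per frame closing speed per cell
  # head-on: flagged iff gap - 2 v h < collision_distance
  for (gap in c(60, 44, 41, 35, 20)) {
    pos <- rbind(c(0, 0), c(gap, 0))
    vel <- rbind(c(v, 0), c(-v, 0))
    flagged <- nrow(detect_collision(pos, vel, cfg)) > 0
    expect_equal(flagged, gap - 2 * v * 5 < 30)
  }
  # parallel, non-converging tracks: never flagged
  pos <- rbind(c(0, 0), c(0, 40))
  vel <- rbind(c(v, 0), c(v, 0))
  expect_equal(nrow(detect_collision(pos, vel, cfg)), 0)
})

test_that("avoidance pulls back exactly one cell of a pair, to its rear", {
  masks <- list(disc_mask(c(40, 48), 10), disc_mask(c(70, 48), 10))
  cent <- rbind(c(40, 48), c(70, 48))
  vel <- rbind(c(1.2, 0), c(-1.2, 0))
  cmds <- lapply(1:2, function(i) {
    aoi <- select_aoi(masks[[i]], cent[i, ], cent[i, ] + vel[i, ] * 10)
    illumination_command(list(aoi), 0.23)
  })
  pairs <- detect_collision(cent, vel, avoidance_config())
  expect_equal(nrow(pairs), 1)

  out <- apply_avoidance(cmds, pairs, masks, cent, vel,
                         config = avoidance_config(tie_break = "lower_id"))
  expect_equal(attr(out, "yielded"), 1L)
  # the yielder's AOI flips behind it: centroid projection onto its previous
  # motion direction becomes negative
  aoi_c <- optoloop:::mask_centroid(out[[1]]$masks[[1]])
  expect_lt((aoi_c[1] - cent[1, 1]) * vel[1, 1], 0)
  # the other cell's command is untouched
  expect_identical(out[[2]], cmds[[2]])

  # no collisions: identity
  none <- matrix(integer(), 0, 2)
  expect_identical(apply_avoidance(cmds, none, masks, cent, vel)[[1]],
                   cmds[[1]])
})

test_that("a three-cell conflict resolves without any near collision", {
  p1 <- rotated_circle(40, c(80, 80), 320)
  p2 <- rotated_circle(40, c(150, 80), 90)
  p3 <- rotated_circle(40, c(115, 145), 200)
  cfg <- experiment_config("migration", duration = 120, seed = 4,
                           population = population_spec(3, "migration",
                                                        cv = list()),
                           paths = list(p1, p2, p3),
                           avoidance = avoidance_config())
  rec <- run_closed_loop(cfg)
  d <- rec$rows
  gaps <- sapply(split(d, d$frame), function(fr) {
    min(dist(cbind(fr$true_x, fr$true_y)))
  })
  expect_gt(sum(rec$events$event == "avoidance_pullback"), 0)
  expect_gte(min(gaps), cfg$avoidance$collision_distance)
})

test_that("the PID law computes, clamps and freezes its integral when saturated", {
  st <- pid_state(i_max = 10)
  # zero error, empty integral: zero output
  r <- pid_step(st, 0, pid_gains(10, 1, 1), dt = 15)
  expect_equal(r$u, 0)
  # pure proportional law: constant error 0.1 at kp 50 gives 5 every step
  st2 <- pid_state(i_max = 10)
  for (i in 1:5) {
    r2 <- pid_step(st2, 0.1, pid_gains(50), dt = 15)
    st2 <- r2$state
    expect_equal(r2$u, 5)
  }
  # outputs stay in [0, i_max] whatever the drive
  set.seed(17)
  st3 <- pid_state(i_max = 10)
  for (i in 1:200) {
    r3 <- pid_step(st3, runif(1, -5, 5), pid_gains(20, 0.5, 2), dt = 15,
                   measurement = runif(1))
    st3 <- r3$state
    expect_gte(r3$u, 0)
    expect_lte(r3$u, 10)
  }
  # non-finite error: fault flagged, previous output held
  r4 <- pid_step(st2, NaN, pid_gains(50), dt = 15)
  expect_true(r4$state$fault)
  expect_equal(r4$u, 5)
})

test_that("anti-windup reduces overshoot after prolonged saturation", {
  overshoot_with <- function(anti) {
    pl <- lexy_plant()
    st <- pid_state(i_max = 10.4, anti_windup = anti)
    g <- pid_gains(5, 0.05)
    bounds <- lexy_norm_bounds(pl, 10.4)
    # 100 steps at an unreachable setpoint saturate the controller
    meas <- 0
    for (i in 1:100) {
      meas <- optoloop:::lexy_normalised(pl, bounds, "cytosol")
      r <- pid_step(st, 1.5 - meas, g, 15, measurement = meas)
      st <- r$state
      pl <- lexy_step(pl, r$u, 15)
    }
    # then a reachable setpoint
    peak <- 0
    for (i in 1:200) {
      meas <- optoloop:::lexy_normalised(pl, bounds, "cytosol")
      r <- pid_step(st, 0.3 - meas, g, 15, measurement = meas)
      st <- r$state
      pl <- lexy_step(pl, r$u, 15)
      peak <- max(peak, meas)
    }
    peak - 0.3
  }
  expect_lt(overshoot_with(TRUE), overshoot_with(FALSE))
})

test_that("gain schedules interpolate linearly and clamp at the ends", {
  sch <- gain_schedule(c(0.2, 0.6, 0.9), list(
    pid_gains(1, 0.1, 0), pid_gains(3, 0.3, 30), pid_gains(5, 0.5, 60)
  ))
  # exactly at an operating point
  expect_equal(schedule_gains(0.6, sch), pid_gains(3, 0.3, 30))
  # midpoint: arithmetic mean of the bracketing gains
  g <- schedule_gains(0.4, sch)
  expect_equal(c(g$kp, g$ki, g$kd), c(2, 0.2, 15))
  # beyond the ends: clamped to the end gains
  expect_equal(schedule_gains(0.05, sch)$kp, 1)
  expect_equal(schedule_gains(0.99, sch)$kp, 5)

  expect_error(gain_schedule(c(0.5, 0.2), list(pid_gains(1), pid_gains(2))))
  expect_error(gain_schedule(0.5, list(pid_gains(1))))
})

test_that("error sign conventions give both compartment controllers positive plant gain", {
  # nucleus above setpoint: positive drive (more light, more export)
  expect_gt(control_error("nucleus", setpoint = 0.4, measurement = 0.6), 0)
  # cytosol above setpoint: negative drive (light off, import restores)
  expect_lt(control_error("cytosol", setpoint = 0.4, measurement = 0.6), 0)

  # both controllers reach their setpoints on the same simulated cell
  pl <- lexy_plant()
  g <- pid_gains(2, 2 / 240)
  sim_c <- simulate_lexy_pid(pl, g, data.frame(frame = 1, setpoint = 0.5),
                             duration = 150, dt = 15, mode = "cytosol")
  expect_lt(abs(tail(sim_c$measurement, 1) - 0.5), 0.03)
  sim_n <- simulate_lexy_pid(pl, g, data.frame(frame = 1, setpoint = 0.5),
                             duration = 150, dt = 15, mode = "nucleus")
  expect_lt(abs(tail(sim_n$measurement, 1) - 0.5), 0.03)
})

test_that("integral action removes steady-state error on the simulated plant", {
  pl <- lexy_plant()
  sim <- simulate_lexy_pid(pl, pid_gains(2, 2 / 120),
                           data.frame(frame = 1, setpoint = 0.35),
                           duration = 200, dt = 15)
  expect_lt(max(abs(tail(sim$measurement, 20) - 0.35)), 0.01)
})
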
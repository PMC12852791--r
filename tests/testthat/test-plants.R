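test_that("migration plant follows the saturating light dose-response", {
  mc <- migrating_cell(position = c(0, 0), angle = 0)

  # dark, noise off: straight-line motion at the baseline speed
  s <- migrate_step(mc, 0, NULL, dt = 60, noise = FALSE)
  expect_equal(s$position, c(mc$speed_base, 0))

  # saturating light toward +x: speed tends to speed_base + v_max
  s2 <- mc
  for (i in 1:20) s2 <- migrate_step(s2, 1e6, s2$position + c(10, 0), 60, noise = FALSE)
  step <- migrate_step(s2, 1e6, s2$position + c(10, 0), 60, noise = FALSE)
  disp <- sqrt(sum((step$position - s2$position)^2))
  expect_equal(disp, mc$speed_base + mc$v_max, tolerance = 1e-6)
  expect_equal(step$position[2], s2$position[2], tolerance = 1e-6)

  # half-saturation: light-induced increment is exactly v_max / 2
  s3 <- migrate_step(mc, mc$K_I, c(10, 0), 60, noise = FALSE)
  expect_equal(sqrt(sum(s3$position^2)), mc$speed_base + mc$v_max / 2,
               tolerance = 1e-9)
})

test_that("undirected migration is an isotropic persistent random walk", {
  set.seed(5)
  n <- 400
  nsteps <- 80
  dt <- 60
  disp <- matrix(NA_real_, n, 2)
  msd_short <- msd_long <- numeric(n)
  for (i in 1:n) {
    s <- migrating_cell(angle = runif(1, -pi, pi))
    pos <- matrix(NA_real_, nsteps + 1, 2)
    pos[1, ] <- s$position
    for (k in 1:nsteps) {
      s <- migrate_step(s, 0, NULL, dt)
      pos[k + 1, ] <- s$position
    }
    disp[i, ] <- pos[nsteps + 1, ]
    msd_short[i] <- sum((pos[3, ] - pos[1, ])^2)   # 2 min << persistence
    msd_long[i] <- sum((pos[nsteps + 1, ] - pos[1, ])^2) # 80 min >> persistence
  }
  # isotropy: mean displacement compatible with zero (3 standard errors)
  se <- apply(disp, 2, sd) / sqrt(n)
  expect_lt(abs(mean(disp[, 1])), 3 * se[1])
  expect_lt(abs(mean(disp[, 2])), 3 * se[2])
  # ballistic at t << persistence_time, sub-ballistic at t >> persistence_time
  v <- 0.5
  expect_gt(mean(msd_short) / (v * 2)^2, 0.8)
  expect_lt(mean(msd_long) / (v * 80)^2, 0.5)
})

test_that("transport plant conserves mass and relaxes to analytic steady states", {
  pl <- lexy_plant()
  total0 <- pl$vol_ratio * pl$N + pl$C

  # dark initial condition is the dark steady state
  ss0 <- lexy_steady_state(pl, 0)
  expect_equal(pl$N, ss0$N, tolerance = 1e-9)
  expect_equal(pl$A, pl$A_dark)

  # saturating light: relaxes to the analytic bright steady state
  x <- pl
  for (i in 1:600) x <- lexy_step(x, 10.4, 15)
  ss <- lexy_steady_state(pl, 10.4)
  expect_equal(x$C, ss$C, tolerance = 1e-5)
  expect_equal(x$A, ss$A, tolerance = 1e-6)
  expect_lt(abs(x$vol_ratio * x$N + x$C - total0) / total0, 1e-9)

  # A stays in [0, 1], concentrations non-negative under erratic drive
  set.seed(8)
  y <- pl
  for (i in 1:200) {
    y <- lexy_step(y, runif(1, 0, 10.4), runif(1, 1, 60))
    expect_true(y$A >= 0 && y$A <= 1 && y$N >= 0 && y$C >= 0)
  }
})

test_that("light-response rate matches the eigenvalue of the linearised system", {
  pl <- lexy_plant()
  irr <- 10.4
  # Jacobian of (A, N, C) at the bright steady state
  ss <- lexy_steady_state(pl, irr)
  ke <- pl$k_exp0 / (1 + pl$expression / pl$K_E)
  J <- rbind(
    c(-(pl$k_on_per_I * irr + pl$k_off), 0, 0),
    c(-ke * ss$N, -ke * ss$A, pl$k_imp / pl$vol_ratio),
    c(pl$vol_ratio * ke * ss$N, pl$vol_ratio * ke * ss$A, -pl$k_imp)
  )
  ev <- eigen(J)$values
  lam <- sort(abs(ev[abs(ev) > 1e-12])) # drop the conservation zero mode
  dominant <- lam[1]

  t <- seq(0, 900, by = 15)
  x <- pl
  C <- numeric(length(t))
  C[1] <- x$C
  for (i in 2:length(t)) {
    x <- lexy_step(x, irr, 15)
    C[i] <- x$C
  }
  fit <- fit_one_phase_decay(t, C)
  expect_true(fit$converged)
  expect_lt(abs(fit$k - dominant) / dominant, 0.1)
})

test_that("export slows with expression while import does not", {
  rates <- vapply(c(250, 500, 1000, 2000, 4000), function(E) {
    pl <- lexy_plant(expression = E)
    t <- seq(0, 900, by = 15)
    C <- numeric(length(t))
    C[1] <- pl$C
    for (i in 2:length(t)) {
      pl <- lexy_step(pl, 10.4, 15)
      C[i] <- pl$C
    }
    fit_one_phase_decay(t, C)$k
  }, numeric(1))
  expect_true(all(diff(rates) < 0))

  # import (dark recovery) rate is expression-independent
  imp <- vapply(c(250, 2000), function(E) {
    pl <- lexy_plant(expression = E)
    ss <- lexy_steady_state(pl, 10.4)
    pl$N <- ss$N; pl$C <- ss$C; pl$A <- ss$A
    t <- seq(0, 900, by = 15)
    C <- numeric(length(t))
    C[1] <- pl$C
    for (i in 2:length(t)) {
      pl <- lexy_step(pl, 0, 15)
      C[i] <- pl$C
    }
    fit_one_phase_decay(t, C)$k
  }, numeric(1))
  expect_equal(imp[1], imp[2], tolerance = 0.05)
})

test_that("steady-state dose-response is monotone over an irradiance grid", {
  pl <- lexy_plant()
  grid <- seq(0, 10.4, length.out = 20)
  C_ss <- vapply(grid, function(I) {
    x <- pl
    for (i in 1:400) x <- lexy_step(x, I, 15)
    x$C
  }, numeric(1))
  expect_true(all(diff(C_ss) >= -1e-9))
})

test_that("population sampling is seeded, unbiased, and degenerates at CV 0", {
  spec0 <- population_spec(5, "migration", cv = list(speed_base = 0, expression = 0))
  cells <- sample_population(spec0)
  expect_true(all(vapply(cells, `[[`, numeric(1), "speed_base") == 0.5))

  s1 <- sample_population(population_spec(8, "lexy", seed = 42))
  s2 <- sample_population(population_spec(8, "lexy", seed = 42))
  expect_identical(attr(s1, "parameters"), attr(s2, "parameters"))

  big <- sample_population(population_spec(1e4, "migration", seed = 9))
  v <- attr(big, "parameters")$speed_base
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.5), 3 * se)

  expect_error(population_spec(3, "lexy", cv = list(expression = -1)), "cv")
  expect_error(sample_population(population_spec(2, "lexy", cv = list(bogus = 0.1))),
               "unknown parameter")
})
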
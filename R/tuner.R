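# Model-based PID tuning on the transport plant.

#' Normalisation bounds of a transport plant
#'
#' Dark-state and saturating-light steady-state concentrations, defining the
#' per-cell dynamic range against which intensities are normalised.
#'
#' @param plant a [lexy_plant].
#' @param i_max saturating irradiance, uW/cm^2.
#' @return list with `C_dark`, `C_sat`, `N_dark`, `N_sat`.
#' @export
lexy_norm_bounds <- function(plant, i_max = 10.4) {
  d <- lexy_steady_state(plant, 0)
  s <- lexy_steady_state(plant, i_max)
  if (s$C - d$C <= 1e-9) {
    stop("plant has no usable light sensitivity: saturating light does not ",
         "move the cytosolic steady state")
  }
  list(C_dark = d$C, C_sat = s$C, N_dark = d$N, N_sat = s$N)
}

# normalised measurement of a plant state under a given convention
lexy_normalised <- function(plant, bounds, mode = "cytosol") {
  if (mode == "cytosol") {
    clamp((plant$C - bounds$C_dark) / (bounds$C_sat - bounds$C_dark), 0, 1)
  } else {
    clamp((plant$N - bounds$N_sat) / (bounds$N_dark - bounds$N_sat), 0, 1)
  }
}

#' Irradiance holding a transport plant at a normalised setpoint
#'
#' Inverts the steady-state map of the plant: the constant irradiance whose
#' steady state sits at the requested fraction of the cytosolic dynamic
#' range. Used to construct operating-point initial conditions for tuning.
#'
#' @param plant a [lexy_plant].
#' @param target normalised cytosolic setpoint in `[0, 1)`.
#' @param i_max saturating irradiance defining the dynamic range.
#' @return Irradiance in uW/cm^2.
#' @export
lexy_irradiance_for <- function(plant, target, i_max = 10.4) {
  stopifnot(target >= 0, target <= 1)
  target <- min(target, 1 - 1e-6)
  b <- lexy_norm_bounds(plant, i_max)
  C <- b$C_dark + target * (b$C_sat - b$C_dark)
  total <- plant$vol_ratio * plant$N + plant$C
  ke <- lexy_k_exp(plant)
  A_needed <- plant$k_imp * C / ((total - C) * ke)
  A_needed <- clamp(A_needed, plant$A_dark, 1 - 1e-9)
  if (plant$k_on_per_I <= 0) {
    if (A_needed > plant$A_dark + 1e-12) {
      stop("plant has no light sensitivity (k_on_per_I = 0)")
    }
    return(0)
  }
  I <- plant$k_off * (A_needed - plant$A_dark) /
    (plant$k_on_per_I * (1 - A_needed))
  clamp(I, 0, i_max)
}

#' Simulate the PID loop on the transport plant without imaging
#'
#' Runs the controller directly against the kinetic plant (measurement =
#' true normalised concentration, optionally with additive noise), skipping
#' rendering and segmentation. This is the fast inner loop used for tuning
#' and for controller benchmarks; the full imaging loop is
#' [run_closed_loop()].
#'
#' @param plant a [lexy_plant] (initial state).
#' @param controller a [pid_gains] (fixed PID) or [gain_schedule].
#' @param setpoints data frame with columns `frame` (1-based frame at which
#'   the setpoint takes effect) and `setpoint` (normalised intensity).
#' @param duration total number of frames.
#' @param dt frame interval, seconds.
#' @param mode `"cytosol"` or `"nucleus"`.
#' @param i_max irradiance bound, uW/cm^2.
#' @param meas_noise_sd additive measurement noise (normalised units).
#' @param schedule_smooth frames of moving-average smoothing of the
#'   scheduling variable (default 3).
#' @return Data frame: `frame`, `time_s`, `setpoint`, `measurement`,
#'   `error`, `u`, `kp`, `ki`, `kd`.
#' @export
simulate_lexy_pid <- function(plant, controller, setpoints, duration,
                              dt = 15, mode = c("cytosol", "nucleus"),
                              i_max = 10.4, meas_noise_sd = 0,
                              schedule_smooth = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(plant, "lexy_plant"), duration >= 1,
            is.data.frame(setpoints), all(c("frame", "setpoint") %in% names(setpoints)))
  scheduled <- inherits(controller, "gain_schedule")
  if (!scheduled) stopifnot(inherits(controller, "pid_gains"))
  bounds <- lexy_norm_bounds(plant, i_max)
  st <- pid_state(i_max = i_max)
  sched_buf <- numeric()
  rows <- vector("list", duration)
  for (fi in seq_len(duration)) {
    sp <- setpoints$setpoint[max(which(setpoints$frame <= fi))]
    meas <- lexy_normalised(plant, bounds, mode)
    if (meas_noise_sd > 0) meas <- clamp(meas + rnorm(1, 0, meas_noise_sd), 0, 1)
    sched_buf <- tail(c(sched_buf, meas), schedule_smooth)
    gains <- if (scheduled) schedule_gains(mean(sched_buf), controller) else controller
    err <- control_error(mode, sp, meas)
    res <- pid_step(st, err, gains, dt, measurement = meas)
    st <- res$state
    plant <- lexy_step(plant, res$u, dt)
    rows[[fi]] <- data.frame(frame = fi, time_s = (fi - 1) * dt, setpoint = sp,
                             measurement = meas, error = err, u = res$u,
                             kp = gains$kp, ki = gains$ki, kd = gains$kd)
  }
  do.call(rbind, rows)
}

# closed-loop step metrics for one gain candidate at one operating point
step_response_metrics <- function(plant, gains, from, to, dt, i_max,
                                  horizon_s, settle_tol, mode = "cytosol") {
  duration <- ceiling(horizon_s / dt)
  sim <- simulate_lexy_pid(plant, gains,
                           data.frame(frame = 1, setpoint = to),
                           duration, dt = dt, mode = mode, i_max = i_max)
  step <- abs(to - from)
  overshoot <- if (to >= from) {
    max(sim$measurement - to) / max(step, 1e-9)
  } else {
    max(to - sim$measurement) / max(step, 1e-9)
  }
  inside <- abs(sim$measurement - to) <= settle_tol
  settle <- NA_real_
  for (i in seq_along(inside)) {
    if (all(inside[i:length(inside)])) {
      settle <- i * dt
      break
    }
  }
  list(overshoot = max(overshoot, 0), settle_time = settle,
       settled = !is.na(settle))
}

#' Tune PID gains over the operating range of a transport plant
#'
#' Model-based tuning: at each operating point the plant is initialised at
#' the steady state of the previous point and stepped to the new setpoint
#' under every candidate gain set; candidates violating the overshoot bound
#' or failing to settle within the horizon are discarded, and the fastest
#' settling survivor wins (ties towards the smallest proportional gain).
#' Classical tuning rules are avoided deliberately: the plant gain varies
#' strongly across the operating range, which is the reason a schedule is
#' tuned per operating point at all.
#'
#' @param plant a [lexy_plant] representing the nominal (model) cell.
#' @param operating_points normalised-intensity operating points (default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`). A single point tunes a fixed PID.
#' @param dt controller interval, seconds.
#' @param i_max irradiance bound, uW/cm^2.
#' @param overshoot_max admissible fractional overshoot of a setpoint step
#'   (default 0.05).
#' @param settle_tol settling band, normalised units.
#' @param horizon_s simulation horizon per candidate, seconds.
#' @param kp_grid,ti_grid,td_grid candidate proportional gains, integral
#'   times (s; `Inf` = no integral action) and derivative times (s).
#' @param mode `"cytosol"` or `"nucleus"`.
#' @return A [gain_schedule] (or a single [pid_gains] when only one
#'   operating point is given), with the per-point tuning diagnostics in
#'   attribute `"tuning"`.
#' @export
tune_pid <- function(plant, operating_points = c(0.1, 0.3, 0.5, 0.7, 0.9),
                     dt = 15, i_max = 10.4, overshoot_max = 0.05,
                     settle_tol = 0.02, horizon_s = 1800,
                     kp_grid = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 40),
                     ti_grid = c(60, 120, 240, 480),
                     td_grid = c(0, 15),
                     mode = c("cytosol", "nucleus")) {
  mode <- match.arg(mode)
  stopifnot(inherits(plant, "lexy_plant"), length(operating_points) >= 1,
            all(operating_points > 0), all(operating_points < 1),
            all(diff(operating_points) > 0))
  bounds <- lexy_norm_bounds(plant, i_max) # errors out for insensitive plants
  cand <- expand.grid(kp = kp_grid, ti = ti_grid, td = td_grid)
  gains_at <- vector("list", length(operating_points))
  diag_rows <- list()
  for (p in seq_along(operating_points)) {
    op <- operating_points[p]
    # operating points are approached along the actuated direction (light
    # drives cytosol up / nucleus down; the reverse direction is passive
    # dark recovery, whose overshoot is plant-limited, not tunable):
    # cytosol steps come from the previous operating point, nucleus steps
    # from the dark state
    from <- if (mode == "nucleus") {
      1
    } else if (p == 1) 0 else operating_points[p - 1]
    cyto_from <- if (mode == "cytosol") from else 1 - from
    I0 <- lexy_irradiance_for(plant, cyto_from, i_max)
    ss <- lexy_steady_state(plant, I0)
    p0 <- plant
    p0$A <- ss$A
    p0$N <- ss$N
    p0$C <- ss$C
    best <- NULL
    for (ci in seq_len(nrow(cand))) {
      g <- pid_gains(cand$kp[ci],
                     ki = if (is.finite(cand$ti[ci])) cand$kp[ci] / cand$ti[ci] else 0,
                     kd = cand$kp[ci] * cand$td[ci])
      m <- step_response_metrics(p0, g, from, op, dt, i_max,
                                 horizon_s, settle_tol, mode)
      if (!m$settled || m$overshoot > overshoot_max) next
      if (is.null(best) || m$settle_time < best$settle_time ||
          (m$settle_time == best$settle_time && g$kp < best$gains$kp)) {
        best <- list(gains = g, settle_time = m$settle_time,
                     overshoot = m$overshoot)
      }
    }
    if (is.null(best)) {
      stop(sprintf(
        "tuning infeasible at operating point %.2f: no candidate settles within %.0f s with overshoot <= %.0f%%",
        op, horizon_s, 100 * overshoot_max
      ))
    }
    gains_at[[p]] <- best$gains
    diag_rows[[p]] <- data.frame(operating_point = op,
                                 kp = best$gains$kp, ki = best$gains$ki,
                                 kd = best$gains$kd,
                                 settle_time_s = best$settle_time,
                                 overshoot = best$overshoot)
  }
  diag <- do.call(rbind, diag_rows)
  if (length(operating_points) == 1) {
    out <- gains_at[[1]]
  } else {
    out <- gain_schedule(operating_points, gains_at)
  }
  attr(out, "tuning") <- diag
  out
}
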
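#' PID gains
#'
#' Output units are uW/cm^2 per unit of normalised-intensity error; the
#' integral gain is per second and the derivative gain in seconds.
#'
#' @param kp,ki,kd non-negative proportional, integral and derivative gains.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp, ki = 0, kd = 0) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0)
  if (kp == 0 && ki == 0 && kd == 0) stop("at least one gain must be positive")
  structure(list(kp = kp, ki = ki, kd = kd), class = "pid_gains")
}

#' PID controller state
#'
#' Holds the integral accumulator, the previous error and measurement, and
#' the output bounds. The integral is frozen while the output is saturated
#' (conditional anti-windup), unless `anti_windup = FALSE`.
#'
#' @param i_max upper output bound, uW/cm^2 (lower bound is 0: light cannot
#'   be negative).
#' @param anti_windup logical; freeze the integral while saturated.
#' @return An object of class `pid_state`.
#' @export
pid_state <- function(i_max = 10.4, anti_windup = TRUE) {
  stopifnot(i_max > 0)
  structure(
    list(integral = 0, prev_error = NA_real_, prev_meas = NA_real_,
         last_u = 0, i_max = i_max, anti_windup = anti_windup,
         fault = FALSE),
    class = "pid_state"
  )
}

#' One PID update
#'
#' `u = kp e + ki int(e dt) + kd de/dt`, clamped to `[0, i_max]`. When the
#' measurement is supplied, the derivative acts on the (negated) measurement
#' rather than the error, so setpoint steps do not kick the output. While
#' the output is saturated the integral only accumulates error that drives
#' the output back into range (anti-windup). A non-finite error holds the
#' previous output and raises the fault flag.
#'
#' @param state a [pid_state].
#' @param error setpoint minus measurement, in the controller's error sign
#'   convention (see [control_error()]).
#' @param gains a [pid_gains] (possibly from [schedule_gains()]).
#' @param dt time step, seconds.
#' @param measurement optional raw measurement for derivative-on-measurement.
#' @return list with `u` (commanded irradiance, uW/cm^2) and `state`
#'   (updated).
#' @export
pid_step <- function(state, error, gains, dt, measurement = NULL) {
  stopifnot(inherits(state, "pid_state"), inherits(gains, "pid_gains"), dt > 0)
  if (!is.finite(error)) {
    state$fault <- TRUE
    return(list(u = state$last_u, state = state))
  }
  state$fault <- FALSE
  deriv <- 0
  if (!is.null(measurement) && is.finite(measurement)) {
    if (is.finite(state$prev_meas)) {
      deriv <- -(measurement - state$prev_meas) / dt
    }
    state$prev_meas <- measurement
  } else if (is.finite(state$prev_error)) {
    deriv <- (error - state$prev_error) / dt
  }
  int_candidate <- state$integral + error * dt
  u_raw <- gains$kp * error + gains$ki * int_candidate + gains$kd * deriv
  u <- clamp(u_raw, 0, state$i_max)
  saturated <- u_raw < 0 || u_raw > state$i_max
  if (!saturated || !state$anti_windup ||
      (u_raw > state$i_max && error < 0) || (u_raw < 0 && error > 0)) {
    state$integral <- int_candidate
  }
  state$prev_error <- error
  state$last_u <- u
  list(u = u, state = state)
}

#' Gain schedule over the operating range
#'
#' A value-gain matrix: PID gains tabulated at operating points of the
#' scheduling variable (the measured normalised intensity), interpolated
#' piecewise-linearly in between and held constant beyond the ends. Gain
#' scheduling adapts the controller to the nonlinear plant, whose gain
#' varies strongly across the operating range.
#'
#' @param operating_points strictly increasing values in `[0, 1]`
#'   (length >= 2).
#' @param gains list of [pid_gains], one per operating point.
#' @return An object of class `gain_schedule`.
#' @export
gain_schedule <- function(operating_points, gains) {
  stopifnot(length(operating_points) >= 2,
            length(gains) == length(operating_points),
            all(diff(operating_points) > 0),
            all(operating_points >= 0), all(operating_points <= 1))
  for (g in gains) stopifnot(inherits(g, "pid_gains"))
  structure(list(operating_points = operating_points, gains = gains),
            class = "gain_schedule")
}

#' @export
print.gain_schedule <- function(x, ...) {
  m <- as.data.frame(x)
  cat("gain_schedule:\n")
  print(m, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.gain_schedule <- function(x, ...) {
  data.frame(
    operating_point = x$operating_points,
    kp = vapply(x$gains, `[[`, numeric(1), "kp"),
    ki = vapply(x$gains, `[[`, numeric(1), "ki"),
    kd = vapply(x$gains, `[[`, numeric(1), "kd")
  )
}

#' Interpolate scheduled gains at a measured operating point
#'
#' @param measurement scheduling-variable value (normalised intensity;
#'   clipped to `[0, 1]`).
#' @param schedule a [gain_schedule].
#' @return A [pid_gains] with each gain interpolated piecewise-linearly
#'   between the bracketing operating points (constant beyond the ends).
#' @export
schedule_gains <- function(measurement, schedule) {
  stopifnot(inherits(schedule, "gain_schedule"), is.finite(measurement))
  m <- clamp(measurement, 0, 1)
  tab <- as.data.frame(schedule)
  g <- vapply(c("kp", "ki", "kd"), function(col) {
    approx(tab$operating_point, tab[[col]], xout = m, rule = 2)$y
  }, numeric(1))
  pid_gains(g[["kp"]], g[["ki"]], g[["kd"]])
}

#' Error sign convention for compartment controllers
#'
#' Light drives cargo out of the nucleus: it raises cytosolic intensity
#' (positive plant gain) and lowers nuclear intensity (negative plant gain).
#' The error is folded so the PID always sees a positive plant gain:
#' cytosol mode uses `setpoint - measurement`, nucleus mode
#' `measurement - setpoint`.
#'
#' @param mode `"cytosol"` or `"nucleus"`.
#' @param setpoint target normalised intensity.
#' @param measurement measured normalised intensity.
#' @return Scalar error to feed [pid_step()].
#' @export
control_error <- function(mode = c("cytosol", "nucleus"), setpoint, measurement) {
  mode <- match.arg(mode)
  if (mode == "cytosol") setpoint - measurement else measurement - setpoint
}

#' Select the front sector of a cell mask as the area of illumination
#'
#' Returns the subset of cell-mask pixels whose scalar projection onto the
#' unit vector from the centroid to the target lies in the top
#' `front_fraction` quantile: the region of the cell closest to the next
#' setpoint. Ties at the quantile boundary are included, so the result is
#' deterministic.
#'
#' @param cell_mask logical matrix (the cell's segmentation mask).
#' @param centroid cell centroid, `c(x, y)` um.
#' @param target aim point, `c(x, y)` um; must differ from the centroid.
#' @param front_fraction fraction of the cell to illuminate, in `(0, 1]`.
#' @param pixel_size um per pixel.
#' @return Logical matrix: the AOI (subset of `cell_mask`, non-empty).
#' @export
select_aoi <- function(cell_mask, centroid, target, front_fraction = 0.5,
                       pixel_size = 1) {
  stopifnot(is.matrix(cell_mask), is.logical(cell_mask), any(cell_mask),
            front_fraction > 0, front_fraction <= 1)
  stopifnot_point(centroid, "centroid")
  stopifnot_point(target, "target")
  dir <- target - centroid
  if (vec_norm(dir) < 1e-9) stop("degenerate AOI direction: target equals centroid")
  u <- unit_vec(dir)
  idx <- which(cell_mask, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * pixel_size
  y <- (idx[, 1] - 0.5) * pixel_size
  proj <- (x - centroid[1]) * u[1] + (y - centroid[2]) * u[2]
  k <- ceiling(front_fraction * length(proj))
  thr <- sort(proj, decreasing = TRUE)[k]
  aoi <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
  sel <- proj >= thr
  aoi[idx[sel, , drop = FALSE]] <- TRUE
  aoi
}

# centroid (um) of a logical mask
mask_centroid <- function(mask, pixel_size = 1) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5) * pixel_size
}

#' One step of the orientation-correction trajectory controller
#'
#' Composes the migration control law for one cell: project the tracked
#' centroid onto the guide path, pick the setpoint one lookahead ahead, and
#' illuminate the front sector of the cell mask facing that setpoint at the
#' configured irradiance. A lost track yields an empty command (light off).
#'
#' @param centroid tracked cell centroid (um), or `NULL` if the track is
#'   lost.
#' @param cell_mask logical matrix, the cell's current segmentation mask.
#' @param path a [guide_path].
#' @param irradiance commanded irradiance, uW/cm^2 (constant policy, or a
#'   value from a stepwise schedule).
#' @param lookahead setpoint lookahead along the path, um. The effective
#'   lookahead shrinks (to no less than 30% of this value) as the path
#'   deviation grows — the pure-pursuit refinement: a cell far off the path
#'   is aimed more steeply back at it, instead of shallowly at a distant
#'   waypoint.
#' @param front_fraction fraction of the cell to illuminate.
#' @param pixel_size um per pixel.
#' @param frame_interval frame interval, s.
#' @return An [illumination_command] with one region (or none if the track
#'   is lost), with attributes `projection` (the [project_to_path()] result),
#'   `target` (the aim point) and `completed`.
#' @export
migration_controller_step <- function(centroid, cell_mask, path,
                                      irradiance = 0.23, lookahead = 10,
                                      front_fraction = 0.5, pixel_size = 1,
                                      frame_interval = 60) {
  if (is.null(centroid)) {
    cmd <- illumination_command(frame_interval = frame_interval)
    attr(cmd, "lost") <- TRUE
    return(cmd)
  }
  pr <- project_to_path(centroid, path)
  lookahead_eff <- max(lookahead - pr$deviation, 0.3 * lookahead)
  sp <- next_setpoint(pr, path, lookahead_eff)
  aoi <- select_aoi(cell_mask, centroid, sp$point, front_fraction, pixel_size)
  cmd <- illumination_command(list(aoi), irradiance,
                              frame_interval = frame_interval)
  attr(cmd, "projection") <- pr
  attr(cmd, "target") <- sp$point
  attr(cmd, "completed") <- sp$completed
  cmd
}

#' Collision-avoidance configuration
#'
#' @param lookahead_horizon prediction horizon, frames (>= 1).
#' @param collision_distance minimum admissible centroid-centroid distance,
#'   um.
#' @param release_factor hysteresis: once a pair has been flagged, the
#'   yielding cell keeps pulling back until the pair is farther apart than
#'   `release_factor * collision_distance`, preventing flag/release
#'   chatter that would erode the safety margin.
#' @param tie_break which cell of a flagged pair yields: `"arc"` (the cell
#'   with the smaller remaining arc distance to its current target yields,
#'   minimising path disruption) or `"lower_id"`.
#' @return An object of class `avoidance_config`.
#' @export
avoidance_config <- function(lookahead_horizon = 5, collision_distance = 30,
                             release_factor = 1.5,
                             tie_break = c("arc", "lower_id")) {
  stopifnot(lookahead_horizon >= 1, collision_distance > 0,
            release_factor >= 1)
  structure(
    list(lookahead_horizon = as.integer(lookahead_horizon),
         collision_distance = collision_distance,
         release_factor = release_factor,
         tie_break = match.arg(tie_break)),
    class = "avoidance_config"
  )
}

#' Detect imminent collisions between tracked cells
#'
#' Extrapolates every track at constant velocity over the lookahead horizon
#' and flags each pair whose predicted positions come within the collision
#' distance at any step of the horizon (including the current frame).
#'
#' @param positions n x 2 matrix of current centroids (um).
#' @param velocities n x 2 matrix of velocity estimates (um/frame).
#' @param config an [avoidance_config].
#' @return Integer matrix with columns `i`, `j` (i < j), one row per flagged
#'   pair; zero rows when no collision is imminent.
#' @export
detect_collision <- function(positions, velocities, config = avoidance_config()) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  stopifnot(n >= 2, nrow(velocities) == n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    for (k in 0:config$lookahead_horizon) {
      pi_ <- positions[i, ] + k * velocities[i, ]
      pj <- positions[j, ] + k * velocities[j, ]
      if (sqrt(sum((pi_ - pj)^2)) < config$collision_distance) {
        hit[r] <- TRUE
        break
      }
    }
  }
  out <- pairs[hit, , drop = FALSE]
  colnames(out) <- c("i", "j")
  out
}

#' Pull yielding cells back to avoid collisions
#'
#' For each flagged pair, the yielding cell (chosen by the configured
#' tie-break) has its AOI replaced by the rear sector: the front-sector
#' selection re-aimed opposite to its current motion, so the cell is pulled
#' back in the direction opposing its movement. Other cells' commands are
#' unchanged.
#'
#' @param commands list of per-cell [illumination_command]s (one region
#'   each).
#' @param pairs flagged pairs from [detect_collision()].
#' @param cell_masks list of logical matrices, per cell.
#' @param centroids n x 2 matrix of centroids (um).
#' @param velocities n x 2 matrix of velocity estimates (um/frame).
#' @param remaining_arc numeric vector: remaining arc distance to each
#'   cell's current target (used by the `"arc"` tie-break); `NA` falls back
#'   to `"lower_id"`.
#' @param directions optional n x 2 matrix of pullback reference directions
#'   (the cell's movement direction when the avoidance engaged). Rows of
#'   `NA` fall back to the current velocity estimate. Latching the direction
#'   at engagement keeps the pullback pointing away from the conflict even
#'   after the cell has already turned around.
#' @param config an [avoidance_config].
#' @param front_fraction sector size for the rear AOI.
#' @param pixel_size um per pixel.
#' @return The modified command list, with attribute `"yielded"`: indices of
#'   cells whose AOI was flipped.
#' @export
apply_avoidance <- function(commands, pairs, cell_masks, centroids, velocities,
                            remaining_arc = NULL, directions = NULL,
                            config = avoidance_config(),
                            front_fraction = 0.5, pixel_size = 1) {
  if (!nrow(pairs)) {
    attr(commands, "yielded") <- integer()
    return(commands)
  }
  centroids <- as.matrix(centroids)
  velocities <- as.matrix(velocities)
  yielded <- integer()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    yield <- if (config$tie_break == "arc" && !is.null(remaining_arc) &&
                 is.finite(remaining_arc[i]) && is.finite(remaining_arc[j]) &&
                 remaining_arc[i] != remaining_arc[j]) {
      if (remaining_arc[i] < remaining_arc[j]) i else j
    } else {
      min(i, j)
    }
    v <- if (!is.null(directions) && all(is.finite(directions[yield, ]))) {
      directions[yield, ]
    } else {
      velocities[yield, ]
    }
    if (vec_norm(v) < 1e-9) v <- c(1, 0) # stationary cell: arbitrary fixed rear
    rear_target <- centroids[yield, ] - unit_vec(v) * 10
    cmd <- commands[[yield]]
    if (length(cmd$masks)) {
      aoi <- select_aoi(cell_masks[[yield]], centroids[yield, ], rear_target,
                        front_fraction, pixel_size)
      cmd$masks[[1]] <- aoi
      commands[[yield]] <- cmd
    }
    yielded <- c(yielded, yield)
  }
  attr(commands, "yielded") <- unique(yielded)
  commands
}
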
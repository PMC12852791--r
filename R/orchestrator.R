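#' Closed-loop experiment configuration
#'
#' Bundles everything a closed-loop run needs: the mode, the frame interval
#' (60 s for migration, 15 s for nucleocytoplasmic transport by default,
#' matching the acquisition intervals the two assays use), the plant
#' population, guide paths, controller, optics and seed.
#'
#' @param mode `"migration"` (trajectory controller), `"lexy"` (PID /
#'   gain-scheduled PID on compartment intensity) or `"multi_lexy"`
#'   (per-nucleus pulse-width-modulated illumination of several cells).
#' @param duration run length, frames (>= 1).
#' @param seed integer seed; a run is reproducible bit-exactly from config +
#'   seed.
#' @param frame_interval seconds between frames; `NULL` picks the mode
#'   default (60 migration / 15 lexy).
#' @param n_cells number of cells when `population` is `NULL`.
#' @param population a [population_spec]; `NULL` builds one of `n_cells`
#'   cells with the default heterogeneity for the mode.
#' @param paths migration only: a [guide_path] or list of them (one per
#'   cell). `NULL` gives each cell a 40 um-radius circle, tiled across the
#'   field for multiple cells.
#' @param controller named list merged over the mode defaults. Migration:
#'   `irradiance` (uW/cm^2, scalar or per-frame vector), `lookahead` (um),
#'   `front_fraction`, `max_step`, `max_gap`. Transport: `mode`
#'   (`"cytosol"`/`"nucleus"`), `gains` ([pid_gains]) or `schedule`
#'   ([gain_schedule]) (exactly one), `setpoints` (data frame `frame`,
#'   `setpoint`), `i_max`, `contrast_threshold`, `filter_mode`,
#'   `filter_window`, `schedule_smooth`, `center_fraction` (PWM region
#'   radius as a fraction of the nucleus radius).
#' @param optics an [optics_config]; `NULL` sizes the field of view
#'   automatically from the paths or the cell layout.
#' @param seg a [seg_params]; `NULL` picks the mode default (Otsu threshold
#'   for migration; background-statistics threshold for transport frames,
#'   whose dim cytosol an Otsu split would merge into background).
#' @param avoidance an [avoidance_config] to activate multi-cell collision
#'   avoidance (migration; `NULL` = off).
#' @param record_frames keep rendered frames in the record (memory-hungry).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("migration", "lexy", "multi_lexy"),
                              duration, seed = 1, frame_interval = NULL,
                              n_cells = 1, population = NULL, paths = NULL,
                              controller = list(), optics = NULL, seg = NULL,
                              avoidance = NULL, record_frames = FALSE) {
  mode <- match.arg(mode)
  stopifnot(duration >= 1, n_cells >= 1)
  if (is.null(frame_interval)) {
    frame_interval <- if (mode == "migration") 60 else 15
  }
  stopifnot(frame_interval > 0)
  if (is.null(population)) {
    kind <- if (mode == "migration") "migration" else "lexy"
    population <- population_spec(n_cells, kind)
  }
  stopifnot(inherits(population, "population_spec"))
  n <- population$n_cells
  defaults <- if (mode == "migration") {
    list(irradiance = 0.23, lookahead = 10, front_fraction = 0.5,
         max_step = 10, max_gap = 3)
  } else {
    list(mode = "cytosol", gains = NULL, schedule = NULL,
         setpoints = data.frame(frame = 1, setpoint = 0.5),
         i_max = 10.4, contrast_threshold = 0.05, filter_mode = "hold",
         filter_window = 5, schedule_smooth = 3, center_fraction = 0.5,
         max_step = 10, max_gap = 3)
  }
  stopifnot(is.list(controller))
  for (nm in names(controller)) defaults[[nm]] <- controller[[nm]]
  controller <- defaults
  if (mode == "migration") {
    if (is.null(paths)) paths <- default_migration_paths(n)
    if (inherits(paths, "guide_path")) paths <- list(paths)
    if (length(paths) != n) stop("need one guide path per cell")
    for (p in paths) stopifnot(inherits(p, "guide_path"))
  } else {
    has_g <- inherits(controller$gains, "pid_gains")
    has_s <- inherits(controller$schedule, "gain_schedule")
    if (has_g == has_s) {
      stop("transport controller needs exactly one of 'gains' or 'schedule'")
    }
    sp <- controller$setpoints
    stopifnot(is.data.frame(sp), all(c("frame", "setpoint") %in% names(sp)),
              sp$frame[1] == 1, all(diff(sp$frame) > 0),
              all(sp$setpoint >= 0), all(sp$setpoint <= 1))
  }
  if (is.null(seg)) {
    seg <- if (mode == "migration") seg_params()
           else seg_params(threshold = "background", threshold_fraction = 0.01)
  }
  if (!is.null(avoidance)) stopifnot(inherits(avoidance, "avoidance_config"))
  structure(
    list(mode = mode, duration = as.integer(duration), seed = as.integer(seed),
         frame_interval = frame_interval, population = population,
         paths = paths, controller = controller, optics = optics, seg = seg,
         avoidance = avoidance, record_frames = isTRUE(record_frames)),
    class = "experiment_config"
  )
}

# tiled 40 um circles, one per cell, in 160 um blocks; the grid has no
# empty tiles, so the imaged area stays proportional to the cell count
default_migration_paths <- function(n, radius = 40, block = 160) {
  nrow_ <- max(1, floor(sqrt(n)))
  ncol_ <- ceiling(n / nrow_)
  lapply(seq_len(n) - 1, function(i) {
    cx <- (i %% ncol_) * block + block / 2
    cy <- (i %/% ncol_) * block + block / 2
    circle_path(radius, c(cx, cy))
  })
}

migration_fov <- function(paths, margin = 40, pixel_size = 1) {
  v <- do.call(rbind, lapply(paths, `[[`, "vertices"))
  c(ceiling((max(v[, 2]) + margin) / pixel_size),
    ceiling((max(v[, 1]) + margin) / pixel_size))
}

#' Run a closed-loop experiment
#'
#' Executes the full feedback loop for `duration` frames: acquire a frame
#' from the (simulated) microscope, segment and track, measure, compute the
#' control command, illuminate, and advance the plants by one frame
#' interval. The record is reproducible bit-exactly from config + seed
#' (loop compute times, which are logged separately, naturally are not).
#'
#' @param config an [experiment_config].
#' @return An object of class `loop_record`: a list with `mode`, `config`,
#'   `rows` (one data-frame row per frame and cell: measurements, errors,
#'   commands), `commands` (per-region command log), `events`, `timing`
#'   (per-frame wall-clock loop time), `population` (drawn plant
#'   parameters), plus `paths` (migration) or `calibration` (transport),
#'   and `frames` if requested.
#' @export
run_closed_loop <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  plants <- sample_population(config$population)
  if (config$mode == "migration") {
    run_migration_loop(config, plants)
  } else {
    run_lexy_loop(config, plants, pwm = config$mode == "multi_lexy")
  }
}

#' @export
print.loop_record <- function(x, ...) {
  cat(sprintf("loop_record: %s run, %d frames x %d cells, %d events\n",
              x$mode, max(x$rows$frame), length(unique(x$rows$cell)),
              nrow(x$events)))
  invisible(x)
}

new_event_log <- function() {
  data.frame(frame = integer(), cell = integer(), event = character())
}

add_event <- function(events, frame, cell, what) {
  rbind(events, data.frame(frame = frame, cell = cell, event = what))
}

run_migration_loop <- function(config, plants) {
  n <- length(plants)
  ctrl <- config$controller
  paths <- config$paths
  dt <- config$frame_interval
  optics <- config$optics
  if (is.null(optics)) {
    optics <- optics_config(fov_px = migration_fov(paths))
  }
  px <- optics$pixel_size
  # start each cell on its path, polarised along the local tangent
  for (i in seq_len(n)) {
    v <- paths[[i]]$vertices
    tangent <- unit_vec(v[2, ] - v[1, ])
    plants[[i]]$position <- v[1, ]
    plants[[i]]$angle <- atan2(tangent[2], tangent[1])
  }
  irr_of <- function(fi) {
    irr <- ctrl$irradiance
    if (length(irr) == 1) irr else irr[min(fi, length(irr))]
  }
  scope <- sim_microscope(plants, optics, "migration")
  tracker <- track_state(max_step = ctrl$max_step, max_gap = ctrl$max_gap)
  binding <- rep(NA_integer_, n) # cell index -> track id
  rows <- vector("list", config$duration)
  cmd_rows <- vector("list", config$duration)
  frames <- if (config$record_frames) vector("list", config$duration) else NULL
  events <- new_event_log()
  timing <- numeric(config$duration)
  avoid_latch <- matrix(integer(), 0, 2)
  avoid_dir <- matrix(NA_real_, n, 2)
  radii <- vapply(scope$get_plants(), `[[`, numeric(1), "shape_radius")
  for (fi in seq_len(config$duration)) {
    t0 <- proc.time()[[3]]
    ts <- (fi - 1) * dt
    fr <- scope$acquire(ts)
    if (config$record_frames) frames[[fi]] <- fr
    seg <- segment_frame(fr, "cell", config$seg)
    tracker <- track_update(tracker, seg, fi)
    asgn <- attr(tracker, "assignment")
    cur <- scope$get_plants()
    truepos <- t(vapply(cur, `[[`, numeric(2), "position"))
    # bind newly seen tracks to cells by proximity to the true positions
    for (ci in which(is.na(binding))) {
      if (!length(asgn)) break
      d2 <- (seg$centroids[, 1] - truepos[ci, 1])^2 +
            (seg$centroids[, 2] - truepos[ci, 2])^2
      cand <- which.min(d2)
      if (length(cand) && d2[cand] < (2 * radii[ci])^2 &&
          !(asgn[cand] %in% binding)) {
        binding[ci] <- asgn[cand]
      }
    }
    percell <- vector("list", n)
    for (ci in seq_len(n)) {
      label <- if (!is.na(binding[ci])) which(asgn == binding[ci]) else integer()
      if (length(label) == 1) {
        centroid <- seg$centroids[label, ]
        mask <- seg$label_mask == label
        cmd <- migration_controller_step(
          centroid, mask, paths[[ci]], irradiance = irr_of(fi),
          lookahead = ctrl$lookahead, front_fraction = ctrl$front_fraction,
          pixel_size = px, frame_interval = dt
        )
        percell[[ci]] <- list(cmd = cmd, centroid = centroid, mask = mask,
                              lost = FALSE)
      } else {
        percell[[ci]] <- list(
          cmd = illumination_command(frame_interval = dt),
          centroid = c(NA_real_, NA_real_), mask = NULL, lost = TRUE
        )
        events <- add_event(events, fi, ci, "track_lost")
      }
    }
    # multi-cell coordination: lookahead collision avoidance, with a
    # latched release distance so the pullback does not chatter
    yielded <- integer()
    if (n >= 2 && !is.null(config$avoidance)) {
      tracked <- which(vapply(percell, function(p) !p$lost, logical(1)))
      if (length(tracked) >= 2) {
        cent <- t(vapply(percell[tracked], `[[`, numeric(2), "centroid"))
        tr <- tracker$tracks
        vel <- t(vapply(binding[tracked], function(id) {
          r <- which(tr$id == id)
          c(tr$vx[r], tr$vy[r])
        }, numeric(2)))
        pairs <- detect_collision(cent, vel, config$avoidance)
        release <- config$avoidance$release_factor *
          config$avoidance$collision_distance
        if (nrow(avoid_latch)) {
          keep <- apply(avoid_latch, 1, function(pr) {
            ki <- match(pr[1], tracked)
            kj <- match(pr[2], tracked)
            !is.na(ki) && !is.na(kj) &&
              sqrt(sum((cent[ki, ] - cent[kj, ])^2)) < release
          })
          held <- avoid_latch[keep, , drop = FALSE]
          held_k <- cbind(match(held[, 1], tracked), match(held[, 2], tracked))
          pairs <- unique(rbind(pairs, held_k))
        }
        avoid_latch <- cbind(tracked[pairs[, 1]], tracked[pairs[, 2]])
        if (nrow(pairs)) {
          cmds <- lapply(percell[tracked], `[[`, "cmd")
          masks <- lapply(percell[tracked], `[[`, "mask")
          cmds <- apply_avoidance(cmds, pairs, masks, cent, vel,
                                  remaining_arc = rep(ctrl$lookahead, length(tracked)),
                                  directions = avoid_dir[tracked, , drop = FALSE],
                                  config = config$avoidance,
                                  front_fraction = ctrl$front_fraction,
                                  pixel_size = px)
          yielded <- tracked[attr(cmds, "yielded")]
          for (k in seq_along(tracked)) percell[[tracked[k]]]$cmd <- cmds[[k]]
          for (ci in yielded) events <- add_event(events, fi, ci, "avoidance_pullback")
          # latch each yielder's pre-engagement movement direction
          for (ci in yielded) {
            if (!all(is.finite(avoid_dir[ci, ]))) {
              k <- match(ci, tracked)
              if (sum(vel[k, ]^2) > 1e-12) avoid_dir[ci, ] <- vel[k, ]
            }
          }
          avoid_dir[setdiff(seq_len(n), yielded), ] <- NA_real_
        }
      }
      if (!length(yielded)) avoid_dir[] <- NA_real_
    }
    # merge per-cell commands into one frame command and illuminate
    owner <- which(vapply(percell, function(p) length(p$cmd$masks) > 0, logical(1)))
    combined <- illumination_command(
      masks = lapply(percell[owner], function(p) p$cmd$masks[[1]]),
      irradiances = vapply(percell[owner], function(p) p$cmd$irradiances[1], numeric(1)),
      frame_interval = dt, i_max = optics$i_max
    )
    scope$illuminate(combined)
    eff <- apply_illumination(combined, truepos, px, radii = radii)
    aoi_centroids <- lapply(percell, function(p) {
      if (length(p$cmd$masks) && any(p$cmd$masks[[1]])) {
        mask_centroid(p$cmd$masks[[1]], px)
      } else NULL
    })
    for (ci in seq_len(n)) {
      cur[[ci]] <- migrate_step(cur[[ci]], eff[ci], aoi_centroids[[ci]], dt)
    }
    scope$set_plants(cur)
    rows[[fi]] <- do.call(rbind, lapply(seq_len(n), function(ci) {
      p <- percell[[ci]]
      pr <- attr(p$cmd, "projection")
      tg <- attr(p$cmd, "target")
      data.frame(
        frame = fi, time_s = ts, cell = ci,
        track_id = binding[ci],
        x = p$centroid[1], y = p$centroid[2],
        true_x = truepos[ci, 1], true_y = truepos[ci, 2],
        deviation = if (is.null(pr)) NA_real_ else pr$deviation,
        arc = if (is.null(pr)) NA_real_ else pr$arc_position,
        target_x = if (is.null(tg)) NA_real_ else tg[1],
        target_y = if (is.null(tg)) NA_real_ else tg[2],
        irradiance_cmd = if (length(p$cmd$irradiances)) p$cmd$irradiances[1] else 0,
        irradiance_eff = eff[ci],
        yielded = ci %in% yielded, lost = p$lost
      )
    }))
    cmd_rows[[fi]] <- if (length(owner)) {
      data.frame(
        frame = fi, region_id = seq_along(owner), cell = owner,
        irradiance_uW_cm2 = combined$irradiances,
        duty = combined$duty_cycles,
        mask_px = vapply(combined$masks, sum, numeric(1))
      )
    } else NULL
    timing[fi] <- proc.time()[[3]] - t0
  }
  structure(
    list(mode = "migration", config = config,
         rows = do.call(rbind, rows),
         commands = do.call(rbind, cmd_rows),
         events = events,
         timing = data.frame(frame = seq_len(config$duration),
                             loop_time_s = timing, n_cells = n),
         population = attr(plants, "parameters"),
         paths = paths, frames = frames),
    class = "loop_record"
  )
}

# grid layout for transport cells: one `block` um square per cell
lexy_layout <- function(plants, block = 96) {
  n <- length(plants)
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  for (i in seq_len(n)) {
    col <- (i - 1) %% ncol_
    row <- (i - 1) %/% ncol_
    plants[[i]]$center <- c(col * block + block / 2, row * block + block / 2)
  }
  attr(plants, "fov_um") <- c(nrow_ * block, ncol_ * block)
  plants
}

plant_at_ss <- function(plant, irradiance) {
  ss <- lexy_steady_state(plant, irradiance)
  plant$A <- ss$A
  plant$N <- ss$N
  plant$C <- ss$C
  plant
}

run_lexy_loop <- function(config, plants, pwm = FALSE) {
  n <- length(plants)
  ctrl <- config$controller
  dt <- config$frame_interval
  cmode <- match.arg(ctrl$mode, c("cytosol", "nucleus"))
  pars <- attr(plants, "parameters")
  plants <- lexy_layout(plants)
  fov_um <- attr(plants, "fov_um")
  optics <- config$optics
  if (is.null(optics)) {
    optics <- optics_config(fov_px = fov_um, psf_sigma = 1, i_max = ctrl$i_max)
  }
  px <- optics$pixel_size
  centers <- t(vapply(plants, `[[`, numeric(2), "center"))
  # pre-run calibration: render the dark and saturating steady states
  dark_fr <- render_lexy_frame(lapply(plants, plant_at_ss, irradiance = 0),
                               optics)
  sat_fr <- render_lexy_frame(lapply(plants, plant_at_ss, irradiance = ctrl$i_max),
                              optics)
  cal <- calibrate_range(dark_fr, sat_fr, config$seg)
  cellcal <- vapply(seq_len(n), function(ci) {
    which.min((cal$x - centers[ci, 1])^2 + (cal$y - centers[ci, 2])^2)
  }, integer(1))
  scheduled <- inherits(ctrl$schedule, "gain_schedule")
  states <- replicate(n, pid_state(i_max = ctrl$i_max), simplify = FALSE)
  filters <- replicate(n, temporal_filter(ctrl$filter_mode, ctrl$filter_window),
                       simplify = FALSE)
  sched_bufs <- replicate(n, numeric(), simplify = FALSE)
  scope <- sim_microscope(plants, optics, "lexy")
  tracker <- track_state(max_step = ctrl$max_step, max_gap = ctrl$max_gap)
  binding <- rep(NA_integer_, n)
  rows <- vector("list", config$duration)
  cmd_rows <- vector("list", config$duration)
  frames <- if (config$record_frames) vector("list", config$duration) else NULL
  events <- new_event_log()
  timing <- numeric(config$duration)
  for (fi in seq_len(config$duration)) {
    t0 <- proc.time()[[3]]
    ts <- (fi - 1) * dt
    fr <- scope$acquire(ts)
    if (config$record_frames) frames[[fi]] <- fr
    seg <- segment_frame(fr, "nucleus_cytosol", config$seg)
    tracker <- track_update(tracker, seg, fi)
    asgn <- attr(tracker, "assignment")
    for (ci in which(is.na(binding))) {
      if (!length(asgn)) break
      d2 <- (seg$centroids[, 1] - centers[ci, 1])^2 +
            (seg$centroids[, 2] - centers[ci, 2])^2
      cand <- which.min(d2)
      if (length(cand) && d2[cand] < (min(plants[[ci]]$cell_axes))^2 &&
          !(asgn[cand] %in% binding)) {
        binding[ci] <- asgn[cand]
      }
    }
    sp <- ctrl$setpoints$setpoint[max(which(ctrl$setpoints$frame <= fi))]
    masks <- list()
    irrs <- numeric()
    duties <- numeric()
    owner <- integer()
    framerows <- vector("list", n)
    cur <- scope$get_plants()
    for (ci in seq_len(n)) {
      label <- if (!is.na(binding[ci])) which(asgn == binding[ci]) else integer()
      meas <- if (length(label) == 1) {
        measure_compartments(seg, label, cal[cellcal[ci], ],
                             ctrl$contrast_threshold)
      } else {
        measure_compartments_invalid()
      }
      value <- if (cmode == "cytosol") meas$normalised_cytosol else meas$normalised_nucleus
      fu <- filter_update(filters[[ci]], value,
                          meas$valid && meas$contrast_ok)
      filters[[ci]] <- fu$filter
      if (!meas$valid || !meas$contrast_ok) {
        events <- add_event(events, fi, ci,
                            if (!meas$valid) "measurement_invalid" else "low_contrast")
      }
      if (is.na(fu$value)) {
        u <- 0
        err <- NA_real_
        gains <- pid_gains(0, 0, 1e-12) # placeholder for logging only
        deferred <- TRUE
      } else {
        sched_bufs[[ci]] <- tail(c(sched_bufs[[ci]], fu$value),
                                 ctrl$schedule_smooth)
        gains <- if (scheduled) {
          schedule_gains(mean(sched_bufs[[ci]]), ctrl$schedule)
        } else ctrl$gains
        err <- control_error(cmode, sp, fu$value)
        res <- pid_step(states[[ci]], err, gains, dt, measurement = fu$value)
        states[[ci]] <- res$state
        u <- res$u
        deferred <- FALSE
      }
      if (length(label) == 1 && u > 0) {
        if (pwm) {
          # fixed-irradiance PWM on a small central region of the cell
          region <- matrix(FALSE, nrow(seg$label_mask), ncol(seg$label_mask))
          region <- add_disc_mask(region, seg$centroids[label, ],
                                  ctrl$center_fraction * cur[[ci]]$nucleus_radius,
                                  px)
          masks <- c(masks, list(region & TRUE))
          irrs <- c(irrs, ctrl$i_max)
          duties <- c(duties, clamp(u / ctrl$i_max, 0, 1))
        } else {
          masks <- c(masks, list(seg$label_mask == label))
          irrs <- c(irrs, u)
          duties <- c(duties, 1)
        }
        owner <- c(owner, ci)
      }
      framerows[[ci]] <- data.frame(
        frame = fi, time_s = ts, cell = ci, track_id = binding[ci],
        setpoint = sp,
        nucleus_mean = meas$nucleus_mean, cytosol_mean = meas$cytosol_mean,
        norm_nucleus = meas$normalised_nucleus,
        norm_cytosol = meas$normalised_cytosol,
        measurement = fu$value, contrast_ok = meas$contrast_ok,
        valid = meas$valid, deferred = deferred,
        error = err, kp = gains$kp, ki = gains$ki, kd = gains$kd,
        u = u, true_N = cur[[ci]]$N, true_C = cur[[ci]]$C,
        true_A = cur[[ci]]$A
      )
    }
    combined <- illumination_command(masks, irrs, duties, frame_interval = dt,
                                     i_max = optics$i_max)
    scope$illuminate(combined)
    eff <- apply_illumination(combined, centers, px)
    for (ci in seq_len(n)) {
      cur[[ci]] <- lexy_step(cur[[ci]], eff[ci], dt)
      framerows[[ci]]$irradiance_eff <- eff[ci]
    }
    scope$set_plants(cur)
    rows[[fi]] <- do.call(rbind, framerows)
    cmd_rows[[fi]] <- if (length(owner)) {
      data.frame(frame = fi, region_id = seq_along(owner), cell = owner,
                 irradiance_uW_cm2 = irrs, duty = duties,
                 mask_px = vapply(masks, sum, numeric(1)))
    } else NULL
    timing[fi] <- proc.time()[[3]] - t0
  }
  structure(
    list(mode = if (pwm) "multi_lexy" else "lexy", config = config,
         rows = do.call(rbind, rows),
         commands = do.call(rbind, cmd_rows),
         events = events,
         timing = data.frame(frame = seq_len(config$duration),
                             loop_time_s = timing, n_cells = n),
         population = pars, calibration = cal, frames = frames),
    class = "loop_record"
  )
}

measure_compartments_invalid <- function() {
  structure(
    list(nucleus_mean = NA_real_, cytosol_mean = NA_real_,
         normalised_nucleus = NA_real_, normalised_cytosol = NA_real_,
         ratio = NA_real_, contrast_ok = FALSE, valid = FALSE),
    class = "compartment_measurement"
  )
}

# disc mask helper for PWM centre regions
add_disc_mask <- function(mask, center_um, radius_um, pixel_size) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  ci <- center_um[2] / pixel_size + 0.5
  cj <- center_um[1] / pixel_size + 0.5
  r <- max(radius_um / pixel_size, 1)
  ii <- clamp(floor(ci - r), 1, nr):clamp(ceiling(ci + r), 1, nr)
  jj <- clamp(floor(cj - r), 1, nc):clamp(ceiling(cj + r), 1, nc)
  d <- sqrt(outer((ii - ci)^2, (jj - cj)^2, "+"))
  mask[ii, jj] <- mask[ii, jj] | (d <= r)
  mask
}

#' Summarise a closed-loop run
#'
#' Migration runs: per-cell mean and maximum path deviation over the run and
#' the per-loop breakdown from [loop_deviation_summary()]. Transport runs:
#' per cell and setpoint epoch, the steady-state error from
#' [steady_state_error()] (in normalised units and as percent of the
#' calibrated dynamic range).
#'
#' @param record a [run_closed_loop()] record.
#' @param smooth_window,tol settling-detector parameters passed to
#'   [steady_state_error()] (transport runs).
#' @return For migration: list with `cells` (per-cell deviation stats) and
#'   `loops`. For transport: a data frame `cell`, `epoch`, `setpoint`,
#'   `settled`, `settle_index`, `mean_abs_error`, `pct_error`.
#' @export
run_summary <- function(record, smooth_window = 5, tol = 1e-3) {
  stopifnot(inherits(record, "loop_record"))
  if (record$mode == "migration") {
    cells <- do.call(rbind, lapply(split(record$rows, record$rows$cell), function(d) {
      ok <- is.finite(d$deviation)
      data.frame(cell = d$cell[1], n_frames = nrow(d), n_tracked = sum(ok),
                 mean_deviation = mean(d$deviation[ok]),
                 max_deviation = if (any(ok)) max(d$deviation[ok]) else NA_real_)
    }))
    rownames(cells) <- NULL
    loops <- do.call(rbind, lapply(unique(record$rows$cell), function(ci) {
      d <- record$rows[record$rows$cell == ci & is.finite(record$rows$x), ]
      p <- record$paths[[ci]]
      if (!p$closed || nrow(d) < 2) return(NULL)
      s <- loop_deviation_summary(cbind(d$x, d$y), p, record$config$frame_interval)
      if (nrow(s)) s$cell <- ci
      s
    }))
    return(list(cells = cells, loops = loops))
  }
  sp <- record$config$controller$setpoints
  dur <- max(record$rows$frame)
  bounds <- c(sp$frame, dur + 1)
  out <- list()
  for (ci in unique(record$rows$cell)) {
    d <- record$rows[record$rows$cell == ci, ]
    for (e in seq_len(nrow(sp))) {
      seg_rows <- d[d$frame >= bounds[e] & d$frame < bounds[e + 1], ]
      seg_rows <- seg_rows[is.finite(seg_rows$measurement), ]
      if (nrow(seg_rows) <= smooth_window) next
      sse <- steady_state_error(seg_rows$measurement, sp$setpoint[e],
                                interval = record$config$frame_interval,
                                smooth_window = smooth_window, tol = tol,
                                range = 1)
      out[[length(out) + 1]] <- data.frame(
        cell = ci, epoch = e, setpoint = sp$setpoint[e],
        settled = sse$settled, settle_index = sse$settle_index,
        mean_abs_error = sse$mean_abs_error,
        pct_error = 100 * sse$mean_abs_error
      )
    }
  }
  do.call(rbind, out)
}

#' Persist a run record to disk
#'
#' Writes the standard run artefacts: `config.yaml` (full config snapshot),
#' `tracks.csv` (per-frame per-cell rows), `commands.csv` (per-region
#' command log), `events.log`, `summary.csv` and, when frames were
#' recorded, `frames.tiff`.
#'
#' @param record a [run_closed_loop()] record.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_loop_record <- function(record, dir) {
  stopifnot(inherits(record, "loop_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- record$config
  cfg_ser <- list(
    mode = cfg$mode, duration = cfg$duration, seed = cfg$seed,
    frame_interval = cfg$frame_interval,
    population = unclass(cfg$population),
    paths = if (!is.null(cfg$paths)) lapply(cfg$paths, path_to_config),
    controller = lapply(cfg$controller, function(x) {
      if (inherits(x, "gain_schedule")) as.data.frame(x)
      else if (inherits(x, "pid_gains")) unclass(x)
      else x
    }),
    optics = if (!is.null(cfg$optics)) unclass(cfg$optics),
    seg = unclass(cfg$seg),
    avoidance = if (!is.null(cfg$avoidance)) unclass(cfg$avoidance)
  )
  yaml::write_yaml(cfg_ser, file.path(dir, "config.yaml"))
  write.csv(record$rows, file.path(dir, "tracks.csv"), row.names = FALSE)
  if (!is.null(record$population)) {
    write.csv(record$population, file.path(dir, "population.csv"),
              row.names = FALSE)
  }
  if (!is.null(record$commands)) {
    write.csv(record$commands, file.path(dir, "commands.csv"), row.names = FALSE)
  }
  writeLines(
    sprintf("frame=%d cell=%d %s", record$events$frame, record$events$cell,
            record$events$event),
    file.path(dir, "events.log")
  )
  s <- run_summary(record)
  stab <- if (is.data.frame(s)) s else s$cells
  write.csv(stab, file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(record$frames)) {
    write_frames_tiff(record$frames, file.path(dir, "frames.tiff"))
  }
  invisible(dir)
}

#' Benchmark per-frame loop time against the number of controlled cells
#'
#' Runs short migration loops with 1, 2, 4, ... cells, each on its own
#' circle in a field of view whose area grows with the cell count (constant
#' cell density, as adding cells to a real experiment enlarges the imaged
#' field), and reports the median per-frame loop time. The log-log slope
#' estimates the compute-time scaling exponent of the full feedback loop.
#'
#' @param n_grid cell counts to benchmark.
#' @param duration frames per run.
#' @param reps repetitions per cell count; the smallest per-run median is
#'   kept, which rejects transient load on the host.
#' @param seed seed for every run.
#' @return Data frame `n_cells`, `median_loop_s`, with the fitted log-log
#'   `slope` as an attribute.
#' @export
benchmark_loop_scaling <- function(n_grid = c(1, 2, 4, 8), duration = 25,
                                   reps = 2, seed = 1) {
  res <- lapply(n_grid, function(n) {
    cfg <- experiment_config("migration", duration = duration, seed = seed,
                             n_cells = n)
    min(vapply(seq_len(reps), function(r) {
      rec <- run_closed_loop(cfg)
      # drop the first frame: warm-up (allocation, first FFT plan)
      median(rec$timing$loop_time_s[-1])
    }, numeric(1)))
  })
  out <- data.frame(n_cells = n_grid, median_loop_s = unlist(res))
  fit <- lm(log(median_loop_s) ~ log(n_cells), data = out)
  attr(out, "slope") <- unname(coef(fit)[2])
  out
}
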
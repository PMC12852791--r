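#' Virtual light-steerable migrating cell
#'
#' State of a simulated migrating cell whose protrusion machinery is
#' recruited by patterned blue light: when part of the cell is illuminated,
#' polarity re-orients toward the illuminated region and speed increases with
#' irradiance along a saturating dose-response
#' `speed = speed_base + v_max * I / (I + K_I)`. Without light the cell
#' performs a persistent random walk at its baseline speed.
#'
#' Speeds are in um/min and timescales in minutes; positions in um.
#'
#' @param position `c(x, y)` centroid (um).
#' @param angle polarity angle (rad); the polarity vector is
#'   `c(cos(angle), sin(angle))`.
#' @param speed_base baseline (unstimulated) speed, um/min.
#' @param v_max maximal light-induced speed increment, um/min.
#' @param K_I half-saturation irradiance, uW/cm^2.
#' @param expression fluorescence expression level (total integrated counts
#'   rendered for this cell).
#' @param shape_radius cell body radius for rendering/segmentation, um.
#' @param persistence_time persistence time of the undirected random walk,
#'   minutes. Sets the rotational diffusion of the polarity angle; ~30 min
#'   is typical of persistent mesenchymal migration.
#' @param align_time time constant of polarity re-orientation toward an
#'   illuminated region, minutes. Optogenetic protrusion induction is faster
#'   than the intrinsic polarity persistence, so this is a separate, shorter
#'   timescale.
#' @return An object of class `migrating_cell`.
#' @export
migrating_cell <- function(position = c(0, 0), angle = 0,
                           speed_base = 0.5, v_max = 1.0, K_I = 0.1,
                           expression = 1.5e5, shape_radius = 12,
                           persistence_time = 30, align_time = 1.0) {
  stopifnot_point(position)
  stopifnot(
    is.finite(angle),
    speed_base >= 0, v_max > 0, K_I > 0, expression > 0,
    shape_radius > 0, persistence_time > 0, align_time > 0
  )
  structure(
    list(position = position, angle = angle, speed_base = speed_base,
         v_max = v_max, K_I = K_I, expression = expression,
         shape_radius = shape_radius, persistence_time = persistence_time,
         align_time = align_time),
    class = "migrating_cell"
  )
}

#' @export
print.migrating_cell <- function(x, ...) {
  cat(sprintf("migrating_cell at (%.1f, %.1f) um, base speed %.2f um/min\n",
              x$position[1], x$position[2], x$speed_base))
  invisible(x)
}

#' Polarity unit vector of a migrating cell
#' @param state a [migrating_cell].
#' @return unit `c(x, y)` vector.
#' @export
polarity <- function(state) c(cos(state$angle), sin(state$angle))

#' Advance a migrating cell by one time step
#'
#' If an illuminated region is active (`aoi_centroid` given and
#' `irradiance > 0`), the polarity angle relaxes toward the direction from
#' the centroid to the AOI centroid with time constant `align_time`, and the
#' speed gains the saturating light-induced increment. Otherwise the cell
#' continues its persistent random walk at baseline speed. Rotational
#' diffusion noise (variance `2 * dt / persistence_time`) is added when
#' `noise = TRUE`; draws come from the current RNG stream, so runs are
#' reproducible under `set.seed()`.
#'
#' @param state a [migrating_cell].
#' @param irradiance effective irradiance seen by the cell, uW/cm^2.
#' @param aoi_centroid centroid of the illuminated region (um), or `NULL`
#'   when no region is illuminated.
#' @param dt time step in seconds.
#' @param noise logical; add rotational diffusion noise.
#' @return The updated [migrating_cell].
#' @export
migrate_step <- function(state, irradiance = 0, aoi_centroid = NULL, dt = 60,
                         noise = TRUE) {
  stopifnot(inherits(state, "migrating_cell"), dt > 0, irradiance >= 0)
  dt_min <- dt / 60
  lit <- !is.null(aoi_centroid) && irradiance > 0
  speed <- state$speed_base
  if (lit) {
    stopifnot_point(aoi_centroid, "aoi_centroid")
    dir <- aoi_centroid - state$position
    if (vec_norm(dir) > .Machine$double.eps) {
      target <- atan2(dir[2], dir[1])
      gain <- 1 - exp(-dt_min / state$align_time)
      state$angle <- state$angle + gain * wrap_angle(target - state$angle)
    }
    speed <- speed + state$v_max * irradiance / (irradiance + state$K_I)
  }
  if (noise) {
    state$angle <- state$angle + rnorm(1, 0, sqrt(2 * dt_min / state$persistence_time))
  }
  state$angle <- wrap_angle(state$angle)
  state$position <- state$position + speed * dt_min * polarity(state)
  state
}

#' Virtual light-gated nucleocytoplasmic transport plant
#'
#' A three-state kinetic model of a nuclear protein carrying a light-caged
#' nuclear export sequence. Blue light converts exporters to the active state
#' `A`; active exporters move cargo from nucleus to cytosol; a constitutive
#' import pathway returns it:
#' \deqn{dA/dt = k_{on} I (1 - A) - k_{off} (A - A_{dark})}
#' \deqn{dN/dt = k_{imp} C / \rho - k_{exp}(E) A N}
#' \deqn{dC/dt = \rho k_{exp}(E) A N - k_{imp} C}
#' with expression-dependent export `k_exp(E) = k_exp0 / (1 + E / K_E)`
#' (higher-expressing cells export more slowly) and expression-independent
#' import. With production and bleaching off, the total amount
#' `rho * N + C` is conserved. `A_dark` is the dark-state leak of the cage:
#' a small fraction of exporters stays active without light, so the cytosol
#' retains a visible baseline signal.
#'
#' Concentrations are normalised so that `rho * N + C = 1` at default
#' initial conditions; rendered pixel intensities scale as
#' `expression * concentration`.
#'
#' @param N,C initial nuclear and cytosolic concentrations. Defaults start
#'   from the dark steady state of the default parameters.
#' @param A initial activated-exporter fraction in `[0, 1]`.
#' @param expression expression level E (arbitrary units; also the rendered
#'   brightness scale in counts per unit concentration).
#' @param vol_ratio nuclear-to-cytosolic volume ratio rho.
#' @param k_on_per_I activation rate per unit irradiance, 1/(s uW/cm^2).
#' @param k_off dark reversion rate, 1/s.
#' @param A_dark dark-state active fraction (leak), in `[0, 1)`.
#' @param k_exp0 maximal export rate at zero expression, 1/s.
#' @param K_E expression half-saturation of export, units of `expression`.
#' @param k_imp import rate, 1/s.
#' @param production zero-order production rate into the nucleus
#'   (concentration/s; default 0, e.g. for induction drift studies).
#' @param bleach first-order photobleaching/dilution rate, 1/s (default 0).
#' @param center cell centre for rendering, `c(x, y)` um.
#' @param cell_axes cytosol ellipse semi-axes `c(a, b)`, um.
#' @param nucleus_radius nucleus disc radius, um.
#' @return An object of class `lexy_plant`.
#' @export
lexy_plant <- function(N = NULL, C = NULL, A = NULL,
                       expression = 800, vol_ratio = 0.5,
                       k_on_per_I = 0.05, k_off = 0.012, A_dark = 0.2,
                       k_exp0 = 0.010, K_E = 500, k_imp = 0.008,
                       production = 0, bleach = 0,
                       center = c(48, 48), cell_axes = c(20, 16),
                       nucleus_radius = 7) {
  stopifnot(
    vol_ratio > 0, k_on_per_I >= 0, k_off > 0, A_dark >= 0, A_dark < 1,
    k_exp0 > 0, K_E > 0, k_imp > 0, expression > 0,
    production >= 0, bleach >= 0,
    all(cell_axes > 0), nucleus_radius > 0, nucleus_radius < min(cell_axes)
  )
  stopifnot_point(center, "center")
  st <- structure(
    list(N = 1, C = 0, A = if (is.null(A)) A_dark else A,
         expression = expression, vol_ratio = vol_ratio,
         k_on_per_I = k_on_per_I, k_off = k_off, A_dark = A_dark,
         k_exp0 = k_exp0, K_E = K_E, k_imp = k_imp,
         production = production, bleach = bleach,
         center = center, cell_axes = cell_axes,
         nucleus_radius = nucleus_radius),
    class = "lexy_plant"
  )
  if (is.null(N) || is.null(C)) {
    # default initial condition: dark steady state at unit total amount
    st$N <- 1 / vol_ratio
    st$C <- 0
    ss <- lexy_steady_state(st, irradiance = 0)
    st$N <- ss$N
    st$C <- ss$C
    if (is.null(A)) st$A <- ss$A
  } else {
    stopifnot(N >= 0, C >= 0)
    st$N <- N
    st$C <- C
  }
  stopifnot(st$A >= 0, st$A <= 1)
  st
}

#' @export
print.lexy_plant <- function(x, ...) {
  cat(sprintf("lexy_plant: N = %.3f, C = %.3f, A = %.3f, E = %.0f\n",
              x$N, x$C, x$A, x$expression))
  invisible(x)
}

# expression-dependent export rate (1/s)
lexy_k_exp <- function(state) state$k_exp0 / (1 + state$expression / state$K_E)

#' Steady state of the transport plant at constant irradiance
#'
#' Closed-form steady state of the production-free model: the activated
#' fraction balances activation against dark reversion, and cytosolic
#' concentration follows from the export/import balance at fixed total
#' amount.
#'
#' @param state a [lexy_plant] (total amount `rho N + C` is taken from it).
#' @param irradiance constant irradiance, uW/cm^2.
#' @return list with `A`, `N`, `C` at steady state.
#' @export
lexy_steady_state <- function(state, irradiance) {
  stopifnot(inherits(state, "lexy_plant"), irradiance >= 0)
  total <- state$vol_ratio * state$N + state$C
  if (!is.finite(total) || total <= 0) total <- 1
  kon <- state$k_on_per_I * irradiance
  A <- (kon + state$k_off * state$A_dark) / (kon + state$k_off)
  ke <- lexy_k_exp(state) * A
  C <- total * ke / (ke + state$k_imp)
  list(A = A, N = (total - C) / state$vol_ratio, C = C)
}

lexy_derivs <- function(state, A, N, C) {
  ke <- lexy_k_exp(state)
  dN <- state$k_imp * C / state$vol_ratio - ke * A * N +
    state$production - state$bleach * N
  dC <- state$vol_ratio * ke * A * N - state$k_imp * C - state$bleach * C
  c(dN, dC)
}

#' Advance the transport plant by one time step
#'
#' Integrates the kinetics over `dt` at constant irradiance. The activated
#' fraction, a linear ODE at fixed irradiance, is advanced exactly; the
#' concentrations use a classical Runge-Kutta step with automatic
#' substepping so that the relative state change per substep stays below 5%.
#' Each stage derivative conserves `rho N + C` exactly (production and
#' bleaching off), so the integrator inherits conservation to rounding
#' error.
#'
#' @param state a [lexy_plant].
#' @param irradiance effective irradiance over the interval, uW/cm^2.
#' @param dt time step, seconds.
#' @return The updated [lexy_plant].
#' @export
lexy_step <- function(state, irradiance, dt) {
  stopifnot(inherits(state, "lexy_plant"), dt > 0, irradiance >= 0,
            is.finite(irradiance))
  kon <- state$k_on_per_I * irradiance
  rate_A <- kon + state$k_off
  A_ss <- (kon + state$k_off * state$A_dark) / rate_A
  # fastest relevant rate bounds the substep size (5% change per substep);
  # A is advanced exactly, so its rate only needs to be sampled well enough
  # for the concentration stages and enters at a tenth of its value
  fastest <- max(rate_A / 10, lexy_k_exp(state) + state$k_imp, state$bleach)
  n_sub <- max(1L, ceiling(dt * fastest / 0.05))
  h <- dt / n_sub
  A <- state$A
  N <- state$N
  C <- state$C
  a_decay <- exp(-rate_A * h)
  for (i in seq_len(n_sub)) {
    # A(t) is known exactly within the substep; evaluate at stage times
    A0 <- A
    Ah <- A_ss + (A0 - A_ss) * exp(-rate_A * h / 2)
    A1 <- A_ss + (A0 - A_ss) * a_decay
    k1 <- lexy_derivs(state, A0, N, C)
    k2 <- lexy_derivs(state, Ah, N + h / 2 * k1[1], C + h / 2 * k1[2])
    k3 <- lexy_derivs(state, Ah, N + h / 2 * k2[1], C + h / 2 * k2[2])
    k4 <- lexy_derivs(state, A1, N + h * k3[1], C + h * k3[2])
    N <- N + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    C <- C + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    A <- A1
  }
  if (N < 0 || C < 0) {
    if (min(N, C) > -1e-9) {
      N <- max(N, 0)
      C <- max(C, 0)
    } else {
      stop("lexy_step produced negative concentrations; reduce dt")
    }
  }
  state$A <- clamp(A, 0, 1)
  state$N <- N
  state$C <- C
  state
}

#' Drive a transport plant with explicit pulse-width modulation
#'
#' Splits one frame interval into on/off sub-intervals of a fixed PWM period
#' and integrates the plant through them, instead of using the fast-PWM
#' time-averaged irradiance. Used to check the fast-PWM limit.
#'
#' @param state a [lexy_plant].
#' @param irradiance on-state irradiance, uW/cm^2.
#' @param duty duty cycle in `[0, 1]`.
#' @param period PWM period, seconds.
#' @param frame_interval frame interval to integrate over, seconds.
#' @return The updated [lexy_plant].
#' @export
lexy_step_pwm <- function(state, irradiance, duty, period, frame_interval) {
  stopifnot(duty >= 0, duty <= 1, period > 0, frame_interval > 0)
  n <- max(1L, round(frame_interval / period))
  for (i in seq_len(n)) {
    if (duty > 0) state <- lexy_step(state, irradiance, duty * period)
    if (duty < 1) state <- lexy_step(state, 0, (1 - duty) * period)
  }
  state
}

#' Population specification for heterogeneous plants
#'
#' Describes a population of simulated cells with log-normally distributed
#' cell-to-cell variability, the dominant axes of heterogeneity being
#' baseline migration speed and expression level.
#'
#' @param n_cells number of cells (>= 1).
#' @param kind `"migration"` or `"lexy"`.
#' @param mean named list of parameter means overriding the defaults of
#'   [migrating_cell()] / [lexy_plant()].
#' @param cv named list of coefficients of variation (>= 0) for log-normally
#'   varying parameters. Defaults: 30% CV on `speed_base` and `expression`
#'   for migration cells, 30% CV on `expression` for transport cells.
#' @param seed optional integer seed; the draw is deterministic given the
#'   seed and leaves the caller's RNG stream untouched. `NULL` draws from
#'   the current stream.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, kind = c("migration", "lexy"),
                            mean = list(), cv = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_cells >= 1)
  if (is.null(cv)) {
    cv <- if (kind == "migration") list(speed_base = 0.3, expression = 0.3)
          else list(expression = 0.3)
  }
  if (length(cv) && (!is.list(cv) || is.null(names(cv)) || any(unlist(cv) < 0))) {
    stop("'cv' must be a named list of non-negative coefficients of variation")
  }
  if (length(mean) && (!is.list(mean) || is.null(names(mean)) || any(unlist(mean) <= 0))) {
    stop("'mean' must be a named list of positive parameter means")
  }
  structure(
    list(n_cells = as.integer(n_cells), kind = kind, mean = mean, cv = cv,
         seed = seed),
    class = "population_spec"
  )
}

# lognormal with given arithmetic mean and CV; CV = 0 degenerates to the mean
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a heterogeneous plant population
#'
#' Draws `n_cells` plant states from a [population_spec]. Parameters listed
#' in the spec's `cv` are drawn log-normally around their means; all others
#' are fixed at their means. With the same seed the population is
#' reproduced exactly.
#'
#' @param spec a [population_spec].
#' @return A list of [migrating_cell] or [lexy_plant] states, with the drawn
#'   parameter table attached as attribute `"parameters"` (a data frame, one
#'   row per cell).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  ctor <- if (spec$kind == "migration") migrating_cell else lexy_plant
  defaults <- formals(ctor)
  base <- list()
  for (nm in names(defaults)) {
    v <- defaults[[nm]]
    if (!is.name(v) && !is.null(v)) base[[nm]] <- eval(v)
  }
  base[names(spec$mean)] <- spec$mean
  unknown <- setdiff(names(spec$cv), names(base))
  if (length(unknown)) {
    stop("cv given for unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  n <- spec$n_cells
  draws <- with_seed(spec$seed, {
    out <- list()
    for (nm in names(spec$cv)) {
      out[[nm]] <- rlnorm_mean_cv(n, base[[nm]], spec$cv[[nm]])
    }
    out
  })
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    args <- base
    for (nm in names(draws)) args[[nm]] <- draws[[nm]][i]
    cells[[i]] <- do.call(ctor, args)
  }
  scalars <- names(base)[vapply(base, function(x) is.numeric(x) && length(x) == 1, TRUE)]
  par_tab <- data.frame(cell = seq_len(n))
  for (nm in scalars) {
    par_tab[[nm]] <- vapply(cells, function(s) s[[nm]], numeric(1))
  }
  attr(cells, "parameters") <- par_tab
  cells
}
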
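#' Mean steady-state error after settling
#'
#' Estimates the settling point of a controlled signal within one setpoint
#' epoch and averages the absolute error from there on, cleaning the error
#' of the transition time. The settling index is the first time the
#' smoothed derivative of the signal crosses zero / changes sign, or falls
#' below a tolerance (a pure exponential approach never changes sign), after
#' the setpoint change.
#'
#' @param signal numeric time series (one setpoint epoch, starting at the
#'   setpoint change).
#' @param setpoint the epoch's setpoint.
#' @param interval sample interval (any unit; only used to scale the
#'   derivative).
#' @param smooth_window centred moving-average window for the derivative
#'   (odd; default 5).
#' @param tol derivative zero-tolerance as a fraction of `range` per sample
#'   (default 1e-3).
#' @param range the signal's dynamic range used by the tolerance (default 1,
#'   i.e. normalised-intensity signals).
#' @return list with `mean_abs_error`, `settle_index` and `settled`
#'   (logical; `FALSE` when the signal never settles, in which case
#'   `mean_abs_error` is `NA`).
#' @export
steady_state_error <- function(signal, setpoint, interval = 1,
                               smooth_window = 5, tol = 1e-3, range = 1) {
  stopifnot(is.numeric(signal), smooth_window >= 1, range > 0)
  if (anyNA(signal)) stop("signal contains missing values")
  n <- length(signal)
  if (n <= smooth_window) stop("epoch shorter than the smoothing window")
  w <- smooth_window
  # centred moving average with shrinking windows at the edges
  sm <- vapply(seq_len(n), function(i) {
    h <- min((w - 1) %/% 2, i - 1, n - i)
    mean(signal[(i - h):(i + h)])
  }, numeric(1))
  d <- diff(sm) / interval
  tol_abs <- tol * range / interval
  settle <- NA_integer_
  for (i in seq_along(d)) {
    if (abs(d[i]) < tol_abs || (i > 1 && d[i - 1] * d[i] < 0)) {
      settle <- i
      break
    }
  }
  if (is.na(settle)) {
    return(list(mean_abs_error = NA_real_, settle_index = NA_integer_,
                settled = FALSE))
  }
  list(
    mean_abs_error = mean(abs(signal[settle:n] - setpoint)),
    settle_index = settle,
    settled = TRUE
  )
}

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `y = plateau + (y0 - plateau) * exp(-k * t)` with
#' `k > 0`, the standard model for light-induced export and dark import
#' kinetics of compartment intensities.
#'
#' @param t numeric vector of times (increasing).
#' @param y numeric vector of observations.
#' @return list with `k`, `y0`, `plateau`, `converged` (logical) and
#'   `sigma` (residual standard deviation). On non-convergence or an
#'   unidentifiable fit (constant series), `converged` is `FALSE` and the
#'   parameters are `NA`.
#' @export
fit_one_phase_decay <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 4, all(diff(t) > 0))
  failed <- list(k = NA_real_, y0 = NA_real_, plateau = NA_real_,
                 converged = FALSE, sigma = NA_real_)
  if (sd(y) == 0) return(failed)
  plateau0 <- mean(tail(y, max(3, length(y) %/% 5)))
  y00 <- y[1]
  amp <- y00 - plateau0
  if (abs(amp) < 1e-12 * max(abs(y), 1)) return(failed)
  # log-linear starting rate from the early phase
  z <- (y - plateau0) / amp
  ok <- which(z > 0.05)
  k0 <- if (length(ok) >= 2) {
    f <- lm(log(z[ok]) ~ t[ok])
    max(-coef(f)[2], 1e-6)
  } else {
    1 / max(t[length(t)] / 3, .Machine$double.eps)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ plateau + (y0 - plateau) * exp(-k * t),
      start = list(plateau = plateau0, y0 = y00, k = k0),
      lower = c(plateau = -Inf, y0 = -Inf, k = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  p <- coef(fit)
  if (!is.finite(p[["k"]]) || p[["k"]] <= 0) return(failed)
  list(k = unname(p[["k"]]), y0 = unname(p[["y0"]]),
       plateau = unname(p[["plateau"]]), converged = TRUE,
       sigma = sd(residuals(fit)))
}

#' Per-loop deviation and speed summary of a guided trajectory
#'
#' Splits a centroid trajectory on a closed path into individual loops (at
#' wraps of the unwrapped arc position) and reports per-loop path-deviation
#' statistics and mean projected speed.
#'
#' @param centroids n x 2 matrix of centroids (um) or a migration
#'   `loop_record` (in which case one summary row per cell and loop is
#'   produced from the measured centroids).
#' @param path the closed [guide_path].
#' @param interval imaging interval, seconds.
#' @return Data frame with columns `cell`, `loop` (0-based; only complete
#'   loops), `n_frames`, `mean_deviation`, `max_deviation`,
#'   `mean_projected_speed` (um/min). Zero completed loops yield a zero-row
#'   data frame with attribute `incomplete = TRUE`.
#' @export
loop_deviation_summary <- function(centroids, path, interval = 60) {
  stopifnot(inherits(path, "guide_path"), path$closed)
  if (inherits(centroids, "loop_record")) {
    rec <- centroids
    out <- do.call(rbind, lapply(split(rec$rows, rec$rows$cell), function(d) {
      ok <- is.finite(d$x) & is.finite(d$y)
      s <- loop_deviation_summary(cbind(d$x[ok], d$y[ok]), path,
                                  rec$config$frame_interval)
      if (nrow(s)) s$cell <- d$cell[1]
      s
    }))
    rownames(out) <- NULL
    return(out)
  }
  centroids <- as.matrix(centroids)
  sp <- projected_speed(centroids, path, interval)
  arc <- attr(sp, "arc")
  signed <- attr(sp, "signed")
  L <- path$total_length
  ds <- diff(arc)
  ds <- ds - L * round(ds / L)
  unwrapped <- cumsum(c(arc[1], ds))
  loop_id <- floor((unwrapped - unwrapped[1]) / L)
  dev <- vapply(seq_len(nrow(centroids)), function(i) {
    project_to_path(centroids[i, ], path)$deviation
  }, numeric(1))
  complete <- unique(loop_id)
  # the last loop index is complete only if the trajectory left it
  complete <- complete[complete >= 0 & complete < max(loop_id)]
  if (!length(complete)) {
    out <- data.frame(cell = integer(), loop = integer(), n_frames = integer(),
                      mean_deviation = numeric(), max_deviation = numeric(),
                      mean_projected_speed = numeric())
    attr(out, "incomplete") <- TRUE
    return(out)
  }
  out <- do.call(rbind, lapply(complete, function(l) {
    sel <- which(loop_id == l)
    selv <- sel[sel <= length(sp)]
    data.frame(
      cell = 1L, loop = l, n_frames = length(sel),
      mean_deviation = mean(dev[sel]),
      max_deviation = max(dev[sel]),
      mean_projected_speed = mean(sp[selv])
    )
  }))
  rownames(out) <- NULL
  out
}
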
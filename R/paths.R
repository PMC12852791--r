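#' Guide paths for trajectory control
#'
#' A guide path is an ordered polyline of setpoints in stage coordinates that
#' a cell centroid is steered along. Closed paths (loops) connect the last
#' vertex back to the first.
#'
#' @param vertices numeric matrix (or two-column data frame) of vertices,
#'   columns x and y, in micrometres. Consecutive duplicated vertices are
#'   dropped.
#' @param closed logical; if `TRUE` the path is a loop.
#' @return An object of class `guide_path` with fields `vertices` (n x 2
#'   matrix), `closed`, `arc` (cumulative arc length at each vertex, um) and
#'   `total_length` (um; for closed paths this includes the closing segment).
#' @examples
#' p <- guide_path(cbind(c(0, 100), c(0, 0)))
#' p$total_length
#' @export
guide_path <- function(vertices, closed = FALSE) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2 || anyNA(v)) {
    stop("'vertices' must be a numeric n x 2 matrix without missing values")
  }
  # drop consecutive duplicates (zero-length segments)
  if (nrow(v) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(v))) > 0)
    v <- v[keep, , drop = FALSE]
  }
  # a closed path given with an explicit repeated first vertex
  if (closed && nrow(v) > 2 && all(v[1, ] == v[nrow(v), ])) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 2) stop("invalid path: fewer than 2 distinct vertices")
  seg <- diff(v)
  seglen <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  if (closed) {
    closing <- sqrt(sum((v[1, ] - v[nrow(v), ])^2))
    if (closing <= 0) stop("invalid closed path: closing segment has zero length")
    total <- total + closing
  }
  structure(
    list(vertices = unname(v), closed = closed, arc = arc, total_length = total),
    class = "guide_path"
  )
}

#' @export
print.guide_path <- function(x, ...) {
  cat(sprintf(
    "guide_path: %d vertices, %s, length %.2f um\n",
    nrow(x$vertices), if (x$closed) "closed" else "open", x$total_length
  ))
  invisible(x)
}

#' Circular guide path
#'
#' Polygonises a circle into a closed guide path at a fixed angular
#' resolution. Circle paths are the standard benchmark geometry for
#' long-term cell guidance.
#'
#' @param radius circle radius (um).
#' @param center circle centre, `c(x, y)` in um.
#' @param by_deg angular resolution in degrees (default 1).
#' @return A closed [guide_path].
#' @export
circle_path <- function(radius, center = c(0, 0), by_deg = 1) {
  stopifnot(radius > 0, by_deg > 0, by_deg < 180)
  stopifnot_point(center, "center")
  theta <- seq(0, 2 * pi, by = by_deg * pi / 180)
  theta <- theta[theta < 2 * pi - 1e-12]
  guide_path(cbind(center[1] + radius * cos(theta),
                   center[2] + radius * sin(theta)), closed = TRUE)
}

# segment table for a path: start, end, length, arc at start (closed paths
# include the wrap-around segment)
path_segments <- function(path) {
  v <- path$vertices
  n <- nrow(v)
  if (path$closed) {
    p1 <- v
    p2 <- v[c(2:n, 1), , drop = FALSE]
    arc0 <- c(path$arc)
  } else {
    p1 <- v[-n, , drop = FALSE]
    p2 <- v[-1, , drop = FALSE]
    arc0 <- path$arc[-n]
  }
  len <- sqrt(rowSums((p2 - p1)^2))
  list(p1 = p1, p2 = p2, len = len, arc0 = arc0)
}

#' Project a point onto a guide path
#'
#' Finds the nearest point on the polyline (the projected position). The
#' distance between a cell centroid and its projected position is the path
#' deviation. Ties between equidistant segments are broken towards the
#' smallest arc position, so the result is deterministic.
#'
#' @param point numeric `c(x, y)` in um.
#' @param path a [guide_path].
#' @return A list of class `path_projection` with `projected_point` (um),
#'   `arc_position` (um along the path) and `deviation` (um, >= 0).
#' @examples
#' p <- circle_path(50)
#' pr <- project_to_path(c(52, 0), p)
#' pr$deviation  # ~2 um
#' @export
project_to_path <- function(point, path) {
  stopifnot_point(point)
  stopifnot(inherits(path, "guide_path"))
  s <- path_segments(path)
  d <- s$p2 - s$p1
  w1 <- point[1] - s$p1[, 1]
  w2 <- point[2] - s$p1[, 2]
  t <- (w1 * d[, 1] + w2 * d[, 2]) / (s$len^2)
  t <- clamp(t, 0, 1)
  px <- s$p1[, 1] + t * d[, 1]
  py <- s$p1[, 2] + t * d[, 2]
  dist2 <- (point[1] - px)^2 + (point[2] - py)^2
  dmin <- min(dist2)
  cand <- which(dist2 <= dmin + 1e-12 * max(dmin, 1))
  arcs <- s$arc0[cand] + t[cand] * s$len[cand]
  i <- cand[which.min(arcs)]
  arc <- s$arc0[i] + t[i] * s$len[i]
  if (path$closed && arc >= path$total_length) arc <- arc - path$total_length
  structure(
    list(
      projected_point = c(px[i], py[i]),
      arc_position = arc,
      deviation = sqrt(dist2[i])
    ),
    class = "path_projection"
  )
}

#' Point at a given arc position along a path
#'
#' @param path a [guide_path].
#' @param arc arc position in um. Wraps for closed paths; clamped to
#'   `[0, total_length]` for open paths.
#' @return numeric `c(x, y)`.
#' @export
point_at_arc <- function(path, arc) {
  stopifnot(inherits(path, "guide_path"), is.numeric(arc), length(arc) == 1)
  L <- path$total_length
  if (path$closed) arc <- arc %% L else arc <- clamp(arc, 0, L)
  s <- path_segments(path)
  i <- findInterval(arc, c(s$arc0, L), rightmost.closed = TRUE)
  i <- clamp(i, 1, length(s$len))
  t <- (arc - s$arc0[i]) / s$len[i]
  c(s$p1[i, ] + clamp(t, 0, 1) * (s$p2[i, ] - s$p1[i, ]))
}

#' Next setpoint ahead of a projected position
#'
#' Returns the point a fixed lookahead arc length ahead of the current
#' projection; the trajectory controller aims the illuminated cell region at
#' this point. Closed paths wrap; open paths clamp to the terminal vertex and
#' flag completion.
#'
#' @param projection a `path_projection` from [project_to_path()].
#' @param path the [guide_path] the projection refers to.
#' @param lookahead lookahead distance in um (> 0; default 10, about one
#'   cell radius: short enough for a strong lateral correction gain, long
#'   enough that the aim point stays ahead of the cell).
#' @return list with `point` (`c(x, y)` um) and `completed` (logical; `TRUE`
#'   when an open path is exhausted).
#' @export
next_setpoint <- function(projection, path, lookahead = 10) {
  stopifnot(inherits(projection, "path_projection"), inherits(path, "guide_path"),
            lookahead > 0)
  s <- projection$arc_position + lookahead
  completed <- FALSE
  if (!path$closed && s >= path$total_length) {
    s <- path$total_length
    completed <- TRUE
  }
  list(point = point_at_arc(path, s), completed = completed)
}

#' Projected speed along a path
#'
#' Projects a centroid time series onto the path and divides the arc-length
#' distance between consecutive projected positions by the imaging interval.
#' For closed paths, arc steps are unwrapped to the shortest signed
#' displacement around the loop.
#'
#' @param centroids n x 2 matrix of centroids (um), one row per frame.
#' @param path a [guide_path].
#' @param interval imaging interval in seconds.
#' @return Numeric vector of length n - 1: projected speed magnitudes in
#'   um/min. The signed speeds (positive = increasing arc position) are kept
#'   in attribute `"signed"`; arc positions per frame in attribute `"arc"`.
#' @export
projected_speed <- function(centroids, path, interval) {
  centroids <- as.matrix(centroids)
  stopifnot(ncol(centroids) == 2, nrow(centroids) >= 2, interval > 0)
  arc <- apply(centroids, 1, function(p) project_to_path(p, path)$arc_position)
  ds <- diff(arc)
  if (path$closed) {
    L <- path$total_length
    ds <- ds - L * round(ds / L)
  }
  signed <- ds / interval * 60
  out <- abs(signed)
  attr(out, "signed") <- signed
  attr(out, "arc") <- arc
  out
}

#' Serialise and restore guide paths
#'
#' `path_to_config()` turns a path into a plain list (suitable for a YAML/JSON
#' experiment config); `path_from_config()` inverts it. `path_from_csv()`
#' reads a path from a CSV file with columns `x_um` and `y_um`.
#'
#' @param path a [guide_path].
#' @return `path_to_config()`: a list with `vertices` (list of `c(x, y)`) and
#'   `closed`. The others return a [guide_path].
#' @export
path_to_config <- function(path) {
  stopifnot(inherits(path, "guide_path"))
  list(
    vertices = lapply(seq_len(nrow(path$vertices)), function(i) unname(path$vertices[i, ])),
    closed = path$closed
  )
}

#' @rdname path_to_config
#' @param config a list as produced by `path_to_config()`.
#' @export
path_from_config <- function(config) {
  v <- do.call(rbind, lapply(config$vertices, as.numeric))
  guide_path(v, closed = isTRUE(config$closed))
}

#' @rdname path_to_config
#' @param file CSV file with numeric columns `x_um`, `y_um`.
#' @param closed logical; whether the listed vertices form a loop.
#' @export
path_from_csv <- function(file, closed = FALSE) {
  d <- read.csv(file)
  if (!all(c("x_um", "y_um") %in% names(d))) {
    stop("path CSV must have columns 'x_um' and 'y_um'")
  }
  guide_path(cbind(d$x_um, d$y_um), closed = closed)
}
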
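#' Segmentation parameters
#'
#' Parameters of the classical segmentation backend: Gaussian smoothing,
#' global threshold (Otsu by default), hole filling, connected components and
#' a minimum-area filter. A brighter/dimmer class split inside each cell
#' yields nucleus and cytosol compartments in `nucleus_cytosol` mode.
#'
#' @param smooth_sigma pre-threshold Gaussian smoothing, um.
#' @param min_area minimum object area, pixels.
#' @param threshold `"otsu"` for a global Otsu threshold; `"background"` to
#'   threshold at `median + max(threshold_k * MAD, threshold_fraction *
#'   (max - median))` of the smoothed frame — keyed to the background
#'   statistics, so cells of very different brightness (and compartments
#'   much dimmer than the brightest nucleus) are all captured whole;
#'   `"fraction"` to threshold at
#'   `background + threshold_fraction * (max - background)`.
#' @param threshold_k background-noise multiple for the `"background"`
#'   method.
#' @param threshold_fraction fraction for the `"fraction"` method, and the
#'   threshold floor of the `"background"` method.
#' @param erode_px mask erosion (pixels) applied before intensity
#'   measurements, to keep PSF-blurred boundary pixels out of compartment
#'   means.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma = 1, min_area = 50,
                       threshold = c("otsu", "background", "fraction"),
                       threshold_k = 6, threshold_fraction = 0.05,
                       erode_px = 3) {
  threshold <- match.arg(threshold)
  stopifnot(smooth_sigma >= 0, min_area >= 1, threshold_k > 0,
            threshold_fraction > 0, threshold_fraction < 1, erode_px >= 0)
  structure(
    list(smooth_sigma = smooth_sigma, min_area = min_area,
         threshold = threshold, threshold_k = threshold_k,
         threshold_fraction = threshold_fraction, erode_px = erode_px),
    class = "seg_params"
  )
}

# robust background: median outside all dilated foreground masks
estimate_background <- function(pixels, fg_mask) {
  if (any(fg_mask)) {
    dil <- EBImage::dilate(fg_mask * 1, EBImage::makeBrush(7, "disc")) > 0
    bgpx <- pixels[!dil]
    if (length(bgpx) > 20) return(median(bgpx))
  }
  median(pixels)
}

erode_mask <- function(mask, px) {
  if (px <= 0 || !any(mask)) return(mask)
  EBImage::erode(mask * 1, EBImage::makeBrush(2 * px + 1, "disc")) > 0
}

otsu_counts <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(rng[2])
  EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)), range = c(0, 1)) *
    diff(rng) + rng[1]
}

#' Segment a synthetic fluorescence frame
#'
#' Classical backend: Gaussian smoothing, global threshold, hole filling,
#' connected components, minimum-area filter. In `nucleus_cytosol` mode a
#' second intensity split inside each cell separates the nucleus (the
#' interior intensity class, identified as the class that avoids the cell
#' boundary) from the cytosol. Any other segmenter producing the same result
#' structure can be plugged into the loop in its place.
#'
#' @param frame a [sim_frame].
#' @param mode `"cell"` (whole-cell labels) or `"nucleus_cytosol"`.
#' @param params a [seg_params].
#' @return An object of class `segmentation` with `label_mask` (integer
#'   matrix, 0 = background), `centroids` (n x 2, um, intensity-weighted),
#'   `areas` (pixels), `mean_intensities` (background-corrected),
#'   `background` (counts) and, in `nucleus_cytosol` mode, `nucleus_mask`
#'   (integer matrix sharing cell labels) plus per-cell `nucleus_mean` and
#'   `cytosol_mean`. Zero foreground yields an empty (zero-label) result.
#' @export
segment_frame <- function(frame, mode = c("cell", "nucleus_cytosol"),
                          params = seg_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "sim_frame"), inherits(params, "seg_params"))
  px <- frame$pixels
  sm <- if (params$smooth_sigma > 0) {
    EBImage::gblur(px, sigma = params$smooth_sigma / frame$pixel_size)
  } else px
  if (params$threshold == "otsu") {
    thr <- otsu_counts(sm)
  } else if (params$threshold == "background") {
    med <- median(sm)
    thr <- med + max(params$threshold_k * stats::mad(sm),
                     params$threshold_fraction * (max(sm) - med))
  } else {
    bg0 <- median(sm)
    thr <- bg0 + params$threshold_fraction * (max(sm) - bg0)
  }
  bw <- sm > thr
  empty <- function(bg) {
    structure(
      list(label_mask = matrix(0L, nrow(px), ncol(px)),
           centroids = matrix(numeric(), 0, 2), areas = integer(),
           mean_intensities = numeric(), background = bg, mode = mode),
      class = "segmentation"
    )
  }
  if (!any(bw)) return(empty(median(px)))
  bw <- EBImage::fillHull(bw * 1) > 0
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area)
  if (!length(keep)) return(empty(estimate_background(px, bw)))
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  lab_new <- matrix(0L, nrow(px), ncol(px))
  nz <- lab > 0
  lab_new[nz] <- relab[lab[nz]]
  n <- length(keep)
  bg <- estimate_background(px, lab_new > 0)
  # per-label statistics from the foreground pixels only (one pass, so the
  # cost stays proportional to the segmented area, not labels x frame area)
  fg <- which(lab_new > 0)
  idx <- arrayInd(fg, dim(lab_new))
  labs <- lab_new[fg]
  pxv <- px[fg]
  w <- pmax(pxv - bg, 0)
  wsum <- rowsum(w, labs)[, 1]
  flat <- wsum <= 0
  if (any(flat)) w[labs %in% which(flat)] <- 1
  wsum <- rowsum(w, labs)[, 1]
  centroids <- cbind(
    rowsum(w * (idx[, 2] - 0.5), labs)[, 1] / wsum * frame$pixel_size,
    rowsum(w * (idx[, 1] - 0.5), labs)[, 1] / wsum * frame$pixel_size
  )
  dimnames(centroids) <- NULL
  areas_out <- tabulate(labs, n)
  mean_int <- unname(rowsum(pxv, labs)[, 1] / areas_out - bg)
  res <- structure(
    list(label_mask = lab_new, centroids = centroids, areas = areas_out,
         mean_intensities = mean_int, background = bg, mode = mode),
    class = "segmentation"
  )
  if (mode == "nucleus_cytosol") {
    res <- split_compartments(res, px, params)
  }
  res
}

# nucleus/cytosol split inside each cell label: Otsu on the intensities of
# an eroded cell core (the erosion keeps the PSF halo at the cell boundary
# out of the intensity histogram); the nucleus is the intensity class that
# avoids the cell boundary.
split_compartments <- function(res, px, params) {
  lab <- res$label_mask
  n <- length(res$areas)
  nuc_mask <- matrix(0L, nrow(lab), ncol(lab))
  nucleus_mean <- rep(NA_real_, n)
  cytosol_mean <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    cell <- lab == k
    core <- erode_mask(cell, max(params$erode_px, 2))
    if (!any(core)) core <- cell
    v <- px[core]
    thr2 <- otsu_counts(matrix(v, ncol = 1))
    bright <- core & (px > thr2)
    dim_ <- core & !bright
    boundary <- core & !erode_mask(core, 1)
    nb <- sum(boundary)
    frac_bright <- if (nb) sum(bright & boundary) / nb else 1
    frac_dim <- if (nb) sum(dim_ & boundary) / nb else 1
    cand <- if (frac_bright <= frac_dim) bright else dim_
    if (!any(cand)) next
    cc <- EBImage::bwlabel(cand * 1)
    sizes <- tabulate(cc[cc > 0])
    nuc <- EBImage::fillHull((cc == which.max(sizes)) * 1) > 0
    nuc <- nuc & cell
    nuc_mask[nuc] <- k
    nuc_er <- erode_mask(nuc, params$erode_px)
    nuc_dil <- EBImage::dilate(nuc * 1, EBImage::makeBrush(2 * params$erode_px + 1, "disc")) > 0
    cyt_er <- core & !nuc_dil
    if (!any(nuc_er)) nuc_er <- nuc
    if (!any(cyt_er)) cyt_er <- cell & !nuc
    # median rather than mean: pixels straddling the PSF-blurred compartment
    # boundaries are dimmed and would bias a plain mean at low thresholds
    nucleus_mean[k] <- median(px[nuc_er]) - res$background
    if (any(cyt_er)) cytosol_mean[k] <- median(px[cyt_er]) - res$background
  }
  res$nucleus_mask <- nuc_mask
  res$nucleus_mean <- nucleus_mean
  res$cytosol_mean <- cytosol_mean
  res
}

#' Nearest-neighbour identity tracking across frames
#'
#' `track_state()` creates an empty tracker; `track_update()` assigns the
#' detections of one frame to existing tracks by greedy nearest-centroid
#' matching gated at `max_step`: the globally closest (track, detection)
#' pair is linked first, then the next closest among the rest. Unmatched
#' tracks persist up to `max_gap` frames before closing; unmatched
#' detections spawn new track ids. Greedy matching is not globally optimal,
#' which is adequate at the low cell counts this loop controls.
#'
#' @param max_step maximum centroid displacement per frame gap, um.
#' @param max_gap frames a track may go unseen before it is closed.
#' @return `track_state()`: an object of class `track_state` with a
#'   `tracks` data frame (`id`, `x`, `y`, `vx`, `vy` in um/frame,
#'   `last_frame`, `active`).
#' @export
track_state <- function(max_step = 15, max_gap = 3) {
  stopifnot(max_step > 0, max_gap >= 0)
  structure(
    list(
      tracks = data.frame(id = integer(), x = numeric(), y = numeric(),
                          vx = numeric(), vy = numeric(),
                          last_frame = integer(), active = logical()),
      next_id = 1L, max_step = max_step, max_gap = max_gap
    ),
    class = "track_state"
  )
}

#' @rdname track_state
#' @param state a `track_state`.
#' @param seg a `segmentation` result for the current frame.
#' @param frame_index integer frame counter (monotone increasing).
#' @return `track_update()`: the updated `track_state`, with attribute
#'   `"assignment"`: an integer vector mapping each segmentation label to
#'   its track id.
#' @export
track_update <- function(state, seg, frame_index) {
  stopifnot(inherits(state, "track_state"), inherits(seg, "segmentation"))
  tr <- state$tracks
  ndet <- nrow(seg$centroids)
  assignment <- rep(NA_integer_, ndet)
  act <- which(tr$active)
  if (length(act) && ndet) {
    gap <- frame_index - tr$last_frame[act]
    pred_x <- tr$x[act] + tr$vx[act] * gap
    pred_y <- tr$y[act] + tr$vy[act] * gap
    d <- sqrt(outer(pred_x, seg$centroids[, 1], "-")^2 +
              outer(pred_y, seg$centroids[, 2], "-")^2)
    gate <- outer(gap, rep(1, ndet)) * state$max_step
    d[d > gate] <- Inf
    while (any(is.finite(d))) {
      k <- arrayInd(which.min(d), dim(d))
      ti <- act[k[1]]
      di <- k[2]
      gap_i <- frame_index - tr$last_frame[ti]
      tr$vx[ti] <- (seg$centroids[di, 1] - tr$x[ti]) / gap_i
      tr$vy[ti] <- (seg$centroids[di, 2] - tr$y[ti]) / gap_i
      tr$x[ti] <- seg$centroids[di, 1]
      tr$y[ti] <- seg$centroids[di, 2]
      tr$last_frame[ti] <- frame_index
      assignment[di] <- tr$id[ti]
      d[k[1], ] <- Inf
      d[, k[2]] <- Inf
    }
  }
  # spawn new tracks for unmatched detections
  for (di in which(is.na(assignment))) {
    tr <- rbind(tr, data.frame(
      id = state$next_id, x = seg$centroids[di, 1], y = seg$centroids[di, 2],
      vx = 0, vy = 0, last_frame = frame_index, active = TRUE
    ))
    assignment[di] <- state$next_id
    state$next_id <- state$next_id + 1L
  }
  # close tracks unseen for longer than max_gap
  stale <- tr$active & (frame_index - tr$last_frame > state$max_gap)
  tr$active[stale] <- FALSE
  state$tracks <- tr
  attr(state, "assignment") <- assignment
  state
}

#' Per-cell intensity calibration against the dynamic range
#'
#' Establishes, per cell, the compartment intensity extremes between the
#' dark state and the saturating-light state, so that runtime measurements
#' can be normalised to `[0, 1]` of each cell's own dynamic range.
#' Cells are matched between the two frames by nearest centroid.
#'
#' @param dark_frame,light_frame [sim_frame]s of the same cells at the dark
#'   steady state and at the saturating-light steady state.
#' @param params a [seg_params].
#' @return A data frame of class `range_calibration`, one row per cell:
#'   centroid, and `nucleus_min/max`, `cytosol_min/max` (background-corrected
#'   counts).
#' @export
calibrate_range <- function(dark_frame, light_frame,
                            params = seg_params(threshold = "background",
                                                threshold_fraction = 0.01)) {
  sd_ <- segment_frame(dark_frame, "nucleus_cytosol", params)
  sl <- segment_frame(light_frame, "nucleus_cytosol", params)
  if (!length(sd_$areas) || !length(sl$areas)) {
    stop("calibration failure: no cells segmented in a calibration frame")
  }
  n <- length(sd_$areas)
  out <- data.frame(
    cell = seq_len(n), x = sd_$centroids[, 1], y = sd_$centroids[, 2],
    nucleus_min = NA_real_, nucleus_max = NA_real_,
    cytosol_min = NA_real_, cytosol_max = NA_real_
  )
  for (k in seq_len(n)) {
    d2 <- (sl$centroids[, 1] - sd_$centroids[k, 1])^2 +
          (sl$centroids[, 2] - sd_$centroids[k, 2])^2
    m <- which.min(d2)
    nuc <- sort(c(sd_$nucleus_mean[k], sl$nucleus_mean[m]))
    cyt <- sort(c(sd_$cytosol_mean[k], sl$cytosol_mean[m]))
    if (anyNA(nuc) || anyNA(cyt) || nuc[1] >= nuc[2] || cyt[1] >= cyt[2]) {
      stop("calibration failure: dark and saturated intensities do not bracket a range")
    }
    out$nucleus_min[k] <- nuc[1]
    out$nucleus_max[k] <- nuc[2]
    out$cytosol_min[k] <- cyt[1]
    out$cytosol_max[k] <- cyt[2]
  }
  class(out) <- c("range_calibration", class(out))
  out
}

#' Measure nucleus and cytosol intensities of one segmented cell
#'
#' Background-corrected compartment means, normalised against the cell's
#' calibrated dynamic range and clipped to `[0, 1]`. The measurement is
#' flagged low-contrast (`contrast_ok = FALSE`) when the nucleus/cytosol
#' intensity difference falls below `contrast_threshold` of the calibrated
#' dynamic range, and invalid when the nucleus is missing.
#'
#' @param seg a `nucleus_cytosol` [segment_frame()] result.
#' @param label cell label within `seg`.
#' @param calibration one row of a [calibrate_range()] result (or a list
#'   with the same fields).
#' @param contrast_threshold minimum contrast as a fraction of the dynamic
#'   range (default 0.05).
#' @return A list of class `compartment_measurement`: `nucleus_mean`,
#'   `cytosol_mean`, `normalised_nucleus`, `normalised_cytosol`, `ratio`
#'   (nucleus:cytosol of background-corrected means), `contrast_ok`,
#'   `valid`.
#' @export
measure_compartments <- function(seg, label, calibration,
                                 contrast_threshold = 0.05) {
  stopifnot(inherits(seg, "segmentation"),
            identical(seg$mode, "nucleus_cytosol"))
  nm <- seg$nucleus_mean[label]
  cm <- seg$cytosol_mean[label]
  if (is.na(nm) || is.na(cm)) {
    return(structure(
      list(nucleus_mean = nm, cytosol_mean = cm,
           normalised_nucleus = NA_real_, normalised_cytosol = NA_real_,
           ratio = NA_real_, contrast_ok = FALSE, valid = FALSE),
      class = "compartment_measurement"
    ))
  }
  nrange <- calibration$nucleus_max - calibration$nucleus_min
  crange <- calibration$cytosol_max - calibration$cytosol_min
  dyn <- max(nrange, crange)
  structure(
    list(
      nucleus_mean = nm, cytosol_mean = cm,
      normalised_nucleus = clamp((nm - calibration$nucleus_min) / nrange, 0, 1),
      normalised_cytosol = clamp((cm - calibration$cytosol_min) / crange, 0, 1),
      ratio = nm / cm,
      contrast_ok = abs(nm - cm) / dyn >= contrast_threshold,
      valid = TRUE
    ),
    class = "compartment_measurement"
  )
}

#' Temporal filter for low-contrast measurements
#'
#' Keeps the controller fed with plausible values across frames whose
#' nucleus/cytosol contrast is too low to trust: valid frames pass their own
#' value through, invalid frames are replaced by the last valid value
#' (`"hold"`, default) or by the median of the valid values in a rolling
#' window (`"median"`). Until a first valid frame is seen the output is `NA`
#' and the controller start is deferred.
#'
#' @param mode `"hold"` or `"median"`.
#' @param window rolling window length in frames (>= 1).
#' @return `temporal_filter()`: an object of class `temporal_filter`.
#' @export
temporal_filter <- function(mode = c("hold", "median"), window = 5) {
  mode <- match.arg(mode)
  stopifnot(window >= 1)
  structure(list(mode = mode, window = window, history = numeric(),
                 last_valid = NA_real_),
            class = "temporal_filter")
}

#' @rdname temporal_filter
#' @param filter a `temporal_filter`.
#' @param value measured value for this frame.
#' @param valid logical; whether this frame's measurement is trustworthy
#'   (e.g. `contrast_ok && valid` of a [measure_compartments()] result).
#' @return `filter_update()`: list with `value` (the filtered measurement,
#'   `NA` while no valid frame has ever been seen) and `filter` (updated
#'   state).
#' @export
filter_update <- function(filter, value, valid = TRUE) {
  stopifnot(inherits(filter, "temporal_filter"))
  if (isTRUE(valid) && is.finite(value)) {
    filter$history <- tail(c(filter$history, value), filter$window)
    filter$last_valid <- value
    out <- value
  } else {
    out <- if (filter$mode == "hold") {
      filter$last_valid
    } else if (length(filter$history)) {
      median(filter$history)
    } else {
      NA_real_
    }
  }
  list(value = out, filter = filter)
}

#' Corrected total cell fluorescence
#'
#' `integrated density - area * background mean`: the cell's summed
#' intensity minus the background contribution over its area. The standard
#' proxy for total expression level.
#'
#' @param image intensity matrix or [sim_frame].
#' @param cell_mask logical matrix selecting the cell.
#' @param background_mask logical matrix selecting a background region
#'   (disjoint from the cell mask).
#' @return Scalar CTCF value (counts).
#' @export
ctcf <- function(image, cell_mask, background_mask) {
  if (inherits(image, "sim_frame")) image <- image$pixels
  stopifnot(is.matrix(image), is.logical(cell_mask), is.logical(background_mask))
  if (any(cell_mask & background_mask)) {
    stop("cell and background masks must be disjoint")
  }
  if (!any(background_mask)) stop("background region is empty")
  if (!any(cell_mask)) stop("cell mask is empty")
  sum(image[cell_mask]) - sum(cell_mask) * mean(image[background_mask])
}
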
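#' Optics configuration for the virtual microscope
#'
#' Camera and illumination-path parameters used to render synthetic
#' fluorescence frames. The camera model is Poisson shot noise plus additive
#' Gaussian read noise at unit gain (1 count/photon).
#'
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian PSF standard deviation, um.
#' @param background mean background level, counts.
#' @param read_noise read noise standard deviation, counts.
#' @param fov_px field of view `c(rows, cols)` in pixels.
#' @param noise logical; apply shot + read noise.
#' @param i_max maximal deliverable irradiance, uW/cm^2 (hardware limit of
#'   the illumination path).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size = 1, psf_sigma = 1.5, background = 100,
                          read_noise = 3, fov_px = c(160, 160), noise = TRUE,
                          i_max = 10.4) {
  stopifnot(pixel_size > 0, psf_sigma >= 0, background >= 0, read_noise >= 0,
            length(fov_px) == 2, all(fov_px >= 8), i_max > 0)
  structure(
    list(pixel_size = pixel_size, psf_sigma = psf_sigma,
         background = background, read_noise = read_noise,
         fov_px = as.integer(fov_px), noise = noise, i_max = i_max),
    class = "optics_config"
  )
}

#' A synthetic fluorescence frame
#'
#' @param pixels matrix of non-negative intensities (counts); rows map to y,
#'   columns to x.
#' @param pixel_size um per pixel.
#' @param timestamp acquisition time, seconds.
#' @param channel channel label.
#' @return An object of class `sim_frame`.
#' @export
sim_frame <- function(pixels, pixel_size, timestamp = 0, channel = "fluor") {
  stopifnot(is.matrix(pixels), all(pixels >= 0), pixel_size > 0)
  structure(
    list(pixels = pixels, pixel_size = pixel_size, timestamp = timestamp,
         channel = channel),
    class = "sim_frame"
  )
}

#' @export
print.sim_frame <- function(x, ...) {
  cat(sprintf("sim_frame %dx%d px (%.2f um/px), t = %.0f s, channel %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$timestamp,
              x$channel))
  invisible(x)
}

# pixel-centre coordinate grids in um (x = columns, y = rows)
px_centers <- function(n, pixel_size) (seq_len(n) - 0.5) * pixel_size

# um -> pixel index (row or col)
um_to_px <- function(u, pixel_size) floor(u / pixel_size) + 1

# anti-aliased disc coverage, blurred by the PSF in a local patch, added
# into `img` (modified copy returned); returns NULL if the disc is fully
# outside the frame. Blurring per cell keeps the render cost proportional
# to the number of cells, not the field-of-view area.
add_disc <- function(img, center_um, radius_um, total, pixel_size,
                     psf_sigma = 0) {
  nr <- nrow(img)
  nc <- ncol(img)
  r_px <- radius_um / pixel_size
  s_px <- psf_sigma / pixel_size
  pad <- ceiling(r_px + 4 * s_px + 2)
  ci <- center_um[2] / pixel_size + 0.5 # row of centre in pixel units
  cj <- center_um[1] / pixel_size + 0.5
  i0 <- floor(ci) - pad
  j0 <- floor(cj) - pad
  ii <- i0:(floor(ci) + pad)
  jj <- j0:(floor(cj) + pad)
  dist <- sqrt(outer((ii - ci)^2, (jj - cj)^2, "+"))
  cov <- clamp(r_px + 0.5 - dist, 0, 1)
  s <- sum(cov)
  if (s <= 0) return(NULL)
  patch <- cov * (total / s)
  if (s_px > 0) patch <- pmax(EBImage::gblur(patch, sigma = s_px), 0)
  keep_i <- which(ii >= 1 & ii <= nr)
  keep_j <- which(jj >= 1 & jj <= nc)
  if (!length(keep_i) || !length(keep_j)) return(NULL)
  clipped <- patch[keep_i, keep_j, drop = FALSE]
  if (sum(clipped) < 0.05 * total) return(NULL) # essentially out of view
  img[ii[keep_i], jj[keep_j]] <- img[ii[keep_i], jj[keep_j]] + clipped
  img
}

# anti-aliased ellipse coverage (axis-aligned), values 0..1, on given
# pixel-index rows/cols
ellipse_coverage <- function(ii, jj, center_um, axes_um, pixel_size) {
  ci <- center_um[2] / pixel_size + 0.5
  cj <- center_um[1] / pixel_size + 0.5
  a <- axes_um[1] / pixel_size # x semi-axis, pixels
  b <- axes_um[2] / pixel_size # y semi-axis
  # signed "radial" excess, approximately in pixels near the boundary
  q <- sqrt(outer(((ii - ci) / b)^2, ((jj - cj) / a)^2, "+"))
  edge <- (1 - q) * min(a, b)
  clamp(edge + 0.5, 0, 1)
}

apply_camera_noise <- function(pixels, optics) {
  if (!optics$noise) return(pixels)
  shot <- matrix(rpois(length(pixels), lambda = pmax(pixels, 0)),
                 nrow = nrow(pixels))
  out <- shot + matrix(rnorm(length(pixels), 0, optics$read_noise),
                       nrow = nrow(pixels))
  pmax(out, 0)
}

#' Render a frame of migrating cells
#'
#' Each cell is drawn as an anti-aliased disc of its shape radius, blurred by
#' the Gaussian PSF, with total integrated intensity equal to the cell's
#' expression level, on a uniform background. Cells whose body lies fully
#' outside the field of view are omitted with a warning.
#'
#' @param states list of [migrating_cell] states (a single state is
#'   accepted).
#' @param optics an [optics_config].
#' @param timestamp frame timestamp, seconds.
#' @return A [sim_frame].
#' @export
render_migration_frame <- function(states, optics = optics_config(),
                                   timestamp = 0) {
  if (inherits(states, "migrating_cell")) states <- list(states)
  stopifnot(inherits(optics, "optics_config"))
  img <- matrix(0, optics$fov_px[1], optics$fov_px[2])
  for (s in states) {
    res <- add_disc(img, s$position, s$shape_radius, s$expression,
                    optics$pixel_size, optics$psf_sigma)
    if (is.null(res)) {
      warning(sprintf("cell at (%.1f, %.1f) um outside field of view; omitted",
                      s$position[1], s$position[2]))
    } else {
      img <- res
    }
  }
  img <- img + optics$background
  sim_frame(apply_camera_noise(img, optics), optics$pixel_size, timestamp)
}

#' Render a frame of nucleocytoplasmic transport cells
#'
#' Each cell is an ellipse of cytosol with a nuclear disc inside: cytosol
#' pixels carry `expression * C` counts and nucleus pixels `expression * N`,
#' over the uniform background, blurred by the PSF.
#'
#' @param states list of [lexy_plant] states (a single state is accepted);
#'   rendering geometry is taken from each state's `center`, `cell_axes` and
#'   `nucleus_radius`.
#' @param optics an [optics_config].
#' @param timestamp frame timestamp, seconds.
#' @return A [sim_frame].
#' @export
render_lexy_frame <- function(states, optics = optics_config(fov_px = c(96, 96)),
                              timestamp = 0) {
  if (inherits(states, "lexy_plant")) states <- list(states)
  stopifnot(inherits(optics, "optics_config"))
  nr <- optics$fov_px[1]
  nc <- optics$fov_px[2]
  px_sz <- optics$pixel_size
  s_px <- optics$psf_sigma / px_sz
  img <- matrix(0, nr, nc)
  for (s in states) {
    pad <- ceiling(max(s$cell_axes) / px_sz + 4 * s_px + 2)
    ci <- floor(s$center[2] / px_sz)
    cj <- floor(s$center[1] / px_sz)
    ii <- (ci - pad):(ci + pad)
    jj <- (cj - pad):(cj + pad)
    cell_cov <- ellipse_coverage(ii, jj, s$center, s$cell_axes, px_sz)
    nuc_cov <- ellipse_coverage(ii, jj, s$center,
                                rep(s$nucleus_radius, 2), px_sz)
    cyto_cov <- pmax(cell_cov - nuc_cov, 0)
    patch <- s$expression * (cyto_cov * s$C + nuc_cov * s$N)
    if (s_px > 0) patch <- pmax(EBImage::gblur(patch, sigma = s_px), 0)
    keep_i <- which(ii >= 1 & ii <= nr)
    keep_j <- which(jj >= 1 & jj <= nc)
    clipped <- patch[keep_i, keep_j, drop = FALSE]
    if (!length(clipped) || sum(clipped) < 0.05 * sum(patch)) {
      warning(sprintf("cell at (%.1f, %.1f) um outside field of view; omitted",
                      s$center[1], s$center[2]))
      next
    }
    img[ii[keep_i], jj[keep_j]] <- img[ii[keep_i], jj[keep_j]] + clipped
  }
  img <- img + optics$background
  sim_frame(apply_camera_noise(img, optics), optics$pixel_size, timestamp)
}

#' Illumination command for one frame interval
#'
#' One binary mask, irradiance and PWM duty cycle per controlled region. The
#' effective dose delivered to a region over the frame interval is
#' `duty * irradiance` (fast-PWM limit).
#'
#' @param masks list of logical matrices (frame-sized pixel masks), one per
#'   region. May be empty (light off).
#' @param irradiances numeric vector of irradiances, uW/cm^2, one per region.
#' @param duty_cycles numeric vector in `[0, 1]`, one per region (default 1).
#' @param frame_interval frame interval, seconds.
#' @param i_max hardware irradiance limit used for validation.
#' @return An object of class `illumination_command`.
#' @export
illumination_command <- function(masks = list(), irradiances = numeric(),
                                 duty_cycles = rep(1, length(irradiances)),
                                 frame_interval = 60, i_max = Inf) {
  if (length(masks) != length(irradiances) ||
      length(masks) != length(duty_cycles)) {
    stop("masks, irradiances and duty_cycles must have equal length")
  }
  stopifnot(all(irradiances >= 0), all(irradiances <= i_max),
            all(duty_cycles >= 0), all(duty_cycles <= 1), frame_interval > 0)
  for (m in masks) {
    if (!is.matrix(m) || !is.logical(m)) stop("each mask must be a logical matrix")
  }
  structure(
    list(masks = masks, irradiances = irradiances, duty_cycles = duty_cycles,
         frame_interval = frame_interval),
    class = "illumination_command"
  )
}

#' Effective irradiance received by each plant
#'
#' Computes what each plant "sees" during one frame interval: the sum over
#' regions of `duty * irradiance` for every region whose mask covers the
#' plant's sensitive point (its centroid), plus, optionally, a scattering
#' halo delivering a fraction of a region's dose to plants within a halo
#' radius of the mask (unintended activation of close neighbours).
#'
#' @param command an [illumination_command].
#' @param positions n x 2 matrix of plant sensitive points (um).
#' @param pixel_size um per pixel (to map positions into the masks).
#' @param radii sensitive-region radius per plant, um (recycled; default 0 =
#'   point-like). A plant receives a region's dose when its sensitive region
#'   overlaps the mask, i.e. some mask pixel lies within this radius.
#' @param scatter_fraction fraction of a region's dose received inside the
#'   halo (default 0 = no scatter).
#' @param scatter_halo halo radius beyond the sensitive region, um.
#' @return Numeric vector of effective irradiances (uW/cm^2), one per plant.
#' @export
apply_illumination <- function(command, positions, pixel_size = 1, radii = 0,
                               scatter_fraction = 0, scatter_halo = 0) {
  stopifnot(inherits(command, "illumination_command"),
            scatter_fraction >= 0, scatter_fraction <= 1, scatter_halo >= 0,
            all(radii >= 0))
  positions <- matrix(as.numeric(positions), ncol = 2)
  n <- nrow(positions)
  radii <- rep_len(radii, n)
  eff <- numeric(n)
  if (!length(command$masks)) return(eff)
  for (r in seq_along(command$masks)) {
    mask <- command$masks[[r]]
    dose <- command$duty_cycles[r] * command$irradiances[r]
    if (dose == 0 || !any(mask)) next
    idx <- which(mask, arr.ind = TRUE)
    mask_x <- (idx[, 2] - 0.5) * pixel_size
    mask_y <- (idx[, 1] - 0.5) * pixel_size
    for (k in seq_len(n)) {
      i <- um_to_px(positions[k, 2], pixel_size)
      j <- um_to_px(positions[k, 1], pixel_size)
      at_point <- i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) &&
        mask[i, j]
      d <- sqrt(min((mask_x - positions[k, 1])^2 + (mask_y - positions[k, 2])^2))
      if (at_point || d <= radii[k]) {
        eff[k] <- eff[k] + dose
      } else if (scatter_fraction > 0 && scatter_halo > 0 &&
                 d <= radii[k] + scatter_halo) {
        eff[k] <- eff[k] + scatter_fraction * dose
      }
    }
  }
  eff
}

#' Simulated microscope backend
#'
#' Binds plants and optics into an object satisfying the abstract microscope
#' contract used by the closed-loop runner: `acquire()` returns the current
#' frame and `illuminate(command)` stores the command and returns the
#' effective mean irradiance per region (`duty * irradiance`). A hardware
#' backend exposing the same two operations could be substituted without
#' changing the loop.
#'
#' @param plants list of plant states ([migrating_cell] or [lexy_plant]).
#' @param optics an [optics_config].
#' @param mode `"migration"` or `"lexy"`; selects the renderer.
#' @return An environment of class `sim_microscope` with functions
#'   `acquire(timestamp)`, `illuminate(command)`, `get_plants()`,
#'   `set_plants(plants)` and `last_command()`.
#' @export
sim_microscope <- function(plants, optics = optics_config(),
                           mode = c("migration", "lexy")) {
  mode <- match.arg(mode)
  env <- new.env(parent = emptyenv())
  env$plants <- plants
  env$optics <- optics
  env$command <- NULL
  render <- if (mode == "migration") render_migration_frame else render_lexy_frame
  env$acquire <- function(timestamp = 0) render(env$plants, env$optics, timestamp)
  env$illuminate <- function(command) {
    stopifnot(inherits(command, "illumination_command"))
    if (any(command$irradiances > env$optics$i_max)) {
      stop("commanded irradiance exceeds the hardware limit")
    }
    env$command <- command
    command$duty_cycles * command$irradiances
  }
  env$get_plants <- function() env$plants
  env$set_plants <- function(p) env$plants <- p
  env$last_command <- function() env$command
  class(env) <- c("sim_microscope", class(env))
  env
}

#' Write and read multi-page TIFF stacks
#'
#' Frames are stored as 16-bit grayscale TIFF pages; intensities are counts
#' (clipped to `[0, 65535]` and rounded on write).
#'
#' @param frames list of [sim_frame] objects.
#' @param path output file.
#' @return `write_frames_tiff()` returns `path` invisibly;
#'   `read_frames_tiff()` returns a list of [sim_frame] objects.
#' @export
write_frames_tiff <- function(frames, path) {
  if (inherits(frames, "sim_frame")) frames <- list(frames)
  pages <- lapply(frames, function(f) clamp(round(f$pixels), 0, 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @param pixel_size um per pixel to attach to the frames read back.
#' @export
read_frames_tiff <- function(path, pixel_size = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(seq_along(pages), function(i) {
    sim_frame(pages[[i]] * 65535, pixel_size, timestamp = i - 1)
  })
}

#' Append illumination commands to a per-frame CSV log
#'
#' One row per region and frame: frame index, region id, irradiance, duty
#' cycle and mask area in pixels.
#'
#' @param command an [illumination_command].
#' @param frame frame index.
#' @param file CSV path; created with a header if absent.
#' @return The file path, invisibly.
#' @export
write_illumination_log <- function(command, frame, file) {
  n <- length(command$masks)
  d <- data.frame(
    frame = rep(frame, n),
    region_id = seq_len(n),
    irradiance_uW_cm2 = command$irradiances,
    duty = command$duty_cycles,
    mask_px = vapply(command$masks, sum, numeric(1))
  )
  write.table(d, file, sep = ",", row.names = FALSE,
              col.names = !file.exists(file), append = file.exists(file))
  invisible(file)
}

#' Export and import masks
#'
#' Integer label masks round-trip through 16-bit grayscale TIFF (label value
#' = pixel value); binary masks can also be written as PNG images for quick
#' inspection.
#'
#' @param mask integer label matrix (`write_label_tiff`) or logical matrix
#'   (`write_mask_png`).
#' @param path output file.
#' @return The file path (writers, invisibly) or the integer label matrix
#'   (`read_label_tiff`).
#' @export
write_label_tiff <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask <= 65535))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' @rdname write_label_tiff
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG masks")
  }
  png::writePNG(mask * 1, path)
  invisible(path)
}
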
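test_that("segmentation recovers position, count and size of rendered cells", {
  opt <- optics_config(fov_px = c(160, 160), noise = FALSE)

  # single noise-free cell: one label, centroid within 0.2 px of ground truth
  mc <- migrating_cell(position = c(80.3, 60.7))
  seg <- segment_frame(render_migration_frame(mc, opt), "cell")
  expect_length(seg$areas, 1)
  expect_lt(max(abs(seg$centroids[1, ] - mc$position)), 0.2)

  # blank frame: zero labels, not an error
  seg0 <- segment_frame(render_migration_frame(list(), opt), "cell")
  expect_length(seg0$areas, 0)
  expect_true(all(seg0$label_mask == 0))

  # two identically parameterised cells: areas within 5%
  a <- migrating_cell(position = c(50, 50))
  b <- migrating_cell(position = c(110, 110))
  seg2 <- segment_frame(render_migration_frame(list(a, b), opt), "cell")
  expect_length(seg2$areas, 2)
  expect_lt(abs(diff(seg2$areas)) / mean(seg2$areas), 0.05)
})

test_that("compartment measurement round-trips the true nucleus:cytosol ratio", {
  opt <- noise_free_optics()
  sp <- seg_params(threshold = "background", threshold_fraction = 0.01)
  # reachable plant states: rho * N + C = 1
  for (Cv in seq(0.09, 0.32, length.out = 5)) {
    Nv <- (1 - Cv) / 0.5
    seg <- segment_frame(render_lexy_frame(lexy_plant(N = Nv, C = Cv), opt),
                         "nucleus_cytosol", sp)
    expect_length(seg$areas, 1)
    expect_lt(abs(seg$nucleus_mean / seg$cytosol_mean - Nv / Cv) / (Nv / Cv),
              0.02)
  }
})

test_that("calibration brackets runtime intensities and rejects flat input", {
  opt <- optics_config(fov_px = c(96, 96), psf_sigma = 1, noise = TRUE)
  pl <- lexy_plant()
  sat <- lexy_steady_state(pl, 10.4)
  pl_sat <- pl
  pl_sat$N <- sat$N; pl_sat$C <- sat$C; pl_sat$A <- sat$A
  set.seed(2)
  cal <- calibrate_range(render_lexy_frame(pl, opt),
                         render_lexy_frame(pl_sat, opt))
  expect_lt(cal$nucleus_min, cal$nucleus_max)
  expect_lt(cal$cytosol_min, cal$cytosol_max)
  # runtime values at an intermediate state fall inside the calibrated range
  mid <- lexy_steady_state(pl, 0.5)
  pl_mid <- pl
  pl_mid$N <- mid$N; pl_mid$C <- mid$C; pl_mid$A <- mid$A
  segm <- segment_frame(render_lexy_frame(pl_mid, opt), "nucleus_cytosol",
                        seg_params(threshold = "background",
                                   threshold_fraction = 0.01))
  expect_gt(segm$cytosol_mean, cal$cytosol_min - 5)
  expect_lt(segm$cytosol_mean, cal$cytosol_max + 5)

  # identical frames cannot define a dynamic range
  f <- render_lexy_frame(pl, noise_free_optics())
  expect_error(calibrate_range(f, f), "calibration failure")
})

test_that("compartment measurements normalise against the calibrated range", {
  cal <- list(nucleus_min = 20, nucleus_max = 100,
              cytosol_min = 10, cytosol_max = 60)
  seg <- structure(
    list(mode = "nucleus_cytosol", nucleus_mean = 100, cytosol_mean = 35),
    class = "segmentation"
  )
  m <- measure_compartments(seg, 1, cal)
  expect_equal(m$normalised_nucleus, 1.0) # at the calibration maximum
  expect_equal(m$normalised_cytosol, 0.5)
  expect_true(m$contrast_ok)
  expect_equal(m$ratio, 100 / 35)

  # equal compartment means: below the contrast threshold
  seg$nucleus_mean <- seg$cytosol_mean <- 40
  expect_false(measure_compartments(seg, 1, cal)$contrast_ok)

  # missing nucleus: invalid, controller must hold
  seg$nucleus_mean <- NA_real_
  mbad <- measure_compartments(seg, 1, cal)
  expect_false(mbad$valid)
})

test_that("temporal filter bridges invalid frames and defers before first valid", {
  tf <- temporal_filter("hold", 5)
  # before any valid frame: NA (controller start deferred)
  r0 <- filter_update(tf, NA_real_, FALSE)
  expect_true(is.na(r0$value))
  # valid frames pass through unchanged
  r1 <- filter_update(r0$filter, 0.4, TRUE)
  expect_equal(r1$value, 0.4)
  # an invalid frame holds the last valid value
  r2 <- filter_update(r1$filter, 0.9, FALSE)
  expect_equal(r2$value, 0.4)
  # alternating valid/invalid: piecewise constant at the valid values
  vals <- c(0.5, NA, 0.6, NA, 0.7)
  out <- numeric(5)
  f <- tf
  for (i in 1:5) {
    r <- filter_update(f, vals[i], !is.na(vals[i]))
    out[i] <- r$value
    f <- r$filter
  }
  expect_equal(out, c(0.5, 0.5, 0.6, 0.6, 0.7))

  # median mode and the convex-hull property: output never leaves the range
  # of valid measurements seen in the window
  set.seed(31)
  f <- temporal_filter("median", 5)
  seen <- c()
  for (i in 1:100) {
    v <- runif(1)
    ok <- runif(1) > 0.4
    r <- filter_update(f, v, ok)
    f <- r$filter
    if (ok) seen <- tail(c(seen, v), 5)
    if (length(seen)) {
      expect_gte(r$value, min(seen) - 1e-12)
      expect_lte(r$value, max(seen) + 1e-12)
    }
  }
})

test_that("greedy gated tracking keeps identities and spawns/retires tracks", {
  mkseg <- function(pts) {
    structure(list(
      label_mask = matrix(0L, 10, 10),
      centroids = matrix(pts, ncol = 2, byrow = TRUE),
      areas = rep(10L, length(pts) / 2),
      mean_intensities = rep(1, length(pts) / 2),
      background = 0, mode = "cell"
    ), class = "segmentation")
  }
  ts <- track_state(max_step = 10, max_gap = 2)
  # one cell moving 2 um/frame: a single persistent track
  for (fi in 1:10) {
    ts <- track_update(ts, mkseg(c(2 * fi, 0)), fi)
    expect_equal(attr(ts, "assignment"), 1L)
  }
  # disappearing for max_gap + 1 frames closes the track; a new id spawns
  for (fi in 11:13) ts <- track_update(ts, mkseg(numeric()), fi)
  expect_false(ts$tracks$active[1])
  ts <- track_update(ts, mkseg(c(26, 0)), 14)
  expect_equal(attr(ts, "assignment"), 2L)

  # two cells whose swap would require steps beyond the gate: both retired,
  # not swapped
  ts2 <- track_state(max_step = 10, max_gap = 0)
  ts2 <- track_update(ts2, mkseg(c(0, 0, 100, 0)), 1)
  ts2 <- track_update(ts2, mkseg(c(0, 1, 100, 1)), 2)
  expect_equal(attr(ts2, "assignment"), c(1L, 2L))
  # both detections jump to the other's position and beyond the gate
  ts2 <- track_update(ts2, mkseg(c(50, 40, 150, 40)), 3)
  expect_equal(attr(ts2, "assignment"), c(3L, 4L))
  expect_false(any(ts2$tracks$active[1:2]))
})

test_that("identities persist over a long two-cell imaging sequence", {
  # scripted well-separated orbits, rendered and re-detected every frame
  opt <- optics_config(fov_px = c(200, 200), noise = TRUE)
  set.seed(77)
  ts <- track_state(max_step = 10, max_gap = 3)
  ids <- matrix(NA_integer_, 500, 2)
  for (fi in 1:500) {
    th <- 0.02 * fi
    a <- migrating_cell(position = c(60 + 15 * cos(th), 60 + 15 * sin(th)))
    b <- migrating_cell(position = c(140 + 15 * cos(-th), 140 + 15 * sin(-th)))
    seg <- segment_frame(render_migration_frame(list(a, b), opt), "cell")
    ts <- track_update(ts, seg, fi)
    asgn <- attr(ts, "assignment")
    # order labels by x to identify which detection is which cell
    ord <- order(seg$centroids[, 1])
    ids[fi, ] <- asgn[ord]
  }
  expect_equal(unique(ids[, 1]), 1L)
  expect_equal(unique(ids[, 2]), 2L)
})

test_that("corrected total cell fluorescence follows its defining formula", {
  img <- matrix(5, 20, 20)
  cellm <- matrix(FALSE, 20, 20)
  cellm[5:9, 5:9] <- TRUE # 25 px
  bgm <- matrix(FALSE, 20, 20)
  bgm[15:20, 15:20] <- TRUE
  img[cellm] <- 1000 / 25 + 5 # integrated density 1125 over 25 px
  expect_equal(ctcf(img, cellm, bgm), 1000)

  # a uniform image gives zero
  expect_equal(ctcf(matrix(7, 10, 10), disc_mask(c(3, 3), 2, c(10, 10)),
                    disc_mask(c(8, 8), 1.5, c(10, 10))), 0)

  # a rendered cell recovers its total signal
  opt <- optics_config(fov_px = c(160, 160), noise = FALSE)
  mc <- migrating_cell(position = c(80, 80))
  fr <- render_migration_frame(mc, opt)
  cellm2 <- disc_mask(c(80, 80), 30, c(160, 160))
  bgm2 <- !disc_mask(c(80, 80), 45, c(160, 160))
  expect_equal(ctcf(fr$pixels, cellm2, bgm2), mc$expression,
               tolerance = 0.01)

  expect_error(ctcf(img, cellm, cellm), "disjoint")
  expect_error(ctcf(img, cellm, matrix(FALSE, 20, 20)), "background")
})
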
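# Shared fixtures and independent oracles for the test suite.

# dense-sampling brute-force projection oracle: distance from a point to the
# nearest of `n_samples` points placed uniformly in arc length along the
# path (vectorised linear interpolation, independent of project_to_path)
dense_projection_oracle <- function(point, path, n_samples = 1e5) {
  v <- path$vertices
  if (path$closed) v <- rbind(v, v[1, ])
  seglen <- sqrt(rowSums(diff(v)^2))
  arc0 <- c(0, cumsum(seglen))
  L <- arc0[length(arc0)]
  arcs <- seq(0, L, length.out = n_samples)
  i <- findInterval(arcs, arc0, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), nrow(v) - 1)
  t <- (arcs - arc0[i]) / seglen[i]
  x <- v[i, 1] + t * (v[i + 1, 1] - v[i, 1])
  y <- v[i, 2] + t * (v[i + 1, 2] - v[i, 2])
  sqrt(min((x - point[1])^2 + (y - point[2])^2))
}

# random open polyline in a 200 um box
random_path <- function(n_vertices = 10, box = 200) {
  guide_path(cbind(runif(n_vertices, 0, box), runif(n_vertices, 0, box)))
}

rigid_transform <- function(pts, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(pts %*% t(R), 2, -shift)
}

# logical disc mask in a square frame
disc_mask <- function(center, radius, dim = c(96, 96), pixel_size = 1) {
  ii <- (seq_len(dim[1]) - 0.5) * pixel_size
  jj <- (seq_len(dim[2]) - 0.5) * pixel_size
  outer(ii, jj, function(y, x) (x - center[1])^2 + (y - center[2])^2) <= radius^2
}

noise_free_optics <- function(fov = c(96, 96), psf = 1) {
  optics_config(fov_px = fov, psf_sigma = psf, noise = FALSE)
}

# tuned controllers are expensive; compute once per test run
.fixture_env <- new.env()

tuned_schedule <- function() {
  if (is.null(.fixture_env$sched)) {
    .fixture_env$sched <- tune_pid(lexy_plant())
  }
  .fixture_env$sched
}

tuned_nucleus_schedule <- function() {
  if (is.null(.fixture_env$schedn)) {
    .fixture_env$schedn <- tune_pid(lexy_plant(), mode = "nucleus")
  }
  .fixture_env$schedn
}

tuned_fixed_pid <- function() {
  if (is.null(.fixture_env$fixed)) {
    .fixture_env$fixed <- tune_pid(lexy_plant(), operating_points = 0.5)
  }
  .fixture_env$fixed
}

# rotated circle path: starts at a chosen angle (for collision scenarios)
rotated_circle <- function(radius, center, start_deg) {
  th <- (seq(0, 359) + start_deg) * pi / 180
  guide_path(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)),
             closed = TRUE)
}
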
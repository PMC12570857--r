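# Independent brute-force oracles used to pin down the closed-form
# components. These deliberately re-derive each quantity by the most naive
# route available and share no code with the implementation.

# Two-sided signed-rank p by full enumeration of all 2^n sign assignments.
oracle_wilcoxon_p <- function(apical, basal) {
  d <- basal - apical
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) return(1)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Elbow threshold by explicit loop over every distinct candidate intensity,
# with the point-to-chord distance written out from the two-point line form.
oracle_elbow <- function(v) {
  v <- v[is.finite(v) & v > 0]
  if (length(v) < 10) return(0)
  th <- sort(unique(v))
  n <- length(th)
  if (n == 1) return(th)
  cnt <- vapply(th, function(t) sum(v >= t), 0)
  x <- (th - th[1]) / (th[n] - th[1])
  y <- (cnt - cnt[n]) / (cnt[1] - cnt[n])
  # chord through (x1,y1)=(0,1), (x2,y2)=(1,0); signed distance below it
  best <- -Inf; bt <- th[1]
  for (i in seq_len(n)) {
    d <- -((0 - 1) * (1 - y[i]) - (1 - 0) * (0 - x[i])) /
      sqrt((0 - 1)^2 + (1 - 0)^2)
    if (d > best) { best <- d; bt <- th[i] }
  }
  bt
}

# Point-in-polygon by winding angle summation (independent of the
# crossing-number implementation). Only meaningful away from the boundary.
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  ang <- 0
  for (k in seq_len(n)) {
    a <- poly[k, ] - c(px, py)
    b <- poly[if (k == n) 1 else k + 1, ] - c(px, py)
    ang <- ang + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  abs(ang) > pi
}

# Small two-zone synthetic epithelium used by several suites.
make_small_sim <- function(truths, n_pairs = 20, seed = 1, ...) {
  cfg <- sim_config(truths, n_pairs = n_pairs, ...)
  rois <- generate_rois(cfg)
  sim <- simulate_spots(rois, cfg, seed = seed)
  asg <- assign_spots(sim$spots, rois)
  list(config = cfg, rois = rois, sim = sim, assigned = asg,
       cube = count_cube(asg, rois))
}

# Greedy one-to-one matching F1 between retained detections and true spot
# positions (um), within tol.
detection_f1 <- function(detections, true_x, true_y, tol) {
  used <- rep(FALSE, length(true_x))
  tp <- 0L
  for (i in seq_len(nrow(detections))) {
    d <- sqrt((detections$x[i] - true_x)^2 + (detections$y[i] - true_y)^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { tp <- tp + 1L; used[j] <- TRUE }
  }
  fp <- nrow(detections) - tp
  fn <- length(true_x) - tp
  2 * tp / (2 * tp + fp + fn)
}

# One rendered detection instance at the benchmark scale: 6 x 6 grid of spots,
# 1.5 um pitch, sigma 2 px PSF, 0.1 um pixels.
render_grid_instance <- function(snr, seed, n_side = 6, pitch = 1.5,
                                 pixel_size = 0.1, sigma_um = 0.2) {
  g <- expand.grid(x = seq(2, 2 + (n_side - 1) * pitch, pitch),
                   y = seq(2, 2 + (n_side - 1) * pitch, pitch))
  spots <- spot_table(rep("G", nrow(g)), g$x, g$y)
  peak <- pixel_size^2 / (2 * pi * sigma_um^2)
  img <- render_image(spots, sigma_um, pixel_size,
                      noise_sd = if (is.finite(snr)) peak / snr else 0,
                      seed = seed)
  list(img = img, x = g$x, y = g$y, peak = peak,
       sigma_px = sigma_um / pixel_size)
}
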
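#' Maximum intensity projection
#'
#' Collapses a 3D stack to 2D by taking, for each (row, col) pixel, the
#' maximum over the z planes. A single-plane stack projects to itself.
#'
#' @param stack 3D numeric array (row, col, z) or a matrix (returned as-is).
#' @return Numeric matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || any(dim(stack) == 0))
    stop("stack must be a non-empty 3D array or a matrix")
  apply(stack, c(1, 2), max)
}

#' Read a TIFF image or stack
#'
#' Multi-page TIFFs are returned as a (row, col, z) array suitable for
#' [max_project()]; single pages as a matrix.
#'
#' @param path path to a TIFF file.
#' @return Matrix or 3D array.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) == 1) return(pages[[1]])
  simplify2array(pages)
}

log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  g <- seq(-half, half)
  k <- outer(g, g, function(i, j) {
    r2 <- i^2 + j^2
    -(1 / (pi * sigma^4)) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
  })
  k - mean(k)  # zero-sum: flat background gives zero response
}

# Convolution with replicate padding (EBImage::filter2 is FFT/circular,
# so pad the borders ourselves before filtering and crop after).
conv2_replicate <- function(img, kernel) {
  half <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, half), seq_len(nr), rep(nr, half))
  ci <- c(rep(1L, half), seq_len(nc), rep(nc, half))
  padded <- img[ri, ci]
  out <- EBImage::imageData(EBImage::filter2(padded, kernel))
  out[half + seq_len(nr), half + seq_len(nc)]
}

local_maxima <- function(resp) {
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(cbind(row = integer(0), col = integer(0)))
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  ok <- matrix(TRUE, nr - 2, nc - 2)
  # raster-order tie-break: strict > against later neighbors, >= against
  # earlier ones, so exactly one pixel of a flat plateau qualifies
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  for (o in offs) {
    nb <- resp[2:(nr - 1) + o[1], 2:(nc - 1) + o[2]]
    later <- o[2] > 0 || (o[2] == 0 && o[1] > 0)  # column-major "after"
    ok <- ok & if (later) core > nb else core >= nb
  }
  w <- which(ok, arr.ind = TRUE)
  cbind(row = w[, 1] + 1L, col = w[, 2] + 1L)
}

# 2D isotropic Gaussian + constant fit on a window; returns NULL on failure.
fit_gaussian2d <- function(img, row, col, sigma0) {
  row <- as.vector(row); col <- as.vector(col)
  half <- max(2L, ceiling(3 * sigma0))
  rows <- max(1, row - half):min(nrow(img), row + half)
  cols <- max(1, col - half):min(ncol(img), col + half)
  w <- img[rows, cols]
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  b0 <- stats::median(w)
  a0 <- max(w) - b0
  if (a0 <= 0) return(NULL)
  res_fn <- function(p) {
    as.vector(w - (p["b"] + p["A"] *
      exp(-((rr - p["r0"])^2 + (cc - p["c0"])^2) / (2 * p["s"]^2))))
  }
  fit <- suppressWarnings(tryCatch(
    minpack.lm::nls.lm(par = c(A = a0, r0 = row, c0 = col, s = sigma0, b = b0),
                       fn = res_fn,
                       lower = c(A = 0, r0 = min(rows) - 1, c0 = min(cols) - 1,
                                 s = 0.3, b = -Inf),
                       upper = c(A = Inf, r0 = max(rows) + 1, c0 = max(cols) + 1,
                                 s = 4 * half, b = Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL))
  if (is.null(fit) || fit$info %in% c(0, 5)) return(NULL)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["A"]] <= 0 || cf[["s"]] <= 0) return(NULL)
  as.list(cf)
}

#' Detect candidate spots in a 2D image
#'
#' Laplacian-of-Gaussian blob response at the expected scale, local-maximum
#' candidate selection, and a per-candidate isotropic Gaussian fit yielding
#' sub-pixel position, amplitude, and FWHM diameter. All candidates above
#' background (positive blob response) are returned unthresholded, sorted by
#' decreasing intensity (ties broken by row, then column); pass the result to
#' [auto_threshold()] to separate signal from noise.
#'
#' The `intensity` used for ranking and thresholding is the scale-normalized
#' LoG response at the candidate — the statistic the detection filter
#' maximizes for a matched blob, and far more stable on noise-only maxima
#' than a free Gaussian fit (whose amplitude diverges without a real spot
#' underneath). The fitted amplitude is reported separately as `amplitude`.
#'
#' @param image numeric matrix; attributes `pixel_size`/`origin` (as set by
#'   [render_image()]) are honoured when converting to micrometres.
#' @param expected_sigma expected PSF standard deviation in pixels (>= 0.5).
#' @param pixel_size pixel edge in um (default taken from the image
#'   attribute, else 1).
#' @return `data.frame` with columns `x`, `y` (um), `row`, `col` (pixels),
#'   `intensity` (LoG response), `amplitude` (fitted peak amplitude, `NA`
#'   when the fit failed), `diameter` (FWHM, um; `NA` when the fit failed).
#' @export
detect_candidates <- function(image, expected_sigma, pixel_size = NULL) {
  stopifnot(is.matrix(image))
  if (expected_sigma < 0.5) stop("expected_sigma must be >= 0.5 pixels")
  if (is.null(pixel_size))
    pixel_size <- attr(image, "pixel_size") %||% 1
  origin <- attr(image, "origin") %||% c(0, 0)
  empty <- data.frame(x = numeric(0), y = numeric(0), row = integer(0),
                      col = integer(0), intensity = numeric(0),
                      amplitude = numeric(0), diameter = numeric(0))
  if (all(image == image[1])) return(empty)
  resp <- conv2_replicate(image, -log_kernel(expected_sigma) * expected_sigma^2)
  lm <- local_maxima(resp)
  if (nrow(lm) == 0) return(empty)
  # background floor: keep maxima with positive blob response
  keep <- resp[lm] > 0
  lm <- lm[keep, , drop = FALSE]
  if (nrow(lm) == 0) return(empty)
  out <- lapply(seq_len(nrow(lm)), function(i) {
    r <- lm[i, 1]; cl <- lm[i, 2]
    fit <- fit_gaussian2d(image, r, cl, expected_sigma)
    if (is.null(fit)) {
      data.frame(row = r, col = cl, r0 = r, c0 = cl,
                 intensity = resp[r, cl], amplitude = NA_real_,
                 diameter = NA_real_)
    } else {
      data.frame(row = r, col = cl, r0 = fit$r0, c0 = fit$c0,
                 intensity = resp[r, cl], amplitude = fit$A,
                 diameter = 2 * sqrt(2 * log(2)) * fit$s * pixel_size)
    }
  })
  out <- do.call(rbind, out)
  out$x <- origin[1] + (out$c0 - 0.5) * pixel_size
  out$y <- origin[2] + (out$r0 - 0.5) * pixel_size
  out <- out[order(-out$intensity, out$row, out$col), ]
  rownames(out) <- NULL
  out[, c("x", "y", "row", "col", "intensity", "amplitude", "diameter")]
}

#' Automatic detection threshold at the evidential drop
#'
#' Operationalizes the elbow ("evidential drop") of the
#' detections-retained-versus-threshold curve: false positives
#' (low-intensity noise) vanish quickly as the threshold rises while true
#' positives decay slowly, and the threshold is placed at the point of
#' maximum perpendicular distance between the (threshold, retained-count)
#' curve and the chord joining its endpoints, on the convex (below-chord)
#' side where the drop lives. Thresholds are evaluated at the distinct
#' candidate intensities, both axes normalized to \[0, 1\] before the
#' distance is taken; ties go to the lower threshold. The companion
#' methods vignette motivates the linear threshold axis and the one-sided
#' distance.
#'
#' @param intensities numeric vector of candidate intensities (or a
#'   candidate data.frame from [detect_candidates()]).
#' @return The intensity threshold; candidates with intensity >= threshold
#'   are retained. With fewer than 10 candidates, 0 with a warning.
#' @export
auto_threshold <- function(intensities) {
  if (is.data.frame(intensities)) intensities <- intensities$intensity
  intensities <- intensities[is.finite(intensities) & intensities > 0]
  if (length(intensities) < 10) {
    warning("fewer than 10 candidates; threshold set to 0")
    return(0)
  }
  th <- sort(unique(intensities))
  if (length(th) == 1) return(th)
  counts <- vapply(th, function(t) sum(intensities >= t), 0)
  x <- (th - th[1]) / (th[length(th)] - th[1])
  y <- (counts - counts[length(counts)]) /
    (counts[1] - counts[length(counts)])
  # signed distance below the chord (0,1)-(1,0); the evidential drop is the
  # convex knee, so only below-chord excursions count
  d <- (1 - x - y) / sqrt(2)
  th[which.max(d)]
}

#' Measure a focus diameter by Gaussian fitting
#'
#' Fits a 2D isotropic Gaussian (free sigma, constant background) in a
#' window of about 6 expected sigma around the spot and reports the
#' full width at half maximum, `2 * sqrt(2 * log(2)) * sigma * pixel_size`.
#'
#' @param image numeric matrix.
#' @param row,col pixel position of the spot (e.g. from
#'   [detect_candidates()]).
#' @param pixel_size pixel edge, um.
#' @param expected_sigma initial sigma in pixels (sets the fit window).
#' @return FWHM in micrometres, or `NA` (with a warning) when the fit does
#'   not converge.
#' @export
measure_focus_diameter <- function(image, row, col, pixel_size,
                                   expected_sigma = 2) {
  stopifnot(row >= 1, row <= nrow(image), col >= 1, col <= ncol(image))
  fit <- fit_gaussian2d(image, round(row), round(col), expected_sigma)
  if (is.null(fit)) {
    warning("Gaussian fit did not converge; diameter is NA")
    return(NA_real_)
  }
  2 * sqrt(2 * log(2)) * fit$s * pixel_size
}

#' Classify foci as RNA granules by diameter
#'
#' A focus counts as a granule when its diameter strictly exceeds the
#' cutoff (default 0.5 um); a diffraction-limited single molecule
#' (about 0.2 um) does not.
#'
#' @param diameters numeric vector of focus diameters, um (`NA`s allowed,
#'   flagged `NA`).
#' @param cutoff diameter cutoff, um.
#' @return List with `is_granule` (logical per focus), `n_granules`, and
#'   `mean_diameter` (over non-missing diameters).
#' @export
classify_granules <- function(diameters, cutoff = 0.5) {
  if (length(diameters) == 0)
    return(list(is_granule = logical(0), n_granules = 0L,
                mean_diameter = NA_real_))
  if (any(diameters <= 0, na.rm = TRUE)) stop("diameters must be positive")
  flags <- diameters > cutoff
  list(is_granule = flags,
       n_granules = sum(flags, na.rm = TRUE),
       mean_diameter = mean(diameters, na.rm = TRUE))
}
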
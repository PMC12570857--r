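#' Ground truth for one simulated gene
#'
#' Describes how a gene behaves in the synthetic epithelium: how many
#' molecules a paired region expresses on average, what fraction of them fall
#' on the apical side (optionally zone-dependent), and whether molecules
#' aggregate into foci ("granules") of a given diameter.
#'
#' @param gene gene symbol.
#' @param apical_prob probability that a molecule falls in the apical half.
#'   Either a single number or a named vector keyed by zone label (entries
#'   named `"default"` or unnamed serve as the fallback), enabling
#'   zone-dependent bias switching.
#' @param mean_molecules expected molecules per paired region (Poisson mean).
#' @param granule_fraction fraction of molecules emitted inside foci.
#' @param granule_diameter focus diameter (FWHM of the molecule cloud), um.
#' @param granule_multiplicity molecules per focus.
#' @return A `gene_truth` list.
#' @export
gene_truth <- function(gene, apical_prob = 0.5, mean_molecules = 50,
                       granule_fraction = 0, granule_diameter = 0.6,
                       granule_multiplicity = 5) {
  stopifnot(is.character(gene), nzchar(gene),
            all(apical_prob >= 0 & apical_prob <= 1),
            mean_molecules >= 0, granule_fraction >= 0, granule_fraction <= 1,
            granule_multiplicity >= 1)
  if (granule_fraction > 0 && granule_diameter <= 0)
    stop("granule_diameter must be > 0 when granule_fraction > 0")
  structure(list(gene = gene, apical_prob = apical_prob,
                 mean_molecules = mean_molecules,
                 granule_fraction = granule_fraction,
                 granule_diameter = granule_diameter,
                 granule_multiplicity = granule_multiplicity),
            class = "gene_truth")
}

truth_apical_prob <- function(truth, zone) {
  p <- truth$apical_prob
  if (is.null(names(p))) return(unname(p[1]))
  if (zone %in% names(p)) return(unname(p[[zone]]))
  if ("default" %in% names(p)) return(unname(p[["default"]]))
  unname(p[[1]])
}

#' Configuration of a synthetic epithelium
#'
#' The defaults encode the conditions the shipped validation analyses
#' assume: 149 paired regions (each an apical/basal half of one measured
#' region), enterocyte-scale 10 x 20 um rectangular cells, and no background
#' noise unless asked for.
#'
#' @param genes list of [gene_truth()] objects.
#' @param n_pairs number of paired regions (default 149).
#' @param zone_layout optional named integer vector of pairs per zone, in
#'   order (must sum to `n_pairs`); default assigns every pair zone `"none"`.
#' @param cell_width,cell_height cell rectangle dimensions, um.
#' @param background_rate unbiased noise spots per um^2, genes drawn
#'   uniformly from the panel.
#' @param seed optional integer seed stored with the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genes, n_pairs = 149, zone_layout = NULL,
                       cell_width = 10, cell_height = 20,
                       background_rate = 0, seed = NULL) {
  stopifnot(n_pairs >= 1, cell_width > 0, cell_height > 0, background_rate >= 0)
  if (inherits(genes, "gene_truth")) genes <- list(genes)
  stopifnot(length(genes) >= 1,
            all(vapply(genes, inherits, TRUE, "gene_truth")))
  if (!is.null(zone_layout)) {
    if (sum(zone_layout) != n_pairs)
      stop("zone_layout must sum to n_pairs")
  }
  structure(list(genes = genes, n_pairs = n_pairs, zone_layout = zone_layout,
                 cell_width = cell_width, cell_height = cell_height,
                 background_rate = background_rate, seed = seed),
            class = "sim_config")
}

#' Generate the ROI pairs of a synthetic epithelium
#'
#' Each pair is a `cell_width` x `cell_height` rectangle split across its
#' long axis into two equal halves; the half with the larger coordinate along
#' the long axis is the apical one. Cells are laid out in a row with a 2 um
#' gap. Volumes are set to the polygon areas (units `"um2"`).
#'
#' @param config a [sim_config()].
#' @return An [roi_set()] with `2 * n_pairs` ROIs.
#' @export
generate_rois <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$cell_width; h <- config$cell_height
  gap <- 2
  zones <- if (is.null(config$zone_layout)) rep("none", config$n_pairs)
           else rep(names(config$zone_layout), config$zone_layout)
  rows <- list(); polys <- list()
  for (i in seq_len(config$n_pairs)) {
    x0 <- (i - 1) * (w + gap)
    pid <- sprintf("P%04d", i)
    if (h >= w) {  # long axis vertical: apical = upper half
      basal  <- cbind(c(x0, x0 + w, x0 + w, x0), c(0, 0, h / 2, h / 2))
      apical <- cbind(c(x0, x0 + w, x0 + w, x0), c(h / 2, h / 2, h, h))
    } else {       # long axis horizontal: apical = right half
      basal  <- cbind(c(x0, x0 + w / 2, x0 + w / 2, x0), c(0, 0, h, h))
      apical <- cbind(c(x0 + w / 2, x0 + w, x0 + w, x0 + w / 2), c(0, 0, h, h))
    }
    for (side in c("apical", "basal")) {
      poly <- if (side == "apical") apical else basal
      id <- paste0(pid, "_", substr(side, 1, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        roi_id = id, pair_id = pid, subregion = side, zone = zones[i],
        volume = polygon_area(poly), stringsAsFactors = FALSE)
      polys[[id]] <- poly
    }
  }
  roi_set(do.call(rbind, rows), polys, units = "um2")
}

# Place `n` molecules of which a binomial fraction sit in Gaussian foci.
place_molecules <- function(n, poly, truth) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  n_gran <- if (truth$granule_fraction > 0)
    stats::rbinom(1, n, truth$granule_fraction) else 0L
  pts <- runif_in_polygon(n - n_gran, poly)
  if (n_gran > 0) {
    sdv <- truth$granule_diameter / (2 * sqrt(2 * log(2)))
    n_foci <- ceiling(n_gran / truth$granule_multiplicity)
    centers <- runif_in_polygon(n_foci, poly)
    sizes <- rep(floor(n_gran / n_foci), n_foci)
    extra <- n_gran - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    for (k in seq_len(n_foci)) {
      if (sizes[k] == 0) next
      gx <- stats::rnorm(sizes[k], centers[k, 1], sdv)
      gy <- stats::rnorm(sizes[k], centers[k, 2], sdv)
      # truncate to the owning polygon: resample strays, fall back to center
      for (tries in 1:20) {
        out <- !points_in_polygon(gx, gy, poly)
        if (!any(out)) break
        gx[out] <- stats::rnorm(sum(out), centers[k, 1], sdv)
        gy[out] <- stats::rnorm(sum(out), centers[k, 2], sdv)
      }
      out <- !points_in_polygon(gx, gy, poly)
      gx[out] <- centers[k, 1]; gy[out] <- centers[k, 2]
      pts <- rbind(pts, cbind(x = gx, y = gy))
    }
  }
  pts
}

#' Simulate a spot table over an ROI set
#'
#' For every pair and gene the molecule count is Poisson with the gene's
#' `mean_molecules`; each molecule falls apical with the zone's
#' `apical_prob` and is placed uniformly inside the chosen half (or inside a
#' Gaussian focus when granules are configured, with the focus kept entirely
#' in one subregion). Background spots, when configured, are uniform over
#' both halves with genes drawn uniformly from the panel. Identical seed and
#' config give an identical spot table.
#'
#' @param rois an [roi_set()], e.g. from [generate_rois()].
#' @param truths list of [gene_truth()] objects (or a [sim_config()]).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param background_rate spots per um^2 of unbiased noise (overrides the
#'   config value when `truths` is a `sim_config`).
#' @return List with `spots` (a spot table carrying the generating
#'   `pair_id`/`subregion` as `true_pair_id`/`true_subregion`) and `truth`
#'   (per gene x pair realized apical/basal molecule counts).
#' @export
simulate_spots <- function(rois, truths, seed = NULL, background_rate = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  if (inherits(truths, "sim_config")) {
    if (is.null(background_rate)) background_rate <- truths$background_rate
    truths <- truths$genes
  }
  if (is.null(background_rate)) background_rate <- 0
  if (inherits(truths, "gene_truth")) truths <- list(truths)
  if (!is.null(seed)) set.seed(seed)
  genes <- vapply(truths, `[[`, "", "gene")
  info <- rois$info
  pair_ids <- unique(info$pair_id)
  sx <- list(); sy <- list(); sg <- list(); sp <- list(); ss <- list()
  tr <- list()
  for (pid in pair_ids) {
    sub <- info[info$pair_id == pid, ]
    zone <- sub$zone[1]
    apoly <- rois$polygons[[sub$roi_id[sub$subregion == "apical"]]]
    bpoly <- rois$polygons[[sub$roi_id[sub$subregion == "basal"]]]
    n_tot <- stats::rpois(length(truths),
                          vapply(truths, `[[`, 0, "mean_molecules"))
    p_ap <- vapply(truths, truth_apical_prob, 0, zone = zone)
    n_ap <- stats::rbinom(length(truths), n_tot, p_ap)
    n_ba <- n_tot - n_ap
    for (side in c("apical", "basal")) {
      counts <- if (side == "apical") n_ap else n_ba
      poly <- if (side == "apical") apoly else bpoly
      tot <- sum(counts)
      if (tot == 0 && background_rate == 0) next
      pts <- do.call(rbind, lapply(seq_along(truths), function(g)
        place_molecules(counts[g], poly, truths[[g]])))
      gvec <- rep(genes, counts)
      if (background_rate > 0) {
        nb <- stats::rpois(1, background_rate * polygon_area(poly))
        if (nb > 0) {
          bpts <- runif_in_polygon(nb, poly)
          pts <- rbind(pts, bpts)
          gvec <- c(gvec, sample(genes, nb, replace = TRUE))
        }
      }
      if (is.null(pts) || nrow(pts) == 0) next
      sx[[length(sx) + 1L]] <- pts[, 1]; sy[[length(sy) + 1L]] <- pts[, 2]
      sg[[length(sg) + 1L]] <- gvec
      sp[[length(sp) + 1L]] <- rep(pid, length(gvec))
      ss[[length(ss) + 1L]] <- rep(side, length(gvec))
    }
    tr[[length(tr) + 1L]] <- data.frame(
      gene = genes, pair_id = pid, zone = zone,
      n_apical = n_ap, n_basal = n_ba, stringsAsFactors = FALSE)
  }
  spots <- data.frame(gene = unlist(sg) %||% character(0),
                      x = unlist(sx) %||% numeric(0),
                      y = unlist(sy) %||% numeric(0),
                      true_pair_id = unlist(sp) %||% character(0),
                      true_subregion = unlist(ss) %||% character(0),
                      stringsAsFactors = FALSE)
  list(spots = validate_spot_table(spots), truth = do.call(rbind, tr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a fluorescence image of simulated spots
#'
#' Each molecule contributes an isotropic 2D Gaussian point-spread function
#' of standard deviation `psf_sigma` and unit integrated intensity; optional
#' additive Gaussian read noise is applied per pixel. The pixel grid covers
#' the bounding box of the supplied polygons (or of the spots), padded by
#' 3 sigma.
#'
#' @param spots spot table (coordinates um) of the molecules to render.
#' @param psf_sigma PSF standard deviation, um.
#' @param pixel_size pixel edge, um.
#' @param noise_sd standard deviation of additive read noise, arbitrary units.
#' @param seed integer seed for the noise.
#' @param polygons optional list of polygons whose joint bounding box sets
#'   the field of view.
#' @return Numeric matrix (rows = y, cols = x) with attributes `pixel_size`
#'   and `origin` (um coordinates of the image corner).
#' @export
render_image <- function(spots, psf_sigma, pixel_size, noise_sd = 0,
                         seed = NULL, polygons = NULL) {
  stopifnot(psf_sigma > 0, pixel_size > 0)
  if (!is.null(seed)) set.seed(seed)
  pad <- 3 * psf_sigma
  if (!is.null(polygons)) {
    allv <- do.call(rbind, polygons)
    xr <- range(allv[, 1]); yr <- range(allv[, 2])
  } else if (nrow(spots)) {
    xr <- range(spots$x); yr <- range(spots$y)
  } else {
    xr <- c(0, 10); yr <- c(0, 10)
  }
  x0 <- xr[1] - pad; y0 <- yr[1] - pad
  nc <- max(1L, ceiling((xr[2] + pad - x0) / pixel_size))
  nr <- max(1L, ceiling((yr[2] + pad - y0) / pixel_size))
  img <- matrix(0, nr, nc)
  sig_px <- psf_sigma / pixel_size
  half <- ceiling(4 * sig_px)
  norm <- pixel_size^2 / (2 * pi * psf_sigma^2)  # unit integrated intensity
  for (i in seq_len(nrow(spots))) {
    cx <- (spots$x[i] - x0) / pixel_size + 0.5  # pixel-center coordinates
    cy <- (spots$y[i] - y0) / pixel_size + 0.5
    cols <- max(1, floor(cx - half)):min(nc, ceiling(cx + half))
    rows <- max(1, floor(cy - half)):min(nr, ceiling(cy + half))
    gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
    gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
    img[rows, cols] <- img[rows, cols] + norm * outer(gy, gx)
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  attr(img, "pixel_size") <- pixel_size
  attr(img, "origin") <- c(x0, y0)
  img
}
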
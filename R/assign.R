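#' Assign spots to apical/basal ROIs
#'
#' Labels every spot with the subregion and pair of the polygon that
#' contains it. Containment is boundary inclusive; a spot falling inside
#' more than one polygon is resolved deterministically: apical beats basal,
#' then the lexicographically lowest `roi_id` wins. Spots in no polygon are
#' labeled `"unassigned"` — a legal outcome, not an error.
#'
#' @param spots a spot table ([spot_table()]/[read_spot_table()]).
#' @param rois a validated [roi_set()].
#' @return The spot table with `subregion`, `pair_id`, and `roi_id` columns
#'   filled in.
#' @export
assign_spots <- function(spots, rois) {
  spots <- validate_spot_table(spots)
  stopifnot(inherits(rois, "roi_set"))
  n <- nrow(spots)
  sub <- rep("unassigned", n)
  pid <- rep(NA_character_, n)
  rid <- rep(NA_character_, n)
  info <- rois$info
  # processing order implements the tie rule: apical first, then roi_id
  ord <- order(info$subregion != "apical", info$roi_id)
  for (i in ord) {
    poly <- rois$polygons[[info$roi_id[i]]]
    todo <- which(sub == "unassigned")
    if (!length(todo)) break
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    cand <- todo[spots$x[todo] >= xr[1] - 1e-9 & spots$x[todo] <= xr[2] + 1e-9 &
                 spots$y[todo] >= yr[1] - 1e-9 & spots$y[todo] <= yr[2] + 1e-9]
    if (!length(cand)) next
    hit <- cand[points_in_polygon(spots$x[cand], spots$y[cand], poly)]
    sub[hit] <- info$subregion[i]
    pid[hit] <- info$pair_id[i]
    rid[hit] <- info$roi_id[i]
  }
  spots$subregion <- sub
  spots$pair_id <- pid
  spots$roi_id <- rid
  spots
}

#' Volume-normalized count cube
#'
#' Tabulates assigned spots into a gene x pair x subregion array of counts
#' divided by the owning ROI's volume (or area): spots per um^3 (or um^2).
#' Genes absent from a pair get zero.
#'
#' @param assigned spot table with `subregion`/`pair_id` filled (see
#'   [assign_spots()]); unassigned spots are ignored.
#' @param rois the [roi_set()] supplying volumes.
#' @param genes optional gene universe (default: genes present in
#'   `assigned`, sorted).
#' @return 3D array with dimnames (gene, pair, subregion) and class
#'   `count_cube`; attribute `units` records the denominator's units.
#' @export
count_cube <- function(assigned, rois, genes = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  if (!"subregion" %in% names(assigned))
    stop("spots are not assigned; run assign_spots() first")
  info <- rois$info
  if (any(!is.finite(info$volume) | info$volume <= 0))
    stop("zero or missing volume for ROI(s): ",
         paste(info$roi_id[!is.finite(info$volume) | info$volume <= 0],
               collapse = ", "))
  pairs <- sort(unique(info$pair_id))
  if (is.null(genes)) genes <- sort(unique(assigned$gene))
  keep <- assigned$subregion %in% c("apical", "basal") &
    assigned$gene %in% genes & assigned$pair_id %in% pairs
  a <- assigned[keep, , drop = FALSE]
  cube <- array(0, dim = c(length(genes), length(pairs), 2),
                dimnames = list(gene = genes, pair = pairs,
                                subregion = c("apical", "basal")))
  if (nrow(a)) {
    tab <- table(factor(a$gene, genes), factor(a$pair_id, pairs),
                 factor(a$subregion, c("apical", "basal")))
    cube[] <- as.numeric(tab)
  }
  vol <- matrix(NA_real_, length(pairs), 2,
                dimnames = list(pairs, c("apical", "basal")))
  for (i in seq_len(nrow(info)))
    vol[info$pair_id[i], info$subregion[i]] <- info$volume[i]
  for (s in c("apical", "basal"))
    cube[, , s] <- sweep(cube[, , s, drop = FALSE], 2, vol[, s], "/")
  attr(cube, "units") <- rois$units
  class(cube) <- c("count_cube", class(cube))
  cube
}

#' @export
print.count_cube <- function(x, ...) {
  d <- dim(x)
  cat("count_cube:", d[1], "genes x", d[2], "pairs x apical/basal;",
      "normalized per", attr(x, "units") %||% "um3", "\n")
  invisible(x)
}

#' Signed centerline offsets (apico-basal gradient statistic)
#'
#' For every spot of one cell, computes the perpendicular distance to the
#' cell's centerline, signs it by side (positive toward the apical side, as
#' determined by the apical subregion centroid), and normalizes by the
#' maximum ROI width measured perpendicular to the centerline (sampled at
#' 100 evenly spaced centerline points). For a straight centerline through a
#' cell, spots on the apical boundary score +0.5 and spots on the centerline
#' score 0.
#'
#' @param spots spot table of one cell.
#' @param centerline 2-column vertex matrix (>= 2 distinct vertices), um.
#' @param polygon the cell outline polygon.
#' @param apical_ref point (x, y) on the apical side, typically the apical
#'   subregion centroid; defines the positive direction.
#' @return `data.frame` with `offset` (signed, normalized), `distance` (um,
#'   unsigned), and the `max_width` used (as an attribute).
#' @export
gradient_offsets <- function(spots, centerline, polygon, apical_ref) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2) stop("centerline needs >= 2 vertices")
  segs <- cbind(centerline[-nrow(centerline), , drop = FALSE],
                centerline[-1, , drop = FALSE])
  lens <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  if (all(lens == 0)) stop("degenerate (zero-length) centerline")
  segs <- segs[lens > 0, , drop = FALSE]
  lens <- lens[lens > 0]

  nearest_signed <- function(x, y) {
    best_d <- rep(Inf, length(x)); best_s <- rep(0, length(x))
    for (k in seq_len(nrow(segs))) {
      r <- dist_points_segment(x, y, segs[k, 1:2], segs[k, 3:4])
      upd <- r$dist < best_d - 1e-12
      best_s[upd] <- r$side[upd]
      best_d[upd] <- r$dist[upd]
    }
    list(dist = best_d, side = best_s)
  }

  # orientation: the apical reference point defines the positive side
  ap <- nearest_signed(apical_ref[1], apical_ref[2])
  orient <- if (ap$side >= 0) 1 else -1

  # maximum ROI width perpendicular to the local centerline direction
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  samp <- seq(0, total, length.out = 100)
  widths <- vapply(samp, function(s) {
    k <- max(1L, min(nrow(segs), findInterval(s, cum, rightmost.closed = TRUE)))
    t <- if (lens[k] > 0) (s - cum[k]) / lens[k] else 0
    org <- c(segs[k, 1] + t * (segs[k, 3] - segs[k, 1]),
             segs[k, 2] + t * (segs[k, 4] - segs[k, 2]))
    dir <- c(segs[k, 3] - segs[k, 1], segs[k, 4] - segs[k, 2]) / lens[k]
    line_polygon_chord(org, c(-dir[2], dir[1]), polygon)
  }, 0)
  max_width <- max(widths)
  if (max_width <= 0) stop("could not measure ROI width")

  r <- nearest_signed(spots$x, spots$y)
  out <- data.frame(offset = orient * r$side * r$dist / max_width,
                    distance = r$dist)
  attr(out, "max_width") <- max_width
  out
}
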
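#' Region-of-interest sets
#'
#' An `roi_set` bundles the polygonal regions the analysis consumes: each
#' measured region is one apical and one basal polygon sharing a `pair_id`,
#' carrying a zone label and a normalization volume (um^3) or area (um^2,
#' declared via `units`).
#'
#' @param info data.frame with columns `roi_id`, `pair_id`, `subregion`,
#'   `zone`, `volume`.
#' @param polygons named list of vertex matrices (names = `roi_id`).
#' @param units `"um3"` (volumes) or `"um2"` (areas); the value is used as
#'   the count-normalization denominator either way.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(info, polygons, units = c("um3", "um2")) {
  units <- match.arg(units)
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  req <- c("roi_id", "pair_id", "subregion", "zone", "volume")
  miss <- setdiff(req, names(info))
  if (length(miss)) stop("roi info missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(info$roi_id)) stop("duplicated roi_id")
  if (!all(info$subregion %in% c("apical", "basal")))
    stop("subregion must be 'apical' or 'basal'")
  zones_ok <- c("crypt", "villus_bottom", "villus_middle", "villus_top",
                "crypt_bottom", "crypt_top", "organoid", "none")
  bad <- setdiff(unique(info$zone), zones_ok)
  if (length(bad)) stop("unknown zone label(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(info$volume) | info$volume <= 0))
    stop("volume must be positive for every ROI")
  if (!setequal(names(polygons), info$roi_id))
    stop("polygon names must match roi_id")
  for (id in info$roi_id) {
    p <- check_polygon_matrix(polygons[[id]])
    if (polygon_area(p) <= 0) stop("polygon of ROI '", id, "' has zero area")
    if (!polygon_is_simple(p)) stop("polygon of ROI '", id, "' is self-intersecting")
    polygons[[id]] <- p
  }
  # complete apical/basal pairs
  tab <- table(info$pair_id, factor(info$subregion, c("apical", "basal")))
  bad <- rownames(tab)[tab[, "apical"] != 1 | tab[, "basal"] != 1]
  if (length(bad))
    stop("pair_id(s) without exactly one apical and one basal ROI: ",
         paste(bad, collapse = ", "))
  structure(list(info = info, polygons = polygons[info$roi_id], units = units),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", nrow(x$info), "ROIs /", length(unique(x$info$pair_id)),
      "pairs; units:", x$units, "\n")
  zt <- table(x$info$zone[x$info$subregion == "apical"])
  cat("zones:", paste(sprintf("%s=%d", names(zt), zt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.roi_set <- function(x, ...) x$info

#' Read an ROI set from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with properties `roi_id`,
#' `pair_id`, `subregion`, `zone`, `volume`; an optional top-level `units`
#' member declares whether `volume` is um^3 or um^2 (default `"um3"`).
#' Coordinates are micrometres; any CRS member is ignored. Pair completeness
#' and polygon simplicity are validated on read, so any set accepted here is
#' safe for downstream assignment.
#'
#' @param path path to a GeoJSON file.
#' @return An [roi_set()].
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  units <- if (!is.null(gj$units)) gj$units else "um3"
  rows <- list(); polys <- list()
  for (f in gj$features) {
    pr <- f$properties
    for (k in c("roi_id", "pair_id", "subregion", "zone", "volume"))
      if (is.null(pr[[k]])) stop("feature missing property '", k, "'")
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature '", pr$roi_id, "' is not a Polygon")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    # drop the GeoJSON closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = pr$roi_id, pair_id = pr$pair_id, subregion = pr$subregion,
      zone = pr$zone, volume = as.numeric(pr$volume), stringsAsFactors = FALSE)
    polys[[pr$roi_id]] <- m
  }
  roi_set(do.call(rbind, rows), polys, units = units)
}

#' Write an ROI set to GeoJSON
#'
#' Inverse of [read_roi_set()]; mainly used to persist synthetic ROI sets.
#'
#' @param rois an [roi_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  feats <- lapply(seq_len(nrow(rois$info)), function(i) {
    r <- rois$info[i, ]
    poly <- rois$polygons[[r$roi_id]]
    ring <- lapply(seq_len(nrow(poly)), function(k) c(poly[k, 1], poly[k, 2]))
    ring[[length(ring) + 1L]] <- ring[[1]]
    list(type = "Feature",
         properties = list(roi_id = r$roi_id, pair_id = r$pair_id,
                           subregion = r$subregion, zone = r$zone,
                           volume = r$volume),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", units = rois$units, features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read centerlines from GeoJSON
#'
#' LineString features with a `pair_id` property; returns a named list of
#' vertex matrices used by [gradient_offsets()].
#'
#' @param path path to a GeoJSON file.
#' @return Named list of 2-column matrices.
#' @export
read_centerlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "LineString")) next
    id <- f$properties$pair_id
    if (is.null(id)) stop("centerline feature missing pair_id")
    out[[id]] <- do.call(rbind, lapply(f$geometry$coordinates,
                                       function(v) c(v[[1]], v[[2]])))
  }
  out
}
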
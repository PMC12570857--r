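#' Per-zone localization profiles
#'
#' Runs [localize()] independently within each zone's ROI pairs (the range
#' denominator is recomputed per zone, so each zone's scores are internally
#' comparable) and assembles a long gene x zone profile table. Zones with
#' fewer than 2 pairs are skipped with a warning.
#'
#' @param cube a [count_cube()] over all pairs.
#' @param rois the [roi_set()] carrying the zone label of each pair.
#' @param zones zone labels to analyze, in axis order (default: the zones
#'   present, in first-appearance order).
#' @param params a [score_params()].
#' @return `data.frame` of class `zone_profiles` with columns `gene`,
#'   `zone`, `score`, `class`, `p_raw`, `p_adj`, `n_pairs`.
#' @export
per_zone_scores <- function(cube, rois, zones = NULL, params = score_params()) {
  stopifnot(inherits(cube, "count_cube"), inherits(rois, "roi_set"))
  info <- rois$info[rois$info$subregion == "apical", ]  # one row per pair
  pair_zone <- stats::setNames(info$zone, info$pair_id)
  if (is.null(zones)) zones <- unique(info$zone)
  out <- list()
  for (z in zones) {
    zp <- names(pair_zone)[pair_zone == z]
    zp <- intersect(zp, dimnames(cube)$pair)
    if (length(zp) < 2) {
      warning("zone '", z, "' has fewer than 2 pairs; skipped")
      next
    }
    fit <- localize(cube, params = params, pairs = zp)
    r <- fit$results
    out[[z]] <- data.frame(gene = r$gene, zone = z, score = r$score,
                           class = r$class, p_raw = r$p_raw, p_adj = r$p_adj,
                           n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no zone with >= 2 pairs")
  profiles <- do.call(rbind, out)
  rownames(profiles) <- NULL
  class(profiles) <- c("zone_profiles", class(profiles))
  profiles
}

#' Genes switching localization class between zones
#'
#' Returns the genes classified apical (score below the apical threshold)
#' in `from_zone` and basal (score above the basal threshold) in `to_zone`.
#' Both inequalities are strict, so boundary scores never transition. Swap
#' the arguments for the opposite direction; the two directions are
#' disjoint.
#'
#' @param profiles a [per_zone_scores()] table.
#' @param from_zone,to_zone zone labels present in `profiles`.
#' @param params a [score_params()] supplying the thresholds.
#' @return Character vector of gene symbols.
#' @export
find_transitions <- function(profiles, from_zone, to_zone,
                             params = score_params()) {
  for (z in c(from_zone, to_zone))
    if (!z %in% profiles$zone) stop("zone '", z, "' not in profiles")
  a <- profiles[profiles$zone == from_zone, ]
  b <- profiles[profiles$zone == to_zone, ]
  shared <- intersect(a$gene, b$gene)
  sa <- stats::setNames(a$score, a$gene)[shared]
  sb <- stats::setNames(b$score, b$gene)[shared]
  shared[sa < params$apical_threshold & sb > params$basal_threshold]
}

go_categories <- c("Nutrient sensing & digesting",
                   "Apical membrane receptor & receptor binding",
                   "Basal membrane receptor & receptor binding",
                   "Pathogen defense",
                   "Junctional & cytoskeletal",
                   "Other")

#' GO-category priority presets
#'
#' Ordered category lists used to collapse multiple GO-category memberships
#' to a single label. The `sequencing` preset prioritizes
#' Nutrient sensing & digesting > Apical membrane receptor & receptor
#' binding > Pathogen defense > Junctional & cytoskeletal > Other; the
#' `imaging` preset puts Basal membrane receptor & receptor binding first,
#' then Apical membrane receptor & receptor binding, Nutrient sensing &
#' digesting, Pathogen defense, Junctional & cytoskeletal, Other.
#'
#' @param preset `"imaging"` or `"sequencing"`.
#' @return Ordered character vector of category labels (`Other` last).
#' @export
category_priority <- function(preset = c("imaging", "sequencing")) {
  preset <- match.arg(preset)
  switch(preset,
    sequencing = c("Nutrient sensing & digesting",
                   "Apical membrane receptor & receptor binding",
                   "Pathogen defense",
                   "Junctional & cytoskeletal",
                   "Other"),
    imaging = c("Basal membrane receptor & receptor binding",
                "Apical membrane receptor & receptor binding",
                "Nutrient sensing & digesting",
                "Pathogen defense",
                "Junctional & cytoskeletal",
                "Other"))
}

#' Read a gene-to-GO-category map
#'
#' Two-column tab-separated text, `gene<TAB>category`, one row per
#' membership (genes may appear on several rows). Categories must come from
#' the curated label set.
#'
#' @param path path to the TSV file.
#' @return Named list mapping gene symbol to a character vector of
#'   categories.
#' @export
read_go_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          col.names = c("gene", "category"),
                          stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$category), go_categories)
  if (length(bad)) stop("unknown GO category label(s): ",
                        paste(bad, collapse = "; "))
  split(df$category, df$gene)
}

#' Assign each gene its highest-priority GO category
#'
#' Genes belonging to several categories get the highest-priority one;
#' genes with no membership get `"Other"`. Idempotent and independent of
#' membership order.
#'
#' @param genes character vector of gene symbols.
#' @param map a [read_go_map()] result (named list gene -> categories).
#' @param priority an ordered category vector, see [category_priority()].
#' @return Character vector of single categories, one per gene.
#' @export
assign_category <- function(genes, map, priority = category_priority("imaging")) {
  present <- unique(unlist(map[intersect(genes, names(map))],
                           use.names = FALSE))
  uncovered <- setdiff(present, priority)
  if (length(uncovered))
    stop("priority list does not cover categor(ies): ",
         paste(uncovered, collapse = "; "))
  vapply(genes, function(g) {
    mem <- map[[g]]
    if (is.null(mem) || !length(mem)) return("Other")
    priority[min(match(mem, priority))]
  }, "", USE.NAMES = FALSE)
}

#' Exclusive set intersections (UpSet-style)
#'
#' Partitions the union of the input sets into the non-empty exclusive
#' intersections (every element counted once, in the cell matching its
#' exact membership pattern) and reports their sizes in descending order.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return `data.frame` with columns `sets` (ampersand-joined member names),
#'   `degree`, and `size`, sorted by decreasing size; the `members`
#'   attribute holds the element lists.
#' @export
overlap_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1, function(row)
    paste(names(sets)[row], collapse = " & "))
  groups <- split(universe, pattern)
  out <- data.frame(sets = names(groups),
                    degree = lengths(strsplit(names(groups), " & ", fixed = TRUE)),
                    size = lengths(groups), stringsAsFactors = FALSE)
  ord <- order(-out$size, out$sets)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "members") <- groups[out$sets]
  out
}

#' RNA-protein correlation over shared genes
#'
#' Pearson product-moment correlation between per-gene scaled RNA values
#' (e.g. [region_total_expression()]) and an external per-gene protein
#' table, over the genes present and finite in both.
#'
#' @param scaled_rna,protein named numeric vectors keyed by gene symbol.
#' @return List with `estimate` (Pearson r), `n_shared`, and `genes`. A
#'   constant vector gives `NA` with a warning.
#' @export
rna_protein_correlation <- function(scaled_rna, protein) {
  stopifnot(!is.null(names(scaled_rna)), !is.null(names(protein)))
  shared <- intersect(names(scaled_rna), names(protein))
  a <- scaled_rna[shared]; b <- protein[shared]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need >= 3 shared genes with finite values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: correlation undefined")
    return(list(estimate = NA_real_, n_shared = length(a),
                genes = names(a)))
  }
  list(estimate = stats::cor(a, b), n_shared = length(a), genes = names(a))
}
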
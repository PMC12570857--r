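#' Construct and validate a spot table
#'
#' A spot table holds one record per detected transcript molecule: gene symbol
#' and micrometre coordinates, plus optional z, detection intensity, and the
#' assignment labels (`pair_id`, `subregion`) filled in by [assign_spots()].
#'
#' @param gene character vector of gene symbols (non-empty strings).
#' @param x,y numeric coordinates in micrometres.
#' @param z optional numeric z coordinate in micrometres.
#' @param intensity optional detection intensity (arbitrary units).
#' @param pair_id optional paired-region identifier.
#' @param subregion optional label, one of `"apical"`, `"basal"`,
#'   `"unassigned"`.
#' @return A `data.frame` with (at least) columns `gene`, `x`, `y`.
#' @export
spot_table <- function(gene, x, y, z = NULL, intensity = NULL,
                       pair_id = NULL, subregion = NULL) {
  df <- data.frame(gene = as.character(gene), x = as.numeric(x),
                   y = as.numeric(y), stringsAsFactors = FALSE)
  if (!is.null(z)) df$z <- as.numeric(z)
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  if (!is.null(pair_id)) df$pair_id <- as.character(pair_id)
  if (!is.null(subregion)) df$subregion <- as.character(subregion)
  validate_spot_table(df)
}

#' @rdname spot_table
#' @param spots a data.frame to validate as a spot table.
#' @export
validate_spot_table <- function(spots) {
  req <- c("gene", "x", "y")
  miss <- setdiff(req, names(spots))
  if (length(miss))
    stop("spot table is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(spots)) {
    if (any(is.na(spots$gene) | !nzchar(spots$gene)))
      stop("spot table has empty gene symbols")
    for (cc in intersect(c("x", "y", "z"), names(spots)))
      if (!all(is.finite(spots[[cc]])))
        stop("non-finite coordinates in column '", cc, "'")
    if ("subregion" %in% names(spots)) {
      bad <- setdiff(unique(spots$subregion), c("apical", "basal", "unassigned"))
      if (length(bad))
        stop("invalid subregion label(s): ", paste(bad, collapse = ", "))
    }
  }
  spots
}

#' Read a spot table from delimited text
#'
#' Two dialects are supported: `generic_csv` expects columns `gene,x,y[,z]`;
#' `merscope` maps the transcript-export column names `gene`, `global_x`,
#' `global_y` (and `global_z` when present) onto `gene,x,y,z`. Unknown columns
#' are preserved untouched.
#'
#' @param path path to a CSV/TSV file (delimiter sniffed from the header).
#' @param dialect `"generic_csv"` or `"merscope"`.
#' @return A validated spot table (`data.frame`), see [spot_table()].
#' @export
read_spot_table <- function(path, dialect = c("generic_csv", "merscope")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (dialect == "merscope") {
    map <- c(global_x = "x", global_y = "y", global_z = "z")
    for (from in names(map))
      if (from %in% names(df)) names(df)[names(df) == from] <- map[[from]]
  }
  miss <- setdiff(c("gene", "x", "y"), names(df))
  if (length(miss))
    stop("spot file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cc in intersect(c("x", "y", "z"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop("non-numeric coordinate in column '", cc, "' at data line ",
           bad[1], " of ", path)
    df[[cc]] <- v
  }
  df$gene <- as.character(df$gene)
  validate_spot_table(df)
}

#' Write and re-read localization results
#'
#' Results are written as tab-separated text with columns
#' `gene apical_total basal_total score class p_raw p_adj n_pairs`. Numeric
#' fields round-trip through [read_results()] at (better than) 6 significant
#' digits.
#'
#' @param results a data.frame of per-gene localization results, e.g.
#'   `as.data.frame()` of a [localize()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("gene", "apical_total", "basal_total", "score", "class",
            "p_raw", "p_adj", "n_pairs")
  out <- as.data.frame(results)[, intersect(cols, names(results)), drop = FALSE]
  ok <- tryCatch({
    utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  num <- intersect(c("apical_total", "basal_total", "score", "p_raw",
                     "p_adj", "n_pairs"), names(df))
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  df
}
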
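#' Scoring parameters
#'
#' Thresholds and testing options for [localize()]. A gene is called apical
#' when its score falls below `apical_threshold` (-0.5), basal above
#' `basal_threshold` (+0.5), and non-localizing in between (negative scores
#' mean apical enrichment, positive basal).
#'
#' @param apical_threshold negative score cutoff (default -0.5).
#' @param basal_threshold positive score cutoff (default +0.5).
#' @param alpha significance level for adjusted p-values (default 0.05).
#' @param adjust_method multiple-testing correction passed to
#'   [stats::p.adjust()] (default Benjamini-Hochberg).
#' @return A `score_params` list.
#' @export
score_params <- function(apical_threshold = -0.5, basal_threshold = 0.5,
                         alpha = 0.05, adjust_method = "BH") {
  if (!(apical_threshold < 0 && basal_threshold > 0))
    stop("need apical_threshold < 0 < basal_threshold")
  structure(list(apical_threshold = apical_threshold,
                 basal_threshold = basal_threshold,
                 alpha = alpha, adjust_method = adjust_method),
            class = "score_params")
}

#' Signed range-normalized log2 localization score
#'
#' Three steps: (1) the basal minus apical difference of the per-gene
#' volume-normalized totals; (2) division by the count range of the region
#' (the spread of per-gene totals across the gene panel) and multiplication
#' by 100; (3) a signed log2 shrink, `log2(|x| + 1)` carrying the sign of
#' `x` (with `sign(0) = +1`, giving score 0). Negative scores indicate
#' apical enrichment, positive basal.
#'
#' @param apical_total,basal_total per-gene volume-normalized count totals
#'   (vectors of equal length).
#' @param region_range the count range of the region (a positive scalar
#'   shared by all genes of one analysis).
#' @return Numeric vector of scores.
#' @export
localization_score <- function(apical_total, basal_total, region_range) {
  if (length(region_range) != 1 || !is.finite(region_range) || region_range <= 0)
    stop("region_range must be a single positive number")
  if (any(apical_total < 0) || any(basal_total < 0))
    stop("totals must be non-negative")
  x <- 100 * (basal_total - apical_total) / region_range
  ifelse(x < 0, -log2(abs(x) + 1), log2(abs(x) + 1))
}

classify_score <- function(score, params = score_params()) {
  ifelse(score < params$apical_threshold, "apical",
         ifelse(score > params$basal_threshold, "basal", "non_localizing"))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired volume-normalized counts, one
#' replicate per ROI pair. Zero differences are dropped (Wilcoxon's
#' convention) and ties among absolute differences are mid-ranked. With at
#' most 25 nonzero differences the exact null distribution of the rank sum
#' over all 2^n sign assignments is computed (tie-aware, via the
#' generating-polynomial recursion); beyond that a normal approximation
#' with tie correction is used. The two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param apical,basal numeric vectors of equal length (one entry per pair).
#' @return An object of class `htest` with `p.value`, `statistic` (rank sum
#'   of positive differences), `parameter` (n nonzero pairs), and a logical
#'   `degenerate` element (`TRUE` when all differences are zero, in which
#'   case `p.value` is 1).
#' @export
paired_wilcoxon <- function(apical, basal) {
  stopifnot(length(apical) == length(basal), length(apical) >= 1)
  d <- basal - apical
  if (any(!is.finite(d))) stop("non-finite differences")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    out <- list(statistic = c(W = 0), parameter = c(n = 0), p.value = 1,
                method = "Paired Wilcoxon signed-rank test (degenerate)",
                data.name = "basal - apical", degenerate = TRUE)
    class(out) <- "htest"
    return(out)
  }
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(r, W)
    method <- "Paired Wilcoxon signed-rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Paired Wilcoxon signed-rank test (normal approximation)"
  }
  out <- list(statistic = c(W = W), parameter = c(n = n), p.value = p,
              method = method, data.name = "basal - apical",
              degenerate = FALSE)
  class(out) <- "htest"
  out
}

# Exact two-sided p over all 2^n sign assignments. Midranks are multiples
# of 1/2, so doubled ranks are integers and the distribution of the doubled
# rank sum is built by convolving (1 + x^{2 r_i}); counts stay exact in
# doubles for n <= 25 (2^25 < 2^53).
signed_rank_exact_p <- function(ranks, W) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  cnt <- numeric(total + 1)
  cnt[1] <- 1
  for (si in s) {
    cnt[(si + 1):(total + 1)] <- cnt[(si + 1):(total + 1)] +
      cnt[1:(total + 1 - si)]
  }
  w2 <- as.integer(round(2 * W))
  tot <- 2^length(s)
  p_le <- sum(cnt[1:(w2 + 1)]) / tot
  p_ge <- sum(cnt[(w2 + 1):(total + 1)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Fit per-gene apical-basal localization
#'
#' The central estimator: from a volume-normalized count cube it computes,
#' per gene, the apical and basal totals over pairs, the signed
#' range-normalized log2 localization score (one shared range denominator
#' per analysis, so scores are comparable across genes), the
#' apical/basal/non-localizing class, and a paired Wilcoxon signed-rank
#' p-value across ROI pairs with Benjamini-Hochberg adjustment across
#' genes.
#'
#' @param cube a [count_cube()].
#' @param params a [score_params()].
#' @param pairs optional character vector restricting the analysis to a
#'   subset of pairs (e.g. one zone); the range denominator is recomputed
#'   within the subset.
#' @return An object of class `localization_fit`; see
#'   [as.data.frame.localization_fit()], [coef.localization_fit()],
#'   [summary.localization_fit()], [plot.localization_fit()].
#' @export
localize <- function(cube, params = score_params(), pairs = NULL) {
  stopifnot(inherits(cube, "count_cube"))
  if (!is.null(pairs)) {
    missing_pairs <- setdiff(pairs, dimnames(cube)$pair)
    if (length(missing_pairs))
      stop("unknown pair(s): ", paste(missing_pairs, collapse = ", "))
    cube <- cube[, pairs, , drop = FALSE]
  }
  genes <- dimnames(cube)[[1]]
  n_pairs <- dim(cube)[2]
  apical <- cube[, , "apical", drop = FALSE]
  basal <- cube[, , "basal", drop = FALSE]
  dim(apical) <- dim(basal) <- dim(cube)[1:2]
  apical_total <- rowSums(apical)
  basal_total <- rowSums(basal)
  combined <- apical_total + basal_total
  region_range <- max(combined) - min(combined)
  diffs <- basal_total - apical_total
  if (region_range <= 0) {
    if (length(genes) < 2)
      stop("region count range is zero: need >= 2 genes with distinct totals")
    if (all(diffs == 0)) {
      score <- rep(0, length(genes))
    } else {
      stop("region count range is zero: need >= 2 genes with distinct totals")
    }
  } else {
    score <- localization_score(apical_total, basal_total, region_range)
  }
  tests <- lapply(seq_along(genes), function(g)
    paired_wilcoxon(apical[g, ], basal[g, ]))
  p_raw <- vapply(tests, `[[`, 0, "p.value")
  degenerate <- vapply(tests, `[[`, TRUE, "degenerate")
  p_adj <- stats::p.adjust(p_raw, method = params$adjust_method)
  results <- data.frame(
    gene = genes, apical_total = apical_total, basal_total = basal_total,
    score = score, class = classify_score(score, params),
    p_raw = p_raw, p_adj = p_adj, degenerate = degenerate,
    n_pairs = n_pairs, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = results, region_range = region_range,
                 params = params, n_pairs = n_pairs,
                 call = match.call()),
            class = "localization_fit")
}

#' @export
print.localization_fit <- function(x, ...) {
  cat("Apical-basal localization fit\n")
  cat("  genes:", nrow(x$results), "  pairs:", x$n_pairs,
      "  range denominator:", format(x$region_range, digits = 6), "\n")
  tab <- table(factor(x$results$class,
                      c("apical", "basal", "non_localizing")))
  cat(sprintf("  classes: apical %d, basal %d, non-localizing %d\n",
              tab["apical"], tab["basal"], tab["non_localizing"]))
  cat(sprintf("  significant at alpha = %g (adjusted): %d\n",
              x$params$alpha, sum(x$results$p_adj < x$params$alpha,
                                  na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.localization_fit <- function(object, n = 6, ...) {
  r <- object$results
  structure(list(fit = object,
                 top_apical = utils::head(r[order(r$score), ], n),
                 top_basal = utils::head(r[order(-r$score), ], n)),
            class = "summary.localization_fit")
}

#' @export
print.summary.localization_fit <- function(x, ...) {
  print(x$fit)
  cat("\nMost apical (lowest scores):\n")
  print(x$top_apical, row.names = FALSE, digits = 4)
  cat("\nMost basal (highest scores):\n")
  print(x$top_basal, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract per-gene localization scores
#' @param object a `localization_fit`.
#' @param ... unused.
#' @return Named numeric vector of signed log2 scores.
#' @export
coef.localization_fit <- function(object, ...) {
  stats::setNames(object$results$score, object$results$gene)
}

#' Per-gene results table of a localization fit
#' @param x a `localization_fit`.
#' @param ... unused.
#' @export
as.data.frame.localization_fit <- function(x, ...) x$results

#' Score-versus-significance plot of a localization fit
#'
#' Signed score on the x axis, -log10 adjusted p on the y axis; class
#' thresholds drawn as vertical lines.
#'
#' @param x a `localization_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.localization_fit <- function(x, ...) {
  r <- x$results
  lp <- -log10(pmax(r$p_adj, .Machine$double.xmin))
  cols <- c(apical = "#2aa8c4", basal = "#c4357f",
            non_localizing = "grey60")[r$class]
  graphics::plot(r$score, lp, pch = 19, col = cols,
                 xlab = "localization score (negative = apical)",
                 ylab = "-log10 adjusted p", ...)
  graphics::abline(v = c(x$params$apical_threshold,
                         x$params$basal_threshold), lty = 2)
  invisible(x)
}

#' Scaled log2 total expression per region
#'
#' Per-gene sums of volume-normalized counts over the selected pairs and
#' subregion(s), scaled by 100 over the range across genes, then
#' signed-log2 shrunk exactly as in [localization_score()]. Used for the
#' per-region total-abundance of each gene.
#'
#' @param cube a [count_cube()].
#' @param subregion `"apical"`, `"basal"`, or `"both"`.
#' @param pairs optional pair subset defining the region.
#' @return Named numeric vector of scaled log2 sums.
#' @export
region_total_expression <- function(cube, subregion = c("both", "apical", "basal"),
                                    pairs = NULL) {
  stopifnot(inherits(cube, "count_cube"))
  subregion <- match.arg(subregion)
  if (!is.null(pairs)) cube <- cube[, pairs, , drop = FALSE]
  if (dim(cube)[1] < 2) stop("need >= 2 genes")
  sums <- switch(subregion,
    both = rowSums(cube[, , "apical", drop = FALSE]) +
           rowSums(cube[, , "basal", drop = FALSE]),
    apical = rowSums(cube[, , "apical", drop = FALSE]),
    basal = rowSums(cube[, , "basal", drop = FALSE]))
  rng <- max(sums) - min(sums)
  if (rng <= 0) stop("count range over genes is zero")
  x <- 100 * sums / rng
  stats::setNames(ifelse(x < 0, -log2(abs(x) + 1), log2(abs(x) + 1)),
                  dimnames(cube)[[1]])
}

#' Row-wise z-scores
#'
#' Centers and scales every row of a gene x sample matrix to mean 0 and
#' sample standard deviation 1 (n - 1 denominator). Constant rows become
#' all-`NA` with a warning.
#'
#' @param mat numeric matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need >= 2 samples per row")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    warning(sum(flat), " constant row(s) set to NA")
    sdv[flat] <- NA_real_
  }
  (mat - mu) / sdv
}

#' Signed GSEA rank statistic
#'
#' `-log(p) / sign(logfc)` with the natural log; since the sign is +/-1 the
#' division equals multiplication by the sign. `logfc == 0` gives `NA` with
#' a warning; `p == 0` is clipped to the largest finite magnitude plus an
#' offset ordered by `|logfc|`, preserving rank order.
#'
#' @param p p-values in (0, 1].
#' @param logfc signed log2 fold changes.
#' @return Numeric vector of rank statistics.
#' @export
gsea_rank <- function(p, logfc) {
  stopifnot(length(p) == length(logfc))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  s <- sign(logfc)
  out <- -log(p) * s
  if (any(s == 0, na.rm = TRUE)) {
    warning("logfc of 0: rank statistic undefined, set to NA")
    out[s == 0] <- NA_real_
  }
  inf <- is.infinite(out)
  if (any(inf)) {
    base <- max(abs(out[is.finite(out)]), 0)
    o <- rank(abs(logfc)[inf], ties.method = "first")
    out[inf] <- sign(out[inf]) * (base + o)
  }
  out
}
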
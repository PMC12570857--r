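make_cube <- function(counts_apical, counts_basal, genes = NULL) {
  # counts_*: gene x pair matrices of already-normalized counts
  ng <- nrow(counts_apical); np <- ncol(counts_apical)
  if (is.null(genes)) genes <- paste0("G", seq_len(ng))
  cube <- array(0, c(ng, np, 2),
                dimnames = list(gene = genes, pair = paste0("P", seq_len(np)),
                                subregion = c("apical", "basal")))
  cube[, , "apical"] <- counts_apical
  cube[, , "basal"] <- counts_basal
  attr(cube, "units") <- "um2"
  class(cube) <- c("count_cube", class(cube))
  cube
}

test_that("localization score reproduces the stated three-step formula", {
  expect_equal(localization_score(10, 10, 100), 0)
  # basal 30, apical 10, range 100 -> x2 = 20 -> log2(21)
  expect_equal(localization_score(10, 30, 100), log2(21), tolerance = 1e-12)
  expect_equal(localization_score(30, 10, 100), -log2(21), tolerance = 1e-12)
  expect_equal(localization_score(10, 30, 100), 4.3923, tolerance = 1e-4)
  expect_error(localization_score(1, 2, 0), "positive")
  expect_error(localization_score(-1, 2, 10), "non-negative")
})

test_that("score is antisymmetric and strictly monotone in basal - apical", {
  set.seed(4)
  a <- runif(500, 0, 50); b <- runif(500, 0, 50); r <- runif(500, 1, 100)
  for (i in 1:500)
    expect_equal(localization_score(a[i], b[i], r[i]),
                 -localization_score(b[i], a[i], r[i]), tolerance = 1e-12)
  d <- sort(runif(100, -30, 30))
  s <- localization_score(pmax(-d, 0), pmax(d, 0), 40)
  expect_true(all(diff(s) > 0))
})

test_that("paired Wilcoxon matches enumeration on small instances", {
  # all-positive n = 6: p = 2 / 2^6
  w <- paired_wilcoxon(rep(0, 6), 1:6)
  expect_equal(w$p.value, 0.03125)
  expect_false(w$degenerate)

  # identical vectors: degenerate, p = 1
  wd <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wd$p.value, 1)
  expect_true(wd$degenerate)

  set.seed(12)
  for (i in 1:100) {
    n <- sample(1:10, 1)
    a <- sample(0:4, n, replace = TRUE)   # discrete -> ties and zeros
    b <- sample(0:4, n, replace = TRUE)
    expect_equal(paired_wilcoxon(a, b)$p.value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("exact branch agrees with wilcox.test on tie-free data", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value
    expect_equal(paired_wilcoxon(a, b)$p.value, ref, tolerance = 1e-12)
  }
})

test_that("large-n normal approximation tracks wilcox.test", {
  set.seed(14)
  a <- rnorm(60); b <- rnorm(60, 0.3)
  ref <- wilcox.test(b, a, paired = TRUE, exact = FALSE, correct = FALSE)$p.value
  expect_equal(paired_wilcoxon(a, b)$p.value, ref, tolerance = 1e-10)
})

test_that("localize scores, classifies, and adjusts per gene", {
  # one purely apical and one purely basal gene with equal totals (a third,
  # weaker gene keeps the across-gene count range positive)
  ap <- rbind(c(2, 2, 2), c(0, 0, 0), c(0.5, 0.5, 0.5))
  ba <- rbind(c(0, 0, 0), c(2, 2, 2), c(0.5, 0.5, 0.5))
  fit <- localize(make_cube(ap, ba))
  r <- as.data.frame(fit)
  expect_equal(r$score[1], -r$score[2])
  expect_equal(r$class, c("apical", "basal", "non_localizing"))

  # all genes identical apical and basal totals: scores 0, non-localizing
  m <- matrix(1, 3, 4)
  fit0 <- localize(make_cube(m, m))
  expect_true(all(fit0$results$score == 0))
  expect_true(all(fit0$results$class == "non_localizing"))

  # single-gene cube: range undefined
  expect_error(localize(make_cube(matrix(1, 1, 3), matrix(2, 1, 3))),
               ">= 2 genes")

  # simulated strongly apical gene comes out apical
  truths <- c(list(gene_truth("TARGET", 0.9, 50)),
              lapply(1:4, function(i) gene_truth(paste0("N", i), 0.5,
                                                 10 * i)))
  run <- make_small_sim(truths, n_pairs = 30, seed = 2)
  fit2 <- localize(run$cube)
  expect_equal(fit2$results$class[fit2$results$gene == "TARGET"], "apical")
})

test_that("localization_fit methods expose the results", {
  ap <- rbind(c(2, 2), c(0, 0)); ba <- rbind(c(0, 0), c(1, 1))
  fit <- localize(make_cube(ap, ba))
  expect_s3_class(fit, "localization_fit")
  expect_named(coef(fit), c("G1", "G2"))
  expect_output(print(fit), "classes")
  expect_output(print(summary(fit)), "Most apical")
  expect_equal(nrow(as.data.frame(fit)), 2)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("region totals are scaled and shrunk like the score", {
  ap <- rbind(c(0, 0), c(30, 20)); ba <- rbind(c(0, 0), c(30, 20))
  cube <- make_cube(ap, ba)
  tot <- region_total_expression(cube)  # sums 0 and 100 -> 0 and log2(101)
  expect_equal(unname(tot), c(0, log2(101)), tolerance = 1e-12)
  expect_equal(unname(tot[2]), 6.6582, tolerance = 1e-4)

  # invariant to multiplying all sums by a constant
  tot2 <- region_total_expression(make_cube(3 * ap, 3 * ba))
  expect_equal(tot, tot2, tolerance = 1e-12)

  expect_error(region_total_expression(make_cube(matrix(1, 2, 2),
                                                 matrix(1, 2, 2))), "range")
})

test_that("row z-scores have mean zero and unit sample sd", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  set.seed(6)
  m <- matrix(rnorm(50), 5)
  zz <- zscore_rows(m)
  expect_equal(rowMeans(zz), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(zz, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_warning(zc <- zscore_rows(rbind(c(1, 2, 3), c(5, 5, 5))), "constant")
  expect_true(all(is.na(zc[2, ])))
  expect_error(zscore_rows(matrix(1, 2, 1)), ">= 2 samples")
})

test_that("GSEA rank statistic is -log(p) carrying the fold-change sign", {
  expect_equal(gsea_rank(0.01, 2), -log(0.01))
  expect_equal(gsea_rank(0.01, 2), 4.6052, tolerance = 1e-4)
  expect_equal(gsea_rank(0.01, -2), log(0.01))
  expect_equal(gsea_rank(1, -3), 0)
  expect_warning(r0 <- gsea_rank(0.5, 0), "undefined")
  expect_true(is.na(r0))
  # p = 0 clipped above the largest finite rank, ordered by |logfc|
  r <- gsea_rank(c(0.01, 0, 0, 0.5), c(1, 2, -5, -1))
  expect_true(all(is.finite(r)))
  expect_gt(r[2], r[1])
  expect_lt(r[3], 0)
  expect_gt(abs(r[3]), abs(r[2]))
})
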
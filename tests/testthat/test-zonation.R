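test_that("single-zone profiling reduces exactly to localize", {
  truths <- list(gene_truth("A", 0.8, 40), gene_truth("B", 0.3, 25),
                 gene_truth("C", 0.5, 15))
  run <- make_small_sim(truths, n_pairs = 10, seed = 4,
                        zone_layout = c(crypt = 10))
  prof <- per_zone_scores(run$cube, run$rois)
  fit <- localize(run$cube)
  expect_equal(prof$zone, rep("crypt", 3))
  expect_equal(prof$score, fit$results$score)
  expect_equal(prof$p_adj, fit$results$p_adj)
})

test_that("zone-dependent bias switching is recovered as a transition", {
  switcher <- gene_truth("SWITCH",
                         apical_prob = c(crypt = 0.9, villus_top = 0.1),
                         mean_molecules = 60)
  stable <- gene_truth("STAY", apical_prob = 0.85, mean_molecules = 60)
  filler <- lapply(1:3, function(i) gene_truth(paste0("F", i), 0.5, 10 * i))
  run <- make_small_sim(c(list(switcher, stable), filler), n_pairs = 40,
                        seed = 9,
                        zone_layout = c(crypt = 20, villus_top = 20))
  prof <- per_zone_scores(run$cube, run$rois,
                          zones = c("crypt", "villus_top"))
  sw <- prof[prof$gene == "SWITCH", ]
  expect_lt(sw$score[sw$zone == "crypt"], -0.5)
  expect_gt(sw$score[sw$zone == "villus_top"], 0.5)

  tr <- find_transitions(prof, "crypt", "villus_top")
  expect_true("SWITCH" %in% tr)
  expect_false("STAY" %in% tr)
  # the two directions never overlap
  rev <- find_transitions(prof, "villus_top", "crypt")
  expect_length(intersect(tr, rev), 0)
})

test_that("transition calls use strict threshold inequalities", {
  prof <- data.frame(gene = c("A", "A", "B", "B"),
                     zone = c("z1", "z2", "z1", "z2"),
                     score = c(-1.2, 0.8, -0.5, 0.5),
                     class = NA, p_raw = NA, p_adj = NA, n_pairs = 4)
  expect_equal(find_transitions(prof, "z1", "z2"), "A")  # B is boundary
  prof2 <- prof; prof2$score <- c(-1.2, -0.2, -0.6, 0.4)
  expect_length(find_transitions(prof2, "z1", "z2"), 0)
  expect_error(find_transitions(prof, "z1", "nope"), "nope")
})

test_that("zones with too few pairs are skipped with a warning", {
  truths <- list(gene_truth("A", 0.8, 40), gene_truth("B", 0.3, 25))
  run <- make_small_sim(truths, n_pairs = 5, seed = 3,
                        zone_layout = c(crypt = 4, villus_top = 1))
  expect_warning(prof <- per_zone_scores(run$cube, run$rois), "villus_top")
  expect_equal(unique(prof$zone), "crypt")
})

test_that("category assignment honours the priority presets", {
  map <- list(
    Sis = c("Nutrient sensing & digesting", "Pathogen defense"),
    Col4a1 = c("Basal membrane receptor & receptor binding",
               "Nutrient sensing & digesting"),
    Actb = "Junctional & cytoskeletal")
  expect_equal(assign_category("Sis", map, category_priority("sequencing")),
               "Nutrient sensing & digesting")
  expect_equal(assign_category("Col4a1", map, category_priority("imaging")),
               "Basal membrane receptor & receptor binding")
  expect_equal(assign_category("Unknown", map), "Other")
  # idempotent and independent of membership order
  map_rev <- lapply(map, rev)
  genes <- c("Sis", "Col4a1", "Actb", "Unknown")
  expect_equal(assign_category(genes, map), assign_category(genes, map_rev))
  # a membership outside the priority list is an error
  expect_error(
    assign_category("Sis", map, priority = "Other"), "cover")
})

test_that("GO maps read from two-column TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Sis\tNutrient sensing & digesting",
               "Sis\tPathogen defense",
               "Actb\tJunctional & cytoskeletal"), f)
  map <- read_go_map(f)
  expect_equal(sort(names(map)), c("Actb", "Sis"))
  expect_length(map$Sis, 2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Sis\tMade-up category", f2)
  expect_error(read_go_map(f2), "unknown GO category")
})

test_that("exclusive intersections partition the union", {
  # worked example: A = {1,2,3}, B = {2,3,4}, C = {3}
  sets <- list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3")
  om <- overlap_matrix(sets)
  sz <- setNames(om$size, om$sets)
  expect_equal(unname(sz["A & B & C"]), 1)
  expect_equal(unname(sz["A & B"]), 1)
  expect_equal(unname(sz["A"]), 1)
  expect_equal(unname(sz["B"]), 1)
  expect_equal(sum(om$size), 4)        # |union|
  expect_true(all(diff(om$size) <= 0)) # descending

  ident <- overlap_matrix(list(X = letters[1:5], Y = letters[1:5]))
  expect_equal(ident$sets, "X & Y")
  expect_equal(ident$size, 5)

  disj <- overlap_matrix(list(X = "a", Y = "b"))
  expect_equal(sort(disj$sets), c("X", "Y"))
  expect_equal(disj$size, c(1, 1))

  # partition property on random families
  set.seed(19)
  for (i in 1:10) {
    fam <- lapply(1:4, function(j) sample(letters, sample(3:15, 1)))
    names(fam) <- paste0("S", 1:4)
    om2 <- overlap_matrix(fam)
    expect_equal(sum(om2$size), length(unique(unlist(fam))))
  }
})

test_that("RNA-protein correlation is plain Pearson over shared genes", {
  rna <- c(A = 1, B = 2, C = 3)
  expect_equal(rna_protein_correlation(rna, rna)$estimate, 1)
  expect_equal(rna_protein_correlation(rna, -rna)$estimate, -1)
  prot <- c(A = 2, B = 4, C = 7, D = 100)
  r <- rna_protein_correlation(rna, prot)
  expect_equal(r$n_shared, 3)
  expect_equal(r$estimate, 0.9934, tolerance = 1e-4)
  expect_error(rna_protein_correlation(c(A = 1, B = 2), prot), ">= 3")
  expect_warning(rc <- rna_protein_correlation(c(A = 1, B = 1, C = 1), prot),
                 "constant")
  expect_true(is.na(rc$estimate))
})
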
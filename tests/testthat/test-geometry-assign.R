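square <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

two_pair_rois <- function() {
  info <- data.frame(
    roi_id = c("P1_a", "P1_b", "P2_a", "P2_b"),
    pair_id = c("P1", "P1", "P2", "P2"),
    subregion = c("apical", "basal", "apical", "basal"),
    zone = "none", volume = c(50, 50, 50, 50), stringsAsFactors = FALSE)
  roi_set(info, list(P1_a = square(0, 5, 10, 5), P1_b = square(0, 0, 10, 5),
                     P2_a = square(12, 5, 10, 5), P2_b = square(12, 0, 10, 5)),
          units = "um2")
}

test_that("spots are assigned to containing polygons, outsiders stay unassigned", {
  rois <- two_pair_rois()
  sp <- spot_table(c("A", "A", "A"), c(5, 17, 30), c(7.5, 2, 2))
  asg <- assign_spots(sp, rois)
  expect_equal(asg$subregion, c("apical", "basal", "unassigned"))
  expect_equal(asg$pair_id, c("P1", "P2", NA))
})

test_that("a spot on the shared apical/basal edge goes apical, deterministically", {
  rois <- two_pair_rois()
  asg <- assign_spots(spot_table("A", 5, 5), rois)  # exactly on the split line
  expect_equal(asg$subregion, "apical")
  expect_equal(asg$roi_id, "P1_a")
})

test_that("assignment conserves spots and matches the per-spot oracle", {
  rois <- two_pair_rois()
  set.seed(8)
  n <- 5000
  sp <- spot_table(rep("A", n), runif(n, -2, 25), runif(n, -2, 12))
  asg <- assign_spots(sp, rois)
  tab <- table(factor(asg$subregion, c("apical", "basal", "unassigned")))
  expect_equal(sum(tab), n)  # conservation

  # oracle: first containing polygon in (apical-first, roi_id) order
  ord <- order(rois$info$subregion != "apical", rois$info$roi_id)
  want <- vapply(seq_len(n), function(i) {
    for (k in ord) {
      poly <- rois$polygons[[rois$info$roi_id[k]]]
      if (points_in_polygon(sp$x[i], sp$y[i], poly))
        return(rois$info$subregion[k])
    }
    "unassigned"
  }, "")
  expect_equal(asg$subregion, want)
})

test_that("count cube divides by ROI volume and scales accordingly", {
  rois <- two_pair_rois()
  # 50 spots of one gene inside P1 apical (area 50 um^2) -> 1.0 per um^2;
  # halving the area would double the density
  sp <- spot_table(rep("A", 50), runif(50, 1, 9), runif(50, 6, 9))
  cube <- count_cube(assign_spots(sp, rois), rois)
  expect_equal(cube["A", "P1", "apical"], 1.0)
  expect_equal(cube["A", "P1", "basal"], 0)

  # doubling every volume halves every count
  rois2 <- rois; rois2$info$volume <- rois2$info$volume * 2
  cube2 <- count_cube(assign_spots(sp, rois2), rois2)
  expect_equal(as.numeric(cube2), as.numeric(cube) / 2)

  # genes absent from a pair give an all-zero slice
  cube3 <- count_cube(assign_spots(sp, rois), rois, genes = c("A", "B"))
  expect_true(all(cube3["B", , ] == 0))

  rois_bad <- rois; rois_bad$info$volume[1] <- 0
  expect_error(count_cube(assign_spots(sp, rois_bad), rois_bad), "P1_a")
})

test_that("gradient offsets reproduce the rectangle worked cases exactly", {
  # 10 um wide cell, straight centerline along the long axis
  poly <- square(0, 0, 20, 10)
  cl <- cbind(c(0, 20), c(5, 5))
  apical_ref <- c(10, 7.5)  # apical side is y > 5
  sp <- spot_table(c("A", "A", "A"), c(10, 10, 10), c(5, 7.5, 10))
  off <- gradient_offsets(sp, cl, poly, apical_ref)
  expect_equal(off$offset, c(0, 0.25, 0.5), tolerance = 1e-9)
  expect_equal(attr(off, "max_width"), 10, tolerance = 1e-9)
  # basal side is negative
  off2 <- gradient_offsets(spot_table("A", 4, 2), cl, poly, apical_ref)
  expect_equal(off2$offset, -0.3, tolerance = 1e-9)
})

test_that("gradient offsets are invariant under rigid motions", {
  set.seed(21)
  poly <- square(0, 0, 20, 10)
  cl <- cbind(c(1, 8, 19), c(5, 5.5, 5))
  apical_ref <- c(10, 8)
  sp <- spot_table(rep("A", 200), runif(200, 0, 20), runif(200, 0, 10))
  base <- gradient_offsets(sp, cl, poly, apical_ref)$offset
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); tr <- runif(2, -30, 30)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- function(m) sweep(as.matrix(m) %*% t(R), 2, -tr)
    spr <- sp; spr[, c("x", "y")] <- rot(cbind(sp$x, sp$y))
    got <- gradient_offsets(spr, rot(cl), rot(poly),
                            as.vector(rot(rbind(apical_ref))))$offset
    expect_equal(got, base, tolerance = 1e-6)
  }
})

test_that("degenerate centerlines are rejected", {
  poly <- square(0, 0, 20, 10)
  expect_error(gradient_offsets(spot_table("A", 1, 1),
                                cbind(c(5, 5), c(5, 5)), poly, c(1, 8)),
               "degenerate")
})

test_that("mean offset sign rises with apical probability", {
  signs <- vapply(c(0.2, 0.5, 0.8), function(p) {
    cfg <- sim_config(gene_truth("A", p, 300), n_pairs = 4)
    rois <- generate_rois(cfg)
    sim <- simulate_spots(rois, cfg, seed = 17)
    means <- vapply(unique(rois$info$pair_id), function(pid) {
      sub <- rois$info[rois$info$pair_id == pid, ]
      ap <- rois$polygons[[sub$roi_id[sub$subregion == "apical"]]]
      ba <- rois$polygons[[sub$roi_id[sub$subregion == "basal"]]]
      cell <- rbind(ba[1:2, ], ap[3:4, ])  # full rectangle
      xr <- range(cell[, 1])
      cln <- cbind(xr, c(10, 10))  # horizontal mid-height centerline
      spp <- sim$spots[sim$spots$true_pair_id == pid, ]
      mean(gradient_offsets(spp, cln, cell, polygon_centroid(ap))$offset)
    }, 0)
    mean(means)
  }, 0)
  expect_true(all(diff(signs) > 0))
})
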
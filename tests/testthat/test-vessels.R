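# Vessel classification and niche assignment rules.

test_that("classify_vessels applies the 0.01% overlap-ratio rule with LV at the boundary", {
  # 100 x 100 CD31 surface (area 1e4): a 1 um^2 LYVE-1 overlap is exactly
  # the 0.01% cutoff
  cd31 <- surface_set(list(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
                           cbind(c(200, 300, 300, 200), c(0, 0, 100, 100)),
                           cbind(c(400, 500, 500, 400), c(0, 0, 100, 100))),
                      marker_class = "CD31", surface_id = c("v1", "v2", "v3"))
  lyve1 <- surface_set(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),        # = cutoff
                            cbind(c(200, 250, 250, 200), c(0, 0, 100, 100))), # 50%
                       marker_class = "LYVE1")
  v <- classify_vessels(cd31, lyve1)
  expect_equal(v$class, c("LV", "LV", "BV"))
  expect_equal(v$lyve1_overlap_ratio, c(1e-4, 0.5, 0), tolerance = 1e-9)
  # no LYVE-1 at all: everything is BV
  v0 <- classify_vessels(cd31, dcniche:::empty_surface_set())
  expect_true(all(v0$class == "BV"))
})

toy_vessels <- function() {
  # BV strip at x in [0,10], LV strip at x in [60,70], both tall
  v <- surface_set(list(cbind(c(0, 10, 10, 0), c(-50, -50, 50, 50)),
                        cbind(c(60, 70, 70, 60), c(-50, -50, 50, 50))),
                   marker_class = "CD31", surface_id = c("bv", "lv"))
  v$class <- c("BV", "LV")
  v$ccl19_covered <- NA
  class(v) <- c("vessel_set", class(v))
  v
}

test_that("associate_cells applies the nearer-class rule with cutoff and tie conventions", {
  v <- toy_vessels()
  # unit squares: d_bv = left edge - 10, d_lv = 60 - right edge
  sq <- function(x) cbind(c(x, x + 1, x + 1, x), c(0, 0, 1, 1))
  dcs <- surface_set(list(sq(15),   # d_bv 5,  d_lv 44 -> BV
                          sq(44),   # d_bv 34, d_lv 15 -> LV
                          sq(35),   # d_bv 25, d_lv 24 -> LV within? 24 > 20 -> none
                          sq(34.5), # d_bv 24.5, d_lv 24.5 -> both > 20 -> none
                          sq(30)),  # d_bv 20, d_lv 29 -> BV (<= cutoff qualifies)
                     marker_class = "FSCN1")
  a <- associate_cells(dcs, v)
  expect_equal(a$label, c("BV", "LV", "none", "none", "BV"))
  expect_equal(a$d_bv, c(5, 34, 25, 24.5, 20))
  expect_equal(a$d_lv, c(44, 15, 24, 24.5, 29))
  # exact tie within the cutoff resolves to BV
  tie <- surface_set(list(cbind(c(34.5, 35.5, 35.5, 34.5), c(0, 0, 1, 1))),
                     marker_class = "FSCN1")
  # d_bv = 24.5 -> shrink the gap so both distances are 10
  v2 <- toy_vessels()
  v2$boundary[[1L]] <- cbind(c(0, 24.5, 24.5, 0), c(-50, -50, 50, 50))
  v2$boundary[[2L]] <- cbind(c(45.5, 70, 70, 45.5), c(-50, -50, 50, 50))
  a2 <- associate_cells(tie, v2)
  expect_equal(a2$d_bv, a2$d_lv)
  expect_equal(a2$label, "BV")
})

test_that("a missing vessel class is flagged and the remaining class wins", {
  v <- toy_vessels()
  bv_only <- dcniche:::surface_subset(v, 1L)
  dcs <- surface_set(list(cbind(c(15, 16, 16, 15), c(0, 0, 1, 1))),
                     marker_class = "FSCN1")
  a <- associate_cells(dcs, bv_only)
  expect_equal(a$label, "BV")
  expect_equal(attr(a, "missing_class"), "LV")
})

test_that("every DC gets exactly one label and fractions sum to one; cutoff is monotone", {
  sc <- generate_scene(scene_config(n_dc = 120, n_treg = 0, n_other = 0,
                                    perivascular_fraction = 0.5,
                                    lv_fraction = 0.2, seed = 12))
  a20 <- associate_cells(sc$detections, sc$vessels)
  expect_true(all(a20$label %in% c("BV", "LV", "none")))
  fr <- prop.table(table(factor(a20$label, levels = c("BV", "LV", "none"))))
  expect_equal(sum(fr), 1)
  # planted fractions recovered exactly under the construction margins
  expect_equal(as.vector(fr), as.vector(sc$truth$planted_fractions))
  # shrinking the cutoff never moves a DC from none to a vessel class
  a10 <- associate_cells(sc$detections, sc$vessels,
                         association_config(vessel_cutoff = 10))
  expect_true(all(!(a20$label == "none" & a10$label != "none")))
})

test_that("centroid dialect measures centroid-to-centroid distances", {
  v <- toy_vessels() # centroids at (5, 0) and (65, 0)
  cells <- data.frame(cell_id = "c1", x_um = 20, y_um = 0)
  a <- associate_cells(cells, v, association_config(preset = "human_multispectral"))
  expect_equal(a$d_bv, 15)
  expect_equal(a$d_lv, 45)
  expect_equal(a$label, "BV")
})

test_that("associate_clusters uses the 50% proximal-area rule", {
  v <- toy_vessels()
  sq <- function(x, a = 100) {
    s <- sqrt(a) / 2
    cbind(c(x - s, x + s, x + s, x - s), c(-s, s + (-2 * s), s, s))
  }
  # all members within 20 um of the BV
  near <- surface_set(list(disk_polygon(c(15, 0), 150),
                           disk_polygon(c(18, 10), 150),
                           disk_polygon(c(20, -8), 150),
                           disk_polygon(c(16, 20), 150)),
                      marker_class = "FSCN1")
  cl <- delaunay_cluster(near, min_total_area = 400)
  out <- associate_clusters(cl, near, v)
  expect_equal(out$association, "BV")
  # 2 of 5 equal-area members proximal (40%): unassociated. Disks of
  # radius ~4 at x = 35 sit in the neutral corridor (> 20 um from both the
  # BV edge at 10 and the LV edge at 60).
  mixed <- surface_set(list(disk_polygon(c(15, 0), 50),
                            disk_polygon(c(15, 10), 50),
                            disk_polygon(c(35, 0), 50),
                            disk_polygon(c(35, 10), 50),
                            disk_polygon(c(35, 20), 50)),
                       marker_class = "FSCN1")
  clm <- delaunay_cluster(mixed, min_total_area = 200)
  expect_equal(nrow(clm), 1)
  outm <- associate_clusters(clm, mixed, v)
  expect_equal(outm$bv_area_fraction, 0.4, tolerance = 1e-9)
  expect_equal(outm$association, "none")
})

test_that("cluster labels match a brute-force per-detection distance oracle", {
  set.seed(55)
  for (rep in 1:4) {
    sc <- generate_scene(scene_config(n_dc = 60, n_treg = 0, n_other = 0,
                                      perivascular_fraction = 0.6,
                                      seed = 100 + rep))
    cl <- delaunay_cluster(sc$detections, min_total_area = 100)
    out <- associate_clusters(cl, sc$detections, sc$vessels)
    dmat <- dcniche:::surface_distance_matrix(sc$detections, sc$vessels)
    is_bv <- sc$vessels$class == "BV"
    for (i in seq_len(nrow(out))) {
      rows <- match(out$members[[i]], sc$detections$surface_id)
      area <- sc$detections$area_um2[rows]
      bf <- sum(area[apply(dmat[rows, is_bv, drop = FALSE], 1, min) <= 20]) / sum(area)
      lf <- sum(area[apply(dmat[rows, !is_bv, drop = FALSE], 1, min) <= 20]) / sum(area)
      ref <- if (bf >= 0.5 && bf >= lf) "BV" else if (lf >= 0.5) "LV" else "none"
      expect_equal(out$association[i], ref)
    }
  }
})

test_that("ccl19_coverage flags any positive overlap and conserves area fractions", {
  v <- toy_vessels()
  shell <- surface_set(list(cbind(c(8, 12, 12, 8), c(-10, -10, 10, 10))),
                       marker_class = "Ccl19")
  out <- ccl19_coverage(v, shell)
  expect_equal(out$ccl19_covered, c(TRUE, FALSE))
  fr <- attr(out, "bv_area_fractions")
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["covered"]), 1) # the only BV is covered
  # no contact at all
  far <- surface_set(list(cbind(c(500, 501, 501, 500), c(0, 0, 1, 1))),
                     marker_class = "Ccl19")
  out0 <- ccl19_coverage(v, far)
  expect_false(any(out0$ccl19_covered))
  # scene ground truth is recovered
  sc <- generate_scene(scene_config(seed = 4, n_dc = 0, n_treg = 0, n_other = 0))
  vc <- classify_vessels(sc$surfaces$cd31, sc$surfaces$lyve1)
  vc <- ccl19_coverage(vc, sc$surfaces$ccl19)
  expect_equal(vc$ccl19_covered, sc$truth$ccl19_covered$covered)
})

test_that("ccl21_membership is centroid-in-region and vertex-order invariant", {
  region <- cbind(c(0, 50, 50, 0), c(0, 0, 50, 50))
  regions <- surface_set(list(region), marker_class = "CCL21")
  det <- surface_set(list(disk_polygon(c(25, 25), 50),   # centroid inside
                          disk_polygon(c(100, 100), 50)), # outside
                     marker_class = "FSCN1")
  cl <- list(c("s1", "s2"), "s2")
  clusters <- dcniche:::empty_cluster_set()
  clusters <- data.frame(cluster_id = c("cl1", "cl2"), n_members = c(2L, 1L),
                         total_area_um2 = NA, centroid_x = NA, centroid_y = NA,
                         association = "unassigned")
  clusters$members <- cl
  class(clusters) <- c("cluster_set", "data.frame")
  expect_equal(ccl21_membership(clusters, det, regions), c(TRUE, FALSE))
  # reversed vertex order of the region polygon changes nothing
  regions_rev <- surface_set(list(region[4:1, ]), marker_class = "CCL21")
  expect_equal(ccl21_membership(clusters, det, regions_rev), c(TRUE, FALSE))
})

test_that("vessel_dc_load sums proximal DC area with the >= 500 rule", {
  v <- toy_vessels()
  sq <- function(x, area) {
    s <- sqrt(area) / 2
    cbind(c(x - s, x + s, x + s, x - s), c(-s, -s, s, s))
  }
  dcs <- surface_set(lapply(c(12, 14, 16, 18, 20), function(x) sq(x, 120)),
                     marker_class = "FSCN1")
  out <- vessel_dc_load(v, dcs)
  expect_equal(out$dc_area_um2[1L], 600, tolerance = 1e-9)
  expect_true(out$cluster_associated[1L])
  expect_equal(out$dc_area_um2[2L], 0)
  expect_false(out$cluster_associated[2L])
  # 499 is below the >= 500 rule
  one <- surface_set(list(cbind(c(12, 12 + 499, 12 + 499, 12), c(0, 0, 1, 1))),
                     marker_class = "FSCN1")
  # width 499 x height 1 rectangle is partly far away; use a compact shape
  one <- surface_set(list(sq(14, 499)), marker_class = "FSCN1")
  out1 <- vessel_dc_load(v, one)
  expect_equal(out1$dc_area_um2[1L], 499, tolerance = 1e-9)
  expect_false(out1$cluster_associated[1L])
  # random scenes match direct summation
  set.seed(6)
  sc <- generate_scene(scene_config(n_dc = 50, n_treg = 0, n_other = 0,
                                    perivascular_fraction = 0.5, seed = 61))
  load <- vessel_dc_load(sc$vessels, sc$detections)
  dmat <- dcniche:::surface_distance_matrix(sc$detections, sc$vessels)
  for (j in seq_len(nrow(sc$vessels))) {
    expect_equal(load$dc_area_um2[j],
                 sum(sc$detections$area_um2[dmat[, j] <= 20]))
  }
})
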
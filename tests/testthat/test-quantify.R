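rect_mask <- function(rows, cols, n = 64L) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  m
}

test_that("areas and intersections on constructed rectangles are exact", {
  a <- rect_mask(1:10, 1:10)            # 100 px
  b <- rect_mask(6:11, 6:15)            # 60 px, overlap 25 px
  areas <- measure_areas(list(nuclear = list(a), dead_membrane = list(b)))
  expect_identical(unname(areas$area[["nuclear"]]), 100)
  expect_identical(unname(areas$area[["dead_membrane"]]), 60)
  expect_identical(unname(areas$intersections[["dead_membrane&nuclear"]]), 25)
})

test_that("disjoint masks have zero intersection", {
  a <- rect_mask(1:5, 1:5)
  b <- rect_mask(20:25, 20:25)
  areas <- measure_areas(list(nuclear = list(a), lineage_gfp = list(b)))
  expect_identical(unname(areas$intersections[["lineage_gfp&nuclear"]]), 0)
  expect_identical(coloc_fraction(areas, "lineage_gfp", "nuclear"), 0)
})

test_that("intersections equal a pixel-by-pixel double loop on random masks", {
  set.seed(31)
  for (i in 1:50) {
    a <- matrix(runif(32 * 32) < runif(1, 0.05, 0.5), 32, 32)
    b <- matrix(runif(32 * 32) < runif(1, 0.05, 0.5), 32, 32)
    areas <- measure_areas(list(dead_membrane = list(a),
                                dead_apoptotic = list(b)))
    expect_identical(
      unname(areas$intersections[["dead_apoptotic&dead_membrane"]]),
      as.numeric(intersection_oracle(a, b)))
  }
})

test_that("intersection counts never exceed either member's area", {
  set.seed(32)
  for (i in 1:10) {
    masks <- list(nuclear = list(matrix(runif(64) < 0.4, 8, 8)),
                  dead_membrane = list(matrix(runif(64) < 0.4, 8, 8)),
                  dead_apoptotic = list(matrix(runif(64) < 0.4, 8, 8)))
    areas <- measure_areas(masks)
    for (nm in names(areas$intersections)) {
      pair <- strsplit(nm, "&", fixed = TRUE)[[1L]]
      expect_lte(areas$intersections[[nm]],
                 min(areas$area[[pair[1L]]], areas$area[[pair[2L]]]))
    }
  }
})

test_that("measure_areas is invariant to slice order", {
  set.seed(33)
  sl <- replicate(4, matrix(runif(64) < 0.3, 8, 8), simplify = FALSE)
  s2 <- replicate(4, matrix(runif(64) < 0.3, 8, 8), simplify = FALSE)
  a1 <- measure_areas(list(nuclear = sl, dead_membrane = s2))
  perm <- c(3L, 1L, 4L, 2L)
  a2 <- measure_areas(list(nuclear = sl[perm], dead_membrane = s2[perm]))
  expect_identical(a1$area, a2$area)
  expect_identical(a1$intersections, a2$intersections)
})

test_that("shape mismatches are hard errors", {
  expect_error(measure_areas(list(nuclear = list(matrix(TRUE, 4, 4)),
                                  dead_membrane = list(matrix(TRUE, 5, 4)))),
               "shape mismatch")
  expect_error(measure_areas(list(
    nuclear = list(matrix(TRUE, 4, 4), matrix(TRUE, 4, 4)),
    dead_membrane = list(matrix(TRUE, 4, 4)))), "slice counts")
})

test_that("dead area applies inclusion-exclusion over the two dead markers", {
  mk <- function(e, a, o) {
    # e px EtHd, a px apopxin, o overlapping
    m1 <- matrix(FALSE, 40, 40); m1[seq_len(e)] <- TRUE
    m2 <- matrix(FALSE, 40, 40); m2[seq(e - o + 1L, e - o + a)] <- TRUE
    measure_areas(list(dead_membrane = list(m1), dead_apoptotic = list(m2)))
  }
  expect_identical(dead_area(mk(400, 300, 120)), 580)
  # full containment: apopxin inside EtHd
  m1 <- rect_mask(1:20, 1:20); m2 <- rect_mask(5:10, 5:10)
  areas <- measure_areas(list(dead_membrane = list(m1),
                              dead_apoptotic = list(m2)))
  expect_identical(dead_area(areas), unname(areas$area[["dead_membrane"]]))
})

test_that("a single configured death channel is returned as-is", {
  areas <- measure_areas(list(nuclear = list(rect_mask(1:10, 1:10)),
                              dead_membrane = list(rect_mask(1:5, 1:5))))
  expect_identical(dead_area(areas), 25)
  expect_error(dead_area(measure_areas(list(nuclear =
                                              list(rect_mask(1:2, 1:2))))),
               "no death channel")
})

test_that("both-marked cells are counted once through the full mask path", {
  sc <- default_scene(13, fractions = list(dead_both = 0.4))
  st <- render_scene(sc, c("nuclear", "dead_membrane", "dead_apoptotic"))
  res <- analyze_stacks(st, threshold = PLATE_THRESHOLD)
  # the overlap-subtraction path is exercised: nonzero, non-total overlap
  inter <- res$areas$intersections[["dead_apoptotic&dead_membrane"]]
  expect_gt(inter, 0)
  expect_lt(inter, min(res$areas$area[["dead_membrane"]],
                       res$areas$area[["dead_apoptotic"]]))
  # no double counting: strictly below the naive channel sum
  dead <- dead_area(res$areas)
  expect_lt(dead, res$areas$area[["dead_membrane"]] +
              res$areas$area[["dead_apoptotic"]])
  # the union is covered but never wildly inflated: the apopxin ring is a
  # 3 px annulus whose two soft edges and defocus halo at most double its
  # geometric footprint
  truth_union <- sum(mapply(function(a, b) sum(a | b),
                            ground_truth_mask(sc, "dead_membrane"),
                            ground_truth_mask(sc, "dead_apoptotic")))
  expect_gt(dead, 0.85 * truth_union)
  expect_lt(dead, 2 * truth_union)
})

test_that("co-culture channel arithmetic matches the constructed example", {
  hoechst <- rect_mask(1:25, 1:40)                    # 1000 px
  gfp <- rect_mask(1:20, 22:41)                       # 400 px, 380 inside
  ethd <- rect_mask(1:15, 22:31) | rect_mask(30:39, 1:5)  # 200 px
  areas <- measure_areas(list(nuclear = list(hoechst),
                              dead_membrane = list(ethd),
                              lineage_gfp = list(gfp)))
  cc <- coculture_areas(areas)
  expect_identical(unname(cc$hoechst_total), 1000)
  expect_identical(unname(cc$gfp), 400)
  expect_identical(unname(cc$ethd_total), 200)
  expect_identical(unname(cc$hoechst_target), 620)
  expect_identical(unname(cc$ethd_target), 50)
  expect_identical(unname(cc$ethd_fibroblast), 150)
})

test_that("empty GFP reduces co-culture areas to the monoculture limit", {
  areas <- measure_areas(list(nuclear = list(rect_mask(1:25, 1:40)),
                              dead_membrane = list(rect_mask(30:39, 1:20)),
                              lineage_gfp = list(rect_mask(integer(0),
                                                           integer(0)))))
  cc <- coculture_areas(areas)
  expect_identical(cc$hoechst_target, cc$hoechst_total)
  expect_identical(cc$ethd_target, cc$ethd_total)
  expect_identical(unname(cc$ethd_fibroblast), 0)
})

test_that("colocalization fraction behaves per definition", {
  hoechst <- rect_mask(1:20, 1:20)   # 400 px
  gfp <- rect_mask(1:20, 2:21)       # 380 inside hoechst
  areas <- measure_areas(list(nuclear = list(hoechst),
                              lineage_gfp = list(gfp)))
  expect_identical(coloc_fraction(areas, "lineage_gfp", "nuclear"), 0.95)
  empty <- measure_areas(list(nuclear = list(rect_mask(integer(0),
                                                       integer(0))),
                              lineage_gfp = list(gfp)))
  expect_warning(v <- coloc_fraction(empty, "lineage_gfp", "nuclear"),
                 "undefined")
  expect_true(is.na(v))
})

test_that("GFP-Hoechst colocalization passes the QC bar on fibroblasts", {
  sc <- simulate_scene(scene_params(n_cells = 30L, nucleus_radius_px = 4,
                                    volume_shape = c(12L, 256L, 256L),
                                    fractions = list(gfp_lineage = 1),
                                    seed = 7))
  res <- analyze_stacks(render_scene(sc, c("nuclear", "lineage_gfp")),
                        threshold = PLATE_THRESHOLD)
  expect_gt(coloc_fraction(res$areas, "lineage_gfp", "nuclear"), 0.8)
})
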
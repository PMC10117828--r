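# Densities, hotspots and Morisita-Horn indices.

test_that("region densities are counts over areas, with the weighted-mean property", {
  ann <- square_annotation(side_um = 1000, im_width = 100)  # TC area 1 mm^2
  set.seed(51)
  inner <- runif_points(50, c(450, 650), c(450, 650))  # 0.04 mm^2 window
  d <- region_density(inner, ann)
  expect_equal(d$density[d$region == "TC"], 50 / 1.0, tolerance = 1e-6)
  # the same 50 points against a 200x200 um TC give 1250 cells/mm^2
  small <- tumor_annotation(cbind(c(450, 650, 650, 450), c(450, 450, 650, 650)),
                            extent = ann$extent, im_width = 100)
  d2 <- region_density(inner, small)
  expect_equal(d2$density[d2$region == "TC"], 1250, tolerance = 1e-6)
  expect_equal(region_density(inner[0, ], ann)$density, rep(0, 3))
  # with disjoint regions, the union density lies between the parts
  set.seed(52)
  pts <- runif_points(3000, ann$extent[1:2], ann$extent[3:4])
  dd <- region_density(pts, ann, disjoint = TRUE)
  expect_gte(dd$density[3], min(dd$density[1:2]) - 1e-9)
  expect_lte(dd$density[3], max(dd$density[1:2]) + 1e-9)
})

test_that("densities are invariant to rigid motion of pattern plus annotation", {
  set.seed(53)
  spec <- cohort_spec()
  ann <- simulate_geometry(spec)
  pat <- simulate_pattern(ann, 400, 2)
  d0 <- region_density(pat, ann)
  th <- 0.3; sh <- c(150, -80)
  rot <- function(m) cbind(cos(th) * m[, 1] - sin(th) * m[, 2] + sh[1],
                           sin(th) * m[, 1] + cos(th) * m[, 2] + sh[2])
  ann2 <- tumor_annotation(rot(ann$tc_polygon), extent = ann$extent + c(-500, 500, -500, 500),
                           im_width = ann$im_width)
  pat2 <- tibble::as_tibble(setNames(as.data.frame(rot(cbind(pat$x, pat$y))), c("x", "y")))
  d1 <- region_density(pat2, ann2)
  expect_equal(d1$n_cells, d0$n_cells)
  expect_equal(d1$density, d0$density, tolerance = 0.02)  # areas re-integrated numerically
})

test_that("tile densities and hotspots follow the sort-and-rank rule", {
  ann <- square_annotation(side_um = 1000, im_width = 100)
  grid <- effective_tiles(make_tile_grid(ann$extent, 0.2, 1000), ann, "TC")
  tile_mm2 <- 0.04
  # all points in one tile
  pts <- runif_points(40, c(410, 590), c(410, 590))
  td <- tile_densities(pts, grid)
  expect_equal(sum(td$n_cells), 40)
  expect_equal(max(td$density), 40 / tile_mm2)
  expect_equal(sum(td$density > 0), 1)
  h <- hotspot_top3(td)
  expect_equal(h$density, c(1000, 0, 0))
  expect_equal(h$hotspot, 1:3)
  # hand fixture {5, 3, 9, 1} -> (9, 5, 3)
  fake <- tibble::tibble(tile = 1:4, density = c(5, 3, 9, 1))
  expect_equal(hotspot_top3(fake)$density, c(9, 5, 3))
  # ties break by ascending tile index; short input pads with NA
  tie <- tibble::tibble(tile = c(7, 2, 5), density = c(4, 4, 4))
  expect_equal(hotspot_top3(tie)$tile, c(2, 5, 7))
  two <- tibble::tibble(tile = 1:2, density = c(2, 8))
  expect_equal(hotspot_top3(two)$density, c(8, 2, NA))
  expect_error(hotspot_top3(fake[0, ]), "no effective tiles")
})

test_that("hotspot extraction equals a brute-force sort oracle on random grids", {
  set.seed(54)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    dens <- round(runif(n, 0, 50), 2)
    tiles <- tibble::tibble(tile = sample.int(1000, n), density = dens)
    got <- hotspot_top3(tiles)
    ord <- tiles[order(-tiles$density, tiles$tile), ]
    expect_equal(got$density, ord$density[1:3])
    expect_equal(got$tile, ord$tile[1:3])
    expect_gte(got$density[1], mean(tiles$density))
  }
})

test_that("the MH index matches its closed forms and invariances", {
  expect_equal(mh_index(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mh_index(c(1, 1, 0, 0), c(0, 0, 2, 5)), 0)
  # hand evaluation: p = (1, 0), q = (0.5, 0.5) -> 2*(0.5) / (1 + 0.5)
  expect_equal(mh_index(c(1, 0), c(0.5, 0.5)), 2 / 3, tolerance = 1e-12)
  set.seed(55)
  for (i in 1:200) {
    k <- sample(2:50, 1)
    p <- rdirichlet1(k); q <- rdirichlet1(k)
    v <- mh_index(p, q)
    expect_equal(v, mh_index(q, p))                 # symmetry
    expect_equal(v, mh_index(p * 37.5, q))          # count-scale invariance
    expect_equal(v, mh_oracle(p, q), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
  }
  expect_warning(out <- mh_index(c(0, 0), c(1, 2)), "empty")
  expect_true(is.na(out))
})

test_that("pooled immune-vs-CK MH equals MH on concatenated points", {
  set.seed(56)
  ann <- square_annotation(side_um = 1200, im_width = 100)
  grid <- effective_tiles(make_tile_grid(ann$extent, 0.2, 1000), ann, "TC")
  a <- runif_points(300, c(350, 1400), c(350, 1400))
  b <- runif_points(200, c(350, 1400), c(350, 1400))
  ck <- runif_points(500, c(350, 1400), c(350, 1400))
  pooled <- mh_pooled_immune_vs_ck(list(a, b), ck, grid)
  manual <- mh_index(tile_distribution(dplyr::bind_rows(a, b), grid),
                     tile_distribution(ck, grid))
  expect_equal(pooled, manual)
  # pooling a single marker reduces to the pairwise index
  expect_equal(mh_pooled_immune_vs_ck(list(a), ck, grid),
               mh_index(tile_distribution(a, grid), tile_distribution(ck, grid)))
  # identical point sets colocalize perfectly
  expect_equal(mh_pooled_immune_vs_ck(list(ck), ck, grid), 1)
})

test_that("the patient parameter vector assembles 47 parameters in the documented order", {
  set.seed(57)
  spec <- cohort_spec()
  ann <- simulate_geometry(spec)
  slides <- lapply(spec$markers, function(m)
    simulate_pattern(ann, spec$base_intensity[[m]], spec$im_enrichment[[m]], spec$cluster))
  names(slides) <- spec$markers
  pv <- quantify_patient(slides, ann)
  expect_equal(ncol(pv), 47)
  expect_identical(names(pv)[1:3], c("TC_CD3", "IM_CD3", "TCIM_CD3"))
  expect_identical(names(pv)[47], "Immunoscore")
  expect_true(is.na(pv$Immunoscore))  # cohort percentiles not yet available
  # stage-by-stage oracle for a handful of entries
  areas <- region_areas(ann)
  d_cd3 <- region_density(slides$CD3, ann, areas = areas)
  expect_equal(pv$TC_CD3, d_cd3$density[d_cd3$region == "TC"])
  expect_equal(pv$IM_CD3, d_cd3$density[d_cd3$region == "IM"])
  grid_tc <- effective_tiles(make_tile_grid(ann$extent, 0.2, 1000), ann, "TC")
  h_cd8 <- hotspot_top3(tile_densities(slides$CD8, grid_tc))
  expect_equal(pv$Hotspot1_CD8, h_cd8$density[1])
  expect_equal(pv$Hotspot3_CD8, h_cd8$density[3])
  grid_u <- effective_tiles(make_tile_grid(ann$extent, 0.2, 1000), ann, "TC+IM")
  expect_equal(pv$MH_CD3_CD4, mh_index(tile_distribution(slides$CD3, grid_u),
                                       tile_distribution(slides$CD4, grid_u)))
  expect_equal(pv$MH_CK_Immune,
               mh_pooled_immune_vs_ck(slides[c("CD3", "CD4", "CD8", "CD19", "CD163")],
                                      slides$CK, grid_u))
  # a missing marker slide blanks exactly its dependent entries
  slides2 <- slides; slides2$CD19 <- slides$CD19[0, ]
  pv2 <- quantify_patient(slides2, ann)
  cd19_cols <- grep("CD19", names(pv2), value = TRUE)
  expect_true(all(is.na(unlist(pv2[cd19_cols]))))
  other <- setdiff(names(pv2), c(cd19_cols, "Immunoscore"))
  expect_false(anyNA(unlist(pv2[other])))
})
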
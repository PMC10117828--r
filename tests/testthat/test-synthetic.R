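# The synthetic-cohort generator: geometry, point process, misalignment,
# survival.

test_that("generated tumor polygons are simple across many seeds", {
  spec <- cohort_spec()
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    ann <- simulate_geometry(spec)
    immunoscape:::ring_is_simple(ann$tc_polygon)
  }, logical(1))
  expect_true(all(ok))
})

test_that("unperturbed geometry is an exact ellipse and generation is deterministic", {
  spec <- cohort_spec()
  spec$geometry$perturbation <- 0
  set.seed(5)
  ann <- simulate_geometry(spec)
  # all vertices satisfy the (rotated) ellipse equation: radii constant
  ctr <- c(mean(ann$extent[1:2]), mean(ann$extent[3:4]))
  d <- sweep(ann$tc_polygon, 2, ctr)
  # an affine map takes it to a circle: check via the fitted conic residual
  M <- cbind(d[, 1]^2, d[, 1] * d[, 2], d[, 2]^2)
  coef <- qr.solve(M, rep(1, nrow(M)))
  expect_lt(max(abs(M %*% coef - 1)), 1e-8)
  set.seed(77)
  a1 <- simulate_geometry(spec)
  set.seed(77)
  a2 <- simulate_geometry(spec)
  expect_identical(a1$tc_polygon, a2$tc_polygon)
})

test_that("the point process realizes the configured region intensities", {
  set.seed(31)
  spec <- cohort_spec()
  ann <- simulate_geometry(spec)
  # zero intensity -> no points
  expect_equal(nrow(simulate_pattern(ann, 0, 2)), 0)
  # Monte-Carlo check of the generator contract: band density ~= 2x core
  # density (core measured outside the band, regions disjoint)
  areas <- region_areas(ann, disjoint = TRUE)
  a_tc <- areas$area_mm2[areas$region == "TC"]
  a_im <- areas$area_mm2[areas$region == "IM"]
  ratios <- replicate(200, {
    p <- simulate_pattern(ann, 500, 2, spec$cluster)
    lab <- assign_region(p, ann, disjoint = TRUE)
    (sum(lab$in_im) / a_im) / (sum(lab$in_tc) / a_tc)
  })
  expect_equal(mean(ratios), 2.0, tolerance = 0.1)
})

test_that("large cluster scatter approaches the Poisson (CSR) limit in tile counts", {
  set.seed(32)
  # square tumor filling most of the slide, so most tiles are interior
  ann <- square_annotation(side_um = 3000, margin_um = 400, im_width = 100)
  grid <- effective_tiles(make_tile_grid(ann$extent, 0.2, 1000), ann, region = "TC")
  vmr <- function(sigma_um) {
    mean(replicate(10, {
      p <- simulate_pattern(ann, 300, 1, cluster = list(sigma_um = sigma_um, mu = 15))
      td <- tile_densities(p, grid)
      interior <- td[td$frac == 1, ]
      var(interior$n_cells) / mean(interior$n_cells)
    }))
  }
  expect_lt(vmr(5000), 1.6)   # near-Poisson
  expect_gt(vmr(40), 3)       # strongly clustered
})

test_that("misalignment transforms behave as exact, reproducible maps", {
  set.seed(33)
  ann <- square_annotation()
  pts <- runif_points(500, c(400, 1200), c(400, 1200))
  # zero-amplitude parameters -> identity
  tr0 <- sample_misalignment(list(max_rotation_deg = 0, max_translation_um = 0,
                                  warp_amplitude_um = 0, n_warp_components = 3),
                             ann$extent)
  expect_equal(apply_misalignment(pts, tr0)$x, pts$x, tolerance = 1e-12)
  # pure translation shifts every point exactly
  tr_t <- tr0
  tr_t$translation <- c(10, -5)
  moved <- apply_misalignment(pts, tr_t)
  expect_equal(moved$x, pts$x + 10, tolerance = 1e-9)
  expect_equal(moved$y, pts$y - 5, tolerance = 1e-9)
  # stored ground truth reproduces the misaligned coordinates exactly
  tr <- sample_misalignment(list(max_rotation_deg = 10, max_translation_um = 50,
                                 warp_amplitude_um = 20, n_warp_components = 3),
                            ann$extent)
  m1 <- apply_misalignment(pts, tr)
  m2 <- apply_misalignment(pts, tr)
  expect_lt(max(abs(m1$x - m2$x) + abs(m1$y - m2$y)), 1e-9)
  # a pattern pushed past the slide edge errors
  edge <- tibble::tibble(x = ann$extent[2] - 1, y = ann$extent[4] - 1)
  tr_big <- tr0; tr_big$translation <- c(500, 0)
  expect_error(apply_misalignment(edge, tr_big, extent = ann$extent), "extent")
})

test_that("survival generation follows the planted proportional-hazards model", {
  set.seed(34)
  hz <- cohort_spec()$hazard
  dens <- tibble::tibble(TC_CD3 = rlnorm(1000, 6, 0.5))
  # null model: no density-survival link
  hz0 <- hz; hz0$log_hr <- c(TC_CD3 = 0); hz0$censoring_rate <- 0
  s0 <- simulate_survival(dens, hz0)
  expect_lt(abs(cor(s0$dfs_months, dens$TC_CD3)), 0.08)
  expect_true(all(s0$dfs_months <= s0$os_months + 1e-12))
  # planted log-HR recovered by a Cox fit on the true densities
  hz1 <- hz; hz1$log_hr <- c(TC_CD3 = -0.7); hz1$censoring_rate <- 0.2
  s1 <- simulate_survival(dens, hz1)
  z <- as.numeric(scale(dens$TC_CD3))
  fit <- survival::coxph(survival::Surv(s1$dfs_months, s1$dfs_event) ~ z)
  expect_equal(unname(coef(fit)), -0.7, tolerance = 0.15)
  # invalid configurations are rejected
  hz_bad <- hz; hz_bad$censoring_rate <- 1
  expect_error(simulate_survival(dens, hz_bad), "censoring")
  hz_neg <- hz; hz_neg$baseline_dfs <- -1
  expect_error(simulate_survival(dens, hz_neg), "baseline")
})

test_that("identical spec and seed give byte-identical cohorts", {
  spec <- cohort_spec(n_patients = 2, seed = 99)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
})
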
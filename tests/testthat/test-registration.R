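# Rasterization, rigid and demons registration, point transfer.

test_that("rasterization conserves mass and localizes points", {
  ext <- c(0, 640, 0, 640)
  one <- tibble::tibble(x = 320, y = 320)
  img <- rasterize_pattern(one, ext, side = 64, sigma = 0)
  expect_equal(sum(img), 1)
  hit <- which(img > 0, arr.ind = TRUE)
  expect_equal(unname(hit), matrix(c(33, 33), 1))  # centre bin (half-open)
  set.seed(41)
  pts <- runif_points(500, ext[1:2], ext[3:4])
  expect_equal(sum(rasterize_pattern(pts, ext, 64, sigma = 0)), 500)
  expect_warning(rasterize_pattern(pts[0, ], ext, 64), "empty")
})

test_that("a planted translation produces the right cross-correlation peak", {
  set.seed(42)
  ext <- c(0, 640, 0, 640)  # 10 um per working pixel at side 64
  pts <- runif_points(800, c(100, 500), c(100, 500))
  a <- rasterize_pattern(pts, ext, 64, sigma = 1)
  b <- rasterize_pattern(dplyr::mutate(pts, x = x + 100), ext, 64, sigma = 1)
  # pull-back: sampling the un-shifted image 10 px back reproduces the
  # shifted one, so the estimated u is -10 px along x
  got <- immunoscape:::xcorr_peak(b, a, 16)$u
  # brute-force correlation oracle over integer shifts of b against a
  best <- c(NA, NA); bestv <- -Inf
  for (dr in -12:12) for (dc in -12:12) {
    ra <- max(1, 1 + dr):min(64, 64 + dr)
    va <- a[ra - dr, , drop = FALSE]; vb <- b[ra, , drop = FALSE]
    rc <- max(1, 1 + dc):min(64, 64 + dc)
    v <- sum(va[, rc - dc] * vb[, rc])
    if (v > bestv) { bestv <- v; best <- c(dr, dc) }
  }
  expect_equal(best, c(10, 0))
  expect_equal(round(got), -best)
})

test_that("rigid registration recovers planted transforms and never hurts the score", {
  set.seed(43)
  spec <- cohort_spec()
  ann <- simulate_geometry(spec)
  pat <- simulate_pattern(ann, 800, 1.5)
  fixed <- rasterize_pattern(pat, ann$extent, 500, 2)
  # moving = fixed: near-identity estimate
  self <- register_rigid(fixed, fixed)
  expect_lt(abs(self$theta) * 180 / pi, 0.1)
  expect_lt(max(abs(self$u)), 0.5)
  expect_gte(self$score, self$score_identity)
  # planted rotation + shift on the same pattern
  tr <- sample_misalignment(list(max_rotation_deg = 0, max_translation_um = 0,
                                 warp_amplitude_um = 0, n_warp_components = 1),
                            ann$extent)
  tr$theta <- 5 * pi / 180
  tr$translation <- c(8, -3) * 8  # 8 um per working pixel
  mis <- apply_misalignment(pat, tr, ann$extent)
  est <- register_rigid(rasterize_pattern(pat, ann$extent, 500, 2),
                        rasterize_pattern(mis, ann$extent, 500, 2))
  expect_lt(abs(est$theta + tr$theta) * 180 / pi, 0.5)
  expect_lt(max(abs(est$u * 8 + tr$translation)), 8)  # within 1 working pixel
  # flat image falls back to the identity with a warning
  expect_warning(register_rigid(matrix(1, 128, 128), matrix(1, 128, 128)), "flat")
})

test_that("demons registration recovers a planted smooth warp", {
  set.seed(44)
  n <- 200
  xy <- expand.grid(r = seq_len(n) - 1, c = seq_len(n) - 1)
  base <- matrix(0, n, n)
  for (k in 1:30) {  # smooth random blobs
    cr <- runif(1, 20, n - 20); cc <- runif(1, 20, n - 20)
    base <- base + matrix(exp(-((xy$r - cr)^2 + (xy$c - cc)^2) / (2 * 12^2)), n, n)
  }
  # identical images: displacement stays at the regularization floor
  f0 <- register_nonrigid(base, base, max_iter = 20)
  expect_lt(max(abs(f0$ux)), 0.2)
  expect_lte(f0$mse, f0$trace[1])
  # planted sinusoidal warp of amplitude 5 px, pull-back sampled
  ur_true <- matrix(5 * sin(2 * pi * xy$r / n) * sin(2 * pi * xy$c / n), n, n)
  uc_true <- matrix(5 * cos(2 * pi * xy$r / n) * sin(2 * pi * xy$c / n), n, n)
  warped <- matrix(immunoscape:::cpp_bilinear_sample(base, xy$r + as.vector(ur_true),
                                                     xy$c + as.vector(uc_true)), n, n)
  # fixed = warped, moving = base: the true field IS (ur_true, uc_true)
  fit <- register_nonrigid(base, warped, sigma_field = 8, max_iter = 80)
  err <- sqrt((fit$ux - ur_true)^2 + (fit$uy - uc_true)^2)
  interior <- err[30:(n - 30), 30:(n - 30)]
  expect_lt(mean(interior), 1.5)
  expect_lte(fit$mse, fit$trace[1])
})

test_that("point transfer converts field units correctly", {
  ext <- c(0, 1000, 0, 1000)
  pts <- tibble::tibble(x = c(200, 500, 900), y = c(300, 500, 100))
  # zero field -> identity
  zf <- deformation_field(matrix(0, 100, 100), matrix(0, 100, 100), ext)
  expect_equal(transform_points(zf, pts, extent = ext), pts, ignore_attr = TRUE)
  # constant displacement of 5 full-resolution pixels at 0.2 um/px = 1 um in x
  cf <- deformation_field(matrix(5, 100, 100), matrix(0, 100, 100), ext,
                          units = "px", resolution = 0.2)
  out <- transform_points(cf, pts, extent = ext)
  expect_equal(out$x, pts$x + 1, tolerance = 1e-9)
  expect_equal(out$y, pts$y)
  # micrometre units pass through unchanged
  uf <- deformation_field(matrix(-3, 50, 50), matrix(7, 50, 50), ext, units = "um")
  out2 <- transform_points(uf, pts, extent = ext)
  expect_equal(out2$x, pts$x - 3, tolerance = 1e-9)
  expect_equal(out2$y, pts$y + 7, tolerance = 1e-9)
})

test_that("stacks align to the middle slide and report per-slide scores", {
  expect_equal(middle_slide_index(7), 4)  # 4th of 7 serial sections
  expect_equal(middle_slide_index(6), 3)
  set.seed(45)
  spec <- cohort_spec()
  ann <- simulate_geometry(spec)
  pat <- simulate_pattern(ann, 400, 1.5)
  slides <- lapply(1:7, function(i) {
    tr <- sample_misalignment(spec$misalignment, ann$extent)
    apply_misalignment(pat, tr, ann$extent)
  })
  names(slides) <- paste0("s", 1:7)
  slides$s4 <- pat  # reference slide stays un-misaligned
  al <- align_slides(slides, ann$extent, working_side = 128, nonrigid = FALSE)
  expect_identical(al$reference, "s4")
  expect_equal(sum(vapply(al$registrations, function(r) isTRUE(r$identity), logical(1))), 1)
  expect_equal(sum(!vapply(al$registrations, function(r) isTRUE(r$identity), logical(1))), 6)
  expect_true(all(al$scores$score_after >= al$scores$score_before - 1e-9))
  expect_error(align_slides(list(), ann$extent), "empty")
  # single slide: identity result
  single <- align_slides(slides[4], ann$extent)
  expect_true(al$registrations$s4$identity)
  expect_identical(single$slides[[1]], slides[[4]])
})
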
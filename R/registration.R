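# Slide-to-slide registration on downsampled density rasters: a rigid step
# (normalized cross-correlation over rotation x translation) followed by a
# diffusion-regularized demons non-rigid step, and transfer of
# full-resolution point coordinates through the interpolated field.
#
# Convention (pull-back): register_rigid()/register_nonrigid() estimate a
# transform T with moving(T(x)) ~= fixed(x). When the *reference* slide plays
# the moving role and a misaligned slide plays the fixed role, T maps the
# misaligned slide's coordinates into the reference frame, so the estimated
# transform applies directly to that slide's cell coordinates
# (transform_points()). Composition is rigid o (id + nonrigid displacement):
# a point p is first offset by the interpolated demons field, then passed
# through the rigid transform.

#' Rasterize a point pattern to a working-scale density image
#'
#' 2-D histogram of the points over a `side` x `side` grid spanning
#' `extent`, optionally Gaussian-smoothed. Before smoothing the image sums
#' to the number of in-extent points.
#'
#' @param points data frame with `x`, `y` in micrometres.
#' @param extent `c(xmin, xmax, ymin, ymax)` in micrometres.
#' @param side working-scale image side in pixels (default 500).
#' @param sigma smoothing sd in working pixels (0 = no smoothing).
#' @return `side` x `side` matrix; `img[i, j]` is the bin at x-index `i`,
#'   y-index `j`. Attributes: `extent`, `px_um` (x and y micrometres per
#'   working pixel).
#' @export
rasterize_pattern <- function(points, extent, side = 500, sigma = 2) {
  stopifnot(side >= 64)
  px <- c((extent[2] - extent[1]) / side, (extent[4] - extent[3]) / side)
  if (nrow(points) == 0) {
    warning("empty pattern: returning a zero image")
    img <- matrix(0, side, side)
  } else {
    ix <- pmin(side, pmax(1, floor((points$x - extent[1]) / px[1]) + 1L))
    iy <- pmin(side, pmax(1, floor((points$y - extent[3]) / px[2]) + 1L))
    img <- matrix(tabulate((iy - 1L) * side + ix, nbins = side * side), side, side)
  }
  if (sigma > 0) img <- cpp_gauss_blur(img, sigma)
  structure(img, extent = as.numeric(extent), px_um = px, sigma = sigma)
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

# cross-correlation via FFT; returns best integer + parabolic-subpixel shift
# u (rows, cols) within |u| <= max_shift, and the raw correlation peak
xcorr_peak <- function(fixed, moving, max_shift) {
  n <- nrow(fixed)
  C <- Re(stats::fft(Conj(stats::fft(fixed)) * stats::fft(moving), inverse = TRUE)) / (n * n)
  # u = 0 at [1,1]; wrap negative shifts
  idx <- c(0:max_shift, (n - max_shift):(n - 1))
  shifts <- c(0:max_shift, -(max_shift:1))
  W <- C[idx + 1, idx + 1]
  best <- arrayInd(which.max(W), dim(W))
  u <- c(shifts[best[1]], shifts[best[2]])
  # parabolic refinement along each axis (circular neighbours in C)
  ref1 <- function(i0, j0, axis) {
    get <- function(di, dj) C[(i0 + di) %% n + 1, (j0 + dj) %% n + 1]
    c0 <- get(0, 0)
    if (axis == 1) { cm <- get(-1, 0); cp <- get(1, 0) } else { cm <- get(0, -1); cp <- get(0, 1) }
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  i0 <- u[1] %% n; j0 <- u[2] %% n
  u <- u + c(ref1(i0, j0, 1), ref1(i0, j0, 2))
  list(u = u, peak = max(W))
}

block_downsample <- function(img, f) {
  n <- nrow(img); m <- (n %/% f) * f
  img <- img[seq_len(m), seq_len(m)]
  g <- m %/% f
  out <- matrix(0, g, g)
  for (a in seq_len(f)) for (b in seq_len(f))
    out <- out + img[seq(a, m, by = f), seq(b, m, by = f)]
  out / f^2
}

#' Rigid registration by rotation-translation search
#'
#' Finds the rotation and translation maximizing the normalized
#' cross-correlation between `moving` resampled through the candidate
#' transform and `fixed`. The search is coarse-to-fine: a coarse angle grid
#' on 4x-downsampled images, then local refinement at full working scale
#' with FFT cross-correlation for the translation and parabolic sub-pixel /
#' sub-step interpolation. If no candidate beats the identity transform, the
#' identity is returned (registration never worsens similarity).
#'
#' @param moving,fixed equal-sized working-scale images
#'   ([rasterize_pattern()]).
#' @param max_rotation_deg half-width of the rotation search (default 12).
#' @param max_shift_px half-width of the translation search in working
#'   pixels (default side/6).
#' @param coarse_step_deg,refine_step_deg angle grid steps.
#' @return Object of class `rigid_transform`: `theta` (radians), `u`
#'   (translation, working pixels, row/col order), `center`, `score`
#'   (NCC after), `score_identity`.
#' @export
register_rigid <- function(moving, fixed, max_rotation_deg = 12,
                           max_shift_px = NULL,
                           coarse_step_deg = 1, refine_step_deg = 0.25) {
  stopifnot(all(dim(moving) == dim(fixed)))
  n <- nrow(fixed)
  if (is.null(max_shift_px)) max_shift_px <- floor(n / 6)
  identity <- structure(
    list(theta = 0, u = c(0, 0), center = c((n - 1) / 2, (n - 1) / 2),
         score = ncc(moving, fixed), score_identity = ncc(moving, fixed), side = n),
    class = "rigid_transform")
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0) {
    warning("flat image: returning identity transform")
    return(identity)
  }
  # coarse angle grid on 4x-downsampled images, refinement on 2x
  search_level <- function(img_f, img_m, angles, shift) {
    peaks <- vapply(angles, function(th) {
      rot <- cpp_rigid_resample(img_m, th, 0, 0)
      xcorr_peak(img_f, rot, shift)$peak
    }, numeric(1))
    k <- which.max(peaks)
    theta <- angles[k]
    if (k > 1 && k < length(angles)) {
      den <- peaks[k - 1] - 2 * peaks[k] + peaks[k + 1]
      step <- angles[2] - angles[1]
      if (den < 0) theta <- theta + step *
          max(-0.5, min(0.5, 0.5 * (peaks[k - 1] - peaks[k + 1]) / den))
    }
    theta
  }
  fx4 <- block_downsample(fixed, 4L); mv4 <- block_downsample(moving, 4L)
  th0 <- search_level(fx4, mv4,
                      seq(-max_rotation_deg, max_rotation_deg, by = coarse_step_deg) * pi / 180,
                      max(2L, ceiling(max_shift_px / 4)))
  fx2 <- block_downsample(fixed, 2L); mv2 <- block_downsample(moving, 2L)
  theta <- search_level(fx2, mv2,
                        seq(th0 - 1.25 * pi / 180, th0 + 1.25 * pi / 180,
                            by = refine_step_deg * pi / 180),
                        max(2L, ceiling(max_shift_px / 2)))
  rot <- cpp_rigid_resample(moving, theta, 0, 0)
  u <- xcorr_peak(fixed, rot, max_shift_px)$u
  # u found as shift of the rotated moving image in its own frame:
  # warped(x) = moving(R(x + R^-1 u' ...)); resample directly to score
  warped <- cpp_rigid_resample(moving, theta, u[1], u[2])
  score <- ncc(warped, fixed)
  if (score < identity$score_identity) {
    warning("rigid search did not beat the identity; returning identity")
    return(identity)
  }
  structure(list(theta = theta, u = u, center = c((n - 1) / 2, (n - 1) / 2),
                 score = score, score_identity = identity$score_identity, side = n),
            class = "rigid_transform")
}

#' Apply a rigid transform to a working-scale image
#' @param transform a `rigid_transform`.
#' @param img working-scale image.
#' @return Resampled image.
#' @export
apply_rigid <- function(transform, img) {
  cpp_rigid_resample(img, transform$theta, transform$u[1], transform$u[2])
}

#' Demons non-rigid registration
#'
#' Iterative demons displacement estimation with diffusion-like
#' regularization (the field is Gaussian-smoothed each iteration). The rigid
#' step must already be applied to `moving`. Iterations stop at `max_iter`
#' or when the mean-squared dissimilarity stops improving by a relative
#' `tol` for `patience` successive iterations; the best-so-far field is
#' returned, so the final dissimilarity never exceeds the initial one.
#'
#' @param moving,fixed equal-sized working-scale images, rigidly aligned.
#' @param sigma_field regularization: Gaussian sd (working pixels) applied
#'   to the displacement field each iteration.
#' @param max_iter,step,tol,patience iteration controls.
#' @return Object of class `deformation_field`: matrices `ux`, `uy`
#'   (displacement in working pixels along the x- and y-index axes), `mse`,
#'   `trace`, `side`.
#' @export
register_nonrigid <- function(moving, fixed, sigma_field = 8, max_iter = 60,
                              step = 1.5, tol = 1e-4, patience = 5) {
  stopifnot(all(dim(moving) == dim(fixed)))
  fit <- cpp_demons(fixed, moving, sigma_field, max_iter, step, tol, patience)
  if (fit$mse > fit$trace[1]) {
    warning("demons iterations diverged; returning zero field")
    fit$ur <- fit$ur * 0; fit$uc <- fit$uc * 0; fit$mse <- fit$trace[1]
  }
  structure(list(ux = fit$ur, uy = fit$uc, mse = fit$mse, trace = fit$trace,
                 side = nrow(fixed)),
            class = "deformation_field")
}

#' Construct a deformation field from displacement grids
#'
#' Displacements may be given in micrometres or in full-resolution pixels
#' (converted via `resolution` micrometres/pixel); internally the field is
#' kept in working pixels of the grid it is defined on.
#'
#' @param dx,dy displacement grids along x and y.
#' @param extent slide extent in micrometres the grids span.
#' @param units `"px_work"`, `"um"` or `"px"` (full-resolution pixels).
#' @param resolution micrometres per full-resolution pixel (for
#'   `units = "px"`).
#' @return A `deformation_field`.
#' @export
deformation_field <- function(dx, dy, extent, units = c("px_work", "um", "px"),
                              resolution = 0.2) {
  units <- match.arg(units)
  stopifnot(all(dim(dx) == dim(dy)), nrow(dx) == ncol(dx))
  side <- nrow(dx)
  px <- c((extent[2] - extent[1]) / side, (extent[4] - extent[3]) / side)
  if (units == "um") { dx <- dx / px[1]; dy <- dy / px[2] }
  if (units == "px") { dx <- dx * resolution / px[1]; dy <- dy * resolution / px[2] }
  if (any(!is.finite(dx)) || any(!is.finite(dy))) stop("non-finite displacements")
  structure(list(ux = dx, uy = dy, mse = NA_real_, trace = numeric(0), side = side),
            class = "deformation_field")
}

#' Full registration of one slide against a reference
#'
#' Registers in the pull-back sense (reference as moving image, slide as
#' fixed image), so the estimated transform maps slide coordinates into the
#' reference frame.
#'
#' @param slide_points,reference_points point tables (`x`, `y` um).
#' @param extent slide extent in micrometres.
#' @param working_side working-scale image side (default 500).
#' @param sigma raster smoothing sd in working pixels.
#' @param nonrigid run the demons step after the rigid step.
#' @param ... passed to [register_rigid()] and [register_nonrigid()].
#' @return Object of class `slide_registration`: `rigid`, `field` (or NULL),
#'   `extent`, `working_side`, `score_before`, `score_after`.
#' @export
register_slide <- function(slide_points, reference_points, extent,
                           working_side = 500, sigma = 2, nonrigid = TRUE, ...) {
  dots <- list(...)
  take <- function(f) dots[intersect(names(dots), names(formals(f)))]
  fixed <- rasterize_pattern(slide_points, extent, working_side, sigma)
  moving <- rasterize_pattern(reference_points, extent, working_side, sigma)
  rigid <- do.call(register_rigid, c(list(moving = moving, fixed = fixed), take(register_rigid)))
  field <- NULL
  score_after <- rigid$score
  if (nonrigid) {
    moving2 <- apply_rigid(rigid, moving)
    field <- do.call(register_nonrigid,
                     c(list(moving = moving2, fixed = fixed), take(register_nonrigid)))
    warped <- warp_image(field, moving2)
    score_after <- max(ncc(warped, fixed), rigid$score)
  }
  structure(list(rigid = rigid, field = field, extent = as.numeric(extent),
                 working_side = working_side,
                 score_before = rigid$score_identity, score_after = score_after),
            class = "slide_registration")
}

# warp an image through a deformation field (pull-back)
warp_image <- function(field, img) {
  n <- nrow(img)
  r <- matrix(rep(seq_len(n) - 1, n), n, n)
  c_ <- t(r)
  w <- cpp_bilinear_sample(img, as.vector(r + field$ux), as.vector(c_ + field$uy))
  matrix(w, n, n)
}

#' Transfer full-resolution point coordinates through a registration
#'
#' Converts micrometre coordinates to working-scale pixel coordinates,
#' offsets each point by the bilinearly interpolated demons displacement,
#' applies the rigid transform and converts back to micrometres. Points
#' outside the field domain are handled by nearest-edge extrapolation and
#' counted in the `n_extrapolated` attribute.
#'
#' @param registration a `slide_registration` (or `rigid_transform` /
#'   `deformation_field` with `extent` supplied).
#' @param points data frame with `x`, `y` in micrometres.
#' @param extent required when `registration` is not a `slide_registration`.
#' @return The input tibble with transformed `x`, `y`.
#' @export
transform_points <- function(registration, points, extent = NULL) {
  if (inherits(registration, "slide_registration")) {
    rigid <- registration$rigid; field <- registration$field
    extent <- registration$extent; side <- registration$working_side
  } else if (inherits(registration, "deformation_field")) {
    rigid <- NULL; field <- registration; side <- registration$side
    if (is.null(extent)) stop("`extent` required")
  } else if (inherits(registration, "rigid_transform")) {
    rigid <- registration; field <- NULL; side <- registration$side
    if (is.null(extent)) stop("`extent` required")
  } else stop("unsupported registration object")
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) return(points)
  x <- points$x; y <- points$y
  n_extra <- 0L
  if (!is.null(field)) {
    sf <- field$side
    pxf <- c((extent[2] - extent[1]) / sf, (extent[4] - extent[3]) / sf)
    r <- (x - extent[1]) / pxf[1] - 0.5
    c_ <- (y - extent[3]) / pxf[2] - 0.5
    outside <- r < 0 | r > sf - 1 | c_ < 0 | c_ > sf - 1
    n_extra <- sum(outside)
    if (n_extra > 0) warning(n_extra, " points outside the field domain; nearest-edge extrapolation")
    x <- x + cpp_bilinear_sample(field$ux, r, c_) * pxf[1]
    y <- y + cpp_bilinear_sample(field$uy, r, c_) * pxf[2]
  }
  if (!is.null(rigid)) {
    sr <- rigid$side
    pxr <- c((extent[2] - extent[1]) / sr, (extent[4] - extent[3]) / sr)
    r <- (x - extent[1]) / pxr[1] - 0.5
    c_ <- (y - extent[3]) / pxr[2] - 0.5
    ct <- cos(rigid$theta); st <- sin(rigid$theta)
    dr <- r + rigid$u[1] - rigid$center[1]
    dc <- c_ + rigid$u[2] - rigid$center[2]
    r <- ct * dr - st * dc + rigid$center[1]
    c_ <- st * dr + ct * dc + rigid$center[2]
    x <- (r + 0.5) * pxr[1] + extent[1]
    y <- (c_ + 0.5) * pxr[2] + extent[3]
  }
  points$x <- x
  points$y <- y
  attr(points, "n_extrapolated") <- n_extra
  points
}

#' Middle-slide reference index
#'
#' For a stack of `n` serial sections the reference is the middle slide,
#' e.g. the 4th of 7 (1-based).
#' @param n number of slides.
#' @return 1-based index of the reference slide.
#' @export
middle_slide_index <- function(n) as.integer((n + 1) %/% 2)

#' Align a stack of marker slides to a reference slide
#'
#' Registers every non-reference slide to the reference (default: the middle
#' slide) and transfers each slide's cell coordinates into the reference
#' frame. The reference slide gets an identity result.
#'
#' @param slides named list of point tables (`x`, `y` um), in section order.
#' @param extent slide extent in micrometres.
#' @param reference name or 1-based index of the reference slide (default
#'   the middle of the stack).
#' @inheritParams register_slide
#' @return List with `registrations` (per slide; NULL field/identity for the
#'   reference), `slides` (transformed point tables), `reference` (name),
#'   `scores` tibble.
#' @export
align_slides <- function(slides, extent, reference = NULL, working_side = 500,
                         sigma = 2, nonrigid = TRUE, ...) {
  if (length(slides) == 0) stop("empty slide list")
  if (is.null(names(slides))) names(slides) <- paste0("slide", seq_along(slides))
  if (is.null(reference)) reference <- middle_slide_index(length(slides))
  if (is.character(reference)) reference <- match(reference, names(slides))
  if (is.na(reference) || reference < 1 || reference > length(slides))
    stop("invalid reference slide")
  ref_name <- names(slides)[reference]
  regs <- vector("list", length(slides)); names(regs) <- names(slides)
  out <- slides
  for (i in seq_along(slides)) {
    if (i == reference) {
      regs[[i]] <- structure(list(rigid = NULL, field = NULL,
                                  extent = as.numeric(extent),
                                  working_side = working_side,
                                  score_before = 1, score_after = 1,
                                  identity = TRUE),
                             class = "slide_registration")
      next
    }
    regs[[i]] <- register_slide(slides[[i]], slides[[reference]], extent,
                                working_side = working_side, sigma = sigma,
                                nonrigid = nonrigid, ...)
    out[[i]] <- transform_points(regs[[i]], slides[[i]])
  }
  scores <- tibble::tibble(
    slide = names(slides),
    reference = names(slides) == ref_name,
    score_before = vapply(regs, `[[`, numeric(1), "score_before"),
    score_after = vapply(regs, `[[`, numeric(1), "score_after"))
  list(registrations = regs, slides = out, reference = ref_name, scores = scores)
}

#' @export
print.slide_registration <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<slide_registration> identity (reference slide)\n")
  } else {
    cat(sprintf(
      "<slide_registration> rigid: %.2f deg, shift (%.2f, %.2f) px | nonrigid: %s | NCC %.3f -> %.3f\n",
      x$rigid$theta * 180 / pi, x$rigid$u[1], x$rigid$u[2],
      if (is.null(x$field)) "none" else "demons", x$score_before, x$score_after))
  }
  invisible(x)
}
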
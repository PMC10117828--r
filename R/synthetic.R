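# Synthetic cohorts with the spatial and statistical structure the pipeline
# assumes: blob-like tumor geometries, Thomas-cluster immune/tumor point
# patterns with invasive-margin enrichment, planted per-slide misalignments
# (ground truth retained) and proportional-hazards survival linked to the
# true densities.

#' Cohort simulation settings
#'
#' Defaults describe a 68-patient triple-negative breast cancer cohort with
#' six marker slides per patient (CD3, CD4, CD8, CD19, CD163, CK).
#' Lymphocyte markers are enriched 2x in the invasive margin relative to the
#' tumor core; CD163 macrophages and CK tumor cells are evenly distributed.
#' Heterogeneity is modelled as a Thomas cluster process (Poisson parents,
#' Gaussian-scattered offspring, inhomogeneous thinning to the target
#' region intensities).
#'
#' @param n_patients cohort size (default 68).
#' @param markers marker names, in section order.
#' @param base_intensity named TC intensities, cells/mm^2.
#' @param im_enrichment named multiplicative IM intensity factors.
#' @param resolution micrometres per full-resolution pixel (default 0.2).
#' @param extent_um square slide side in micrometres.
#' @param geometry list: `center_radius_um` (mean tumor radius),
#'   `eccentricity`, `perturbation` (relative radial amplitude),
#'   `n_vertices`.
#' @param im_width_um invasive-margin half-width (default 100).
#' @param cluster list: `sigma_um` (offspring scatter sd), `mu` (mean
#'   offspring per parent).
#' @param misalignment list: `max_rotation_deg`, `max_translation_um`,
#'   `warp_amplitude_um`, `n_warp_components`.
#' @param hazard list: `baseline_dfs`, `baseline_os_lag` (per-month rates),
#'   `log_hr` (named, per unit standardized true density),
#'   `censoring_rate` in \[0, 1), `followup_max` months, `model`
#'   (`"exponential"` or `"weibull"`), `weibull_shape`,
#'   `p_metastasis_given_recurrence`.
#' @param seed integer seed making the cohort reproducible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(
    n_patients = 68,
    markers = c("CD3", "CD4", "CD8", "CD19", "CD163", "CK"),
    base_intensity = c(CD3 = 500, CD4 = 300, CD8 = 250, CD19 = 100,
                       CD163 = 150, CK = 1500),
    im_enrichment = c(CD3 = 2, CD4 = 2, CD8 = 2, CD19 = 2, CD163 = 1, CK = 1),
    resolution = 0.2,
    extent_um = 4000,
    geometry = list(center_radius_um = 1000, eccentricity = 0.8,
                    perturbation = 0.12, n_vertices = 96),
    im_width_um = 100,
    cluster = list(sigma_um = 50, mu = 15),
    misalignment = list(max_rotation_deg = 10, max_translation_um = 50,
                        warp_amplitude_um = 20, n_warp_components = 3),
    hazard = list(baseline_dfs = 0.010, baseline_os_lag = 0.03,
                  log_hr = c(TC_CD3 = -0.7),
                  censoring_rate = 0.5, followup_max = 120,
                  model = "exponential", weibull_shape = 1,
                  p_metastasis_given_recurrence = 0.7),
    seed = 1L) {
  stopifnot(n_patients >= 1, resolution > 0, extent_um > 0,
            all(base_intensity >= 0), all(im_enrichment > 0),
            im_width_um > 0)
  if (hazard$censoring_rate < 0 || hazard$censoring_rate >= 1)
    stop("censoring rate must be in [0, 1)")
  if (hazard$baseline_dfs <= 0 || hazard$baseline_os_lag <= 0)
    stop("baseline hazards must be positive")
  structure(
    list(n_patients = n_patients, markers = markers,
         base_intensity = base_intensity, im_enrichment = im_enrichment,
         resolution = resolution, extent_um = extent_um, geometry = geometry,
         im_width_um = im_width_um, cluster = cluster,
         misalignment = misalignment, hazard = hazard, seed = seed),
    class = "cohort_spec")
}

#' Simulate a blob-like tumor geometry
#'
#' A radially perturbed ellipse centred on the slide: radius
#' `r(t) = a(t) * (1 + sum_k c_k cos(k t + phi_k))` over low harmonics
#' k = 2..5. Degenerate (self-intersecting) polygons are regenerated, up to
#' `max_retries` attempts. The invasive front is the polygon boundary.
#'
#' @param spec a [cohort_spec()].
#' @param max_retries attempts before giving up.
#' @return A [tumor_annotation()].
#' @export
simulate_geometry <- function(spec, max_retries = 20) {
  g <- spec$geometry
  ext <- c(0, spec$extent_um, 0, spec$extent_um)
  ctr <- spec$extent_um / 2
  for (try in seq_len(max_retries)) {
    a <- g$center_radius_um * stats::runif(1, 0.9, 1.1)
    b <- a * g$eccentricity * stats::runif(1, 0.9, 1.1)
    rot <- stats::runif(1, 0, pi)
    t <- seq(0, 2 * pi, length.out = g$n_vertices + 1)[-(g$n_vertices + 1)]
    pert <- rep(0, length(t))
    if (g$perturbation > 0) {
      for (k in 2:5) {
        pert <- pert + stats::runif(1, 0.2, 1) * cos(k * t + stats::runif(1, 0, 2 * pi))
      }
      pert <- pert * g$perturbation / 2
    }
    r <- 1 + pert
    ex <- a * r * cos(t); ey <- b * r * sin(t)
    poly <- cbind(ctr + ex * cos(rot) - ey * sin(rot),
                  ctr + ex * sin(rot) + ey * cos(rot))
    if (ring_is_simple(poly)) {
      return(tumor_annotation(poly, extent = ext, im_width = spec$im_width_um))
    }
  }
  stop("failed to generate a simple tumor polygon after ", max_retries, " attempts")
}

#' Simulate a Thomas-cluster marker point pattern
#'
#' Poisson parents over the (expanded) slide, `Poisson(mu)` offspring per
#' parent scattered `N(0, sigma^2)`, then inhomogeneous thinning to the
#' target intensity surface: `base * enrichment` within the IM band, `base`
#' in the rest of the tumor core, 0 outside the tumor region. Thinning a
#' cluster process preserves its first moment, so realized region densities
#' are Poisson-consistent with the targets (enrichment is realized exactly
#' in the band; the core density measured over the full TC polygon includes
#' the enriched inner band unless regions are treated as disjoint).
#'
#' @param annotation a [tumor_annotation()].
#' @param intensity base TC intensity, cells/mm^2.
#' @param enrichment IM multiplicative factor.
#' @param cluster list with `sigma_um`, `mu`.
#' @return Tibble with `x`, `y` in micrometres.
#' @export
simulate_pattern <- function(annotation, intensity, enrichment = 1,
                             cluster = list(sigma_um = 50, mu = 15)) {
  stopifnot(intensity >= 0, enrichment > 0)
  ext <- annotation$extent
  if (intensity == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  lambda_max <- intensity * max(1, enrichment) / 1e6  # cells per um^2
  sigma <- cluster$sigma_um; mu <- cluster$mu
  pad <- 4 * sigma
  area <- (ext[2] - ext[1] + 2 * pad) * (ext[4] - ext[3] + 2 * pad)
  if (area <= 0) {
    warning("zero-area region: empty pattern")
    return(tibble::tibble(x = numeric(0), y = numeric(0)))
  }
  n_par <- stats::rpois(1, lambda_max / mu * area)
  if (n_par == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  px <- stats::runif(n_par, ext[1] - pad, ext[2] + pad)
  py <- stats::runif(n_par, ext[3] - pad, ext[4] + pad)
  n_off <- stats::rpois(n_par, mu)
  x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  keep <- x >= ext[1] & x <= ext[2] & y >= ext[3] & y <= ext[4]
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  in_im <- in_im_band(x, y, annotation)
  in_tc <- point_in_polygon(x, y, annotation$tc_polygon)
  lambda <- ifelse(in_im, intensity * enrichment, ifelse(in_tc, intensity, 0)) / 1e6
  u <- stats::runif(length(x))
  keep <- u < lambda / lambda_max
  tibble::tibble(x = x[keep], y = y[keep])
}

#' Sample a planted slide misalignment
#'
#' Rotation (uniform within the bound, about the slide centre), translation
#' (uniform per axis) and a smooth warp: per axis, the sum of
#' `n_warp_components` low-frequency sinusoidal displacement components with
#' total amplitude `warp_amplitude_um`. The returned object is the exact
#' forward transform, applied by [apply_misalignment()].
#'
#' @param params misalignment list, see [cohort_spec()].
#' @param extent slide extent in micrometres.
#' @return Object of class `misalignment` (theta, translation, warp
#'   coefficients, centre).
#' @export
sample_misalignment <- function(params, extent) {
  L <- max(extent[2] - extent[1], extent[4] - extent[3])
  nw <- params$n_warp_components
  warp <- lapply(c("x", "y"), function(axis) {
    list(amp = params$warp_amplitude_um / nw * stats::runif(nw, 0.5, 1),
         fx = stats::runif(nw, 0.3, 1.2) / L,
         fy = stats::runif(nw, 0.3, 1.2) / L,
         phase = stats::runif(nw, 0, 2 * pi))
  })
  names(warp) <- c("x", "y")
  structure(
    list(theta = stats::runif(1, -1, 1) * params$max_rotation_deg * pi / 180,
         translation = stats::runif(2, -1, 1) * params$max_translation_um,
         warp = warp,
         center = c(mean(extent[1:2]), mean(extent[3:4]))),
    class = "misalignment")
}

warp_displacement <- function(w, x, y) {
  d <- numeric(length(x))
  for (k in seq_along(w$amp))
    d <- d + w$amp[k] * sin(2 * pi * (w$fx[k] * x + w$fy[k] * y) + w$phase[k])
  d
}

#' Apply a planted misalignment to point coordinates
#'
#' Forward transform: rigid rotation about the slide centre plus
#' translation, then the smooth warp displacement evaluated at the rigidly
#' moved location. Errors if the transformed pattern leaves the slide
#' extent (warp/rigid bounds too large for the geometry).
#'
#' @param points data frame with `x`, `y` in micrometres.
#' @param transform a [sample_misalignment()] object.
#' @param extent optional extent to validate against.
#' @return Tibble with transformed `x`, `y`.
#' @export
apply_misalignment <- function(points, transform, extent = NULL) {
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) return(points)
  ct <- cos(transform$theta); st <- sin(transform$theta)
  dx <- points$x - transform$center[1]; dy <- points$y - transform$center[2]
  x1 <- ct * dx - st * dy + transform$center[1] + transform$translation[1]
  y1 <- st * dx + ct * dy + transform$center[2] + transform$translation[2]
  x2 <- x1 + warp_displacement(transform$warp$x, x1, y1)
  y2 <- y1 + warp_displacement(transform$warp$y, x1, y1)
  if (!is.null(extent) &&
      (any(x2 < extent[1] | x2 > extent[2]) || any(y2 < extent[3] | y2 > extent[4])))
    stop("misaligned pattern leaves the slide extent; reduce misalignment bounds")
  dplyr::mutate(points, x = x2, y = y2)
}

#' Simulate survival linked to true densities
#'
#' Proportional-hazards event times with linear predictor
#' `sum(log_hr * standardized density)`: relapse time from the DFS baseline
#' hazard, death lagging relapse by an exponential post-relapse survival
#' time, independent exponential censoring calibrated to `censoring_rate`
#' and an administrative follow-up cap. DFS is time to relapse or death,
#' whichever first; recurrence/metastasis flags describe events observed
#' during follow-up.
#'
#' @param true_densities tibble of per-patient densities; must contain the
#'   columns named by `hazard$log_hr`.
#' @param hazard hazard list, see [cohort_spec()].
#' @return Tibble: `patient`, `dfs_months`, `dfs_event`, `os_months`,
#'   `os_event`, `recurrence`, `metastasis`, and clinical covariates
#'   (`age_group`, `stage`, `tumor_size`, `grade`, `ki67`, `p53`,
#'   `basal_like`).
#' @export
simulate_survival <- function(true_densities, hazard) {
  if (hazard$baseline_dfs <= 0) stop("baseline hazard must be positive")
  if (hazard$censoring_rate < 0 || hazard$censoring_rate >= 1)
    stop("censoring rate must be in [0, 1)")
  n <- nrow(true_densities)
  lp <- numeric(n)
  for (nm in names(hazard$log_hr)) {
    if (!nm %in% names(true_densities))
      stop("log_hr names a density column not present: ", nm)
    v <- true_densities[[nm]]
    s <- stats::sd(v)
    z <- if (!is.na(s) && s > 0) (v - mean(v)) / s else v * 0
    lp <- lp + hazard$log_hr[[nm]] * z
  }
  rate_r <- hazard$baseline_dfs * exp(lp)
  t_r <- if (identical(hazard$model, "weibull")) {
    (stats::rexp(n) / rate_r)^(1 / hazard$weibull_shape)
  } else {
    stats::rexp(n, rate_r)
  }
  t_d <- t_r + stats::rexp(n, hazard$baseline_os_lag)
  cr <- hazard$censoring_rate
  cens <- if (cr > 0) stats::rexp(n, hazard$baseline_dfs * cr / (1 - cr)) else Inf
  cens <- pmin(cens, hazard$followup_max)
  dfs <- pmin(t_r, t_d, cens)
  os <- pmin(t_d, cens)
  tibble::tibble(
    patient = seq_len(n),
    dfs_months = dfs,
    dfs_event = pmin(t_r, t_d) <= cens,
    os_months = os,
    os_event = t_d <= cens,
    recurrence = t_r <= pmin(t_d, cens),
    metastasis = (t_r <= pmin(t_d, cens)) &
      (stats::runif(n) < hazard$p_metastasis_given_recurrence),
    age_group = sample(c("<=50", ">50"), n, replace = TRUE),
    stage = sample(c("I", "IIA", "IIB", "IIIA", "IIIB", "IIIC"), n,
                   replace = TRUE, prob = c(.10, .30, .25, .20, .10, .05)),
    tumor_size = sample(c("<=2cm", ">2cm"), n, replace = TRUE),
    grade = sample(c("2", "3"), n, replace = TRUE, prob = c(.35, .65)),
    ki67 = round(stats::runif(n, 5, 80)),
    p53 = sample(0:1, n, replace = TRUE),
    basal_like = sample(0:1, n, replace = TRUE))
}

#' Simulate a full synthetic cohort
#'
#' Per patient: a tumor geometry, one true (pre-misalignment) point pattern
#' per marker, misaligned slides for every non-reference slide (ground-truth
#' transforms retained) and true per-region densities; cohort-level:
#' survival records linked to the true densities by the configured
#' proportional-hazards model.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `synthetic_cohort`: `spec`, `patients` (list with
#'   `annotation`, `slides_true`, `slides`, `transforms`, `reference`),
#'   `true_densities` (tibble), `clinical` (tibble).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ref <- middle_slide_index(length(spec$markers))
  patients <- vector("list", spec$n_patients)
  dens_rows <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    ann <- simulate_geometry(spec)
    slides_true <- lapply(spec$markers, function(m) {
      simulate_pattern(ann, spec$base_intensity[[m]], spec$im_enrichment[[m]],
                       spec$cluster)
    })
    names(slides_true) <- spec$markers
    areas <- region_areas(ann)
    dens <- lapply(spec$markers, function(m) {
      d <- region_density(slides_true[[m]], ann, areas = areas)
      stats::setNames(d$density, paste0(c("TC_", "IM_", "TCIM_"), m))
    })
    dens_rows[[i]] <- tibble::as_tibble(as.list(unlist(dens)))
    transforms <- vector("list", length(spec$markers))
    names(transforms) <- spec$markers
    slides <- slides_true
    for (j in seq_along(spec$markers)) {
      if (j == ref) next
      transforms[[j]] <- sample_misalignment(spec$misalignment, ann$extent)
      slides[[j]] <- apply_misalignment(slides_true[[j]], transforms[[j]],
                                        extent = ann$extent)
    }
    patients[[i]] <- list(annotation = ann, slides_true = slides_true,
                          slides = slides, transforms = transforms,
                          reference = spec$markers[ref])
  }
  true_densities <- dplyr::bind_rows(dens_rows)
  clinical <- simulate_survival(true_densities, spec$hazard)
  structure(list(spec = spec, patients = patients,
                 true_densities = true_densities, clinical = clinical),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients x %d markers (reference: %s), seed %d\n",
              length(x$patients), length(x$spec$markers),
              x$patients[[1]]$reference, x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Per patient `pt<i>`: `cells.csv` (slide, marker, x_um, y_um, positive)
#' with the misaligned coordinates, and `annotation.geojson`; cohort-level
#' `clinical.csv`. These are exactly the formats [read_cell_table()],
#' [read_annotation()] and [read_clinical()] consume.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    pdir <- file.path(dir, sprintf("pt%03d", i))
    dir.create(pdir, showWarnings = FALSE)
    cells <- dplyr::bind_rows(lapply(seq_along(p$slides), function(j) {
      s <- p$slides[[j]]
      tibble::tibble(slide = j, marker = names(p$slides)[j],
                     x_um = s$x, y_um = s$y, positive = 1L)
    }))
    readr::write_csv(cells, file.path(pdir, "cells.csv"), progress = FALSE)
    write_annotation(p$annotation, file.path(pdir, "annotation.geojson"))
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"), progress = FALSE)
  invisible(dir)
}
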
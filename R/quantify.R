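# Per-patient spatial parameters: region densities, tile/hotspot densities
# and Morisita-Horn colocalization indices.

#' Positive-cell density in an analysis region
#'
#' Density = number of points assigned to the region / region area in mm^2.
#'
#' @param points data frame with `x`, `y` in micrometres (positive cells of
#'   one marker).
#' @param annotation a [tumor_annotation()].
#' @param regions which regions to report.
#' @param areas optional precomputed [region_areas()] tibble (saves the
#'   numeric IM-area integration when calling per marker).
#' @inheritParams assign_region
#' @return Tibble with `region`, `n_cells`, `area_mm2`, `density` (cells/mm^2).
#' @export
region_density <- function(points, annotation, regions = c("TC", "IM", "TC+IM"),
                           side = "both", disjoint = FALSE, areas = NULL) {
  if (is.null(areas)) areas <- region_areas(annotation, side = side, disjoint = disjoint)
  lab <- assign_region(points, annotation, side = side, disjoint = disjoint)
  counts <- c("TC" = sum(lab$in_tc), "IM" = sum(lab$in_im), "TC+IM" = sum(lab$in_tcim))
  out <- dplyr::filter(areas, .data$region %in% regions)
  if (any(out$area_mm2 <= 0)) stop("zero-area region: ", paste(out$region[out$area_mm2 <= 0], collapse = ", "))
  dplyr::mutate(out, n_cells = as.numeric(counts[.data$region]),
                density = .data$n_cells / .data$area_mm2)[
    , c("region", "n_cells", "area_mm2", "density")]
}

#' Per-tile positive-cell densities
#'
#' Counts points per effective tile and divides by the nominal tile area in
#' mm^2 (the full tile area, not the tile-region intersection).
#'
#' @param points data frame with `x`, `y` in micrometres.
#' @param grid a [effective_tiles()]-flagged tile grid.
#' @return Tibble of effective tiles with `n_cells` and `density` columns.
#' @export
tile_densities <- function(points, grid) {
  if (!"effective" %in% names(grid))
    stop("`grid` must carry effectiveness flags; run effective_tiles() first")
  eff <- dplyr::filter(tibble::as_tibble(grid), .data$effective)
  if (nrow(eff) == 0) {
    warning("no effective tiles")
    return(dplyr::mutate(eff, n_cells = numeric(0), density = numeric(0)))
  }
  tile_area_mm2 <- attr(grid, "tile_um")^2 / 1e6
  ids <- tile_of_point(points, grid)
  cnt <- table(factor(ids[!is.na(ids)], levels = eff$tile))
  dplyr::mutate(eff, n_cells = as.numeric(cnt[as.character(.data$tile)]),
                density = .data$n_cells / tile_area_mm2)
}

#' Top-3 hotspot densities
#'
#' Sorts the effective-tile densities from high to low and reports the top
#' three (Hotspot1 >= Hotspot2 >= Hotspot3). Ties are broken by ascending
#' tile index; with fewer than three effective tiles the missing ranks are NA.
#'
#' @param tiles a [tile_densities()] tibble.
#' @return Tibble with `hotspot` (1:3), `tile`, `density`.
#' @export
hotspot_top3 <- function(tiles) {
  if (nrow(tiles) == 0) stop("no effective tiles to rank")
  ord <- order(-tiles$density, tiles$tile)
  top <- tiles[ord[seq_len(min(3L, nrow(tiles)))], c("tile", "density")]
  if (nrow(top) < 3) {
    pad <- tibble::tibble(tile = rep(NA_integer_, 3 - nrow(top)),
                          density = rep(NA_real_, 3 - nrow(top)))
    top <- dplyr::bind_rows(top, pad)
  }
  dplyr::bind_cols(tibble::tibble(hotspot = 1:3), top)
}

#' Morisita-Horn colocalization index
#'
#' For two markers dissected over the same R tiles with per-tile proportions
#' \eqn{p_i} and \eqn{q_i},
#' \deqn{MH = \frac{2 \sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}.}
#' MH lies in \[0, 1\] (Cauchy-Schwarz), equals 1 for identical tile
#' distributions and 0 for disjoint supports; it is symmetric and invariant
#' to rescaling either marker's counts.
#'
#' @param p,q tile proportion (or count) vectors of equal length; counts are
#'   normalized internally.
#' @return MH index, or NA (with a warning) if either side is all zero.
#' @export
mh_index <- function(p, q) {
  stopifnot(length(p) == length(q))
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) {
    warning("MH index undefined: one distribution is empty")
    return(NA_real_)
  }
  p <- p / sp; q <- q / sq
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' Per-tile proportion distribution of a marker
#'
#' @inheritParams tile_densities
#' @return Numeric vector of counts over the effective tiles (in tile order),
#'   the input [mh_index()] consumes.
#' @export
tile_distribution <- function(points, grid) {
  tile_densities(points, grid)$n_cells
}

#' MH index of pooled immune cells versus tumor cells
#'
#' Pools the positive cells of all immune markers into a single point set and
#' computes its MH index against the tumor (CK) distribution on the same grid.
#'
#' @param immune_points list of data frames with `x`, `y` (one per immune
#'   marker).
#' @param ck_points tumor-cell (CK-positive) points.
#' @param grid effective-tile grid shared by all markers.
#' @return MH index.
#' @export
mh_pooled_immune_vs_ck <- function(immune_points, ck_points, grid) {
  pooled <- dplyr::bind_rows(lapply(immune_points, function(p) p[c("x", "y")]))
  mh_index(tile_distribution(pooled, grid), tile_distribution(ck_points, grid))
}

# canonical parameter order of the per-patient vector
param_names <- function(immune_markers = c("CD3", "CD4", "CD8", "CD19", "CD163"),
                        ck_marker = "CK") {
  dens <- as.vector(outer(c("TC", "IM", "TCIM"), immune_markers, paste, sep = "_"))
  hot <- as.vector(outer(paste0("Hotspot", 1:3), immune_markers, paste, sep = "_"))
  pairs <- utils::combn(immune_markers, 2)
  mh_imm <- paste("MH", pairs[1, ], pairs[2, ], sep = "_")
  mh_ck <- paste("MH", ck_marker, immune_markers, sep = "_")
  c(dens, hot, mh_imm, mh_ck, paste0("MH_", ck_marker, "_Immune"), "Immunoscore")
}

#' Quantify one patient: the 47-parameter vector
#'
#' Assembles, from registered slides and the region annotation, the full
#' per-patient parameter set: per-marker densities in TC, IM and TC+IM (15),
#' Hotspot1-3 densities (15), the 10 pairwise immune-marker MH indices, the 5
#' CK-versus-immune-marker MH indices and the pooled-immune-versus-CK MH
#' index (46 spatial parameters); the 47th slot, the Immunoscore, needs
#' cohort percentiles and is filled by [add_immunoscore()] at cohort level.
#' A missing or empty marker slide yields NA for every parameter that depends
#' on it.
#'
#' @param slides named list of per-marker point tables (`x`, `y` in um) for
#'   one patient, already registered to the common frame.
#' @param annotation a [tumor_annotation()].
#' @param immune_markers,ck_marker marker names expected in `slides`.
#' @param resolution um/pixel used for the tile grid (default 0.2).
#' @param tile_side tile side in pixels (default 1000).
#' @param mh_region region whose effective tiles carry the Morisita-Horn
#'   proportions (default `"TC+IM"`).
#' @inheritParams assign_region
#' @return One-row tibble of named parameters (Immunoscore = NA).
#' @export
quantify_patient <- function(slides, annotation,
                             immune_markers = c("CD3", "CD4", "CD8", "CD19", "CD163"),
                             ck_marker = "CK", resolution = 0.2, tile_side = 1000,
                             side = "both", disjoint = FALSE, mh_region = "TC+IM") {
  areas <- region_areas(annotation, side = side, disjoint = disjoint)
  grid_tc <- effective_tiles(
    make_tile_grid(annotation$extent, resolution, tile_side), annotation, region = "TC")
  grid_tcim <- if (identical(mh_region, "TC")) grid_tc else effective_tiles(
    make_tile_grid(annotation$extent, resolution, tile_side), annotation, region = mh_region)
  out <- stats::setNames(as.list(rep(NA_real_, length(param_names(immune_markers, ck_marker)))),
                         param_names(immune_markers, ck_marker))
  has <- function(m) !is.null(slides[[m]]) && nrow(slides[[m]]) > 0
  dists <- list()
  for (m in c(immune_markers, ck_marker)) {
    if (!has(m)) next
    dists[[m]] <- tile_distribution(slides[[m]], grid_tcim)
  }
  for (m in immune_markers) {
    if (!has(m)) next
    d <- region_density(slides[[m]], annotation, side = side, disjoint = disjoint, areas = areas)
    out[[paste0("TC_", m)]] <- d$density[d$region == "TC"]
    out[[paste0("IM_", m)]] <- d$density[d$region == "IM"]
    out[[paste0("TCIM_", m)]] <- d$density[d$region == "TC+IM"]
    h <- hotspot_top3(tile_densities(slides[[m]], grid_tc))
    for (k in 1:3) out[[paste0("Hotspot", k, "_", m)]] <- h$density[k]
  }
  pairs <- utils::combn(immune_markers, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (has(a) && has(b))
      out[[paste("MH", a, b, sep = "_")]] <- mh_index(dists[[a]], dists[[b]])
  }
  if (has(ck_marker)) {
    for (m in immune_markers) {
      if (has(m))
        out[[paste("MH", ck_marker, m, sep = "_")]] <- mh_index(dists[[ck_marker]], dists[[m]])
    }
    present <- immune_markers[vapply(immune_markers, has, logical(1))]
    if (length(present) > 0)
      out[[paste0("MH_", ck_marker, "_Immune")]] <- mh_pooled_immune_vs_ck(
        slides[present], slides[[ck_marker]], grid_tcim)
  }
  tibble::as_tibble(out)
}
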
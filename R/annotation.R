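#' Tumor region annotation
#'
#' Bundles the pathologist annotation a slide analysis needs: the tumor-core
#' (TC) polygon, the invasive front (IF) polyline along the tumor-stroma
#' boundary, the slide extent and the invasive-margin (IM) half-width. By
#' convention the IF is the boundary of the TC polygon and the IM is the band
#' of all points within `im_width` micrometres of the IF (both sides by
#' default; see [assign_region()]).
#'
#' @param tc_polygon two-column matrix of TC vertices in micrometres
#'   (a simple, i.e. non-self-intersecting, ring).
#' @param extent slide extent `c(xmin, xmax, ymin, ymax)` in micrometres;
#'   defaults to the polygon bounding box padded by `im_width`.
#' @param if_polyline invasive-front vertices; defaults to the TC boundary.
#' @param im_width IM half-width in micrometres (default 100).
#' @return An object of class `tumor_annotation`.
#' @export
tumor_annotation <- function(tc_polygon, extent = NULL, if_polyline = tc_polygon,
                             im_width = 100) {
  tc_polygon <- close_ring(as.matrix(tc_polygon), open = TRUE)
  if (im_width <= 0) stop("`im_width` must be positive")
  if (nrow(if_polyline) < 2) stop("degenerate invasive-front polyline")
  if (is.null(extent)) {
    extent <- c(min(tc_polygon[, 1]) - im_width, max(tc_polygon[, 1]) + im_width,
                min(tc_polygon[, 2]) - im_width, max(tc_polygon[, 2]) + im_width)
  }
  structure(
    list(tc_polygon = tc_polygon, if_polyline = as.matrix(if_polyline),
         extent = as.numeric(extent), im_width = im_width),
    class = "tumor_annotation"
  )
}

#' @export
print.tumor_annotation <- function(x, ...) {
  cat(sprintf(
    "<tumor_annotation> TC polygon: %d vertices, %.3f mm^2 | IM width: %g um | extent: [%g, %g] x [%g, %g] um\n",
    nrow(x$tc_polygon), polygon_area(x$tc_polygon) / 1e6, x$im_width,
    x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  invisible(x)
}

#' Read / write region annotations as GeoJSON
#'
#' The TC polygon is stored as a GeoJSON `Polygon` feature and the IF as a
#' `LineString` feature; coordinates are micrometres. Feature properties
#' `region` (`"TC"` / `"IF"`), `im_width_um` and `extent_um` are used, so a
#' written file round-trips losslessly.
#'
#' @param path file path.
#' @return `read_annotation()` returns a [tumor_annotation()].
#' @export
read_annotation <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a GeoJSON FeatureCollection")
  tc <- NULL; ifl <- NULL; im_width <- 100; extent <- NULL
  for (f in gj$features) {
    coords <- f$geometry$coordinates
    if (identical(f$properties$region, "TC")) {
      ring <- coords[[1]]
      tc <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
      if (!is.null(f$properties$im_width_um)) im_width <- f$properties$im_width_um
      if (!is.null(f$properties$extent_um)) extent <- as.numeric(unlist(f$properties$extent_um))
    } else if (identical(f$properties$region, "IF")) {
      ifl <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p))))
    }
  }
  if (is.null(tc)) stop("no TC polygon feature in ", path)
  if (is.null(ifl)) ifl <- tc
  tumor_annotation(tc, extent = extent, if_polyline = ifl, im_width = im_width)
}

#' @rdname read_annotation
#' @param annotation a [tumor_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  tc <- close_ring(annotation$tc_polygon)
  ring <- lapply(seq_len(nrow(tc)), function(i) as.numeric(tc[i, ]))
  ifl <- annotation$if_polyline
  line <- lapply(seq_len(nrow(ifl)), function(i) as.numeric(ifl[i, ]))
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(region = "TC",
                             im_width_um = annotation$im_width,
                             extent_um = annotation$extent),
           geometry = list(type = "Polygon", coordinates = list(ring))),
      list(type = "Feature",
           properties = list(region = "IF"),
           geometry = list(type = "LineString", coordinates = line))
    )
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
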
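#' Planned-land plot polygons
#'
#' Simple polygons (outer ring only, no holes) with a plot id, a land-use
#' type and an area. The stated area defaults to, and must stay within 1%
#' of, the shoelace area of the ring.
#'
#' @param rings list of two-column coordinate matrices (m); rings may be
#'   open (last vertex != first) or closed.
#' @param plot_id character ids (default P1, P2, ...).
#' @param landuse land-use types (recycled).
#' @param area_m2 optional stated areas; default geometric.
#' @return Object of class `planned_plots`: a list with `rings`, `plot_id`,
#'   `landuse`, `area_m2`.
#' @export
planned_plots <- function(rings, plot_id = NULL, landuse = "residential",
                          area_m2 = NULL) {
  stopifnot(is.list(rings), length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    # drop closing vertex if present
    if (all(r[1, ] == r[nrow(r), ]) && nrow(r) > 3) r <- r[-nrow(r), , drop = FALSE]
    r
  })
  geom <- vapply(rings, shoelace_area, numeric(1))
  if (any(geom <= 0)) stop("degenerate polygon (zero area)")
  if (is.null(plot_id)) plot_id <- paste0("P", seq_along(rings))
  if (is.null(area_m2)) area_m2 <- geom
  if (any(abs(area_m2 - geom) / geom > 0.01))
    stop("stated plot area differs from geometric area by more than 1%")
  structure(list(rings = rings, plot_id = as.character(plot_id),
                 landuse = rep_len(as.character(landuse), length(rings)),
                 area_m2 = as.numeric(area_m2)),
            class = "planned_plots")
}

#' @export
print.planned_plots <- function(x, ...) {
  cat(sprintf("planned_plots: %d plot(s), %.2f hm2 total\n",
              length(x$rings), sum(x$area_m2) / 1e4))
  invisible(x)
}

shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Which points fall inside a plot polygon
#'
#' @param ring two-column vertex matrix.
#' @param xy two-column point matrix.
#' @return Logical vector.
#' @keywords internal
points_in_ring <- function(ring, xy) {
  bnd <- rbind(ring, ring[1, ])
  mgcv::in.out(bnd, xy)
}

#' Read planned plots from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (outer ring used) or
#' single-polygon MultiPolygon features with optional properties
#' `plot_id`, `landuse`, `area_m2`.
#'
#' @param path GeoJSON file.
#' @return A [planned_plots()] set.
#' @export
read_plots_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  rings <- list(); ids <- character(); lus <- character(); areas <- numeric()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    coords <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported geometry type: ", geom$type))
    ring <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    rings[[i]] <- ring
    p <- f$properties
    ids[i] <- if (!is.null(p$plot_id)) as.character(p$plot_id) else paste0("P", i)
    lus[i] <- if (!is.null(p$landuse)) as.character(p$landuse) else "residential"
    areas[i] <- if (!is.null(p$area_m2)) as.numeric(p$area_m2) else NA_real_
  }
  geo <- vapply(rings, shoelace_area, numeric(1))
  areas[is.na(areas)] <- geo[is.na(areas)]
  planned_plots(rings, plot_id = ids, landuse = lus, area_m2 = areas)
}

#' @rdname read_plots_geojson
#' @param plots a [planned_plots()] set.
#' @export
write_plots_geojson <- function(plots, path) {
  feats <- lapply(seq_along(plots$rings), function(i) {
    ring <- plots$rings[[i]]
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(plot_id = plots$plot_id[i],
                           landuse = plots$landuse[i],
                           area_m2 = plots$area_m2[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(j) as.numeric(ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Regular-polygon ring helper
#'
#' @param center (x, y) centre.
#' @param radius radius in metres.
#' @param n_vertices number of vertices (default 32).
#' @param arc optional angular interval (radians, length 2) for a sector;
#'   the centre is appended so sectors close properly.
#' @return Two-column vertex matrix.
#' @export
regular_ring <- function(center, radius, n_vertices = 32, arc = NULL) {
  if (is.null(arc)) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  } else {
    th <- seq(arc[1], arc[2], length.out = n_vertices)
    rbind(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)),
          center)
  }
}
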
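#' The seven landscape classes of a reclaimed subsidence area
#'
#' Cultivated land, woodland, grassland, transportation land, natural water
#' bodies, built-up land and subsided water bodies, with their default
#' integer codes (1--7).
#'
#' @return Named integer vector mapping class name to raster code.
#' @export
landcover_classes <- function() {
  c(cultivated = 1L, woodland = 2L, grassland = 3L, transportation = 4L,
    natural_water = 5L, built_up = 6L, subsided_water = 7L)
}

#' Construct a categorical land-cover grid
#'
#' @param values integer matrix of class codes, row 1 = north; `NA` or the
#'   `nodata` code marks cells outside the study area.
#' @param cell_size cell edge in metres (square cells).
#' @param origin (x, y) of the top-left corner.
#' @param legend named integer vector, name = class, value = code. Every
#'   non-nodata code present in `values` must appear in the legend.
#' @param nodata reserved code for missing cells.
#' @return An object of class `land_grid`.
#' @export
land_grid <- function(values, cell_size, origin = c(0, 0),
                      legend = landcover_classes(), nodata = -9999L) {
  stopifnot(is.matrix(values), cell_size > 0, nrow(values) >= 1,
            ncol(values) >= 1)
  v <- values
  storage.mode(v) <- "integer"
  v[v == as.integer(nodata)] <- NA
  codes <- sort(unique(v[!is.na(v)]))
  unknown <- setdiff(codes, as.integer(legend))
  if (length(unknown) > 0)
    stop("class code(s) not in legend: ", paste(unknown, collapse = ", "))
  structure(
    list(values = v,
         spec = grid_spec(nrow(v), ncol(v), cell_size, origin),
         legend = legend, nodata = as.integer(nodata)),
    class = "land_grid")
}

#' @export
print.land_grid <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf("land_grid: %d x %d cells @ %g m (%d in study area)\n",
              x$spec$nrow, x$spec$ncol, x$spec$cell_size, n_ok))
  print(tabulate_areas(x))
  invisible(x)
}

#' Read a land-cover grid from an ESRI ASCII raster
#'
#' @param path single-band integer raster in ESRI ASCII grid format.
#' @param legend named integer vector (class -> code); may also be the path
#'   of a JSON file holding such a map.
#' @return A [land_grid()].
#' @export
read_landcover_grid <- function(path, legend = landcover_classes()) {
  if (is.character(legend) && length(legend) == 1 && file.exists(legend))
    legend <- read_legend(legend)
  g <- read_ascii_grid(path)
  if (any(abs(g$values - round(g$values)) > 1e-9, na.rm = TRUE))
    stop("raster has non-integer class codes: not a categorical grid")
  land_grid(g$values, g$spec$cell_size, g$spec$origin, legend = legend,
            nodata = g$nodata)
}

#' Write a land-cover grid (raster + legend)
#'
#' @param grid a [land_grid()].
#' @param path output raster path (.asc); the legend goes to
#'   `legend_path` as JSON.
#' @param legend_path optional path for the JSON legend.
#' @export
write_landcover_grid <- function(grid, path, legend_path = NULL) {
  write_ascii_grid(grid$values, path, grid$spec, nodata = grid$nodata)
  if (!is.null(legend_path))
    jsonlite::write_json(as.list(grid$legend), legend_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname read_landcover_grid
#' @export
read_legend <- function(path) {
  l <- jsonlite::read_json(path)
  stats::setNames(vapply(l, as.integer, integer(1)), names(l))
}

#' Tabulate class areas of a land-cover grid
#'
#' Areas are pure cell counts times cell area: one cell of a `cell_size`-m
#' grid contributes `cell_size^2 / 10^4` hm2 (1 hm2 = 10,000 m2). Classes in
#' the legend with no cells get zero rows so that before/after tables share
#' a class universe.
#'
#' @param grid a [land_grid()].
#' @param digits_percent decimal places for the reported percentages
#'   (default 2, round half up, matching conventional table precision).
#' @return A data frame of class `landscape_area_table` with columns
#'   `class`, `area_hm2`, `percent` and attributes `total_hm2`, `cell_size`.
#' @export
tabulate_areas <- function(grid, digits_percent = 2) {
  stopifnot(inherits(grid, "land_grid"))
  v <- grid$values[!is.na(grid$values)]
  if (length(v) == 0) stop("grid is all nodata: nothing to tabulate")
  cell_hm2 <- grid$spec$cell_size^2 / 1e4
  counts <- vapply(grid$legend, function(code) sum(v == code), numeric(1))
  area <- counts * cell_hm2
  total <- sum(area)
  pct <- round_half_up(100 * area / total, digits_percent)
  out <- data.frame(class = names(grid$legend), area_hm2 = unname(area),
                    percent = unname(pct), stringsAsFactors = FALSE)
  structure(out, total_hm2 = total, cell_size = grid$spec$cell_size,
            class = c("landscape_area_table", "data.frame"))
}

#' Build a landscape area table directly from per-class areas
#'
#' Used for printed tables and hand-made cases; percentages are recomputed
#' from the areas.
#'
#' @param areas_hm2 named numeric vector of class areas in hm2.
#' @param digits_percent as in [tabulate_areas()].
#' @return A `landscape_area_table`.
#' @export
area_table <- function(areas_hm2, digits_percent = 2) {
  stopifnot(length(areas_hm2) > 0, !is.null(names(areas_hm2)))
  total <- sum(areas_hm2)
  pct <- if (total > 0)
    round_half_up(100 * areas_hm2 / total, digits_percent)
  else rep(0, length(areas_hm2))
  out <- data.frame(class = names(areas_hm2), area_hm2 = unname(areas_hm2),
                    percent = unname(pct), stringsAsFactors = FALSE)
  structure(out, total_hm2 = total, cell_size = NA_real_,
            class = c("landscape_area_table", "data.frame"))
}

#' Before/after structural change of the landscape
#'
#' Per-class absolute (hm2) and relative (%) change, plus the total-water
#' aggregate: reclamation converts subsided water bodies into (natural)
#' lake wetland, so the meaningful water change is
#' `natural_water_after - (natural_water_before + subsided_water_before)`.
#'
#' @param before,after `landscape_area_table`s over the same class universe
#'   and the same total area (within `tol_total` hm2).
#' @param tol_total tolerance on the total-area match, hm2.
#' @return A data frame of class `area_change_table` with one row per class
#'   (`area_before`, `area_after`, `change_hm2`, `change_pct`; the relative
#'   change is `NA` where the class had zero area before) and attributes
#'   `water_change_hm2`, `water_change_pct`.
#' @export
area_change <- function(before, after, tol_total = 0.01) {
  stopifnot(inherits(before, "landscape_area_table"),
            inherits(after, "landscape_area_table"))
  if (!setequal(before$class, after$class))
    stop("before/after tables cover different class universes")
  tb <- attr(before, "total_hm2"); ta <- attr(after, "total_hm2")
  if (abs(tb - ta) > tol_total)
    stop(sprintf("total areas differ (%.4f vs %.4f hm2): grids must cover the same extent",
                 tb, ta))
  a <- after[match(before$class, after$class), ]
  chg <- a$area_hm2 - before$area_hm2
  rel <- ifelse(before$area_hm2 > 0, chg / before$area_hm2 * 100, NA_real_)
  out <- data.frame(class = before$class,
                    area_before = before$area_hm2, area_after = a$area_hm2,
                    change_hm2 = chg, change_pct = rel,
                    stringsAsFactors = FALSE)
  wb <- sum(before$area_hm2[before$class %in% c("natural_water", "subsided_water")])
  wa <- sum(a$area_hm2[a$class %in% c("natural_water", "subsided_water")])
  wchg <- wa - wb
  structure(out,
            water_change_hm2 = wchg,
            water_change_pct = if (wb > 0) wchg / wb * 100 else NA_real_,
            class = c("area_change_table", "data.frame"))
}

# round half away from zero at `digits` decimals (tables convention; R's
# round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
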
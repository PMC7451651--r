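#' Average regional rise in land prices
#'
#' r = (mean_after - mean_before) / mean_before over the region mask of two
#' price surfaces on the same grid; removes the market-wide component
#' (inflation, region-level location trends) before the spillover is
#' isolated. Returned as a dimensionless fraction (1.0 = 100%).
#'
#' @param before,after [price_surface()]s with identical geometry.
#' @param region_mask optional logical matrix restricting the averaging
#'   region; default: cells valid in both surfaces.
#' @return The rise `r` as a fraction.
#' @export
average_rise <- function(before, after, region_mask = NULL) {
  stopifnot(inherits(before, "price_surface"), inherits(after, "price_surface"))
  if (!same_geometry(before$spec, after$spec))
    stop("surfaces have different grid geometry")
  m <- before$mask & after$mask
  if (!is.null(region_mask)) m <- m & region_mask
  if (!any(m)) stop("region mask selects no valid cells")
  mb <- mean(before$values[m]); ma <- mean(after$values[m])
  if (mb <= 0) stop("mean price before is not positive")
  ma / mb - 1
}

#' Excess-price surface and spillover mask
#'
#' Cellwise Lp_after - Lp_before (1 + r): what remains of the price change
#' once the average regional rise is removed. Cells with positive excess
#' form the spillover mask (impact range); negative cells are retained in
#' the grid but excluded from the mask.
#'
#' @param before,after [price_surface()]s with identical geometry.
#' @param r average rise (fraction, > -1), from [average_rise()].
#' @return List with `excess` (matrix, yuan/m2), `mask` (logical matrix:
#'   excess > 0 and both surfaces valid) and `spec`.
#' @export
excess_surface <- function(before, after, r) {
  stopifnot(r > -1)
  if (!same_geometry(before$spec, after$spec))
    stop("surfaces have different grid geometry")
  ex <- after$values - before$values * (1 + r)
  valid <- before$mask & after$mask
  ex[!valid] <- NA
  list(excess = ex, mask = valid & !is.na(ex) & ex > 0, spec = before$spec)
}

#' Spillover-effect value over planned plots
#'
#' Zonal integration of the positive excess over the planned plots:
#' per plot, SEV_j = sum over grid cells whose centre lies in the plot and
#' in the mask of excess x cell area; the total SEV is the sum over plots.
#' Cell membership is by cell-centre-in-polygon, the raster-calculator
#' convention, so results are bit-reproducible for a given grid.
#'
#' @param excess list from [excess_surface()] (or any list with `excess`,
#'   `mask`, `spec`).
#' @param plots a [planned_plots()] set.
#' @return Object of class `spillover_result`: `sev_yuan` (total),
#'   `per_plot` (data frame: plot_id, landuse, area_m2, sev_yuan, n_cells),
#'   `max_excess`, `mean_excess` (yuan/m2 over mask-covered plot cells),
#'   `affected_area_hm2` (area of plots intersecting the mask).
#' @export
compute_sev <- function(excess, plots) {
  stopifnot(inherits(plots, "planned_plots"))
  spec <- excess$spec
  cell_area <- spec$cell_size^2
  xy <- cell_centers(spec)
  in_mask <- as.vector(excess$mask)
  exv <- as.vector(excess$excess)
  per <- lapply(seq_along(plots$rings), function(i) {
    inside <- points_in_ring(plots$rings[[i]], xy)
    sel <- inside & in_mask & !is.na(exv)
    data.frame(plot_id = plots$plot_id[i], landuse = plots$landuse[i],
               area_m2 = plots$area_m2[i],
               sev_yuan = sum(exv[sel]) * cell_area,
               n_cells = sum(sel),
               max_excess = if (any(sel)) max(exv[sel]) else NA_real_,
               sum_excess = sum(exv[sel]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (all(per$n_cells == 0)) warning("plots do not overlap the spillover mask")
  covered <- per$n_cells > 0
  n_cells_total <- sum(per$n_cells)
  structure(list(
    sev_yuan = sum(per$sev_yuan),
    per_plot = per[, c("plot_id", "landuse", "area_m2", "sev_yuan", "n_cells")],
    max_excess = if (n_cells_total > 0) max(per$max_excess, na.rm = TRUE) else NA_real_,
    mean_excess = if (n_cells_total > 0) sum(per$sum_excess) / n_cells_total else NA_real_,
    affected_area_hm2 = sum(per$area_m2[covered]) / 1e4),
    class = "spillover_result")
}

#' @export
print.spillover_result <- function(x, ...) {
  cat(sprintf("spillover result: SEV = %.0f yuan (%.2f yiyuan)\n",
              x$sev_yuan, x$sev_yuan / 1e8))
  if (!is.null(x$r))
    cat(sprintf("  average rise r = %.4f (%.2f%%)\n", x$r, 100 * x$r))
  cat(sprintf("  impact over plots: max %.2f, mean %.2f yuan/m2; affected %.2f hm2\n",
              x$max_excess, x$mean_excess, x$affected_area_hm2))
  invisible(x)
}

#' Full spillover pipeline: screen, fit, krige, difference, integrate
#'
#' The three-step spillover procedure over two epochs of price samples:
#' (1) screening (normality and Moran's I, advisory unless
#' `strict_screening`); (2) per epoch, empirical semivariogram, candidate
#' model fits and LOO-cross-validated selection, then ordinary kriging onto
#' the shared analysis grid; (3) average rise, excess surface/mask, and
#' zonal SEV over the planned plots.
#'
#' @param points_before,points_after [price_points()] per epoch (n >= 10).
#' @param grid a [grid_spec()] (15-m cells in the study design).
#' @param plots a [planned_plots()] set.
#' @param n_bins,max_lag,families variogram estimation settings
#'   (see [empirical_semivariogram()], [fit_variogram()]).
#' @param max_neighbors kriging neighborhood (see [ordinary_kriging()]).
#' @param n_perm,seed permutation count/seed for the Moran screening.
#' @param strict_screening abort (error) when screening fails instead of
#'   warning.
#' @return A `spillover_result` additionally carrying `r`, `excess`,
#'   `surfaces` (both epochs), `models` (selected per epoch), `screening`,
#'   and `provenance` (settings used).
#' @export
run_spillover_pipeline <- function(points_before, points_after, grid, plots,
                                   n_bins = 12, max_lag = NULL,
                                   families = c("spherical", "exponential",
                                                "gaussian"),
                                   max_neighbors = Inf, n_perm = 999,
                                   seed = 1L, strict_screening = FALSE) {
  stopifnot(nrow(points_before) >= 10, nrow(points_after) >= 10)
  screen_one <- function(pts, label) {
    nt <- normality_test(pts$price)
    mi <- morans_i(pts, n_perm = n_perm, seed = seed)
    if (!nt$pass) {
      msg <- sprintf("%s prices fail normality (p = %.3g); consider a log-transform",
                     label, nt$p_value)
      if (strict_screening) stop(msg) else warning(msg, call. = FALSE)
    }
    if (mi$p_value > 0.05) {
      msg <- sprintf("%s prices show no significant spatial autocorrelation (Moran p = %.3g)",
                     label, mi$p_value)
      if (strict_screening) stop(msg) else warning(msg, call. = FALSE)
    }
    list(normality = nt, moran = mi)
  }
  scr <- list(before = screen_one(points_before, "before"),
              after = screen_one(points_after, "after"))

  fit_epoch <- function(pts) {
    emp <- empirical_semivariogram(pts, n_bins = n_bins, max_lag = max_lag)
    cand <- fit_variogram(emp, families = families)
    ranked <- loo_cross_validate(pts, cand)
    list(empirical = emp, candidates = ranked, best = ranked[[1]])
  }
  fb <- fit_epoch(points_before)
  fa <- fit_epoch(points_after)
  sb <- ordinary_kriging(points_before, fb$best, grid,
                         max_neighbors = max_neighbors)
  sa <- ordinary_kriging(points_after, fa$best, grid,
                         max_neighbors = max_neighbors)

  r <- average_rise(sb, sa)
  ex <- excess_surface(sb, sa, r)
  res <- compute_sev(ex, plots)
  res$r <- r
  res$excess <- ex
  res$surfaces <- list(before = sb, after = sa)
  res$models <- list(before = fb, after = fa)
  res$screening <- scr
  res$provenance <- list(n_bins = n_bins, max_lag = max_lag,
                         families = families, max_neighbors = max_neighbors,
                         n_perm = n_perm, seed = seed,
                         n_before = nrow(points_before),
                         n_after = nrow(points_after),
                         grid = unclass(grid))
  res
}

#' Write a spillover result bundle
#'
#' JSON summary (r, SEV, max/mean impact, affected area, selected models)
#' plus the excess and mask grids as ESRI ASCII rasters.
#'
#' @param result a `spillover_result` from [run_spillover_pipeline()].
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_spillover_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(json = file.path(out_dir, "spillover_result.json"),
                excess = file.path(out_dir, "excess_price.asc"),
                mask = file.path(out_dir, "spillover_mask.asc"))
  model_info <- lapply(result$models, function(m)
    list(family = m$best$family, nugget = m$best$nugget,
         psill = m$best$psill, range = m$best$range,
         loo_rmse = m$best$loo_rmse))
  jsonlite::write_json(list(
    r = result$r, r_pct = 100 * result$r, sev_yuan = result$sev_yuan,
    max_excess_yuan_m2 = result$max_excess,
    mean_excess_yuan_m2 = result$mean_excess,
    affected_area_hm2 = result$affected_area_hm2,
    per_plot = result$per_plot, models = model_info,
    provenance = result$provenance),
    paths$json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$excess)) {
    write_ascii_grid(result$excess$excess, paths$excess, result$excess$spec)
    write_ascii_grid(result$excess$mask + 0, paths$mask, result$excess$spec)
  }
  invisible(paths)
}
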
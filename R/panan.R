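#' Published landscape structure of the Pan'an Lake subsidence area
#'
#' Per-class areas (hm2) before (2008) and after (2017) reclamation of the
#' Pan'an Lake mining-subsidence area, Jiawang District, Xuzhou, as published
#' with the study. At a 10-m synthesis cell every area is an exact integer
#' cell count (1 cell = 0.01 hm2); the total study area is 5309.42 hm2.
#'
#' @param epoch `"2008"` or `"2017"`.
#' @return Named numeric vector of areas in hm2.
#' @export
panan_landscape_areas <- function(epoch = c("2008", "2017")) {
  epoch <- match.arg(epoch)
  if (epoch == "2008")
    c(cultivated = 2918.97, woodland = 33.62, grassland = 128.75,
      transportation = 209.69, natural_water = 336.59, built_up = 1098.91,
      subsided_water = 582.89)
  else
    c(cultivated = 2084.89, woodland = 449.84, grassland = 498.67,
      transportation = 223.85, natural_water = 1071.63, built_up = 980.54,
      subsided_water = 0)
}

#' Published per-class ESV of the Pan'an Lake area (wanyuan)
#'
#' The printed valuation table. The 2017 column is internally inconsistent
#' with the 2017 landscape areas for transportation and built-up land (the
#' printed ESVs imply slightly different areas than the printed area table);
#' totals and change rates are therefore validated against this printed
#' table, while per-class recomputation from areas is validated on the
#' consistent cells.
#'
#' @param epoch `"2008"` or `"2017"`.
#' @return An [esv_report()] built from the printed values.
#' @export
panan_esv_printed <- function(epoch = c("2008", "2017")) {
  epoch <- match.arg(epoch)
  v <- if (epoch == "2008")
    c(cultivated = 1784.75, woodland = 65, grassland = 82.49,
      transportation = -112.65, natural_water = 1369.12,
      built_up = -193.46, subsided_water = 590.81)
  else
    c(cultivated = 1274.77, woodland = 869.73, grassland = 319.47,
      transportation = -128.31, natural_water = 4359.02,
      built_up = -169.98, subsided_water = 0)
  esv_report(v)
}

#' Write the Pan'an Lake fixture bundle
#'
#' Generates both epoch land-cover rasters (10-m cells, class areas matching
#' the published landscape-structure table exactly), the class legend, the
#' coefficient table and an expectations JSON carrying the published
#' area/ESV/storage values, into `out_dir`. Rasters are synthetic layouts
#' (seeded region growth): the class *areas* are the published ones; the
#' spatial arrangement is generated, not observed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed controlling the synthetic layouts.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_panan_fixture <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    raster_2008 = file.path(out_dir, "panan_landcover_2008_synthetic.asc"),
    raster_2017 = file.path(out_dir, "panan_landcover_2017_synthetic.asc"),
    legend = file.path(out_dir, "legend.json"),
    coefficients = file.path(out_dir, "value_coefficients.csv"),
    expectations = file.path(out_dir, "expectations.json"))

  g08 <- generate_landcover(panan_landscape_areas("2008"), cell_size = 10,
                            seed = seed)
  g17 <- generate_landcover(panan_landscape_areas("2017"), cell_size = 10,
                            seed = seed + 1L)
  write_landcover_grid(g08, paths$raster_2008, legend_path = paths$legend)
  write_landcover_grid(g17, paths$raster_2017)
  write_coefficients(builtin_coefficients(), paths$coefficients)

  exp <- list(
    total_area_hm2 = 5309.42,
    areas_2008 = as.list(panan_landscape_areas("2008")),
    areas_2017 = as.list(panan_landscape_areas("2017")),
    esv_2008 = as.list(stats::setNames(panan_esv_printed("2008")$esv_wanyuan,
                                       panan_esv_printed("2008")$class)),
    esv_2017 = as.list(stats::setNames(panan_esv_printed("2017")$esv_wanyuan,
                                       panan_esv_printed("2017")$class)),
    esv_total_2008 = 3586.06, esv_total_2017 = 6524.69,
    esv_total_change = 2938.63, esv_total_rate_pct = 81.95,
    ess_2008 = 0.6754, ess_2017 = 1.2289,
    ess_conversion_quantity = 0.5535, ess_conversion_pct_pa = 6.15,
    cultivated_share_2008 = 54.98, cultivated_share_2017 = 39.27,
    water_change_hm2 = 152.15, water_change_pct = 16.55)
  jsonlite::write_json(exp, paths$expectations, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' End-to-end ESV accounting over two land-cover rasters
#'
#' Reads both rasters, tabulates areas, computes per-class ESV, the change
#' report, and the ecological-storage states and conversion.
#'
#' @param path_before,path_after ESRI ASCII land-cover rasters.
#' @param legend legend (named vector or JSON path).
#' @param coeffs a `vc_table`.
#' @param years span between the epochs (for the conversion percent).
#' @return List with `areas_before`, `areas_after`, `area_change`,
#'   `esv_before`, `esv_after`, `esv_change`, `ess_before`, `ess_after`,
#'   `ess_conversion`.
#' @export
esv_pipeline <- function(path_before, path_after,
                         legend = landcover_classes(),
                         coeffs = builtin_coefficients(), years = 9) {
  gb <- read_landcover_grid(path_before, legend)
  ga <- read_landcover_grid(path_after, legend)
  ab <- tabulate_areas(gb); aa <- tabulate_areas(ga)
  eb <- compute_esv(ab, coeffs); ea <- compute_esv(aa, coeffs)
  sb <- compute_ess(attr(eb, "total_wanyuan"), attr(ab, "total_hm2"))
  sa <- compute_ess(attr(ea, "total_wanyuan"), attr(aa, "total_hm2"))
  list(areas_before = ab, areas_after = aa,
       area_change = area_change(ab, aa),
       esv_before = eb, esv_after = ea, esv_change = esv_change(eb, ea),
       ess_before = sb, ess_after = sa,
       ess_conversion = ess_conversion(sb, sa, years))
}
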
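#' Built-in ecosystem-service value coefficients
#'
#' Per-class value coefficients (yuan per hm2 per year) for the seven
#' ecosystems of a high-groundwater mining-subsidence area: the Costanza-type
#' valuation with Chinese-equivalent coefficients for terrestrial classes,
#' a full-function coefficient for natural water bodies and a degraded
#' coefficient for subsided (ponded) water bodies, and negative coefficients
#' for industry/transportation and urban construction land.
#'
#' The water-class coefficients carry a per-service breakdown over eight
#' service functions; the subsided water body performs no soil formation and
#' no recreation/culture function and degraded shares of the rest, so each
#' of its service values is at most the natural-water counterpart.
#'
#' @return A data frame of class `vc_table` with columns `class`,
#'   `vc_yuan_per_hm2_a`, and attribute `breakdown` (a data frame of the
#'   per-service water-class values).
#' @export
builtin_coefficients <- function() {
  vc <- c(cultivated = 6114.3, woodland = 19334, grassland = 6406.5,
          natural_water = 40676.4, subsided_water = 10135.9,
          industry_transportation = -5372.1, urban = -1760.5)
  breakdown <- data.frame(
    service = c("climate_regulation", "water_conservation",
                "soil_formation_conservation", "waste_treatment",
                "biodiversity_maintenance", "food_production",
                "raw_material", "recreation_culture"),
    natural_water = c(407, 18033.2, 8.8, 16086.6, 2203.3, 88.5, 8.8, 3840.2),
    subsided_water = c(407, 4508.3, 0, 4021.65, 1101.65, 88.5, 8.8, 0),
    stringsAsFactors = FALSE)
  out <- data.frame(class = names(vc), vc_yuan_per_hm2_a = unname(vc),
                    stringsAsFactors = FALSE)
  structure(out, breakdown = breakdown,
            class = c("vc_table", "data.frame"))
}

#' Default binding of land-cover classes to coefficient classes
#'
#' Transportation land carries the industry/transportation coefficient and
#' built-up land the urban coefficient; the rest bind to their namesakes.
#'
#' @return Named character vector, land-cover class -> coefficient class.
#' @export
default_class_binding <- function() {
  c(cultivated = "cultivated", woodland = "woodland", grassland = "grassland",
    transportation = "industry_transportation",
    natural_water = "natural_water", built_up = "urban",
    subsided_water = "subsided_water")
}

#' Read/write coefficient tables as CSV
#'
#' @param path CSV with columns `class`, `vc_yuan_per_hm2_a`.
#' @return A `vc_table` (without breakdown).
#' @export
read_coefficients <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "vc_yuan_per_hm2_a") %in% names(d)))
  structure(d[, c("class", "vc_yuan_per_hm2_a")],
            class = c("vc_table", "data.frame"))
}

#' @rdname read_coefficients
#' @param coeffs a `vc_table`.
#' @export
write_coefficients <- function(coeffs, path) {
  utils::write.csv(as.data.frame(coeffs), path, row.names = FALSE)
  invisible(path)
}

#' Ecosystem-service value of a landscape
#'
#' ESV = sum over classes of area_i (hm2) x VC_i (yuan/hm2/a). The report is
#' in wanyuan (1 wanyuan = 10^4 yuan), the only unit in which per-class
#' values of a ~5000-hm2 study area are readable.
#'
#' @param areas a `landscape_area_table` ([tabulate_areas()] or
#'   [area_table()]).
#' @param coeffs a `vc_table`; defaults to [builtin_coefficients()].
#' @param class_binding named character vector mapping each land-cover class
#'   to a coefficient class.
#' @return A data frame of class `esv_report` with columns `class`,
#'   `esv_wanyuan`, `contribution_pct` and attribute `total_wanyuan`.
#'   Contribution ratios may be negative (construction classes) and sum
#'   to 100.
#' @export
compute_esv <- function(areas, coeffs = builtin_coefficients(),
                        class_binding = default_class_binding()) {
  stopifnot(inherits(areas, "landscape_area_table"),
            inherits(coeffs, "vc_table"))
  vc <- stats::setNames(coeffs$vc_yuan_per_hm2_a, coeffs$class)
  bound <- class_binding[areas$class]
  missing_bind <- is.na(bound) | !(bound %in% names(vc))
  if (any(missing_bind & areas$area_hm2 > 0))
    stop("no coefficient bound for class(es): ",
         paste(areas$class[missing_bind & areas$area_hm2 > 0], collapse = ", "))
  esv <- ifelse(missing_bind, 0, areas$area_hm2 * vc[bound] / 1e4)
  total <- sum(esv)
  pct <- if (abs(total) > 0) 100 * esv / total else rep(0, length(esv))
  out <- data.frame(class = areas$class, esv_wanyuan = unname(esv),
                    contribution_pct = unname(pct), stringsAsFactors = FALSE)
  structure(out, total_wanyuan = total,
            class = c("esv_report", "data.frame"))
}

#' Build an ESV report from printed per-class values
#'
#' For validating change rates against a published table's own inputs.
#'
#' @param esv_wanyuan named numeric vector, class -> ESV in wanyuan.
#' @return An `esv_report`.
#' @export
esv_report <- function(esv_wanyuan) {
  total <- sum(esv_wanyuan)
  out <- data.frame(class = names(esv_wanyuan),
                    esv_wanyuan = unname(esv_wanyuan),
                    contribution_pct = unname(100 * esv_wanyuan / total),
                    stringsAsFactors = FALSE)
  structure(out, total_wanyuan = total,
            class = c("esv_report", "data.frame"))
}

#' Change in ecosystem-service value
#'
#' Per-class and total change (wanyuan) with the signed relative rate
#' `change / before x 100`. The signed denominator is deliberate: for a
#' class whose ESV is negative (construction land), a move toward zero is a
#' *decrease in ecological damage* and the convention prints it with the
#' sign of the damage trend (e.g. -193.46 -> -169.98 gives -12.14%).
#' Classes with zero ESV before get an `NA` rate.
#'
#' @param before,after `esv_report`s over the same class universe.
#' @return A data frame of class `esv_change_report` with attributes
#'   `total_before`, `total_after`, `total_change`, `total_rate_pct`.
#' @export
esv_change <- function(before, after) {
  stopifnot(inherits(before, "esv_report"), inherits(after, "esv_report"))
  if (!setequal(before$class, after$class))
    stop("before/after reports cover different class universes")
  a <- after[match(before$class, after$class), ]
  chg <- a$esv_wanyuan - before$esv_wanyuan
  rate <- ifelse(before$esv_wanyuan != 0,
                 chg / before$esv_wanyuan * 100, NA_real_)
  tb <- attr(before, "total_wanyuan"); ta <- attr(after, "total_wanyuan")
  out <- data.frame(class = before$class,
                    esv_before = before$esv_wanyuan,
                    esv_after = a$esv_wanyuan,
                    change_wanyuan = chg, change_rate_pct = rate,
                    stringsAsFactors = FALSE)
  structure(out, total_before = tb, total_after = ta,
            total_change = ta - tb,
            total_rate_pct = if (tb != 0) (ta - tb) / tb * 100 else NA_real_,
            class = c("esv_change_report", "data.frame"))
}

#' Ecological storage state
#'
#' ESS = total ESV / (h x total area), a per-hectare-per-year density of the
#' region's ecological stock; h = 1 gives the state of a single year.
#'
#' @param total_esv_wanyuan total ESV, wanyuan.
#' @param total_area_hm2 total area, hm2 (> 0).
#' @param h estimation window in years (>= 1).
#' @return An object of class `eco_storage` with fields `ess` (wanyuan/hm2),
#'   `ess_yuan_per_hm2`, `h`, `total_esv_wanyuan`, `total_area_hm2`.
#' @export
compute_ess <- function(total_esv_wanyuan, total_area_hm2, h = 1) {
  if (total_area_hm2 <= 0) stop("total area must be positive")
  stopifnot(h >= 1)
  ess <- total_esv_wanyuan / (h * total_area_hm2)
  structure(list(ess = ess, ess_yuan_per_hm2 = ess * 1e4, h = h,
                 total_esv_wanyuan = total_esv_wanyuan,
                 total_area_hm2 = total_area_hm2),
            class = "eco_storage")
}

#' @export
print.eco_storage <- function(x, ...) {
  cat(sprintf("ecological storage state: %.4f wanyuan/hm2 (%.0f yuan/hm2), h = %g a\n",
              x$ess, x$ess_yuan_per_hm2, x$h))
  invisible(x)
}

#' Conversion of ecological storage between two states
#'
#' Quantity = ESS_after - ESS_before (wanyuan/hm2); the annual conversion
#' percent is the linear annualization quantity / years x 100.
#'
#' @param ess_before,ess_after [compute_ess()] states.
#' @param years span between the states (>= 1).
#' @return List with `quantity_wanyuan_per_hm2` and `percent_per_annum`.
#' @export
ess_conversion <- function(ess_before, ess_after, years) {
  stopifnot(inherits(ess_before, "eco_storage"),
            inherits(ess_after, "eco_storage"), years >= 1)
  q <- ess_after$ess - ess_before$ess
  list(quantity_wanyuan_per_hm2 = q,
       percent_per_annum = q / years * 100)
}

#' Currency helpers
#'
#' @param yuan amount in yuan.
#' @return Amount in wanyuan (10^4 yuan) or yiyuan (10^8 yuan).
#' @export
yuan_to_wanyuan <- function(yuan) yuan / 1e4

#' @rdname yuan_to_wanyuan
#' @param wanyuan amount in wanyuan.
#' @export
wanyuan_to_yuan <- function(wanyuan) wanyuan * 1e4

#' @rdname yuan_to_wanyuan
#' @export
yuan_to_yiyuan <- function(yuan) yuan / 1e8
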
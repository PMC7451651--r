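#' Simulate a stationary Gaussian random field on a regular grid
#'
#' Circulant-embedding spectral synthesis: the covariance of the smooth
#' (non-nugget) variogram component is embedded on a torus at least twice
#' the grid size, its eigenvalues obtained by FFT (tiny negative values
#' from imperfect embeddability are clipped to zero), and one real field is
#' read off an FFT of complex white noise. Exact up to the clipping, and
#' fast enough for hundreds of cells a side.
#'
#' @param spec a [grid_spec()].
#' @param model a [vgm_model()]; only its smooth component (psill, range,
#'   family) is simulated -- the nugget is micro-scale noise that belongs
#'   on point observations, not on the surface.
#' @param seed integer seed.
#' @return Matrix `spec$nrow` x `spec$ncol`, mean 0, variance ~ psill.
#' @export
simulate_grf <- function(spec, model, seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"), inherits(model, "variogram_model"))
  nr <- spec$nrow; nc <- spec$ncol; cs <- spec$cell_size
  if (model$psill == 0) return(matrix(0, nr, nc))
  M1 <- stats::nextn(2 * nr, 2); M2 <- stats::nextn(2 * nc, 2)
  # torus distances
  i <- 0:(M1 - 1); j <- 0:(M2 - 1)
  di <- pmin(i, M1 - i) * cs
  dj <- pmin(j, M2 - j) * cs
  D <- sqrt(outer(di^2, dj^2, "+"))
  C <- vgm_cov_smooth(model, D)
  lam <- Re(stats::fft(C))
  lam[lam < 0] <- 0
  field <- withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(M1 * M2), M1, M2) +
      1i * matrix(stats::rnorm(M1 * M2), M1, M2)
    Re(stats::fft(sqrt(lam / (M1 * M2)) * eps))
  })
  field[seq_len(nr), seq_len(nc)]
}

#' Synthetic two-epoch price-field scenario
#'
#' Defines the ground truth for the spillover recovery experiment:
#' epoch-1 surface = planar baseline + correlated residual from a stated
#' variogram; epoch-2 = epoch-1 x (1 + g) + a conical spillover kernel
#' A max(0, 1 - d/R) centred on the restored wetland, whose zonal integral
#' over the plots (SEV_true) is known. Defaults describe a suburban
#' district around a ~1 km-scale restoration site; see the package
#' vignette for the reasoning behind each value.
#'
#' @param extent domain edge length (m); the analysis grid is
#'   `extent/cell_size` cells a side.
#' @param cell_size analysis cell (m), 15 in the study design.
#' @param baseline intercept of the planar price trend (yuan/m2).
#' @param trend (dx, dy) slope of the baseline plane (yuan/m2 per m).
#' @param model residual variogram truth, a [vgm_model()]; its nugget is
#'   the sampling noise variance on observed points.
#' @param growth epoch growth fraction g.
#' @param kernel_amplitude,kernel_radius spillover cone A (yuan/m2), R (m).
#' @param kernel_center cone centre; default domain centre.
#' @param n_before,n_after samples per epoch (>= 10).
#' @param plots a [planned_plots()] set; default two half-disc 32-gon
#'   plots of radius 1.1 R around the kernel centre.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(extent = 3990, cell_size = 15,
                          baseline = 1200, trend = c(0.04, 0.02),
                          model = vgm_model("spherical", nugget = 25,
                                            psill = 900, range = 900),
                          growth = 1.7681,
                          kernel_amplitude = 350, kernel_radius = 500,
                          kernel_center = NULL,
                          n_before = 300, n_after = 300,
                          plots = NULL) {
  stopifnot(extent > 0, cell_size > 0, kernel_amplitude >= 0,
            kernel_radius > 0, n_before >= 10, n_after >= 10)
  n_cells <- round(extent / cell_size)
  stopifnot(abs(n_cells * cell_size - extent) < 1e-9)
  if (is.null(kernel_center)) kernel_center <- c(extent / 2, extent / 2)
  grid <- grid_spec(n_cells, n_cells, cell_size, origin = c(0, extent))
  if (is.null(plots)) {
    rad <- 1.1 * kernel_radius
    plots <- planned_plots(
      list(regular_ring(kernel_center, rad, 17, arc = c(0, pi)),
           regular_ring(kernel_center, rad, 17, arc = c(pi, 2 * pi))),
      plot_id = c("north_half", "south_half"), landuse = "residential")
  }
  structure(list(extent = extent, cell_size = cell_size, grid = grid,
                 baseline = baseline, trend = trend, model = model,
                 growth = growth, kernel_amplitude = kernel_amplitude,
                 kernel_radius = kernel_radius, kernel_center = kernel_center,
                 n_before = n_before, n_after = n_after, plots = plots),
            class = "scenario_spec")
}

# conical kernel A max(0, 1 - d/R) at locations xy
spillover_kernel <- function(xy, center, amplitude, radius) {
  d <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
  amplitude * pmax(0, 1 - d / radius)
}

#' Ground-truth SEV of a scenario
#'
#' Zonal integral of the spillover kernel over the plot set, computed
#' numerically on a fine grid (cell-centre membership, the same zonal rule
#' the pipeline uses). For a plot set covering the whole kernel disc the
#' value approaches the closed-form cone integral pi A R^2 / 3.
#'
#' @param spec a [scenario_spec()].
#' @param resolution integration cell (m), default 2.5.
#' @return SEV_true in yuan.
#' @export
scenario_sev_true <- function(spec, resolution = 2.5) {
  if (spec$kernel_amplitude == 0) return(0)
  R <- spec$kernel_radius; ctr <- spec$kernel_center
  lo <- ctr - R * 1.3; hi <- ctr + R * 1.3
  xs <- seq(lo[1] + resolution / 2, hi[1], by = resolution)
  ys <- seq(lo[2] + resolution / 2, hi[2], by = resolution)
  xy <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  k <- spillover_kernel(xy, ctr, spec$kernel_amplitude, R)
  inside <- rep(FALSE, nrow(xy))
  for (ring in spec$plots$rings) inside <- inside | points_in_ring(ring, xy)
  sum(k[inside]) * resolution^2
}

#' Generate the two-epoch price fields and samples of a scenario
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed driving the field, the sampling locations and
#'   the observation noise.
#' @return List: `truth_before`, `truth_after` ([price_surface()]s on the
#'   scenario grid), `points_before`, `points_after` ([price_points()]),
#'   `sev_true` (yuan), `plots`, `spec`.
#' @export
generate_price_field <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- spec$grid
  xy <- cell_centers(grid)
  base <- spec$baseline + spec$trend[1] * xy[, 1] + spec$trend[2] * xy[, 2]
  resid <- simulate_grf(grid, spec$model, seed = seed)
  v1 <- matrix(base, grid$nrow, grid$ncol) + resid
  if (any(v1 <= 0))
    stop("non-positive epoch-1 prices: raise the baseline or lower the residual variance")
  kern <- matrix(spillover_kernel(xy, spec$kernel_center,
                                  spec$kernel_amplitude, spec$kernel_radius),
                 grid$nrow, grid$ncol)
  v2 <- v1 * (1 + spec$growth) + kern
  t1 <- price_surface(v1, spec = grid, epoch = "before")
  t2 <- price_surface(v2, spec = grid, epoch = "after")

  sample_epoch <- function(surface, n, epoch, sub_seed) {
    withr::with_seed(sub_seed, {
      repeat {
        x <- stats::runif(n, 0, spec$extent)
        y <- stats::runif(n, 0, spec$extent)
        val <- bilinear_at(surface, cbind(x, y)) +
          stats::rnorm(n, 0, sqrt(spec$model$nugget))
        if (all(val > 0)) break
        warning("non-positive sampled price(s): resampling", call. = FALSE)
      }
      price_points(x, y, val, epoch = epoch)
    })
  }
  p1 <- sample_epoch(t1, spec$n_before, "before", seed + 1000L)
  p2 <- sample_epoch(t2, spec$n_after, "after", seed + 2000L)
  list(truth_before = t1, truth_after = t2,
       points_before = p1, points_after = p2,
       sev_true = scenario_sev_true(spec), plots = spec$plots, spec = spec)
}

# bilinear interpolation of a price_surface at points xy (clamped to the
# grid's centre hull)
bilinear_at <- function(surface, xy) {
  sp <- surface$spec; cs <- sp$cell_size
  col <- (xy[, 1] - sp$origin[1]) / cs + 0.5
  row <- (sp$origin[2] - xy[, 2]) / cs + 0.5
  col <- pmin(pmax(col, 1), sp$ncol)
  row <- pmin(pmax(row, 1), sp$nrow)
  c0 <- pmin(floor(col), sp$ncol - 1); r0 <- pmin(floor(row), sp$nrow - 1)
  fc <- col - c0; fr <- row - r0
  v <- surface$values
  idx <- function(r, c) v[cbind(r, c)]
  idx(r0, c0) * (1 - fr) * (1 - fc) + idx(r0 + 1, c0) * fr * (1 - fc) +
    idx(r0, c0 + 1) * (1 - fr) * fc + idx(r0 + 1, c0 + 1) * fr * fc
}
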
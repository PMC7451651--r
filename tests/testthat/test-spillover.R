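make_surface <- function(values, spec, epoch = "e") {
  price_surface(values, spec = spec, epoch = epoch)
}

test_that("average rise recovers closed-form growth", {
  g <- grid_spec(10, 10, 15, origin = c(0, 150))
  b <- make_surface(matrix(100 + 1:100, 10, 10), g)
  expect_equal(average_rise(b, b), 0)
  a2 <- make_surface(2 * b$values, g)
  expect_equal(average_rise(b, a2), 1.0)
  g2 <- grid_spec(10, 10, 30, origin = c(0, 300))
  expect_error(average_rise(b, make_surface(b$values, g2)), "geometry")
  zero <- make_surface(matrix(0, 10, 10), g)
  expect_error(average_rise(zero, b), "positive")
})

test_that("excess surface isolates departures from uniform growth", {
  g <- grid_spec(10, 10, 15, origin = c(0, 150))
  b <- make_surface(matrix(100 + 1:100, 10, 10), g)
  r <- 0.4
  uniform <- make_surface(b$values * (1 + r), g)
  ex <- excess_surface(b, uniform, r)
  expect_equal(max(abs(ex$excess)), 0, tolerance = 1e-10)
  expect_false(any(ex$mask))

  bump <- uniform
  bump$values[4, 7] <- bump$values[4, 7] + 100
  ex2 <- excess_surface(b, bump, r)
  expect_equal(ex2$excess[4, 7], 100)
  expect_equal(sum(ex2$mask), 1)
  expect_true(ex2$mask[4, 7])
})

test_that("a conical kernel produces a disc-shaped mask", {
  ext <- 1500; cs <- 15
  g <- grid_spec(ext / cs, ext / cs, cs, origin = c(0, ext))
  xy <- cell_centers(g)
  base <- matrix(500, g$nrow, g$ncol)
  kern <- matrix(ecospill:::spillover_kernel(xy, c(750, 750), 200, 300),
                 g$nrow, g$ncol)
  r <- 0.5
  after <- make_surface(base * (1 + r) + kern, g)
  ex <- excess_surface(make_surface(base, g), after, r)
  d <- sqrt((xy[, 1] - 750)^2 + (xy[, 2] - 750)^2)
  expect_true(all(ex$mask[matrix(d < 290, g$nrow)]))
  expect_false(any(ex$mask[matrix(d > 310, g$nrow)]))
})

test_that("zonal SEV integration does hand arithmetic", {
  g <- grid_spec(20, 20, 10, origin = c(0, 200))
  # one 100 x 100 m plot fully inside the mask, uniform excess 100 yuan/m2
  plot1 <- planned_plots(list(rbind(c(50, 50), c(150, 50),
                                    c(150, 150), c(50, 150))))
  expect_equal(plot1$area_m2, 10000)
  ex <- list(excess = matrix(100, 20, 20),
             mask = matrix(TRUE, 20, 20), spec = g)
  res <- compute_sev(ex, plot1)
  expect_equal(res$sev_yuan, 1e6)
  expect_equal(res$max_excess, 100)
  expect_equal(res$mean_excess, 100)
  expect_equal(res$affected_area_hm2, 1)

  # empty mask -> zero SEV, with a warning about no overlap
  ex0 <- list(excess = matrix(100, 20, 20),
              mask = matrix(FALSE, 20, 20), spec = g)
  expect_warning(res0 <- compute_sev(ex0, plot1), "overlap")
  expect_equal(res0$sev_yuan, 0)
})

test_that("SEV of the analytic cone converges with grid refinement", {
  A <- 200; R <- 300; ctr <- c(750, 750); ext <- 1500
  analytic <- pi * A * R^2 / 3
  plot_disc <- planned_plots(list(regular_ring(ctr, R * 1.2, 64)))
  err <- vapply(c(60, 30, 15), function(cs) {
    g <- grid_spec(ext / cs, ext / cs, cs, origin = c(0, ext))
    xy <- cell_centers(g)
    kern <- matrix(ecospill:::spillover_kernel(xy, ctr, A, R), g$nrow, g$ncol)
    ex <- list(excess = kern, mask = kern > 0, spec = g)
    abs(compute_sev(ex, plot_disc)$sev_yuan - analytic) / analytic
  }, numeric(1))
  expect_true(all(diff(err) < 0))   # monotone shrinking discretization error
  expect_lt(err[3], 0.02)           # within 2% at 15 m
})

test_that("spillover respects homogeneity and the coupling identities", {
  g <- grid_spec(30, 30, 15, origin = c(0, 450))
  vals <- matrix(400, 30, 30) + simulate_grf(g, vgm_model("spherical", 0, 100, 200), seed = 71)
  b <- make_surface(vals, g)
  a <- make_surface(vals * 1.6 + 50 * (vals > 400), g)
  plots <- planned_plots(list(rbind(c(30, 30), c(420, 30), c(420, 420), c(30, 420))))
  r <- average_rise(b, a)
  sev1 <- compute_sev(excess_surface(b, a, r), plots)$sev_yuan

  # scaling both epochs by c leaves r unchanged and scales SEV by c
  cc <- 3.5
  bc <- make_surface(vals * cc, g); ac <- make_surface(a$values * cc, g)
  expect_equal(average_rise(bc, ac), r, tolerance = 1e-12)
  sev2 <- compute_sev(excess_surface(bc, ac, r), plots)$sev_yuan
  expect_equal(sev2, cc * sev1, tolerance = 1e-9)

  # after = before(1 + r) exactly -> SEV = 0 regardless of plots
  exact <- make_surface(vals * (1 + r), g)
  expect_equal(suppressWarnings(
    compute_sev(excess_surface(b, exact, r), plots)$sev_yuan), 0)
})

test_that("enlarging plots never decreases SEV", {
  g <- grid_spec(40, 40, 15, origin = c(0, 600))
  xy <- cell_centers(g)
  kern <- matrix(ecospill:::spillover_kernel(xy, c(300, 300), 150, 200),
                 g$nrow, g$ncol)
  ex <- list(excess = kern, mask = kern > 0, spec = g)
  radii <- c(100, 200, 300)
  sevs <- vapply(radii, function(rad)
    compute_sev(ex, planned_plots(list(regular_ring(c(300, 300), rad, 48))))$sev_yuan,
    numeric(1))
  expect_true(all(diff(sevs) >= 0))
})

test_that("the pipeline on one epoch reused twice returns zero spillover", {
  sc <- scenario_spec(extent = 1500, n_before = 60, n_after = 60,
                      kernel_amplitude = 0)
  gen <- generate_price_field(sc, seed = 81)
  res <- suppressWarnings(run_spillover_pipeline(
    gen$points_before, gen$points_before, sc$grid, gen$plots, seed = 81))
  expect_equal(res$r, 0, tolerance = 1e-12)
  expect_equal(res$sev_yuan, 0)
})

test_that("plots round-trip through GeoJSON", {
  plots <- planned_plots(
    list(rbind(c(0, 0), c(100, 0), c(100, 80), c(0, 80)),
         regular_ring(c(500, 500), 120, 12)),
    plot_id = c("a", "b"), landuse = c("residential", "commercial"))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_plots_geojson(plots, path)
  plots2 <- read_plots_geojson(path)
  expect_equal(plots2$plot_id, plots$plot_id)
  expect_equal(plots2$landuse, plots$landuse)
  expect_equal(plots2$area_m2, plots$area_m2, tolerance = 1e-9)
  expect_equal(plots2$rings[[2]], plots$rings[[2]], ignore_attr = TRUE)

  expect_error(planned_plots(list(rbind(c(0, 0), c(1, 0), c(2, 0)))),
               "degenerate")
  expect_error(planned_plots(list(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))),
                             area_m2 = 12000), "1%")
})
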
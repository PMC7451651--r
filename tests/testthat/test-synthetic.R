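test_that("land-cover synthesis hits any representable target exactly", {
  for (seed in 1:4) {
    targets <- withr::with_seed(seed, {
      a <- sample(1:5000, 5) / 100          # arbitrary 2-decimal hm2 values
      names(a) <- sample(names(landcover_classes()), 5)
      a
    })
    g <- generate_landcover(targets, cell_size = 10, seed = seed)
    at <- tabulate_areas(g)
    got <- stats::setNames(at$area_hm2, at$class)[names(targets)]
    expect_equal(got, targets, tolerance = 1e-12)
  }

  # single class, 1 hm2 at 10 m -> exactly 100 cells
  g1 <- generate_landcover(c(woodland = 1), cell_size = 10, seed = 1)
  expect_equal(sum(g1$values == 2L, na.rm = TRUE), 100)

  # a target not representable at this cell size names the class
  expect_error(generate_landcover(c(woodland = 1.005), cell_size = 10, seed = 1),
               "woodland")
})

test_that("land-cover synthesis is seed-deterministic with varied layouts", {
  targets <- c(cultivated = 30, natural_water = 12.5, built_up = 7.5)
  g1 <- generate_landcover(targets, cell_size = 10, seed = 9)
  g2 <- generate_landcover(targets, cell_size = 10, seed = 9)
  g3 <- generate_landcover(targets, cell_size = 10, seed = 10)
  expect_identical(g1$values, g2$values)
  expect_false(identical(g1$values, g3$values))
  expect_equal(tabulate_areas(g3)$area_hm2, tabulate_areas(g1)$area_hm2)
})

test_that("simulated fields have the stated variance and no trend", {
  g <- grid_spec(150, 150, 15, origin = c(0, 2250))
  m <- vgm_model("exponential", nugget = 50, psill = 400, range = 300)
  vars <- vapply(1:8, function(s) var(as.vector(simulate_grf(g, m, seed = s))),
                 numeric(1))
  # nugget is excluded from the surface; variance targets the partial sill
  expect_equal(mean(vars), m$psill, tolerance = 0.25)
  means <- vapply(1:8, function(s) mean(simulate_grf(g, m, seed = s)),
                  numeric(1))
  expect_lt(abs(mean(means)), 5)
})

test_that("scenario ground truth matches the closed-form cone integral", {
  ctr <- c(1995, 1995)
  disc <- planned_plots(list(regular_ring(ctr, 550, 64)))
  sc <- scenario_spec(kernel_amplitude = 350, kernel_radius = 500,
                      plots = disc)
  expect_equal(scenario_sev_true(sc), pi * 350 * 500^2 / 3,
               tolerance = 0.01)
  sc0 <- scenario_spec(kernel_amplitude = 0)
  expect_equal(scenario_sev_true(sc0), 0)
})

test_that("generated price samples are positive, seeded and epoch-scaled", {
  sc <- scenario_spec(extent = 1500, n_before = 40, n_after = 40)
  gen <- generate_price_field(sc, seed = 5)
  gen2 <- generate_price_field(sc, seed = 5)
  expect_identical(gen$points_before$price, gen2$points_before$price)
  expect_true(all(gen$points_before$price > 0))
  expect_true(all(gen$points_after$price > 0))
  expect_equal(nrow(gen$points_before), 40)
  # epoch-2 mean reflects the growth factor
  ratio <- mean(gen$truth_after$values) / mean(gen$truth_before$values)
  expect_equal(ratio, 1 + sc$growth, tolerance = 0.02)
})

test_that("sampled points carry the truth surface plus nugget noise", {
  sc <- scenario_spec(extent = 1500, n_before = 200, n_after = 40)
  gen <- generate_price_field(sc, seed = 6)
  truth_at <- ecospill:::bilinear_at(gen$truth_before,
                                     cbind(gen$points_before$x,
                                           gen$points_before$y))
  resid <- gen$points_before$price - truth_at
  expect_lt(abs(mean(resid)), 2)
  expect_equal(stats::sd(resid), sqrt(sc$model$nugget), tolerance = 0.25)
})

test_that("the fixture bundle reproduces the published accounting", {
  out <- withr::local_tempdir()
  paths <- make_panan_fixture(out, seed = 1)
  expect_true(all(file.exists(unlist(paths))))
  pipe <- esv_pipeline(paths$raster_2008, paths$raster_2017, paths$legend,
                       read_coefficients(paths$coefficients))
  expect_equal(attr(pipe$areas_before, "total_hm2"), 5309.42, tolerance = 1e-9)
  expect_equal(attr(pipe$areas_after, "total_hm2"), 5309.42, tolerance = 1e-9)
  expect_equal(attr(pipe$esv_before, "total_wanyuan"), 3586.06,
               tolerance = 0.01)
  expect_equal(pipe$ess_before$ess, 0.6754, tolerance = 5e-5)

  exp <- jsonlite::read_json(paths$expectations)
  expect_equal(exp$esv_total_2008, 3586.06)
  expect_equal(exp$water_change_hm2, 152.15)

  # regenerating with the same seed is byte-identical
  out2 <- withr::local_tempdir()
  paths2 <- make_panan_fixture(out2, seed = 1)
  expect_identical(readLines(paths2$raster_2008), readLines(paths$raster_2008))
})
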
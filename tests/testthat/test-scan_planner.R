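test_that("dose, flux and throughput reproduce the worked numbers", {
  expect_identical(dose_per_length(1.0, 100), 0.01)
  expect_equal(energy_flux(1.0, 100, 50), 0.2, tolerance = 1e-12)
  expect_identical(dose_per_length(0, 123), 0)
  # linearity of flux in power
  expect_equal(energy_flux(3, 100, 50), 3 * energy_flux(1, 100, 50))
  # internal consistency: flux = dose / width
  expect_equal(energy_flux(0.8, 100, 50), dose_per_length(0.8, 100) / 0.05)

  expect_equal(throughput(100, 10), 10000)
  expect_equal(throughput(1000, 10), 100000)
  expect_equal(throughput(100, 20), throughput(100, 10) / 2)

  expect_error(dose_per_length(1, 0), "positive")
  expect_error(energy_flux(1, 100, -5), "positive")
  expect_error(throughput(-1), "positive")
})

test_that("equal P/v combinations give identical dose and flux", {
  combos <- list(c(2.5, 500), c(2.0, 400), c(1.6, 320), c(1.0, 200))
  doses <- vapply(combos, function(pv) dose_per_length(pv[1], pv[2]), numeric(1))
  fluxes <- vapply(combos, function(pv) energy_flux(pv[1], pv[2], 50), numeric(1))
  expect_true(all(doses == doses[1]))
  expect_true(all(fluxes == fluxes[1]))
})

test_that("pattern planning counts lines correctly and clips to the region", {
  sq <- region_rect(0, 0, 1000, 1000)
  las <- laser_params(1, 100, 50, 100)
  lat <- plan_pattern("lattice", sq, las)
  # 2 * (floor(L/d) + 1) lines over a square
  expect_equal(nrow(lat$segments), 2L * (1000 %/% 100 + 1L))

  ras <- plan_pattern("raster", sq, las)
  expect_equal(nrow(ras$segments), 11L)
  expect_true(all(ras$segments$length_um == 1000))

  # chord sum over a circle converges to area / interval
  circ <- region_circle(5000)
  rc <- plan_pattern("raster", circ, laser_params(1, 100, 50, 100))
  expect_equal(sum(rc$segments$length_um), pi * 5000^2 / 100, tolerance = 0.01)
  # chords never exceed the diameter
  expect_true(all(rc$segments$length_um <= 10000))

  expect_equal(nrow(plan_pattern("line", sq, las)$segments), 1L)
  # interval larger than the region extent yields a single line, not an error
  wide <- plan_pattern("raster", sq, laser_params(1, 100, 50, 5000))
  expect_equal(nrow(wide$segments), 1L)
  expect_error(region_rect(0, 0, -5, 10), "positive")
  expect_error(region_circle(0), "positive")
})

test_that("gating covers exactly the target spans and is monotone in threshold", {
  # 200 um square target aligned with the 25 um line grid
  m <- matrix(0L, 400, 400)
  m[101:301, 101:301] <- 2L   # y, x in [100, 300] um
  mk <- label_mask(m, 1)
  p <- plan_pattern("raster", region_rect(0, 0, 399, 399),
                    laser_params(0.8, 100, 50, 25))
  g <- gate_path(p, mk, dilate_um = 0)
  n_on <- sum(vapply(g$on, nrow, integer(1)) > 0)
  expect_equal(n_on, 200 / 25 + 1)           # 9 lines cross the square
  expect_equal(on_length_um(g), 9 * 200, tolerance = 0.02)

  # dilation by the beam half-width extends coverage outward
  gd <- gate_path(p, mk)
  expect_gt(on_length_um(gd), on_length_um(g))

  # probability-map gating: threshold 0 -> fully ON; > 1 -> fully OFF
  pm <- structure(list(probs = matrix(runif(400 * 400), 400, 400),
                       pixel_size_um = 1), class = "ProbabilityMap")
  full <- gate_path(p, pm, threshold = 0, dilate_um = 0)
  expect_equal(on_length_um(full), sum(p$segments$length_um))
  off <- gate_path(p, pm, threshold = 1.001, dilate_um = 0)
  expect_equal(on_length_um(off), 0)

  # monotonicity: lowering the threshold never decreases ON length
  lens <- vapply(c(0.9, 0.6, 0.3, 0.1), function(th)
    on_length_um(gate_path(p, pm, threshold = th, dilate_um = 0)), numeric(1))
  expect_true(all(diff(lens) >= 0))
  # gating conservation: ON length never exceeds the path length
  expect_true(all(lens <= sum(p$segments$length_um)))
})

test_that("path statistics follow the arithmetic of the dose model", {
  las <- laser_params(1, 100, 50, 25)
  one <- plan_pattern("line", region_rect(0, 0, 30000, 100), las)
  st <- path_stats(one)
  expect_equal(st$total_time_s, 0.3)
  expect_equal(st$delivered_energy_J, 1 * 30 / 100)
  expect_equal(st$dose_J_per_mm, 0.01)
  expect_equal(st$flux_J_per_mm2, 0.2)
  expect_equal(st$throughput_cells_per_s, 10000)

  # turnaround overhead adds (n - 1) pauses
  p <- plan_pattern("raster", region_rect(0, 0, 1000, 1000),
                    laser_params(1, 100, 50, 100), turnaround_s = 0.5)
  st2 <- path_stats(p)
  expect_equal(st2$total_time_s, 11 * 1 / 100 + 10 * 0.5)

  # energy of a gated path is at most the ungated energy
  m <- matrix(0L, 1001, 1001); m[400:600, 400:600] <- 2L
  g <- gate_path(plan_pattern("raster", region_rect(0, 0, 1000, 1000),
                              laser_params(1, 100, 50, 100)),
                 label_mask(m, 1))
  expect_lt(path_stats(g)$delivered_energy_J, st2$delivered_energy_J)
})

test_that("scan paths round-trip through CSV + JSON", {
  td <- withr::local_tempdir()
  m <- matrix(0L, 401, 401); m[150:250, 150:250] <- 2L
  p <- plan_pattern("raster", region_rect(0, 0, 400, 400),
                    laser_params(0.8, 100, 50, 50))
  g <- gate_path(p, label_mask(m, 1))
  fp <- file.path(td, "path.csv")
  write_scan_path(g, fp)
  back <- read_scan_path(fp)
  expect_equal(back$segments$x0, g$segments$x0)
  expect_equal(back$segments$length_um, g$segments$length_um)
  expect_equal(back$laser$power_W, g$laser$power_W)
  expect_true(back$gated)
  expect_equal(on_length_um(back), on_length_um(g), tolerance = 1e-9)
})
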
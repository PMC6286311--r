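test_that("kill calibration pins the threshold to the deployment flux", {
  km <- calibrate_kill()
  expect_equal(km$dose_threshold_J_mm2, energy_flux(0.8, 100, 50))
  expect_equal(km$kill_halfwidth_um, 25)
  expect_error(calibrate_kill(0), "positive")
})

test_that("dose accumulates as a uniform band, sums over passes, and is zero when OFF", {
  las <- laser_params(1, 100, 50, 25)
  p <- plan_pattern("line", region_rect(0, 0, 999, 199), las)
  d <- accumulate_dose(p, 200, 1000, 1)
  vals <- unique(as.vector(d$dose))
  expect_setequal(round(vals, 10), c(0, 0.2))
  # band width: pixels within 25 um of the centerline at y = 99.5
  expect_equal(sum(d$dose[, 500] > 0), 50)

  # two identical passes double exactly
  p2 <- p
  p2$segments <- rbind(p$segments, p$segments)
  p2$on <- c(p$on, p$on)
  d2 <- accumulate_dose(p2, 200, 1000, 1)
  expect_equal(d2$dose, 2 * d$dose)

  # fully gated-off path deposits nothing
  poff <- p
  poff$on <- list(matrix(numeric(0), 0, 2))
  poff$gated <- TRUE
  expect_equal(max(accumulate_dose(poff, 200, 1000, 1)$dose), 0)
})

test_that("the kill rule is binary at the cell center with the expected swath", {
  cells <- data.frame(x_um = rep(500, 9),
                      y_um = 99.5 + c(0, 10, 20, 24.9, -24.9, 26, -26, 100, 400),
                      diameter_um = 10, type = "undifferentiated",
                      alive = TRUE, stringsAsFactors = FALSE)
  km <- calibrate_kill()

  # zero dose: untouched
  zero <- structure(list(dose = matrix(0, 500, 1000), pixel_size_um = 1),
                    class = "DoseField")
  expect_identical(apply_kill(cells, zero, km)$alive, rep(TRUE, 9))

  # uniform supra-threshold dose: all dead
  hot <- structure(list(dose = matrix(1, 500, 1000), pixel_size_um = 1),
                   class = "DoseField")
  expect_identical(apply_kill(cells, hot, km)$alive, rep(FALSE, 9))

  # a 1.0 W / 100 mm/s line kills within ~25 um of the centerline only
  las <- laser_params(1.0, 100, 50, 25)
  d <- accumulate_dose(plan_pattern("line", region_rect(0, 0, 999, 199), las),
                       500, 1000, 1)
  out <- apply_kill(cells, d, km)
  expect_identical(out$alive, abs(cells$y_um - 99.5) > 25.5)

  # 0.7 W at the same speed is sub-threshold: everyone survives
  d7 <- accumulate_dose(plan_pattern("line", region_rect(0, 0, 999, 199),
                                     laser_params(0.7, 100, 50, 25)),
                        500, 1000, 1)
  expect_true(all(apply_kill(cells, d7, km)$alive))

  # monotonicity: raising power never resurrects a cell
  d12 <- accumulate_dose(plan_pattern("line", region_rect(0, 0, 999, 199),
                                      laser_params(1.2, 100, 50, 25)),
                         500, 1000, 1)
  dead08 <- !apply_kill(cells, d, km)$alive
  dead12 <- !apply_kill(cells, d12, km)$alive
  expect_true(all(dead12[dead08]))
})

test_that("purity accounting is conserved and the flow analogue agrees", {
  cells <- data.frame(x_um = runif(100, 0, 99), y_um = runif(100, 0, 99),
                      diameter_um = 10,
                      type = rep(c("differentiated", "undifferentiated"),
                                 c(30, 70)),
                      alive = TRUE, stringsAsFactors = FALSE)
  rep0 <- purity_report(cells)
  expect_equal(rep0$n_alive + rep0$n_dead, rep0$n_total)
  expect_equal(rep0$purity, 0.7)
  fa <- flow_analog(cells)
  expect_equal(fa$positive_fraction, rep0$purity)

  cells$alive <- FALSE
  dead <- purity_report(cells)
  expect_false(dead$defined)
  expect_true(is.na(dead$purity))
  expect_false(flow_analog(cells)$defined)
  expect_equal(dead$n_alive + dead$n_dead, dead$n_total)
})

test_that("oracle targeting purifies to ~100% and bounds the deployed loop", {
  sim <- small_sim_params(seed = 200)
  orep <- run_closed_loop(sim, seed = 200, targeting = "oracle")
  expect_true(orep$defined)
  expect_gte(orep$purity, 0.995)
  expect_gt(orep$n_alive, 0)
  expect_equal(orep$n_alive + orep$n_dead, orep$n_total)
  # dose accounting on the gated path is consistent with P/v
  expect_equal(orep$stats$dose_J_per_mm, 0.008)
  expect_equal(orep$stats$flux_J_per_mm2, 0.16)
})

test_that("a fully undifferentiated culture passes through unharmed in purity", {
  sim <- small_sim_params(seed = 201, differentiated_fraction = 0)
  rep <- run_closed_loop(sim, seed = 201, targeting = "oracle")
  expect_equal(rep$purity_before, 1)
  expect_equal(rep$purity, 1)
  # nothing is targeted, so nothing dies
  expect_equal(rep$n_dead, 0)
})

test_that("the CNN-targeted loop improves purity and stays below the oracle bound", {
  sim <- small_sim_params(seed = 202)
  hy <- train_hyper(epochs = 3)
  rep <- run_closed_loop(sim, hyper = hy, seed = 202, n_train_fields = 1,
                         stride_px = 35L)
  orep <- run_closed_loop(sim, seed = 202, targeting = "oracle")
  expect_gte(rep$purity, rep$purity_before)
  expect_lte(rep$purity, orep$purity + 0.01)
  expect_gt(rep$heldout_accuracy, 0.8)
  expect_equal(rep$n_alive_undiff + rep$n_alive_diff, rep$n_alive)
})
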
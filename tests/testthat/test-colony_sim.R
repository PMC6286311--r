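test_that("the generator is deterministic and honours degenerate fractions", {
  p <- small_sim_params(seed = 11)
  a <- generate_field(p)
  b <- generate_field(p)
  expect_identical(a$phase$pixels, b$phase$pixels)
  expect_identical(a$fluor$pixels, b$fluor$pixels)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$cells, b$cells)

  z <- generate_field(small_sim_params(seed = 2, differentiated_fraction = 0))
  expect_equal(sum(z$mask$labels == 2L), 0)
  expect_true(all(z$cells$type == "undifferentiated"))
  expect_true(all(z$cells$alive))

  expect_error(colony_sim_params(differentiated_fraction = 1.5), "\\[0, 1\\]")
  expect_error(colony_sim_params(field_width_px = 0), "positive")
  expect_error(colony_sim_params(pixel_size_um = -1), "positive")
})

test_that("realized differentiated area fraction matches its target on average", {
  target <- 0.2
  fr <- vapply(1:12, function(s) {
    lab <- generate_field(small_sim_params(seed = 100 + s))$mask$labels
    sum(lab == 2L) / sum(lab > 0L)
  }, numeric(1))
  # brute-force pixel counting against the generator's own target
  expect_lt(abs(mean(fr) - target), 0.02)
})

test_that("differentiated pixels occur only inside colony footprints and cells match the mask", {
  f <- generate_field(small_sim_params(seed = 7))
  lab <- f$mask$labels
  expect_true(all(lab %in% 0:2))
  # every cell's type equals the mask class at its center
  i <- round(f$cells$y_um) + 1; j <- round(f$cells$x_um) + 1
  at <- lab[cbind(i, j)]
  expect_true(all(at > 0))
  expect_identical(c("undifferentiated", "differentiated")[at], f$cells$type)
})

test_that("thresholding fluorescence at the class midpoint recovers the mask", {
  p <- small_sim_params(seed = 21)
  f <- generate_field(p)
  mid <- (p$fluor_pos_level + p$fluor_neg_level) / 2
  err <- mean((f$fluor$pixels > mid) != (f$mask$labels == 1L))
  expect_lt(err, 0.05)
})

test_that("grid patch extraction tiles disjointly, in bounds, with the expected counts", {
  # candidate count on the native geometry: all-undifferentiated mask keeps
  # every crop, floor(1920/70) * floor(1200/70) = 27 * 17 = 459
  fr <- image_frame(matrix(1000, 1200, 1920), "phase", 1)
  mk <- label_mask(matrix(1L, 1200, 1920), 1)
  ps <- extract_patches(fr, mk, 70L, "grid_nonoverlap")
  expect_equal(dim(ps$x)[3], 459L)
  expect_true(all(ps$label == "undifferentiated"))

  # exact tiling of a 140 x 140 frame into 4 disjoint crops
  fr2 <- image_frame(matrix(1, 140, 140), "phase", 1)
  mk2 <- label_mask(matrix(1L, 140, 140), 1)
  ps2 <- extract_patches(fr2, mk2, 70L, "grid_nonoverlap")
  expect_equal(dim(ps2$x)[3], 4L)
  expect_setequal(paste(ps2$origin$row, ps2$origin$col),
                  c("1 1", "1 71", "71 1", "71 71"))

  # property: disjointness and bounds for random frame sizes
  set.seed(99)
  for (k in 1:6) {
    h <- sample(70:300, 1); w <- sample(70:300, 1)
    fr3 <- image_frame(matrix(1, h, w), "phase", 1)
    mk3 <- label_mask(matrix(1L, h, w), 1)
    ps3 <- extract_patches(fr3, mk3, 70L, "grid_nonoverlap")
    expect_equal(dim(ps3$x)[3], (h %/% 70) * (w %/% 70))
    expect_true(all(ps3$origin$row + 69 <= h & ps3$origin$col + 69 <= w))
    # non-overlap: origins are unique multiples of the patch size
    expect_true(all((ps3$origin$row - 1) %% 70 == 0))
    expect_true(all((ps3$origin$col - 1) %% 70 == 0))
    expect_false(any(duplicated(ps3$origin)))
  }
  expect_error(extract_patches(fr2, mk2, 141L), "exceeds")
})

test_that("patch labels follow the majority rule with the purity filter", {
  lab <- matrix(0L, 70, 140)
  lab[, 1:70] <- 1L           # pure undifferentiated patch
  lab[, 71:105] <- 1L         # right patch: half undiff, half diff
  lab[, 106:140] <- 2L
  fr <- image_frame(matrix(1, 70, 140), "phase", 1)
  ps <- extract_patches(fr, label_mask(lab, 1), 70L, "grid_nonoverlap",
                        purity_threshold = 0.8)
  # the mixed patch falls below 0.8 purity and is dropped
  expect_equal(dim(ps$x)[3], 1L)
  expect_equal(as.character(ps$label), "undifferentiated")

  # background counts against purity unless folded into undifferentiated
  lab2 <- matrix(0L, 70, 70); lab2[1:70, 1:30] <- 1L
  fr2 <- image_frame(matrix(1, 70, 70), "phase", 1)
  expect_error(extract_patches(fr2, label_mask(lab2, 1), 70L,
                               "grid_nonoverlap", purity_threshold = 0.8),
               "no patch")
  ps2 <- extract_patches(fr2, label_mask(lab2, 1), 70L, "grid_nonoverlap",
                         purity_threshold = 0.8,
                         background_policy = "undifferentiated")
  expect_equal(as.character(ps2$label), "undifferentiated")

  # random policy is seeded and in bounds
  f <- generate_field(small_sim_params(seed = 5))
  r1 <- extract_patches(f$phase, f$mask, policy = "random", n_random = 60,
                        seed = 3)
  r2 <- extract_patches(f$phase, f$mask, policy = "random", n_random = 60,
                        seed = 3)
  expect_identical(r1$x, r2$x)
  expect_true(all(r1$origin$row + 69 <= nrow(f$phase$pixels)))
})

test_that("raster, mask and cell-table IO round-trip", {
  f <- generate_field(small_sim_params(seed = 31))
  td <- withr::local_tempdir()

  tp <- file.path(td, "phase.tif")
  write_frame(f$phase, tp)
  back <- read_frame(tp, "phase", f$phase$pixel_size_um)
  expect_lt(max(abs(back$pixels - round(f$phase$pixels))), 1.5)

  # PNG is 8-bit: round trip within one 8-bit quantization step
  pp <- file.path(td, "phase.png")
  write_frame(f$phase, pp)
  expect_lt(max(abs(read_frame(pp)$pixels - round(f$phase$pixels))), 258)

  mp <- file.path(td, "mask.png")
  write_mask(f$mask, mp)
  expect_identical(read_mask(mp, 1)$labels, f$mask$labels)

  cp <- file.path(td, "cells.csv")
  write_cells(f$cells, cp)
  back_cells <- read_cells(cp)
  expect_equal(back_cells$type, f$cells$type)
  expect_equal(back_cells$x_um, f$cells$x_um, tolerance = 1e-9)
  expect_identical(back_cells$alive, f$cells$alive)
})
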
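test_that("the architecture size chain and probability normalization hold", {
  arch <- cnn_arch()
  sh <- arch$shape
  expect_equal(sh$conv1, 66L)
  expect_equal(sh$pool1, 22L)
  expect_equal(sh$conv2, 20L)
  expect_equal(sh$pool2, 10L)
  expect_equal(sh$fc_in, 3200L)
  expect_error(cnn_arch(input_px = 64), "70")

  m <- build_model(arch, seed = 4)
  set.seed(1)
  x <- array(rnorm(70 * 70 * 5), c(70, 70, 5))
  pr <- predict_patches(m, x)
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("the forward pass matches a brute-force reference to 1e-6", {
  arch <- cnn_arch()
  m <- build_model(arch, seed = 9)
  set.seed(2)
  for (k in 1:3) {
    x <- matrix(rnorm(4900), 70, 70)
    xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    got <- predict_patches(m, array(x, c(70, 70, 1)))
    want <- ref_forward(xs, m$weights, arch)
    expect_equal(as.numeric(got), want, tolerance = 1e-6)
  }
})

test_that("initialisation and training are deterministic under a fixed seed", {
  expect_identical(build_model(seed = 3)$weights, build_model(seed = 3)$weights)
  expect_false(identical(build_model(seed = 3)$weights$W1,
                         build_model(seed = 4)$weights$W1))

  f <- generate_field(small_sim_params(seed = 41))
  ps <- extract_patches(f$phase, f$mask, policy = "random", n_random = 80,
                        seed = 5)
  hy <- train_hyper(epochs = 2, seed = 6)
  m1 <- train_round(build_model(seed = 3), ps, hy)
  m2 <- train_round(build_model(seed = 3), ps, hy)
  expect_identical(m1$weights, m2$weights)
  # the log records a decreasing training loss
  expect_lt(tail(m1$log[[1]]$epoch_loss, 1), m1$log[[1]]$epoch_loss[1])
})

test_that("training rejects degenerate inputs", {
  f <- generate_field(small_sim_params(seed = 42))
  ps <- extract_patches(f$phase, f$mask, policy = "random", n_random = 60,
                        seed = 1)
  only_und <- subset_idx <- which(ps$label == "undifferentiated")
  one_class <- cellcull:::subset_patch_set(ps, only_und)
  expect_error(train_round(build_model(seed = 1), one_class, train_hyper()),
               "both classes")
})

test_that("the classifier separates the two textures and collapses on permuted labels", {
  fields <- small_fields(seeds = c(51, 52))
  hy <- train_hyper(epochs = 4, seed = 7)
  clf <- train_with_mining(fields, hyper = hy, n_random_per_field = 150)

  held <- generate_field(small_sim_params(seed = 53))
  hp <- extract_patches(held$phase, held$mask, policy = "grid_nonoverlap")
  pr <- predict_patches(clf, hp)
  pred <- ifelse(pr[, "differentiated"] >= 0.5, "differentiated",
                 "undifferentiated")
  acc <- mean(pred == as.character(hp$label))
  expect_gt(acc, 0.95)

  # no-signal null: permuted labels give chance-level held-out accuracy
  ps <- extract_patches(fields[[1]]$phase, fields[[1]]$mask,
                        policy = "random", n_random = 200, seed = 8)
  set.seed(9)
  ps$label <- sample(ps$label)
  m0 <- train_round(build_model(seed = 1), ps, train_hyper(epochs = 2, seed = 2))
  pr0 <- predict_patches(m0, hp)
  pred0 <- ifelse(pr0[, "differentiated"] >= 0.5, "differentiated",
                  "undifferentiated")
  acc0 <- mean(pred0 == as.character(hp$label))
  expect_lt(abs(acc0 - 0.5), 0.35)
})

test_that("mining returns exactly the misclassified undifferentiated patches", {
  fields <- small_fields(seeds = 61)
  # degenerate classifier forced to output one class via the head bias
  always_diff <- build_model(seed = 1)
  always_diff$weights$W3[] <- 0
  always_diff$weights$b3 <- c(10, -10)
  always_diff$trained <- TRUE
  mined <- mine_hard_examples(always_diff, fields)
  ref <- extract_patches(fields[[1]]$phase, fields[[1]]$mask,
                         policy = "grid_nonoverlap")
  expect_equal(dim(mined$x)[3], sum(ref$label == "undifferentiated"))
  expect_true(all(mined$label == "undifferentiated"))

  never_diff <- always_diff
  never_diff$weights$b3 <- c(-10, 10)
  empty <- mine_hard_examples(never_diff, fields)
  expect_equal(dim(empty$x)[3], 0L)
})

test_that("round-2 training does not increase the false-differentiated rate", {
  fields <- small_fields(seeds = c(71, 72))
  # deliberately light round-1 training so mining has something to correct
  hy <- train_hyper(epochs = 2, seed = 11)
  clf <- train_with_mining(fields, hyper = hy, n_random_per_field = 120)
  expect_equal(length(clf$log), 2L)

  held <- generate_field(small_sim_params(seed = 73))
  hp <- extract_patches(held$phase, held$mask, policy = "grid_nonoverlap")
  und <- cellcull:::subset_patch_set(hp, which(hp$label == "undifferentiated"))
  fd1 <- sum(predict_patches(clf$round1, und)[, "differentiated"] >= 0.5)
  fd2 <- sum(predict_patches(clf, und)[, "differentiated"] >= 0.5)
  expect_lte(fd2, fd1)

  # full determinism of the two-round pipeline
  clf2 <- train_with_mining(fields, hyper = hy, n_random_per_field = 120)
  expect_identical(clf$weights, clf2$weights)
})

test_that("probability maps are block-wise at native stride and margins are filled", {
  fields <- small_fields(seeds = 81)
  hy <- train_hyper(epochs = 3, seed = 12)
  clf <- train_with_mining(fields, hyper = hy, n_random_per_field = 120)
  f <- generate_field(small_sim_params(seed = 82))
  pm <- predict_map(clf, f$phase, stride_px = 70L)
  expect_identical(dim(pm$probs), dim(f$phase$pixels))
  expect_true(all(pm$probs >= 0 & pm$probs <= 1))
  # piecewise constant on the 70 px block grid
  expect_equal(length(unique(as.vector(pm$probs[1:70, 1:70]))), 1L)
  expect_equal(length(unique(as.vector(pm$probs[71:140, 1:70]))), 1L)
  # bottom/right margins replicate the nearest covered block
  h <- nrow(pm$probs)
  expect_equal(pm$probs[h, 1], pm$probs[(h %/% 70) * 70, 1])
  expect_error(predict_map(clf, f$fluor), "phase")

  small <- image_frame(matrix(1, 50, 50), "phase", 1)
  expect_error(predict_map(clf, small), "smaller")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  td <- withr::local_tempdir()
  m <- build_model(seed = 13)
  ck <- file.path(td, "clf.rds")
  save_classifier(m, ck)
  expect_true(file.exists(file.path(td, "clf.json")))
  back <- load_classifier(ck)
  expect_identical(back$weights, m$weights)
})
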
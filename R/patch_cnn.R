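## patch_cnn: the 70x70 patch classifier and its two-round training scheme.
##
## Architecture (fixed chain): 70x70x1 input -> conv 32 filters 5x5 (valid)
## -> ReLU -> max pool 3x3 (stride 3) -> conv 32 filters 3x3 (valid) -> ReLU
## -> max pool 2x2 (stride 2) -> fully connected to 2 class logits -> softmax
## cross-entropy. With these conventions the spatial chain is
## 70 -> 66 -> 22 -> 20 -> 10, so the head sees 10*10*32 = 3200 units.
## ReLU activations, valid convolutions and pool stride = pool kernel are
## conventions of this implementation (they yield the clean size chain), not
## properties fixed by the classifier's two-class formulation.
## Class order everywhere: 1 = differentiated, 2 = undifferentiated; reported
## probabilities are P(differentiated).

#' Architecture of the patch classifier
#'
#' @param input_px patch edge length (70 unless `allow_nonstandard`).
#' @param conv1_filters,conv1_kernel,pool1 first conv/pool stage.
#' @param conv2_filters,conv2_kernel,pool2 second conv/pool stage.
#' @param allow_nonstandard permit input sizes other than 70 (used for
#'   reduced test instances).
#' @return a `CnnArch` object, including the derived spatial size chain.
#' @export
cnn_arch <- function(input_px = 70L, conv1_filters = 32L, conv1_kernel = 5L,
                     pool1 = 3L, conv2_filters = 32L, conv2_kernel = 3L,
                     pool2 = 2L, allow_nonstandard = FALSE) {
  if (input_px != 70L && !allow_nonstandard)
    stopf("input_px must be 70 (set allow_nonstandard = TRUE to override)")
  a <- list(input_px = as.integer(input_px),
            conv1_filters = as.integer(conv1_filters),
            conv1_kernel = as.integer(conv1_kernel), pool1 = as.integer(pool1),
            conv2_filters = as.integer(conv2_filters),
            conv2_kernel = as.integer(conv2_kernel), pool2 = as.integer(pool2),
            n_classes = 2L)
  a$shape <- cnn_shape(a)
  class(a) <- "CnnArch"
  a
}

#' Spatial size chain of the architecture
#'
#' Valid convolutions shrink a side by `kernel - 1`; pooling divides by the
#' pool kernel (floor), with stride equal to the kernel.
#'
#' @param arch a [cnn_arch()] (or plain list with the same fields).
#' @return named list of side lengths after each stage plus the flattened
#'   feature count `fc_in`.
#' @export
cnn_shape <- function(arch) {
  s1 <- arch$input_px - arch$conv1_kernel + 1L
  s2 <- s1 %/% arch$pool1
  s3 <- s2 - arch$conv2_kernel + 1L
  s4 <- s3 %/% arch$pool2
  if (s4 < 1L) stopf("architecture collapses below 1 px (input too small)")
  list(input = arch$input_px, conv1 = s1, pool1 = s2, conv2 = s3, pool2 = s4,
       fc_in = s4 * s4 * arch$conv2_filters)
}

#' Training hyperparameters
#'
#' The published classifier fixes the architecture and loss but no training
#' schedule; these defaults are the package's own (Adam, 1e-3, small batches,
#' inverse-frequency class weighting to absorb the differentiated /
#' undifferentiated imbalance of randomly cropped patches).
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs epochs per training round.
#' @param class_weighting weight the loss by inverse class frequency.
#' @param seed seed controlling weight init and shuffling.
#' @return a `TrainHyper` object.
#' @export
train_hyper <- function(learning_rate = 1e-3, batch_size = 32L, epochs = 8L,
                        class_weighting = TRUE, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed)), class = "TrainHyper")
}

#' Build an untrained classifier
#'
#' He-normal initialisation drawn from R's RNG, so two builds with the same
#' seed are bit-identical.
#'
#' @param arch a [cnn_arch()].
#' @param seed integer seed for the initial weights.
#' @return a `cnn_classifier` object.
#' @export
build_model <- function(arch = cnn_arch(), seed = 1L) {
  sh <- arch$shape
  k1 <- arch$conv1_kernel; k2 <- arch$conv2_kernel
  f1 <- arch$conv1_filters; f2 <- arch$conv2_filters
  with_seed(seed, {
    he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
    w <- list(
      W1 = he(f1, k1 * k1, k1 * k1),
      b1 = numeric(f1),
      W2 = he(f2, k2 * k2 * f1, k2 * k2 * f1),
      b2 = numeric(f2),
      W3 = he(arch$n_classes, sh$fc_in, sh$fc_in),
      b3 = numeric(arch$n_classes),
      geom = c(k1, k1, arch$pool1, k2, k2, arch$pool2))
    structure(list(arch = arch, weights = w, trained = FALSE,
                   log = list(), init_seed = as.integer(seed)),
              class = "cnn_classifier")
  })
}

#' @export
print.cnn_classifier <- function(x, ...) {
  sh <- x$arch$shape
  cat(sprintf(
    "patch CNN (%dx%d -> conv%d -> pool%d -> conv%d -> pool%d -> FC %d -> 2), %s\n",
    x$arch$input_px, x$arch$input_px, x$arch$conv1_kernel, x$arch$pool1,
    x$arch$conv2_kernel, x$arch$pool2, sh$fc_in,
    if (x$trained) sprintf("trained (%d round%s)", length(x$log),
                           if (length(x$log) > 1) "s" else "") else "untrained"))
  invisible(x)
}

# per-patch standardization to zero mean / unit variance
standardize_patches <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  sd_ <- sqrt(pmax(colMeans(m^2) - mu^2, 1e-12))
  m <- sweep(sweep(m, 2, mu, "-"), 2, sd_, "/")
  array(m, d)
}

#' Class probabilities for a set of patches
#'
#' @param model a trained (or untrained) [build_model()] classifier.
#' @param x a `PatchSet` or a `p x p x n` array of raw patch intensities.
#' @param batch number of patches per forward call.
#' @return `n x 2` matrix of probabilities, columns
#'   `differentiated`, `undifferentiated`; rows sum to 1.
#' @export
predict_patches <- function(model, x, batch = 512L) {
  if (inherits(x, "PatchSet")) x <- x$x
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  if (dim(x)[1] != model$arch$input_px || dim(x)[2] != model$arch$input_px)
    stopf("patch size %dx%d does not match the model input (%d)",
          dim(x)[1], dim(x)[2], model$arch$input_px)
  xs <- standardize_patches(x)
  n <- dim(xs)[3]
  out <- matrix(NA_real_, n, 2,
                dimnames = list(NULL, c("differentiated", "undifferentiated")))
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    out[s:e, ] <- cnn_forward_cpp(xs[, , s:e, drop = FALSE], model$weights)
  }
  out
}

patch_labels_int <- function(label) {
  # 0-based class index for the C++ loss: 0 = differentiated
  ifelse(as.character(label) == "differentiated", 0L, 1L)
}

#' Train the classifier for one round
#'
#' Minibatch Adam on the weighted softmax cross-entropy. The training log
#' records the mean loss of every epoch.
#'
#' @param model classifier from [build_model()] (or an earlier round).
#' @param patches a `PatchSet` containing both classes.
#' @param hyper a [train_hyper()].
#' @param round_seed seed for shuffling in this round (defaults to
#'   `hyper$seed`).
#' @return the fitted classifier; `model$log` gains one entry with per-epoch
#'   losses and the class counts seen.
#' @export
train_round <- function(model, patches, hyper = train_hyper(),
                        round_seed = hyper$seed) {
  y <- patch_labels_int(patches$label)
  n <- length(y)
  if (length(unique(y)) < 2)
    stopf("training patches must contain both classes")
  cw <- if (hyper$class_weighting) {
    tab <- c(sum(y == 0L), sum(y == 1L))
    n / (2 * tab)
  } else c(1, 1)

  xs <- standardize_patches(patches$x)
  w <- model$weights
  pn <- c("W1", "b1", "W2", "b2", "W3", "b3")
  mom <- lapply(w[pn], function(z) z * 0)
  vel <- lapply(w[pn], function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  losses <- numeric(hyper$epochs)

  with_seed(round_seed, {
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      bl <- c()
      for (s in seq(1, n, by = hyper$batch_size)) {
        idx <- ord[s:min(s + hyper$batch_size - 1, n)]
        g <- cnn_grad_cpp(xs[, , idx, drop = FALSE], y[idx], w, cw)
        if (!is.finite(g$loss))
          stopf("non-finite loss at epoch %d (lr too high or degenerate data)", ep)
        t <- t + 1L
        for (p in pn) {
          gp <- g[[paste0("g", p)]]
          mom[[p]] <- beta1 * mom[[p]] + (1 - beta1) * gp
          vel[[p]] <- beta2 * vel[[p]] + (1 - beta2) * gp^2
          mhat <- mom[[p]] / (1 - beta1^t)
          vhat <- vel[[p]] / (1 - beta2^t)
          w[[p]] <- w[[p]] - hyper$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        bl <- c(bl, g$loss)
      }
      losses[ep] <- mean(bl)
    }
  })
  model$weights <- w
  model$trained <- TRUE
  model$log <- c(model$log, list(list(
    epoch_loss = losses,
    n_patches = n,
    class_counts = c(differentiated = sum(y == 0L),
                     undifferentiated = sum(y == 1L)),
    hyper = unclass(hyper), round_seed = round_seed)))
  model
}

#' Collect hard examples: undifferentiated patches the model calls differentiated
#'
#' Applies the current model to non-overlapping grid patches of the given
#' frames and returns exactly the undifferentiated-labeled patches whose
#' predicted differentiated probability is 0.5 or more. An empty result is
#' legitimate (a perfect model mines nothing).
#'
#' @param model a trained classifier.
#' @param fields list of `list(phase = ImageFrame, mask = LabelMask)` pairs.
#' @param purity_threshold patch purity filter passed to [extract_patches()].
#' @return a `PatchSet` (possibly with zero patches).
#' @export
mine_hard_examples <- function(model, fields, purity_threshold = 0.8) {
  p <- model$arch$input_px
  mined <- NULL
  for (f in fields) {
    ps <- extract_patches(f$phase, f$mask, patch_px = p,
                          policy = "grid_nonoverlap",
                          purity_threshold = purity_threshold)
    und <- which(ps$label == "undifferentiated")
    if (!length(und)) next
    sub <- subset_patch_set(ps, und)
    pr <- predict_patches(model, sub)
    hard <- which(pr[, "differentiated"] >= 0.5)
    if (!length(hard)) next
    sel <- subset_patch_set(sub, hard)
    mined <- if (is.null(mined)) sel else combine_patch_sets(mined, sel)
  }
  if (is.null(mined))
    mined <- structure(list(x = array(0, c(p, p, 0)),
                            label = factor(character(),
                                           levels = c("differentiated",
                                                      "undifferentiated")),
                            origin = data.frame(row = integer(), col = integer()),
                            patch_px = p), class = "PatchSet")
  mined
}

#' Two-round training with hard-example mining
#'
#' Round 1 trains on randomly cropped patches; the trained model is then
#' applied back to the frames, the undifferentiated patches it misclassifies
#' as differentiated are added to the training set, and training continues
#' from the round-1 weights (fine-tuning, the package's reading of "trained
#' again"). The returned classifier carries both rounds in its log and keeps
#' the round-1 model for paired comparisons.
#'
#' @param fields list of `list(phase, mask)` training fields.
#' @param arch a [cnn_arch()].
#' @param hyper a [train_hyper()]; `hyper$seed` drives init, cropping and both
#'   rounds deterministically.
#' @param n_random_per_field random crops drawn from each field for round 1.
#' @param purity_threshold patch purity filter.
#' @return the round-2 `cnn_classifier`, with `$round1` (round-1 model) and
#'   `$mined_n` (number of hard examples added) attached.
#' @export
train_with_mining <- function(fields, arch = cnn_arch(),
                              hyper = train_hyper(),
                              n_random_per_field = 250L,
                              purity_threshold = 0.8) {
  train_ps <- NULL
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    ps <- extract_patches(f$phase, f$mask, patch_px = arch$input_px,
                          policy = "random", n_random = n_random_per_field,
                          purity_threshold = purity_threshold,
                          seed = derive_seed(hyper$seed, paste0("crop", k)))
    train_ps <- if (is.null(train_ps)) ps else combine_patch_sets(train_ps, ps)
  }
  m0 <- build_model(arch, seed = derive_seed(hyper$seed, "init"))
  m1 <- train_round(m0, train_ps, hyper,
                    round_seed = derive_seed(hyper$seed, "round1"))
  mined <- mine_hard_examples(m1, fields, purity_threshold)
  aug <- combine_patch_sets(train_ps, mined)
  m2 <- train_round(m1, aug, hyper,
                    round_seed = derive_seed(hyper$seed, "round2"))
  m2$round1 <- m1
  m2$mined_n <- dim(mined$x)[3]
  m2
}

#' Per-pixel differentiated-probability map from a phase-contrast frame
#'
#' The frame is tiled by `input_px` windows at the given stride; each
#' window's differentiated probability is written to every pixel it covers,
#' overlapping windows are averaged, and uncovered right/bottom margins take
#' the value of the nearest covered pixel. `stride_px = 70` (the default)
#' reproduces block-wise non-overlapping assignment.
#'
#' @param model trained classifier.
#' @param phase a phase-channel [image_frame()] (inference never sees
#'   fluorescence).
#' @param stride_px window stride in pixels; smaller values give smoother maps
#'   at proportionally higher cost.
#' @return a `ProbabilityMap`: list with `probs` (matrix in `[0,1]`, same
#'   geometry as the frame) and `pixel_size_um`.
#' @export
predict_map <- function(model, phase, stride_px = 70L) {
  if (phase$channel != "phase")
    stopf("probability maps are computed from the phase channel only")
  p <- model$arch$input_px
  px <- phase$pixels
  h <- nrow(px); w <- ncol(px)
  if (h < p || w < p) stopf("frame smaller than one %d px patch", p)
  r0 <- seq(1L, h - p + 1L, by = stride_px)
  c0 <- seq(1L, w - p + 1L, by = stride_px)
  wins <- expand.grid(row = r0, col = c0)
  x <- array(0, c(p, p, nrow(wins)))
  for (k in seq_len(nrow(wins)))
    x[, , k] <- px[wins$row[k]:(wins$row[k] + p - 1L),
                   wins$col[k]:(wins$col[k] + p - 1L)]
  pr <- predict_patches(model, x)[, "differentiated"]
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (k in seq_len(nrow(wins))) {
    ri <- wins$row[k]:(wins$row[k] + p - 1L)
    ci <- wins$col[k]:(wins$col[k] + p - 1L)
    acc[ri, ci] <- acc[ri, ci] + pr[k]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  probs <- acc / pmax(cnt, 1)
  # fill uncovered margins from the nearest covered row/column
  lastr <- max(r0) + p - 1L; lastc <- max(c0) + p - 1L
  if (lastr < h) probs[(lastr + 1L):h, ] <- probs[rep(lastr, h - lastr), ]
  if (lastc < w) probs[, (lastc + 1L):w] <- probs[, rep(lastc, w - lastc)]
  structure(list(probs = probs, pixel_size_um = phase$pixel_size_um),
            class = "ProbabilityMap")
}

#' @export
print.ProbabilityMap <- function(x, ...) {
  cat(sprintf("ProbabilityMap %d x %d px, %.3g um/px, P(diff) in [%.3f, %.3f]\n",
              nrow(x$probs), ncol(x$probs), x$pixel_size_um,
              min(x$probs), max(x$probs)))
  invisible(x)
}

#' Save / load a classifier checkpoint
#'
#' The weights are serialised as RDS next to a plain-text JSON sidecar
#' recording the architecture, training log and seeds.
#'
#' @param model a `cnn_classifier`; `path` the `.rds` checkpoint path.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  side <- list(arch = unclass(model$arch)[setdiff(names(unclass(model$arch)), "shape")],
               shape = model$arch$shape,
               trained = model$trained, init_seed = model$init_seed,
               log = model$log, mined_n = model$mined_n)
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cnn_classifier")) stopf("not a classifier checkpoint")
  m
}
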
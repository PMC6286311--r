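# shared fixtures: reduced-size fields keep the unit tests fast; the
# full-geometry study conditions are exercised in test-acceptance.R.

small_sim_params <- function(seed = 1L, ...) {
  args <- list(field_width_px = 700L, field_height_px = 500L,
               n_colonies = 3L, colony_radius_um = c(90, 140),
               differentiated_fraction = 0.2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(colony_sim_params, args)
}

small_fields <- function(seeds) {
  lapply(seeds, function(s) {
    f <- generate_field(small_sim_params(seed = s))
    list(phase = f$phase, mask = f$mask, cells = f$cells, fluor = f$fluor)
  })
}

# brute-force forward pass of the full architecture, written independently of
# the C++ path (plain nested loops); the oracle for forward equivalence.
ref_forward <- function(x, w, arch) {
  conv <- function(img, W, b, k) {
    C <- dim(img)[3]
    oh <- dim(img)[1] - k + 1; ow <- dim(img)[2] - k + 1
    out <- array(0, c(oh, ow, nrow(W)))
    for (f in seq_len(nrow(W))) {
      ker <- array(W[f, ], c(k, k, C))
      for (i in seq_len(oh)) for (j in seq_len(ow))
        out[i, j, f] <- sum(img[i:(i + k - 1), j:(j + k - 1), , drop = FALSE] * ker) + b[f]
    }
    out
  }
  pool <- function(a, k) {
    oh <- floor(dim(a)[1] / k); ow <- floor(dim(a)[2] / k)
    out <- array(0, c(oh, ow, dim(a)[3]))
    for (f in seq_len(dim(a)[3])) for (i in seq_len(oh)) for (j in seq_len(ow))
      out[i, j, f] <- max(a[((i - 1) * k + 1):(i * k),
                            ((j - 1) * k + 1):(j * k), f])
    out
  }
  p1 <- pool(pmax(conv(array(x, c(dim(x), 1)), w$W1, w$b1, arch$conv1_kernel), 0),
             arch$pool1)
  p2 <- pool(pmax(conv(p1, w$W2, w$b2, arch$conv2_kernel), 0), arch$pool2)
  z <- as.vector(w$W3 %*% as.vector(p2) + w$b3)
  e <- exp(z - max(z))
  e / sum(e)
}

on_length_um <- function(path) {
  sum(vapply(path$on, function(m) if (nrow(m)) sum(m[, 2] - m[, 1]) else 0,
             numeric(1)))
}
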
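## colony_sim: seedable synthetic hiPSC culture fields with ground truth.
##
## A field is a pair of 16-bit-range rasters (phase contrast + rBC2LCN-style
## fluorescence), a per-pixel label mask {0 = background, 1 = undifferentiated,
## 2 = differentiated} and a matched point-cell population. Colonies are
## rendered as wobbled discs; spontaneously differentiated sub-regions are
## contiguous patches inside a colony whose phase texture is coarser and of
## lower local contrast than the fine-grained undifferentiated texture, which
## is what gives a patch classifier a learnable morphological signal.
## Coordinate convention (shared by all modules): origin at the top-left pixel
## center, x rightward along columns, y downward along rows, physical position
## in micrometers = pixel index * pixel_size_um.

#' Parameters of the synthetic colony field generator
#'
#' @param field_width_px,field_height_px frame geometry in pixels; the default
#'   1920 x 1200 matches the native camera geometry of whole-dish tiling
#'   devices for adherent culture.
#' @param pixel_size_um physical pixel pitch in micrometers per pixel. The
#'   instrument magnification is not fixed by the model, so this is an
#'   explicit parameter; the default 1 um/px makes a frame about 1.9 x 1.2 mm.
#' @param n_colonies number of colonies placed in the field.
#' @param colony_radius_um length-2 range from which colony radii are drawn
#'   uniformly (micrometers).
#' @param differentiated_fraction expected fraction of each colony's area
#'   occupied by a contiguous differentiated patch, in `[0, 1]`.
#' @param texture_noise_sd standard deviation of additive sensor noise
#'   (intensity counts) applied to both channels.
#' @param fluor_pos_level,fluor_neg_level mean fluorescence intensity of
#'   undifferentiated (probe-positive) pixels and of differentiated /
#'   background pixels.
#' @param cell_diameter_um nominal cell diameter, default 10 um.
#' @param cell_density_per_um2 areal density of cells inside colony
#'   footprints (cells per square micrometer).
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return an object of class `ColonySimParams`.
#' @export
colony_sim_params <- function(field_width_px = 1920L,
                              field_height_px = 1200L,
                              pixel_size_um = 1,
                              n_colonies = 6L,
                              colony_radius_um = c(150, 280),
                              differentiated_fraction = 0.2,
                              texture_noise_sd = 300,
                              fluor_pos_level = 30000,
                              fluor_neg_level = 3000,
                              cell_diameter_um = 10,
                              cell_density_per_um2 = 0.005,
                              seed = 1L) {
  p <- list(field_width_px = as.integer(field_width_px),
            field_height_px = as.integer(field_height_px),
            pixel_size_um = pixel_size_um,
            n_colonies = as.integer(n_colonies),
            colony_radius_um = as.numeric(colony_radius_um),
            differentiated_fraction = differentiated_fraction,
            texture_noise_sd = texture_noise_sd,
            fluor_pos_level = fluor_pos_level,
            fluor_neg_level = fluor_neg_level,
            cell_diameter_um = cell_diameter_um,
            cell_density_per_um2 = cell_density_per_um2,
            seed = as.integer(seed))
  class(p) <- "ColonySimParams"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (!is_count(p$field_width_px) || !is_count(p$field_height_px))
    stopf("field dimensions must be positive integers")
  if (!is_scalar(p$pixel_size_um) || p$pixel_size_um <= 0)
    stopf("pixel_size_um must be a positive number")
  if (!is_count(p$n_colonies)) stopf("n_colonies must be a positive integer")
  if (length(p$colony_radius_um) != 2 || any(p$colony_radius_um <= 0) ||
      p$colony_radius_um[1] > p$colony_radius_um[2])
    stopf("colony_radius_um must be an increasing positive range")
  if (!is_scalar(p$differentiated_fraction) ||
      p$differentiated_fraction < 0 || p$differentiated_fraction > 1)
    stopf("differentiated_fraction must lie in [0, 1]")
  if (!is_scalar(p$texture_noise_sd) || p$texture_noise_sd < 0)
    stopf("texture_noise_sd must be nonnegative")
  for (f in c("fluor_pos_level", "fluor_neg_level"))
    if (!is_scalar(p[[f]]) || p[[f]] < 0 || p[[f]] > 65535)
      stopf("%s must lie within the 16-bit intensity range", f)
  if (!is_scalar(p$cell_diameter_um) || p$cell_diameter_um <= 0)
    stopf("cell_diameter_um must be positive")
  if (!is_scalar(p$cell_density_per_um2) || p$cell_density_per_um2 <= 0)
    stopf("cell_density_per_um2 must be positive")
  invisible(p)
}

#' Construct an image frame
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param channel `"phase"` or `"fluorescence"`.
#' @param pixel_size_um physical pixel pitch, micrometers.
#' @return an `ImageFrame` object.
#' @export
image_frame <- function(pixels, channel = c("phase", "fluorescence"),
                        pixel_size_um = 1) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !all(is.finite(pixels)) || any(pixels < 0))
    stopf("pixels must be a finite nonnegative matrix")
  structure(list(pixels = pixels, channel = channel,
                 pixel_size_um = pixel_size_um),
            class = "ImageFrame")
}

#' @export
print.ImageFrame <- function(x, ...) {
  cat(sprintf("ImageFrame [%s] %d x %d px, %.3g um/px, range [%.0f, %.0f]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a label mask
#'
#' @param labels integer matrix with values 0 (background),
#'   1 (undifferentiated), 2 (differentiated).
#' @param pixel_size_um physical pixel pitch, micrometers.
#' @return a `LabelMask` object.
#' @export
label_mask <- function(labels, pixel_size_um = 1) {
  if (!is.matrix(labels) || !all(labels %in% 0:2))
    stopf("labels must be a matrix over {0, 1, 2}")
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "LabelMask")
}

# zero-mean Gaussian-filtered noise with exact target sd (texture primitive)
filtered_noise <- function(h, w, sigma, sd_target) {
  m <- matrix(rnorm(h * w), h, w)
  if (sigma > 0) m <- EBImage::gblur(m, sigma = sigma)
  m <- m - mean(m)
  m * (sd_target / stats::sd(as.vector(m)))
}

# wobbled-disc radius: smooth low-order angular modulation of a base radius
wobble_radius <- function(theta, R, amp, phase3, phase5) {
  R * (1 + amp[1] * sin(3 * theta + phase3) + amp[2] * sin(5 * theta + phase5))
}

#' Generate a synthetic culture field
#'
#' Renders one phase-contrast frame, one fluorescence frame, the ground-truth
#' label mask and a matched cell population. Fluorescence is high exactly on
#' undifferentiated colony pixels (the probe-positive class) and low on
#' differentiated and background pixels. Cells are Poisson-sampled inside
#' colony footprints with their type read off the mask at the cell center.
#'
#' @param params a [colony_sim_params()] object.
#' @return list with elements `phase`, `fluor` ([image_frame()]s), `mask`
#'   ([label_mask()]) and `cells` (data.frame with columns
#'   `x_um, y_um, diameter_um, type, alive`).
#' @export
generate_field <- function(params) {
  validate_sim_params(params)
  p <- params
  h <- p$field_height_px; w <- p$field_width_px; ps <- p$pixel_size_um
  with_seed(p$seed, {
    ## colony geometry ---------------------------------------------------
    Rmin <- p$colony_radius_um[1]; Rmax <- p$colony_radius_um[2]
    W_um <- (w - 1) * ps; H_um <- (h - 1) * ps
    # Colonies are kept strictly disjoint (overlap would corrupt the
    # ground-truth area accounting): radii are drawn first, then centers are
    # rejection-sampled against the realised pairwise separations; a colony
    # that cannot be placed is shrunk and retried.
    R <- sort(runif(p$n_colonies, Rmin, Rmax), decreasing = TRUE)
    cx <- cy <- numeric(p$n_colonies)
    for (k in seq_len(p$n_colonies)) {
      repeat {
        placed <- FALSE
        mg <- R[k] * 1.15
        for (try in seq_len(2000)) {
          nx <- runif(1, min(mg, W_um / 2), max(W_um - mg, W_um / 2))
          ny <- runif(1, min(mg, H_um / 2), max(H_um - mg, H_um / 2))
          if (k == 1 || all(sqrt((cx[seq_len(k - 1)] - nx)^2 +
                                 (cy[seq_len(k - 1)] - ny)^2) >=
                            1.18 * (R[seq_len(k - 1)] + R[k]))) {
            cx[k] <- nx; cy[k] <- ny; placed <- TRUE; break
          }
        }
        if (placed) break
        R[k] <- R[k] * 0.85
        if (R[k] < 20) { cx[k] <- W_um / 2; cy[k] <- H_um / 2; break }
      }
    }
    amp <- matrix(runif(2 * p$n_colonies, 0.02, 0.06), ncol = 2)
    ph3 <- runif(p$n_colonies, 0, 2 * pi); ph5 <- runif(p$n_colonies, 0, 2 * pi)
    f <- p$differentiated_fraction
    rd <- R * sqrt(f)
    dphi <- runif(p$n_colonies, 0, 2 * pi)
    dmax <- pmax(0, 0.85 * R - rd)
    du <- runif(p$n_colonies, 0, 1) * dmax
    dx0 <- cx + du * cos(dphi); dy0 <- cy + du * sin(dphi)
    damp <- matrix(runif(2 * p$n_colonies, 0.01, 0.04), ncol = 2)
    dph3 <- runif(p$n_colonies, 0, 2 * pi); dph5 <- runif(p$n_colonies, 0, 2 * pi)

    labels <- matrix(0L, h, w)
    ring <- matrix(FALSE, h, w)
    xs <- (seq_len(w) - 1) * ps; ys <- (seq_len(h) - 1) * ps
    for (k in seq_len(p$n_colonies)) {
      rmaxk <- R[k] * 1.1
      jr <- which(xs >= cx[k] - rmaxk & xs <= cx[k] + rmaxk)
      ir <- which(ys >= cy[k] - rmaxk & ys <= cy[k] + rmaxk)
      if (!length(jr) || !length(ir)) next
      dxg <- matrix(xs[jr] - cx[k], length(ir), length(jr), byrow = TRUE)
      dyg <- matrix(ys[ir] - cy[k], length(ir), length(jr))
      rr <- sqrt(dxg^2 + dyg^2)
      th <- atan2(dyg, dxg)
      rw <- wobble_radius(th, R[k], amp[k, ], ph3[k], ph5[k])
      inside <- rr <= rw
      sub <- labels[ir, jr]
      sub[inside & sub == 0L] <- 1L   # never erase an earlier colony's patch
      if (f > 0 && rd[k] > 0) {
        ddx <- dxg - (dx0[k] - cx[k]); ddy <- dyg - (dy0[k] - cy[k])
        rr2 <- sqrt(ddx^2 + ddy^2)
        th2 <- atan2(ddy, ddx)
        rw2 <- wobble_radius(th2, rd[k], damp[k, ], dph3[k], dph5[k])
        sub[inside & rr2 <= rw2] <- 2L
      }
      labels[ir, jr] <- sub
      ring[ir, jr] <- ring[ir, jr] | (inside & rr > rw - 3 * ps)
    }

    ## phase channel ------------------------------------------------------
    # undifferentiated: fine-grained, high local contrast; differentiated:
    # coarser granularity, lower contrast; colony rim gets a bright halo as in
    # phase-contrast optics.
    bg_tex <- filtered_noise(h, w, 1.5, 400)
    fine <- filtered_noise(h, w, 0.8, 4500)
    coarse <- filtered_noise(h, w, 3.5, 2200)
    phase <- 3000 + bg_tex
    und <- labels == 1L; dif <- labels == 2L
    phase[und] <- 18000 + fine[und]
    phase[dif] <- 21000 + coarse[dif]
    phase[ring] <- phase[ring] + 12000
    phase <- phase + rnorm(h * w, sd = p$texture_noise_sd)
    phase <- clamp(phase, 0, 65535)

    ## fluorescence channel ----------------------------------------------
    fluor <- matrix(p$fluor_neg_level, h, w)
    fluor[und] <- p$fluor_pos_level
    fluor <- fluor + rnorm(h * w, sd = p$texture_noise_sd)
    fluor <- clamp(fluor, 0, 65535)

    ## cell population ----------------------------------------------------
    cells <- vector("list", p$n_colonies)
    for (k in seq_len(p$n_colonies)) {
      n <- rpois(1, pi * R[k]^2 * p$cell_density_per_um2)
      if (n == 0) { cells[[k]] <- NULL; next }
      # oversample in the enclosing disc, keep points inside the footprint
      m <- ceiling(n * 1.5) + 20
      rr <- R[k] * 1.08 * sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
      x <- cx[k] + rr * cos(th); y <- cy[k] + rr * sin(th)
      rw <- wobble_radius(th, R[k], amp[k, ], ph3[k], ph5[k])
      keep <- rr <= rw & x >= 0 & x <= W_um & y >= 0 & y <= H_um
      x <- x[keep][seq_len(min(n, sum(keep)))]
      y <- y[keep][seq_len(min(n, sum(keep)))]
      if (!length(x)) { cells[[k]] <- NULL; next }
      i <- clamp(round(y / ps) + 1, 1, h); j <- clamp(round(x / ps) + 1, 1, w)
      lab <- labels[cbind(i, j)]
      ok <- lab > 0L
      cells[[k]] <- data.frame(
        x_um = x[ok], y_um = y[ok], diameter_um = p$cell_diameter_um,
        type = c("undifferentiated", "differentiated")[lab[ok]],
        alive = TRUE, stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, cells)
    if (is.null(cells))
      cells <- data.frame(x_um = numeric(), y_um = numeric(),
                          diameter_um = numeric(), type = character(),
                          alive = logical(), stringsAsFactors = FALSE)
    rownames(cells) <- NULL

    list(phase = image_frame(phase, "phase", ps),
         fluor = image_frame(fluor, "fluorescence", ps),
         mask = label_mask(labels, ps),
         cells = cells)
  })
}

#' Crop labeled training patches from a frame
#'
#' Cuts `patch_px` x `patch_px` crops from the frame and labels each by the
#' majority class of its mask pixels. A patch is discarded when the majority
#' class covers less than `purity_threshold` of its pixels, which drops both
#' mixed boundary patches and background-dominated patches.
#'
#' @param frame an [image_frame()] (the phase channel for training).
#' @param mask the matching [label_mask()].
#' @param patch_px patch edge length in pixels (default 70).
#' @param policy `"grid_nonoverlap"` tiles the frame with
#'   `floor(W/patch_px) * floor(H/patch_px)` disjoint crops; `"random"` draws
#'   `n_random` uniformly placed (possibly overlapping) crops.
#' @param n_random number of crops under the random policy.
#' @param purity_threshold minimum fraction of patch pixels the majority
#'   class must cover for the patch to be kept (default 0.8).
#' @param seed seed for the random policy.
#' @param background_policy `"exclude"` (default) labels by the majority of
#'   non-background pixels and counts background against purity;
#'   `"undifferentiated"` folds background into the undifferentiated class,
#'   useful for whole-frame inference robustness.
#' @return a `PatchSet`: list with `x` (patch_px x patch_px x n array),
#'   `label` (factor, levels `differentiated`, `undifferentiated`) and
#'   `origin` (data.frame of top-left row/col indices, 1-based).
#' @export
extract_patches <- function(frame, mask, patch_px = 70L,
                            policy = c("grid_nonoverlap", "random"),
                            n_random = 500L, purity_threshold = 0.8,
                            seed = 1L,
                            background_policy = c("exclude", "undifferentiated")) {
  policy <- match.arg(policy)
  background_policy <- match.arg(background_policy)
  px <- frame$pixels; lab <- mask$labels
  if (!identical(dim(px), dim(lab)))
    stopf("frame and mask geometries differ")
  h <- nrow(px); w <- ncol(px); p <- as.integer(patch_px)
  if (p > h || p > w) stopf("patch_px (%d) exceeds frame dimensions", p)
  if (purity_threshold < 0 || purity_threshold > 1)
    stopf("purity_threshold must lie in [0, 1]")

  if (policy == "grid_nonoverlap") {
    r0 <- seq(1L, h - p + 1L, by = p)
    c0 <- seq(1L, w - p + 1L, by = p)
    origin <- expand.grid(row = r0, col = c0)
  } else {
    origin <- with_seed(seed, data.frame(
      row = sample.int(h - p + 1L, n_random, replace = TRUE),
      col = sample.int(w - p + 1L, n_random, replace = TRUE)))
  }

  lab2 <- lab
  if (background_policy == "undifferentiated") lab2[lab2 == 0L] <- 1L

  n <- nrow(origin)
  keep <- logical(n); plab <- integer(n)
  tot <- p * p
  for (k in seq_len(n)) {
    i <- origin$row[k]; j <- origin$col[k]
    sub <- lab2[i:(i + p - 1L), j:(j + p - 1L)]
    n1 <- sum(sub == 1L); n2 <- sum(sub == 2L)
    if (n1 + n2 == 0L) next
    maj <- if (n2 > n1) 2L else 1L
    if (max(n1, n2) / tot >= purity_threshold) { keep[k] <- TRUE; plab[k] <- maj }
  }
  if (!any(keep)) stopf("no patch passed the purity filter")
  idx <- which(keep)
  x <- array(0, dim = c(p, p, length(idx)))
  for (q in seq_along(idx)) {
    i <- origin$row[idx[q]]; j <- origin$col[idx[q]]
    x[, , q] <- px[i:(i + p - 1L), j:(j + p - 1L)]
  }
  structure(list(
    x = x,
    label = factor(c("undifferentiated", "differentiated")[ifelse(plab[idx] == 2L, 2L, 1L)],
                   levels = c("differentiated", "undifferentiated")),
    origin = origin[idx, , drop = FALSE],
    patch_px = p), class = "PatchSet")
}

#' @export
print.PatchSet <- function(x, ...) {
  cat(sprintf("PatchSet: %d patches of %d x %d px (%s)\n",
              dim(x$x)[3], x$patch_px, x$patch_px,
              paste(sprintf("%s: %d", levels(x$label), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

combine_patch_sets <- function(a, b) {
  if (is.null(b) || dim(b$x)[3] == 0) return(a)
  stopifnot(a$patch_px == b$patch_px)
  structure(list(
    x = array(c(a$x, b$x), dim = c(a$patch_px, a$patch_px,
                                   dim(a$x)[3] + dim(b$x)[3])),
    label = factor(c(as.character(a$label), as.character(b$label)),
                   levels = levels(a$label)),
    origin = rbind(a$origin, b$origin),
    patch_px = a$patch_px), class = "PatchSet")
}

subset_patch_set <- function(ps, idx) {
  structure(list(x = ps$x[, , idx, drop = FALSE],
                 label = ps$label[idx],
                 origin = ps$origin[idx, , drop = FALSE],
                 patch_px = ps$patch_px), class = "PatchSet")
}

## ---- raster / tabular IO ---------------------------------------------------

#' Write / read image frames as 16-bit grayscale TIFF (or PNG)
#'
#' @param frame an [image_frame()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`). TIFF carries the full 16-bit range; PNG is written 8-bit.
#' @export
write_frame <- function(frame, path) {
  m <- clamp(frame$pixels / 65535, 0, 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stopf("unsupported image extension '%s'", ext)
  invisible(path)
}

#' @rdname write_frame
#' @param channel,pixel_size_um frame metadata to attach on read.
#' @export
read_frame <- function(path, channel = "phase", pixel_size_um = 1) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
       if (ext == "png") png::readPNG(path) else
       stopf("unsupported image extension '%s'", ext)
  if (length(dim(m)) == 3) m <- m[, , 1]
  image_frame(round(m * 65535), channel, pixel_size_um)
}

#' Write / read label masks as 8-bit PNG (palette 0/1/2)
#' @param mask a [label_mask()]; `path` the PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @param pixel_size_um pixel pitch to attach on read.
#' @export
read_mask <- function(path, pixel_size_um = 1) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_mask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
             pixel_size_um)
}

#' Write / read cell populations as CSV
#' @param cells a cell population data.frame; `path` the CSV path.
#' @export
write_cells <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "diameter_um", "type", "alive")
  if (!all(need %in% names(d))) stopf("cell CSV lacks required columns")
  d$alive <- as.logical(d$alive)
  d
}
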
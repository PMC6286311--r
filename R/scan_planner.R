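## scan_planner: beam parameters, scan-path geometry, ON/OFF gating and
## dose / energy / time accounting.
##
## Physical model: a beam of power P [W] scanned at v [mm/s] deposits
## P / v joules per mm of line; spread over the beam width w the areal energy
## flux is P / (v w) [J/mm^2]. Gating switches the beam ON only while its
## center is over target pixels. All coordinates are micrometers in the shared
## top-left-origin convention; arc length along a segment is micrometers from
## the segment start.

#' Laser beam parameters
#'
#' @param power_W beam power P in watts.
#' @param speed_mm_s scan speed v in mm per second.
#' @param beam_width_um effective beam width w (default 50 um).
#' @param line_interval_um spacing between adjacent scan lines (450 um for
#'   colony sectioning, 25 um for full-coverage purification).
#' @return a `LaserParams` object.
#' @export
laser_params <- function(power_W = 0.8, speed_mm_s = 100, beam_width_um = 50,
                         line_interval_um = 25) {
  if (!is_scalar(power_W) || power_W < 0) stopf("power_W must be nonnegative")
  if (!is_scalar(speed_mm_s) || speed_mm_s <= 0) stopf("speed_mm_s must be positive")
  if (!is_scalar(beam_width_um) || beam_width_um <= 0) stopf("beam_width_um must be positive")
  if (!is_scalar(line_interval_um) || line_interval_um <= 0)
    stopf("line_interval_um must be positive")
  structure(list(power_W = power_W, speed_mm_s = speed_mm_s,
                 beam_width_um = beam_width_um,
                 line_interval_um = line_interval_um), class = "LaserParams")
}

#' Energy deposited per unit line length
#'
#' @param power_W beam power P (W).
#' @param speed_mm_s scan speed v (mm/s).
#' @return P / v in joules per mm.
#' @export
dose_per_length <- function(power_W, speed_mm_s) {
  if (!is_scalar(speed_mm_s) || speed_mm_s <= 0) stopf("speed must be positive")
  if (!is_scalar(power_W) || power_W < 0) stopf("power must be nonnegative")
  power_W / speed_mm_s
}

#' Areal energy flux under the beam
#'
#' @inheritParams dose_per_length
#' @param beam_width_um beam width w (um).
#' @return P / (v w) in joules per mm^2.
#' @export
energy_flux <- function(power_W, speed_mm_s, beam_width_um = 50) {
  if (!is_scalar(beam_width_um) || beam_width_um <= 0)
    stopf("beam width must be positive")
  dose_per_length(power_W, speed_mm_s) / (beam_width_um / 1000)
}

#' Cell throughput of a linear scan
#'
#' Cells traversed per second along the scan line, assuming a nominal cell
#' diameter.
#'
#' @param speed_mm_s scan speed (mm/s).
#' @param cell_diameter_um nominal cell diameter (default 10 um).
#' @return cells per second, `speed_um_s / cell_diameter_um`.
#' @export
throughput <- function(speed_mm_s, cell_diameter_um = 10) {
  if (!is_scalar(speed_mm_s) || speed_mm_s <= 0) stopf("speed must be positive")
  if (!is_scalar(cell_diameter_um) || cell_diameter_um <= 0)
    stopf("cell diameter must be positive")
  speed_mm_s * 1000 / cell_diameter_um
}

## ---- regions ---------------------------------------------------------------

#' Scan regions
#'
#' `region_circle()` is a disc (the dish); `region_rect()` an axis-aligned
#' rectangle (e.g. one camera field); `dish_region()` a disc whose area
#' matches the effective scannable surface of a culture dish (default
#' 9 cm^2 for a 35 mm dish).
#'
#' @param radius_um,center_um disc radius and center (um).
#' @return a `ScanRegion` object.
#' @export
region_circle <- function(radius_um, center_um = c(0, 0)) {
  if (!is_scalar(radius_um) || radius_um <= 0) stopf("radius must be positive")
  structure(list(kind = "circle", radius_um = radius_um,
                 center_um = as.numeric(center_um)), class = "ScanRegion")
}

#' @rdname region_circle
#' @param x0_um,y0_um,width_um,height_um rectangle origin and extent (um).
#' @export
region_rect <- function(x0_um = 0, y0_um = 0, width_um, height_um) {
  if (width_um <= 0 || height_um <= 0) stopf("region extent must be positive")
  structure(list(kind = "rect", x0_um = x0_um, y0_um = y0_um,
                 width_um = width_um, height_um = height_um),
            class = "ScanRegion")
}

#' @rdname region_circle
#' @param area_cm2 effective scannable dish area (cm^2).
#' @export
dish_region <- function(area_cm2 = 9) {
  if (!is_scalar(area_cm2) || area_cm2 <= 0) stopf("area must be positive")
  region_circle(sqrt(area_cm2 * 1e8 / pi))
}

#' @rdname region_circle
#' @param frame an [image_frame()] whose pixel-center extent becomes the
#'   region.
#' @export
frame_region <- function(frame) {
  ps <- frame$pixel_size_um
  region_rect(0, 0, (ncol(frame$pixels) - 1) * ps, (nrow(frame$pixels) - 1) * ps)
}

## ---- path construction -----------------------------------------------------

new_scan_path <- function(segments, laser, turnaround_s = 0, gated = FALSE,
                          threshold = NA_real_) {
  segments$length_um <- sqrt((segments$x1 - segments$x0)^2 +
                             (segments$y1 - segments$y0)^2)
  on <- lapply(segments$length_um, function(L) matrix(c(0, L), 1, 2))
  structure(list(segments = segments, on = on, laser = laser,
                 turnaround_s = turnaround_s, gated = gated,
                 threshold = threshold), class = "ScanPath")
}

#' @export
print.ScanPath <- function(x, ...) {
  st <- path_stats(x)
  cat(sprintf(
    "ScanPath: %d segments, %.1f mm total, %.1f mm ON (%s), %.2f W @ %.0f mm/s\n",
    nrow(x$segments), sum(x$segments$length_um) / 1000, st$active_length_mm,
    if (x$gated) sprintf("gated at %.2f", x$threshold) else "ungated",
    x$laser$power_W, x$laser$speed_mm_s))
  invisible(x)
}

# line family covering a region at a given spacing; horizontal lines are
# y = const, vertical lines x = const; circles are clipped to chords.
line_family <- function(region, interval, orientation = c("h", "v")) {
  orientation <- match.arg(orientation)
  if (region$kind == "rect") {
    if (orientation == "h") {
      ys <- region$y0_um + seq(0, region$height_um, by = interval)
      data.frame(x0 = region$x0_um, y0 = ys,
                 x1 = region$x0_um + region$width_um, y1 = ys)
    } else {
      xs <- region$x0_um + seq(0, region$width_um, by = interval)
      data.frame(x0 = xs, y0 = region$y0_um,
                 x1 = xs, y1 = region$y0_um + region$height_um)
    }
  } else {
    R <- region$radius_um; cx <- region$center_um[1]; cy <- region$center_um[2]
    off <- seq(-R, R, by = interval)
    half <- sqrt(pmax(R^2 - off^2, 0))
    keep <- half > 0
    off <- off[keep]; half <- half[keep]
    if (!length(off)) stopf("interval larger than region: no chords")
    if (orientation == "h")
      data.frame(x0 = cx - half, y0 = cy + off, x1 = cx + half, y1 = cy + off)
    else
      data.frame(x0 = cx + off, y0 = cy - half, x1 = cx + off, y1 = cy + half)
  }
}

serpentine <- function(seg) {
  flip <- seq_len(nrow(seg)) %% 2 == 0
  tmp <- seg[flip, ]
  seg[flip, c("x0", "y0", "x1", "y1")] <- tmp[, c("x1", "y1", "x0", "y0")]
  seg
}

#' Plan a scan pattern over a region
#'
#' Pattern kinds: `raster` (one family of parallel lines at the laser's line
#' interval), `lattice` (two orthogonal families, the sectioning pattern),
#' `rectangle` / `circle` (outline only), `line` (one segment through the
#' region center). Lines are clipped to the region boundary, so a circular
#' dish produces chords. Raster/lattice lines are ordered serpentine
#' (alternating direction) to minimise travel; this affects no reported
#' statistic.
#'
#' @param kind pattern kind.
#' @param region a `ScanRegion`.
#' @param laser a [laser_params()]; its `line_interval_um` sets the spacing.
#' @param turnaround_s per-line overhead added between consecutive segments
#'   in [path_stats()]; default 0 (pure active-scan accounting).
#' @return an ungated `ScanPath` (beam ON over every full segment).
#' @export
plan_pattern <- function(kind = c("raster", "lattice", "rectangle", "circle",
                                  "line"),
                         region, laser = laser_params(), turnaround_s = 0) {
  kind <- match.arg(kind)
  if (!inherits(region, "ScanRegion")) stopf("region must be a ScanRegion")
  d <- laser$line_interval_um
  seg <- switch(kind,
    raster = serpentine(line_family(region, d, "h")),
    lattice = rbind(serpentine(line_family(region, d, "h")),
                    serpentine(line_family(region, d, "v"))),
    rectangle = {
      if (region$kind != "rect") stopf("rectangle pattern needs a rect region")
      x0 <- region$x0_um; y0 <- region$y0_um
      x1 <- x0 + region$width_um; y1 <- y0 + region$height_um
      data.frame(x0 = c(x0, x1, x1, x0), y0 = c(y0, y0, y1, y1),
                 x1 = c(x1, x1, x0, x0), y1 = c(y0, y1, y1, y0))
    },
    circle = {
      if (region$kind != "circle") stopf("circle pattern needs a circle region")
      R <- region$radius_um
      n <- max(16L, ceiling(2 * pi * R / 50))
      th <- seq(0, 2 * pi, length.out = n + 1)
      data.frame(x0 = region$center_um[1] + R * cos(th[-(n + 1)]),
                 y0 = region$center_um[2] + R * sin(th[-(n + 1)]),
                 x1 = region$center_um[1] + R * cos(th[-1]),
                 y1 = region$center_um[2] + R * sin(th[-1]))
    },
    line = {
      if (region$kind == "rect")
        data.frame(x0 = region$x0_um, y0 = region$y0_um + region$height_um / 2,
                   x1 = region$x0_um + region$width_um,
                   y1 = region$y0_um + region$height_um / 2)
      else
        data.frame(x0 = region$center_um[1] - region$radius_um,
                   y0 = region$center_um[2],
                   x1 = region$center_um[1] + region$radius_um,
                   y1 = region$center_um[2])
    })
  new_scan_path(seg, laser, turnaround_s)
}

## ---- gating ----------------------------------------------------------------

# binary target matrix from a ProbabilityMap or LabelMask
target_matrix <- function(targets, threshold) {
  if (inherits(targets, "ProbabilityMap"))
    list(bin = targets$probs >= threshold, ps = targets$pixel_size_um)
  else if (inherits(targets, "LabelMask"))
    list(bin = targets$labels == 2L, ps = targets$pixel_size_um)
  else stopf("targets must be a ProbabilityMap or LabelMask")
}

#' Gate a scan path on a target map
#'
#' Computes, for every segment, the arc-length spans over which the beam
#' center lies above target pixels (probability at least `threshold`, or the
#' differentiated class of a label mask); the beam is switched ON only there.
#' By default the target is first dilated by half the beam width so that
#' target edges receive full-width coverage (conservative elimination).
#'
#' @param path an ungated (or previously gated) `ScanPath`.
#' @param targets a `ProbabilityMap` or `LabelMask` registered to the same
#'   coordinate frame as the path.
#' @param threshold probability cutoff for targeting (default 0.5).
#' @param dilate_um morphological dilation radius applied to the target
#'   before gating; `NULL` (default) uses half the beam width, `0` disables.
#' @return the gated `ScanPath`.
#' @export
gate_path <- function(path, targets, threshold = 0.5, dilate_um = NULL) {
  tm <- target_matrix(targets, threshold)
  ps <- tm$ps
  bin <- tm$bin
  if (is.null(dilate_um)) dilate_um <- path$laser$beam_width_um / 2
  if (dilate_um > 0 && any(bin)) {
    r_px <- max(1L, round(dilate_um / ps))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    bin <- EBImage::dilate(bin * 1, brush) > 0
  }
  h <- nrow(bin); w <- ncol(bin)
  step <- ps / 2
  on <- vector("list", nrow(path$segments))
  for (k in seq_len(nrow(path$segments))) {
    s <- path$segments[k, ]
    L <- s$length_um
    if (L == 0) { on[[k]] <- matrix(numeric(0), 0, 2); next }
    ts <- seq(0, L, by = step)
    if (ts[length(ts)] < L) ts <- c(ts, L)
    x <- s$x0 + (s$x1 - s$x0) * ts / L
    y <- s$y0 + (s$y1 - s$y0) * ts / L
    i <- round(y / ps) + 1; j <- round(x / ps) + 1
    ok <- i >= 1 & i <= h & j >= 1 & j <= w
    hit <- logical(length(ts))
    hit[ok] <- bin[cbind(i[ok], j[ok])]
    r <- rle(hit)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    iv <- cbind(pmax(ts[starts[r$values]] - step / 2, 0),
                pmin(ts[ends[r$values]] + step / 2, L))
    on[[k]] <- if (nrow(iv)) iv else matrix(numeric(0), 0, 2)
  }
  path$on <- on
  path$gated <- TRUE
  path$threshold <- threshold
  path
}

#' Dose, energy, time and throughput of a scan path
#'
#' Total time covers the full traversal of every segment (the beam moves at
#' scan speed whether ON or OFF) plus per-line turnaround overhead; delivered
#' energy counts ON spans only.
#'
#' @param path a `ScanPath`.
#' @param cell_diameter_um nominal cell diameter for the throughput figure.
#' @return a `PathStats` list: `active_length_mm`, `total_length_mm`,
#'   `total_time_s`, `delivered_energy_J`, `dose_J_per_mm`, `flux_J_per_mm2`,
#'   `throughput_cells_per_s`, `n_segments`.
#' @export
path_stats <- function(path, cell_diameter_um = 10) {
  v <- path$laser$speed_mm_s; P <- path$laser$power_W
  on_mm <- sum(vapply(path$on, function(m)
    if (nrow(m)) sum(m[, 2] - m[, 1]) else 0, numeric(1))) / 1000
  tot_mm <- sum(path$segments$length_um) / 1000
  nseg <- nrow(path$segments)
  structure(list(
    active_length_mm = on_mm,
    total_length_mm = tot_mm,
    total_time_s = tot_mm / v + max(nseg - 1, 0) * path$turnaround_s,
    delivered_energy_J = P * on_mm / v,
    dose_J_per_mm = dose_per_length(P, v),
    flux_J_per_mm2 = energy_flux(P, v, path$laser$beam_width_um),
    throughput_cells_per_s = throughput(v, cell_diameter_um),
    n_segments = nseg), class = "PathStats")
}

#' @export
print.PathStats <- function(x, ...) {
  cat(sprintf(paste0(
    "PathStats: %d segments | %.1f mm path, %.1f mm ON | %.1f s | %.3g J ",
    "delivered | %.3g J/mm, %.3g J/mm2 | %.3g cells/s\n"),
    x$n_segments, x$total_length_mm, x$active_length_mm, x$total_time_s,
    x$delivered_energy_J, x$dose_J_per_mm, x$flux_J_per_mm2,
    x$throughput_cells_per_s))
  invisible(x)
}

#' Export / import a scan path (CSV + JSON sidecar)
#'
#' The CSV holds one row per segment
#' (`x0_um,y0_um,x1_um,y1_um,speed_mm_s,power_W`); the sidecar records the
#' laser parameters, turnaround and per-segment ON intervals.
#'
#' @param path a `ScanPath`; `file` the CSV path (sidecar gets `.json`).
#' @export
write_scan_path <- function(path, file) {
  seg <- path$segments
  out <- data.frame(x0_um = seg$x0, y0_um = seg$y0, x1_um = seg$x1,
                    y1_um = seg$y1, speed_mm_s = path$laser$speed_mm_s,
                    power_W = path$laser$power_W)
  write.csv(out, file, row.names = FALSE)
  side <- list(laser = unclass(path$laser), turnaround_s = path$turnaround_s,
               gated = path$gated, threshold = path$threshold,
               on = lapply(path$on, function(m) unname(as.data.frame(m))))
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(file), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_scan_path
#' @export
read_scan_path <- function(file) {
  seg <- read.csv(file)
  side <- jsonlite::read_json(paste0(tools::file_path_sans_ext(file), ".json"),
                              simplifyVector = TRUE)
  laser <- do.call(laser_params, side$laser)
  p <- new_scan_path(data.frame(x0 = seg$x0_um, y0 = seg$y0_um,
                                x1 = seg$x1_um, y1 = seg$y1_um),
                     laser, side$turnaround_s)
  if (isTRUE(side$gated)) {
    p$on <- lapply(side$on, function(d) {
      m <- as.matrix(as.data.frame(d))
      if (!nrow(m)) matrix(numeric(0), 0, 2) else unname(m)
    })
    p$gated <- TRUE
    p$threshold <- side$threshold
  }
  p
}
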
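## kill_eval: calibrated cell-kill rule, dose rasterization and closed-loop
## purity scoring.
##
## The default kill criterion is an areal-dose threshold calibrated at the
## deployment condition (0.8 W at 100 mm/s with a 50 um beam is the lowest
## power that reliably kills, so its flux is the threshold). Death is binary
## at the cell center: no partial damage and no bystander effect, which
## mirrors sharply local killing; the ~50 um death swath emerges from the
## beam width alone. A peak-temperature mode backed by the photothermal
## module exists for cross-speed studies.

#' Cell-kill model
#'
#' @param mode `"dose_threshold"` (default) or `"peak_temperature"`.
#' @param dose_threshold_J_mm2 areal dose at or above which a cell dies.
#' @param kill_temp_C peak temperature at or above which a cell dies
#'   (temperature mode; default 50 degC).
#' @param kill_halfwidth_um nominal half-width of the death swath (default
#'   25 um, half the beam width).
#' @return a `KillModel` object.
#' @export
kill_model <- function(mode = c("dose_threshold", "peak_temperature"),
                       dose_threshold_J_mm2 = 0.16, kill_temp_C = 50,
                       kill_halfwidth_um = 25) {
  mode <- match.arg(mode)
  stopifnot(dose_threshold_J_mm2 > 0, kill_temp_C > 0, kill_halfwidth_um > 0)
  structure(list(mode = mode, dose_threshold_J_mm2 = dose_threshold_J_mm2,
                 kill_temp_C = kill_temp_C,
                 kill_halfwidth_um = kill_halfwidth_um), class = "KillModel")
}

#' Calibrate the kill model from the threshold scan condition
#'
#' The dose threshold is the energy flux of the lowest power/speed
#' combination that reliably kills (0.8 W at 100 mm/s with a 50 um beam).
#'
#' @param threshold_power_W lowest reliably killing power (W).
#' @param speed_mm_s scan speed of the calibration condition (mm/s).
#' @param beam_width_um beam width (um).
#' @return a [kill_model()] in dose mode.
#' @export
calibrate_kill <- function(threshold_power_W = 0.8, speed_mm_s = 100,
                           beam_width_um = 50) {
  if (threshold_power_W <= 0 || speed_mm_s <= 0 || beam_width_um <= 0)
    stopf("calibration arguments must be positive")
  kill_model("dose_threshold",
             dose_threshold_J_mm2 =
               energy_flux(threshold_power_W, speed_mm_s, beam_width_um),
             kill_halfwidth_um = beam_width_um / 2)
}

#' Rasterize the delivered dose of a (gated) scan path
#'
#' Every pixel whose center lies within half a beam width of an ON span
#' accrues the path's energy flux `P/(v w)`; overlapping passes sum.
#'
#' @param path a `ScanPath` (gated or not).
#' @param nrow_px,ncol_px,pixel_size_um geometry of the dose raster, shared
#'   with the imaging coordinate frame.
#' @return a `DoseField`: list with `dose` (J/mm^2 matrix) and
#'   `pixel_size_um`.
#' @export
accumulate_dose <- function(path, nrow_px, ncol_px, pixel_size_um = 1) {
  ps <- pixel_size_um
  flux <- energy_flux(path$laser$power_W, path$laser$speed_mm_s,
                      path$laser$beam_width_um)
  hw <- path$laser$beam_width_um / 2
  dose <- matrix(0, nrow_px, ncol_px)
  xs <- (seq_len(ncol_px) - 1) * ps
  ys <- (seq_len(nrow_px) - 1) * ps
  for (k in seq_len(nrow(path$segments))) {
    s <- path$segments[k, ]
    iv <- path$on[[k]]
    if (!nrow(iv)) next
    L <- s$length_um
    ux <- if (L > 0) (s$x1 - s$x0) / L else 0
    uy <- if (L > 0) (s$y1 - s$y0) / L else 0
    horiz <- abs(uy) < 1e-12; vert <- abs(ux) < 1e-12
    for (q in seq_len(nrow(iv))) {
      t0 <- iv[q, 1]; t1 <- iv[q, 2]
      if (horiz || vert) {
        ax0 <- s$x0 + ux * t0; ax1 <- s$x0 + ux * t1
        ay0 <- s$y0 + uy * t0; ay1 <- s$y0 + uy * t1
        jj <- which(xs >= min(ax0, ax1) - ps / 2 - (if (vert) hw else 0) &
                    xs <= max(ax0, ax1) + ps / 2 + (if (vert) hw else 0))
        ii <- which(ys >= min(ay0, ay1) - ps / 2 - (if (horiz) hw else 0) &
                    ys <= max(ay0, ay1) + ps / 2 + (if (horiz) hw else 0))
        if (horiz) {
          ii <- which(abs(ys - ay0) <= hw)
          jj <- which(xs >= min(ax0, ax1) & xs <= max(ax0, ax1))
        } else {
          jj <- which(abs(xs - ax0) <= hw)
          ii <- which(ys >= min(ay0, ay1) & ys <= max(ay0, ay1))
        }
        if (length(ii) && length(jj))
          dose[ii, jj] <- dose[ii, jj] + flux
      } else {
        # generic oblique segment: distance of pixel centers to the ON span
        px0 <- s$x0 + ux * t0; py0 <- s$y0 + uy * t0
        jj <- which(xs >= min(px0, s$x0 + ux * t1) - hw - ps &
                    xs <= max(px0, s$x0 + ux * t1) + hw + ps)
        ii <- which(ys >= min(py0, s$y0 + uy * t1) - hw - ps &
                    ys <= max(py0, s$y0 + uy * t1) + hw + ps)
        if (!length(ii) || !length(jj)) next
        gx <- matrix(xs[jj], length(ii), length(jj), byrow = TRUE)
        gy <- matrix(ys[ii], length(ii), length(jj))
        tproj <- clamp((gx - s$x0) * ux + (gy - s$y0) * uy, t0, t1)
        d2 <- (gx - (s$x0 + ux * tproj))^2 + (gy - (s$y0 + uy * tproj))^2
        hitm <- d2 <= hw^2
        dose[ii, jj] <- dose[ii, jj] + flux * hitm
      }
    }
  }
  structure(list(dose = dose, pixel_size_um = ps), class = "DoseField")
}

# nearest-pixel lookup of a field matrix at cell centers
lookup_at_cells <- function(m, ps, cells) {
  i <- clamp(round(cells$y_um / ps) + 1, 1, nrow(m))
  j <- clamp(round(cells$x_um / ps) + 1, 1, ncol(m))
  m[cbind(i, j)]
}

#' Apply the kill rule to a cell population
#'
#' A cell's alive flag is cleared iff the dose (or peak temperature) at its
#' center meets the model threshold; all other cells are untouched.
#'
#' @param cells cell population data.frame (`x_um, y_um, diameter_um, type,
#'   alive`).
#' @param field a `DoseField` (dose mode) or `ThermalField` (temperature
#'   mode).
#' @param model a [kill_model()].
#' @return the population with updated `alive` flags.
#' @export
apply_kill <- function(cells, field, model = calibrate_kill()) {
  if (!nrow(cells)) return(cells)
  if (model$mode == "dose_threshold") {
    if (!inherits(field, "DoseField")) stopf("dose mode needs a DoseField")
    v <- lookup_at_cells(field$dose, field$pixel_size_um, cells)
    hit <- v >= model$dose_threshold_J_mm2
  } else {
    if (!inherits(field, "ThermalField"))
      stopf("temperature mode needs a ThermalField")
    xs <- cells$x_um - field$origin_um[1]
    ys <- cells$y_um - field$origin_um[2]
    i <- clamp(round(ys / field$grid_um) + 1, 1, nrow(field$maxfield))
    j <- clamp(round(xs / field$grid_um) + 1, 1, ncol(field$maxfield))
    inside <- xs >= 0 & ys >= 0 &
      xs <= (ncol(field$maxfield) - 1) * field$grid_um &
      ys <= (nrow(field$maxfield) - 1) * field$grid_um
    v <- rep(-Inf, nrow(cells))
    v[inside] <- field$maxfield[cbind(i[inside], j[inside])]
    hit <- v >= model$kill_temp_C
  }
  cells$alive <- cells$alive & !hit
  cells
}

#' Purity summary of a processed population
#'
#' @param cells population after [apply_kill()].
#' @return a `PurityReport`: counts, survivor purity (undifferentiated among
#'   alive) and the pre-irradiation purity (undifferentiated among all).
#' @export
purity_report <- function(cells) {
  n_total <- nrow(cells)
  n_alive <- sum(cells$alive)
  n_alive_undiff <- sum(cells$alive & cells$type == "undifferentiated")
  n_alive_diff <- n_alive - n_alive_undiff
  structure(list(
    n_total = n_total, n_alive = n_alive, n_dead = n_total - n_alive,
    n_alive_undiff = n_alive_undiff, n_alive_diff = n_alive_diff,
    purity = if (n_alive > 0) n_alive_undiff / n_alive else NA_real_,
    purity_before = if (n_total > 0)
      sum(cells$type == "undifferentiated") / n_total else NA_real_,
    defined = n_alive > 0), class = "PurityReport")
}

#' @export
print.PurityReport <- function(x, ...) {
  cat(sprintf(
    "PurityReport: %d cells, %d alive (%d undiff / %d diff); purity %.1f%% (before %.1f%%)\n",
    x$n_total, x$n_alive, x$n_alive_undiff, x$n_alive_diff,
    100 * x$purity, 100 * x$purity_before))
  invisible(x)
}

#' Flow-cytometry-style readout of a processed population
#'
#' Summarises the undifferentiated fraction among harvested cells like a
#' two-gate flow readout. Dead cells are excluded from the harvest (assumed
#' washed away before collection).
#'
#' @param cells processed population.
#' @param harvest harvest model; only `"alive_only"` is defined.
#' @return list with gate counts, `positive_fraction` (undifferentiated among
#'   harvested) and `defined` (FALSE when nothing is harvested).
#' @export
flow_analog <- function(cells, harvest = "alive_only") {
  harvest <- match.arg(harvest, "alive_only")
  al <- cells[cells$alive, , drop = FALSE]
  n <- nrow(al)
  npos <- sum(al$type == "undifferentiated")
  list(n_harvested = n, n_positive = npos, n_negative = n - npos,
       positive_fraction = if (n > 0) npos / n else NA_real_,
       defined = n > 0)
}

#' Run the full in-silico purification loop
#'
#' Composes the whole pipeline: synthesise training fields and a held-out
#' evaluation field, train the patch classifier with two-round hard-example
#' mining (phase channel only at inference), render the probability map of
#' the held-out field, gate a 25 um raster over it, rasterize the delivered
#' dose, apply the kill rule and score survivor purity.
#'
#' @param sim a [colony_sim_params()]; its `seed` is ignored in favour of
#'   per-field seeds derived from `seed`.
#' @param hyper a [train_hyper()]; its seed is likewise derived.
#' @param laser a [laser_params()] (deployment default 0.8 W, 100 mm/s,
#'   50 um beam, 25 um interval).
#' @param model a [kill_model()].
#' @param threshold probability threshold for targeting (default 0.5).
#' @param seed global seed of the run; every stochastic stage derives its
#'   own seed from it.
#' @param n_train_fields training fields synthesised for the classifier.
#' @param stride_px probability-map stride; 35 px (half a patch) smooths the
#'   map across patch boundaries at moderate cost.
#' @param targeting `"cnn"` (deployed loop) or `"oracle"` (gate on the
#'   ground-truth mask instead; upper-bound run).
#' @return a `PurityReport` with the gated-path statistics (`$stats`), the
#'   seeds used (`$seeds`), the mined-patch count (`$mined_n`) and, for CNN
#'   targeting, held-out patch accuracy (`$heldout_accuracy`).
#' @export
run_closed_loop <- function(sim = colony_sim_params(),
                            hyper = train_hyper(),
                            laser = laser_params(),
                            model = calibrate_kill(),
                            threshold = 0.5, seed = 1L,
                            n_train_fields = 2L, stride_px = 35L,
                            targeting = c("cnn", "oracle")) {
  targeting <- match.arg(targeting)
  seeds <- list(fields = vapply(seq_len(n_train_fields), function(k)
    derive_seed(seed, paste0("field", k)), integer(1)),
    eval = derive_seed(seed, "eval"),
    cnn = derive_seed(seed, "cnn"))

  ev_par <- sim; ev_par$seed <- seeds$eval
  ev <- generate_field(ev_par)

  mined_n <- NA_integer_; acc <- NA_real_
  if (targeting == "cnn") {
    fields <- lapply(seeds$fields, function(s) {
      p <- sim; p$seed <- s
      f <- generate_field(p)
      list(phase = f$phase, mask = f$mask)
    })
    hyper$seed <- seeds$cnn
    clf <- train_with_mining(fields, hyper = hyper)
    mined_n <- clf$mined_n
    hop <- extract_patches(ev$phase, ev$mask, policy = "grid_nonoverlap")
    pr <- predict_patches(clf, hop)
    pred <- ifelse(pr[, "differentiated"] >= 0.5, "differentiated",
                   "undifferentiated")
    acc <- mean(pred == as.character(hop$label))
    targets <- predict_map(clf, ev$phase, stride_px = stride_px)
  } else {
    targets <- ev$mask
  }

  path <- plan_pattern("raster", frame_region(ev$phase), laser)
  gated <- gate_path(path, targets, threshold = threshold)
  dose <- accumulate_dose(gated, nrow(ev$phase$pixels), ncol(ev$phase$pixels),
                          ev$phase$pixel_size_um)
  pop <- apply_kill(ev$cells, dose, model)
  rep <- purity_report(pop)
  rep$stats <- path_stats(gated, sim$cell_diameter_um)
  rep$seeds <- seeds
  rep$mined_n <- mined_n
  rep$heldout_accuracy <- acc
  rep$targeting <- targeting
  rep$population <- pop
  rep
}
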
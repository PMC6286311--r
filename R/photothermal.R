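## photothermal: 2-D heat diffusion on the light-responsive layer under a
## moving laser spot.
##
## Model: dT/dt = D lap(T) - lambda (T - T_amb) + S(x, t) on the substrate
## surface, integrated by explicit forward-time centered-space (FTCS) with
## Dirichlet ambient boundaries on a padded domain. The surface (2-D) model is
## justified by the thin-layer geometry: the published observables (diffusion
## coefficient, comet timing) are all surface quantities. The source S is a
## top-hat spot of the beam diameter (Gaussian optional) carrying the absorbed
## optical power times a coupling constant; `coupling` [degC mm^2 / J]
## collapses the layer's unpublished areal heat capacity, and `loss_rate_s`
## the interface losses, into two calibration constants. They are fitted once
## (scripts/calibrate_thermal.R in the source repository) so that a
## 0.3 W / 80 mm/s / 50 um scan peaks just above 50 degC and relaxes to
## physiological temperature on the ~10 ms scale; the fitted values are the
## defaults below.

#' Thermal model parameters
#'
#' @param D_mm2_s thermal diffusion coefficient of the substrate surface
#'   (default 0.1 mm^2/s).
#' @param ambient_C ambient (initial and boundary) temperature, default
#'   29.5 degC.
#' @param absorbance_405 optical absorbance of the layer at 405 nm
#'   (default 0.25); sets the absorbed power fraction `1 - 10^-A`.
#' @param coupling calibration constant converting absorbed areal power
#'   density to heating rate, degC mm^2 per J.
#' @param loss_rate_s Newton-cooling rate to ambient, 1/s.
#' @param grid_um spatial step of the integrator, micrometers.
#' @param dt_s time step; `NULL` (default) picks `safety * grid^2 / (4 D)`.
#' @param safety fraction of the explicit-scheme stability bound used when
#'   `dt_s` is automatic.
#' @param source_profile `"tophat"` (default, a disc of the beam diameter) or
#'   `"gaussian"` (sigma = diameter / 4).
#' @return a `ThermalParams` object.
#' @export
thermal_params <- function(D_mm2_s = 0.1, ambient_C = 29.5,
                           absorbance_405 = 0.25, coupling = 700,
                           loss_rate_s = 30, grid_um = 5, dt_s = NULL,
                           safety = 0.4,
                           source_profile = c("tophat", "gaussian")) {
  source_profile <- match.arg(source_profile)
  stopifnot(D_mm2_s > 0, grid_um > 0, coupling >= 0, loss_rate_s >= 0,
            safety > 0, safety < 1)
  if (absorbance_405 < 0) stopf("absorbance must be nonnegative")
  h_mm <- grid_um / 1000
  dt_max <- h_mm^2 / (4 * D_mm2_s)
  if (is.null(dt_s)) dt_s <- safety * dt_max
  if (dt_s > dt_max)
    stopf("dt_s = %.3g s violates the stability bound; admissible dt <= %.3g s",
          dt_s, dt_max)
  structure(list(D_mm2_s = D_mm2_s, ambient_C = ambient_C,
                 absorbance_405 = absorbance_405, coupling = coupling,
                 loss_rate_s = loss_rate_s, grid_um = grid_um, dt_s = dt_s,
                 source_profile = source_profile), class = "ThermalParams")
}

#' Absorbed fraction of the incident beam
#'
#' @param A optical absorbance (base 10).
#' @return `1 - 10^-A`, in `[0, 1)`.
#' @export
absorbed_fraction <- function(A) {
  if (any(A < 0)) stopf("absorbance must be nonnegative")
  1 - 10^(-A)
}

#' Beam transit time over a point
#'
#' @param beam_width_um beam width (um).
#' @param speed_mm_s scan speed (mm/s).
#' @return `w / v` in milliseconds.
#' @export
transit_time <- function(beam_width_um, speed_mm_s) {
  if (beam_width_um <= 0 || speed_mm_s <= 0) stopf("arguments must be positive")
  beam_width_um / speed_mm_s
}

#' Diffusion length
#'
#' @param D_mm2_s diffusion coefficient (mm^2/s).
#' @param t_s time (s).
#' @return `sqrt(4 D t)` in micrometers.
#' @export
diffusion_length <- function(D_mm2_s, t_s) {
  if (D_mm2_s <= 0 || any(t_s < 0)) stopf("D must be positive and t nonnegative")
  sqrt(4 * D_mm2_s * t_s) * 1000
}

# source stamp: heating-rate density (degC/s) over the spot footprint.
# Power is normalised over the realised stamp area so the injected total is
# exact on the grid.
source_stamp <- function(laser, params) {
  h_mm <- params$grid_um / 1000
  Pabs <- laser$power_W * absorbed_fraction(params$absorbance_405)
  r_px <- max(1, round(laser$beam_width_um / 2 / params$grid_um))
  n <- 2L * r_px + 1L
  d2 <- outer((seq_len(n) - r_px - 1)^2, (seq_len(n) - r_px - 1)^2, "+")
  if (params$source_profile == "tophat") {
    m <- (d2 <= r_px^2) * 1
  } else {
    sg <- (laser$beam_width_um / 4 / params$grid_um)
    m <- exp(-d2 / (2 * sg^2))
  }
  s <- m / (sum(m) * h_mm^2)            # 1/mm^2, integrates to 1
  list(stamp = params$coupling * Pabs * s, r_px = r_px)
}

#' Simulate the temperature field under a moving beam
#'
#' Integrates the surface heat equation while the spot traverses a line
#' segment at the laser speed, then for `tail_s` more with the source off.
#' With `coupling = 0` (or zero absorbance / power) the field stays at
#' ambient, the behaviour of an uncoated dish.
#'
#' @param segment list/row with `x0, y0, x1, y1` in um (trajectory of the spot
#'   center).
#' @param laser a [laser_params()].
#' @param params a [thermal_params()].
#' @param tail_s source-off time simulated after the traversal (s).
#' @param pad_um domain padding beyond the trajectory; `NULL` picks
#'   10 diffusion lengths of the run duration (at least 250 um).
#' @param snapshot_every_s spacing of stored full-field snapshots.
#' @return a `ThermalField`: snapshots (3-D array, degC) with time stamps, the
#'   per-step temperature history of a probe point at the trajectory midpoint,
#'   the per-step profile along the scan row, the running maximum field, and
#'   the grid geometry needed to map positions to pixels.
#' @export
simulate_thermal <- function(segment, laser, params = thermal_params(),
                             tail_s = 0.025, pad_um = NULL,
                             snapshot_every_s = 0.002) {
  x0 <- segment$x0; y0 <- segment$y0; x1 <- segment$x1; y1 <- segment$y1
  L_um <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  v_um_s <- laser$speed_mm_s * 1000
  t_on <- L_um / v_um_s
  t_tot <- t_on + tail_s
  if (is.null(pad_um))
    pad_um <- max(250, 10 * diffusion_length(params$D_mm2_s, t_tot) / 2)
  h <- params$grid_um
  gx0 <- min(x0, x1) - pad_um; gx1 <- max(x0, x1) + pad_um
  gy0 <- min(y0, y1) - pad_um; gy1 <- max(y0, y1) + pad_um
  nc <- ceiling((gx1 - gx0) / h) + 1L
  nr <- ceiling((gy1 - gy0) / h) + 1L

  dt <- params$dt_s
  nsteps <- max(1L, ceiling(t_tot / dt))
  tgrid <- (seq_len(nsteps) - 0.5) * dt
  frac <- pmin(tgrid / t_on, 1)
  sx <- x0 + (x1 - x0) * frac
  sy <- y0 + (y1 - y0) * frac
  st <- source_stamp(laser, params)
  ci <- round((sy - gy0) / h) - st$r_px       # 0-based stamp top-left
  cj <- round((sx - gx0) / h) - st$r_px
  off <- tgrid > t_on
  ci[off] <- -1L
  centers <- cbind(as.integer(ci), as.integer(cj))

  probe_x <- (x0 + x1) / 2; probe_y <- (y0 + y1) / 2
  pi_ <- as.integer(round((probe_y - gy0) / h))
  pj_ <- as.integer(round((probe_x - gx0) / h))
  prof_i <- as.integer(round((y0 - gy0) / h))

  T0 <- matrix(params$ambient_C, nr, nc)
  alpha <- params$D_mm2_s * dt / (h / 1000)^2
  snap_every <- max(1L, round(snapshot_every_s / dt))
  res <- heat_run_cpp(T0, params$ambient_C, alpha, params$loss_rate_s * dt, dt,
                      st$stamp, centers, snap_every, pi_, pj_, prof_i)
  structure(list(
    snapshots = res$snapshots, snapshot_t = as.numeric(res$snapshot_t),
    probe = as.numeric(res$probe), probe_xy_um = c(probe_x, probe_y),
    profile = res$profile, profile_y_um = y0,
    maxfield = res$maxfield, final = res$final,
    dt_s = dt, t_on_s = t_on, t_total_s = nsteps * dt,
    origin_um = c(gx0, gy0), grid_um = h,
    segment = list(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
    laser = laser, params = params), class = "ThermalField")
}

#' @export
print.ThermalField <- function(x, ...) {
  cat(sprintf(
    "ThermalField %d x %d px @ %.3g um, %.1f ms simulated (%.1f ms beam-on), peak %.1f degC\n",
    nrow(x$final), ncol(x$final), x$grid_um, 1000 * x$t_total_s,
    1000 * x$t_on_s, max(x$maxfield)))
  invisible(x)
}

# temperature history at the fixed probe point, with time axis
probe_series <- function(field) {
  list(t_s = seq(0, by = field$dt_s, length.out = length(field$probe)),
       T_C = field$probe)
}

#' Comet metrics of a moving-spot thermal field
#'
#' Quantifies the "comet" behaviour of the thermal image: `rise_time_ms` is
#' the 10%-to-90%-of-peak-excess rise at a fixed point on the scan line,
#' `decay_time_ms` the time from that point's peak back down to
#' `physiological_C`, and `tail_length_um` the instantaneous distance from
#' the spot center to the farthest trailing point on the scan line still
#' above `physiological_C` (measured late in the traversal, when the tail is
#' developed). When the field never exceeds `physiological_C` the metrics are
#' undefined and flagged rather than reported as zero.
#'
#' @param field a [simulate_thermal()] result.
#' @param physiological_C threshold temperature (default 37 degC).
#' @return list with `defined`, `rise_time_ms`, `decay_time_ms`,
#'   `tail_length_um`, `peak_C`.
#' @export
comet_metrics <- function(field, physiological_C = 37) {
  ps <- probe_series(field)
  peak <- max(ps$T_C)
  amb <- field$params$ambient_C
  if (peak <= physiological_C)
    return(list(defined = FALSE, rise_time_ms = NA_real_,
                decay_time_ms = NA_real_, tail_length_um = NA_real_,
                peak_C = peak))
  excess <- ps$T_C - amb
  pk <- which.max(excess)
  i10 <- which(excess[seq_len(pk)] >= 0.1 * excess[pk])[1]
  i90 <- which(excess[seq_len(pk)] >= 0.9 * excess[pk])[1]
  rise_ms <- (ps$t_s[i90] - ps$t_s[i10]) * 1000
  after <- seq(pk, length(excess))
  idec <- which(ps$T_C[after] <= physiological_C)[1]
  decay_ms <- if (is.na(idec)) NA_real_ else
    (ps$t_s[after[idec]] - ps$t_s[pk]) * 1000

  # tail length at 90% of the traversal (spot still moving, tail developed)
  tm <- 0.9 * field$t_on_s
  step <- min(max(1L, round(tm / field$dt_s)), nrow(field$profile) - 1L) + 1L
  prof <- field$profile[step, ]
  seg <- field$segment
  frac <- min((step - 1) * field$dt_s / field$t_on_s, 1)
  spot_x <- seg$x0 + (seg$x1 - seg$x0) * frac
  xs <- field$origin_um[1] + (seq_along(prof) - 1) * field$grid_um
  dirx <- sign(seg$x1 - seg$x0)
  trailing <- which(prof > physiological_C &
                    (xs - spot_x) * dirx < 0)
  tail_um <- if (!length(trailing)) 0 else
    max(abs(xs[trailing] - spot_x))
  list(defined = TRUE, rise_time_ms = rise_ms, decay_time_ms = decay_ms,
       tail_length_um = tail_um, peak_C = peak)
}

#' Low-level FTCS diffusion run (no source)
#'
#' Exposes the bare integrator for numerical verification: conservation of
#' excess heat with losses off, monotone decay of extrema, and comparison
#' against closed-form kernels.
#'
#' @param T0 initial temperature matrix (degC).
#' @param params a [thermal_params()]; `grid_um`, `dt_s`, `D_mm2_s`,
#'   `loss_rate_s` and `ambient_C` are used.
#' @param nsteps number of time steps.
#' @param snapshot_every store every n-th field.
#' @return list with `final`, `snapshots`, `snapshot_t`.
#' @export
heat_diffuse <- function(T0, params = thermal_params(), nsteps,
                         snapshot_every = nsteps) {
  h_mm <- params$grid_um / 1000
  alpha <- params$D_mm2_s * params$dt_s / h_mm^2
  if (alpha > 0.25)
    stopf("dt violates stability; admissible dt <= %.3g s",
          0.25 * h_mm^2 / params$D_mm2_s)
  centers <- matrix(-1L, nsteps, 2)
  res <- heat_run_cpp(T0, params$ambient_C, alpha,
                      params$loss_rate_s * params$dt_s, params$dt_s,
                      matrix(0, 1, 1), centers, as.integer(snapshot_every),
                      0L, 0L, 0L)
  list(final = res$final, snapshots = res$snapshots,
       snapshot_t = as.numeric(res$snapshot_t))
}

#' Stationary continuous source run
#'
#' Holds the source fixed at the domain center for `duration_s`; used to
#' check the integrator against the closed-form continuous point-source
#' solution `dT(r, t) = Q / (4 pi D) E1(r^2 / (4 D t))`.
#'
#' @param power_W optical power of the stationary beam.
#' @param duration_s simulated time.
#' @param params a [thermal_params()].
#' @param spot_diameter_um source footprint diameter; the grid step gives a
#'   near-point source.
#' @param domain_um square domain edge length.
#' @return a list like [heat_diffuse()] plus `origin_um`, `grid_um`,
#'   `center_um` and the total source strength `Q_Cmm2_s`.
#' @export
simulate_stationary_spot <- function(power_W, duration_s,
                                     params = thermal_params(),
                                     spot_diameter_um = params$grid_um,
                                     domain_um = 2000) {
  h <- params$grid_um
  n <- 2L * ceiling(domain_um / 2 / h) + 1L
  laser <- laser_params(power_W = power_W, speed_mm_s = 1,
                        beam_width_um = max(spot_diameter_um, h / 2))
  st <- source_stamp(laser, params)
  nsteps <- max(1L, ceiling(duration_s / params$dt_s))
  ctr <- (n - 1L) %/% 2L
  centers <- matrix(rep(as.integer(ctr - st$r_px), 2L * nsteps), nsteps, 2)
  T0 <- matrix(params$ambient_C, n, n)
  alpha <- params$D_mm2_s * params$dt_s / (h / 1000)^2
  res <- heat_run_cpp(T0, params$ambient_C, alpha,
                      params$loss_rate_s * params$dt_s, params$dt_s,
                      st$stamp, centers, nsteps, as.integer(ctr),
                      as.integer(ctr), as.integer(ctr))
  Pabs <- power_W * absorbed_fraction(params$absorbance_405)
  list(final = res$final, grid_um = h, n = n,
       center_px = ctr + 1L, t_s = nsteps * params$dt_s,
       Q_Cmm2_s = params$coupling * Pabs)
}
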
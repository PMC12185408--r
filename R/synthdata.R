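# Synthetic-data generator: cell populations, loading waveforms, deformation
# records and whole datasets with the statistical structure the analysis
# assumes (Gaussian initial area/perimeter, uniform initial angle, peak
# pressures clustered into levels, state-equation response with
# water-exchange fluctuation noise, occasional detachment).

# Shallow configuration merge. Unlike utils::modifyList this replaces data
# frames and sub-specs wholesale (no column-wise recursion) and lets an
# override of NULL disable a default (e.g. detach = NULL).
merge_config <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[nm] <- list(overrides[[nm]])
  defaults
}

#' Default peak-pressure levels of the study design
#'
#' Fifteen pressure levels (group centre, dispersion, group size) spanning
#' the corrected compression-stress range of the loading apparatus. Sizes
#' for the two highest levels are 13 and 9; the remaining 176 cells are
#' split over the lower thirteen levels (seven groups of 14, six of 13) to
#' total 198.
#'
#' @return Data frame with columns `label`, `center_kPa`, `sd_kPa`, `n`.
#' @export
default_pressure_levels <- function() {
  data.frame(
    label = paste0("Lvl", 1:15),
    center_kPa = c(478, 550, 640, 760, 837, 986, 1094, 1198, 1315, 1489,
                   1703, 1880, 2261, 2598, 3178),
    sd_kPa = c(24.2, 18.1, 22.7, 18.3, 27.6, 44.2, 16.2, 36.0, 37.0, 35.4,
               43.7, 58.4, 85.1, 115.6, 195.2),
    n = c(rep(14L, 7L), rep(13L, 6L), 13L, 9L))
}

#' Specification of a synthetic cell population
#'
#' Initial areas and perimeters are Gaussian (truncated at zero by
#' resampling); initial inclination angles are uniform. Defaults mirror the
#' study scale: 198 cells with realistic adherent-macrophage morphometrics.
#'
#' @param n_cells number of cells (>= 0).
#' @param area_mean,area_sd initial projected area distribution (um^2).
#' @param perim_mean,perim_sd initial perimeter distribution (um).
#' @param angle_low,angle_high uniform angle range (degrees),
#'   `0 <= angle_low < angle_high <= 180`.
#' @param seed optional integer seed for reproducible sampling.
#' @return Object of class `"population_spec"`.
#' @export
population_spec <- function(n_cells = 198L, area_mean = 550, area_sd = 150,
                            perim_mean = 100, perim_sd = 18,
                            angle_low = 0, angle_high = 180, seed = NULL) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (area_sd < 0 || perim_sd < 0) stop("standard deviations must be >= 0")
  if (!(angle_low >= 0 && angle_low < angle_high && angle_high <= 180))
    stop("require 0 <= angle_low < angle_high <= 180")
  structure(list(n_cells = as.integer(n_cells), area_mean = area_mean,
                 area_sd = area_sd, perim_mean = perim_mean,
                 perim_sd = perim_sd, angle_low = angle_low,
                 angle_high = angle_high, seed = seed),
            class = "population_spec")
}

rnorm_positive <- function(n, mean, sd) {
  # truncation at 0 by resampling; negligible unless mean/sd is small
  if (n == 0L) return(numeric(0L))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample a synthetic cell population
#'
#' @param spec a [population_spec()].
#' @return Data frame with `cell_id`, `area_um2`, `perimeter_um`,
#'   `angle_deg`.
#' @export
sample_cell_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_cells
  data.frame(cell_id = seq_len(n),
             area_um2 = rnorm_positive(n, spec$area_mean, spec$area_sd),
             perimeter_um = rnorm_positive(n, spec$perim_mean, spec$perim_sd),
             angle_deg = stats::runif(n, spec$angle_low, spec$angle_high))
}

#' Generate a constant-rate pressure ramp
#'
#' Builds a sampled loading waveform: a pre-arrival baseline at `p0`
#' followed by a linear ramp to `p_peak` over `duration` (the whole impact
#' does not exceed 0.1 ms), sampled at the camera frame rate so image stacks
#' and pressure samples align one-to-one. The pressure rate
#' `p_dot = (p_peak - p0)/duration` is constant along the ramp.
#'
#' @param p0 baseline pressure (kPa).
#' @param p_peak peak pressure (kPa), > `p0`.
#' @param duration ramp duration (ms).
#' @param fps sampling/frame rate (frames per second).
#' @param baseline_frames number of pre-arrival baseline samples.
#' @param baseline_noise_sd sensor noise on the baseline segment (kPa).
#' @return Object of class `"loading_waveform"` with `times` (ms),
#'   `pressures` (kPa), `p0`, `p_dot` (kPa/ms), `arrival_index` (first
#'   sample with pressure above baseline) and `peak_index`.
#' @export
generate_waveform <- function(p0, p_peak, duration = 0.1, fps = 2e5,
                              baseline_frames = 10L, baseline_noise_sd = 0) {
  stopifnot(p_peak > p0, duration > 0, fps > 0, baseline_frames >= 1L)
  n_int <- fps * duration / 1000
  if (n_int < 2) stop("too few frames: fps * duration must cover >= 2 samples")
  n_int <- round(n_int)
  dt <- 1000 / fps  # ms per frame
  ramp <- seq(p0, p_peak, length.out = n_int + 1L)
  base <- rep(p0, baseline_frames)
  if (baseline_noise_sd > 0)
    base <- base + stats::rnorm(baseline_frames, 0, baseline_noise_sd)
  pressures <- c(base, ramp)
  times <- (seq_along(pressures) - 1L) * dt
  structure(list(times = times, pressures = pressures, p0 = p0,
                 p_dot = (p_peak - p0) / duration,
                 arrival_index = baseline_frames + 2L,  # first sample > p0
                 peak_index = which.max(pressures)),
            class = "loading_waveform")
}

#' @export
print.loading_waveform <- function(x, ...) {
  cat(sprintf(
    "Loading waveform: %d samples, p0 = %.6g kPa, peak = %.6g kPa, p_dot = %.6g kPa/ms\n",
    length(x$pressures), x$p0, max(x$pressures), x$p_dot))
  invisible(x)
}

#' Water-exchange fluctuation specification
#'
#' Transmembrane water flux perturbs the observed final area. Under a
#' stationary fluid the fluctuation is uniform on `[-amplitude, +amplitude]`;
#' under unidirectional flow (the loading device drives flow in a fixed
#' direction) it is Gaussian with standard deviation `amplitude`. Applied
#' multiplicatively to the final area.
#'
#' @param flow_mode `"unidirectional"` (default, Gaussian) or
#'   `"stationary"` (uniform).
#' @param amplitude fractional fluctuation scale, >= 0.
#' @param seed optional seed.
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(flow_mode = c("unidirectional", "stationary"),
                       amplitude = 0.05, seed = NULL) {
  flow_mode <- match.arg(flow_mode)
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(flow_mode = flow_mode, amplitude = amplitude, seed = seed),
            class = "noise_spec")
}

draw_fluctuation <- function(noise, n = 1L) {
  if (noise$amplitude == 0) return(rep(0, n))
  switch(noise$flow_mode,
         stationary = stats::runif(n, -noise$amplitude, noise$amplitude),
         unidirectional = stats::rnorm(n, 0, noise$amplitude))
}

#' Size coupling of state-equation parameters
#'
#' Larger cells deform proportionally less at the same pressure. This is
#' emulated by scaling the pressure-scale parameter of the state equation
#' with the cell's initial area: `theta(A0) = theta_ref *
#' (reference_area/A0)^exponent`, applied to `alpha3` (Tait family) or
#' `p_ref` (exponential and li families). The default exponent `-0.5` makes
#' larger cells effectively stiffer, which reproduces the observed signs
#' `dzeta/dA < 0`, `d2zeta/dA2 > 0` and `dzeta/dp * dzeta/dA < 0`.
#'
#' @param reference_area reference initial area (um^2), > 0.
#' @param exponent coupling exponent (dimensionless).
#' @return Object of class `"size_coupling"`.
#' @export
size_coupling <- function(reference_area = 550, exponent = -0.5) {
  stopifnot(reference_area > 0)
  structure(list(reference_area = reference_area, exponent = exponent),
            class = "size_coupling")
}

#' Adapt a state equation to one cell's initial area
#'
#' Returns the model with `A0` set to the cell's area and its pressure-scale
#' parameter rescaled by the size coupling.
#'
#' @inheritParams eos_area
#' @param A0_cell the cell's initial area (um^2).
#' @param coupling a [size_coupling()], or `NULL` for no rescaling.
#' @return A [state_equation()].
#' @export
apply_coupling <- function(model, A0_cell, coupling = size_coupling()) {
  stopifnot(inherits(model, "state_equation"), A0_cell > 0)
  m <- model
  m$A0 <- A0_cell
  if (!is.null(coupling)) {
    f <- (coupling$reference_area / A0_cell)^coupling$exponent
    if (model$family == "tait") m$alpha3 <- m$alpha3 * f
    else m$p_ref <- m$p_ref * f
  }
  m
}

#' Simulate one cell's deformation record
#'
#' Computes the noiseless final area from the size-coupled state equation at
#' the peak pressure, applies a multiplicative water-exchange fluctuation,
#' and optionally detaches the cell (with probability `detach_prob`), in
#' which case the effective maximum pressure is re-read at a random
#' pre-detachment frame of the ramp and the response re-evaluated there.
#'
#' @param cell one-row data frame (or list) with `cell_id`, `area_um2`,
#'   `perimeter_um`, `angle_deg`.
#' @param waveform a [generate_waveform()] result.
#' @param model a [state_equation()].
#' @param noise a [noise_spec()]; amplitude 0 gives the closed-form
#'   response.
#' @param coupling a [size_coupling()] or `NULL`.
#' @param detach_prob probability of detachment during the ramp.
#' @return One-row data frame (class `"deformation_record"`) with columns
#'   `cell_id`, `p0_kPa`, `pmax_kPa`, `A_initial_um2`, `A_final_um2`,
#'   `zeta`, `perimeter_um`, `angle_deg`, `detached`.
#' @export
simulate_response <- function(cell, waveform, model, noise = noise_spec(amplitude = 0),
                              coupling = size_coupling(), detach_prob = 0) {
  stopifnot(inherits(waveform, "loading_waveform"),
            inherits(model, "state_equation"))
  A0 <- cell$area_um2
  if (is.null(A0) || A0 <= 0) stop("cell area must be > 0")
  m <- apply_coupling(model, A0, coupling)
  detached <- detach_prob > 0 && stats::runif(1L) < detach_prob
  if (detached) {
    lo <- waveform$arrival_index
    hi <- waveform$peak_index - 1L
    j <- if (hi <= lo) lo else sample(lo:hi, 1L)
    p_eff <- waveform$pressures[j]
  } else {
    p_eff <- max(waveform$pressures)
  }
  p_eff <- max(p_eff, m$p0 * (1 + 1e-9))  # stay inside the family domain
  A_true <- eos_area(m, p_eff)
  A_final <- A_true * (1 + draw_fluctuation(noise))
  rec <- data.frame(cell_id = cell$cell_id, p0_kPa = m$p0, pmax_kPa = p_eff,
                    A_initial_um2 = A0, A_final_um2 = A_final,
                    zeta = A_final / A0, perimeter_um = cell$perimeter_um,
                    angle_deg = cell$angle_deg, detached = detached)
  class(rec) <- c("deformation_record", "data.frame")
  rec
}

#' Generate a full synthetic dataset of deformation records
#'
#' Draws a cell population, assigns cells to peak-pressure levels, builds a
#' constant-rate ramp per cell and simulates each deformation record. The
#' defaults reproduce the study design: 198 cells over the 15 pressure
#' levels of [default_pressure_levels()], a Tait-family response with size
#' coupling, 5% Gaussian (unidirectional-flow) fluctuation and a logistic
#' pressure-dependent detachment probability. Drawn peak pressures are
#' truncated to the configured span (defaults to the corrected study range
#' 156.48-3603.85 kPa) and must also lie within the pressure sensor range.
#'
#' @param config named list overriding any of the defaults; see
#'   `formals(generate_dataset)` fields in the returned `truth` for the
#'   resolved values. Principal entries: `population` ([population_spec()]),
#'   `levels` (data frame as [default_pressure_levels()]), `model`
#'   ([state_equation()]), `noise` ([noise_spec()]), `coupling`
#'   ([size_coupling()]), `pressure_range`, `sensor_range` (kPa),
#'   `pressure_cv` (overrides the level dispersions with a common
#'   coefficient of variation), `detach` (list `intercept`, `slope` of the
#'   logistic detachment model in `pmax`, or `NULL` for none), `duration`
#'   (ms), `fps`, `seed`.
#' @return List of class `"shock_dataset"` with `records` (data frame) and
#'   `truth` (full provenance: seed, model, coupling, noise, levels).
#' @export
generate_dataset <- function(config = list()) {
  cfg <- merge_config(default_dataset_config(), config)
  lv <- cfg$levels
  if (is.null(lv$label) || anyDuplicated(lv$label))
    stop("config error: pressure levels need unique labels")
  if (any(lv$center_kPa < cfg$sensor_range[1L]) ||
      any(lv$center_kPa > cfg$sensor_range[2L]))
    stop("config error: group center outside the configured sensor range")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- sum(lv$n)
  pop_spec <- cfg$population
  pop_spec$n_cells <- n
  pop_spec$seed <- NULL  # one dataset-level seed governs everything
  pop <- sample_cell_population(pop_spec)
  pop$group_label <- rep(lv$label, lv$n)

  sds <- if (!is.null(cfg$pressure_cv)) cfg$pressure_cv * lv$center_kPa else lv$sd_kPa
  records <- vector("list", n)
  for (i in seq_len(n)) {
    g <- match(pop$group_label[i], lv$label)
    repeat {
      pmax <- stats::rnorm(1L, lv$center_kPa[g], sds[g])
      if (pmax >= cfg$pressure_range[1L] && pmax <= cfg$pressure_range[2L] &&
          pmax > cfg$model$p0 * 1.05) break
    }
    wf <- generate_waveform(cfg$model$p0, pmax, cfg$duration, cfg$fps)
    dp <- if (is.null(cfg$detach)) 0 else
      stats::plogis(cfg$detach$intercept + cfg$detach$slope * pmax)
    rec <- simulate_response(pop[i, ], wf, cfg$model, cfg$noise,
                             cfg$coupling, detach_prob = dp)
    rec$group_label <- pop$group_label[i]
    records[[i]] <- rec
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  structure(list(records = records,
                 truth = list(seed = cfg$seed, model = unclass(cfg$model),
                              coupling = unclass(cfg$coupling),
                              noise = unclass(cfg$noise),
                              detach = cfg$detach, levels = lv,
                              pressure_range = cfg$pressure_range,
                              duration_ms = cfg$duration, fps = cfg$fps)),
            class = "shock_dataset")
}

#' Default configuration of [generate_dataset()]
#' @return Named list of defaults (documented there).
#' @export
default_dataset_config <- function() {
  list(population = population_spec(),
       levels = default_pressure_levels(),
       model = state_equation("tait"),
       noise = noise_spec(),
       coupling = size_coupling(),
       pressure_range = c(156.48, 3603.85),
       sensor_range = c(0, 34475),
       pressure_cv = NULL,
       detach = list(intercept = -4.5, slope = 6e-4),
       duration = 0.1, fps = 2e5, seed = NULL)
}

#' @export
print.shock_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "Synthetic shock-loading dataset: %d records, %d pressure levels\n",
    nrow(r), length(unique(r$group_label))))
  cat(sprintf("  pmax %.6g-%.6g kPa, zeta %.3g-%.3g, %d detached\n",
              min(r$pmax_kPa), max(r$pmax_kPa), min(r$zeta), max(r$zeta),
              sum(r$detached)))
  invisible(x)
}

#' Noiseless deformation-ratio surface of a generator configuration
#'
#' Evaluates `zeta(A0, p)` on a grid from a state equation plus size
#' coupling -- the response surface the synthetic records fluctuate around.
#'
#' @inheritParams eos_area
#' @param A0_grid initial areas (um^2).
#' @param p_grid pressures (kPa).
#' @param coupling a [size_coupling()] or `NULL`.
#' @return Matrix of `zeta` values, rows `A0_grid`, columns `p_grid`.
#' @export
zeta_surface <- function(model, A0_grid, p_grid, coupling = size_coupling()) {
  out <- matrix(NA_real_, length(A0_grid), length(p_grid))
  for (i in seq_along(A0_grid)) {
    m <- apply_coupling(model, A0_grid[i], coupling)
    out[i, ] <- eos_zeta(m, p_grid)
  }
  dimnames(out) <- list(signif(A0_grid, 6), signif(p_grid, 6))
  out
}

#' Read and write deformation-record tables
#'
#' Plain-CSV serialization of the record schema (`cell_id`, `group_label`,
#' `p0_kPa`, `pmax_kPa`, `A_initial_um2`, `A_final_um2`, `zeta`,
#' `perimeter_um`, `angle_deg`, `detached`).
#'
#' @param records data frame of records.
#' @param path file path.
#' @return `read_records` returns the data frame; `write_records` returns
#'   `path` invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
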
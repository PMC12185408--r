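# Parameter-recovery harness: generate -> (optionally image) -> fit ->
# tabulate bias, RMSE and interval coverage across replicates.

#' Re-measure a record through the imaging pipeline
#'
#' Renders the record's initial and final states as synthetic frames,
#' segments them and returns the record with areas and `zeta` replaced by
#' the imaging measurements -- the full render -> segment -> measure round
#' trip for one cell.
#'
#' @param record one-row deformation record.
#' @param spec an [image_spec()].
#' @param noise_sd sensor noise fraction, see [render_frames()].
#' @return The record with measured `A_initial_um2`, `A_final_um2`, `zeta`,
#'   plus `A_initial_true`/`A_final_true`; or `NULL` when the cell (at its
#'   final area) does not fit the canvas.
#' @export
measure_record_by_imaging <- function(record, spec = image_spec(),
                                      noise_sd = 0.01) {
  sfun <- blob_shape(seed = 7901L + as.integer(record$cell_id),
                     angle = record$angle_deg %||% 0)
  unit_area <- attr(sfun, "unit_area")
  phi <- seq(0, 2 * pi, length.out = 721L)[-721L]
  smax <- max(sfun(phi))
  center <- c((spec$width - 1L) / 2, (spec$height - 1L) / 2) * spec$pixel_size
  half_min <- min(spec$height, spec$width) / 2 * spec$pixel_size
  Amax <- max(record$A_initial_um2, record$A_final_um2)
  if (sqrt(Amax / unit_area) * smax > half_min - spec$pixel_size)
    return(NULL)
  maxI <- 2^spec$bit_depth - 1
  measure_one <- function(area) {
    covg <- rasterize_blob(sqrt(area / unit_area), sfun, center, spec)
    img <- 0.18 + covg * (0.62 - 0.18)
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    frame <- round(pmin(pmax(img, 0), 1) * maxI)
    seg <- segment_cell(matrix(frame, spec$height, spec$width),
                        spec$pixel_size)
    if (!seg$found) return(NA_real_)
    seg$area_um2
  }
  ai <- measure_one(record$A_initial_um2)
  af <- measure_one(record$A_final_um2)
  if (is.na(ai) || is.na(af)) return(NULL)
  out <- record
  out$A_initial_true <- record$A_initial_um2
  out$A_final_true <- record$A_final_um2
  out$A_initial_um2 <- ai
  out$A_final_um2 <- af
  out$zeta <- af / ai
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly generates synthetic datasets from known ground truth,
#' optionally routes every record through the imaging round trip, fits the
#' state equation, and tabulates per-parameter bias, RMSE, median absolute
#' relative error and nominal-95% Wald interval coverage.
#'
#' @param config named list: `family` (fit family; also the generator's
#'   model family unless `model` is given), `model` (true
#'   [state_equation()]), `coupling`, `noise_amplitude`, `n_replicates`,
#'   `seed`, `imaging` (logical), `levels`, `population`, `level`
#'   (confidence level, default 0.95), plus any [generate_dataset()]
#'   overrides under `dataset`.
#' @return Object of class `"recovery_report"`: `summary` (per-parameter
#'   table) and `estimates` (per-replicate draws).
#' @export
recovery_harness <- function(config = list()) {
  cfg <- merge_config(list(
    family = "tait", model = state_equation("tait"),
    coupling = size_coupling(), noise_amplitude = 0.05,
    n_replicates = 50L, seed = 1L, imaging = FALSE, level = 0.95,
    levels = default_pressure_levels(), population = population_spec(),
    dataset = list()), config)
  true <- switch(cfg$family,
    tait = c(kappa = cfg$model$kappa, alpha3 = cfg$model$alpha3),
    exponential = c(Bprime = cfg$model$Bprime, p_ref = cfg$model$p_ref),
    li = c(alpha1 = cfg$model$alpha1))
  ests <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    ds_cfg <- merge_config(list(
      seed = (cfg$seed + 7919L * r) %% 2147483647L,
      model = cfg$model, coupling = cfg$coupling,
      levels = cfg$levels, population = cfg$population,
      noise = noise_spec(amplitude = cfg$noise_amplitude)), cfg$dataset)
    ds <- generate_dataset(ds_cfg)
    recs <- ds$records
    if (isTRUE(cfg$imaging)) {
      out <- lapply(seq_len(nrow(recs)), function(i)
        measure_record_by_imaging(recs[i, ]))
      recs <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
    }
    fit <- fit_state_equation(recs, cfg$family, coupling = cfg$coupling,
                              seed = ds_cfg$seed)
    if (!fit$converged) next
    ci <- confint(fit, level = cfg$level)
    row <- data.frame(replicate = r, parameter = names(true),
                      true = unname(true),
                      estimate = unname(fit$coefficients[names(true)]),
                      se = unname(fit$se[names(true)]),
                      lower = ci[names(true), 1L], upper = ci[names(true), 2L])
    ests[[r]] <- row
  }
  est <- do.call(rbind, ests)
  summ <- do.call(rbind, lapply(split(est, est$parameter), function(e) {
    err <- e$estimate - e$true
    data.frame(parameter = e$parameter[1L], true = e$true[1L],
               n_fits = nrow(e), bias = mean(err),
               rmse = sqrt(mean(err^2)),
               median_abs_rel_error = stats::median(abs(err / e$true)),
               coverage = mean(e$lower <= e$true & e$true <= e$upper))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, estimates = est,
                 config = cfg[c("family", "noise_amplitude", "n_replicates",
                                "imaging", "level", "seed")]),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %s family, noise %.3g, %d replicates%s\n",
              x$config$family, x$config$noise_amplitude,
              x$config$n_replicates,
              if (isTRUE(x$config$imaging)) " (imaging round trip)" else ""))
  print(transform(x$summary, bias = signif(bias, 4), rmse = signif(rmse, 4),
                  median_abs_rel_error = signif(median_abs_rel_error, 4)),
        row.names = FALSE)
  invisible(x)
}
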
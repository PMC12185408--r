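# End-to-end pipeline: simulate -> (group) -> (fit) -> report, with
# validated configuration, per-stage derived seeds and a run manifest.

# Deterministic per-stage seed: a small polynomial hash of the stage name
# folded into the global seed, kept below 2^31.
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(global_seed) * 2654435761 + h * 97) %% 2147483629)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every missing field with the package defaults (the study-design
#' pressure levels, acquisition geometry and pressure span) and checks the
#' result for contradictions. On failure returns the full structured error
#' list -- never a partially defaulted configuration.
#'
#' @param config named list; see [generate_dataset()] for the dataset
#'   fields, plus `fit_family`, `stages` (subset of `"simulate"`,
#'   `"group"`, `"fit"`, `"report"`), `cv_max`, `min_size`, `seed`.
#' @return The normalized configuration (class `"run_config"`), or an
#'   object of class `"config_errors"` whose `errors` field names each
#'   offending path.
#' @export
validate_config <- function(config = list()) {
  defaults <- c(default_dataset_config(),
                list(fit_family = "tait",
                     stages = c("simulate", "group", "fit", "report"),
                     cv_max = 0.05, min_size = 4L, seed = 20260920L,
                     image = image_spec()))
  # the default end-to-end run draws level pressures with a CV-compliant
  # spread so that regrouping the simulated records reproduces the levels
  defaults$pressure_cv <- 0.01
  defaults["detach"] <- list(NULL)
  cfg <- merge_config(defaults, config)
  errs <- character(0)
  lv <- cfg$levels
  if (is.null(lv$label) || is.null(lv$center_kPa) || is.null(lv$n))
    errs <- c(errs, "levels: must have label, center_kPa, n")
  else {
    if (anyDuplicated(lv$label))
      errs <- c(errs, "levels.label: duplicate group labels")
    if (any(lv$center_kPa <= cfg$model$p0))
      errs <- c(errs, "levels.center_kPa / model.p0: peak pressure below baseline")
    if (any(lv$center_kPa < cfg$sensor_range[1L] |
            lv$center_kPa > cfg$sensor_range[2L]))
      errs <- c(errs, "levels.center_kPa / sensor_range: center outside sensor range")
    if (any(lv$n < 1L)) errs <- c(errs, "levels.n: group sizes must be >= 1")
  }
  if (cfg$pressure_range[1L] >= cfg$pressure_range[2L])
    errs <- c(errs, "pressure_range: lower bound not below upper bound")
  if (cfg$duration <= 0) errs <- c(errs, "duration: must be > 0")
  if (cfg$fps * cfg$duration / 1000 < 2)
    errs <- c(errs, "fps / duration: too few frames on the ramp")
  if (!inherits(cfg$population, "population_spec"))
    errs <- c(errs, "population: not a population_spec")
  if (!inherits(cfg$model, "state_equation"))
    errs <- c(errs, "model: not a state_equation")
  if (!cfg$fit_family %in% c("tait", "exponential", "li"))
    errs <- c(errs, "fit_family: unknown family")
  if (!all(cfg$stages %in% c("simulate", "group", "fit", "report")))
    errs <- c(errs, "stages: unknown stage name")
  if (length(errs))
    return(structure(list(errors = errs), class = "config_errors"))
  structure(cfg, class = "run_config")
}

#' @export
print.config_errors <- function(x, ...) {
  cat("Invalid pipeline configuration:\n")
  for (e in x$errors) cat("  -", e, "\n")
  invisible(x)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order -- simulate (records CSV +
#' ground-truth JSON), group (groups CSV), fit (fit JSON) and report
#' (figures and a manifest with versions, seeds and file digests). Every
#' stochastic stage derives its seed deterministically from the global
#' seed, so a given seed reproduces the run byte-for-byte. A stage failure
#' aborts with a stage-tagged error; outputs of completed stages remain on
#' disk.
#'
#' @param config a list passed to [validate_config()], or a ready
#'   `run_config`.
#' @param out_dir output directory (created if needed).
#' @return Object of class `"pipeline_run"` with the stage objects and
#'   file paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("cellshock_run_")) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (inherits(cfg, "config_errors")) {
    print(cfg)
    stop("invalid configuration")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  objects <- list()
  seeds <- list()
  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ds <- NULL
  if ("simulate" %in% cfg$stages) {
    seeds$simulate <- stage_seed(cfg$seed, "simulate")
    ds <- run_stage("simulate", function() {
      cfg2 <- unclass(cfg)
      cfg2$seed <- seeds$simulate
      generate_dataset(cfg2)
    })
    paths$records <- file.path(out_dir, "records.csv")
    write_records(ds$records, paths$records)
    paths$truth <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(ds$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    objects$dataset <- ds
  } else {
    if (is.null(cfg$records_csv))
      stop("[stage simulate] disabled and no records_csv provided")
    ds <- list(records = read_records(cfg$records_csv))
  }

  grouping <- NULL
  if ("group" %in% cfg$stages) {
    grouping <- run_stage("group", function()
      group_by_pressure(ds$records, cfg$cv_max, cfg$min_size))
    paths$groups <- file.path(out_dir, "groups.csv")
    utils::write.csv(grouping$groups, paths$groups, row.names = FALSE)
    objects$grouping <- grouping
    objects$group_lines <- run_stage("group", function()
      fit_group_lines(grouping))
  }

  fit <- NULL
  if ("fit" %in% cfg$stages) {
    seeds$fit <- stage_seed(cfg$seed, "fit")
    fit <- run_stage("fit", function()
      fit_state_equation(ds$records, cfg$fit_family,
                         coupling = cfg$coupling, seed = seeds$fit))
    paths$fits <- file.path(out_dir, "fits.json")
    jsonlite::write_json(
      list(family = fit$family, converged = fit$converged,
           coefficients = as.list(fit$coefficients),
           std_errors = as.list(fit$se), rss = fit$rss, sigma = fit$sigma,
           n = fit$n, seed = seeds$fit),
      paths$fits, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    objects$fit <- fit
  }

  if ("report" %in% cfg$stages) {
    run_stage("report", function() {
      if (!is.null(grouping)) {
        paths$fig_zeta <<- file.path(out_dir, "fig_zeta_vs_area.png")
        grDevices::png(paths$fig_zeta, 900, 600)
        plot_zeta_groups(grouping, objects$group_lines)
        grDevices::dev.off()
      }
      if (!is.null(fit) && fit$converged) {
        paths$fig_eos <<- file.path(out_dir, "fig_area_pressure.png")
        grDevices::png(paths$fig_eos, 900, 600)
        plot_area_pressure(fit)
        grDevices::dev.off()
        paths$fig_traj <<- file.path(out_dir, "fig_trajectory.png")
        grDevices::png(paths$fig_traj, 900, 600)
        m <- eos_fit_model(fit, stats::median(ds$records$A_initial_um2))
        plot(isobaric_trajectory(m, max(ds$records$pmax_kPa), 40L))
        grDevices::dev.off()
      }
      invisible(NULL)
    })
    manifest <- list(
      package = "cellshock",
      package_version = as.character(utils::packageVersion("cellshock")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      global_seed = cfg$seed, stage_seeds = seeds,
      files = lapply(paths, function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p)),
             bytes = file.size(p))))
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  structure(list(config = cfg, out_dir = out_dir, paths = paths,
                 objects = objects, seeds = seeds),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run ->", x$out_dir, "\n")
  cat("  stages:", paste(x$config$stages, collapse = ", "), "\n")
  cat("  outputs:", paste(basename(unlist(x$paths)), collapse = ", "), "\n")
  invisible(x)
}

plot_zeta_groups <- function(grouping, lines_tab = NULL) {
  recs <- grouping$records
  labs <- grouping$groups$label
  cols <- grDevices::hcl.colors(max(length(labs), 2L), "Zissou 1")
  ci <- match(recs$pressure_group, labs)
  graphics::plot(recs$A_initial_um2, recs$zeta,
                 col = ifelse(is.na(ci), "grey70", cols[ci]), pch = 20,
                 xlab = expression(A[initial] ~ (mu * m^2)),
                 ylab = expression(zeta),
                 main = "Deformation ratio by pressure level")
  if (!is.null(lines_tab)) {
    for (k in seq_len(nrow(lines_tab))) {
      if (is.na(lines_tab$slope[k])) next
      graphics::abline(lines_tab$intercept[k], lines_tab$slope[k],
                       col = cols[k], lwd = 1.5)
    }
  }
}

plot_area_pressure <- function(fit) {
  d <- fit$data
  A0 <- stats::median(d$A_initial_um2)
  m <- eos_fit_model(fit, A0)
  pg <- seq(m$p0 * 1.01, max(d$pmax_kPa), length.out = 200L)
  dom <- eos_domain(m)
  pg <- pg[pg > dom[1L] & pg < dom[2L]]
  A <- eos_area(m, pg)
  graphics::plot(pg, A, type = "l", lwd = 2, col = "#d95f02",
                 xlab = "pressure (kPa)", ylab = expression(A ~ (mu * m^2)),
                 main = sprintf("Fitted area-pressure curve (A0 = %.0f um^2)", A0))
  infl <- find_inflection(m, range(pg))
  if (infl$exists) {
    graphics::points(infl$p_k, infl$A_k, pch = 4, cex = 2, lwd = 2)
    graphics::text(infl$p_k, infl$A_k, "  inflection", adj = 0)
  }
}
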
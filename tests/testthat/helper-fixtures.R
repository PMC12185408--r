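# Shared fixtures, built in code.

# star-shaped random polygon about the origin: jittered angular grid keeps
# every angular gap below pi, so the polygon is always simple
random_polygon <- function(n = 10L, r_mean = 10, r_jitter = 0.4) {
  phi <- 2 * pi * (seq_len(n) - 1L) / n +
    stats::runif(n, 0, 0.9 * 2 * pi / n)
  r <- r_mean * (1 + stats::runif(n, -r_jitter, r_jitter))
  cbind(r * cos(phi), r * sin(phi))
}

regular_polygon <- function(n = 64L, r = 10) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(phi), r * sin(phi))
}

# circular-cell frame without sensor noise: exact pixel-coverage rendering
disk_frame <- function(radius_px, spec = image_spec(),
                       center_px = c((spec$width - 1) / 2, (spec$height - 1) / 2),
                       noise_sd = 0) {
  sfun <- blob_shape(1L, elongation_amp = 0, harmonic_amps = c(0, 0, 0))
  covg <- cellshock:::rasterize_blob(radius_px * spec$pixel_size, sfun,
                                     center_px * spec$pixel_size, spec)
  img <- 0.18 + covg * (0.62 - 0.18)
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  maxI <- 2^spec$bit_depth - 1
  matrix(round(pmin(pmax(img, 0), 1) * maxI), spec$height, spec$width)
}

# compact imaging study configuration: smaller cells that fit the canvas
# with moderate expansion (exponential family, see the methods vignette)
imaging_study_config <- function(seed, n_scale = 1) {
  lv <- default_pressure_levels()
  lv$n <- pmax(2L, round(lv$n * n_scale))
  list(seed = seed,
       population = population_spec(area_mean = 280, area_sd = 40),
       model = state_equation("exponential", A0 = 280, p0 = 101.325,
                              p_ref = 5000, Bprime = -0.25),
       coupling = size_coupling(reference_area = 280),
       noise = noise_spec(amplitude = 0.02),
       detach = NULL, levels = lv)
}
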
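test_that("population sampling honours the spec and its invariants", {
  expect_equal(nrow(sample_cell_population(population_spec(0))), 0L)
  expect_identical(population_spec()$n_cells, 198L)  # study scale
  expect_error(population_spec(area_sd = -1), "deviations")
  expect_error(population_spec(angle_low = 90, angle_high = 20), "angle")
  s <- population_spec(50, seed = 99)
  expect_identical(sample_cell_population(s), sample_cell_population(s))
  # law of large numbers on the truncated-Gaussian area
  big <- sample_cell_population(population_spec(1e4, seed = 5))
  expect_lt(abs(mean(big$area_um2) - 550), 3 * 150 / sqrt(1e4))
  expect_true(all(big$area_um2 > 0 & big$perimeter_um > 0))
  expect_true(all(big$angle_deg >= 0 & big$angle_deg < 180))
})

test_that("waveforms are constant-rate ramps sampled at the frame rate", {
  wf <- generate_waveform(100, 3100, duration = 0.1, fps = 2e5)
  ramp <- wf$pressures[-(1:10)]
  expect_length(ramp, 21L)              # 20 intervals at 2e5 fps over 0.1 ms
  expect_identical(ramp[1L], 100)       # ramp starts at baseline exactly
  expect_equal(wf$p_dot, 30000)         # (3100 - 100) / 0.1 kPa/ms
  expect_equal(unique(round(diff(ramp), 9)), 150)
  expect_true(all(diff(wf$pressures[wf$arrival_index:wf$peak_index]) >= 0))
  expect_identical(wf$peak_index, which.max(wf$pressures))
  expect_true(all(diff(wf$times) > 0))
  expect_error(generate_waveform(100, 300, duration = 0.001, fps = 1000),
               "too few frames")
})

test_that("noiseless responses equal the closed-form state equation", {
  # B' = 0 exponential response at (essentially) baseline pressure: zeta = 1
  m0 <- state_equation("exponential", A0 = 300, p0 = 100, Bprime = 0)
  expect_equal(eos_zeta(m0, 100), 1)
  cell <- data.frame(cell_id = 1L, area_um2 = 300, perimeter_um = 65,
                     angle_deg = 10)
  wf <- generate_waveform(100, 100 + 1e-9, duration = 0.1, fps = 2e5)
  rec <- simulate_response(cell, wf, m0, noise_spec(amplitude = 0),
                           coupling = NULL)
  expect_equal(rec$zeta, 1, tolerance = 1e-8)
  # whole noiseless dataset agrees with the coupled closed form
  ds <- generate_dataset(list(seed = 21, noise = noise_spec(amplitude = 0),
                              detach = NULL))
  truth <- ds$truth
  z_model <- vapply(seq_len(nrow(ds$records)), function(i) {
    r <- ds$records[i, ]
    m <- apply_coupling(state_equation("tait", A0 = r$A_initial_um2,
                                       p0 = r$p0_kPa,
                                       kappa = truth$model$kappa,
                                       alpha3 = truth$model$alpha3),
                        r$A_initial_um2, size_coupling())
    eos_zeta(m, r$pmax_kPa)
  }, numeric(1L))
  expect_equal(ds$records$zeta, z_model, tolerance = 1e-12)
})

test_that("fluctuations are centred on the closed form and two-sided", {
  cell <- data.frame(cell_id = 1L, area_um2 = 300, perimeter_um = 65,
                     angle_deg = 10)
  m <- state_equation("tait", A0 = 300, p0 = 100)
  wf <- generate_waveform(100, 900, 0.1, 2e5)
  z0 <- eos_zeta(apply_coupling(m, 300, size_coupling()), 900)
  set.seed(31)
  z <- replicate(500, simulate_response(cell, wf, m,
                                        noise_spec(amplitude = 0.05))$zeta)
  expect_lt(abs(mean(z) - z0), 3 * 0.05 * z0 / sqrt(500))
  expect_true(any(z < z0) && any(z > z0))
  # near-unity baseline response: both expansion and shrinkage occur
  mflat <- state_equation("exponential", A0 = 300, p0 = 100, p_ref = 1e6)
  set.seed(32)
  zf <- replicate(200, simulate_response(cell, wf, mflat,
                                         noise_spec(amplitude = 0.05))$zeta)
  expect_true(any(zf < 1) && any(zf > 1))
})

test_that("dataset generation is deterministic with faithful defaults", {
  cfg <- default_dataset_config()
  expect_equal(cfg$pressure_range, c(156.48, 3603.85))  # corrected span
  expect_equal(nrow(cfg$levels), 15L)
  expect_equal(sum(cfg$levels$n), 198L)
  d1 <- generate_dataset(list(seed = 8))
  d2 <- generate_dataset(list(seed = 8))
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth$seed, 8)
  # one zero-dispersion group: all records share the centre pressure
  one <- generate_dataset(list(
    seed = 3, levels = data.frame(label = "only", center_kPa = 700,
                                  sd_kPa = 0, n = 6L), detach = NULL))
  expect_equal(unique(one$records$pmax_kPa), 700)
  expect_error(generate_dataset(list(
    levels = data.frame(label = "bad", center_kPa = 99999, sd_kPa = 1, n = 4L))),
    "sensor range")
})

test_that("rendered masks track the intended area within two percent", {
  cfg <- imaging_study_config(seed = 17)
  ds <- generate_dataset(cfg)
  r <- ds$records[c(1, 30, 90), ]
  wf <- generate_waveform(101.325, max(r$pmax_kPa), 0.1, 2e5)
  for (i in seq_len(nrow(r))) {
    rec <- r[i, ]
    cell <- data.frame(cell_id = rec$cell_id, area_um2 = rec$A_initial_um2,
                       angle_deg = rec$angle_deg)
    rn <- render_frames(cell, rec, wf, noise_sd = 0)
    px2 <- image_spec()$pixel_size^2
    for (t in c(1L, dim(rn$frames)[3L])) {
      expect_equal(sum(rn$masks[, , t]) * px2, rn$areas_um2[t],
                   tolerance = 0.02)
      # ground-truth polygon area is exact
      expect_equal(polygon_area(rn$polygons[[t]]), rn$areas_um2[t],
                   tolerance = 1e-10)
    }
  }
  expect_equal(dim(rn$frames)[1:2], c(48L, 160L))
  huge <- r[1, ]; huge$A_initial_um2 <- 5000; huge$A_final_um2 <- 5000
  cellh <- data.frame(cell_id = 1L, area_um2 = 5000, angle_deg = 0)
  expect_error(render_frames(cellh, huge, wf), "larger than canvas")
})

test_that("frame stacks round-trip through 16-bit TIFF", {
  cfg <- imaging_study_config(seed = 23)
  ds <- generate_dataset(cfg)
  rec <- ds$records[1, ]
  cell <- data.frame(cell_id = rec$cell_id, area_um2 = rec$A_initial_um2,
                     angle_deg = rec$angle_deg)
  wf <- generate_waveform(101.325, rec$pmax_kPa, 0.1, 2e5, baseline_frames = 2L)
  rn <- render_frames(cell, rec, wf, noise_sd = 0.005)
  fp <- tempfile(fileext = ".tif"); mp <- tempfile(fileext = ".tif")
  write_frames(rn, fp, mp)
  back <- read_frames(fp)
  expect_equal(dim(back), dim(rn$frames))
  expect_equal(back, rn$frames, tolerance = 1e-7)
  expect_true(max(rn$frames) <= 2^12 - 1)
})
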
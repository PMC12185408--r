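test_that("segmentation recovers a rendered disk within two percent", {
  spec <- image_spec()
  frame <- disk_frame(10, spec)
  seg <- segment_cell(frame, spec$pixel_size)
  expect_true(seg$found)
  expect_equal(seg$area_px, pi * 100, tolerance = 0.02)
  expect_equal(seg$area_um2, pi * 100 * spec$pixel_size^2, tolerance = 0.02)
})

test_that("blank and degenerate frames give a no-cell result", {
  set.seed(2)
  seg <- segment_cell(blank_frame(), 0.75)
  expect_false(seg$found)
  expect_false(segment_cell(matrix(7, 48, 160), 0.75)$found)
})

test_that("the largest connected component is the segmented cell", {
  spec <- image_spec()
  big <- disk_frame(sqrt(400 / pi), spec, center_px = c(40, 24))
  small <- disk_frame(sqrt(50 / pi), spec, center_px = c(120, 24))
  frame <- pmax(big, small)
  seg <- segment_cell(frame, spec$pixel_size)
  expect_true(seg$found)
  expect_equal(seg$area_px, 400, tolerance = 0.05)
  # centroid sits on the larger blob
  cen <- colMeans(seg$contour) / spec$pixel_size
  expect_lt(abs(cen[1L] - 40), 3)
})

test_that("shape descriptors are exact on canonical polygons", {
  sq <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20))
  sh <- measure_shape(sq)
  expect_equal(sh$area, 400)
  expect_equal(sh$perimeter, 80)
  expect_equal(sh$solidity, 1)
  expect_equal(sh$convexity, 1)
  expect_equal(sh$compactness, 1 / sh$circularity)
  # isoperimetric limit: circularity -> 1 with vertex count
  circ <- vapply(c(16L, 64L, 1024L), function(n)
    measure_shape(regular_polygon(n, 10))$circularity, numeric(1L))
  expect_true(all(diff(circ) > 0))
  expect_equal(circ[3L], 1, tolerance = 1e-5)
  # five-pointed star: strictly non-convex
  phi <- seq(0, 2 * pi, length.out = 11L)[-11L]
  star <- cbind(ifelse(seq_len(10L) %% 2 == 1, 10, 4) * cos(phi),
                ifelse(seq_len(10L) %% 2 == 1, 10, 4) * sin(phi))
  sh2 <- measure_shape(star)
  expect_lt(sh2$convexity, 1)
  expect_lt(sh2$solidity, 1)
  # convex polygons: convexity = solidity = 1 to float precision
  set.seed(5)
  for (i in 1:10) {
    pts <- matrix(stats::rnorm(40), ncol = 2L)
    hull <- pts[grDevices::chull(pts), ]
    shc <- measure_shape(hull)
    expect_equal(shc$convexity, 1, tolerance = 1e-12)
    expect_equal(shc$solidity, 1, tolerance = 1e-12)
  }
  expect_error(measure_shape(cbind(c(0, 2, 2, 0), c(0, 2, 0, 2))),
               "self-intersecting")
})

test_that("elongation and angle follow the principal axis", {
  th <- 35
  rot <- matrix(c(cos(th * pi / 180), sin(th * pi / 180),
                  -sin(th * pi / 180), cos(th * pi / 180)), 2L)
  ell <- regular_polygon(256L, 1)
  ell[, 1L] <- ell[, 1L] * 12; ell[, 2L] <- ell[, 2L] * 5
  sh <- measure_shape(t(rot %*% t(ell)))
  expect_equal(sh$angle, th, tolerance = 0.5)
  expect_equal(sh$elongation, 1 - (5 / 12)^2, tolerance = 1e-3)
})

test_that("area and perimeter are invariant to translation and 90-degree rotation", {
  spec <- image_spec()
  base <- disk_frame(9, spec, center_px = c(60, 24))
  shifted <- disk_frame(9, spec, center_px = c(95, 20))
  s1 <- segment_cell(base, spec$pixel_size)$shape
  s2 <- segment_cell(shifted, spec$pixel_size)$shape
  expect_equal(s2$area, s1$area, tolerance = 0.01)
  expect_equal(s2$perimeter, s1$perimeter, tolerance = 0.01)
  # 90-degree rotation of the pixel grid
  sq <- image_spec(height = 64L, width = 64L)
  sfun <- blob_shape(3L, angle = 20)
  covg <- cellshock:::rasterize_blob(8 * sq$pixel_size, sfun,
                                     c(31.5, 31.5) * sq$pixel_size, sq)
  f <- 0.18 + covg * 0.44
  rot <- t(f)[, rev(seq_len(64L))]  # 90-degree rotation
  sa <- segment_cell(f, sq$pixel_size)$shape
  sb <- segment_cell(rot, sq$pixel_size)$shape
  expect_equal(sb$area, sa$area, tolerance = 0.01)
  expect_equal(sb$perimeter, sa$perimeter, tolerance = 0.01)
  expect_equal((sa$angle + 90) %% 180, sb$angle, tolerance = 2)
})

test_that("frame selection applies the arrival, peak and detachment rules", {
  cfg <- imaging_study_config(seed = 41)
  ds <- generate_dataset(cfg)
  rec <- ds$records[5, ]
  cell <- data.frame(cell_id = rec$cell_id, area_um2 = rec$A_initial_um2,
                     angle_deg = rec$angle_deg)
  wf <- generate_waveform(101.325, rec$pmax_kPa, 0.1, 2e5,
                          baseline_frames = 5L, baseline_noise_sd = 0.3)
  set.seed(1)
  rn <- render_frames(cell, rec, wf, model = cfg$model,
                      coupling = cfg$coupling)
  sel <- select_frames(rn$frames, wf)
  expect_identical(sel$initial_index, wf$arrival_index - 1L)  # frame before arrival
  expect_identical(sel$final_index, wf$peak_index)            # nearest the peak
  expect_false(sel$detached)
  expect_equal(sel$p_at_final, rec$pmax_kPa)
  # zeta round trip against generator ground truth
  z <- compute_zeta(sel$initial_shape, sel$final_shape)
  expect_equal(z, rec$zeta, tolerance = 0.03)
  # detachment: cell vanishes mid-ramp -> last adhered frame is terminal
  rn2 <- rn
  gone <- blank_frame(noise_sd = 0)
  for (t in 18:dim(rn2$frames)[3L]) rn2$frames[, , t] <- gone
  sel2 <- select_frames(rn2$frames, wf)
  expect_true(sel2$detached)
  expect_identical(sel2$final_index, 17L)
  expect_equal(sel2$p_at_final, wf$pressures[17L])
  # arrival detection failure
  flat <- wf
  flat$pressures[] <- 101.325
  flat$peak_index <- length(flat$pressures)
  expect_error(select_frames(rn$frames, flat), "arrival never detected")
})

test_that("zeta is the final-to-initial area ratio with guarded domain", {
  expect_equal(compute_zeta(300, 300), 1)
  expect_equal(compute_zeta(300, 450), 1.5)
  expect_error(compute_zeta(0, 10), "initial area")
})
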
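# Synthetic high-speed frame rendering: star-convex perturbed blobs whose
# area tracks the loading response, on a small bright-field-like canvas,
# with paired ground-truth masks and polygons.

#' Image-geometry specification
#'
#' Defaults mirror the acquisition geometry: 160 x 48 pixels, 0.75 um pixel
#' side, 12-bit depth, 2e5 frames per second. Pixel coordinates are 0-based
#' `(row, col)` with the origin at the top-left; physical positions are
#' `(col * pixel_size, row * pixel_size)` um.
#'
#' @param height,width canvas size in pixels.
#' @param pixel_size pixel side length (um).
#' @param bit_depth sensor bit depth; intensities lie in
#'   `[0, 2^bit_depth - 1]` (stored in 16-bit containers on disk).
#' @param fps frame rate (frames per second).
#' @return Object of class `"image_spec"`.
#' @export
image_spec <- function(height = 48L, width = 160L, pixel_size = 0.75,
                       bit_depth = 12L, fps = 2e5) {
  stopifnot(height >= 4L, width >= 4L, pixel_size > 0, bit_depth >= 1L)
  structure(list(height = as.integer(height), width = as.integer(width),
                 pixel_size = pixel_size, bit_depth = as.integer(bit_depth),
                 fps = fps),
            class = "image_spec")
}

#' Star-convex blob shape
#'
#' A radial profile `s(phi) = 1 + a2*cos(2*(phi - angle)) + sum_k a_k *
#' cos(k*phi + psi_k)` whose random higher harmonics break the strict
#' geometric perimeter-area linkage of a circle. Amplitudes are kept small
#' enough that the profile stays positive and star-convex about its centre.
#'
#' @param seed integer seed for the random harmonics.
#' @param angle orientation of the elongation axis (degrees).
#' @param elongation_amp amplitude of the order-2 (elongation) harmonic.
#' @param harmonic_amps amplitudes of orders 3..5; default drawn uniformly
#'   in `[0.02, 0.06]`.
#' @return Function `s(phi)` (phi in radians) with attribute
#'   `"unit_area"` = area enclosed by `r = s(phi)`.
#' @export
blob_shape <- function(seed = 1L, angle = 0, elongation_amp = 0.12,
                       harmonic_amps = NULL) {
  set.seed(seed)
  k <- 3:5
  if (is.null(harmonic_amps)) harmonic_amps <- stats::runif(3L, 0.02, 0.06)
  psi <- stats::runif(3L, 0, 2 * pi)
  th <- angle * pi / 180
  s <- function(phi) {
    v <- 1 + elongation_amp * cos(2 * (phi - th))
    for (j in seq_along(k)) v <- v + harmonic_amps[j] * cos(k[j] * phi + psi[j])
    v
  }
  phi <- seq(0, 2 * pi, length.out = 2049L)[-2049L]
  attr(s, "unit_area") <- sum(s(phi)^2) * (2 * pi / 2048) / 2
  s
}

# Coverage rasterization of r = R*s(phi) centred at (cx, cy) um, by n x n
# subpixel sampling. Returns the fractional-coverage matrix (height x width).
rasterize_blob <- function(R_um, sfun, center_um, spec, supersample = 3L) {
  px <- spec$pixel_size
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * px
  rows <- (seq_len(spec$height) - 1L) * px
  cols <- (seq_len(spec$width) - 1L) * px
  cov <- matrix(0, spec$height, spec$width)
  for (oy in off) for (ox in off) {
    dy <- rows + oy - center_um[2L]
    dx <- cols + ox - center_um[1L]
    DX <- matrix(dx, spec$height, spec$width, byrow = TRUE)
    DY <- matrix(dy, spec$height, spec$width)
    phi <- atan2(DY, DX)
    rr <- R_um * sfun(phi)
    cov <- cov + (DX^2 + DY^2 <= rr^2)
  }
  cov / supersample^2
}

blob_polygon <- function(R_um, sfun, center_um, n = 360L, target_area = NULL) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- R_um * sfun(phi)
  poly <- cbind(r * cos(phi), r * sin(phi))
  if (!is.null(target_area))  # make the polygon area exact, not just the
    poly <- poly * sqrt(target_area / polygon_area(poly))  # smooth limit
  cbind(center_um[1L] + poly[, 1L], center_um[2L] + poly[, 2L])
}

#' Render a synthetic high-speed image stack for one cell
#'
#' Draws one star-convex blob per waveform sample, with the enclosed area
#' following the loading response: constant at `A_initial` before wave
#' arrival, then interpolated along the pressure ramp (through the state
#' equation when `model` is supplied, linearly in pressure otherwise) and
#' blended so the frame at peak (or pre-detachment) pressure encloses
#' exactly `A_final`. Intensities are background plus
#' coverage-weighted foreground with additive Gaussian sensor noise, on the
#' `[0, 2^bit_depth - 1]` scale. Detached cells vanish from the frame after
#' the detachment instant.
#'
#' @param cell one-row data frame with `cell_id`, `area_um2`, `angle_deg`.
#' @param record the cell's [simulate_response()] record.
#' @param waveform the cell's [generate_waveform()] waveform.
#' @param spec an [image_spec()].
#' @param model optional [state_equation()] used for the in-ramp area
#'   interpolation.
#' @param coupling a [size_coupling()] used with `model`.
#' @param noise_sd additive sensor noise, as a fraction of full scale.
#' @param fg,bg foreground/background levels, fractions of full scale.
#' @param supersample subpixel sampling factor per axis.
#' @return List with `frames` (height x width x n array, digital numbers),
#'   `masks` (logical array, coverage >= 0.5), `polygons` (ground-truth
#'   vertex lists, um), `areas_um2` (intended area per frame; `NA` after
#'   detachment), `detach_frame` and `spec`.
#' @export
render_frames <- function(cell, record, waveform, spec = image_spec(),
                          model = NULL, coupling = size_coupling(),
                          noise_sd = 0.01, fg = 0.62, bg = 0.18,
                          supersample = 3L) {
  stopifnot(inherits(spec, "image_spec"))
  p <- waveform$pressures
  nf <- length(p)
  A0 <- record$A_initial_um2
  Afin <- record$A_final_um2
  # frame index at which the effective maximum pressure is reached
  i_fin <- which(p >= record$pmax_kPa - 1e-9)[1L]
  if (is.na(i_fin)) i_fin <- waveform$peak_index
  detach_frame <- if (isTRUE(record$detached)) i_fin + 1L else NA_integer_

  areas <- rep(A0, nf)
  ramp <- seq(waveform$arrival_index - 1L, i_fin)
  if (length(ramp) > 1L) {
    frac <- (p[ramp] - waveform$p0) / (record$pmax_kPa - waveform$p0)
    frac <- pmin(pmax(frac, 0), 1)
    if (!is.null(model)) {
      m <- apply_coupling(model, A0, coupling)
      Am <- vapply(p[ramp], function(pp)
        eos_area(m, max(pp, m$p0 * (1 + 1e-9))), numeric(1L))
      areas[ramp] <- Am + frac * (Afin - Am[length(Am)])
    } else {
      areas[ramp] <- A0 + frac * (Afin - A0)
    }
  }
  if (i_fin < nf) areas[(i_fin + 1L):nf] <- areas[i_fin]
  if (!is.na(detach_frame) && detach_frame <= nf)
    areas[detach_frame:nf] <- NA_real_

  sfun <- blob_shape(seed = 7901L + as.integer(cell$cell_id),
                     angle = cell$angle_deg)
  unit_area <- attr(sfun, "unit_area")
  phi <- seq(0, 2 * pi, length.out = 721L)[-721L]
  smax <- max(sfun(phi))
  center <- c((spec$width - 1L) / 2, (spec$height - 1L) / 2) * spec$pixel_size
  half_min <- min(spec$height, spec$width) / 2 * spec$pixel_size
  Rmax <- sqrt(max(areas, na.rm = TRUE) / unit_area) * smax
  if (Rmax > half_min - spec$pixel_size)
    stop("render error: cell larger than canvas")

  maxI <- 2^spec$bit_depth - 1
  frames <- array(0, c(spec$height, spec$width, nf))
  masks <- array(FALSE, c(spec$height, spec$width, nf))
  polygons <- vector("list", nf)
  for (t in seq_len(nf)) {
    if (is.na(areas[t])) {
      covg <- matrix(0, spec$height, spec$width)
    } else {
      R <- sqrt(areas[t] / unit_area)
      covg <- rasterize_blob(R, sfun, center, spec, supersample)
      polygons[[t]] <- blob_polygon(R, sfun, center, target_area = areas[t])
      masks[, , t] <- covg >= 0.5
    }
    img <- bg + covg * (fg - bg)
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    frames[, , t] <- round(pmin(pmax(img, 0), 1) * maxI)
  }
  list(frames = frames, masks = masks, polygons = polygons,
       areas_um2 = areas, detach_frame = detach_frame, spec = spec)
}

#' A background-only frame
#'
#' @inheritParams render_frames
#' @return Matrix of digital numbers with only background and sensor noise.
#' @export
blank_frame <- function(spec = image_spec(), noise_sd = 0.01, bg = 0.18) {
  maxI <- 2^spec$bit_depth - 1
  img <- bg + stats::rnorm(spec$height * spec$width, 0, noise_sd)
  matrix(round(pmin(pmax(img, 0), 1) * maxI), spec$height, spec$width)
}

#' Write a rendered stack to multi-page TIFF
#'
#' Frames go to 16-bit grayscale TIFF (12-bit data in 16-bit containers);
#' masks to 8-bit TIFF.
#'
#' @param rendered a [render_frames()] result.
#' @param frames_path,masks_path output file paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_frames <- function(rendered, frames_path, masks_path = NULL) {
  nf <- dim(rendered$frames)[3L]
  imgs <- lapply(seq_len(nf), function(t) rendered$frames[, , t] / 65535)
  tiff::writeTIFF(imgs, frames_path, bits.per.sample = 16L)
  if (!is.null(masks_path)) {
    m <- lapply(seq_len(nf), function(t) rendered$masks[, , t] * 1)
    tiff::writeTIFF(m, masks_path, bits.per.sample = 8L)
  }
  invisible(c(frames_path, masks_path))
}

#' Read a multi-page TIFF stack as a numeric array
#'
#' @param path TIFF file path.
#' @param scale multiply pixel values (tiff returns `[0, 1]`) by this factor
#'   to recover digital numbers; default 65535 matches [write_frames()].
#' @return height x width x n numeric array.
#' @export
read_frames <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale
  arr
}
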
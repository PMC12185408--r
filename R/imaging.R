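# Segmentation and morphometrics: Otsu threshold -> morphological open/close
# -> largest connected component -> marching-squares subpixel contour, then
# shape descriptors from the contour polygon.

#' Segment the cell in a single frame
#'
#' Pipeline: intensities normalized to `[0, 1]`; Otsu threshold;
#' morphological opening and closing (disc brush); largest connected
#' component above a minimum-area floor; subpixel contour by marching
#' squares (level halfway between the component's foreground and the
#' background) on the intensity image. A frame with no admissible component
#' yields a no-cell result, not an error.
#'
#' @param frame numeric matrix of intensities (any scale).
#' @param pixel_size pixel side length (um).
#' @param min_area_px minimum component size (pixels) to count as a cell.
#' @param max_fill maximum fraction of the canvas the component may cover;
#'   larger components are percolating threshold noise, not a cell.
#' @param brush_size diameter of the morphological structuring element.
#' @return List with `found` (logical); when found: `contour` (n x 2 um
#'   polygon, `(x, y) = (col, row) * pixel_size`), `mask` (logical matrix),
#'   `area_px` (pixel count), `area_um2` (contour shoelace area) and
#'   `shape` (a [measure_shape()] result).
#' @export
segment_cell <- function(frame, pixel_size = 0.75, min_area_px = 30L,
                         max_fill = 0.5, brush_size = 3L) {
  frame <- as.matrix(frame)
  if (!is.numeric(frame) || length(dim(frame)) != 2L)
    stop("frame must be a single-channel numeric matrix")
  none <- list(found = FALSE, contour = NULL, mask = NULL,
               area_px = 0, area_um2 = 0, shape = NULL)
  rng <- range(frame)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(none)
  z <- (frame - rng[1L]) / diff(rng)

  img <- EBImage::Image(z)
  thr <- EBImage::otsu(img, range = c(0, 1))
  bw <- img > thr
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  bw <- EBImage::closing(EBImage::opening(bw, brush), brush)
  lab <- EBImage::bwlabel(bw)
  labv <- as.integer(EBImage::imageData(lab))
  if (all(labv == 0L)) return(none)
  sizes <- tabulate(labv)
  if (max(sizes) < min_area_px || max(sizes) > max_fill * length(labv))
    return(none)
  biggest <- which.max(sizes)
  mask <- matrix(labv == biggest, nrow(frame), ncol(frame))

  # marching-squares contour on the intensity image, restricted to the
  # neighbourhood of the chosen component, level midway between the
  # component foreground and the background
  grow <- EBImage::dilate(EBImage::Image(mask * 1),
                          EBImage::makeBrush(5L, shape = "disc")) > 0.5
  grow <- matrix(as.logical(EBImage::imageData(grow)), nrow(frame), ncol(frame))
  fg <- stats::median(z[mask])
  bgv <- stats::median(z[!grow])
  # a component with no real intensity contrast is threshold noise
  if (!is.finite(fg) || !is.finite(bgv) || fg - bgv < 0.25) return(none)
  level <- (fg + bgv) / 2
  zc <- matrix(bgv, nrow(frame) + 2L, ncol(frame) + 2L)  # pad: closed contours
  zc[2:(nrow(frame) + 1L), 2:(ncol(frame) + 1L)] <-
    ifelse(grow, z, pmin(z, level - 1e-6))
  cls <- grDevices::contourLines(seq_len(nrow(zc)), seq_len(ncol(zc)), zc,
                                 levels = level)
  if (length(cls) == 0L) return(none)
  # keep the contour enclosing the largest area
  areas <- vapply(cls, function(cl)
    polygon_area(cbind(cl$x, cl$y)), numeric(1L))
  cl <- cls[[which.max(areas)]]
  # grid index k maps to 0-based pixel k - 2 after padding
  contour <- cbind(x = (cl$y - 2) * pixel_size, y = (cl$x - 2) * pixel_size)
  n <- nrow(contour)
  if (isTRUE(all.equal(contour[1L, ], contour[n, ]))) contour <- contour[-n, ]
  shape <- measure_shape(contour)
  list(found = TRUE, contour = contour, mask = mask,
       area_px = sum(mask), area_um2 = shape$area, shape = shape)
}

#' Morphometric descriptors of a cell contour
#'
#' Computes the standard shape descriptors from a simple polygon: area
#' (shoelace), perimeter (edge sum), orientation angle of the principal
#' axis of the second-order moments (degrees from the flow/x axis, in
#' `[0, 180)`), elongation `1 - lambda_min/lambda_max`, circularity
#' `4*pi*A/P^2`, compactness `P^2/(4*pi*A)` (inverse circularity),
#' convexity `P_hull/P` and solidity `A/A_hull`.
#'
#' @param contour n x 2 vertex matrix (um), a simple polygon.
#' @return Object of class `"cell_shape"`.
#' @export
measure_shape <- function(contour) {
  poly <- as_polygon(contour)
  if (!polygon_is_simple(poly))
    stop("geometry error: contour is self-intersecting")
  A <- polygon_area(poly)
  if (A <= 0) stop("degenerate contour: zero area")
  P <- polygon_perimeter(poly)
  M <- polygon_second_moments(poly)
  ev <- eigen(M, symmetric = TRUE)
  lmax <- ev$values[1L]; lmin <- ev$values[2L]
  v <- ev$vectors[, 1L]
  ang <- atan2(v[2L], v[1L]) * 180 / pi
  ang <- ang %% 180
  hull <- polygon_convex_hull(poly)
  Ph <- polygon_perimeter(hull)
  Ah <- polygon_area(hull)
  structure(list(contour = poly, area = A, perimeter = P,
                 angle = ang,
                 elongation = 1 - lmin / max(lmax, .Machine$double.eps),
                 circularity = 4 * pi * A / P^2,
                 compactness = P^2 / (4 * pi * A),
                 convexity = Ph / P,
                 solidity = A / Ah),
            class = "cell_shape")
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf(
    "Cell shape: area %.6g um^2, perimeter %.6g um, angle %.4g deg\n",
    x$area, x$perimeter, x$angle))
  cat(sprintf(
    "  elongation %.3g, circularity %.3g, compactness %.3g, convexity %.3g, solidity %.3g\n",
    x$elongation, x$circularity, x$compactness, x$convexity, x$solidity))
  invisible(x)
}

mask_iou <- function(a, b) {
  if (is.null(a) || is.null(b)) return(0)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Select the initial and final frames of a loading event
#'
#' The initial state is the last frame whose pressure is still below
#' baseline plus `k` baseline-noise standard deviations (the frame
#' immediately before wave arrival). The final state is the frame nearest
#' the pressure peak, unless the cell detaches first -- detachment being a
#' segmentation dropout or a frame-to-frame mask IoU below
#' `iou_threshold` -- in which case the last pre-detachment frame is used
#' and the effective maximum pressure is re-read there.
#'
#' @param stack height x width x n image array, frame-aligned with
#'   `waveform`.
#' @param waveform a [generate_waveform()] result.
#' @param pixel_size pixel side length (um).
#' @param k arrival threshold in baseline-noise standard deviations.
#' @param iou_threshold IoU below which consecutive masks indicate
#'   detachment.
#' @param min_area_px segmentation floor, see [segment_cell()].
#' @return Object of class `"frame_selection"`: `initial_index`,
#'   `final_index`, `detached`, `p_at_final`, plus the measured
#'   `initial_shape` and `final_shape`.
#' @export
select_frames <- function(stack, waveform, pixel_size = 0.75, k = 3,
                          iou_threshold = 0.3, min_area_px = 30L) {
  p <- waveform$pressures
  stopifnot(dim(stack)[3L] == length(p))
  nbase <- max(waveform$arrival_index - 2L, 1L)
  sd_base <- if (nbase >= 2L) stats::sd(p[seq_len(nbase)]) else 0
  thr <- waveform$p0 + k * sd_base + 1e-9 * max(abs(waveform$p0), 1)
  if (max(p) <= thr) stop("selection error: arrival never detected")
  peak <- waveform$peak_index
  below <- which(p[seq_len(peak)] <= thr)
  if (length(below) == 0L) stop("selection error: arrival never detected")
  initial_index <- max(below)

  seg_prev <- segment_cell(stack[, , initial_index], pixel_size,
                           min_area_px = min_area_px)
  if (!seg_prev$found)
    stop("selection error: no cell in the initial frame")
  initial_shape <- seg_prev$shape
  detached <- FALSE
  final_index <- peak
  final_shape <- NULL
  j <- initial_index + 1L
  while (j <= peak) {
    seg <- segment_cell(stack[, , j], pixel_size, min_area_px = min_area_px)
    if (!seg$found || mask_iou(seg$mask, seg_prev$mask) < iou_threshold) {
      detached <- TRUE
      final_index <- j - 1L
      break
    }
    seg_prev <- seg
    j <- j + 1L
  }
  final_shape <- seg_prev$shape
  if (final_index <= initial_index)
    stop("selection error: no usable loaded frame before detachment")
  structure(list(initial_index = initial_index, final_index = final_index,
                 detached = detached, p_at_final = p[final_index],
                 initial_shape = initial_shape, final_shape = final_shape),
            class = "frame_selection")
}

#' @export
print.frame_selection <- function(x, ...) {
  cat(sprintf(
    "Frame selection: initial %d, final %d%s, p_at_final = %.6g kPa\n",
    x$initial_index, x$final_index,
    if (x$detached) " (detached)" else "", x$p_at_final))
  invisible(x)
}

#' Final-to-initial area ratio
#'
#' `zeta = A_final / A_initial`, the global deformation measure.
#'
#' @param initial,final [measure_shape()] results, or positive areas
#'   (um^2).
#' @return The dimensionless ratio.
#' @export
compute_zeta <- function(initial, final) {
  ai <- if (inherits(initial, "cell_shape")) initial$area else initial
  af <- if (inherits(final, "cell_shape")) final$area else final
  if (!is.numeric(ai) || !is.numeric(af) || any(ai <= 0))
    stop("domain error: initial area must be > 0")
  if (any(af <= 0)) stop("domain error: final area must be > 0")
  af / ai
}
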
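#' Locate the maximum-deformation-rate inflection point
#'
#' Finds the pressure `p_k` at which the curvature of `A(p)` changes sign,
#' i.e. where the area growth rate `dA/dp` is maximal. For the exponential
#' family the root is analytic: the curvature factor `Bprime + (B0 +
#' Bprime*phat)^2` vanishes at `phat_k = (-B0 + sqrt(-Bprime))/Bprime`
#' (requires `Bprime < 0`); the analytic location is always confirmed by
#' bracketed root finding on a central-difference curvature estimate. The
#' Tait family has fixed-sign curvature and never reports an interior
#' inflection; the li family is scanned numerically. Absence is a valid
#' result (`exists = FALSE`), and ties are broken by the smallest pressure.
#'
#' @inheritParams eos_area
#' @param p_range pressure interval to search (kPa); default is the family's
#'   admissible domain (trimmed when unbounded).
#' @param n_grid number of scan points for the numeric search.
#' @return An object of class `"inflection_point"` with fields `exists`,
#'   `p_k`, `A_k`, `zeta_k`.
#' @export
find_inflection <- function(model, p_range = NULL, n_grid = 400L) {
  dom <- eos_domain(model)
  if (is.null(p_range)) {
    hi <- if (is.finite(dom[2L])) dom[2L] else model$p0 + 50 * model$p_ref
    p_range <- c(dom[1L], hi)
  }
  p_range <- sort(p_range)
  if (p_range[1L] < dom[1L] || p_range[2L] > dom[2L])
    stop("p_range outside the family's admissible domain")
  none <- structure(list(exists = FALSE, p_k = NA_real_, A_k = NA_real_,
                         zeta_k = NA_real_, family = model$family),
                    class = "inflection_point")

  if (model$family == "tait") {
    # A ~ (p - p0)^(1/kappa): curvature sign is fixed by (1/k)(1/k - 1)
    return(none)
  }

  d2 <- function(p) eos_deriv(model, p, order = 2L)

  p_k <- NA_real_
  if (model$family == "exponential") {
    if (model$Bprime >= 0) return(none)
    phat_k <- (-model$B0 + sqrt(-model$Bprime)) / model$Bprime
    p_k <- model$p0 + model$p_ref * phat_k
    if (p_k <= p_range[1L] || p_k >= p_range[2L]) return(none)
    # confirm by bracketing a central-difference curvature estimate
    w <- 1e-2 * model$p_ref
    nd2 <- function(p) {
      h <- 1e-4 * model$p_ref
      (eos_area(model, p + h) - 2 * eos_area(model, p) +
         eos_area(model, p - h)) / h^2
    }
    lo <- max(p_range[1L], p_k - w); hi <- min(p_range[2L], p_k + w)
    if (nd2(lo) * nd2(hi) < 0)
      p_k_num <- stats::uniroot(nd2, c(lo, hi), tol = 1e-10)$root
    else p_k_num <- p_k
    p_k <- p_k  # analytic value is authoritative; numeric value confirms
    attr(p_k, "numeric_check") <- p_k_num
  } else {
    # li family: scan the curvature for sign changes
    pad <- diff(p_range) * 1e-3
    grid <- seq(p_range[1L] + pad, p_range[2L] - pad, length.out = n_grid)
    v <- vapply(grid, function(pp)
      tryCatch(d2(pp), error = function(e) NA_real_), numeric(1L))
    keep <- is.finite(v)
    grid <- grid[keep]; v <- v[keep]
    if (length(v) < 2L) return(none)
    s <- sign(v)
    idx <- which(s[-1L] * s[-length(s)] < 0)
    if (length(idx) == 0L) return(none)
    i <- idx[1L]  # smallest-p tie break
    p_k <- stats::uniroot(d2, c(grid[i], grid[i + 1L]), tol = 1e-10)$root
  }
  A_k <- eos_area(model, as.numeric(p_k))
  structure(list(exists = TRUE, p_k = as.numeric(p_k), A_k = A_k,
                 zeta_k = A_k / model$A0, family = model$family,
                 p_k_numeric = attr(p_k, "numeric_check")),
            class = "inflection_point")
}

#' @export
print.inflection_point <- function(x, ...) {
  if (!x$exists) {
    cat("No interior inflection point (", x$family, " family)\n", sep = "")
  } else {
    cat(sprintf(
      "Inflection point (%s family): p_k = %.6g kPa, A_k = %.6g um^2, zeta_k = %.6g\n",
      x$family, x$p_k, x$A_k, x$zeta_k))
  }
  invisible(x)
}

#' Concave quadratic nucleus response
#'
#' Convenience core-area model `A_core(p) = A_core0 + slope*(p - p0) -
#' curvature*(p - p0)^2` for the two-compartment integrator. `curvature > 0`
#' enforces the required concavity (`d2 A_core/dp2 < 0`), emulating
#' progressive collapse of nuclear pores under load.
#'
#' @param A_core0 initial nucleus area (um^2).
#' @param curvature quadratic coefficient (um^2/kPa^2), > 0.
#' @param slope linear coefficient (um^2/kPa).
#' @param p0 baseline pressure (kPa).
#' @return List of functions `f`, `df`, `d2f` of pressure.
#' @export
quadratic_core <- function(A_core0, curvature, slope = 0, p0 = 101.325) {
  stopifnot(curvature >= 0)
  list(f  = function(p) A_core0 + slope * (p - p0) - curvature * (p - p0)^2,
       df = function(p) slope - 2 * curvature * (p - p0),
       d2f = function(p) rep(-2 * curvature, length(p)))
}

#' Two-compartment (cytoplasm + nucleus) area response
#'
#' Integrates the refined cell-area balance
#' `dA_cell/dp = ((A_cell - A_core)/A_cell) * dA_cyto/dp
#'             + C * (A_core/A_cell) * (dA_core/dp + p * d2A_core/dp2)`
#' with a fixed-step classical 4th-order Runge-Kutta scheme over `p_grid`,
#' accumulating the cytoplasm and core contributions separately so that the
#' conservation identity `dA_cell = dA_cyto + dA_core` can be verified at
#' every grid point (reported as attribute `"conservation_error"`).
#'
#' @param p_grid increasing pressure grid (kPa); the first entry is the
#'   initial state.
#' @param A_core0 initial nucleus area (um^2), > 0.
#' @param A_cyto0 initial cytoplasm area (um^2), >= 0; the total initial cell
#'   area is `A_core0 + A_cyto0`.
#' @param C dimensionless core-coupling constant.
#' @param dAcyto_dp cytoplasm area slope (um^2/kPa), a constant.
#' @param core core response, a list of functions `f(p)`, `df(p)`, `d2f(p)`
#'   as returned by [quadratic_core()]; must be concave (`d2f < 0`) on the
#'   whole grid.
#' @return A data frame (class `"two_compartment"`) with columns `p`,
#'   `A_cell`, `dA_cell`, `dA_cyto`, `dA_core`.
#' @export
two_compartment_area <- function(p_grid, A_core0, A_cyto0, C = 1,
                                 dAcyto_dp = 0.05, core = NULL) {
  stopifnot(A_core0 > 0, A_cyto0 >= 0, length(p_grid) >= 2L,
            all(diff(p_grid) > 0))
  if (is.null(core))
    core <- quadratic_core(A_core0, curvature = 1e-5, p0 = p_grid[1L])
  # the core concavity requirement only constrains an active core term
  if (C != 0 && any(core$d2f(p_grid) >= 0))
    stop("core response violates the concavity requirement (d2A_core/dp2 < 0)")
  A_cell0 <- A_core0 + A_cyto0
  rhs <- function(p, y, parms) {
    ac <- core$f(p)
    t_cyto <- ((y[1L] - ac) / y[1L]) * dAcyto_dp
    t_core <- C * (ac / y[1L]) * (core$df(p) + p * core$d2f(p))
    list(c(t_cyto + t_core, t_cyto, t_core))
  }
  sol <- deSolve::rk4(c(A_cell = A_cell0, cyto = 0, core = 0),
                      times = p_grid, func = rhs, parms = NULL)
  out <- data.frame(p = sol[, "time"], A_cell = sol[, "A_cell"],
                    dA_cell = sol[, "A_cell"] - A_cell0,
                    dA_cyto = sol[, "cyto"], dA_core = sol[, "core"])
  err <- max(abs(out$dA_cell - (out$dA_cyto + out$dA_core)))
  attr(out, "conservation_error") <- err
  class(out) <- c("two_compartment", "data.frame")
  out
}

#' Discrete isobaric trajectory of the loading process
#'
#' Represents shock loading as a sequence of equilibrium states at equal
#' pressure increments (constant pressure rate), each transition carrying a
#' step ratio `zeta_i = A_{i+1}/A_i`. The initial equilibrium is anchored at
#' `(p0, A0)`; subsequent areas come from the family's forward model. The
#' step ratios telescope: `prod(zeta_i) = A_n/A_0`.
#'
#' @inheritParams eos_area
#' @param p_end final pressure (kPa), inside the family domain.
#' @param n_steps number of pressure increments (>= 1).
#' @return Object of class `"isobaric_trajectory"` with `pressures`, `areas`
#'   and `step_ratios`.
#' @export
isobaric_trajectory <- function(model, p_end, n_steps) {
  stopifnot(n_steps >= 1L, p_end > model$p0)
  pressures <- seq(model$p0, p_end, length.out = n_steps + 1L)
  areas <- c(model$A0, eos_area(model, pressures[-1L]))
  structure(list(pressures = pressures, areas = areas,
                 step_ratios = areas[-1L] / areas[-length(areas)],
                 family = model$family),
            class = "isobaric_trajectory")
}

#' @export
print.isobaric_trajectory <- function(x, ...) {
  n <- length(x$step_ratios)
  cat(sprintf(
    "Isobaric trajectory (%s family): %d steps, p %.6g -> %.6g kPa, A %.6g -> %.6g um^2\n",
    x$family, n, x$pressures[1L], x$pressures[n + 1L],
    x$areas[1L], x$areas[n + 1L]))
  cat(sprintf("  overall zeta = %.6g, max step ratio = %.6g\n",
              x$areas[n + 1L] / x$areas[1L], max(x$step_ratios)))
  invisible(x)
}

#' @export
plot.isobaric_trajectory <- function(x, ...) {
  graphics::plot(x$pressures, x$areas, type = "s", xlab = "pressure (kPa)",
                 ylab = expression(A ~ (mu * m^2)),
                 main = "Discrete isobaric trajectory", ...)
  graphics::points(x$pressures, x$areas, pch = 20, cex = 0.6)
  invisible(x)
}

#' Loading-rate continuation of the maximum-deformation-rate locus
#'
#' Holds the final state `(p_end, A(p_end))` fixed and discretizes the
#' loading path with each step count in `steps_list` (coarse steps emulate
#' high loading rates, fine steps low rates). For each discretization the
#' maximum-deformation-rate step -- the step with the largest area increment
#' `A_{i+1} - A_i`, whose continuous limit is the inflection point of
#' `A(p)` -- is located and reported with its step ratio and post-step
#' coordinates. Coarser discretizations push this locus toward larger areas.
#'
#' @inheritParams isobaric_trajectory
#' @param steps_list integer vector of step counts.
#' @return A data frame (class `"rate_continuation"`), one row per step
#'   count, ordered from coarsest (largest pressure step) to finest, with
#'   columns `n_steps`, `dp`, `step_index`, `p_locus`, `A_locus`,
#'   `zeta_step`.
#' @export
loading_rate_continuation <- function(model, p_end, steps_list) {
  stopifnot(length(steps_list) >= 1L, all(steps_list >= 1L))
  rows <- lapply(as.integer(steps_list), function(n) {
    tr <- isobaric_trajectory(model, p_end, n)
    dA <- diff(tr$areas)
    i <- which.max(dA)
    data.frame(n_steps = n, dp = diff(tr$pressures)[1L], step_index = i,
               p_locus = tr$pressures[i + 1L], A_locus = tr$areas[i + 1L],
               zeta_step = tr$step_ratios[i])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$dp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rate_continuation", "data.frame")
  out
}

#' Sign-constraint audit of a deformation-ratio surface
#'
#' Checks a sampled surface `zeta(A0, p)` against the qualitative
#' constraints observed experimentally: at fixed pressure `zeta` decreases
#' and is convex in the initial area (`dzeta/dA < 0`, `d2zeta/dA2 > 0`);
#' below the critical area `A_k` pressure drives `zeta` up
#' (`dzeta/dp > 0`); and the two first derivatives compete
#' (`dzeta/dp * dzeta/dA < 0`). Derivatives are estimated by central
#' differences on the interior of the grid.
#'
#' @param zeta matrix of ratios, rows indexed by `A0_grid`, columns by
#'   `p_grid`.
#' @param A0_grid increasing initial areas (um^2), length >= 3.
#' @param p_grid increasing pressures (kPa), length >= 3.
#' @param A_k optional critical area: the `dzeta/dp` check is restricted to
#'   rows with `A0 < A_k`.
#' @return Object of class `"surface_signs"`: named fractions of interior
#'   cells satisfying each constraint.
#' @export
check_surface_signs <- function(zeta, A0_grid, p_grid, A_k = NULL) {
  zeta <- as.matrix(zeta)
  if (nrow(zeta) < 3L || ncol(zeta) < 3L)
    stop("grid too small: need at least 3 x 3 samples")
  stopifnot(nrow(zeta) == length(A0_grid), ncol(zeta) == length(p_grid),
            all(is.finite(zeta)))
  ri <- 2:(nrow(zeta) - 1L); ci <- 2:(ncol(zeta) - 1L)
  dA <- outer(A0_grid[ri + 1L] - A0_grid[ri - 1L], rep(1, length(ci)))
  dp <- outer(rep(1, length(ri)), p_grid[ci + 1L] - p_grid[ci - 1L])
  dz_dA <- (zeta[ri + 1L, ci] - zeta[ri - 1L, ci]) / dA
  dz_dp <- (zeta[ri, ci + 1L] - zeta[ri, ci - 1L]) / dp
  hA <- outer(diff(A0_grid)[ri - 1L], rep(1, length(ci)))  # assume ~uniform
  d2z_dA2 <- (zeta[ri + 1L, ci] - 2 * zeta[ri, ci] + zeta[ri - 1L, ci]) / hA^2
  sel_p <- if (is.null(A_k)) rep(TRUE, length(ri)) else A0_grid[ri] < A_k
  frac <- c(
    dzeta_dA_negative  = mean(dz_dA < 0),
    d2zeta_dA2_positive = mean(d2z_dA2 > 0),
    dzeta_dp_positive  = if (any(sel_p)) mean(dz_dp[sel_p, ] > 0) else NA_real_,
    cross_product_negative = mean(dz_dp * dz_dA < 0))
  structure(list(fractions = frac, n_interior = length(ri) * length(ci),
                 A_k = A_k),
            class = "surface_signs")
}

#' @export
print.surface_signs <- function(x, ...) {
  cat("Deformation-surface sign constraints (fraction of",
      x$n_interior, "interior cells):\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-24s %.3f\n", nm, x$fractions[[nm]]))
  invisible(x)
}
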
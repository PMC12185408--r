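#' Construct an area-pressure state equation for a single cell
#'
#' A state equation relates the hydraulic pressure `p` (kPa) acting on an
#' adherent cell to its projected cross-sectional area `A` (um^2), by analogy
#' with a material equation of state. Three families are supported:
#'
#' * `"exponential"` -- the area modulus `B(p) = B0 + B' * phat` is linear in
#'   the nondimensional overpressure `phat = (p - p0)/p_ref`, giving
#'   `A = A0 * exp(B0*phat + B'*phat^2/2)`. With `B' < 0` the curve has an
#'   interior inflection (maximum area-growth rate).
#' * `"li"` -- the area properties vary continuously with pressure; the
#'   pressure is `p = p0 * (1 + exp(alpha1 * li(A/A0)))` where `li` is the
#'   logarithmic integral regularized at its `A/A0 = 1` divergence by a finite
#'   lower limit `1 + eps`.
#' * `"tait"` -- a Tait-like power law `p = alpha3 * p0 * (A/A0)^kappa + p0`,
#'   where `kappa` is the composite exponent (the product of the underlying
#'   correction factor and `1 + gamma`, which are not separately identifiable).
#'
#' Pressures are nondimensionalized as `phat = (p - p0)/p_ref`; by default
#' `p_ref = p0` so that `B0 = 1` reproduces the unit initial condition of the
#' modulus expansion.
#'
#' @param family one of `"exponential"`, `"li"`, `"tait"`.
#' @param A0 initial projected area (um^2), > 0.
#' @param p0 baseline (pre-arrival) pressure (kPa), > 0.
#' @param p_ref pressure nondimensionalization scale (kPa); default `p0`.
#' @param B0 initial area modulus (dimensionless), exponential family.
#' @param Bprime modulus pressure-derivative `dB/dphat` (dimensionless).
#' @param alpha1 correction factor of the li family (dimensionless, nonzero).
#' @param eps li-family regularization offset (> 0).
#' @param kappa composite Tait exponent (dimensionless, nonzero).
#' @param alpha3 Tait pressure-scale correction factor (dimensionless, >= 0).
#' @return An object of class `"state_equation"`.
#' @examples
#' m <- state_equation("tait", A0 = 300, p0 = 100, kappa = 1.5, alpha3 = 0.8)
#' eos_area(m, 500)
#' @export
state_equation <- function(family = c("exponential", "li", "tait"),
                           A0 = 550, p0 = 101.325, p_ref = p0,
                           B0 = 1, Bprime = 0,
                           alpha1 = 0.4, eps = 1e-6,
                           kappa = 1.5, alpha3 = 0.8) {
  family <- match.arg(family)
  stopifnot(A0 > 0, p0 > 0, p_ref > 0, eps > 0)
  if (family == "tait" && kappa == 0) stop("tait family requires kappa != 0")
  if (family == "li" && alpha1 == 0) stop("li family requires alpha1 != 0")
  structure(list(family = family, A0 = A0, p0 = p0, p_ref = p_ref,
                 B0 = B0, Bprime = Bprime, alpha1 = alpha1, eps = eps,
                 kappa = kappa, alpha3 = alpha3),
            class = "state_equation")
}

#' @export
print.state_equation <- function(x, ...) {
  cat("Cell area-pressure state equation [", x$family, "]\n", sep = "")
  cat(sprintf("  A0 = %.6g um^2, p0 = %.6g kPa, p_ref = %.6g kPa\n",
              x$A0, x$p0, x$p_ref))
  pars <- switch(x$family,
    exponential = sprintf("  B0 = %.6g, B' = %.6g", x$B0, x$Bprime),
    li          = sprintf("  alpha1 = %.6g, eps = %.3g", x$alpha1, x$eps),
    tait        = sprintf("  kappa = %.6g, alpha3 = %.6g", x$kappa, x$alpha3))
  cat(pars, "\n")
  invisible(x)
}

eos_phat <- function(model, p) (p - model$p0) / model$p_ref

#' Exponential-family area response
#'
#' Evaluates `A(p) = A0 * exp(B0*phat + Bprime*phat^2/2)` with
#' `phat = (p - p0)/p_ref`. The admissible domain is `B0 + Bprime*phat > 0`
#' (positive area modulus, hence `dA/dp > 0`).
#'
#' @param p pressure (kPa), vectorized.
#' @inheritParams state_equation
#' @return Area (um^2).
#' @export
area_exponential <- function(p, A0, p0, p_ref = p0, B0 = 1, Bprime = 0) {
  phat <- (p - p0) / p_ref
  if (any(B0 + Bprime * phat <= 0))
    stop("pressure outside the exponential family domain (B0 + B'*phat <= 0)")
  A0 * exp(B0 * phat + 0.5 * Bprime * phat^2)
}

#' Area modulus of the exponential family
#'
#' `B(phat) = B0 + Bprime * phat`, the normalized area compressibility
#' `(1/A) dA/dphat`. Non-positive values violate the model contract
#' (`B > 0`); they are reported via the `"positive"` attribute rather than an
#' error so that admissibility boundaries can be mapped.
#'
#' @inheritParams area_exponential
#' @return Numeric vector of modulus values with logical attribute
#'   `"positive"`.
#' @export
area_modulus <- function(p, p0, p_ref = p0, B0 = 1, Bprime = 0) {
  phat <- (p - p0) / p_ref
  b <- B0 + Bprime * phat
  attr(b, "positive") <- b > 0
  b
}

#' Regularized logarithmic integral
#'
#' Computes `integral_{1+eps}^{x} du / log(u)`, the logarithmic integral with
#' its divergence at `u = 1` removed by a finite lower limit. Evaluated as
#' `li(x) - li(1 + eps)` through the exponential integral
#' (`li(x) = Ei(log x)`).
#'
#' @param x upper limit(s), each `>= 1 + eps`.
#' @param eps regularization offset (> 0), default `1e-6`.
#' @return Numeric vector of integral values (0 at `x = 1 + eps`).
#' @export
li_regularized <- function(x, eps = 1e-6) {
  stopifnot(eps > 0)
  if (any(x < 1 + eps - 1e-15))
    stop("li_regularized requires x >= 1 + eps")
  x <- pmax(x, 1 + eps)
  vapply(x, function(z) pracma::li(z), numeric(1L)) - pracma::li(1 + eps)
}

#' Pressure predicted by the li-family state equation
#'
#' `p = p0 * (1 + exp(alpha1 * li((A/A0); eps)))`, arising when the cell's
#' area modulus varies continuously with pressure.
#'
#' @param A projected area (um^2), `>= A0*(1+eps)`.
#' @inheritParams state_equation
#' @return Pressure (kPa).
#' @export
pressure_li_model <- function(A, A0, p0, alpha1, eps = 1e-6) {
  if (any(A < A0 * (1 + eps) * (1 - 1e-15)))
    stop("pressure_li_model requires A >= A0*(1+eps)")
  p0 * (1 + exp(alpha1 * li_regularized(A / A0, eps)))
}

#' Area of the li family by numeric inversion
#'
#' Inverts [pressure_li_model()] by bracketed root finding on the area ratio.
#'
#' @inheritParams pressure_li_model
#' @param p pressure (kPa) inside the family's range (`> p0`; above `2*p0`
#'   for `alpha1 > 0`, in `(p0, 2*p0]` for `alpha1 < 0`).
#' @return Area (um^2).
#' @export
area_li_model <- function(p, A0, p0, alpha1, eps = 1e-6) {
  vapply(p, function(pp) {
    if (pp <= p0) stop("li family requires p > p0")
    target <- log((pp - p0) / p0) / alpha1
    if (target < 0)
      stop("pressure outside the li family range for this alpha1")
    if (target == 0) return(A0 * (1 + eps))
    lo <- 1 + eps; hi <- 2
    while (li_regularized(hi, eps) < target) hi <- hi * 2
    z <- stats::uniroot(function(z) li_regularized(z, eps) - target,
                        c(lo, hi), tol = 1e-12)$root
    A0 * z
  }, numeric(1L))
}

#' Tait-like pressure and area
#'
#' Forward and inverse forms of the Tait-like state equation
#' `p = alpha3 * p0 * (A/A0)^kappa + p0`. `kappa` is the composite exponent;
#' `tait_area` requires `p > p0` and `alpha3 > 0`.
#'
#' @inheritParams state_equation
#' @param A projected area (um^2).
#' @param p pressure (kPa).
#' @return Pressure (kPa) for `tait_pressure`; area (um^2) for `tait_area`.
#' @export
tait_pressure <- function(A, A0, p0, kappa, alpha3) {
  stopifnot(kappa != 0, alpha3 >= 0, all(A > 0))
  alpha3 * p0 * (A / A0)^kappa + p0
}

#' @rdname tait_pressure
#' @export
tait_area <- function(p, A0, p0, kappa, alpha3) {
  stopifnot(kappa != 0)
  u <- (p - p0) / (alpha3 * p0)
  if (alpha3 <= 0 || any(u <= 0))
    stop("tait_area requires alpha3 > 0 and p > p0")
  A0 * u^(1 / kappa)
}

#' Evaluate a state equation
#'
#' `eos_area` gives `A(p)` for any family (the li family is inverted
#' numerically); `eos_zeta` gives the deformation ratio `A(p)/A0`;
#' `eos_pressure` gives the inverse `p(A)`.
#'
#' @param model a [state_equation()].
#' @param p pressures (kPa).
#' @param A areas (um^2).
#' @return Numeric vector.
#' @export
eos_area <- function(model, p) {
  switch(model$family,
    exponential = area_exponential(p, model$A0, model$p0, model$p_ref,
                                   model$B0, model$Bprime),
    li = area_li_model(p, model$A0, model$p0, model$alpha1, model$eps),
    tait = tait_area(p, model$A0, model$p0, model$kappa, model$alpha3))
}

#' @rdname eos_area
#' @export
eos_zeta <- function(model, p) eos_area(model, p) / model$A0

#' @rdname eos_area
#' @export
eos_pressure <- function(model, A) {
  switch(model$family,
    exponential = {
      # solve B0*phat + B'/2 phat^2 = log(A/A0) on the admissible branch
      g <- log(A / model$A0)
      phat <- if (model$Bprime == 0) g / model$B0 else {
        disc <- model$B0^2 + 2 * model$Bprime * g
        if (any(disc < 0)) stop("area outside the exponential family range")
        (-model$B0 + sqrt(disc)) / model$Bprime
      }
      model$p0 + model$p_ref * phat
    },
    li = pressure_li_model(A, model$A0, model$p0, model$alpha1, model$eps),
    tait = tait_pressure(A, model$A0, model$p0, model$kappa, model$alpha3))
}

#' Derivatives of the area response
#'
#' First and second derivatives of `A(p)` with respect to pressure. Analytic
#' for the exponential and Tait families; high-order central differences on
#' [eos_area()] for the li family.
#'
#' @inheritParams eos_area
#' @param order derivative order, 1 or 2.
#' @param h relative step for numeric differentiation (li family).
#' @return Numeric vector, in um^2/kPa (`order = 1`) or um^2/kPa^2.
#' @export
eos_deriv <- function(model, p, order = 1L, h = 1e-4) {
  stopifnot(order %in% c(1L, 2L))
  switch(model$family,
    exponential = {
      phat <- eos_phat(model, p)
      g <- exp(model$B0 * phat + 0.5 * model$Bprime * phat^2)
      b <- model$B0 + model$Bprime * phat
      if (any(b <= 0))
        stop("pressure outside the exponential family domain")
      if (order == 1L) model$A0 * b * g / model$p_ref
      else model$A0 * (model$Bprime + b^2) * g / model$p_ref^2
    },
    tait = {
      u <- (p - model$p0) / (model$alpha3 * model$p0)
      if (model$alpha3 <= 0 || any(u <= 0))
        stop("tait derivatives require alpha3 > 0 and p > p0")
      k <- 1 / model$kappa
      scale <- model$A0 / (model$alpha3 * model$p0)
      if (order == 1L) scale * k * u^(k - 1)
      else scale / (model$alpha3 * model$p0) * k * (k - 1) * u^(k - 2)
    },
    li = {
      dp <- pmax(abs(p), model$p0) * h
      f <- function(pp) eos_area(model, pp)
      if (order == 1L) (f(p + dp) - f(p - dp)) / (2 * dp)
      else (f(p + dp) - 2 * f(p) + f(p - dp)) / dp^2
    })
}

# Admissible open pressure interval of a family (used for default search
# ranges); upper may be Inf.
eos_domain <- function(model) {
  switch(model$family,
    exponential = {
      if (model$Bprime < 0)
        c(model$p0, model$p0 + model$p_ref * (-model$B0 / model$Bprime))
      else c(model$p0, Inf)
    },
    li = {
      if (model$alpha1 > 0) c(2 * model$p0, Inf) else c(model$p0, 2 * model$p0)
    },
    tait = c(model$p0, Inf))
}
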
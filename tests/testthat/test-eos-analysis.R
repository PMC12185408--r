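test_that("inflection point of the exponential family matches the analytic root", {
  for (bp in c(-0.5, -0.25, -0.1)) {
    m <- state_equation("exponential", A0 = 300, p0 = 100, Bprime = bp)
    infl <- find_inflection(m)
    expect_true(infl$exists)
    phat_k <- (-1 + sqrt(-bp)) / bp
    expect_equal((infl$p_k - 100) / 100, phat_k, tolerance = 1e-6)
    # independent oracle: central-difference curvature changes sign there
    nd2 <- function(p) {
      h <- 0.01
      (eos_area(m, p + h) - 2 * eos_area(m, p) + eos_area(m, p - h)) / h^2
    }
    expect_true(nd2(infl$p_k - 1) > 0 && nd2(infl$p_k + 1) < 0)
    expect_equal(infl$zeta_k, infl$A_k / 300)
  }
})

test_that("curvature of fixed-sign families reports no interior inflection", {
  for (bp in c(0, 0.2)) {
    m <- state_equation("exponential", A0 = 300, p0 = 100, Bprime = bp)
    expect_false(find_inflection(m, c(100, 2000))$exists)
  }
  for (k in c(0.5, 2)) {
    m <- state_equation("tait", A0 = 300, p0 = 100, kappa = k, alpha3 = 0.8)
    expect_false(find_inflection(m, c(150, 3000))$exists)
  }
})

test_that("li-family inflection satisfies the curvature-balance diagnostic", {
  # a moderate regularization keeps the inflection at observable pressures
  A0 <- 300; p0 <- 100; a1 <- 0.4; eps <- 0.01
  m <- state_equation("li", A0 = A0, p0 = p0, alpha1 = a1, eps = eps)
  infl <- find_inflection(m, c(2 * p0 * 1.01, 3000), n_grid = 800L)
  expect_true(infl$exists)
  # analytic location: the curvature of p(A) vanishes at A/A0 = 1/alpha1
  expect_equal(infl$A_k / A0, 1 / a1, tolerance = 1e-3)
  # at the inflection, dA/dp * (A0/A) * (p-p0)/A0 = beta * log(A/A0) with
  # beta * alpha1 * A / A0 = 1
  dAdp <- eos_deriv(m, infl$p_k, 1L)
  beta <- dAdp * (A0 / infl$A_k) * (infl$p_k - p0) / A0 / log(infl$A_k / A0)
  expect_equal(beta * a1 * infl$A_k / A0, 1, tolerance = 1e-4)
})

test_that("two-compartment integrator conserves and degenerates correctly", {
  p <- seq(100, 900, length.out = 161L)
  # constant core, C = 0: only the cytoplasm term drives the cell area
  core_const <- list(f = function(p) rep(150, length(p)),
                     df = function(p) rep(0, length(p)),
                     d2f = function(p) rep(0, length(p)))
  tc <- two_compartment_area(p, A_core0 = 150, A_cyto0 = 350, C = 0,
                             dAcyto_dp = 0.05, core = core_const)
  expect_equal(tc$dA_core, rep(0, length(p)))
  slope <- diff(tc$A_cell) / diff(p)
  expected <- ((tc$A_cell - 150) / tc$A_cell * 0.05)[-length(p)]
  expect_equal(slope, expected, tolerance = 1e-3)
  # no cytoplasm slope either: the cell area is frozen
  tc0 <- two_compartment_area(p, 150, 350, C = 0, dAcyto_dp = 0,
                              core = core_const)
  expect_equal(tc0$A_cell, rep(500, length(p)))
  # concavity violation is only an error for an active core term
  expect_error(two_compartment_area(p, 150, 350, C = 0.5, dAcyto_dp = 0.05,
                                    core = core_const), "concavity")
  # conservation at every grid point
  tc2 <- two_compartment_area(p, 150, 350, C = 0.8, dAcyto_dp = 0.05,
                              core = quadratic_core(150, 5e-5, 0, 100))
  expect_lt(attr(tc2, "conservation_error"), 1e-9)
})

test_that("two-compartment integrator matches a step-halving Richardson oracle", {
  rk4_oracle <- function(p_grid, C, dAcyto, core, A0c, A0y) {
    y <- A0c + A0y
    for (i in seq_len(length(p_grid) - 1L)) {
      h <- p_grid[i + 1L] - p_grid[i]
      f <- function(p, y) {
        ac <- core$f(p)
        ((y - ac) / y) * dAcyto + C * (ac / y) * (core$df(p) + p * core$d2f(p))
      }
      k1 <- f(p_grid[i], y)
      k2 <- f(p_grid[i] + h / 2, y + h / 2 * k1)
      k3 <- f(p_grid[i] + h / 2, y + h / 2 * k2)
      k4 <- f(p_grid[i] + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  core <- quadratic_core(150, 8e-5, 0.01, 100)
  p <- seq(100, 800, length.out = 101L)
  p_half <- seq(100, 800, length.out = 201L)
  y_h <- rk4_oracle(p, 0.8, 0.05, core, 150, 350)
  y_h2 <- rk4_oracle(p_half, 0.8, 0.05, core, 150, 350)
  richardson <- y_h2 + (y_h2 - y_h) / 15
  tc <- two_compartment_area(p, 150, 350, C = 0.8, dAcyto_dp = 0.05,
                             core = core)
  expect_equal(tc$A_cell[length(p)], richardson, tolerance = 1e-6)
})

test_that("isobaric trajectories telescope and refine toward equilibrium", {
  m <- state_equation("exponential", A0 = 300, p0 = 100, Bprime = -0.25)
  tr1 <- isobaric_trajectory(m, 450, 1L)
  expect_equal(tr1$pressures, c(100, 450))
  expect_equal(tr1$areas, c(300, eos_area(m, 450)))
  tr <- isobaric_trajectory(m, 450, 64L)
  expect_equal(prod(tr$step_ratios), tr$areas[65L] / 300, tolerance = 1e-12)
  expect_true(all(diff(tr$pressures) > 0))
  # refinement: the largest step ratio decays monotonically to 1
  worst <- vapply(10L * 2L^(0:10), function(n)
    max(abs(isobaric_trajectory(m, 450, n)$step_ratios - 1)), numeric(1L))
  expect_true(all(diff(worst) < 0))
  expect_lt(worst[11L], 1e-2)
})

test_that("loading-rate continuation converges to the analytic inflection and orders by rate", {
  m <- state_equation("exponential", A0 = 300, p0 = 100, Bprime = -0.25)
  lc1 <- loading_rate_continuation(m, 450, 1L)
  expect_equal(lc1$A_locus, eos_area(m, 450))
  steps <- c(4L, 16L, 64L, 256L, 1024L, 4096L)
  lc <- loading_rate_continuation(m, 450, steps)
  infl <- find_inflection(m)
  # coarse -> fine ordering: locus area decreases towards A_k
  expect_true(all(diff(lc$A_locus) < 0))
  expect_equal(lc$A_locus[nrow(lc)], infl$A_k, tolerance = 5e-3)
  expect_equal(lc$p_locus[nrow(lc)], infl$p_k, tolerance = 5e-3)
})

test_that("surface sign checks respond to analytic and degenerate surfaces", {
  A0 <- seq(200, 800, length.out = 15L)
  p <- seq(200, 3000, length.out = 15L)
  zs <- outer(A0, p, function(a, pp) 1 + 0.2 * pp / a)
  chk <- check_surface_signs(zs, A0, p)
  expect_true(all(chk$fractions == 1))
  flat <- check_surface_signs(matrix(1, 15L, 15L), A0, p)
  expect_true(all(flat$fractions[c("dzeta_dA_negative",
                                   "dzeta_dp_positive")] == 0))
  expect_error(check_surface_signs(matrix(1, 2L, 5L), c(1, 2), p), "3 x 3")
})
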
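test_that("distribution tests validate the generator's statistical structure", {
  pop <- sample_cell_population(population_spec(198, seed = 61))
  recs <- data.frame(A_initial_um2 = pop$area_um2,
                     perimeter_um = pop$perimeter_um,
                     angle_deg = pop$angle_deg)
  rep <- test_distributions(recs)
  expect_true(all(rep$pass[rep$feature %in% c("area", "perimeter", "angle")]))
  # constant feature: degenerate entry, not an exception
  recs2 <- recs; recs2$A_initial_um2 <- 400
  rep2 <- test_distributions(recs2)
  expect_match(rep2$note[rep2$feature == "area"], "degenerate")
  expect_true(is.na(rep2$p_value[rep2$feature == "area"]))
  # well-separated bimodal areas: normality rejected
  set.seed(62)
  recs3 <- recs
  recs3$A_initial_um2 <- c(stats::rnorm(99, 200, 10), stats::rnorm(99, 900, 10))
  rep3 <- test_distributions(recs3)
  expect_false(rep3$pass[rep3$feature == "area"])
  expect_error(test_distributions(recs[1:5, ]), "at least 8")
})

test_that("pressure grouping follows the five-percent and group-size rules", {
  r4 <- data.frame(pmax_kPa = rep(478, 4L))
  g4 <- group_by_pressure(r4)
  expect_equal(nrow(g4$groups), 1L)
  expect_equal(g4$groups$sd_pmax, 0)
  # "more than three data points": three records stay ungrouped
  g3 <- group_by_pressure(data.frame(pmax_kPa = rep(478, 3L)))
  expect_equal(nrow(g3$groups), 0L)
  expect_true(all(is.na(g3$assignment)))
})

test_that("grouping is permutation-invariant and partitions the records", {
  ds <- generate_dataset(list(seed = 71, pressure_cv = 0.01, detach = NULL))
  recs <- ds$records
  g <- group_by_pressure(recs)
  set.seed(72)
  perm <- sample(nrow(recs))
  gp <- group_by_pressure(recs[perm, ])
  expect_identical(gp$assignment, g$assignment[perm])
  expect_equal(sum(!is.na(g$assignment)) + sum(is.na(g$assignment)),
               nrow(recs))
})

test_that("grouping round-trips the fifteen design levels", {
  ds <- generate_dataset(list(seed = 73, pressure_cv = 0.01, detach = NULL))
  g <- group_by_pressure(ds$records)
  expect_equal(nrow(g$groups), 15L)
  tab <- table(ds$records$group_label, g$assignment)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("per-group lines are exact on linear data and expose the pressure trend", {
  recs <- data.frame(pmax_kPa = rep(c(500, 1000), each = 10L),
                     A_initial_um2 = rep(seq(200, 650, length.out = 10L), 2L))
  recs$zeta <- 2 - 0.001 * recs$A_initial_um2
  g <- group_by_pressure(recs)
  lines <- fit_group_lines(g)
  expect_equal(lines$slope, rep(-0.001, 2L), tolerance = 1e-10)
  expect_equal(lines$intercept, rep(2, 2L), tolerance = 1e-10)
  recs$zeta <- 1.4
  lines0 <- fit_group_lines(group_by_pressure(recs))
  expect_equal(lines0$slope, rep(0, 2L), tolerance = 1e-12)
  # degenerate spread
  bad <- data.frame(pmax_kPa = rep(500, 5L), A_initial_um2 = 300,
                    zeta = stats::runif(5L, 1, 2))
  lb <- fit_group_lines(group_by_pressure(bad))
  expect_match(lb$error[1L], "degenerate")
  # small cells in the high-pressure levels deform the most
  ds <- generate_dataset(list(seed = 74, pressure_cv = 0.01, detach = NULL))
  sub <- ds$records[ds$records$A_initial_um2 < 500, ]
  mz <- tapply(sub$zeta, sub$group_label, mean)
  lv <- default_pressure_levels()
  expect_gt(mean(mz[c("Lvl14", "Lvl15")], na.rm = TRUE),
            mean(mz[c("Lvl1", "Lvl2")], na.rm = TRUE))
})

test_that("shrinking cells are counted and match a calibrated probability", {
  expect_equal(count_shrinking(data.frame(zeta = c(1, 1, 1)))$count, 0L)
  expect_equal(count_shrinking(data.frame(zeta = c(0.9, 1.1, 1)))$count, 1L)
  # flat response + symmetric fluctuation: shrink probability one half
  cell <- data.frame(cell_id = 1L, area_um2 = 300, perimeter_um = 65,
                     angle_deg = 0)
  mflat <- state_equation("exponential", A0 = 300, p0 = 100, p_ref = 1e9)
  wf <- generate_waveform(100, 900, 0.1, 2e5)
  set.seed(81)
  z <- replicate(400, simulate_response(cell, wf, mflat,
                                        noise_spec("stationary", 0.05))$zeta)
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.5)
  cnt <- count_shrinking(data.frame(zeta = z))$count
  expect_true(cnt >= ci[1L] && cnt <= ci[2L])
})

test_that("noiseless fits recover the generating parameters essentially exactly", {
  ds <- generate_dataset(list(seed = 91, noise = noise_spec(amplitude = 0),
                              detach = NULL))
  f <- fit_state_equation(ds$records, "tait", seed = 1)
  expect_true(f$converged)
  expect_equal(unname(coef(f)), c(1.5, 0.8), tolerance = 1e-6)
  # exponential family
  me <- state_equation("exponential", A0 = 550, p0 = 101.325, p_ref = 5000,
                       Bprime = -0.2)
  dse <- generate_dataset(list(seed = 92, model = me, detach = NULL,
                               noise = noise_spec(amplitude = 0)))
  fe <- fit_state_equation(dse$records, "exponential", seed = 1)
  expect_equal(unname(coef(fe)), c(-0.2, 5000), tolerance = 1e-6)
  # li family (one parameter, no size coupling)
  ml <- state_equation("li", A0 = 550, p0 = 101.325, alpha1 = 0.4)
  dsl <- generate_dataset(list(seed = 93, model = ml, coupling = NULL,
                               detach = NULL, noise = noise_spec(amplitude = 0)))
  fl <- fit_state_equation(dsl$records, "li", coupling = NULL, seed = 1)
  expect_equal(unname(coef(fl)), 0.4, tolerance = 1e-5)
})

test_that("detached records are excluded from fits by default", {
  ds <- generate_dataset(list(seed = 95,
                              detach = list(intercept = 0, slope = 0)))  # 50%
  f <- fit_state_equation(ds$records, "tait", seed = 1)
  expect_equal(f$n, sum(!ds$records$detached))
  f2 <- fit_state_equation(ds$records, "tait", seed = 1,
                           include_detached = TRUE)
  expect_equal(f2$n, nrow(ds$records))
  expect_error(fit_state_equation(ds$records[1:6, ], "tait"), "at least 10")
})

test_that("recovery improves as the fluctuation amplitude decreases", {
  errs <- vapply(c(0.1, 0.05, 0.01, 0), function(a) {
    rep <- recovery_harness(list(noise_amplitude = a, n_replicates = 6L,
                                 seed = 101L))
    max(rep$summary$median_abs_rel_error)
  }, numeric(1L))
  expect_lt(errs[4L], 1e-8)                    # zero noise: zero bias
  expect_true(all(diff(errs) < 1e-3))          # non-increasing with noise
  expect_lt(errs[2L], 0.1)
})
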
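# The multi-photopeak estimator: forward model identities, linearized
# initial estimates, the joint weighted fit, its pathologies, and the
# evaluation metrics.

cal_parts <- function(truth) list(sens = lapply(truth, `[[`, "sensitivity"),
                                  bup = lapply(truth, `[[`, "buildup"))

test_that("the forward model collapses to its boundary identities", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  p <- cal_parts(truth)
  at0 <- forward_model(5, 0, mu, p$sens, p$bup)
  for (nm in names(at0))
    expect_equal(at0[[nm]], 5 * (p$sens[[nm]]$c0 + p$sens[[nm]]$c1))
  expect_equal(unname(forward_model(0, 30, mu, p$sens, p$bup)), c(0, 0, 0))
  # independently evaluated arithmetic at A = 10, d = 30
  got <- forward_model(10, 30, mu, p$sens, p$bup)
  expect_equal(unname(got), unname(oracle_rates(10, 30, mu, truth)))
  expect_error(forward_model(10, 30, mu[c("55", "113")], p$sens, p$bup,
                             windows = c("55", "113", "208")),
               "missing calibration")
  expect_true(isTRUE(attr(forward_model(1, -5, mu, p$sens, p$bup),
                          "negative_depth")))
})

test_that("modelled rates decrease monotonically with depth for k < 1", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  p <- cal_parts(truth)
  d_grid <- seq(0, 120, 0.5)
  for (nm in names(mu)) {
    rates <- vapply(d_grid, function(d)
      forward_model(1, d, mu, p$sens, p$bup)[[nm]], numeric(1))
    expect_true(all(diff(rates) < 0), label = paste("monotone window", nm))
  }
})

test_that("initial estimates invert model-consistent rates exactly", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  sens <- lapply(truth, `[[`, "sensitivity")
  A_true <- 5; d_true <- 25
  rates <- vapply(names(mu), function(nm)
    A_true * eval_sensitivity(sens[[nm]], 20) * exp(-d_true * mu[[nm]]),
    numeric(1))
  ms <- measurement_set(data.frame(window = names(mu), rate_cps = rates,
                                   variance = rates / 100))
  init <- initial_estimate(ms, mu, sens, d_fix = 20)
  expect_equal(unname(init["A0"]), 5, tolerance = 1e-10)
  expect_equal(unname(init["d0"]), 25, tolerance = 1e-10)
})

test_that("two-window initial estimates equal the closed-form two-point line", {
  truth <- fixture_truth()
  mu <- fixture_mu()[c("55", "208")]
  sens <- lapply(truth[c("55", "208")], `[[`, "sensitivity")
  r <- c(3.2, 5.9)
  ms <- measurement_set(data.frame(window = c("55", "208"), rate_cps = r,
                                   variance = r / 100))
  init <- initial_estimate(ms, mu, sens, d_fix = 20)
  y <- log(r / c(eval_sensitivity(sens[["55"]], 20),
                 eval_sensitivity(sens[["208"]], 20)))
  d_closed <- (y[1] - y[2]) / (mu[["208"]] - mu[["55"]])
  A_closed <- exp(y[1] + d_closed * mu[["55"]])
  expect_equal(unname(init["d0"]), d_closed)
  expect_equal(unname(init["A0"]), A_closed)
})

test_that("equal rates with equal sensitivities give zero initial depth", {
  mu <- fixture_mu()
  sens <- lapply(names(mu), function(nm)
    sensitivity_model(0.5, 10, 0.02, nm, "MEGP", TRUE))
  names(sens) <- names(mu)
  ms <- measurement_set(data.frame(window = names(mu), rate_cps = rep(4, 3),
                                   variance = rep(0.04, 3)))
  init <- initial_estimate(ms, mu, sens)
  expect_equal(unname(init["d0"]), 0, tolerance = 1e-10)
})

test_that("nearly equal attenuation coefficients are refused as unidentifiable", {
  truth <- fixture_truth()
  sens <- lapply(truth, `[[`, "sensitivity")
  mu_flat <- c("55" = 0.0170, "113" = 0.01701, "208" = 0.017)
  ms <- measurement_set(data.frame(window = names(mu_flat),
                                   rate_cps = c(3, 4, 5),
                                   variance = c(0.03, 0.04, 0.05)))
  expect_error(initial_estimate(ms, mu_flat, sens), "unidentifiable")
  expect_error(estimate_activity_depth(ms, mu_flat, truth), "unidentifiable")
})

test_that("noise-free forward rates are inverted to near machine precision", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  spec <- scenario_spec(8, 35, material_library()$soft_tissue, truth,
                        duration_s = 300, seed = 1)
  ms <- simulate_measurement(spec, noise = FALSE)
  res <- estimate_activity_depth(ms, mu, truth)
  expect_true(res$converged)
  expect_equal(res$A, 8, tolerance = 1e-6)
  expect_equal(res$d, 35, tolerance = 1e-6)
  expect_false(res$negative_depth)
})

test_that("all weighting modes share the optimum for a common duration", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  spec <- scenario_spec(12, 28, material_library()$soft_tissue, truth,
                        duration_s = 300, seed = 5)
  ms <- simulate_measurement(spec)
  res_p <- estimate_activity_depth(ms, mu, truth, weight_mode = "poisson")
  res_i <- estimate_activity_depth(ms, mu, truth, weight_mode = "inverse_rate")
  expect_equal(res_p$A, res_i$A, tolerance = 1e-6)
  expect_equal(res_p$d, res_i$d, tolerance = 1e-6)
})

test_that("rescaling all rates rescales the activity and leaves depth fixed", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  spec <- scenario_spec(6, 40, material_library()$soft_tissue, truth,
                        duration_s = 300, seed = 9)
  ms <- simulate_measurement(spec)
  res <- estimate_activity_depth(ms, mu, truth)
  lam <- 3.7
  ms2 <- ms
  ms2$rates$rate_cps <- ms$rates$rate_cps * lam
  ms2$rates$variance <- ms$rates$variance * lam^2
  res2 <- estimate_activity_depth(ms2, mu, truth)
  expect_equal(res2$A, lam * res$A, tolerance = 1e-6)
  expect_equal(res2$d, res$d, tolerance = 1e-5)
})

test_that("excess 55-keV signal drives the unconstrained fit to negative depth,
           while bounded mode stops at the boundary", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  p <- cal_parts(truth)
  # rates generated at a (non-physical) negative depth have relatively too
  # many 55-keV counts for any positive depth
  rates <- forward_model(10, -15, mu, p$sens, p$bup)
  ms <- measurement_set(data.frame(window = names(rates),
                                   rate_cps = unname(rates),
                                   variance = unname(rates) / 300))
  res <- estimate_activity_depth(ms, mu, truth)
  expect_true(res$negative_depth)
  expect_lt(res$d, 0)
  expect_equal(res$d, -15, tolerance = 1e-4)
  res_b <- estimate_activity_depth(ms, mu, truth, bounded = TRUE)
  expect_false(res_b$negative_depth)
  expect_gte(res_b$d, 0)
  expect_lt(res_b$d, 0.5)
})

test_that("TEW-clamped zero-rate windows are excluded with a warning", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  p <- cal_parts(truth)
  rates <- forward_model(9, 30, mu, p$sens, p$bup)
  df <- data.frame(window = names(rates), rate_cps = unname(rates),
                   variance = unname(rates) / 300, clamped = FALSE)
  df$rate_cps[df$window == "55"] <- 0
  df$clamped[df$window == "55"] <- TRUE
  df$variance[df$window == "55"] <- 1e-4
  ms <- measurement_set(df)
  expect_warning(res <- estimate_activity_depth(ms, mu, truth), "clamped")
  expect_setequal(res$windows_used, c("113", "208"))
  expect_equal(res$A, 9, tolerance = 1e-5)
  expect_equal(res$d, 30, tolerance = 1e-4)
})

test_that("an explicit window mask drops the 208-keV window", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  spec <- scenario_spec(10, 20, material_library()$soft_tissue, truth,
                        duration_s = 600, seed = 12)
  ms <- simulate_measurement(spec)
  res <- estimate_activity_depth(ms, mu, truth, window_mask = c("55", "113"))
  expect_setequal(res$windows_used, c("55", "113"))
  expect_true(res$converged)
})

test_that("gross measurements cannot use TEW calibration entries", {
  truth_tew <- fixture_truth("MEGP", TRUE)
  mu <- fixture_mu()
  spec <- scenario_spec(10, 20, material_library()$soft_tissue, truth_tew,
                        scatter_corrected = FALSE, duration_s = 300, seed = 2)
  # measurement flagged as gross, calibration fitted on TEW net rates
  ms <- simulate_measurement(spec)
  expect_error(estimate_activity_depth(ms, mu, truth_tew), "refused")
})

test_that("the WLS optimum matches the exhaustive grid-search oracle", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  for (s in 1:6) {
    set.seed(1000 + s)
    A_true <- runif(1, 4, 20); d_true <- runif(1, 5, 60)
    spec <- scenario_spec(A_true, d_true, material_library()$soft_tissue,
                          truth, duration_s = 300, seed = s)
    ms <- simulate_measurement(spec)
    res <- estimate_activity_depth(ms, mu, truth)
    ora <- grid_search_estimate(ms, mu, truth)
    expect_true(grid_oracle_agrees(res, ora),
                label = paste("grid agreement, replicate", s))
    # sanity: the two optima sit in the same neighbourhood
    expect_equal(res$A, ora$A, tolerance = 0.02)
    expect_lt(abs(res$d - ora$d), 1.5)
  }
})

test_that("activity bias vanishes as counts grow", {
  truth <- fixture_truth()
  mu <- fixture_mu()
  biases <- vapply(c(30, 300, 30000), function(dur) {
    errs <- vapply(1:40, function(s) {
      spec <- scenario_spec(10, 25, material_library()$soft_tissue, truth,
                            duration_s = dur, seed = s)
      ms <- simulate_measurement(spec)
      estimate_activity_depth(ms, mu, truth)$A - 10
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_lt(biases[3], biases[1])
  expect_lt(biases[3], 0.05)
})

test_that("evaluation metrics follow their definitions", {
  expect_equal(relative_deviation(10, 10), 0)
  expect_equal(relative_deviation(11.7, 10), 0.17)
  # measured one half-life later: decay correction doubles the estimate first
  expect_equal(relative_deviation(5, 10, dt_s = lu177_half_life()), 0)
  expect_error(relative_deviation(5, 0), "positive")
  expect_equal(depth_error(28, 24), 4)
  expect_equal(depth_error(24, 28), -depth_error(28, 24))
})
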
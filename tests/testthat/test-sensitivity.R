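make_table1_data <- function(n, gamma, p1, p0, seed, beta = 1) {
  scen <- table1_scenario(gamma, p1, p0, beta = beta)
  generate_dataset(scen, n, seed = seed)
}

test_that("gamma = 0 reproduces the unadjusted analysis exactly", {
  smp <- make_table1_data(500, 1, 0.9, 0.1, seed = 41)
  fit <- fit_reduced_cox(smp)
  b <- unname(fit$coefficients["exposure"]); s <- unname(fit$se["exposure"])
  map <- build_score_map(smp, fit, sensitivity_params(0, confounder_binary(0.9, 0.1)))
  expect_true(map$identity)
  expect_identical(corrected_estimate(map, fit)$beta_corrected, b)
  expect_identical(corrected_pvalue(map, fit, 0), 2 * pnorm(-abs(b / s)))
  expect_equal(corrected_pvalue(map, fit, b), 1)
  ci <- ci_bound_transform(map, fit)
  expect_identical(as.numeric(ci), sort(b + c(-1, 1) * qnorm(0.975) * s))
  hdi <- ci_bootstrap_hdi(map, fit, B = 50000, seed = 3)
  expect_lt(max(abs(as.numeric(hdi) - as.numeric(ci))), 0.01)
})

test_that("the score map round-trips, is monotone and self-consistent", {
  smp <- make_table1_data(1000, 1, 0.9, 0.1, seed = 42)
  fit <- fit_reduced_cox(smp)
  map <- build_score_map(smp, fit, sensitivity_params(1, confounder_binary(0.9, 0.1)))
  expect_true(map$monotone)
  expect_lt(abs(map$diagnostics$self_consistency), 1e-6)
  # round trip over the working range
  bs <- seq(quantile(map$grid$beta, 0.1), quantile(map$grid$beta, 0.9),
            length.out = 20)
  for (b in bs)
    expect_lt(abs(map$h(map$h_inverse(map$h(b))) - map$h(b)), 1e-6)
  expect_equal(corrected_estimate(map, fit)$beta_corrected,
               map$h_inverse(map$beta_star_hat), tolerance = 1e-7)
})

test_that("the correction recovers the true effect over replicates", {
  gamma <- 2; p1 <- 0.1; p0 <- 0.9; beta <- log(2)
  scen <- scenario(exposure_binary(0.5), confounder_binary(p1, p0),
                   gamma = gamma, beta = beta,
                   censoring = censoring_uniform(1))
  scen <- calibrate_censoring(scen, 0.5, solve_for = "baseline")$scenario
  params <- sensitivity_params(gamma, scen$confounder)
  est <- vapply(1:100, function(r) {
    smp <- generate_dataset(scen, 5000, seed = 6000 + r)
    fit <- fit_reduced_cox(smp)
    build_score_map(smp, fit, params)$beta_corrected
  }, 0)
  expect_lt(abs(mean(est) - beta), 0.03)
})

test_that("correcting for a balanced covariate de-attenuates", {
  scen <- scenario(exposure_binary(0.5), confounder_binary(0.5, 0.5),
                   gamma = 0.8, beta = log(2))
  smp <- generate_dataset(scen, 4000, seed = 43)
  fit <- fit_reduced_cox(smp)
  map <- build_score_map(smp, fit,
                         sensitivity_params(0.8, confounder_binary(0.5, 0.5)))
  expect_gt(map$beta_corrected, map$beta_star_hat)
})

test_that("the corrected test is approximately sized under a true null", {
  scen <- scenario(exposure_binary(0.5), confounder_binary(0.7, 0.3),
                   gamma = 1.5, beta = 0, censoring = censoring_uniform(1))
  scen <- calibrate_censoring(scen, 0.5, solve_for = "baseline")$scenario
  params <- sensitivity_params(1.5, scen$confounder)
  pv <- vapply(1:200, function(r) {
    smp <- generate_dataset(scen, 600, seed = 7000 + r)
    fit <- fit_reduced_cox(smp)
    corrected_pvalue(build_score_map(smp, fit, params), fit, 0)
  }, 0)
  rate <- mean(pv < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("interval constructions agree and order correctly", {
  smp <- make_table1_data(2000, 1, 0.9, 0.1, seed = 44)
  fit <- fit_reduced_cox(smp)
  map <- build_score_map(smp, fit, sensitivity_params(1, confounder_binary(0.9, 0.1)))
  cb <- ci_bound_transform(map, fit)
  hdi <- ci_bootstrap_hdi(map, fit, B = 50000, seed = 9)
  expect_lt(max(abs(as.numeric(cb) - as.numeric(hdi))), 0.02)
  expect_identical(as.numeric(ci_bootstrap_hdi(map, fit, B = 2000, seed = 5)),
                   as.numeric(ci_bootstrap_hdi(map, fit, B = 2000, seed = 5)))

  set.seed(45)
  for (r in 1:12) {
    gm <- runif(1, -1.5, 1.5)
    cf <- confounder_binary(runif(1, 0.15, 0.85), runif(1, 0.15, 0.85))
    m <- build_score_map(smp, fit, sensitivity_params(gm, cf))
    ci <- ci_bound_transform(m, fit)
    expect_lt(ci[1], m$beta_corrected)
    expect_gt(ci[2], m$beta_corrected)
  }
})

test_that("a degenerate sensitivity grid reduces to the unadjusted analysis", {
  smp <- make_table1_data(800, 1.5, 0.8, 0.2, seed = 46)
  fit <- fit_reduced_cox(smp)
  g <- sensitivity_grid(smp, gamma_grid = 0, p1_grid = 0.5, fit = fit)
  b <- unname(fit$coefficients["exposure"]); s <- unname(fit$se["exposure"])
  expect_equal(nrow(g), 1)
  expect_identical(g$point, b)
  expect_identical(g$p_value, 2 * pnorm(-abs(b / s)))
  expect_identical(g$ci_lower, b - qnorm(0.975) * s)
  expect_equal(g$status, "ok")
  expect_error(sensitivity_grid(smp, numeric(), p1_grid = 0.5), "empty")
})

test_that("corrected estimates move monotonically along the gamma grid", {
  smp <- make_table1_data(3000, 1.5, 0.8, 0.2, seed = 47)
  g <- sensitivity_grid(smp, gamma_grid = seq(0, 2, by = 0.5),
                        p1_grid = 0.5, p0_grid = 0.5, outputs = "point")
  expect_true(all(g$status == "ok"))
  expect_true(all(diff(g$point) > 0) || all(diff(g$point) < 0))
})

test_that("the grid cell at the true parameters recovers a true null", {
  scen <- scenario(exposure_binary(0.5), confounder_binary(0.7, 0.3),
                   gamma = 2, beta = 0, censoring = censoring_uniform(1))
  scen <- calibrate_censoring(scen, 0.5, solve_for = "baseline")$scenario
  smp <- generate_dataset(scen, 10000, seed = 48)
  g <- sensitivity_grid(smp, gamma_grid = 2, p1_grid = 0.7, p0_grid = 0.3,
                        outputs = "point")
  expect_equal(g$status, "ok")
  expect_lt(abs(g$point), 0.05)
})
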
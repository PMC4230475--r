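test_that("the generator respects its censoring law and seed discipline", {
  scen <- scenario(exposure_binary(0.5), confounder_binary(0.3, 0.6),
                   gamma = 1, beta = 0.5)
  smp <- generate_dataset(scen, 300, seed = 51)
  expect_true(all(smp$data$event == 1))

  smp2 <- generate_dataset(scen, 300, seed = 51)
  expect_identical(smp$data, smp2$data)
  expect_false(identical(smp$data,
                         generate_dataset(scen, 300, seed = 52)$data))

  # omitted covariate is dropped unless explicitly requested
  expect_null(attr(smp, "confounder"))
  smp3 <- generate_dataset(scen, 300, seed = 51, keep_confounder = TRUE)
  expect_length(attr(smp3, "confounder"), 300)

  # exposure-dependent censoring: arm 1 censored far more often
  scen2 <- scenario(exposure_binary(0.5), confounder_binary(0.5, 0.5),
                    gamma = 0, beta = 0,
                    censoring = censoring_uniform(c(4, 0.5)))
  d4 <- generate_dataset(scen2, 4000, seed = 53)$data
  expect_gt(mean(d4$event[d4$exposure == 0]),
            mean(d4$event[d4$exposure == 1]) + 0.1)
})

test_that("a null model produces exchangeable arms", {
  scen <- scenario(exposure_binary(0.5), confounder_binary(0.4, 0.4),
                   gamma = 0, beta = 0)
  d <- generate_dataset(scen, 10000, seed = 54)$data
  ks <- suppressWarnings(stats::ks.test(d$time[d$exposure == 1],
                                        d$time[d$exposure == 0]))
  expect_gt(ks$p.value, 0.001)
})

test_that("censoring calibration hits its target in model and simulation", {
  base <- scenario(exposure_binary(0.5), confounder_binary(0.9, 0.1),
                   gamma = 1, beta = 1, censoring = censoring_uniform(1))
  cal <- calibrate_censoring(base, 0.5, solve_for = "baseline")
  expect_lt(abs(cal$implied["overall"] - 0.5), 1e-6)
  d <- generate_dataset(cal$scenario, 100000, seed = 55)$data
  expect_lt(abs((1 - mean(d$event)) - 0.5), 0.01)

  # per-arm censoring-parameter calibration
  cal2 <- calibrate_censoring(base, 0.3, solve_for = "censoring",
                              per_arm = TRUE)
  expect_lt(max(abs(cal2$implied - 0.3)), 1e-4)
  d2 <- generate_dataset(cal2$scenario, 100000, seed = 56)$data
  for (arm in 0:1)
    expect_lt(abs((1 - mean(d2$event[d2$exposure == arm])) - 0.3), 0.012)

  # harsher targets need shorter censoring windows, strictly ordered
  thetas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(tg)
    calibrate_censoring(base, tg, solve_for = "censoring",
                        per_arm = FALSE)$parameters[1], 0)
  expect_true(all(diff(thetas) < 0))

  cal0 <- calibrate_censoring(base, 0)
  expect_identical(cal0$scenario$censoring$kind, "none")
})

test_that("bias-curve runs compare simulation, solver and Taylor routes", {
  scen <- scenario(exposure_binary(0.5), confounder_binary(0.5, 0.5),
                   gamma = 0, beta = log(2))
  tab <- run_bias_curve(scen, gamma_grid = c(0, 0.5, 2), n = 6000,
                        seed = 57, replicates = 2)
  expect_equal(names(tab), c("gamma", "bias_sim", "se_sim",
                             "bias_asymptotic", "bias_taylor"))
  z0 <- tab[tab$gamma == 0, ]
  expect_lt(abs(z0$bias_sim), 3 * z0$se_sim)
  expect_identical(z0$bias_asymptotic, 0)
  expect_identical(z0$bias_taylor, 0)
  # simulated and asymptotic biases agree within Monte Carlo error
  expect_true(all(abs(tab$bias_sim - tab$bias_asymptotic) <=
                    3 * tab$se_sim + 0.02))
  # Taylor error grows with gamma
  err <- abs(tab$bias_taylor - tab$bias_asymptotic)
  expect_gt(err[tab$gamma == 2], err[tab$gamma == 0.5])
})

test_that("the coverage-table runner is reproducible and internally coherent", {
  rows <- data.frame(gamma = c(1, 2), p1 = c(0.9, 0.5), p0 = c(0.1, 0.5))
  t1 <- run_table1(rows, n = 250, replicates = 10, seed = 58)
  t2 <- run_table1(rows, n = 250, replicates = 10, seed = 58)
  expect_identical(t1, t2)
  expect_true(all(t1$coverage_proposed >= 0 & t1$coverage_proposed <= 100))
  expect_true(all(abs(t1$fraction_censored - 0.5) < 0.1))
  expect_true(all(t1$n_failed == 0))
  # balanced covariate: the rare-event correction is no adjustment at all
  bal <- t1[t1$p1 == t1$p0, ]
  expect_identical(bal$bias_lin, bal$bias_unadjusted)
  expect_identical(bal$coverage_lin, bal$coverage_unadjusted)
  # replicate subsets are prefixes: fewer replicates, same substreams
  t3 <- run_table1(rows[1, ], n = 250, replicates = 5, seed = 58)
  expect_lt(abs(t3$lambda0 - t1$lambda0[1]), 1e-12)
})

test_that("independent measured covariates barely move the bias at modest gamma", {
  base <- scenario(exposure_binary(0.5), confounder_binary(0.5, 0.5),
                   gamma = 1, beta = 1, censoring = censoring_uniform(2))
  z1 <- list(list(name = "z1", coef = 0,
                  sampler = function(n) rbinom(n, 1, 0.5)))
  without_z <- run_additional_covariate_study(list(), 1, n = 20000,
                                              seed = 59, scenario_obj = base)
  with_z0 <- run_additional_covariate_study(z1, 1, n = 20000,
                                            seed = 60, scenario_obj = base)
  expect_lt(abs(with_z0$bias - without_z$bias), 0.05)
})

test_that("bias grows with the number of measured covariates at extreme gamma", {
  base <- scenario(exposure_binary(0.5), confounder_binary(0.5, 0.5),
                   gamma = -5, beta = 1, censoring = censoring_uniform(2))
  zs <- lapply(1:3, function(i)
    list(name = paste0("z", i), coef = 1,
         sampler = function(n) rbinom(n, 1, 0.5)))
  one <- run_additional_covariate_study(zs[1], -5, n = 30000, seed = 61,
                                        scenario_obj = base)
  three <- run_additional_covariate_study(zs, -5, n = 30000, seed = 61,
                                          scenario_obj = base)
  expect_gte(abs(three$bias), abs(one$bias) - 0.02)
})
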
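nocensor_scen <- function(gamma = 2, beta = log(2), p1 = 0.5, p0 = 0.5,
                          lambda0 = 1)
  scenario(exposure_binary(0.5), confounder_binary(p1, p0), gamma = gamma,
           beta = beta, lambda0 = lambda0)

test_that("every method is exact when no covariate is omitted", {
  scen <- nocensor_scen(gamma = 0)
  for (f in list(solve_beta_star, eq9_binary_beta_star,
                 eq10_nocensor_beta_star, taylor_beta_star,
                 rare_event_relation))
    expect_identical(f(scen)$bias, 0)
  expect_lt(abs(as.numeric(score_limit(scen$beta, scen))), 1e-7)
})

test_that("the score limit is strictly decreasing around the root", {
  scen <- nocensor_scen()
  b <- seq(scen$beta - 3, scen$beta + 3, length.out = 20)
  g <- vapply(b, function(bb) as.numeric(score_limit(bb, scen)), 0)
  expect_true(all(diff(g) < 0))
})

test_that("omitting a balanced covariate attenuates the effect", {
  scen <- nocensor_scen(gamma = 2, beta = log(2))
  res <- solve_beta_star(scen)
  expect_gt(res$beta_star, 0)
  expect_lt(res$beta_star, log(2))
})

test_that("the three code paths agree without censoring", {
  set.seed(31)
  for (r in 1:10) {
    scen <- nocensor_scen(gamma = runif(1, 0.2, 2) * sample(c(-1, 1), 1),
                          beta = runif(1, -1, 1),
                          p1 = runif(1, 0.1, 0.9), p0 = runif(1, 0.1, 0.9),
                          lambda0 = exp(runif(1, -2, 2)))
    a <- solve_beta_star(scen)$beta_star
    b <- eq10_nocensor_beta_star(scen)$beta_star
    c9 <- eq9_binary_beta_star(scen)$beta_star
    expect_lt(abs(a - b), 1e-6)
    expect_lt(abs(a - c9), 1e-6)
  }
})

test_that("the asymptotic value does not depend on the baseline rate without censoring", {
  vals <- vapply(c(0.1, 1, 10), function(l0)
    solve_beta_star(nocensor_scen(gamma = 1.5, beta = 0.8, p1 = 0.8,
                                  p0 = 0.2, lambda0 = l0))$beta_star, 0)
  expect_lt(max(vals) - min(vals), 1e-6)
  vals10 <- vapply(c(0.1, 1, 10), function(l0)
    eq10_nocensor_beta_star(nocensor_scen(gamma = 1.5, beta = 0.8, p1 = 0.8,
                                          p0 = 0.2, lambda0 = l0))$beta_star, 0)
  expect_identical(vals10[1], vals10[2])
  expect_identical(vals10[2], vals10[3])
})

test_that("binary special case agrees with the general solver under censoring", {
  for (gm in c(-2, -1, 1, 2)) {
    for (pp in list(c(0.9, 0.1), c(0.5, 0.5))) {
      scen <- table1_scenario(gm, pp[1], pp[2])
      a <- solve_beta_star(scen)$beta_star
      e9 <- eq9_binary_beta_star(scen)$beta_star
      expect_lt(abs(a - e9), 1e-5)
    }
  }
})

test_that("the uncensoring-rate ratio is reported and sensible", {
  scen <- table1_scenario(1, 0.9, 0.1)
  r <- eq9_binary_beta_star(scen)$diagnostics$uncensoring_ratio
  # treated subjects fail faster here, so the control arm is censored more
  expect_true(is.finite(r) && r > 0)
  expect_lt(r, 1)
})

test_that("Taylor expansion is first-order accurate in gamma", {
  scen_small <- table1_scenario(0.25, 0.9, 0.1)
  scen_large <- table1_scenario(2, 0.9, 0.1)
  err_small <- abs(taylor_beta_star(scen_small)$beta_star -
                     solve_beta_star(scen_small)$beta_star)
  err_large <- abs(taylor_beta_star(scen_large)$beta_star -
                     solve_beta_star(scen_large)$beta_star)
  expect_lt(err_small, err_large)

  set.seed(32)
  for (r in 1:10) {
    scen <- nocensor_scen(gamma = 0.1, beta = runif(1, -1, 1),
                          p1 = runif(1, 0.2, 0.8), p0 = runif(1, 0.2, 0.8))
    expect_lt(abs(taylor_beta_star(scen)$beta_star -
                    solve_beta_star(scen)$beta_star), 0.01)
  }
})

test_that("rare-event relation: balanced covariates need no correction", {
  scen <- nocensor_scen(gamma = 3, p1 = 0.5, p0 = 0.5)
  expect_identical(rare_event_relation(scen)$bias, 0)
  params <- sensitivity_params(3, confounder_binary(0.5, 0.5))
  expect_equal(lin_correction(1.23, params), 1.23)
})

test_that("rare-event relation approximates the score limit under heavy censoring", {
  scen <- scenario(exposure_binary(0.5), confounder_uniform(0, 1),
                   gamma = 1, beta = log(2),
                   censoring = censoring_uniform(1))
  cal <- calibrate_censoring(scen, 0.95, solve_for = "baseline")
  re <- rare_event_relation(cal$scenario)$beta_star
  ex <- solve_beta_star(cal$scenario)$beta_star
  expect_lt(abs(re - ex), 0.02)
})

test_that("rare-event relation matches simulation in the 90%-censoring regime", {
  scen <- scenario(exposure_binary(0.5), confounder_uniform(0, 1),
                   gamma = 1, beta = log(2),
                   censoring = censoring_uniform(1))
  scen <- calibrate_censoring(scen, 0.9, solve_for = "baseline")$scenario
  ests <- vapply(1:150, function(r) {
    smp <- generate_dataset(scen, 5000, seed = 4000 + r)
    unname(fit_reduced_cox(smp)$coefficients["exposure"])
  }, 0)
  expect_lt(abs(rare_event_relation(scen)$beta_star - mean(ests)), 0.02)
})

test_that("bias tends to a finite limit as the omitted effect grows", {
  b10 <- eq10_nocensor_beta_star(nocensor_scen(10, log(2), 0.9, 0.1))$beta_star
  b12 <- eq10_nocensor_beta_star(nocensor_scen(12, log(2), 0.9, 0.1))$beta_star
  expect_lt(abs(b12 - b10), 0.01)
  # and with censoring, through the general quadrature
  s10 <- table1_scenario(10, 0.5, 0.5)
  s12 <- s10; s12$gamma <- 12
  expect_lt(abs(solve_beta_star(s12)$beta_star -
                  solve_beta_star(s10)$beta_star), 0.01)
})

test_that("censoring influences the balanced-covariate bias non-monotonically", {
  # the hump at moderate censoring emerges once the omitted effect is
  # large enough for the late risk sets to be dominated by one C stratum
  base <- scenario(exposure_binary(0.5), confounder_binary(0.5, 0.5),
                   gamma = 4, beta = 1, censoring = censoring_uniform(1))
  bias_at <- function(target) {
    scen <- if (target == 0) {
      s <- base; s$censoring <- censoring_none(); s
    } else calibrate_censoring(base, target, solve_for = "censoring",
                               per_arm = TRUE)$scenario
    abs(solve_beta_star(scen)$bias)
  }
  b0 <- bias_at(0); b50 <- bias_at(0.5); b90 <- bias_at(0.9)
  expect_gt(b50, b0)
  expect_gt(b50, b90)
})

test_that("confounding shifts the asymptotic estimate directionally", {
  b_up <- solve_beta_star(table1_scenario(1, 0.9, 0.1))$beta_star
  b_bal <- solve_beta_star(table1_scenario(1, 0.5, 0.5))$beta_star
  b_dn <- solve_beta_star(table1_scenario(1, 0.1, 0.9))$beta_star
  expect_gt(b_up, b_bal)
  expect_gt(b_bal, b_dn)
})

test_that("a true null with a balanced covariate stays null", {
  scen <- table1_scenario(2, 0.5, 0.5, beta = 0)
  expect_lt(abs(solve_beta_star(scen)$beta_star), 1e-7)
  expect_lt(abs(eq9_binary_beta_star(scen)$beta_star), 1e-7)
})

test_that("marginal hazard ratios behave as non-proportionality predicts", {
  scen0 <- nocensor_scen(gamma = 0, beta = log(2))
  expect_equal(marginal_hazard_ratio(scen0, c(0.01, 1, 5)),
               rep(2, 3), tolerance = 1e-10)
  scen <- nocensor_scen(gamma = 2, beta = log(2))
  mhr <- marginal_hazard_ratio(scen, c(0.01, 0.3))
  expect_gt(abs(mhr[1] - mhr[2]), 0.1)
  scen2 <- nocensor_scen(gamma = 1.5, beta = log(2), p1 = 0.8, p0 = 0.2)
  lim0 <- exp(log(2)) * mgf(scen2$confounder, 1.5, 1) /
    mgf(scen2$confounder, 1.5, 0)
  expect_equal(marginal_hazard_ratio(scen2, 1e-6), lim0, tolerance = 1e-4)
})

test_that("the solver matches the reduced-model fit on a large sample", {
  scen <- table1_scenario(1.5, 0.9, 0.1)
  smp <- generate_dataset(scen, 200000, seed = 77)
  fit <- fit_reduced_cox(smp)
  expect_lt(abs(unname(fit$coefficients["exposure"]) -
                  solve_beta_star(scen)$beta_star),
            3 * unname(fit$se["exposure"]))
})
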
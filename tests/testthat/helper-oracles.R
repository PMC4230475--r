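# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals.

# Newton-Raphson on the exact Cox partial likelihood (Breslow ties),
# with naive O(n * events) risk-set sums.
oracle_cox_nr <- function(y, d, x, tol = 1e-10, max_iter = 50) {
  b <- 0
  for (it in seq_len(max_iter)) {
    w <- exp(b * x)
    ev <- which(d == 1)
    U <- 0; I <- 0
    for (i in ev) {
      at_risk <- y >= y[i]
      s0 <- sum(w[at_risk])
      s1 <- sum(x[at_risk] * w[at_risk])
      s2 <- sum(x[at_risk]^2 * w[at_risk])
      U <- U + x[i] - s1 / s0
      I <- I + s2 / s0 - (s1 / s0)^2
    }
    step <- U / I
    b <- b + step
    if (abs(step) < tol) break
  }
  b
}

# Nelson-Aalen cumulative hazard (no covariates)
oracle_nelson_aalen <- function(y, d) {
  tk <- sort(unique(y[d == 1]))
  dk <- vapply(tk, function(s) sum(y == s & d == 1), 0)
  nk <- vapply(tk, function(s) sum(y >= s), 0)
  list(time = tk, cumhaz = cumsum(dk / nk))
}

# The moderate-censoring reference design: binary exposure (P = 1/2),
# true log-hazard ratio 1, binary omitted covariate, Uniform(0,1)
# censoring with the exponential baseline rate calibrated so that the
# overall censoring fraction is 50%.
table1_scenario <- function(gamma, p1, p0, beta = 1) {
  scen <- scenario(exposure_binary(0.5), confounder_binary(p1, p0),
                   gamma = gamma, beta = beta,
                   censoring = censoring_uniform(1))
  calibrate_censoring(scen, 0.5, solve_for = "baseline")$scenario
}

# minimal cox_fit carrier with a fixed coefficient, for exercising the
# Breslow estimator at a known beta
null_exposure_fit <- function(sample, beta = 0) {
  structure(list(coefficients = c(exposure = beta),
                 covariate_names = character(),
                 fingerprint = coxsens:::sample_fingerprint(sample)),
            class = "cox_fit")
}
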
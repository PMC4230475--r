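#' Confounder models: the conditional law of the omitted covariate
#'
#' A confounder model describes the distribution of the omitted covariate
#' `C` conditional on the exposure `x`. It is a sensitivity input, never
#' estimated from data. Supported kinds:
#'
#' * **binary** — `P(C=1|X=1) = p1`, `P(C=1|X=0) = p0`; for non-binary
#'   exposures the probability is extended by the logistic link
#'   `P(C=1|x) = plogis(qlogis(p0) + (qlogis(p1)-qlogis(p0)) x)`, which
#'   matches `p0`/`p1` exactly at `x = 0`/`1`.
#' * **normal** — `C | x ~ N(mean0 + slope*x, sd^2)`.
#' * **uniform** — `C ~ U(min, max)`, independent of `x` (the regime used by
#'   the classical rare-event correction studies).
#' * **custom** — a user sampler `function(n, x)` plus an optional
#'   closed-form conditional moment generating function `mgf(s, x)`;
#'   expectations without a closed form use seeded Monte Carlo.
#'
#' Probabilities of exactly 0 or 1 are rejected: they make the omitted
#' covariate's effect unidentifiable in the correction.
#'
#' @param p1,p0 `P(C=1|X=1)` and `P(C=1|X=0)`, both in (0, 1).
#' @return An object of class `confounder_model`.
#' @export
confounder_binary <- function(p1, p0 = p1) {
  stopifnot(length(p1) == 1, length(p0) == 1)
  if (p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1)
    stop("p1 and p0 must lie strictly inside (0, 1)")
  structure(list(kind = "binary", p1 = p1, p0 = p0), class = "confounder_model")
}

#' @rdname confounder_binary
#' @param mean0 mean of `C` at `x = 0`.
#' @param slope change in the conditional mean per unit of `x`.
#' @param sd conditional standard deviation, > 0.
#' @export
confounder_normal <- function(mean0 = 0, slope = 0, sd = 1) {
  if (sd <= 0) stop("sd must be > 0")
  structure(list(kind = "normal", mean0 = mean0, slope = slope, sd = sd),
            class = "confounder_model")
}

#' @rdname confounder_binary
#' @param min,max support endpoints of the uniform confounder.
#' @export
confounder_uniform <- function(min = 0, max = 1) {
  if (max <= min) stop("max must exceed min")
  structure(list(kind = "uniform", min = min, max = max),
            class = "confounder_model")
}

#' @rdname confounder_binary
#' @param sampler `function(n, x)` drawing `n` values of `C` at scalar `x`.
#' @param mgf optional `function(s, x)` returning `E[exp(sC) | x]` exactly.
#' @param mc_draws Monte Carlo draws used when no closed form is available.
#' @param mc_seed dedicated seed for Monte Carlo expectations, independent of
#'   any data-generation seed.
#' @export
confounder_custom <- function(sampler, mgf = NULL, mc_draws = 10000,
                              mc_seed = 104729) {
  stopifnot(is.function(sampler))
  structure(list(kind = "custom", sampler = sampler, mgf_fun = mgf,
                 mc_draws = mc_draws, mc_seed = mc_seed),
            class = "confounder_model")
}

#' Binary confounder with logistic dependence on a continuous exposure
#'
#' `P(C=1|x) = plogis(intercept + slope * x)`. Use
#' [calibrate_binary_confounder()] to solve the two parameters from a target
#' marginal prevalence and a target correlation with the exposure.
#'
#' @param intercept,slope logistic coefficients.
#' @export
confounder_binary_logistic <- function(intercept, slope) {
  structure(list(kind = "binary_logistic", intercept = intercept,
                 slope = slope), class = "confounder_model")
}

#' Calibrate a logistic binary confounder to a marginal prevalence and
#' correlation
#'
#' Solves the two logistic parameters so that, over the supplied exposure
#' values, the marginal prevalence of `C` equals `marginal` and the
#' correlation `cor(X, C)` equals `rho`.
#'
#' @param x observed exposure values (defines the exposure distribution).
#' @param marginal target `P(C = 1)`.
#' @param rho target correlation between exposure and confounder.
#' @return A calibrated [confounder_binary_logistic()] model.
#' @export
calibrate_binary_confounder <- function(x, marginal, rho) {
  if (marginal <= 0 || marginal >= 1) stop("marginal must be in (0, 1)")
  if (abs(rho) >= 1) stop("rho must be in (-1, 1)")
  moments <- function(par) {
    p <- stats::plogis(par[1] + par[2] * x)
    m <- mean(p)
    v <- m * (1 - m)
    r <- if (v <= 0) 0 else
      mean((x - mean(x)) * p) / sqrt(stats::var(x) * v * (length(x) - 1) / length(x))
    c(m - marginal, r - rho)
  }
  par <- c(stats::qlogis(marginal), 0)
  for (i in 1:100) {
    f0 <- moments(par)
    if (max(abs(f0)) < 1e-10) break
    J <- matrix(0, 2, 2)
    h <- 1e-6
    for (j in 1:2) {
      pj <- par; pj[j] <- pj[j] + h
      J[, j] <- (moments(pj) - f0) / h
    }
    step <- tryCatch(solve(J, f0), error = function(e)
      stop("calibration failed: singular Jacobian"))
    par <- par - step
  }
  if (max(abs(moments(par))) > 1e-6)
    stop("calibration did not converge to the requested (marginal, rho)")
  confounder_binary_logistic(par[1], par[2])
}

prob_c1 <- function(model, x) {
  switch(model$kind,
         binary = stats::plogis(stats::qlogis(model$p0) +
                                  (stats::qlogis(model$p1) - stats::qlogis(model$p0)) * x),
         binary_logistic = stats::plogis(model$intercept + model$slope * x),
         stop("prob_c1 is defined for binary confounder kinds only"))
}

# Quadrature representation of C | x: nodes and weights such that
# E[f(C)|x] = sum(w * f(c)). Exact for binary; Gauss-Hermite for normal;
# Gauss-Legendre for uniform; fixed-seed Monte Carlo for custom.
cnodes <- function(model, x) {
  switch(model$kind,
    binary = ,
    binary_logistic = {
      p <- prob_c1(model, x)
      list(c = c(0, 1), w = c(1 - p, p), exact = TRUE)
    },
    normal = {
      gh <- pracma::gaussHermite(40)
      mu <- model$mean0 + model$slope * x
      list(c = mu + model$sd * sqrt(2) * gh$x, w = gh$w / sqrt(pi),
           exact = FALSE)
    },
    uniform = {
      gl <- pracma::gaussLegendre(48, model$min, model$max)
      list(c = gl$x, w = gl$w / (model$max - model$min), exact = FALSE)
    },
    custom = {
      draws <- with_seed(model$mc_seed, model$sampler(model$mc_draws, x))
      list(c = draws, w = rep(1 / length(draws), length(draws)),
           exact = FALSE, monte_carlo = TRUE)
    })
}

#' Conditional moment generating function of the omitted covariate
#'
#' Returns `E[exp(s C) | x]`. Exact (closed form) for binary, normal and
#' uniform kinds; custom kinds use their closed form when supplied and
#' seeded Monte Carlo otherwise.
#'
#' @param model a `confounder_model`.
#' @param s argument of the moment generating function.
#' @param x exposure value(s) conditioned on.
#' @export
mgf <- function(model, s, x) {
  out <- switch(model$kind,
    binary = ,
    binary_logistic = {
      p <- prob_c1(model, x)
      (1 - p) + p * exp(s)
    },
    normal = {
      mu <- model$mean0 + model$slope * x
      exp(s * mu + 0.5 * s^2 * model$sd^2)
    },
    uniform = {
      if (abs(s) < 1e-12) rep(1, length(x))
      else rep((exp(s * model$max) - exp(s * model$min)) /
                 (s * (model$max - model$min)), length(x))
    },
    custom = {
      if (!is.null(model$mgf_fun)) model$mgf_fun(s, x)
      else vapply(x, function(xi) {
        nd <- cnodes(model, xi)
        sum(nd$w * exp(s * nd$c))
      }, 0)
    })
  if (any(!is.finite(out)))
    stop("non-finite moment generating function value at s = ", s)
  out
}

#' Sample the omitted covariate conditional on exposure
#'
#' @param model a `confounder_model`.
#' @param x vector of exposure values; one draw of `C` is returned per entry.
#' @param seed optional seed; the caller's RNG stream is left untouched.
#' @export
sample_confounder <- function(model, x, seed = NULL) {
  with_seed(seed, switch(model$kind,
    binary = ,
    binary_logistic = stats::rbinom(length(x), 1, prob_c1(model, x)),
    normal = stats::rnorm(length(x), model$mean0 + model$slope * x, model$sd),
    uniform = stats::runif(length(x), model$min, model$max),
    custom = {
      out <- numeric(length(x))
      for (xi in unique(x)) {
        idx <- which(x == xi)
        out[idx] <- model$sampler(length(idx), xi)
      }
      out
    }))
}

#' Weighted exponential-tilt expectation of the omitted covariate
#'
#' Computes `E[w(C) exp(gamma C) | x]`, the building block of the bias and
#' correction formulae. With `weight = NULL` this is the conditional moment
#' generating function at `gamma`. Analytic (finite sum / quadrature-exact)
#' for binary, normal and uniform kinds; seeded Monte Carlo for custom kinds,
#' with a precision warning attribute when the relative Monte Carlo standard
#' error exceeds 0.5%.
#'
#' @param model a `confounder_model`.
#' @param gamma log-hazard effect of the omitted covariate.
#' @param x scalar exposure value conditioned on.
#' @param weight optional bounded `function(c)`.
#' @export
confounder_expect <- function(model, gamma, x, weight = NULL) {
  if (is.null(weight) && model$kind != "custom") return(mgf(model, gamma, x))
  nd <- cnodes(model, x)
  vals <- exp(gamma * nd$c)
  if (!is.null(weight)) vals <- vals * weight(nd$c)
  est <- sum(nd$w * vals)
  if (isTRUE(nd$monte_carlo)) {
    se <- stats::sd(vals) / sqrt(length(vals))
    if (est != 0 && se / abs(est) > 0.005)
      attr(est, "precision_warning") <-
        sprintf("Monte Carlo relative standard error %.3g exceeds 0.5%%",
                se / abs(est))
    attr(est, "mc_se") <- se
  }
  if (!is.finite(est)) stop("non-finite confounder expectation")
  est
}

#' Bundle of sensitivity parameters
#'
#' @param gamma assumed log-hazard effect of the omitted covariate; finite.
#' @param confounder a `confounder_model` for the law of `C` given exposure.
#' @export
sensitivity_params <- function(gamma, confounder) {
  if (!is.finite(gamma)) stop("gamma must be finite")
  if (!inherits(confounder, "confounder_model"))
    stop("confounder must be a confounder_model")
  structure(list(gamma = gamma, confounder = confounder),
            class = "sensitivity_params")
}
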
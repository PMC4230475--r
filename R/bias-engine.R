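# Asymptotic bias engine: the large-sample limit of the reduced-model
# partial-likelihood score and its special cases.
#
# Under the true hazard lambda0(t) exp(beta x + gamma c) with censoring
# survivor G(t|x), the average partial-likelihood score of the reduced model
# (exposure only, coefficient b) converges to
#
#   g(b) = E_X sum_C w_C  INT  [x - e(t, b)] G(t|x) f(t|x,c) dt
#   e(t, b) = E_X[ X e^{bX} R(t|X) ] / E_X[ e^{bX} R(t|X) ]
#   R(t|x)  = G(t|x) E_{C|x}[ exp(-Lambda0(t) e^{beta x + gamma C}) ]
#
# where f(t|x,c) is the true event-time density. The root b = beta_star of
# g defines the asymptotic value of the reduced-model MLE; bias = beta_star
# minus beta. Each (x, c) mixture component is integrated on its own
# probability scale u = 1 - exp(-Lambda0(t) e^{beta x + gamma c}), which maps
# the component's event-time density to Uniform(0,1) and keeps the
# quadrature accurate for effects as large as |gamma| ~ 12.

#' Exposure laws for data-generating scenarios
#'
#' @param p `P(X = 1)` for a binary exposure, in (0, 1).
#' @return An `exposure_law` object.
#' @export
exposure_binary <- function(p = 0.5) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  structure(list(kind = "binary", p = p), class = "exposure_law")
}

#' @rdname exposure_binary
#' @param mean,sd mean and standard deviation of a normal exposure.
#' @export
exposure_normal <- function(mean = 0, sd = 1) {
  if (sd <= 0) stop("sd must be > 0")
  structure(list(kind = "normal", mean = mean, sd = sd),
            class = "exposure_law")
}

xnodes <- function(law) {
  switch(law$kind,
    binary = list(x = c(0, 1), w = c(1 - law$p, law$p)),
    normal = {
      gl <- pracma::gaussLegendre(64, law$mean - 6 * law$sd,
                                  law$mean + 6 * law$sd)
      w <- gl$w * stats::dnorm(gl$x, law$mean, law$sd)
      list(x = gl$x, w = w / sum(w))
    })
}

#' Censoring laws for data-generating scenarios
#'
#' `theta`/`rate` may be a scalar (same in both arms), a length-2 vector
#' `c(arm0, arm1)` for a binary exposure, or a `function(x)`.
#'
#' @export
censoring_none <- function() structure(list(kind = "none"),
                                       class = "censoring_law")

#' @rdname censoring_none
#' @param theta upper end of the Uniform(0, theta) censoring-time law.
#' @export
censoring_uniform <- function(theta = 1)
  structure(list(kind = "uniform", theta = theta), class = "censoring_law")

#' @rdname censoring_none
#' @param rate rate of an exponential censoring-time law.
#' @export
censoring_exponential <- function(rate = 1)
  structure(list(kind = "exponential", rate = rate), class = "censoring_law")

#' @rdname censoring_none
#' @param survivor `function(t, x)` giving `P(censoring time >= t | x)`,
#'   non-increasing from 1.
#' @param sampler optional `function(n, x)` used by the data generator.
#' @export
censoring_custom <- function(survivor, sampler = NULL)
  structure(list(kind = "custom", survivor = survivor, sampler = sampler),
            class = "censoring_law")

cens_param <- function(param, x) {
  if (is.function(param)) return(param(x))
  if (length(param) == 2L) return(param[[as.integer(x) + 1L]])
  param
}

# vectorized over a subject-level exposure vector
cens_param_vec <- function(param, x) {
  if (is.function(param)) return(param(x))
  if (length(param) == 2L) return(param[as.integer(x) + 1L])
  rep(param, length(x))
}

cens_G <- function(law, t, x) {
  switch(law$kind,
    none = rep(1, length(t)),
    uniform = pmax(0, 1 - t / cens_param(law$theta, x)),
    exponential = exp(-cens_param(law$rate, x) * t),
    custom = law$survivor(t, x))
}

cens_tmax <- function(law, x) {
  switch(law$kind,
    none = Inf,
    uniform = cens_param(law$theta, x),
    exponential = Inf,
    custom = Inf)
}

#' Specify a data-generating scenario
#'
#' A complete data-generating mechanism: exposure law, conditional law of
#' the omitted covariate, true coefficients, exponential baseline hazard
#' (or a user-supplied cumulative hazard) and censoring law.
#'
#' @param exposure an [exposure_binary()] or [exposure_normal()] law.
#' @param confounder a `confounder_model`.
#' @param gamma true log-hazard effect of the omitted covariate.
#' @param beta true log-hazard effect of the exposure.
#' @param lambda0 exponential baseline hazard rate, > 0.
#' @param censoring a censoring law; default none.
#' @param baseline optional list with elements `cumhaz`, `inv_cumhaz` (and
#'   optionally `hazard`) replacing the exponential baseline.
#' @param covariates optional list of additional measured covariates for the
#'   data generator; each element is `list(name=, coef=, sampler=function(n))`.
#' @return An object of class `scenario`.
#' @export
scenario <- function(exposure, confounder, gamma, beta, lambda0 = 1,
                     censoring = censoring_none(), baseline = NULL,
                     covariates = NULL) {
  stopifnot(inherits(exposure, "exposure_law"),
            inherits(confounder, "confounder_model"),
            inherits(censoring, "censoring_law"))
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (!is.finite(gamma) || !is.finite(beta))
    stop("gamma and beta must be finite")
  structure(list(exposure = exposure, confounder = confounder, gamma = gamma,
                 beta = beta, lambda0 = lambda0, censoring = censoring,
                 baseline = baseline, covariates = covariates),
            class = "scenario")
}

Lam0 <- function(scen, t) {
  if (is.null(scen$baseline)) scen$lambda0 * t else scen$baseline$cumhaz(t)
}
Lam0_inv <- function(scen, s) {
  if (is.null(scen$baseline)) s / scen$lambda0 else scen$baseline$inv_cumhaz(s)
}

# capped quadrature nodes for the bias integrals (custom Monte Carlo models
# are thinned so the number of mixture components stays tractable)
cnodes_capped <- function(model, x, max_nodes = 256L) {
  nd <- cnodes(model, x)
  if (length(nd$c) > max_nodes) {
    idx <- round(seq(1L, length(nd$c), length.out = max_nodes))
    nd <- list(c = sort(nd$c)[idx], w = rep(1 / max_nodes, max_nodes))
  }
  nd
}

# shared pre-computation for the score integrals
scen_nodes <- function(scen) {
  xn <- xnodes(scen$exposure)
  cn <- lapply(xn$x, function(xi) cnodes_capped(scen$confounder, xi))
  mult <- lapply(seq_along(xn$x), function(i)
    exp(scen$beta * xn$x[i] + scen$gamma * cn[[i]]$c))
  list(xn = xn, cn = cn, mult = mult)
}

# at-risk probability R(t|x-node i), vectorized over t
risk_prob <- function(scen, nodes, i, t) {
  L <- Lam0(scen, t)
  surv <- exp(-outer(L, nodes$mult[[i]])) %*% nodes$cn[[i]]$w
  drop(surv) * cens_G(scen$censoring, t, nodes$xn$x[i])
}

# e(t, b): at-risk-weighted mean exposure, vectorized over t
ebar_fun <- function(scen, nodes, b) {
  xn <- nodes$xn
  ew <- exp(b * xn$x) * xn$w
  function(t) {
    num <- den <- numeric(length(t))
    for (i in seq_along(xn$x)) {
      r <- risk_prob(scen, nodes, i, t)
      den <- den + ew[i] * r
      num <- num + ew[i] * xn$x[i] * r
    }
    num / den
  }
}

#' Limiting average partial-likelihood score of the reduced model
#'
#' Evaluates the large-sample limit of the reduced-model score at the
#' candidate coefficient `beta_star`, under the given scenario. The root of
#' this function over `beta_star` is the asymptotic value of the
#' reduced-model estimate.
#'
#' @param beta_star candidate reduced-model coefficient (scalar).
#' @param scenario_obj a [scenario()].
#' @return The score value, with attribute `abs_error` carrying the
#'   accumulated absolute quadrature error estimate.
#' @export
score_limit <- function(beta_star, scenario_obj) {
  scen <- scenario_obj
  nodes <- scen_nodes(scen)
  eb <- ebar_fun(scen, nodes, beta_star)
  g <- 0; err <- 0
  for (i in seq_along(nodes$xn$x)) {
    xi <- nodes$xn$x[i]
    tmax <- cens_tmax(scen$censoring, xi)
    for (k in seq_along(nodes$cn[[i]]$c)) {
      m <- nodes$mult[[i]][k]
      umax <- if (is.finite(tmax)) 1 - exp(-Lam0(scen, tmax) * m) else 1
      if (umax <= 0) next
      fu <- function(u) {
        tt <- Lam0_inv(scen, -log1p(-u) / m)
        (xi - eb(tt)) * cens_G(scen$censoring, tt, xi)
      }
      I <- stats::integrate(fu, 0, umax, rel.tol = 1e-8, abs.tol = 1e-9,
                            subdivisions = 400L, stop.on.error = FALSE)
      if (!I$message %in% c("OK", "the integral is probably divergent"))
        stop("quadrature failed for component (x=", xi, ", c=",
             nodes$cn[[i]]$c[k], "): ", I$message)
      g <- g + nodes$xn$w[i] * nodes$cn[[i]]$w[k] * I$value
      err <- err + nodes$xn$w[i] * nodes$cn[[i]]$w[k] * I$abs.error
    }
  }
  structure(g, abs_error = err)
}

bias_result <- function(beta_star, scen, method, diagnostics = list()) {
  structure(list(beta_star = beta_star, bias = beta_star - scen$beta,
                 beta = scen$beta, gamma = scen$gamma, method = method,
                 diagnostics = diagnostics), class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("beta* = %.6f  (true beta = %.4f, bias = %+.6f)  [%s]\n",
              x$beta_star, x$beta, x$bias, x$method))
  invisible(x)
}

solve_root <- function(f, bracket = c(-10, 10), tol = 1e-9, what = "score") {
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (sign(flo) == sign(fhi)) {
    bracket <- 2 * bracket   # widen once, then give up
    flo <- f(bracket[1]); fhi <- f(bracket[2])
    if (sign(flo) == sign(fhi))
      stop("no sign change of the ", what, " in [", bracket[1], ", ",
           bracket[2], "]; supply a manual bracket")
  }
  stats::uniroot(f, bracket, f.lower = flo, f.upper = fhi, tol = tol)
}

#' Asymptotic reduced-model coefficient from the general score limit
#'
#' Solves `score_limit(beta_star) = 0` by Brent's method on the default
#' bracket `[-10, 10]` (widened once automatically).
#'
#' @param scenario_obj a [scenario()].
#' @return A `bias_result` with elements `beta_star`, `bias`, `method`
#'   and solver `diagnostics`.
#' @export
solve_beta_star <- function(scenario_obj) {
  scen <- scenario_obj
  if (scen$gamma == 0)
    return(bias_result(scen$beta, scen, "score-limit",
                       list(residual = 0, iterations = 0L)))
  r <- solve_root(function(b) as.numeric(score_limit(b, scen)))
  bias_result(r$root, scen, "score-limit",
              list(residual = abs(r$f.root), iterations = r$iter,
                   estim_prec = r$estim.prec))
}

#' Asymptotic coefficient for a binary treatment (arm-wise special case)
#'
#' Specialization of the score limit to a binary exposure with a single
#' omitted covariate: the score is assembled arm by arm from the
#' uncensored-event subdensities, and the ratio of uncensoring rates between
#' control and treatment groups is reported as a diagnostic.
#'
#' @inheritParams solve_beta_star
#' @export
eq9_binary_beta_star <- function(scenario_obj) {
  scen <- scenario_obj
  if (scen$exposure$kind != "binary")
    stop("binary-treatment special case requires a binary exposure")
  if (scen$gamma == 0)
    return(bias_result(scen$beta, scen, "eq9-binary",
                       list(residual = 0, uncensoring_ratio = NA_real_)))
  nodes <- scen_nodes(scen)
  p <- scen$exposure$p
  arm_integral <- function(i, fun) {
    # sum over confounder components of the integral of fun(t) against the
    # arm's uncensored-event subdensity
    xi <- nodes$xn$x[i]
    tmax <- cens_tmax(scen$censoring, xi)
    tot <- 0
    for (k in seq_along(nodes$cn[[i]]$c)) {
      m <- nodes$mult[[i]][k]
      umax <- if (is.finite(tmax)) 1 - exp(-Lam0(scen, tmax) * m) else 1
      if (umax <= 0) next
      fu <- function(u) {
        tt <- Lam0_inv(scen, -log1p(-u) / m)
        fun(tt) * cens_G(scen$censoring, tt, xi)
      }
      I <- stats::integrate(fu, 0, umax, rel.tol = 1e-8, abs.tol = 1e-9,
                            subdivisions = 400L, stop.on.error = FALSE)
      tot <- tot + nodes$cn[[i]]$w[k] * I$value
    }
    tot
  }
  pi1 <- arm_integral(2L, function(t) rep(1, length(t)))
  pi0 <- arm_integral(1L, function(t) rep(1, length(t)))
  gfun <- function(b) {
    eb <- ebar_fun(scen, nodes, b)
    p * arm_integral(2L, function(t) 1 - eb(t)) -
      (1 - p) * arm_integral(1L, function(t) eb(t))
  }
  r <- solve_root(gfun)
  bias_result(r$root, scen, "eq9-binary",
              list(residual = abs(r$f.root), iterations = r$iter,
                   uncensoring_ratio = pi0 / pi1,
                   uncensoring_prob = c(arm0 = pi0, arm1 = pi1)))
}

#' Closed-form relation without censoring (baseline-free)
#'
#' With no censoring the observed time given `(x, c)` is exponential with
#' rate `lambda0 exp(beta x + gamma c)`, and after mapping time to the
#' baseline-probability scale the baseline hazard drops out of the score
#' entirely: the asymptotic coefficient does not depend on `lambda0` or on
#' the shape of the baseline hazard. This implementation works on that
#' scale, so the invariance is structural.
#'
#' @inheritParams solve_beta_star
#' @export
eq10_nocensor_beta_star <- function(scenario_obj) {
  scen <- scenario_obj
  if (scen$censoring$kind != "none")
    stop("the no-censoring closed form requires censoring = none")
  if (scen$exposure$kind != "binary")
    stop("the no-censoring closed form requires a binary exposure")
  if (scen$gamma == 0)
    return(bias_result(scen$beta, scen, "eq10-nocensor", list(residual = 0)))
  xn <- xnodes(scen$exposure)
  cn <- lapply(xn$x, function(xi) cnodes_capped(scen$confounder, xi))
  mult <- lapply(seq_along(xn$x), function(i)
    exp(scen$beta * xn$x[i] + scen$gamma * cn[[i]]$c))
  # s = Lambda0(t); R(s|x) = E_C exp(-s e^{beta x + gamma C}); lambda0-free
  Rfun <- function(i, s) drop(exp(-outer(s, mult[[i]])) %*% cn[[i]]$w)
  gfun <- function(b) {
    ew <- exp(b * xn$x) * xn$w
    ebar <- function(s) {
      num <- den <- numeric(length(s))
      for (i in seq_along(xn$x)) {
        r <- Rfun(i, s)
        den <- den + ew[i] * r
        num <- num + ew[i] * xn$x[i] * r
      }
      num / den
    }
    g <- 0
    for (i in seq_along(xn$x)) {
      xi <- xn$x[i]
      for (k in seq_along(cn[[i]]$c)) {
        m <- mult[[i]][k]
        fu <- function(u) xi - ebar(-log1p(-u) / m)
        I <- stats::integrate(fu, 0, 1, rel.tol = 1e-9, abs.tol = 1e-10,
                              subdivisions = 400L, stop.on.error = FALSE)
        g <- g + xn$w[i] * cn[[i]]$w[k] * I$value
      }
    }
    g
  }
  r <- solve_root(gfun)
  bias_result(r$root, scen, "eq10-nocensor",
              list(residual = abs(r$f.root), iterations = r$iter))
}

#' First-order Taylor approximation to the asymptotic coefficient
#'
#' Expands `beta_star(gamma)` around `gamma = 0` (where it equals the true
#' `beta` exactly): `beta_star ~ beta + gamma * d beta_star / d gamma`, with
#' the derivative obtained by implicit differentiation of the score limit.
#' The approximation error grows like `gamma^2`, so accuracy deteriorates
#' for large omitted-covariate effects.
#'
#' @inheritParams solve_beta_star
#' @export
taylor_beta_star <- function(scenario_obj) {
  scen <- scenario_obj
  if (scen$gamma == 0)
    return(bias_result(scen$beta, scen, "taylor", list(residual = 0)))
  h <- 1e-4
  scen_g <- function(g) { s <- scen; s$gamma <- g; s }
  g_gamma <- (as.numeric(score_limit(scen$beta, scen_g(h))) -
                as.numeric(score_limit(scen$beta, scen_g(-h)))) / (2 * h)
  scen0 <- scen_g(0)
  g_b <- (as.numeric(score_limit(scen$beta + h, scen0)) -
            as.numeric(score_limit(scen$beta - h, scen0))) / (2 * h)
  slope <- -g_gamma / g_b
  bias_result(scen$beta + scen$gamma * slope, scen, "taylor",
              list(dbeta_star_dgamma = slope))
}

#' Rare-event (heavy-censoring) relation between true and reduced
#' coefficients
#'
#' Under heavy censoring the at-risk composition barely changes over the
#' observation window and the score-limit relation collapses to
#' `E[X e^{beta X} m(gamma|X)] / E[e^{beta X} m(gamma|X)] =
#'  E[X e^{b X}] / E[e^{b X}]`, with `m` the confounder's conditional moment
#' generating function. For a binary exposure this gives the classical
#' closed-form shift `beta_star = beta + log m(gamma|1) - log m(gamma|0)`,
#' which vanishes when the omitted covariate is balanced.
#'
#' @inheritParams solve_beta_star
#' @export
rare_event_relation <- function(scenario_obj) {
  scen <- scenario_obj
  if (scen$exposure$kind == "binary") {
    shift <- log(mgf(scen$confounder, scen$gamma, 1)) -
      log(mgf(scen$confounder, scen$gamma, 0))
    return(bias_result(scen$beta + shift, scen, "rare-event",
                       list(shift = shift)))
  }
  xn <- xnodes(scen$exposure)
  mg <- vapply(xn$x, function(xi) mgf(scen$confounder, scen$gamma, xi), 0)
  lhs_w <- xn$w * exp(scen$beta * xn$x) * mg
  lhs <- sum(xn$x * lhs_w) / sum(lhs_w)
  r <- solve_root(function(b) {
    w <- xn$w * exp(b * xn$x)
    sum(xn$x * w) / sum(w) - lhs
  })
  bias_result(r$root, scen, "rare-event", list(residual = abs(r$f.root)))
}

#' Invert the rare-event relation on an observed estimate
#'
#' The classical simple sensitivity correction: subtract the rare-event
#' shift implied by the assumed sensitivity parameters from the reduced
#' estimate. Exact inverse of [rare_event_relation()] for a binary exposure;
#' reduces to no adjustment when the omitted covariate is balanced.
#'
#' @param beta_star_hat observed reduced-model coefficient.
#' @param params a [sensitivity_params()].
#' @export
lin_correction <- function(beta_star_hat, params) {
  stopifnot(inherits(params, "sensitivity_params"))
  beta_star_hat - (log(mgf(params$confounder, params$gamma, 1)) -
                     log(mgf(params$confounder, params$gamma, 0)))
}

#' Marginal hazard ratio with the omitted covariate integrated out
#'
#' The hazard ratio between the exposed and unexposed arms after averaging
#' the omitted covariate over its conditional law among survivors at `t`.
#' At `gamma = 0` it equals `exp(beta)` for every `t`; otherwise it varies
#' over time (the marginal hazards are no longer proportional) and tends to
#' finite limits as `t` grows, which is why the reduced-model bias stays
#' bounded as `|gamma|` increases.
#'
#' @param scenario_obj a [scenario()] with binary exposure.
#' @param t evaluation time(s).
#' @export
marginal_hazard_ratio <- function(scenario_obj, t) {
  scen <- scenario_obj
  if (scen$exposure$kind != "binary")
    stop("marginal hazard ratio requires a binary exposure")
  nodes <- scen_nodes(scen)
  L <- Lam0(scen, t)
  arm <- function(i) {
    s <- exp(-outer(L, nodes$mult[[i]]))
    num <- drop(s %*% (nodes$cn[[i]]$w * nodes$mult[[i]]))
    den <- drop(s %*% nodes$cn[[i]]$w)
    num / den   # marginal hazard / lambda0(t)
  }
  arm(2L) / arm(1L)
}
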
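# Reduced-model Cox fitting and the Breslow-type plug-in estimators.
# survival::coxph (Breslow ties) supplies the optimizer and covariance; the
# coefficient is then polished with Newton steps on the exact partial
# likelihood until the average score has max-norm < 1e-8, since the score
# map machinery assumes a stationary point of the Breslow partial likelihood.

# Partial-likelihood value, score and information (Breslow tie handling).
# X is the n x p design matrix. Fully vectorized over events: risk-set sums
# come from cumulative sums over times sorted in decreasing order.
cox_pl_parts <- function(y, d, X, beta) {
  n <- length(y); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(y, decreasing = TRUE)
  ys <- y[ord]; ws <- w[ord]; Xs <- X[ord, , drop = FALSE]
  S0 <- cumsum(ws)
  S1 <- matrix(0, n, p)
  for (k in seq_len(p)) S1[, k] <- cumsum(Xs[, k] * ws)
  ev <- which(d == 1)
  pos <- findInterval(-y[ev], -ys)   # last index with ys >= t (ties included)
  s0 <- S0[pos]
  ebar <- S1[pos, , drop = FALSE] / s0
  U <- colSums(X[ev, , drop = FALSE] - ebar)
  ll <- sum(eta[ev]) - sum(log(s0))
  info <- matrix(0, p, p)
  for (k in seq_len(p)) {
    for (l in k:p) {
      S2kl <- cumsum(Xs[, k] * Xs[, l] * ws)
      v <- sum(S2kl[pos] / s0) - sum(ebar[, k] * ebar[, l])
      info[k, l] <- v; info[l, k] <- v
    }
  }
  list(loglik = ll, score = U, info = info, n = n)
}

#' Fit the reduced Cox model by partial likelihood
#'
#' Fits the proportional hazards model that omits the unmeasured covariate:
#' exposure plus any named measured covariates, with Breslow tie handling
#' (the convention assumed by the plug-in estimators used downstream).
#' The returned coefficient is a stationary point of the exact partial
#' likelihood: the average score has max-norm below 1e-8.
#'
#' @param sample a [survival_sample()].
#' @param covariates character vector of covariate columns to adjust for
#'   (default: exposure only).
#' @return An object of class `cox_fit` with elements `coefficients`,
#'   `vcov`, `se`, `n_events`, `log_partial_likelihood`,
#'   `baseline_survivor` and `censoring_survivor`.
#' @export
fit_reduced_cox <- function(sample, covariates = character()) {
  stopifnot(inherits(sample, "survival_sample"))
  missing_cov <- setdiff(covariates, sample$covariate_names)
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  df <- sample$data
  vars <- c("exposure", covariates)
  X <- as.matrix(df[, vars, drop = FALSE])
  if (qr(scale(X, scale = FALSE))$rank < ncol(X))
    stop("rank-deficient design: a covariate (or the exposure) is constant ",
         "or collinear")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(vars, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-11,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 20))
    stop("monotone partial likelihood detected (coefficient diverging ",
         "beyond |20|): the data separate the risk sets")
  # Newton polish on the exact Breslow partial likelihood
  y <- df$time; d <- df$event
  parts <- cox_pl_parts(y, d, X, beta)
  iter <- 0L
  while (max(abs(parts$score)) / parts$n >= 1e-8 && iter < 25L) {
    step <- solve(parts$info, parts$score)
    if (max(abs(step)) > 1) step <- step / max(abs(step))  # damping
    beta <- beta + step
    if (any(abs(beta) > 20))
      stop("monotone partial likelihood detected during Newton polish")
    parts <- cox_pl_parts(y, d, X, beta)
    iter <- iter + 1L
  }
  if (max(abs(parts$score)) / parts$n >= 1e-8)
    stop("partial-likelihood maximization did not converge: average score ",
         "max-norm ", format(max(abs(parts$score)) / parts$n))
  vcov <- solve(parts$info)
  out <- structure(list(
    coefficients = stats::setNames(as.numeric(beta), vars),
    vcov = vcov,
    se = stats::setNames(sqrt(diag(vcov)), vars),
    n = nrow(df),
    n_events = sum(d),
    log_partial_likelihood = parts$loglik,
    score_max_norm = max(abs(parts$score)) / parts$n,
    covariate_names = covariates,
    fingerprint = sample_fingerprint(sample)
  ), class = "cox_fit")
  out$baseline_survivor <- breslow_baseline_survivor(out, sample)
  out$censoring_survivor <- censoring_survivor(sample)
  out
}

sample_fingerprint <- function(sample) {
  df <- sample$data
  c(n = nrow(df), st = sum(df$time), se = sum(df$event), sx = sum(df$exposure))
}

check_fit_sample <- function(fit, sample) {
  if (!isTRUE(all.equal(fit$fingerprint, sample_fingerprint(sample))))
    stop("fit was not produced from this sample")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("reduced Cox fit: n=%d, events=%d, log PL=%.4f\n",
              x$n, x$n_events, x$log_partial_likelihood))
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   se = x$se, check.names = FALSE))
  invisible(x)
}

#' Breslow baseline survivor function of a reduced Cox fit
#'
#' Cumulative-hazard increments `d_i / sum_(j at risk) exp(beta' x_j)` at
#' each distinct event time, exponentiated to the baseline survivor
#' `S0(t) = exp(-Lambda0(t))` with `S0(0) = 1` and jumps only at event times.
#'
#' @param fit a [fit_reduced_cox()] result.
#' @param sample the sample the fit was produced from.
#' @return A survivor [step_function()].
#' @export
breslow_baseline_survivor <- function(fit, sample) {
  check_fit_sample(fit, sample)
  df <- sample$data
  vars <- c("exposure", fit$covariate_names)
  eta <- drop(as.matrix(df[, vars, drop = FALSE]) %*% fit$coefficients)
  w <- exp(eta)
  ord <- order(df$time)
  ys <- df$time[ord]; ds <- df$event[ord]; ws <- w[ord]
  ev_times <- ys[ds == 1]
  tk <- unique(ev_times)                      # sorted
  dk <- tabulate(match(ev_times, tk), length(tk))
  # risk-set sum at tk = total weight minus weight of subjects failing or
  # censored strictly before tk
  below <- findInterval(tk, ys, left.open = TRUE)
  denom <- sum(ws) - c(0, cumsum(ws))[below + 1L]
  cumhaz <- cumsum(dk / denom)
  step_function(tk, exp(-cumhaz), value_start = 1, survivor = TRUE)
}

# product-limit (reverse Kaplan-Meier) estimate of the censoring survivor;
# at tied times failures are taken to precede censorings, so failures at s
# are removed from the risk set of the censoring "event" at s.
reverse_km <- function(y, d) {
  yc <- sort(y[d == 0])
  if (!length(yc)) return(step_function(numeric(), numeric(), 1, survivor = TRUE))
  ys <- sort(y)
  yf <- sort(y[d == 1])
  ts <- unique(yc)
  count_at <- function(s, sorted)
    findInterval(s, sorted) - findInterval(s, sorted, left.open = TRUE)
  nbelow <- findInterval(ts, ys, left.open = TRUE)
  nfail_at <- count_at(ts, yf)
  nrisk <- length(y) - nbelow - nfail_at
  ncens <- count_at(ts, yc)
  surv <- cumprod(1 - ncens / pmax(nrisk, 1))
  step_function(ts, pmin(pmax(surv, 0), 1), value_start = 1, survivor = TRUE)
}

#' Censoring-time survivor function by role reversal
#'
#' Estimates `G(t|x) = P(censoring time >= t | x)` by treating censored
#' observations as events and events as censored. Modes:
#' `"pooled"` ignores the exposure; `"by-exposure"` (default for a binary
#' exposure) estimates one curve per arm; `"cox-on-covariates"` fits a
#' role-reversed Cox model on exposure and covariates and returns its
#' Breslow baseline plus coefficients. With no censored observations the
#' constant function 1 is returned.
#'
#' @param sample a [survival_sample()].
#' @param mode one of `"auto"`, `"by-exposure"`, `"pooled"`,
#'   `"cox-on-covariates"`.
#' @param covariates covariate names for `"cox-on-covariates"` mode.
#' @return A `censoring_survivor` object; evaluate with [eval_censoring()].
#' @export
censoring_survivor <- function(sample,
                               mode = c("auto", "by-exposure", "pooled",
                                        "cox-on-covariates"),
                               covariates = character()) {
  mode <- match.arg(mode)
  df <- sample$data
  binary_x <- all(df$exposure %in% c(0, 1))
  if (mode == "auto") mode <- if (binary_x) "by-exposure" else "pooled"
  if (mode == "by-exposure" && !binary_x)
    stop("by-exposure mode requires a binary exposure")
  out <- switch(mode,
    pooled = list(mode = "pooled", curve = reverse_km(df$time, df$event)),
    `by-exposure` = list(
      mode = "by-exposure",
      curves = lapply(stats::setNames(c(0, 1), c("0", "1")), function(lev) {
        idx <- df$exposure == lev
        reverse_km(df$time[idx], df$event[idx])
      })),
    `cox-on-covariates` = {
      if (sum(df$event == 0) == 0) {
        list(mode = "pooled", curve = reverse_km(df$time, df$event))
      } else {
        rev_sample <- survival_sample(df$time, 1 - df$event, df$exposure,
          covariates = if (length(sample$covariate_names))
            df[, sample$covariate_names, drop = FALSE] else NULL)
        rev_fit <- fit_reduced_cox(rev_sample, covariates = covariates)
        list(mode = "cox-on-covariates",
             baseline = rev_fit$baseline_survivor,
             coefficients = rev_fit$coefficients,
             covariate_names = covariates)
      }
    })
  structure(out, class = "censoring_survivor")
}

#' Evaluate a censoring survivor estimate
#'
#' @param cs a [censoring_survivor()] object.
#' @param t evaluation times.
#' @param x exposure value (scalar) selecting the arm/linear predictor.
#' @param covariates named covariate values for `"cox-on-covariates"` mode.
#' @param side `"right"` or `"left"` (limit from below).
#' @export
eval_censoring <- function(cs, t, x = 0, covariates = NULL,
                           side = c("right", "left")) {
  side <- match.arg(side)
  switch(cs$mode,
    pooled = eval_step(cs$curve, t, side),
    `by-exposure` = {
      key <- as.character(as.integer(x))
      if (is.null(cs$curves[[key]])) stop("no censoring curve for arm ", x)
      eval_step(cs$curves[[key]], t, side)
    },
    `cox-on-covariates` = {
      z <- c(exposure = x, unlist(covariates))
      eta <- sum(cs$coefficients * z[names(cs$coefficients)])
      eval_step(cs$baseline, t, side)^exp(eta)
    })
}
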
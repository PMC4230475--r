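# Sensitivity analysis: corrected point estimates, P-values and confidence
# intervals for the treatment effect given assumed sensitivity parameters.

new_sensitivity_result <- function(map, fit, beta_corrected, ci = NULL,
                                   p_value = NULL, method_ci = NULL,
                                   diagnostics = list()) {
  structure(list(beta_corrected = beta_corrected,
                 beta_star_hat = map$beta_star_hat,
                 se_reduced = map$se,
                 ci = ci, ci_mass = attr(ci, "mass"),
                 p_value = p_value, method_ci = method_ci,
                 params = map$params, diagnostics = diagnostics),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("corrected log-hazard ratio: %.4f (HR %.3f)\n",
              x$beta_corrected, exp(x$beta_corrected)))
  cat(sprintf("reduced-model estimate:     %.4f (se %.4f)\n",
              x$beta_star_hat, x$se_reduced))
  if (!is.null(x$ci))
    cat(sprintf("%.0f%% CI [%s]: (%.4f, %.4f)\n", 100 * x$ci_mass,
                x$method_ci, x$ci[1], x$ci[2]))
  if (!is.null(x$p_value))
    cat(sprintf("two-sided P-value: %.4g\n", x$p_value))
  invisible(x)
}

#' Corrected point estimate of the treatment effect
#'
#' Inverts the empirical score map at the observed reduced-model
#' coefficient: by functional invariance of the maximum likelihood
#' estimator, `h^{-1}(beta_star_hat)` estimates the true exposure effect
#' under the assumed sensitivity parameters. With `gamma = 0` this is the
#' unadjusted estimate exactly.
#'
#' @param map a [build_score_map()] result.
#' @param fit the reduced [fit_reduced_cox()] the map was built from.
#' @return A `sensitivity_result` (point estimate only).
#' @export
corrected_estimate <- function(map, fit) {
  new_sensitivity_result(map, fit, map$beta_corrected)
}

#' Corrected two-sided P-value
#'
#' Tests the null that the true exposure effect equals `null_beta`. Through
#' the score map the null is equivalent to the reduced-model coefficient
#' equalling `h(null_beta)`, so the usual normal approximation applies on
#' the reduced scale: `P = 2 Phi(-|beta_star_hat - h(null_beta)| / se)`.
#' With `gamma = 0` this is the standard Wald test of the reduced fit.
#'
#' @inheritParams corrected_estimate
#' @param null_beta null value of the true exposure log-hazard ratio.
#' @export
corrected_pvalue <- function(map, fit, null_beta = 0) {
  z <- (map$beta_star_hat - map$h(null_beta)) / map$se
  2 * stats::pnorm(-abs(z))
}

#' Confidence interval by transforming the Wald bounds
#'
#' Maps the reduced fit's Wald confidence bounds through the inverse score
#' map. Valid when the map is monotone (it usually is, and the build step
#' verifies this on a grid); refuses otherwise, pointing to the bootstrap
#' interval.
#'
#' In small samples the map can saturate: the empirical relation may admit
#' no true coefficient extreme enough to reproduce a far-out reduced-scale
#' bound, in which case the preimage of the Wald interval is a half-line
#' and the corresponding limit is returned as `-Inf`/`Inf`.
#'
#' @inheritParams corrected_estimate
#' @param mass interval mass, default 0.95.
#' @return Numeric `c(lower, upper)` with attribute `mass`.
#' @export
ci_bound_transform <- function(map, fit, mass = 0.95) {
  if (!map$monotone)
    stop("score map is not monotone on the working grid; ",
         "use ci_bootstrap_hdi() instead")
  z <- stats::qnorm((1 + mass) / 2)
  bounds <- map$beta_star_hat + c(-1, 1) * z * map$se
  out <- vapply(bounds, function(b) {
    v <- map$h_inverse(b, exact = FALSE)
    if (is.na(v)) return(NA_real_)
    map$h_inverse(b, exact = TRUE)
  }, 0)
  # bound outside the achievable range of h: vacuous constraint on that side
  if (is.na(out[1])) out[1] <- if (map$increasing) -Inf else Inf
  if (is.na(out[2])) out[2] <- if (map$increasing) Inf else -Inf
  out <- sort(out)
  attr(out, "mass") <- mass
  out
}

#' Confidence interval by parametric-bootstrap highest-density interval
#'
#' Draws `B` reduced-scale coefficients from `Normal(beta_star_hat, se^2)`,
#' maps each through the inverse score map, and returns the shortest
#' interval containing `ceiling(mass * B)` of the mapped draws (the
#' empirical highest-density interval, appropriate when the corrected
#' estimator's sampling distribution is skewed).
#'
#' @inheritParams corrected_estimate
#' @param B number of bootstrap draws (>= 500).
#' @param mass interval mass.
#' @param seed RNG seed for the draws.
#' @return Numeric `c(lower, upper)` with attributes `mass` and `B`.
#' @export
ci_bootstrap_hdi <- function(map, fit, B = 2000L, mass = 0.95, seed = 1L) {
  if (B < 500L) stop("B must be at least 500")
  draws <- with_seed(seed, stats::rnorm(B, map$beta_star_hat, map$se))
  mapped <- map$h_inverse(draws, exact = FALSE)
  bad <- sum(!is.finite(mapped))
  if (bad / B > 0.01)
    stop(sprintf("inverse score map failed on %.1f%% of bootstrap draws",
                 100 * bad / B))
  s <- sort(mapped[is.finite(mapped)])
  nkeep <- ceiling(mass * length(s))
  widths <- s[nkeep:length(s)] - s[seq_len(length(s) - nkeep + 1L)]
  i <- which.min(widths)
  out <- c(s[i], s[i + nkeep - 1L])
  attr(out, "mass") <- mass
  attr(out, "B") <- B
  attr(out, "failed") <- bad
  out
}

#' Sensitivity analysis over a grid of assumptions
#'
#' Repeats the correction over a grid of omitted-covariate effects `gamma`
#' and confounder laws, producing a table suitable for contour plots of the
#' corrected estimate, confidence bounds or P-value. Cells where the solver
#' fails carry a status message instead of aborting the grid.
#'
#' @param sample a [survival_sample()].
#' @param gamma_grid vector of gamma values.
#' @param confounders list of `confounder_model`s, or `NULL` to build
#'   binary models from `p1_grid`/`p0_grid` (paired vectors).
#' @param p1_grid,p0_grid paired vectors of binary-confounder probabilities
#'   (used when `confounders` is `NULL`).
#' @param outputs any of `"point"`, `"ci_lower"`, `"ci_upper"`, `"p_value"`.
#' @param null_beta null value for the P-value output.
#' @param ci_method `"bound"` or `"hdi"`.
#' @param fit optional pre-computed reduced fit.
#' @param covariates covariates to adjust for in the reduced fit.
#' @param mass CI mass.
#' @param B,seed bootstrap settings for `ci_method = "hdi"`.
#' @return A data frame with one row per grid cell and a `status` column.
#' @export
sensitivity_grid <- function(sample, gamma_grid, confounders = NULL,
                             p1_grid = NULL, p0_grid = NULL,
                             outputs = c("point", "ci_lower", "ci_upper",
                                         "p_value"),
                             null_beta = 0, ci_method = c("bound", "hdi"),
                             fit = NULL, covariates = character(),
                             mass = 0.95, B = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  outputs <- match.arg(outputs, several.ok = TRUE)
  if (is.null(confounders)) {
    if (is.null(p1_grid))
      stop("supply either a list of confounder models or p1_grid/p0_grid")
    if (is.null(p0_grid)) p0_grid <- p1_grid
    if (length(p0_grid) != length(p1_grid))
      stop("p1_grid and p0_grid must be paired vectors of equal length")
    confounders <- Map(confounder_binary, p1_grid, p0_grid)
  }
  if (!length(gamma_grid) || !length(confounders))
    stop("empty sensitivity grid")
  if (is.null(fit)) fit <- fit_reduced_cox(sample, covariates)
  cells <- expand.grid(ic = seq_along(confounders), gamma = gamma_grid)
  out_cols <- intersect(c("point", "ci_lower", "ci_upper", "p_value"),
                        outputs)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cf <- confounders[[cells$ic[r]]]
    gm <- cells$gamma[r]
    vals <- stats::setNames(as.list(rep(NA_real_, length(out_cols))),
                            out_cols)
    status <- tryCatch({
      map <- build_score_map(sample, fit, sensitivity_params(gm, cf))
      if ("point" %in% out_cols)
        vals$point <- map$h_inverse(map$beta_star_hat, exact = TRUE)
      if (any(c("ci_lower", "ci_upper") %in% out_cols)) {
        ci <- if (ci_method == "bound") ci_bound_transform(map, fit, mass)
              else ci_bootstrap_hdi(map, fit, B = B, mass = mass, seed = seed)
        if ("ci_lower" %in% out_cols) vals$ci_lower <- ci[1]
        if ("ci_upper" %in% out_cols) vals$ci_upper <- ci[2]
      }
      if ("p_value" %in% out_cols)
        vals$p_value <- corrected_pvalue(map, fit, null_beta)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    cbind(data.frame(gamma = gm,
                     p1 = if (!is.null(cf$p1)) cf$p1 else NA_real_,
                     p0 = if (!is.null(cf$p0)) cf$p0 else NA_real_),
          as.data.frame(vals), status = status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
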
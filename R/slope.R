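#' Structural parameters of the incidence-prognosis model
#'
#' Container for the linear structural model in which incidence
#' \eqn{X = \beta_{GX} G + \beta_{UX} U + E_X} and prognosis
#' \eqn{Y = \beta_{GY} G + \beta_{UY} U + \beta_{XY} X + E_Y}, with
#' \eqn{U} the combined common causes of incidence and prognosis and
#' \eqn{E_X}, \eqn{E_Y} trait-specific residuals. From the viewpoint of a
#' single variant in a polygenic trait, the polygenic background belongs
#' to \eqn{U} (shared part) and \eqn{E_X}, \eqn{E_Y} (trait-specific
#' parts).
#'
#' @param var_u Variance of the shared confounder, positive.
#' @param beta_ux,beta_uy Confounder effects on incidence and prognosis.
#' @param var_ex,var_ey Residual variances, positive.
#' @param beta_xy Direct effect of incidence on prognosis (default 0).
#' @return An object of class `structural_params`.
#' @export
structural_params <- function(var_u, beta_ux, beta_uy, var_ex, var_ey,
                              beta_xy = 0) {
  stopifnot(var_u > 0, var_ex > 0, var_ey > 0)
  structure(list(var_u = var_u, beta_ux = beta_ux, beta_uy = beta_uy,
                 var_ex = var_ex, var_ey = var_ey, beta_xy = beta_xy),
            class = "structural_params")
}

#' Analytic confounding slope
#'
#' The coefficient multiplying the incidence effect in the collider bias
#' of the conditional prognosis effect:
#' \deqn{b = -\frac{var(U)\,\beta_{UX}\beta_{UY}}
#'                {var(U)\,\beta_{UX}^2 + var(E_X)}.}
#' It is negative when the confounder acts in the same direction on both
#' traits, and zero when the confounder does not affect prognosis.
#'
#' @param params A [structural_params()] object.
#' @return The slope, a single number.
#' @export
analytic_b <- function(params) {
  stopifnot(inherits(params, "structural_params"))
  denom <- params$var_u * params$beta_ux^2 + params$var_ex
  if (denom <= 0) stop("non-positive denominator in analytic slope")
  -(params$var_u * params$beta_ux * params$beta_uy) / denom
}

new_slope_fit <- function(b_raw, se_b_raw_robust, b_corrected, var_b,
                          ci_low = NA_real_, ci_high = NA_real_,
                          method = c("raw", "hedges_olkin", "simex"),
                          intercept = NA_real_, n_snps = NA_integer_,
                          diagnostics = list()) {
  method <- match.arg(method)
  fit <- structure(list(b_raw = b_raw, se_b_raw_robust = se_b_raw_robust,
                        b_corrected = b_corrected, var_b = var_b,
                        ci_low = ci_low, ci_high = ci_high, method = method,
                        intercept = intercept, n_snps = n_snps,
                        diagnostics = diagnostics),
                   class = "slope_fit")
  if (!is.na(fit$ci_low) && !is.na(fit$ci_high) &&
      (fit$b_corrected < fit$ci_low || fit$b_corrected > fit$ci_high)) {
    stop("internal error: corrected slope outside its confidence interval")
  }
  fit
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("Confounding slope fit (", x$method, ")\n", sep = "")
  cat(sprintf("  raw slope b*        : %#.6g (robust se %#.4g)\n",
              x$b_raw, x$se_b_raw_robust))
  cat(sprintf("  corrected slope b   : %#.6g\n", x$b_corrected))
  cat(sprintf("  var(b)              : %#.4g\n", x$var_b))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI              : (%#.6g, %#.6g)\n",
                x$ci_low, x$ci_high))
  }
  cat(sprintf("  intercept           : %#.4g\n", x$intercept))
  cat(sprintf("  variants in fit     : %d\n", x$n_snps))
  invisible(x)
}

# Fast OLS y ~ 1 + x with an HC1 sandwich se for the slope. Returns
# c(slope, intercept, se_hc1). Used in the SIMEX inner loop where lm()
# overhead would dominate.
.ols_slope <- function(x, y, robust = TRUE) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) return(c(NA_real_, NA_real_, NA_real_))
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  se <- NA_real_
  if (robust) {
    resid <- y - intercept - slope * x
    se <- sqrt(n / (n - 2) * sum(resid^2 * xc^2) / sxx^2)
  }
  c(slope, intercept, se)
}

#' Raw confounding slope by ordinary least squares
#'
#' Regresses the conditional prognosis effects on the incidence effects
#' over the variants flagged for slope estimation (see [set_pruned()]),
#' with an intercept. Because the marginal effects of variants in strong
#' LD or with extreme frequencies have larger sampling variance, the
#' residuals are heteroscedastic, and the slope standard error is the
#' HC1 heteroscedasticity-consistent sandwich estimate.
#'
#' @param pairs Harmonised pairs; only rows with `pruned == TRUE` enter
#'   the regression, unless no row is flagged, in which case all rows are
#'   used with a warning.
#' @param min_pairs Minimum number of variants required (default 10).
#' @return A `slope_fit` with `method = "raw"` and
#'   `b_corrected = b_raw`.
#' @export
fit_raw_slope <- function(pairs, min_pairs = 10) {
  use <- if (any(pairs$pruned)) pairs[pairs$pruned, , drop = FALSE] else {
    warning("no variants flagged as pruned; using all pairs in the ",
            "slope regression")
    pairs
  }
  n <- nrow(use)
  if (n < min_pairs) {
    stop("slope regression needs at least ", min_pairs,
         " variants; got ", n)
  }
  if (stats::var(use$beta_gx) == 0) {
    stop("degenerate design: incidence effects are constant")
  }
  fit <- .ols_slope(use$beta_gx, use$beta_gy_prime)
  new_slope_fit(b_raw = fit[1], se_b_raw_robust = fit[3],
                b_corrected = fit[1], var_b = fit[3]^2,
                ci_low = fit[1] - stats::qnorm(0.975) * fit[3],
                ci_high = fit[1] + stats::qnorm(0.975) * fit[3],
                method = "raw", intercept = fit[2], n_snps = n)
}

#' Hedges-Olkin correction for regression dilution
#'
#' Sampling error in the estimated incidence effects attenuates the raw
#' slope towards zero. The attenuation factor is the ratio of the
#' between-variant variance of the true incidence effects to the variance
#' of their estimates; the former is approximated by the Hedges-Olkin
#' (method of moments) estimator, the observed variance minus the mean
#' squared standard error. The corrected slope is
#' \deqn{\hat b = \hat b^* \,
#'   \frac{var(\hat\beta_{GX})}{var(\hat\beta_{GX}) - E(\sigma^2_{GX})}}
#' equivalently the covariance of the estimates divided by the estimated
#' true-effect variance.
#'
#' Two variance estimators for the corrected slope are available.
#' `"influence"` (the default) is the sandwich variance of the
#' moment-ratio estimator, the sum of squared per-variant influence
#' functions; it accounts for the strong negative correlation between
#' the raw slope and the correction factor (both are driven by the
#' observed effect variance) and matches the realized replicate-to-
#' replicate variance of the corrected slope closely. `"scaled"` is the
#' naive propagation, the squared correction factor times the squared
#' robust standard error of the raw slope, which understates the
#' variance by ignoring that correlation.
#'
#' When the mean squared standard error reaches or exceeds the observed
#' variance the true-effect variance estimate is non-positive: the
#' correction would flip the sign of the slope, which is impossible for a
#' genuine dilution (a ratio of variances), so an error is raised and a
#' simulation-extrapolation correction ([simex_correct()]) should be used
#' instead.
#'
#' @param b_raw Raw slope, or a `slope_fit` from [fit_raw_slope()] (in
#'   which case its robust standard error and intercept are carried
#'   through).
#' @param beta_gx,se_gx Incidence effect estimates and standard errors of
#'   the variants that entered the slope regression.
#' @param se_b_raw Robust standard error of the raw slope; taken from
#'   `b_raw` when that is a `slope_fit`. Required for
#'   `var_method = "scaled"`.
#' @param beta_gy_prime Conditional prognosis effect estimates of the
#'   same variants; required for `var_method = "influence"`.
#' @param var_method `"influence"` (default) or `"scaled"`; see Details.
#' @return A `slope_fit` with `method = "hedges_olkin"`. Diagnostics
#'   record the observed variance, the mean squared standard error and
#'   the correction factor.
#' @export
hedges_olkin_correct <- function(b_raw, beta_gx, se_gx,
                                 beta_gy_prime = NULL, se_b_raw = NA,
                                 var_method = c("influence", "scaled")) {
  var_method <- match.arg(var_method)
  intercept <- NA_real_
  if (inherits(b_raw, "slope_fit")) {
    se_b_raw <- b_raw$se_b_raw_robust
    intercept <- b_raw$intercept
    b_raw <- b_raw$b_raw
  }
  m <- length(beta_gx)
  v_obs <- stats::var(beta_gx)
  mean_s2 <- mean(se_gx^2)
  denom <- v_obs - mean_s2
  if (denom <= 0) {
    stop("dilution correction infeasible: mean squared standard error (",
         format(mean_s2), ") is at least the observed effect variance (",
         format(v_obs), "); the implied true-effect variance is not ",
         "positive. Consider simex_correct().")
  }
  factor <- v_obs / denom
  b_corr <- b_raw * factor
  if (var_method == "influence") {
    if (is.null(beta_gy_prime)) {
      stop("beta_gy_prime is required for the influence-function variance")
    }
    xc <- beta_gx - mean(beta_gx)
    yc <- beta_gy_prime - mean(beta_gy_prime)
    cv <- sum(xc * yc) / (m - 1)
    infl <- (xc * yc - cv) / denom -
      cv * (xc^2 - v_obs - (se_gx^2 - mean_s2)) / denom^2
    var_b <- sum(infl^2) / m^2
  } else {
    var_b <- if (is.na(se_b_raw)) NA_real_ else factor^2 * se_b_raw^2
  }
  ci <- if (is.na(var_b)) c(NA_real_, NA_real_) else {
    b_corr + c(-1, 1) * stats::qnorm(0.975) * sqrt(var_b)
  }
  new_slope_fit(b_raw = b_raw, se_b_raw_robust = se_b_raw,
                b_corrected = b_corr, var_b = var_b,
                ci_low = ci[1], ci_high = ci[2],
                method = "hedges_olkin", intercept = intercept,
                n_snps = m,
                diagnostics = list(var_obs = v_obs, mean_se2 = mean_s2,
                                   correction_factor = factor,
                                   var_method = var_method))
}

# Evaluate a seeded expression without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# One SIMEX pass over a set of pairs: mean slope per lambda, polynomial
# extrapolation to lambda = -1. Returns list(b, mean_slopes, b_raw,
# n_discarded).
.simex_pass <- function(beta_gx, se_gx, beta_gy_prime, lambda_grid, n_sim,
                        extrapolation) {
  lambda_grid <- sort(unique(lambda_grid))
  mean_slopes <- numeric(length(lambda_grid))
  n_discarded <- 0L
  n_total <- 0L
  m <- length(beta_gx)
  for (k in seq_along(lambda_grid)) {
    lam <- lambda_grid[k]
    if (lam == 0) {
      mean_slopes[k] <- .ols_slope(beta_gx, beta_gy_prime, robust = FALSE)[1]
      next
    }
    slopes <- numeric(n_sim)
    keep <- logical(n_sim)
    for (s in seq_len(n_sim)) {
      x_star <- beta_gx + stats::rnorm(m, 0, sqrt(lam) * se_gx)
      sl <- .ols_slope(x_star, beta_gy_prime, robust = FALSE)[1]
      slopes[s] <- sl
      keep[s] <- is.finite(sl)
    }
    n_total <- n_total + n_sim
    n_discarded <- n_discarded + sum(!keep)
    mean_slopes[k] <- mean(slopes[keep])
  }
  if (n_total > 0 && n_discarded > 0.1 * n_total) {
    stop("more than 10% of SIMEX replicates had a degenerate design")
  }
  b_raw <- mean_slopes[lambda_grid == 0]
  n_lam <- length(lambda_grid)
  b <- if (n_lam == 1) {
    b_raw
  } else if (n_lam == 2 || extrapolation == "linear") {
    ext <- stats::lm.fit(cbind(1, lambda_grid), mean_slopes)$coefficients
    ext[1] - ext[2]
  } else {
    ext <- stats::lm.fit(cbind(1, lambda_grid, lambda_grid^2),
                         mean_slopes)$coefficients
    ext[1] - ext[2] + ext[3]
  }
  list(b = unname(b), mean_slopes = mean_slopes, b_raw = b_raw,
       n_discarded = n_discarded)
}

#' Simulation-extrapolation (SIMEX) correction for regression dilution
#'
#' Re-estimates the confounding slope under artificially inflated
#' measurement error and extrapolates the trend back to zero error. For
#' each multiplier \eqn{\lambda > 0} in the grid, Gaussian noise with
#' variance \eqn{\lambda\sigma^2_{GX}} is added to each incidence effect
#' estimate, the slope regression is refit `n_sim` times and the slopes
#' averaged; \eqn{\lambda = 0} is the observed-data fit. A quadratic (or
#' linear) polynomial in \eqn{\lambda} is fit to the mean slopes and
#' evaluated at \eqn{\lambda = -1}, the point of no measurement error.
#'
#' Uncertainty is assessed by a nonparametric bootstrap over variants:
#' the pairs are resampled with replacement, the whole SIMEX procedure is
#' rerun, and the corrected slope's variance and percentile confidence
#' interval are taken from the bootstrap distribution. The bootstrap
#' slopes are returned in the diagnostics and can be fed to
#' [bootstrap_snp_inference()] as an empirical slope distribution,
#' supporting the markedly asymmetric intervals that arise when
#' individual standard errors are large.
#'
#' @param pairs Harmonised pairs; rows with `pruned == TRUE` are used
#'   (all rows when none is flagged).
#' @param lambda_grid Non-negative error-inflation multipliers; must
#'   contain 0. Default `seq(0, 2, 0.25)`.
#' @param n_sim Number of re-noised datasets per positive lambda
#'   (default 100, minimum 20).
#' @param extrapolation `"quadratic"` (default) or `"linear"`.
#' @param n_boot Bootstrap replicates for the confidence interval
#'   (default 200; minimum 100 when a CI is requested). `n_boot = 0`
#'   skips the bootstrap, in which case `var_b` falls back to the
#'   dilution-scaled robust variance of the raw slope.
#' @param seed Optional integer seed; the whole procedure is reproducible
#'   given the seed and does not disturb the caller's RNG state.
#' @param min_pairs Minimum number of variants (default 10).
#' @return A `slope_fit` with `method = "simex"`; diagnostics hold the
#'   per-lambda mean slopes and the bootstrap slope distribution.
#' @export
simex_correct <- function(pairs, lambda_grid = seq(0, 2, by = 0.25),
                          n_sim = 100,
                          extrapolation = c("quadratic", "linear"),
                          n_boot = 200, seed = NULL, min_pairs = 10) {
  extrapolation <- match.arg(extrapolation)
  if (!any(lambda_grid == 0)) stop("lambda_grid must contain 0")
  if (any(lambda_grid < 0)) stop("lambda_grid must be non-negative")
  if (n_sim < 20) stop("n_sim must be at least 20")
  if (n_boot > 0 && n_boot < 100) {
    stop("n_boot must be at least 100 when a bootstrap CI is requested")
  }
  use <- if (any(pairs$pruned)) pairs[pairs$pruned, , drop = FALSE] else pairs
  m <- nrow(use)
  if (m < min_pairs) {
    stop("slope regression needs at least ", min_pairs, " variants; got ", m)
  }
  raw <- fit_raw_slope(use, min_pairs = min_pairs)

  .with_seed(seed, {
    main <- .simex_pass(use$beta_gx, use$se_gx, use$beta_gy_prime,
                        lambda_grid, n_sim, extrapolation)
    boot_b <- NULL
    if (n_boot > 0) {
      boot_b <- numeric(n_boot)
      for (r in seq_len(n_boot)) {
        idx <- sample.int(m, m, replace = TRUE)
        boot_b[r] <- .simex_pass(use$beta_gx[idx], use$se_gx[idx],
                                 use$beta_gy_prime[idx], lambda_grid,
                                 n_sim, extrapolation)$b
      }
    }
    if (!is.null(boot_b)) {
      var_b <- stats::var(boot_b)
      ci <- unname(stats::quantile(boot_b, c(0.025, 0.975)))
      # percentile interval can miss the point estimate in small
      # bootstraps; widen to contain it
      ci[1] <- min(ci[1], main$b)
      ci[2] <- max(ci[2], main$b)
    } else {
      scale <- if (main$b_raw != 0) (main$b / main$b_raw)^2 else 1
      var_b <- scale * raw$se_b_raw_robust^2
      ci <- main$b + c(-1, 1) * stats::qnorm(0.975) * sqrt(var_b)
    }
    new_slope_fit(b_raw = raw$b_raw, se_b_raw_robust = raw$se_b_raw_robust,
                  b_corrected = main$b, var_b = var_b,
                  ci_low = ci[1], ci_high = ci[2], method = "simex",
                  intercept = raw$intercept, n_snps = m,
                  diagnostics = list(lambda_grid = sort(unique(lambda_grid)),
                                     mean_slopes = main$mean_slopes,
                                     n_discarded = main$n_discarded,
                                     boot_slopes = boot_b))
  })
}

#' Estimate the confounding slope
#'
#' Convenience wrapper running the raw slope regression and the requested
#' dilution correction in one call.
#'
#' @param pairs Harmonised pairs (see [harmonize()], [set_pruned()]).
#' @param method `"hedges_olkin"` (default), `"simex"` or `"raw"`.
#' @param ... Further arguments passed to [simex_correct()] when
#'   `method = "simex"`, or `min_pairs` for the other methods.
#' @return A `slope_fit`.
#' @export
estimate_slope <- function(pairs,
                           method = c("hedges_olkin", "simex", "raw"),
                           ...) {
  method <- match.arg(method)
  if (method == "simex") return(simex_correct(pairs, ...))
  raw <- fit_raw_slope(pairs, ...)
  if (method == "raw") return(raw)
  use <- if (any(pairs$pruned)) pairs[pairs$pruned, , drop = FALSE] else pairs
  hedges_olkin_correct(raw, use$beta_gx, use$se_gx,
                       beta_gy_prime = use$beta_gy_prime)
}
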
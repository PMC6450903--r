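#' Apply the index-event bias correction to every variant
#'
#' Subtracts the estimated confounding slope times the incidence effect
#' from each conditional prognosis effect:
#' \deqn{\hat\beta_{GY} = \hat\beta'_{GY} - \hat b\,\hat\beta_{GX},}
#' with standard error
#' \deqn{\sqrt{\sigma_{GY}^2 + \hat b^2\sigma_{GX}^2 +
#'       \hat\beta_{GX}^2 var(\hat b) + \sigma_{GX}^2 var(\hat b)}.}
#' The slope is estimated once from the pruned subset but applied to all
#' variants; the output for a variant therefore does not depend on
#' whether it entered the slope regression. Each adjusted estimate is
#' referred to the standard normal for a two-sided p-value, an
#' approximation that works well in practice; see
#' [bootstrap_snp_inference()] for an empirical alternative for variants
#' with extreme effects.
#'
#' @param pairs Harmonised pairs (all variants, not only the pruned
#'   subset).
#' @param slope A `slope_fit`, e.g. from [estimate_slope()].
#' @return A data frame with the input identifier and effect columns plus
#'   `beta_gy_adj`, `se_adj`, `z`, `p`, and the correction method as
#'   attribute `method`.
#' @export
adjust_effects <- function(pairs, slope) {
  stopifnot(inherits(slope, "slope_fit"))
  var_b <- slope$var_b
  if (is.na(var_b)) var_b <- 0
  if (var_b < 0) stop("negative var(b) in slope fit")
  b <- slope$b_corrected
  beta_adj <- pairs$beta_gy_prime - b * pairs$beta_gx
  se_adj <- sqrt(pairs$se_gy^2 + b^2 * pairs$se_gx^2 +
                   pairs$beta_gx^2 * var_b + pairs$se_gx^2 * var_b)
  z <- beta_adj / se_adj
  out <- data.frame(
    variant_id = pairs$variant_id,
    beta_gx = pairs$beta_gx,
    se_gx = pairs$se_gx,
    beta_gy_prime = pairs$beta_gy_prime,
    se_gy = pairs$se_gy,
    beta_gy_adj = beta_adj,
    se_adj = se_adj,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- slope$method
  out
}

#' Empirical bootstrap inference for a single variant
#'
#' The adjusted estimate is the difference of an estimate and a product
#' of two estimates, so its distribution need not be normal when the
#' slope is imprecise. This generates an empirical distribution by
#' drawing the prognosis effect, the incidence effect and the slope from
#' their sampling distributions (normal around the estimates, or an
#' empirical slope distribution such as the SIMEX bootstrap slopes) and
#' forming \eqn{\hat\beta'_{GY} - b\,\hat\beta_{GX}} for each draw.
#'
#' The two-sided empirical p-value is twice the smaller tail share at
#' zero, floored at `1/n_draws`: a p-value at the floor should be read as
#' an order bound, "less than 1/n_draws", not an exact value.
#'
#' @param pair A single harmonised pair (one-row data frame or list with
#'   `beta_gx`, `se_gx`, `beta_gy_prime`, `se_gy`).
#' @param slope Either a `slope_fit` (draws are normal with mean
#'   `b_corrected` and variance `var_b`) or a numeric vector of slope
#'   draws (an empirical distribution, resampled with replacement).
#' @param n_draws Number of draws, at least 1000 (default 10000).
#' @param seed Optional seed; the caller's RNG state is untouched.
#' @param conf_level Confidence level of the percentile interval
#'   (default 0.95).
#' @return A list with `estimate` (point estimate of the adjusted
#'   effect), `p` (empirical two-sided p-value), `ci` (percentile
#'   interval), `p_floor` (`1/n_draws`), and `draws` summary statistics.
#' @export
bootstrap_snp_inference <- function(pair, slope, n_draws = 10000,
                                    seed = NULL, conf_level = 0.95) {
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1)
    pair <- as.list(pair)
  }
  .with_seed(seed, {
    b_draws <- if (inherits(slope, "slope_fit")) {
      stats::rnorm(n_draws, slope$b_corrected, sqrt(max(slope$var_b, 0)))
    } else {
      slope <- as.numeric(slope)
      if (length(slope) == 0) stop("empty slope distribution")
      sample(slope, n_draws, replace = TRUE)
    }
    gy <- stats::rnorm(n_draws, pair$beta_gy_prime, pair$se_gy)
    gx <- stats::rnorm(n_draws, pair$beta_gx, pair$se_gx)
    draws <- gy - b_draws * gx
    point <- pair$beta_gy_prime - mean(b_draws) * pair$beta_gx
    p <- max(2 * min(mean(draws <= 0), mean(draws >= 0)), 1 / n_draws)
    p <- min(p, 1)
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
    list(estimate = point, p = p, ci = ci, p_floor = 1 / n_draws,
         draws = list(n = n_draws, mean = mean(draws), sd = stats::sd(draws),
                      share_below_zero = mean(draws < 0)))
  })
}

#' Genomic-control inflation factor
#'
#' The median association chi-squared statistic divided by its null
#' median (0.4549), a genome-wide diagnostic of residual inflation.
#'
#' @param p_values Two-sided p-values in (0, 1].
#' @return The inflation factor lambda, with the number of variants used
#'   as attribute `n`.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  attr(lambda, "n") <- length(p_values)
  lambda
}
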
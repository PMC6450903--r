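#' Define a simulation scenario
#'
#' Full generative specification of a synthetic GWAS of incidence and
#' prognosis under the linear structural model: independent
#' Hardy-Weinberg variants, polygenic effects on one or both traits, a
#' shared non-genetic confounder, and optional dichotomisation of
#' incidence (liability threshold) with case/control ascertainment.
#'
#' Defaults reproduce the reference simulation design: 100,000
#' independent SNPs of which 5,000 affect incidence only, 5,000
#' prognosis only and 5,000 both; heritability 0.5 for both traits; a
#' non-genetic confounder explaining 40% of the variance of each trait;
#' no direct effect of incidence on prognosis; minor allele frequencies
#' uniform on (0.01, 0.49); 20,000 individuals; and for binary designs a
#' liability threshold affecting 20% with 10,000 cases and 10,000
#' controls.
#'
#' @param m_total Total number of variants.
#' @param m_inc_only,m_prog_only,m_both Causal variant counts per
#'   category; the remainder are null.
#' @param h2_x,h2_y Heritabilities of incidence and prognosis liability,
#'   in \[0, 1).
#' @param conf_share_x,conf_share_y Variance shares of the shared
#'   non-genetic confounder, in \[0, 1).
#' @param rho_shared Correlation of the effect pairs at shared variants;
#'   the genome-wide genetic correlation is approximately `rho_shared *
#'   m_both / sqrt((m_inc_only + m_both) * (m_prog_only + m_both))`.
#' @param n_individuals Cohort size for quantitative designs (and the
#'   generation pool for binary designs).
#' @param trait_mode `"quantitative"`, `"binary_liability"` or
#'   `"survival"`.
#' @param case_fraction Population fraction affected under the liability
#'   threshold.
#' @param n_cases,n_controls Ascertained sample sizes for binary designs.
#' @param prognosis_mode `"case_only"` (binary prognosis, median split
#'   among cases, logistic regression in cases), `"quantitative_in_cases"`
#'   (linear regression of the quantitative prognosis in cases), or
#'   `"case_control_degenerate"` (prognosis set to 0 in controls,
#'   analysed in the full sample with case/control status as covariate).
#' @param beta_xy Direct effect of incidence on prognosis (default 0).
#' @param maf_low,maf_high Minor allele frequency range, inside (0, 0.5].
#' @param seed Optional default seed carried with the scenario.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(m_total = 100000,
                                m_inc_only = 5000,
                                m_prog_only = 5000,
                                m_both = 5000,
                                h2_x = 0.5, h2_y = 0.5,
                                conf_share_x = 0.4, conf_share_y = 0.4,
                                rho_shared = 0,
                                n_individuals = 20000,
                                trait_mode = c("quantitative",
                                               "binary_liability",
                                               "survival"),
                                case_fraction = 0.2,
                                n_cases = 10000, n_controls = 10000,
                                prognosis_mode = c("case_only",
                                                   "quantitative_in_cases",
                                                   "case_control_degenerate"),
                                beta_xy = 0,
                                maf_low = 0.01, maf_high = 0.49,
                                seed = NULL) {
  trait_mode <- match.arg(trait_mode)
  prognosis_mode <- match.arg(prognosis_mode)
  if (m_inc_only + m_prog_only + m_both > m_total) {
    stop("causal variant counts exceed m_total")
  }
  if (h2_x < 0 || h2_x >= 1 || h2_y < 0 || h2_y >= 1) {
    stop("heritabilities must lie in [0, 1)")
  }
  if (h2_x + conf_share_x > 1 || h2_y + conf_share_y > 1) {
    stop("heritability and confounder share must sum to at most 1")
  }
  if (abs(rho_shared) > 1) stop("rho_shared must lie in [-1, 1]")
  if (maf_low <= 0 || maf_high > 0.5 || maf_low >= maf_high) {
    stop("maf range must satisfy 0 < maf_low < maf_high <= 0.5")
  }
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must lie in (0, 1)")
  }
  structure(list(m_total = m_total, m_inc_only = m_inc_only,
                 m_prog_only = m_prog_only, m_both = m_both,
                 h2_x = h2_x, h2_y = h2_y,
                 conf_share_x = conf_share_x, conf_share_y = conf_share_y,
                 rho_shared = rho_shared, n_individuals = n_individuals,
                 trait_mode = trait_mode, case_fraction = case_fraction,
                 n_cases = n_cases, n_controls = n_controls,
                 prognosis_mode = prognosis_mode, beta_xy = beta_xy,
                 maf_low = maf_low, maf_high = maf_high, seed = seed),
            class = "simulation_scenario")
}

#' Load a simulation scenario from a YAML or JSON file
#'
#' @param path File with fields matching the arguments of
#'   [simulation_scenario()]; unknown fields raise an error.
#' @return A `simulation_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(simulation_scenario))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(simulation_scenario, vals)
}

#' Structural parameters implied by a scenario
#'
#' From the viewpoint of a single variant, the polygenic background and
#' the trait-specific residual both belong to the non-genetic terms of
#' the single-variant structural model, so the implied residual variance
#' of incidence is everything except the confounder share. With
#' confounder effects `sqrt(conf_share)` on each unit-variance trait,
#' the analytic confounding slope reduces to
#' `-sqrt(conf_share_x * conf_share_y)`.
#'
#' @param scenario A [simulation_scenario()].
#' @return A [structural_params()] object.
#' @export
scenario_params <- function(scenario) {
  structural_params(var_u = 1,
                    beta_ux = sqrt(scenario$conf_share_x),
                    beta_uy = sqrt(scenario$conf_share_y),
                    var_ex = 1 - scenario$conf_share_x,
                    var_ey = 1 - scenario$conf_share_y,
                    beta_xy = scenario$beta_xy)
}

#' Simulate independent Hardy-Weinberg genotypes
#'
#' @param n Individuals (rows).
#' @param m Variants (columns).
#' @param maf_low,maf_high Uniform range for minor allele frequencies.
#' @param seed Optional seed.
#' @return List with `dosages` (n x m integer matrix of 0/1/2) and
#'   `maf` (length-m vector).
#' @export
simulate_genotypes <- function(n, m, maf_low = 0.01, maf_high = 0.49,
                               seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (maf_low <= 0 || maf_high > 0.5 || maf_low >= maf_high) {
    stop("maf range must satisfy 0 < maf_low < maf_high <= 0.5")
  }
  .with_seed(seed, {
    maf <- stats::runif(m, maf_low, maf_high)
    dosages <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    list(dosages = dosages, maf = maf)
  })
}

# Draw standardized-scale effects for all categories. Returns list with
# per-variant standardized effects (bs_x, bs_y), category labels and the
# realized standardized-scale genetic covariance. Effects are scaled so
# the summed standardized effect variance equals the target heritability
# exactly.
.draw_std_effects <- function(scenario) {
  m <- scenario$m_total
  mi <- scenario$m_inc_only; mp <- scenario$m_prog_only
  mb <- scenario$m_both
  category <- rep("null", m)
  idx_inc <- seq_len(mi)
  idx_prog <- mi + seq_len(mp)
  idx_both <- mi + mp + seq_len(mb)
  category[idx_inc] <- "inc_only"
  category[idx_prog] <- "prog_only"
  category[idx_both] <- "both"

  bs_x <- numeric(m); bs_y <- numeric(m)
  if (mi + mb > 0 && scenario$h2_x > 0) {
    bs_x[c(idx_inc, idx_both)] <- stats::rnorm(mi + mb)
  }
  if (mp + mb > 0 && scenario$h2_y > 0) {
    bs_y[idx_prog] <- stats::rnorm(mp)
    rho <- scenario$rho_shared
    bs_y[idx_both] <- rho * bs_x[idx_both] +
      sqrt(1 - rho^2) * stats::rnorm(mb)
  }
  if (scenario$h2_x > 0 && sum(bs_x^2) > 0) {
    bs_x <- bs_x * sqrt(scenario$h2_x / sum(bs_x^2))
  }
  if (scenario$h2_y > 0 && sum(bs_y^2) > 0) {
    bs_y <- bs_y * sqrt(scenario$h2_y / sum(bs_y^2))
  }
  list(bs_x = bs_x, bs_y = bs_y, category = category,
       idx_inc = idx_inc, idx_prog = idx_prog, idx_both = idx_both)
}

#' Draw per-variant effect sizes for a scenario
#'
#' Effects are drawn independently from normal distributions on the
#' standardized genotype scale, so every causal variant contributes the
#' same expected share of the heritability regardless of allele
#' frequency; dosage-scale effects are the standardized effects divided
#' by the genotype standard deviation. At shared variants the incidence
#' and prognosis effects are bivariate normal with correlation
#' `rho_shared`. Each trait's effect vector is rescaled so the total
#' standardized effect variance equals the target heritability exactly,
#' which stabilises reduced-scale runs.
#'
#' @param scenario A [simulation_scenario()].
#' @param geno_var Optional length-`m_total` vector of genotype variances
#'   (realized column variances, or `2 p (1 - p)`); when omitted, allele
#'   frequencies are drawn from the scenario's range.
#' @param seed Optional seed.
#' @return A list of class `scenario_truth`: dosage-scale effect vectors
#'   `beta_gx_true`, `beta_gy_true`, standardized effects, the category
#'   label per variant, the realized genetic covariance `gencov`, the
#'   confounder covariance, the model bias slope `b_model`
#'   (`-(confounder covariance + genetic covariance)`), the population
#'   slope `analytic_b_expected` from [scenario_params()], and the
#'   expected target of the slope regression `slope_target`
#'   (`b_model` plus the effect-correlation contribution).
#' @export
draw_effect_vectors <- function(scenario, geno_var = NULL, seed = NULL) {
  .with_seed(seed, {
    maf <- NULL
    if (is.null(geno_var)) {
      maf <- stats::runif(scenario$m_total, scenario$maf_low,
                          scenario$maf_high)
      geno_var <- 2 * maf * (1 - maf)
    }
    if (length(geno_var) != scenario$m_total) {
      stop("geno_var must have length m_total")
    }
    eff <- .draw_std_effects(scenario)
    beta_gx <- eff$bs_x / sqrt(geno_var)
    beta_gy <- eff$bs_y / sqrt(geno_var)
    gencov <- sum(eff$bs_x * eff$bs_y)
    confcov <- sqrt(scenario$conf_share_x * scenario$conf_share_y)
    b_model <- -(confcov + gencov)
    wx <- eff$bs_x^2 / geno_var
    slope_target <- if (sum(wx) > 0) {
      b_model + sum(eff$bs_x * eff$bs_y / geno_var) / sum(eff$bs_x^2 / geno_var)
    } else {
      b_model
    }
    structure(list(beta_gx_true = beta_gx, beta_gy_true = beta_gy,
                   bs_x = eff$bs_x, bs_y = eff$bs_y,
                   category = eff$category, idx_inc = eff$idx_inc,
                   idx_prog = eff$idx_prog, idx_both = eff$idx_both,
                   maf = maf, geno_var = geno_var,
                   gencov = gencov, confcov = confcov, b_model = b_model,
                   slope_target = slope_target,
                   analytic_b_expected = analytic_b(scenario_params(scenario))),
              class = "scenario_truth")
  })
}

#' Simulate incidence and prognosis traits
#'
#' Builds \eqn{X = G\beta_{GX} + \sqrt{c_X} U + E_X} and
#' \eqn{Y = G\beta_{GY} + \sqrt{c_Y} U + \beta_{XY} X + E_Y} with a
#' standard-normal confounder `U` and residual variances chosen so each
#' trait's direct part has unit variance. Genotypes are centred, and the
#' effect vectors are rescaled so the realized genetic variance of each
#' trait equals the target heritability exactly; the returned truth
#' carries the rescaled effects.
#'
#' @param dosages Genotype matrix (individuals x variants).
#' @param truth A `scenario_truth` from [draw_effect_vectors()].
#' @param scenario The scenario.
#' @param seed Optional seed.
#' @return List with `X`, `Y`, `U` and the updated `truth`.
#' @export
simulate_traits <- function(dosages, truth, scenario, seed = NULL) {
  stopifnot(ncol(dosages) == length(truth$beta_gx_true))
  .with_seed(seed, {
    n <- nrow(dosages)
    centred <- sweep(dosages, 2, colMeans(dosages))
    gx <- as.vector(centred %*% truth$beta_gx_true)
    gy <- as.vector(centred %*% truth$beta_gy_true)
    if (scenario$h2_x > 0 && stats::var(gx) > 0) {
      fx <- sqrt(scenario$h2_x / stats::var(gx))
      gx <- gx * fx
      truth$beta_gx_true <- truth$beta_gx_true * fx
      truth$bs_x <- truth$bs_x * fx
    }
    if (scenario$h2_y > 0 && stats::var(gy) > 0) {
      fy <- sqrt(scenario$h2_y / stats::var(gy))
      gy <- gy * fy
      truth$beta_gy_true <- truth$beta_gy_true * fy
      truth$bs_y <- truth$bs_y * fy
    }
    # keep derived covariance quantities consistent with the rescale
    truth$gencov <- sum(truth$bs_x * truth$bs_y)
    truth$b_model <- -(truth$confcov + truth$gencov)
    wx <- truth$bs_x^2 / truth$geno_var
    truth$slope_target <- if (sum(wx) > 0) {
      truth$b_model +
        sum(truth$bs_x * truth$bs_y / truth$geno_var) / sum(wx)
    } else {
      truth$b_model
    }
    U <- stats::rnorm(n)
    ex_var <- 1 - scenario$h2_x - scenario$conf_share_x
    ey_var <- 1 - scenario$h2_y - scenario$conf_share_y
    X <- gx + sqrt(scenario$conf_share_x) * U +
      stats::rnorm(n, 0, sqrt(ex_var))
    Y <- gy + sqrt(scenario$conf_share_y) * U + scenario$beta_xy * X +
      stats::rnorm(n, 0, sqrt(ey_var))
    list(X = X, Y = Y, U = U, truth = truth)
  })
}

#' Dichotomise incidence and ascertain a case/control sample
#'
#' Disease status is the incidence trait exceeding its upper
#' `case_fraction` sample quantile (the liability threshold); binary
#' prognosis is the prognosis trait exceeding its median among the
#' sampled cases. Exactly `n_cases` cases and `n_controls` controls are
#' drawn without replacement; if the pool contains too few of either,
#' an error advises generating a larger pool.
#'
#' @param X,Y Incidence and prognosis traits.
#' @param scenario The scenario (uses `case_fraction`, `n_cases`,
#'   `n_controls`).
#' @param seed Optional seed.
#' @return List with `idx` (sampled indices, cases first), `disease`
#'   (logical per sampled individual), `poor_prognosis` (logical per
#'   sampled case), `case_idx`, `control_idx` and the threshold used.
#' @export
dichotomize_and_sample <- function(X, Y, scenario, seed = NULL) {
  .with_seed(seed, {
    threshold <- stats::quantile(X, 1 - scenario$case_fraction,
                                 names = FALSE)
    affected <- which(X > threshold)
    unaffected <- which(X <= threshold)
    if (length(affected) < scenario$n_cases) {
      stop("pool yielded ", length(affected), " cases but ",
           scenario$n_cases, " were requested; simulate a larger pool")
    }
    if (length(unaffected) < scenario$n_controls) {
      stop("pool yielded ", length(unaffected), " controls but ",
           scenario$n_controls, " were requested; simulate a larger pool")
    }
    case_idx <- sort(sample(affected, scenario$n_cases))
    control_idx <- sort(sample(unaffected, scenario$n_controls))
    poor <- Y[case_idx] > stats::median(Y[case_idx])
    list(idx = c(case_idx, control_idx),
         disease = rep(c(TRUE, FALSE),
                       c(scenario$n_cases, scenario$n_controls)),
         poor_prognosis = poor,
         case_idx = case_idx, control_idx = control_idx,
         threshold = threshold)
  })
}

# --- summary-level engine ---------------------------------------------------

# Liability-to-observed-scale constants for a logistic analysis of a
# thresholded trait: small liability effects map to log odds ratios
# approximately multiplied by phi(t) / (K (1 - K)).
.liability_logit_factor <- function(case_fraction) {
  t <- stats::qnorm(1 - case_fraction)
  stats::dnorm(t) / (case_fraction * (1 - case_fraction))
}

# One summary-level replicate: draws effect estimates from the sampling
# distributions implied by the generative model. RNG state must already
# be set by the caller. When arch_seed is given, the architecture
# (frequencies and true effects) is drawn under that fixed seed while the
# estimation noise still comes from the ambient RNG stream; replicates
# sharing an arch_seed share one genetic architecture, which supports
# decomposing Monte-Carlo variance into architecture and estimation
# components.
.summary_rep <- function(scenario, arch_seed = NULL) {
  m <- scenario$m_total
  arch <- .with_seed(arch_seed, {
    maf <- stats::runif(m, scenario$maf_low, scenario$maf_high)
    v <- 2 * maf * (1 - maf)
    list(maf = maf, truth = draw_effect_vectors(scenario, geno_var = v))
  })
  maf <- arch$maf
  v <- 2 * maf * (1 - maf)
  truth <- arch$truth
  truth$maf <- maf
  bx <- truth$beta_gx_true
  byp <- truth$beta_gy_true + truth$b_model * bx
  rho <- -truth$b_model   # cov(X, Y) net of any direct X->Y effect
  if (scenario$trait_mode == "quantitative") {
    n <- scenario$n_individuals
    se_gx <- sqrt(pmax(1 - bx^2 * v, 0.05) / (n * v))
    se_gy <- sqrt(pmax(1 - rho^2 - byp^2 * v, 0.05) / (n * v))
    bx_obs <- bx
    byp_obs <- byp
  } else if (scenario$trait_mode == "binary_liability") {
    # incidence: logistic regression of ascertained case/control status;
    # prognosis: logistic regression of the median-split prognosis among
    # cases only, with the case-only selection attenuating the collider
    # slope by lambda (lambda - t), the derivative of the truncated-normal
    # mean at the threshold
    K <- scenario$case_fraction
    t <- stats::qnorm(1 - K)
    lam <- stats::dnorm(t) / K
    kappa <- lam * (lam - t)
    c_x <- .liability_logit_factor(K)
    b_case <- -rho * kappa
    sd_y_case <- sqrt(max(1 - rho^2 * kappa, 0.05))
    c_y <- stats::dnorm(0) / (0.25 * sd_y_case)
    n_cc <- scenario$n_cases + scenario$n_controls
    phi_cc <- (scenario$n_cases / n_cc) * (scenario$n_controls / n_cc)
    bx_obs <- c_x * bx
    byp_obs <- c_y * (truth$beta_gy_true + b_case * bx)
    se_gx <- sqrt(1 / (n_cc * phi_cc * v))
    se_gy <- sqrt(1 / (scenario$n_cases * 0.25 * v))
  } else {
    stop("summary-level engine supports quantitative and binary_liability ",
         "modes only")
  }
  if (scenario$beta_xy != 0) {
    stop("summary-level engine requires beta_xy = 0")
  }
  pairs <- data.frame(
    variant_id = paste0("snp", seq_len(m)),
    beta_gx = bx_obs + stats::rnorm(m) * se_gx,
    se_gx = se_gx,
    beta_gy_prime = byp_obs + stats::rnorm(m) * se_gy,
    se_gy = se_gy,
    eaf = maf, info_x = NA_real_, info_y = NA_real_,
    pruned = TRUE,
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, truth = truth)
}

#' Draw summary statistics directly from their sampling distributions
#'
#' Fast replication path for operating-characteristic studies: instead of
#' simulating individuals, the per-variant effect estimates are drawn
#' from the asymptotic sampling distributions implied by the generative
#' model. Incidence estimates are normal around the true effects with
#' variance `residual variance / (n * genotype variance)`; conditional
#' prognosis estimates are normal around `beta_gy_true + b_model *
#' beta_gx_true`, the collider-biased conditional effect. For the
#' binary liability design, effects are mapped to the log-odds scale
#' with the standard liability-to-observed factor and the case-only
#' attenuation of the collider slope, with balanced case/control
#' standard errors.
#'
#' @param scenario A [simulation_scenario()] with `beta_xy = 0` and
#'   quantitative or binary-liability trait mode.
#' @param n_reps Number of replicates.
#' @param seed Optional seed.
#' @return A list of `n_reps` elements, each with `pairs` (harmonised
#'   pair table, all variants flagged pruned) and `truth`.
#' @export
simulate_summary_level <- function(scenario, n_reps = 1, seed = NULL) {
  .with_seed(seed, {
    lapply(seq_len(n_reps), function(r) .summary_rep(scenario))
  })
}
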
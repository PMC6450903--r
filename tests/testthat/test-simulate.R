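test_that("genotypes follow Hardy-Weinberg moments and are seeded", {
  g1 <- simulate_genotypes(4000, 30, seed = 5)
  g2 <- simulate_genotypes(4000, 30, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$maf, g2$maf)
  expect_true(all(g1$dosages %in% 0:2))
  # binomial mean 2p and variance 2p(1-p) within sampling error
  expect_equal(colMeans(g1$dosages), 2 * g1$maf, tolerance = 0.05)
  expect_equal(apply(g1$dosages, 2, var), 2 * g1$maf * (1 - g1$maf),
               tolerance = 0.12)
  # near-degenerate maf range pins the mean dosage at 2p
  gh <- simulate_genotypes(8000, 4, maf_low = 0.499, maf_high = 0.5,
                           seed = 6)
  expect_equal(colMeans(gh$dosages), rep(1, 4), tolerance = 0.04)
  expect_error(simulate_genotypes(10, 2, maf_low = 0, maf_high = 0.5))
})

test_that("effect draws hit the heritability targets exactly", {
  sc <- small_scenario()
  truth <- draw_effect_vectors(sc, seed = 8)
  expect_equal(sum(truth$bs_x^2), sc$h2_x, tolerance = 1e-12)
  expect_equal(sum(truth$bs_y^2), sc$h2_y, tolerance = 1e-12)
  expect_equal(truth$beta_gx_true, truth$bs_x / sqrt(truth$geno_var))
  # categories are laid out as declared
  expect_equal(sum(truth$category == "inc_only"), sc$m_inc_only)
  expect_equal(sum(truth$category == "both"), sc$m_both)
  expect_true(all(truth$beta_gy_true[truth$category == "inc_only"] == 0))
  # no incidence heritability means no incidence effects
  t0 <- draw_effect_vectors(small_scenario(h2_x = 0), seed = 9)
  expect_true(all(t0$beta_gx_true == 0))
})

test_that("shared-effect correlation yields the genome-wide correlation", {
  # effect-pair correlation 0.5 with half the causal variants shared
  # gives genetic correlation near 0.25
  sc <- small_scenario(rho_shared = 0.5)
  rg <- replicate(40, {
    truth <- draw_effect_vectors(sc)
    truth$gencov / sqrt(sc$h2_x * sc$h2_y)
  })
  expect_equal(mean(rg), 0.25, tolerance = 3 * sd(rg) / sqrt(40))
  expect_error(small_scenario(rho_shared = 1.5))
})

test_that("trait construction matches its declared variance components", {
  sc <- simulation_scenario(m_total = 400, m_inc_only = 40,
                           m_prog_only = 40, m_both = 40,
                           n_individuals = 6000)
  geno <- simulate_genotypes(sc$n_individuals, sc$m_total, seed = 10)
  truth <- draw_effect_vectors(sc, geno_var = apply(geno$dosages, 2, var),
                               seed = 11)
  sim <- simulate_traits(geno$dosages, truth, sc, seed = 12)
  expect_equal(var(sim$X), 1, tolerance = 0.05)
  expect_equal(var(sim$Y), 1, tolerance = 0.05)
  # realized genetic variance is rescaled to h2 exactly
  centred <- sweep(geno$dosages, 2, colMeans(geno$dosages))
  expect_equal(var(as.vector(centred %*% sim$truth$beta_gx_true)),
               sc$h2_x, tolerance = 1e-10)

  # without confounding or direct effect, the trait correlation is the
  # genetic covariance alone
  sc0 <- simulation_scenario(m_total = 400, m_inc_only = 40,
                            m_prog_only = 40, m_both = 40,
                            n_individuals = 6000, conf_share_x = 0,
                            conf_share_y = 0, rho_shared = 0.8)
  truth0 <- draw_effect_vectors(sc0, geno_var = apply(geno$dosages, 2, var),
                                seed = 13)
  sim0 <- simulate_traits(geno$dosages, truth0, sc0, seed = 14)
  gx <- as.vector(centred %*% sim0$truth$beta_gx_true)
  gy <- as.vector(centred %*% sim0$truth$beta_gy_true)
  expect_lt(abs(cov(sim0$X, sim0$Y) - cov(gx, gy)), 0.04)

  # all-null scenario: two independent standard normals
  scn <- simulation_scenario(m_total = 100, m_inc_only = 0,
                            m_prog_only = 0, m_both = 0, h2_x = 0,
                            h2_y = 0, conf_share_x = 0, conf_share_y = 0,
                            n_individuals = 6000)
  truthn <- draw_effect_vectors(scn, geno_var = rep(0.3, 100), seed = 15)
  simn <- simulate_traits(geno$dosages[, 1:100], truthn, scn, seed = 16)
  expect_equal(cor(simn$X, simn$Y), 0, tolerance = 0.04)
  expect_equal(var(simn$X), 1, tolerance = 0.05)
})

test_that("liability thresholding and case sampling behave as declared", {
  sc <- simulation_scenario(m_total = 10, m_inc_only = 1, m_prog_only = 1,
                            m_both = 1, trait_mode = "binary_liability",
                            n_cases = 300, n_controls = 300,
                            case_fraction = 0.2, n_individuals = 2000)
  withr::with_seed(20, {
    X <- rnorm(2000); Y <- rnorm(2000)
  })
  s1 <- dichotomize_and_sample(X, Y, sc, seed = 21)
  s2 <- dichotomize_and_sample(X, Y, sc, seed = 21)
  expect_identical(s1$idx, s2$idx)
  expect_equal(length(s1$case_idx), 300)
  expect_equal(length(s1$control_idx), 300)
  # threshold selects the declared top fraction
  expect_equal(mean(X > s1$threshold), 0.2, tolerance = 0.002)
  expect_true(all(X[s1$case_idx] > s1$threshold))
  # median split: half the cases labelled poor (up to ties)
  expect_equal(mean(s1$poor_prognosis), 0.5, tolerance = 1 / 300)
  # insufficient pool is an explicit error
  sc_big <- simulation_scenario(m_total = 10, m_inc_only = 1,
                                m_prog_only = 1, m_both = 1,
                                n_cases = 1000, n_controls = 100,
                                case_fraction = 0.2)
  expect_error(dichotomize_and_sample(X, Y, sc_big, seed = 22),
               "larger pool")
})

test_that("summary-level sampling distributions match the individual level", {
  # per-variant estimator errors from the individual-level engine,
  # standardized by the closed-form standard errors the summary engine
  # draws from, must have unit spread within 5%; pooled over replicates
  # because the errors within one cohort are correlated
  sc <- simulation_scenario(m_total = 2000, m_inc_only = 100,
                            m_prog_only = 100, m_both = 100,
                            n_individuals = 2000)
  zx <- zy <- rx <- ry <- NULL
  for (s in 1:4) {
    geno <- simulate_genotypes(sc$n_individuals, sc$m_total, seed = 30 + s)
    truth <- draw_effect_vectors(sc, geno_var = apply(geno$dosages, 2, var),
                                 seed = 130 + s)
    sim <- simulate_traits(geno$dosages, truth, sc, seed = 230 + s)
    truth <- sim$truth
    inc <- per_snp_linear_gwas(geno$dosages, sim$X)
    prog <- per_snp_linear_gwas(geno$dosages, sim$Y, covariates = sim$X)
    v <- apply(geno$dosages, 2, var)
    rho <- truth$confcov + truth$gencov
    se_sum_x <- sqrt((1 - truth$beta_gx_true^2 * v) / (sc$n_individuals * v))
    byp_true <- truth$beta_gy_true + truth$b_model * truth$beta_gx_true
    se_sum_y <- sqrt((1 - rho^2 - byp_true^2 * v) / (sc$n_individuals * v))
    zx <- c(zx, (inc$beta - truth$beta_gx_true) / se_sum_x)
    zy <- c(zy, (prog$beta - byp_true) / se_sum_y)
    rx <- c(rx, inc$se / se_sum_x)
    ry <- c(ry, prog$se / se_sum_y)
  }
  expect_equal(sd(zx), 1, tolerance = 0.05)
  expect_equal(sd(zy), 1, tolerance = 0.05)
  expect_equal(mean(zy), 0, tolerance = 3 / sqrt(length(zy)))
  # and the per-variant standard errors estimated by the scans agree
  expect_equal(median(rx), 1, tolerance = 0.05)
  expect_equal(median(ry), 1, tolerance = 0.05)
})

test_that("summary engine is reproducible and validates its scope", {
  sc <- small_scenario()
  r1 <- simulate_summary_level(sc, n_reps = 2, seed = 40)
  r2 <- simulate_summary_level(sc, n_reps = 2, seed = 40)
  expect_identical(r1[[1]]$pairs, r2[[1]]$pairs)
  expect_false(identical(r1[[1]]$pairs$beta_gx, r1[[2]]$pairs$beta_gx))
  expect_error(
    simulate_summary_level(small_scenario(trait_mode = "survival")),
    "summary-level")
  expect_error(
    simulate_summary_level(small_scenario(beta_xy = 0.2), seed = 1),
    "beta_xy")
})

test_that("scenario files round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("m_total: 500", "m_inc_only: 25", "m_prog_only: 25",
               "m_both: 25", "rho_shared: 0.5", "n_individuals: 1000"), f)
  sc <- read_scenario(f)
  expect_s3_class(sc, "simulation_scenario")
  expect_equal(sc$m_total, 500)
  expect_equal(sc$rho_shared, 0.5)
  expect_equal(sc$h2_x, 0.5)  # defaults fill the rest
  writeLines("bogus_field: 1", f)
  expect_error(read_scenario(f), "unknown scenario field")
})

test_that("scenario validation rejects inconsistent settings", {
  expect_error(simulation_scenario(m_total = 100, m_inc_only = 90,
                                   m_prog_only = 20, m_both = 0),
               "exceed")
  expect_error(simulation_scenario(h2_x = 0.7, conf_share_x = 0.5),
               "sum to at most 1")
  expect_error(simulation_scenario(case_fraction = 1.2), "case_fraction")
})
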
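# Shared fixtures and reference implementations used across test files.

# A small harmonised pair table with known structure.
make_pairs <- function(m = 50, b = -0.4, se_gx = 0.05, se_gy = 0.05,
                       seed = 42) {
  withr::with_seed(seed, {
    beta_gx <- rnorm(m, 0, 0.3)
    beta_gy <- b * beta_gx + rnorm(m, 0, 0.02)
    data.frame(
      variant_id = paste0("rs", seq_len(m)),
      beta_gx = beta_gx + rnorm(m, 0, se_gx),
      se_gx = rep(se_gx, m),
      beta_gy_prime = beta_gy + rnorm(m, 0, se_gy),
      se_gy = rep(se_gy, m),
      eaf = runif(m, 0.05, 0.95),
      info_x = runif(m, 0.95, 1),
      info_y = runif(m, 0.95, 1),
      pruned = TRUE,
      stringsAsFactors = FALSE
    )
  })
}

# Write a summary-statistics file in the default column layout.
write_sumstats_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_sumstats <- function(ids, beta, se, ea = "A", oa = "G",
                          eaf = NULL, info = NULL) {
  out <- data.frame(SNP = ids, EA = ea, OA = oa, BETA = beta, SE = se,
                    stringsAsFactors = FALSE)
  if (!is.null(eaf)) out$EAF <- eaf
  if (!is.null(info)) out$INFO <- info
  out
}

# Straightforward reference implementation of the greedy pruning rule,
# written independently of the package's implementation.
reference_prune <- function(dosages, r2_threshold, window) {
  ids <- colnames(dosages)
  kept <- integer(0)
  for (j in seq_len(ncol(dosages))) {
    if (var(dosages[, j]) == 0) next
    ok <- TRUE
    for (k in kept) {
      if (k >= j - window &&
          cor(dosages[, j], dosages[, k])^2 >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  ids[kept]
}

# Reduced-scale quantitative scenario used by several tests.
small_scenario <- function(...) {
  simulation_scenario(m_total = 2000, m_inc_only = 100, m_prog_only = 100,
                      m_both = 100, n_individuals = 5000, ...)
}
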
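test_that("read_sumstats parses, drops bad rows and reports config errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats_file(make_sumstats(c("rs1", "rs2", "rs3"),
                                    beta = c(0.1, -0.2, 0.05),
                                    se = c(0.05, 0.04, 0.06)), f)
  ss <- read_sumstats(f, quiet = TRUE)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$beta, c(0.1, -0.2, 0.05))
  expect_equal(attr(ss, "n_dropped"), 0)

  # a zero standard error violates the record invariant and is dropped
  write_sumstats_file(make_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.2),
                                    se = c(0, 0.04)), f)
  expect_message(ss <- read_sumstats(f), "dropped 1")
  expect_equal(nrow(ss), 1)
  expect_equal(ss$variant_id, "rs2")
  expect_equal(attr(ss, "n_dropped"), 1)

  # header lacking a mapped column is a configuration error naming it
  df <- make_sumstats("rs1", 0.1, 0.05)
  names(df)[names(df) == "SE"] <- "STDERR"
  write_sumstats_file(df, f)
  expect_error(read_sumstats(f), "SE")
  expect_silent(res <- read_sumstats(
    f, column_map = c(variant_id = "SNP", effect_allele = "EA",
                      other_allele = "OA", beta = "BETA", se = "STDERR"),
    quiet = TRUE))
  expect_equal(res$se, 0.05)

  writeLines("SNP\tEA\tOA\tBETA\tSE", f)
  expect_error(read_sumstats(f), "empty")
  expect_error(read_sumstats(file.path(tempdir(), "no-such-file.tsv")),
               "not found")

  # duplicated ids are reduced to the first occurrence
  write_sumstats_file(make_sumstats(c("rs1", "rs1"), beta = c(0.1, 0.9),
                                    se = c(0.05, 0.05)), f)
  expect_warning(ss <- read_sumstats(f, quiet = TRUE), "duplicated")
  expect_equal(ss$beta, 0.1)
})

test_that("harmonize aligns alleles, flipping the sign of swapped effects", {
  inc <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                    effect_allele = c("A", "A", "A", "A"),
                    other_allele = c("G", "C", "G", "C"),
                    beta = c(0.1, 0.2, 0.3, 0.4),
                    se = rep(0.05, 4), stringsAsFactors = FALSE)
  prog <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "C", "A", "C"),
                     other_allele = c("G", "A", "G", "G"),
                     beta = c(0.5, 0.3, -0.2, 0.7),
                     se = rep(0.04, 4), eaf = c(0.3, 0.3, 0.3, 0.3),
                     stringsAsFactors = FALSE)
  pairs <- harmonize(inc, prog, quiet = TRUE)
  # rs1 identical alleles: unchanged; rs2 swapped: negated; rs4 mismatch
  expect_equal(pairs$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(pairs$beta_gy_prime, c(0.5, -0.3, -0.2))
  expect_equal(attr(pairs, "n_mismatch"), 1)
})

test_that("allele swap sign convention matches recoding the dosage", {
  # regressing on the recoded dosage 2 - G must negate the slope exactly;
  # the harmonisation applies the same convention to summary effects
  withr::with_seed(7, {
    g <- rbinom(10, 2, 0.4)
    y <- 0.3 * g + rnorm(10)
  })
  b_fwd <- coef(lm(y ~ g))[["g"]]
  b_rev <- coef(lm(y ~ I(2 - g)))[[2]]
  expect_equal(b_rev, -b_fwd, tolerance = 1e-12)
})

test_that("palindromic variants are dropped by default but retainable", {
  inc <- data.frame(variant_id = c("rs1", "rs2"),
                    effect_allele = c("A", "C"),
                    other_allele = c("T", "G"),
                    beta = c(0.1, 0.2), se = c(0.05, 0.05),
                    stringsAsFactors = FALSE)
  prog <- inc
  expect_error(harmonize(inc, prog, quiet = TRUE), "no harmonisable")
  pairs <- harmonize(inc, prog, drop_palindromic = FALSE, quiet = TRUE)
  expect_equal(nrow(pairs), 2)
})

test_that("harmonisation is involution-safe", {
  inc <- data.frame(variant_id = c("rs1", "rs2"),
                    effect_allele = c("A", "A"),
                    other_allele = c("G", "C"),
                    beta = c(0.1, 0.2), se = c(0.05, 0.05),
                    stringsAsFactors = FALSE)
  prog <- data.frame(variant_id = c("rs1", "rs2"),
                     effect_allele = c("G", "A"),
                     other_allele = c("A", "C"),
                     beta = c(0.5, 0.3), se = c(0.04, 0.04),
                     stringsAsFactors = FALSE)
  once <- harmonize(inc, prog, quiet = TRUE)
  prog_aligned <- data.frame(variant_id = once$variant_id,
                             effect_allele = once$effect_allele,
                             other_allele = once$other_allele,
                             beta = once$beta_gy_prime,
                             se = once$se_gy, stringsAsFactors = FALSE)
  twice <- harmonize(inc, prog_aligned, quiet = TRUE)
  expect_equal(twice$beta_gy_prime, once$beta_gy_prime)
  expect_equal(twice$beta_gx, once$beta_gx)
})

test_that("filter_pairs enforces info and frequency thresholds", {
  pairs <- make_pairs(m = 12)
  pairs$info_x <- c(rep(0.995, 6), rep(0.95, 6))
  pairs$info_y <- c(rep(0.991, 11), 0.95)
  kept <- filter_pairs(pairs, min_info = 0.99)
  expect_equal(nrow(kept), 6)
  expect_true(all(kept$info_x >= 0.99 & kept$info_y >= 0.99))

  # thresholds of zero are the identity, and let missing metadata pass
  pairs$info_x[1] <- NA
  pairs$eaf[2] <- NA
  expect_equal(nrow(filter_pairs(pairs)), nrow(pairs))
  # missing info fails a positive threshold
  expect_false("rs1" %in% filter_pairs(pairs, min_info = 0.9)$variant_id)
  # eaf window
  pairs$eaf <- seq(0.01, 0.99, length.out = 12)
  kept <- filter_pairs(pairs, min_eaf = 0.05)
  expect_true(all(kept$eaf >= 0.05 & kept$eaf <= 0.95))
})

test_that("write_adjusted round-trips values exactly, including tiny p", {
  pairs <- make_pairs(m = 12)
  slope <- estimate_slope(pairs, method = "raw")
  adj <- adjust_effects(pairs, slope)
  adj$p[1] <- 1e-300
  f <- withr::local_tempfile(fileext = ".tsv")
  write_adjusted(adj, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  for (cl in c("beta_gx", "se_gx", "beta_gy_prime", "se_gy",
               "beta_gy_adj", "se_adj", "z", "p")) {
    expect_identical(back[[cl]], adj[[cl]], label = cl)
  }
  expect_identical(back$p[1], 1e-300)

  # empty collection produces a header-only file
  write_adjusted(adj[0, ], f)
  expect_equal(length(readLines(f)), 1L)
})
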
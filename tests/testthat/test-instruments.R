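test_that("p-value filter is strict and order-preserving", {
  df <- data.frame(rsid = c("a", "b", "c"), chrom = "1",
                   pos = c(1L, 2L, 3L), effect_allele = "A",
                   other_allele = "G", beta = 0.1, se = 0.02,
                   pval = c(1e-6, 1e-4, 1e-5), eaf = 0.3, n = 1000L,
                   stringsAsFactors = FALSE)
  kept <- filter_by_pvalue(df, 1e-5)
  expect_equal(kept$rsid, "a")                 # 1e-4 above, 1e-5 boundary out
  expect_equal(filter_by_pvalue(df, 1)$rsid, df$rsid)
})

test_that("clumping keeps the smallest-p SNP of a correlated pair and scopes by window", {
  two <- data.frame(rsid = c("lead", "tag"), chrom = "1",
                    pos = c(100000L, 110000L), effect_allele = "A",
                    other_allele = "G", beta = 0.1, se = 0.02,
                    pval = c(1e-8, 1e-6), eaf = 0.3, n = 1000L,
                    stringsAsFactors = FALSE)
  ld <- ld_table(data.frame(rsid_a = "lead", rsid_b = "tag", r2 = 0.5))
  expect_equal(clump(two, ld)$rsid, "lead")

  # same recorded r2 but different chromosomes: window constraint not met
  two$chrom <- c("1", "2")
  expect_setequal(clump(two, ld)$rsid, c("lead", "tag"))

  # within the window but below the r2 threshold: both kept
  two$chrom <- "1"
  ld_low <- ld_table(data.frame(rsid_a = "lead", rsid_b = "tag", r2 = 0.09))
  expect_setequal(clump(two, ld_low)$rsid, c("lead", "tag"))
})

test_that("clumping matches the independent greedy oracle on random 8-SNP panels", {
  for (rep in 1:20) {
    set.seed(400 + rep)
    k <- 8
    snps <- data.frame(
      rsid = paste0("s", 1:k), chrom = as.character(sample(1:2, k, TRUE)),
      pos = sample.int(1200000L, k), effect_allele = "A", other_allele = "G",
      beta = 0.1, se = 0.02, pval = runif(k, 1e-10, 1e-4), eaf = 0.3,
      n = 1000L, stringsAsFactors = FALSE)
    cmb <- combn(snps$rsid, 2)
    take <- runif(ncol(cmb)) < 0.4
    ld <- if (any(take)) {
      ld_table(data.frame(rsid_a = cmb[1, take], rsid_b = cmb[2, take],
                          r2 = runif(sum(take))))
    } else ld_table()
    expect_equal(sort(clump(snps, ld)$rsid), clump_oracle(snps, ld))
  }
})

test_that("clumping is invariant to input row order", {
  set.seed(77)
  k <- 10
  snps <- data.frame(
    rsid = paste0("s", 1:k), chrom = "1", pos = sort(sample.int(2e6, k)),
    effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.02,
    pval = round(runif(k, 1e-9, 1e-5), 10), eaf = 0.3, n = 1000L,
    stringsAsFactors = FALSE)
  snps$pval[2] <- snps$pval[1]  # force a tie
  cmb <- combn(snps$rsid, 2)
  ld <- ld_table(data.frame(rsid_a = cmb[1, ], rsid_b = cmb[2, ],
                            r2 = runif(ncol(cmb))))
  ref <- sort(clump(snps, ld)$rsid)
  for (rep in 1:5) {
    perm <- snps[sample.int(k), ]
    expect_equal(sort(clump(perm, ld)$rsid), ref)
  }
})

test_that("variance explained: printed form equals the simplified closed form and drops EAF", {
  # direct evaluation of the printed formula, written out independently
  beta <- 0.1; eaf <- 0.3; se <- 0.01; n <- 7824
  num <- 2 * beta^2 * eaf * (1 - eaf)
  expected <- num / (num + 2 * se^2 * n * eaf * (1 - eaf))
  expect_equal(variance_explained(beta, eaf, se, n), expected,
               tolerance = 1e-15)
  expect_equal(expected, beta^2 / (beta^2 + se^2 * n), tolerance = 1e-12)

  # EAF cancels: any valid eaf gives the same value
  expect_equal(variance_explained(beta, 0.45, se, n),
               variance_explained(beta, 0.3, se, n), tolerance = 1e-12)
  # missing EAF falls back to the identical simplified form
  fallback <- variance_explained(beta, NA, se, n)
  expect_equal(as.numeric(fallback), expected, tolerance = 1e-12)
  expect_equal(attr(fallback, "eaf_fallback"), 1L)

  expect_equal(variance_explained(0, 0.3, se, n), 0)
  expect_error(variance_explained(0.1, 1.2, 0.01, 100), "eaf")
})

test_that("variance explained identity holds across random inputs", {
  set.seed(11)
  n <- 1000
  beta <- rnorm(n, 0, 0.3)
  eaf <- runif(n, 0.01, 0.99)
  se <- runif(n, 0.005, 0.1)
  nn <- sample(500:500000, n, TRUE)
  expect_equal(variance_explained(beta, eaf, se, nn),
               beta^2 / (beta^2 + se^2 * nn), tolerance = 1e-12)
})

test_that("F statistic matches hand arithmetic and enforces its domain", {
  # r2 = 0.5 gives r2/(1-r2) = 1 so F = (1003-2)/1 = 1001
  expect_equal(f_statistic(0.5, 1003, 1), 1001)
  expect_equal(f_statistic(0, 500), 0)
  expect_equal(f_statistic(0.1, 102, 2), (102 - 3) / 2 * (0.1 / 0.9))
  expect_error(f_statistic(1, 100), "r2")
  expect_error(f_statistic(0.5, 2, 1), "n > k")
})

test_that("outcome-associated and missing SNPs are excluded with separate counts", {
  snps <- fixture_records()
  outcome <- summary_dataset(data.frame(
    rsid = c("rs1", "rs2"), chrom = "1", pos = c(1000L, 2000L),
    effect_allele = c("A", "C"), other_allele = c("G", "T"),
    beta = c(0.5, 0.01), se = c(0.05, 0.05), pval = c(1e-7, 0.3),
    eaf = 0.3, n = 372373L, stringsAsFactors = FALSE),
    "oc", "outcome")
  kept <- exclude_outcome_associated(snps, outcome)
  expect_equal(kept$rsid, "rs2")
  expect_equal(attr(kept, "n_outcome_associated"), 1)
  expect_equal(attr(kept, "n_not_in_outcome"), 1)
})

test_that("end-to-end selection keeps strong independent instruments and flags weak exposures", {
  sim <- simulate_pair(sim_config(k_snps = 40, theta = 0, seed = 5))
  iv <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  expect_true(iv$analyzable)
  expect_gte(nrow(iv$snps), 35)        # strong instruments under a null outcome
  expect_true(all(iv$snps$f_snp >= 10))
  expect_true(all(iv$snps$pval < 1e-5))

  # every SNP weak: all removed at the F stage, exposure unanalyzable
  weak <- sim$exposure
  weak$records$beta <- weak$records$beta / 100
  weak$records$pval <- rep(1e-9, nrow(weak$records))  # pass the p filter
  iv_weak <- select_instruments(weak, sim$outcome, sim$ld)
  expect_false(iv_weak$analyzable)
  expect_equal(nrow(iv_weak$snps), 0)
  expect_equal(iv_weak$audit$weak_f,
               iv_weak$audit$n_input - iv_weak$audit$p_filter -
                 iv_weak$audit$clump)
})

test_that("an exposure retaining exactly two SNPs is not analyzable", {
  sim <- simulate_pair(sim_config(k_snps = 2, h2_exposure = 0.05, seed = 9))
  iv <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  expect_equal(nrow(iv$snps), 2)
  expect_false(iv$analyzable)
})

test_that("selection is monotone in the exposure p threshold", {
  sim <- simulate_pair(sim_config(k_snps = 25, h2_exposure = 0.05, seed = 8,
                                  null_snp_count = 50))
  loose <- select_instruments(sim$exposure, sim$outcome, sim$ld,
                              selection_params(exposure_p_threshold = 1e-4))
  tight <- select_instruments(sim$exposure, sim$outcome, sim$ld,
                              selection_params(exposure_p_threshold = 1e-8))
  expect_true(all(tight$snps$rsid %in% loose$snps$rsid))
})
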
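# Independent truth table for a single allele configuration, written by
# enumerating the biology directly: the exposure pair fixes the frame; the
# outcome pair must be the same pair, the swapped pair, or a strand
# (reverse-complement) image of one of those; palindromic exposure pairs
# are unresolvable and dropped.
oracle_classify <- function(ea_x, oa_x, ea_y, oa_y) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  if (comp[[ea_x]] == oa_x) return("palindromic")
  if (identical(c(ea_y, oa_y), c(ea_x, oa_x))) return("keep")
  if (identical(c(ea_y, oa_y), c(oa_x, ea_x))) return("swap")
  if (identical(c(comp[[ea_y]], comp[[oa_y]]), c(ea_x, oa_x))) return("keep_flip")
  if (identical(c(comp[[ea_y]], comp[[oa_y]]), c(oa_x, ea_x))) return("swap_flip")
  "mismatch"
}

make_pair_datasets <- function(ea_x, oa_x, ea_y, oa_y, beta_y = 0.2,
                               eaf_y = 0.2) {
  exposure <- data.frame(rsid = "rs1", chrom = "1", pos = 100L,
                         effect_allele = ea_x, other_allele = oa_x,
                         beta = 0.1, se = 0.02, pval = 1e-8, eaf = 0.3,
                         n = 7824L, stringsAsFactors = FALSE)
  outcome <- summary_dataset(data.frame(
    rsid = "rs1", chrom = "1", pos = 100L, effect_allele = ea_y,
    other_allele = oa_y, beta = beta_y, se = 0.05, pval = 1e-4,
    eaf = eaf_y, n = 372373L, stringsAsFactors = FALSE), "oc", "outcome")
  list(exposure = exposure, outcome = outcome)
}

test_that("harmonization matches the truth table over all allele configurations", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ea_x = bases, oa_x = bases, ea_y = bases, oa_y = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ea_x != grid$oa_x & grid$ea_y != grid$oa_y, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- make_pair_datasets(g$ea_x, g$oa_x, g$ea_y, g$oa_y)
    h <- harmonize(d$exposure, d$outcome)
    expected <- oracle_classify(g$ea_x, g$oa_x, g$ea_y, g$oa_y)
    label <- paste(g$ea_x, g$oa_x, "vs", g$ea_y, g$oa_y)
    if (expected == "palindromic") {
      expect_equal(h$removed$reason, "palindromic", label = label)
    } else if (expected == "mismatch") {
      expect_equal(h$removed$reason, "allele_mismatch", label = label)
    } else if (expected %in% c("keep", "keep_flip")) {
      expect_equal(h$snps$beta_y, 0.2, label = label)
      expect_equal(h$snps$eaf_y, 0.2, label = label)
    } else {
      expect_equal(h$snps$beta_y, -0.2, label = label)
      expect_equal(h$snps$eaf_y, 0.8, label = label)
    }
    # retained + removed always partitions the input
    expect_equal(nrow(h$snps) + nrow(h$removed), 1)
  }
})

test_that("SNPs missing from the outcome are recorded as not_found", {
  d <- make_pair_datasets("A", "G", "A", "G")
  d$exposure$rsid <- "rs_absent"
  h <- harmonize(d$exposure, d$outcome)
  expect_equal(nrow(h$snps), 0)
  expect_equal(h$removed$reason, "not_found")
})

test_that("harmonizing an already-harmonized frame is idempotent", {
  sim <- simulate_pair(sim_config(k_snps = 15, theta = 0.05, h2_exposure = 0.1, seed = 30,
                                  frac_allele_swapped = 0.4))
  iv <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  h1 <- harmonize(iv, sim$outcome)
  # rebuild an outcome dataset from the harmonized records (now in the
  # exposure frame) and harmonize again: nothing should change
  out2 <- summary_dataset(data.frame(
    rsid = h1$snps$rsid, chrom = h1$snps$chrom, pos = h1$snps$pos,
    effect_allele = h1$snps$effect_allele, other_allele = h1$snps$other_allele,
    beta = h1$snps$beta_y, se = h1$snps$se_y, pval = h1$snps$pval_y,
    eaf = h1$snps$eaf_y, n = h1$snps$n_y, stringsAsFactors = FALSE),
    "oc2", "outcome")
  h2 <- harmonize(iv$snps[iv$snps$rsid %in% h1$snps$rsid, ], out2)
  expect_equal(h2$snps$beta_y, h1$snps$beta_y)
  expect_equal(h2$snps$eaf_y, h1$snps$eaf_y)
  expect_equal(nrow(h2$removed), 0)
})

test_that("IVW after harmonization is invariant to pre-flipping outcome records", {
  sim <- simulate_pair(sim_config(k_snps = 12, theta = 0.05, h2_exposure = 0.1, seed = 31))
  iv <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  h_ref <- harmonize(iv, sim$outcome)
  beta_ref <- mr_ivw(h_ref)$beta

  flipped <- sim$outcome
  i <- c(2, 5, 9)
  tmp <- flipped$records$effect_allele[i]
  flipped$records$effect_allele[i] <- flipped$records$other_allele[i]
  flipped$records$other_allele[i] <- tmp
  flipped$records$beta[i] <- -flipped$records$beta[i]
  flipped$records$eaf[i] <- 1 - flipped$records$eaf[i]
  h_flip <- harmonize(iv, flipped)
  expect_equal(mr_ivw(h_flip)$beta, beta_ref, tolerance = 1e-12)
})

test_that("palindromic instruments are removed unconditionally", {
  sim <- simulate_pair(sim_config(k_snps = 10, seed = 32,
                                  frac_palindromic = 1))
  iv <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  h <- harmonize(iv, sim$outcome)
  expect_equal(nrow(h$snps), 0)
  expect_true(all(h$removed$reason == "palindromic"))
})
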
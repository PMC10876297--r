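# Shared fixture builders. Everything is generated in code; no stored data.

# A small deterministic harmonized set with heterogeneous weights.
fixture_harmonized <- function(k = 10, theta = 0.2, seed = 101,
                               noise = 0.05) {
  set.seed(seed)
  beta_x <- runif(k, 0.1, 0.5) * sample(c(-1, 1), k, replace = TRUE)
  se_x <- runif(k, 0.01, 0.03)
  se_y <- runif(k, 0.02, 0.1)
  beta_y <- theta * beta_x + rnorm(k, 0, noise)
  harmonized_set(beta_x, se_x, beta_y, se_y)
}

# Simulate a pair and assemble the harmonized truth-frame set directly from
# the matched records (bypasses selection; requires no palindromes/swaps).
sim_harmonized <- function(cfg) {
  sim <- simulate_pair(cfg)
  ex <- sim$exposure$records
  inst <- sim$truth$snps$rsid[sim$truth$snps$is_instrument]
  ex <- ex[ex$rsid %in% inst, ]
  oy <- sim$outcome$records[match(ex$rsid, sim$outcome$records$rsid), ]
  harmonized_set(ex$beta, ex$se, oy$beta, oy$se, rsid = ex$rsid,
                 eaf_x = ex$eaf, eaf_y = oy$eaf, n_x = ex$n, n_y = oy$n)
}

# Write a summary dataset fixture to a temp TSV and return the path.
write_fixture_tsv <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

fixture_records <- function() {
  data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    chrom = c("1", "2", "2"),
    pos = c(1000L, 2000L, 900000L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    beta = c(0.12, -0.08, 0.25),
    se = c(0.02, 0.03, 0.04),
    pval = c(2e-9, 7.7e-3, 4e-10),
    eaf = c(0.3, 0.45, 0.12),
    n = c(7824L, 7824L, 7824L),
    stringsAsFactors = FALSE
  )
}

# Independent greedy-clumping oracle: straightforward re-statement of the
# rule with no shared code (sorts once, filters with explicit loops).
clump_oracle <- function(snps, ld, r2_max = 0.1, window_kb = 500) {
  ord <- order(snps$pval, suppressWarnings(as.numeric(snps$chrom)),
               snps$pos, snps$rsid)
  df <- snps[ord, ]
  chosen <- df[0, ]
  removed <- character(0)
  while (nrow(df) > 0) {
    best <- df[1, ]
    chosen <- rbind(chosen, best)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    drop <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(nrow(chosen))) {
        if (df$chrom[i] == chosen$chrom[j] &&
            abs(df$pos[i] - chosen$pos[j]) <= window_kb * 1000 &&
            ld_r2(ld, df$rsid[i], chosen$rsid[j]) >= r2_max) {
          drop[i] <- TRUE
        }
      }
    }
    df <- df[!drop, , drop = FALSE]
  }
  sort(chosen$rsid)
}
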
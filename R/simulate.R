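# Synthetic two-sample GWAS summary-statistic generator with known ground
# truth, emulating a metabolite-exposure / disease-outcome pair: per-SNP
# effects, standard errors, allele frequencies and p-values consistent with
# the stated sample sizes, plus optional pleiotropy, weak instruments,
# LD-proxy clusters, palindromic and allele-swapped records.

#' Simulation configuration
#'
#' Defaults emulate a well-instrumented blood metabolite measured in a
#' metabolomics GWAS of 7,824 individuals against a large biobank
#' case-control outcome GWAS of 372,373 individuals: 50 independent
#' instruments jointly explaining 30% of exposure variance, giving mean
#' per-SNP F around 47 — comfortably past the conventional F >= 10 cut and
#' consistent with instruments reaching p < 1e-5 at that sample size.
#'
#' @param k_snps number of true instruments (>= 1).
#' @param n_exposure exposure GWAS sample size.
#' @param n_outcome outcome GWAS sample size.
#' @param theta true causal effect of the exposure on the outcome
#'   (log-odds per exposure SD).
#' @param h2_exposure total exposure variance explained by the instruments,
#'   in (0, 1).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects centred on
#'   0), `"directional"` (centred on `pleiotropy_mean` in the
#'   exposure-raising allele frame), or `"inside_violated"` (direct effects
#'   proportional to instrument strength, violating the InSIDE assumption).
#' @param pleiotropy_mean mean direct effect for the directional /
#'   inside-violated modes.
#' @param pleiotropy_sd standard deviation of direct effects.
#' @param frac_invalid fraction of instruments given a direct effect.
#' @param frac_palindromic fraction of instruments written as A/T or C/G
#'   pairs.
#' @param frac_allele_swapped fraction of instruments whose outcome record
#'   lists the alleles in the opposite order (with effect sign and EAF
#'   rewritten consistently, so harmonization can recover them).
#' @param ld_proxies_per_snp LD proxies generated per instrument.
#' @param proxy_r2 target r-squared between a proxy and its parent.
#' @param null_snp_count background SNPs with zero true effect.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(k_snps = 50, n_exposure = 7824, n_outcome = 372373,
                       theta = 0, h2_exposure = 0.3,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violated"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       frac_invalid = 0, frac_palindromic = 0,
                       frac_allele_swapped = 0,
                       ld_proxies_per_snp = 0, proxy_r2 = 0.5,
                       null_snp_count = 0, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(k_snps >= 1, h2_exposure > 0, h2_exposure < 1,
            frac_invalid >= 0, frac_invalid <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_allele_swapped >= 0, frac_allele_swapped <= 1,
            proxy_r2 >= 0, proxy_r2 < 1, pleiotropy_sd >= 0)
  cfg <- list(k_snps = as.integer(k_snps), n_exposure = as.integer(n_exposure),
              n_outcome = as.integer(n_outcome), theta = theta,
              h2_exposure = h2_exposure, pleiotropy_mode = pleiotropy_mode,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              frac_invalid = frac_invalid,
              frac_palindromic = frac_palindromic,
              frac_allele_swapped = frac_allele_swapped,
              ld_proxies_per_snp = as.integer(ld_proxies_per_snp),
              proxy_r2 = proxy_r2, null_snp_count = as.integer(null_snp_count),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T")
)
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a matched exposure/outcome summary-statistic pair
#'
#' For instrument `j` with minor-allele frequency `m_j ~ U(0.05, 0.5)`, the
#' true per-allele effect `gamma_j` carries a random sign and a magnitude
#' scaled so the instruments jointly explain `h2_exposure` of the exposure
#' variance (per-SNP contributions vary by a uniform factor). Observed
#' summary effects are drawn as `beta_x ~ N(gamma, se_x^2)` with
#' `se_x = 1/sqrt(2 m (1-m) n_exposure)`, and
#' `beta_y ~ N(theta * gamma + alpha, se_y^2)` analogously at the outcome
#' sample size; p-values are the two-sided normal tails of `beta/se`. Each
#' LD proxy duplicates its parent's signal attenuated by `sqrt(proxy_r2)`,
#' placed within 500 kb, and is recorded in the emitted LD table (with
#' within-cluster proxy-proxy r-squared `proxy_r2^2`). Background null SNPs
#' have `gamma = 0`.
#'
#' @param config a [sim_config()].
#' @return list with `exposure` and `outcome` (`summary_dataset`s), `ld`
#'   (`ld_table`), and `truth` — a list with `theta` and a per-SNP
#'   data.frame (`rsid`, `gamma`, `alpha`, `valid`, `is_instrument`,
#'   `palindromic`, `swapped`, `proxy_parent`, `true_r2`).
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_pair_impl(config))
}

simulate_pair_impl <- function(cfg) {
  k <- cfg$k_snps
  per_snp_h2_max <- cfg$h2_exposure / k * 1.5
  if (per_snp_h2_max >= 1) stop("infeasible h2_exposure for k_snps", call. = FALSE)

  maf <- stats::runif(k, 0.05, 0.5)
  contrib <- stats::runif(k, 0.5, 1.5)
  v <- contrib / sum(contrib) * cfg$h2_exposure   # per-SNP variance explained
  gamma <- sample(c(-1, 1), k, replace = TRUE) * sqrt(v / (2 * maf * (1 - maf)))

  alpha <- numeric(k)
  invalid <- rep(FALSE, k)
  n_invalid <- round(cfg$frac_invalid * k)
  if (cfg$pleiotropy_mode != "none" && n_invalid > 0) {
    invalid[sample.int(k, n_invalid)] <- TRUE
    # directional effects are defined in the exposure-raising allele frame
    # (sign(gamma)); otherwise random instrument signs would cancel the
    # planted direction out of the IVW bias and the Egger intercept
    alpha[invalid] <- switch(
      cfg$pleiotropy_mode,
      balanced = stats::rnorm(n_invalid, 0, cfg$pleiotropy_sd),
      directional = sign(gamma[invalid]) *
        stats::rnorm(n_invalid, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      inside_violated = sign(gamma[invalid]) *
        (cfg$pleiotropy_mean * abs(gamma[invalid]) / mean(abs(gamma)) +
           stats::rnorm(n_invalid, 0, cfg$pleiotropy_sd))
    )
  }

  chrom <- as.character((seq_len(k) - 1L) %% 22L + 1L)
  pos <- 1e6 + ((seq_len(k) - 1L) %/% 22L) * 5e6
  rsid <- paste0("rs", seq_len(k))

  pal <- rep(FALSE, k)
  n_pal <- round(cfg$frac_palindromic * k)
  if (n_pal > 0) pal[sample.int(k, n_pal)] <- TRUE
  pair_idx <- sample.int(nrow(NON_PALINDROMIC_PAIRS), k, replace = TRUE)
  ea <- NON_PALINDROMIC_PAIRS[pair_idx, 1]
  oa <- NON_PALINDROMIC_PAIRS[pair_idx, 2]
  if (any(pal)) {
    pidx <- sample.int(nrow(PALINDROMIC_PAIRS), sum(pal), replace = TRUE)
    ea[pal] <- PALINDROMIC_PAIRS[pidx, 1]
    oa[pal] <- PALINDROMIC_PAIRS[pidx, 2]
  }
  swapped <- rep(FALSE, k)
  n_swap <- round(cfg$frac_allele_swapped * k)
  if (n_swap > 0) swapped[sample.int(k, n_swap)] <- TRUE

  build <- function(rsid, chrom, pos, ea, oa, true_beta, maf, n) {
    se <- 1 / sqrt(2 * maf * (1 - maf) * n)
    beta <- stats::rnorm(length(true_beta), true_beta, se)
    data.frame(rsid = rsid, chrom = chrom, pos = as.integer(pos),
               effect_allele = ea, other_allele = oa,
               beta = beta, se = se, pval = z_pval(beta, se),
               eaf = maf, n = as.integer(n), stringsAsFactors = FALSE)
  }

  exp_rows <- build(rsid, chrom, pos, ea, oa, gamma, maf, cfg$n_exposure)
  out_rows <- build(rsid, chrom, pos, ea, oa, cfg$theta * gamma + alpha, maf,
                    cfg$n_outcome)

  truth <- data.frame(
    rsid = rsid, gamma = gamma, alpha = alpha, valid = !invalid,
    is_instrument = TRUE, palindromic = pal, swapped = swapped,
    proxy_parent = NA_character_, true_r2 = 1, stringsAsFactors = FALSE
  )
  ld_pairs <- NULL

  if (cfg$ld_proxies_per_snp > 0) {
    r <- sqrt(cfg$proxy_r2)
    prx <- list()
    for (j in seq_len(k)) {
      for (q in seq_len(cfg$ld_proxies_per_snp)) {
        prx_id <- paste0(rsid[j], "_p", q)
        prx_pos <- pos[j] + q * 50000L
        # marginal effect of a correlated variant at equal MAF
        g_m <- r * gamma[j]
        e <- build(prx_id, chrom[j], prx_pos, ea[j], oa[j], g_m, maf[j],
                   cfg$n_exposure)
        o <- build(prx_id, chrom[j], prx_pos,  ea[j], oa[j],
                   cfg$theta * g_m + r * alpha[j], maf[j], cfg$n_outcome)
        prx[[length(prx) + 1L]] <- list(e = e, o = o, parent = rsid[j], q = q)
        ld_pairs <- rbind(ld_pairs,
                          data.frame(rsid_a = rsid[j], rsid_b = prx_id,
                                     r2 = cfg$proxy_r2,
                                     stringsAsFactors = FALSE))
      }
      if (cfg$ld_proxies_per_snp > 1) {
        ids <- paste0(rsid[j], "_p", seq_len(cfg$ld_proxies_per_snp))
        cmb <- utils::combn(ids, 2)
        ld_pairs <- rbind(ld_pairs,
                          data.frame(rsid_a = cmb[1, ], rsid_b = cmb[2, ],
                                     r2 = cfg$proxy_r2^2,
                                     stringsAsFactors = FALSE))
      }
    }
    exp_rows <- rbind(exp_rows, do.call(rbind, lapply(prx, `[[`, "e")))
    out_rows <- rbind(out_rows, do.call(rbind, lapply(prx, `[[`, "o")))
    truth <- rbind(truth, do.call(rbind, lapply(prx, function(p) {
      data.frame(rsid = p$e$rsid, gamma = r * gamma[match(p$parent, rsid)],
                 alpha = r * alpha[match(p$parent, rsid)],
                 valid = !invalid[match(p$parent, rsid)],
                 is_instrument = FALSE, palindromic = FALSE, swapped = FALSE,
                 proxy_parent = p$parent, true_r2 = cfg$proxy_r2,
                 stringsAsFactors = FALSE)
    })))
  }

  if (cfg$null_snp_count > 0) {
    m0 <- stats::runif(cfg$null_snp_count, 0.05, 0.5)
    id0 <- paste0("rsnull", seq_len(cfg$null_snp_count))
    chrom0 <- as.character((seq_len(cfg$null_snp_count) - 1L) %% 22L + 1L)
    pos0 <- 2e8 + ((seq_len(cfg$null_snp_count) - 1L) %/% 22L) * 5e6
    pi0 <- sample.int(nrow(NON_PALINDROMIC_PAIRS), cfg$null_snp_count,
                      replace = TRUE)
    exp_rows <- rbind(exp_rows,
                      build(id0, chrom0, pos0, NON_PALINDROMIC_PAIRS[pi0, 1],
                            NON_PALINDROMIC_PAIRS[pi0, 2],
                            rep(0, cfg$null_snp_count), m0, cfg$n_exposure))
    out_rows <- rbind(out_rows,
                      build(id0, chrom0, pos0, NON_PALINDROMIC_PAIRS[pi0, 1],
                            NON_PALINDROMIC_PAIRS[pi0, 2],
                            rep(0, cfg$null_snp_count), m0, cfg$n_outcome))
    truth <- rbind(truth, data.frame(
      rsid = id0, gamma = 0, alpha = 0, valid = TRUE, is_instrument = FALSE,
      palindromic = FALSE, swapped = FALSE, proxy_parent = NA_character_,
      true_r2 = 0, stringsAsFactors = FALSE))
  }

  # allele-swapped outcome records: same association re-expressed on the
  # other allele, so a correct harmonizer recovers the original frame
  sw <- truth$swapped[match(out_rows$rsid, truth$rsid)]
  sw[is.na(sw)] <- FALSE
  if (any(sw)) {
    tmp <- out_rows$effect_allele[sw]
    out_rows$effect_allele[sw] <- out_rows$other_allele[sw]
    out_rows$other_allele[sw] <- tmp
    out_rows$beta[sw] <- -out_rows$beta[sw]
    out_rows$eaf[sw] <- 1 - out_rows$eaf[sw]
  }

  list(
    exposure = summary_dataset(exp_rows, trait_id = "sim_exposure",
                               trait_type = "exposure",
                               default_n = cfg$n_exposure),
    outcome = summary_dataset(out_rows, trait_id = "sim_outcome",
                              trait_type = "outcome",
                              default_n = cfg$n_outcome),
    ld = ld_table(ld_pairs),
    truth = list(theta = cfg$theta, snps = truth, config = cfg)
  )
}

#' Simulate directly to a harmonized set
#'
#' Convenience wrapper for estimator studies: simulates a pair with
#' [simulate_pair()] and assembles the instruments' matched exposure and
#' outcome effects into a `harmonized_set` without running selection or
#' allele harmonization (the generated records are already in a shared
#' frame when no palindromic/swapped alleles are requested).
#'
#' @param config a [sim_config()] with `frac_palindromic = 0` and
#'   `frac_allele_swapped = 0`.
#' @return A `harmonized_set` over the true instruments.
#' @export
simulate_harmonized <- function(config = sim_config()) {
  if (config$frac_palindromic > 0 || config$frac_allele_swapped > 0) {
    stop("simulate_harmonized requires records already in one allele frame",
         call. = FALSE)
  }
  sim <- simulate_pair(config)
  ex <- sim$exposure$records
  inst <- sim$truth$snps$rsid[sim$truth$snps$is_instrument]
  ex <- ex[ex$rsid %in% inst, , drop = FALSE]
  oy <- sim$outcome$records[match(ex$rsid, sim$outcome$records$rsid), ]
  harmonized_set(ex$beta, ex$se, oy$beta, oy$se, rsid = ex$rsid,
                 eaf_x = ex$eaf, eaf_y = oy$eaf, n_x = ex$n, n_y = oy$n,
                 exposure_id = sim$exposure$trait_id,
                 outcome_id = sim$outcome$trait_id)
}

#' Simulate a panel of exposures sharing one outcome
#'
#' Emulates a metabolite-wide screen: `n_exposures` exposure datasets, each
#' with its own instruments (rsids prefixed per exposure so the shared
#' outcome dataset holds them all), of which a `frac_causal` fraction get
#' the base configuration's `theta` and the rest are null. Per-exposure
#' generation uses seeds derived from `seed`, so the panel is reproducible
#' piecewise.
#'
#' @param base a [sim_config()] used for every exposure (its `theta` is the
#'   causal effect given to the causal subset).
#' @param n_exposures number of exposures (>= 1).
#' @param frac_causal fraction of exposures with a true effect.
#' @param seed panel-level RNG seed.
#' @return list with `exposures` (named list of `summary_dataset`),
#'   `outcome` (one combined `summary_dataset`), `ld` (combined
#'   `ld_table`), and `truth` — data.frame of `exposure_id`, `theta`,
#'   `causal`.
#' @export
simulate_metabolite_panel <- function(base = sim_config(), n_exposures = 50,
                                      frac_causal = 0.2, seed = 1L) {
  stopifnot(n_exposures >= 1, frac_causal >= 0, frac_causal <= 1)
  n_causal <- round(frac_causal * n_exposures)
  causal <- with_seed(seed, {
    flags <- rep(FALSE, n_exposures)
    if (n_causal > 0) flags[sample.int(n_exposures, n_causal)] <- TRUE
    flags
  })
  exposures <- list()
  outcome_rows <- list()
  ld_all <- list()
  for (i in seq_len(n_exposures)) {
    cfg_i <- base
    cfg_i$theta <- if (causal[i]) base$theta else 0
    cfg_i$seed <- seed + 1000L * i
    sim <- simulate_pair(cfg_i)
    id <- sprintf("metab_%03d", i)
    ex <- sim$exposure
    prefix <- function(x) paste0("e", i, "_", x)
    ex$records$rsid <- prefix(ex$records$rsid)
    ex$trait_id <- id
    exposures[[id]] <- ex
    orec <- sim$outcome$records
    orec$rsid <- prefix(orec$rsid)
    outcome_rows[[i]] <- orec
    keys <- ls(sim$ld$env)
    if (length(keys) > 0) {
      parts <- strsplit(keys, "\r", fixed = TRUE)
      ld_all[[i]] <- data.frame(
        rsid_a = prefix(vapply(parts, `[`, "", 1)),
        rsid_b = prefix(vapply(parts, `[`, "", 2)),
        r2 = vapply(keys, function(k) sim$ld$env[[k]], 0),
        stringsAsFactors = FALSE)
    }
  }
  outcome <- summary_dataset(do.call(rbind, outcome_rows),
                             trait_id = "sim_outcome", trait_type = "outcome",
                             default_n = base$n_outcome)
  ld <- if (length(ld_all) > 0) ld_table(do.call(rbind, ld_all)) else ld_table()
  truth <- data.frame(exposure_id = names(exposures),
                      theta = ifelse(causal, base$theta, 0),
                      causal = causal, stringsAsFactors = FALSE)
  list(exposures = exposures, outcome = outcome, ld = ld, truth = truth)
}
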
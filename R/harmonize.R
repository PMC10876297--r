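# Allele harmonization: express outcome effects per copy of the exposure's
# effect allele, resolving swaps and strand flips, removing palindromic and
# irreconcilable SNPs.

#' Harmonization policy
#'
#' @param drop_palindromic remove A/T and C/G SNPs unconditionally
#'   (default `TRUE`; allele frequency is never used to rescue them).
#' @param allow_strand_flip resolve non-palindromic reverse-complement
#'   matches silently instead of removing them (default `TRUE`).
#' @return list of policy flags.
#' @export
harmonize_policy <- function(drop_palindromic = TRUE, allow_strand_flip = TRUE) {
  list(drop_palindromic = drop_palindromic,
       allow_strand_flip = allow_strand_flip)
}

# Classify one exposure/outcome allele configuration.
# Returns list(action, flip): action in {keep, swap, drop_palindromic,
# drop_mismatch}; flip TRUE when resolution went through the opposite strand.
classify_alleles <- function(ea_x, oa_x, ea_y, oa_y, policy) {
  if (is_palindromic(ea_x, oa_x)) {
    if (policy$drop_palindromic) {
      return(list(action = "drop_palindromic", flip = FALSE))
    }
    # with palindrome dropping disabled, same-letters orientation is taken
    # at face value (strand is unknowable from alleles alone)
    if (ea_y == ea_x && oa_y == oa_x) return(list(action = "keep", flip = FALSE))
    if (ea_y == oa_x && oa_y == ea_x) return(list(action = "swap", flip = FALSE))
    return(list(action = "drop_mismatch", flip = FALSE))
  }
  if (ea_y == ea_x && oa_y == oa_x) return(list(action = "keep", flip = FALSE))
  if (ea_y == oa_x && oa_y == ea_x) return(list(action = "swap", flip = FALSE))
  if (policy$allow_strand_flip) {
    fe <- complement_allele(ea_y); fo <- complement_allele(oa_y)
    if (fe == ea_x && fo == oa_x) return(list(action = "keep", flip = TRUE))
    if (fe == oa_x && fo == ea_x) return(list(action = "swap", flip = TRUE))
  }
  list(action = "drop_mismatch", flip = FALSE)
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each instrument's outcome association to the exposure's
#' effect-allele frame: identical orientation is kept as-is; swapped alleles
#' negate the outcome beta and complement its EAF; strand-flipped records
#' (reverse-complement alleles, possibly also swapped) are mapped to those
#' two cases; palindromic (A/T, C/G) SNPs are removed, as are SNPs whose
#' allele sets cannot be reconciled or that are absent from the outcome.
#'
#' @param instruments an `instrument_set` (or a data.frame of exposure SNP
#'   records).
#' @param outcome outcome `summary_dataset`.
#' @param policy list from [harmonize_policy()].
#' @return A `harmonized_set`: data.frame `snps` with `rsid`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `r2_snp`, `f_snp` (when
#'   available), plus a `removed` data.frame of `(rsid, reason)` with reason
#'   in `palindromic`, `allele_mismatch`, `not_found`.
#' @export
harmonize <- function(instruments, outcome, policy = harmonize_policy()) {
  snps <- if (inherits(instruments, "instrument_set")) instruments$snps else instruments
  exposure_id <- if (inherits(instruments, "instrument_set")) {
    instruments$exposure_id
  } else "exposure"
  stopifnot(inherits(outcome, "summary_dataset"))
  idx <- match(snps$rsid, outcome$records$rsid)
  keep_rows <- list(); removed <- list()
  for (i in seq_len(nrow(snps))) {
    if (is.na(idx[i])) {
      removed[[length(removed) + 1L]] <- c(snps$rsid[i], "not_found")
      next
    }
    o <- outcome$records[idx[i], ]
    cls <- classify_alleles(snps$effect_allele[i], snps$other_allele[i],
                            o$effect_allele, o$other_allele, policy)
    if (cls$action == "drop_palindromic") {
      removed[[length(removed) + 1L]] <- c(snps$rsid[i], "palindromic")
      next
    }
    if (cls$action == "drop_mismatch") {
      removed[[length(removed) + 1L]] <- c(snps$rsid[i], "allele_mismatch")
      next
    }
    beta_y <- o$beta; eaf_y <- o$eaf
    if (cls$action == "swap") {
      beta_y <- -beta_y
      eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
    }
    keep_rows[[length(keep_rows) + 1L]] <- data.frame(
      rsid = snps$rsid[i], chrom = snps$chrom[i], pos = snps$pos[i],
      effect_allele = snps$effect_allele[i], other_allele = snps$other_allele[i],
      beta_x = snps$beta[i], se_x = snps$se[i], pval_x = snps$pval[i],
      eaf_x = snps$eaf[i], n_x = snps$n[i],
      beta_y = beta_y, se_y = o$se, pval_y = o$pval,
      eaf_y = eaf_y, n_y = o$n,
      r2_snp = if ("r2_snp" %in% names(snps)) snps$r2_snp[i] else NA_real_,
      f_snp = if ("f_snp" %in% names(snps)) snps$f_snp[i] else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  kept <- if (length(keep_rows) > 0) do.call(rbind, keep_rows) else
    data.frame(rsid = character(0), chrom = character(0), pos = integer(0),
               effect_allele = character(0), other_allele = character(0),
               beta_x = numeric(0), se_x = numeric(0), pval_x = numeric(0),
               eaf_x = numeric(0), n_x = integer(0), beta_y = numeric(0),
               se_y = numeric(0), pval_y = numeric(0), eaf_y = numeric(0),
               n_y = integer(0), r2_snp = numeric(0), f_snp = numeric(0),
               stringsAsFactors = FALSE)
  rem <- if (length(removed) > 0) {
    m <- do.call(rbind, removed)
    data.frame(rsid = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(rsid = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome$trait_id,
         snps = kept, removed = rem),
    class = "harmonized_set"
  )
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for estimator inputs that are already expressed
#' in a shared effect-allele frame (e.g. simulation truth or unit-test
#' fixtures).
#'
#' @param beta_x,se_x exposure effects and standard errors.
#' @param beta_y,se_y outcome effects and standard errors.
#' @param rsid optional identifiers (default `snp1..snpk`).
#' @param eaf_x,eaf_y optional effect-allele frequencies.
#' @param n_x,n_y optional per-SNP sample sizes.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y, rsid = NULL,
                           eaf_x = NA_real_, eaf_y = NA_real_,
                           n_x = NA_integer_, n_y = NA_integer_,
                           exposure_id = "exposure", outcome_id = "outcome") {
  k <- length(beta_x)
  stopifnot(length(se_x) == k, length(beta_y) == k, length(se_y) == k,
            all(se_x > 0), all(se_y > 0))
  if (is.null(rsid)) rsid <- paste0("snp", seq_len(k))
  snps <- data.frame(
    rsid = rsid, chrom = NA_character_, pos = NA_integer_,
    effect_allele = NA_character_, other_allele = NA_character_,
    beta_x = beta_x, se_x = se_x, pval_x = z_pval(beta_x, se_x),
    eaf_x = rep_len(eaf_x, k), n_x = rep_len(as.integer(n_x), k),
    beta_y = beta_y, se_y = se_y, pval_y = z_pval(beta_y, se_y),
    eaf_y = rep_len(eaf_y, k), n_y = rep_len(as.integer(n_y), k),
    r2_snp = NA_real_, f_snp = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         snps = snps,
         removed = data.frame(rsid = character(0), reason = character(0),
                              stringsAsFactors = FALSE)),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d SNPs retained, %d removed\n",
              x$exposure_id, x$outcome_id, nrow(x$snps), nrow(x$removed)))
  invisible(x)
}
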
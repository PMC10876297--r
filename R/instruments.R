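# Instrumental-variable selection: p-value thresholding, greedy LD clumping,
# per-SNP variance explained and F statistics, weak-instrument and
# outcome-association exclusion.

#' Selection parameters
#'
#' @param exposure_p_threshold retain exposure SNPs with `pval` strictly
#'   below this (default `1e-5`).
#' @param outcome_p_threshold drop instruments whose outcome `pval` is
#'   strictly below this (default `1e-5`).
#' @param clump_r2 maximum pairwise LD r-squared among retained instruments
#'   within the clump window (default `0.1`).
#' @param clump_kb clump window radius in kilobases (default `500`;
#'   inclusive on both ends).
#' @param f_min minimum per-SNP F statistic (default `10`).
#' @param min_snps minimum instruments for an exposure to be analyzable
#'   (default `3`).
#' @return list of selection parameters.
#' @export
selection_params <- function(exposure_p_threshold = 1e-5,
                             outcome_p_threshold = 1e-5,
                             clump_r2 = 0.1, clump_kb = 500,
                             f_min = 10, min_snps = 3) {
  list(exposure_p_threshold = exposure_p_threshold,
       outcome_p_threshold = outcome_p_threshold,
       clump_r2 = clump_r2, clump_kb = clump_kb,
       f_min = f_min, min_snps = min_snps)
}

#' Filter SNP records by association p-value
#'
#' Strict inequality: a SNP with `pval` exactly at the threshold is excluded.
#'
#' @param ds a `summary_dataset` (or its `records` data.frame).
#' @param threshold p-value threshold in (0, 1].
#' @return data.frame of retained records, input order preserved.
#' @export
filter_by_pvalue <- function(ds, threshold = 1e-5) {
  stopifnot(threshold > 0, threshold <= 1)
  df <- if (inherits(ds, "summary_dataset")) ds$records else ds
  df[df$pval < threshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties: smaller chromosome, then
#' position, then rsid — deterministic regardless of input order), accepts
#' the best SNP, removes every not-yet-accepted SNP on the same chromosome
#' within the window whose r-squared with an accepted SNP is at or above
#' `r2_max`, and repeats. Missing LD pairs count as r-squared 0, so SNPs
#' outside the window or without a recorded pair are always kept.
#'
#' @param snps data.frame of SNP records for one exposure.
#' @param ld an `ld_table` (may be empty).
#' @param r2_max LD threshold (default 0.1); removal uses `r2 >= r2_max`.
#' @param window_kb window radius in kb (default 500), inclusive.
#' @return data.frame of retained records, ordered by ascending p-value.
#' @export
clump <- function(snps, ld = ld_table(), r2_max = 0.1, window_kb = 500) {
  if (nrow(snps) <= 1) return(snps)
  ord <- order(snps$pval, chrom_order(snps$chrom), snps$pos, snps$rsid)
  df <- snps[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(df))
  accepted <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    accepted[i] <- TRUE
    cand <- which(alive & !accepted & df$chrom == df$chrom[i] &
                    abs(df$pos - df$pos[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- ld_r2(ld, df$rsid[cand], df$rsid[i])
      alive[cand[r2 >= r2_max]] <- FALSE
    }
  }
  out <- df[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP variance explained
#'
#' The proportion of exposure variance explained by one SNP:
#' \deqn{R^2 = \frac{2\beta^2 \cdot EAF(1-EAF)}
#'   {2\beta^2 \cdot EAF(1-EAF) + 2\,se(\beta)^2 N \cdot EAF(1-EAF)}}
#' The EAF factor cancels algebraically, so the value equals
#' \eqn{\beta^2/(\beta^2 + se^2 N)}; when `eaf` is missing the simplified
#' form is used directly (identical value, flagged via the `eaf_fallback`
#' attribute when any input lacked EAF).
#'
#' @param beta per-allele effect size.
#' @param eaf effect-allele frequency in (0,1), or `NA`.
#' @param se standard error of `beta` (> 0).
#' @param n sample size (> 0).
#' @return R-squared values in `[0, 1)`. Vectorized.
#' @export
variance_explained <- function(beta, eaf, se, n) {
  stopifnot(all(se > 0), all(n > 0))
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) {
    stop("eaf must lie strictly in (0,1) where present", call. = FALSE)
  }
  k <- pmax(length(beta), length(eaf), length(se), length(n))
  beta <- rep_len(beta, k); eaf <- rep_len(eaf, k)
  se <- rep_len(se, k); n <- rep_len(n, k)
  out <- numeric(k)
  has_eaf <- !is.na(eaf)
  if (any(has_eaf)) {
    num <- 2 * beta[has_eaf]^2 * eaf[has_eaf] * (1 - eaf[has_eaf])
    den <- num + 2 * se[has_eaf]^2 * n[has_eaf] * eaf[has_eaf] * (1 - eaf[has_eaf])
    out[has_eaf] <- num / den
  }
  if (any(!has_eaf)) {
    z2 <- (beta[!has_eaf] / se[!has_eaf])^2
    out[!has_eaf] <- z2 / (z2 + n[!has_eaf])
  }
  if (any(!has_eaf)) attr(out, "eaf_fallback") <- sum(!has_eaf)
  out
}

#' Instrument-strength F statistic
#'
#' \deqn{F = \frac{N - k - 1}{k} \cdot \frac{R^2}{1 - R^2}}
#' Per-SNP screening uses `k = 1`; passing the retained instrument count
#' gives the whole-instrument F.
#'
#' @param r2 variance explained, in `[0, 1)`.
#' @param n sample size; must exceed `k + 1`.
#' @param k number of SNPs (default 1).
#' @return F statistic (>= 0). Vectorized over `r2`.
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  if (any(n <= k + 1)) stop("need n > k + 1", call. = FALSE)
  (n - k - 1) / k * r2 / (1 - r2)
}

#' Drop instruments associated with the outcome
#'
#' Removes SNPs whose outcome p-value is strictly below `threshold`
#' (instrument must not act on the outcome directly), and SNPs absent from
#' the outcome dataset (they could never be harmonized). The two removal
#' classes are counted separately in the returned attributes.
#'
#' @param snps data.frame of instrument records.
#' @param outcome outcome `summary_dataset`.
#' @param threshold outcome p-value threshold (default `1e-5`).
#' @return retained records; attributes `n_outcome_associated` and
#'   `n_not_in_outcome` hold the removal counts.
#' @export
exclude_outcome_associated <- function(snps, outcome, threshold = 1e-5) {
  idx <- match(snps$rsid, outcome$records$rsid)
  absent <- is.na(idx)
  assoc <- !absent & outcome$records$pval[idx] < threshold
  out <- snps[!absent & !assoc, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_outcome_associated") <- sum(assoc)
  attr(out, "n_not_in_outcome") <- sum(absent)
  out
}

#' Select instrumental variables for one exposure
#'
#' Applies, in order: exposure p-value filter, greedy LD clumping, per-SNP
#' variance explained and F statistic with removal of weak instruments
#' (F below `f_min`), and outcome-association exclusion. The exposure is
#' flagged analyzable only if at least `min_snps` instruments survive.
#'
#' @param exposure exposure `summary_dataset`.
#' @param outcome outcome `summary_dataset`.
#' @param ld `ld_table` for clumping (default empty: all pairs r2 = 0).
#' @param params list from [selection_params()].
#' @return An `instrument_set`: retained SNP records with `r2_snp` and
#'   `f_snp` columns, an `analyzable` flag, and a stage-by-stage `audit` of
#'   removal counts.
#' @export
select_instruments <- function(exposure, outcome, ld = ld_table(),
                               params = selection_params()) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  n0 <- nrow(exposure$records)
  sig <- filter_by_pvalue(exposure, params$exposure_p_threshold)
  n_p <- nrow(sig)
  kept <- clump(sig, ld, r2_max = params$clump_r2, window_kb = params$clump_kb)
  n_clump <- nrow(kept)
  eaf_fallback <- 0L
  if (nrow(kept) > 0) {
    nn <- kept$n
    nn[is.na(nn)] <- exposure$default_n
    if (any(is.na(nn))) {
      stop("sample size required for F statistics: set n or default_n",
           call. = FALSE)
    }
    r2 <- variance_explained(kept$beta, kept$eaf, kept$se, nn)
    eaf_fallback <- attr(r2, "eaf_fallback") %||% 0L
    f <- f_statistic(as.numeric(r2), nn, k = 1)
    kept$r2_snp <- as.numeric(r2)
    kept$f_snp <- f
    kept <- kept[kept$f_snp >= params$f_min, , drop = FALSE]
  } else {
    kept$r2_snp <- numeric(0)
    kept$f_snp <- numeric(0)
  }
  n_strong <- nrow(kept)
  kept2 <- exclude_outcome_associated(kept, outcome, params$outcome_p_threshold)
  audit <- list(
    n_input = n0,
    p_filter = n0 - n_p,
    clump = n_p - n_clump,
    weak_f = n_clump - n_strong,
    outcome_associated = attr(kept2, "n_outcome_associated"),
    not_in_outcome = attr(kept2, "n_not_in_outcome"),
    eaf_fallback = eaf_fallback,
    n_retained = nrow(kept2)
  )
  attr(kept2, "n_outcome_associated") <- NULL
  attr(kept2, "n_not_in_outcome") <- NULL
  rownames(kept2) <- NULL
  structure(
    list(exposure_id = exposure$trait_id, snps = kept2,
         analyzable = nrow(kept2) >= params$min_snps,
         min_snps = params$min_snps, audit = audit),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments (analyzable: %s)\n",
              x$exposure_id, nrow(x$snps), x$analyzable))
  a <- x$audit
  cat(sprintf("  removed: p-filter %d | clump %d | weak-F %d | outcome-assoc %d | not-in-outcome %d\n",
              a$p_filter, a$clump, a$weak_f, a$outcome_associated, a$not_in_outcome))
  invisible(x)
}
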
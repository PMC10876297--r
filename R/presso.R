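# MR-PRESSO: simulation-based global heterogeneity test, per-SNP outlier
# test, and distortion test with an outlier-corrected IVW estimate.
#
# Residual construction: for each SNP j, the IVW slope is refit on all SNPs
# except j and SNP j's weighted squared residual (beta_y_j - beta_x_j *
# beta_loo_j)^2 / se_y_j^2 is taken; their sum is the observed residual sum
# of squares (RSS). The null distribution is parametric: exposure and
# outcome effects are redrawn from normals centred on (beta_x_j,
# beta_x_j * beta_loo_j) at their reported standard errors and the whole
# RSS computation repeated. All p-values use add-one smoothing, so they are
# strictly positive. Requires a majority of valid instruments (it leans on
# leave-one-out IVW being close to the truth).

# Leave-one-out IVW slopes for columns of matrices Bx (k x S), By, given
# fixed se_y: returns k x S matrix of slopes excluding row j.
loo_slopes <- function(Bx, By, sey) {
  W <- Bx^2 / sey^2
  WR <- Bx * By / sey^2
  sw <- colSums(W)
  swr <- colSums(WR)
  num <- matrix(swr, nrow(Bx), ncol(Bx), byrow = TRUE) - WR
  den <- matrix(sw, nrow(Bx), ncol(Bx), byrow = TRUE) - W
  num / den
}

presso_rss <- function(Bx, By, sey) {
  # per-SNP weighted squared residuals (k x S) and their column sums
  L <- loo_slopes(Bx, By, sey)
  res2 <- (By - Bx * L)^2 / sey^2
  list(res2 = res2, rss = colSums(res2))
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Detects horizontal pleiotropy as excess residual heterogeneity around
#' the leave-one-out IVW fit. The global test compares the observed
#' residual sum of squares to `n_sim` parametric simulations under the
#' no-pleiotropy model; the outlier test compares each SNP's observed
#' residual to its own simulated distribution, Bonferroni-adjusted across
#' instruments; the distortion test measures how much removing the flagged
#' outliers moves the IVW estimate, calibrated against random removals of
#' the same number of SNPs. The outlier-corrected IVW estimate is reported
#' as a separate result and never overwrites the primary estimate.
#'
#' @param h a `harmonized_set` with at least 4 SNPs (the internal
#'   leave-one-out IVW needs 3).
#' @param n_sim number of parametric simulations (default 1000; values
#'   below 100 trigger a configuration warning).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed RNG seed; identical data and seed give bit-identical
#'   results.
#' @return A `presso_result`: `rss_observed`, `global_p`, `per_snp_p`
#'   (raw), `per_snp_p_adj` (Bonferroni), `outliers` (rsid vector),
#'   `corrected` (`mr_estimate` on non-outliers, or `NULL`),
#'   `distortion_p` (or `NULL`), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1L) {
  s <- h$snps
  k <- nrow(s)
  if (k < 4) {
    out <- list(computable = FALSE, reason = "fewer than 4 SNPs",
                n_sim = n_sim, seed = seed)
    class(out) <- "presso_result"
    return(out)
  }
  if (n_sim < 100) {
    warning("n_sim < 100 gives a very coarse empirical null", call. = FALSE)
  }
  bx <- s$beta_x; by <- s$beta_y; sex <- s$se_x; sey <- s$se_y
  obs <- presso_rss(matrix(bx), matrix(by), sey)
  rss_obs <- obs$rss
  res2_obs <- obs$res2[, 1]
  loo_obs <- loo_slopes(matrix(bx), matrix(by), sey)[, 1]
  with_seed(seed, {
    Bx <- matrix(stats::rnorm(k * n_sim, bx, sex), k, n_sim)
    By <- matrix(stats::rnorm(k * n_sim, bx * loo_obs, sey), k, n_sim)
  })
  sim <- presso_rss(Bx, By, sey)
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  per_snp_p <- (1 + rowSums(sim$res2 >= res2_obs)) / (n_sim + 1)
  per_snp_p_adj <- pmin(1, per_snp_p * k)
  outliers <- s$rsid[per_snp_p_adj < outlier_alpha]
  corrected <- NULL
  distortion_p <- NULL
  n_out <- length(outliers)
  if (n_out > 0 && k - n_out >= 2) {
    keep <- !(s$rsid %in% outliers)
    fit <- ivw_core(bx[keep], by[keep], sey[keep])
    corrected <- mr_estimate("presso_corrected", fit$beta, fit$se,
                             z_pval(fit$beta, fit$se), n_snp = sum(keep))
    full <- ivw_core(bx, by, sey)
    d_obs <- abs(fit$beta - full$beta)
    with_seed(seed + 1L, {
      d_sim <- vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(k, n_out)
        f <- ivw_core(bx[-drop_idx], by[-drop_idx], sey[-drop_idx])
        abs(f$beta - full$beta)
      }, 0)
    })
    distortion_p <- (1 + sum(d_sim >= d_obs)) / (n_sim + 1)
  }
  out <- list(computable = TRUE, rss_observed = rss_obs, global_p = global_p,
              per_snp_p = stats::setNames(per_snp_p, s$rsid),
              per_snp_p_adj = stats::setNames(per_snp_p_adj, s$rsid),
              outliers = outliers, corrected = corrected,
              distortion_p = distortion_p, n_sim = n_sim, seed = seed)
  class(out) <- "presso_result"
  out
}

#' @export
print.presso_result <- function(x, ...) {
  if (!isTRUE(x$computable)) {
    cat("<presso_result> not computable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<presso_result> RSS = %.3f, global p = %.4g, %d outlier(s)\n",
              x$rss_observed, x$global_p, length(x$outliers)))
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$corrected)) {
      cat(sprintf("  corrected IVW beta = %.4g (p = %.3g), distortion p = %.4g\n",
                  x$corrected$beta, x$corrected$pval, x$distortion_p))
    }
  }
  invisible(x)
}
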
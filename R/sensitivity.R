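# Heterogeneity, pleiotropy, influence and directionality diagnostics.

#' Cochran Q heterogeneity test
#'
#' Q = sum over SNPs of `w_j (r_j - beta_IVW)^2`, with the same first-order
#' weights the IVW estimator uses (single source of truth: this is exactly
#' the Q that scales the IVW multiplicative random-effects standard error).
#' Under homogeneity Q is chi-square with `k - 1` degrees of freedom. An
#' optional second-order-weight variant is available.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @param second_order use second-order ratio weights (default `FALSE`).
#' @return list with `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(h, second_order = FALSE) {
  s <- h$snps
  k <- nrow(s)
  if (k < 2) stop("Cochran Q needs at least 2 SNPs", call. = FALSE)
  r <- s$beta_y / s$beta_x
  w <- ratio_weights(h, second_order = second_order)
  beta <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta)^2)
  list(q_stat = q, q_df = k - 1L,
       q_p = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept row of [mr_egger()]: its estimate is the average direct
#' (pleiotropic) effect of the instruments on the outcome; a two-sided
#' t-test with `k - 2` degrees of freedom against zero.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(h) {
  eg <- mr_egger(h)
  list(intercept = eg$intercept$beta, se = eg$intercept$se,
       p = eg$intercept$pval)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each SNP in turn and flags rows
#' whose estimate changes sign, or crosses the nominal 0.05 significance
#' boundary, relative to the full-set estimate — the signature of a single
#' SNP driving the result.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param re_mode IVW random-effects mode.
#' @param alpha nominal significance level for the crossing flag
#'   (default 0.05).
#' @return data.frame with one row per omitted SNP: `omitted`, `nsnp`,
#'   `beta`, `se`, `pval`, `sign_flip`, `significance_change`.
#' @export
leave_one_out <- function(h, re_mode = "multiplicative_random", alpha = 0.05) {
  s <- h$snps
  k <- nrow(s)
  if (k < 3) stop("leave-one-out needs at least 3 SNPs", call. = FALSE)
  full <- mr_ivw(h, re_mode = re_mode)
  rows <- lapply(seq_len(k), function(j) {
    fit <- ivw_core(s$beta_x[-j], s$beta_y[-j], s$se_y[-j], re_mode)
    p <- z_pval(fit$beta, fit$se)
    data.frame(omitted = s$rsid[j], nsnp = k - 1L, beta = fit$beta,
               se = fit$se, pval = p,
               sign_flip = sign(fit$beta) != sign(full$beta),
               significance_change = (p < alpha) != (full$pval < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_beta") <- full$beta
  attr(out, "full_pval") <- full$pval
  out
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precision (1 / first-order ratio
#' standard error); asymmetry of the funnel around the summary estimate
#' suggests directional pleiotropy. Reference-line parameters for the IVW
#' and (when computable) Egger estimates are attached as attributes.
#'
#' @param h a `harmonized_set` with at least 1 SNP.
#' @return data.frame with `rsid`, `ratio`, `precision`; attributes
#'   `ivw_beta` and `egger_beta` (NA when not computable).
#' @export
funnel_data <- function(h) {
  s <- h$snps
  if (nrow(s) < 1) stop("funnel data needs at least 1 SNP", call. = FALSE)
  r <- s$beta_y / s$beta_x
  prec <- abs(s$beta_x) / s$se_y
  out <- data.frame(rsid = s$rsid, ratio = r, precision = prec,
                    stringsAsFactors = FALSE)
  ivw_beta <- if (nrow(s) >= 2) mr_ivw(h)$beta else r[1]
  egger_beta <- if (nrow(s) >= 3) {
    tryCatch(mr_egger(h)$slope$beta, error = function(e) NA_real_)
  } else if (nrow(s) == 1) r[1] else NA_real_
  attr(out, "ivw_beta") <- ivw_beta
  attr(out, "egger_beta") <- egger_beta
  out
}

#' Steiger directionality test
#'
#' Compares the total variance the instruments explain in the exposure
#' against the variance they explain in the outcome. If the outcome-side
#' variance explained exceeds the exposure-side, the assumed causal
#' direction (exposure to outcome) may be reversed. The p-value is a
#' two-sided z-test on the difference of Fisher-transformed correlation
#' magnitudes `atanh(sqrt(R2))` using the two sample sizes. An exact tie
#' reports `direction = FALSE` with `p = 1`.
#'
#' @param h a `harmonized_set`.
#' @param n_exposure,n_outcome study sample sizes; default to the per-SNP
#'   medians recorded in `h`.
#' @return list with `direction` (TRUE when exposure-side variance
#'   explained is larger), `p`, `r2_exposure`, `r2_outcome`.
#' @export
steiger <- function(h, n_exposure = NULL, n_outcome = NULL) {
  s <- h$snps
  n_exposure <- n_exposure %||%
    (if (all(is.na(s$n_x))) NULL else stats::median(s$n_x, na.rm = TRUE))
  n_outcome <- n_outcome %||%
    (if (all(is.na(s$n_y))) NULL else stats::median(s$n_y, na.rm = TRUE))
  if (is.null(n_exposure) || is.null(n_outcome)) {
    stop("Steiger test requires exposure and outcome sample sizes",
         call. = FALSE)
  }
  r2_x <- sum(variance_explained(s$beta_x, s$eaf_x, s$se_x, n_exposure))
  r2_y <- sum(variance_explained(s$beta_y, s$eaf_y, s$se_y, n_outcome))
  r2_x <- min(r2_x, 1 - 1e-12)
  r2_y <- min(r2_y, 1 - 1e-12)
  if (r2_x == r2_y) {
    return(list(direction = FALSE, p = 1, r2_exposure = r2_x,
                r2_outcome = r2_y, z = 0))
  }
  z <- (atanh(sqrt(r2_x)) - atanh(sqrt(r2_y))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(direction = r2_x > r2_y, p = max(p, .Machine$double.xmin),
       r2_exposure = r2_x, r2_outcome = r2_y, z = z)
}

#' Full sensitivity battery
#'
#' Runs Cochran Q, the Egger intercept test, leave-one-out, funnel data and
#' the Steiger directionality test, as the instrument count allows.
#'
#' @param h a `harmonized_set`.
#' @param n_exposure,n_outcome sample sizes for the Steiger test (defaults
#'   as in [steiger()]).
#' @return A `sensitivity_report` list with elements `q`, `egger_intercept`,
#'   `loo`, `funnel`, `steiger` (elements `NULL` when not computable).
#' @export
sensitivity_report <- function(h, n_exposure = NULL, n_outcome = NULL) {
  k <- nrow(h$snps)
  rep <- list(
    q = if (k >= 2) cochran_q(h) else NULL,
    egger_intercept = if (k >= 3) {
      tryCatch(egger_intercept_test(h), error = function(e) NULL)
    } else NULL,
    loo = if (k >= 3) leave_one_out(h) else NULL,
    funnel = if (k >= 1) funnel_data(h) else NULL,
    steiger = tryCatch(steiger(h, n_exposure, n_outcome),
                       error = function(e) NULL)
  )
  class(rep) <- "sensitivity_report"
  rep
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran Q = %.3f (df %d), p = %.3g\n",
                x$q$q_stat, x$q$q_df, x$q$q_p))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4g (se %.4g), p = %.3g\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$p))
  }
  if (!is.null(x$steiger)) {
    cat(sprintf("  Steiger: direction %s (R2 exposure %.3g vs outcome %.3g), p = %.3g\n",
                x$steiger$direction, x$steiger$r2_exposure,
                x$steiger$r2_outcome, x$steiger$p))
  }
  invisible(x)
}
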
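# Causal-effect estimators on a harmonized instrument set: Wald ratio, IVW,
# MR-Egger, weighted median, weighted mode, simple mode.
#
# All ratio-based methods use first-order weights (se of the Wald ratio
# approximated by se_y/|beta_x|, ignoring exposure-side noise); a
# second-order option is available where noted.

mr_estimate <- function(method, beta, se, pval, n_snp, df = NA_integer_) {
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
         pval = pval,
         or_point = exp(beta), or_low = exp(beta - Z975 * se),
         or_high = exp(beta + Z975 * se),
         n_snp = n_snp, df = df),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (se %.4g), OR %.4f (95%% CI %.4f-%.4f), p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$or_point, x$or_low, x$or_high,
              x$pval, x$n_snp))
  invisible(x)
}

#' Collect one or more MR estimates into a table
#'
#' @param x an `mr_estimate` or list of them.
#' @param exposure,outcome optional trait labels for the table.
#' @return data.frame with columns `exposure`, `outcome`, `method`, `nsnp`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or`, `or_low`, `or_high`.
#' @export
estimate_table <- function(x, exposure = NA_character_, outcome = NA_character_) {
  if (inherits(x, "mr_estimate")) x <- list(x)
  do.call(rbind, lapply(x, function(e) {
    data.frame(exposure = exposure, outcome = outcome, method = e$method,
               nsnp = e$n_snp, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               or = e$or_point, or_low = e$or_low, or_high = e$or_high,
               stringsAsFactors = FALSE)
  }))
}

#' Wald ratio estimate for a single SNP
#'
#' The per-SNP causal estimate: outcome effect divided by exposure effect,
#' with first-order (delta-method) standard error `|se_y / beta_x|`.
#'
#' @param beta_x,se_x exposure effect and standard error.
#' @param beta_y,se_y outcome effect and standard error.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("Wald ratio undefined for beta_x = 0", call. = FALSE)
  beta <- beta_y / beta_x
  se <- abs(se_y / beta_x)
  mr_estimate("wald", beta, se, z_pval(beta, se), n_snp = 1L)
}

ratio_weights <- function(h, second_order = FALSE) {
  s <- h$snps
  if (second_order) {
    1 / (s$se_y^2 / s$beta_x^2 + s$beta_y^2 * s$se_x^2 / s$beta_x^4)
  } else {
    s$beta_x^2 / s$se_y^2
  }
}

ivw_core <- function(bx, by, sey, re_mode = "multiplicative_random") {
  w <- bx^2 / sey^2
  r <- by / bx
  beta <- sum(w * r) / sum(w)
  k <- length(bx)
  q <- sum(w * (r - beta)^2)
  se_fixed <- sqrt(1 / sum(w))
  se <- if (re_mode == "multiplicative_random" && k >= 2) {
    se_fixed * max(1, sqrt(q / (k - 1)))
  } else se_fixed
  list(beta = beta, se = se, q = q, q_df = k - 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analysis of per-SNP Wald ratios with first-order inverse-variance
#' weights `beta_x^2 / se_y^2`; algebraically identical to zero-intercept
#' weighted least squares of `beta_y` on `beta_x` with weights `1/se_y^2`.
#' The default multiplicative random-effects model scales the fixed-effect
#' standard error by `max(1, sqrt(Q/(k-1)))`, so it is never narrower than
#' the fixed-effect model. Unbiased when no instrument acts on the outcome
#' through a pathway other than the exposure (no horizontal pleiotropy).
#'
#' @param h a `harmonized_set` with at least 2 SNPs (a single SNP falls back
#'   to the Wald ratio, flagged via the method name `"wald"`).
#' @param re_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw"`; attributes `Q` and `Q_df`
#'   carry the heterogeneity statistic reused by [cochran_q()].
#' @export
mr_ivw <- function(h, re_mode = c("multiplicative_random", "fixed")) {
  re_mode <- match.arg(re_mode)
  s <- h$snps
  if (nrow(s) == 0) stop("no SNPs to estimate from", call. = FALSE)
  if (nrow(s) == 1) {
    return(wald_ratio(s$beta_x, s$se_x, s$beta_y, s$se_y))
  }
  fit <- ivw_core(s$beta_x, s$beta_y, s$se_y, re_mode)
  est <- mr_estimate("ivw", fit$beta, fit$se,
                     z_pval(fit$beta, fit$se), n_snp = nrow(s))
  attr(est, "Q") <- fit$q
  attr(est, "Q_df") <- fit$q_df
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_y` on `beta_x` with a free intercept and
#' weights `1/se_y^2`, after orienting all exposure effects non-negative
#' (outcome signs flipped in step). The slope is the causal estimate under
#' the InSIDE assumption (instrument strength independent of direct
#' effects); the intercept estimates average directional pleiotropy and is
#' zero when IVW is unbiased. Standard errors use the regression residual
#' scale bounded below by 1 (never narrower than the fixed-effect model);
#' inference is t with `k - 2` degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with elements `slope` and `intercept`, both `mr_estimate`s
#'   (methods `"egger_slope"`, `"egger_intercept"`).
#' @export
mr_egger <- function(h) {
  s <- h$snps
  k <- nrow(s)
  if (k < 3) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  sgn <- ifelse(s$beta_x < 0, -1, 1)
  bx <- s$beta_x * sgn
  by <- s$beta_y * sgn
  if (stats::sd(bx) == 0) {
    stop("degenerate design: all exposure effects equal; Egger slope and intercept not identified",
         call. = FALSE)
  }
  w <- 1 / s$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  scale_fix <- min(1, sm$sigma)  # residual scale floored at fixed-effect level
  slope_se <- co["bx", "Std. Error"] / scale_fix
  int_se <- co["(Intercept)", "Std. Error"] / scale_fix
  tp <- function(est, se) {
    max(2 * stats::pt(-abs(est / se), df = k - 2), .Machine$double.xmin)
  }
  slope <- mr_estimate("egger_slope", co["bx", "Estimate"], slope_se,
                       tp(co["bx", "Estimate"], slope_se), n_snp = k,
                       df = k - 2L)
  intercept <- mr_estimate("egger_intercept", co["(Intercept)", "Estimate"],
                           int_se, tp(co["(Intercept)", "Estimate"], int_se),
                           n_snp = k, df = k - 2L)
  list(slope = slope, intercept = intercept)
}

weighted_percentile <- function(x, w, prob = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cs <- cumsum(w) - w / 2
  cs <- cs / sum(w)
  if (prob <= cs[1]) return(x[1])
  if (prob >= cs[length(cs)]) return(x[length(x)])
  stats::approx(cs, x, xout = prob, ties = "ordered")$y
}

boot_se <- function(h, point_fun, n_boot, seed) {
  s <- h$snps
  k <- nrow(s)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, s$beta_x, s$se_x)
      by <- stats::rnorm(k, s$beta_y, s$se_y)
      point_fun(bx, by)
    }, 0)
    stats::sd(ests)
  })
}

#' Weighted median estimate
#'
#' The weighted 50th percentile (with linear interpolation between
#' straddling order statistics) of the per-SNP Wald ratios, weighted by
#' first-order inverse variance. Consistent as long as valid instruments
#' contribute more than half the total weight — i.e. robust to up to (but
#' not including) 50% invalid instruments by weight. Standard error from a
#' seeded parametric bootstrap resampling `beta_x` and `beta_y` from
#' normals at their standard errors.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (results are reproducible given a
#'   seed).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  s <- h$snps
  if (nrow(s) < 3) stop("weighted median needs at least 3 SNPs", call. = FALSE)
  point <- function(bx, by) {
    weighted_percentile(by / bx, bx^2 / s$se_y^2, 0.5)
  }
  beta <- point(s$beta_x, s$beta_y)
  se <- boot_se(h, point, n_boot, seed)
  mr_estimate("weighted_median", beta, se, z_pval(beta, se), n_snp = nrow(s))
}

# Mode of the weighted Gaussian-kernel density of ratio estimates.
# Bandwidth: phi x 0.9 x MAD(r) x k^(-1/5) (normal-reference rule on a
# robust scale). Grid = the ratios themselves, refined by golden-section
# search around the best grid point.
mode_point <- function(r, w, phi) {
  k <- length(r)
  s_mad <- stats::mad(r)
  if (s_mad == 0 || k == 1) {
    # degenerate spread: fall back to the weight-plurality value
    return(r[which.max(w)])
  }
  bw <- phi * 0.9 * s_mad * k^(-1 / 5)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - r) / bw)), 0)
  }
  d_grid <- dens(r)
  best <- which.max(d_grid)
  ord <- sort(r)
  i <- which(ord == r[best])[1]
  lo <- if (i > 1) ord[i - 1] else ord[i] - bw
  hi <- if (i < k) ord[i + 1] else ord[i] + bw
  opt <- stats::optimize(dens, lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  if (opt$objective >= d_grid[best]) opt$maximum else r[best]
}

mode_estimate <- function(h, weighted, phi, n_boot, seed, method) {
  s <- h$snps
  if (nrow(s) < 3) stop("mode estimators need at least 3 SNPs", call. = FALSE)
  point <- function(bx, by) {
    r <- by / bx
    w <- if (weighted) bx^2 / s$se_y^2 else rep(1, length(r))
    mode_point(r, w, phi)
  }
  beta <- point(s$beta_x, s$beta_y)
  se <- boot_se(h, point, n_boot, seed)
  mr_estimate(method, beta, se, z_pval(beta, se), n_snp = nrow(s))
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance-weighted empirical density of per-SNP
#' Wald ratios (Gaussian kernel, normal-reference bandwidth on the median
#' absolute deviation, multiplied by `phi`). Consistent when the largest
#' group of instruments sharing a ratio value is valid, even if they are a
#' minority. Standard error by seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi bandwidth multiplier (default 1).
#' @return An `mr_estimate` with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(h, phi = 1.0, n_boot = 1000, seed = 1L) {
  mode_estimate(h, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed,
                method = "weighted_mode")
}

#' Simple mode estimate
#'
#' As [mr_weighted_mode()] with equal weights: lower precision, but less
#' sensitive to the weighting of invalid instruments.
#'
#' @inheritParams mr_weighted_mode
#' @return An `mr_estimate` with method `"simple_mode"`.
#' @export
mr_simple_mode <- function(h, phi = 1.0, n_boot = 1000, seed = 1L) {
  mode_estimate(h, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed,
                method = "simple_mode")
}

#' Run all applicable estimators
#'
#' Applies Wald/IVW, MR-Egger, weighted median, weighted mode and simple
#' mode as the instrument count allows (Egger, median and modes need 3 or
#' more SNPs; IVW needs 2, falling back to the Wald ratio at 1), and flags
#' whether every computed slope-type estimate shares the IVW estimate's
#' sign.
#'
#' @param h a `harmonized_set`.
#' @param phi mode bandwidth multiplier.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed for the bootstraps.
#' @param re_mode IVW random-effects mode.
#' @return list with `estimates` (named list of `mr_estimate`; slot
#'   `egger_intercept` included when computable), `direction_consistent`
#'   flag, and `not_computable` (character vector of skipped methods).
#' @export
estimate_all <- function(h, phi = 1.0, n_boot = 1000, seed = 1L,
                         re_mode = "multiplicative_random") {
  k <- nrow(h$snps)
  if (k == 0) stop("empty harmonized set", call. = FALSE)
  out <- list()
  skipped <- character(0)
  out$ivw <- mr_ivw(h, re_mode = re_mode)
  if (k >= 3) {
    eg <- tryCatch(mr_egger(h), error = function(e) NULL)
    if (!is.null(eg)) {
      out$egger_slope <- eg$slope
      out$egger_intercept <- eg$intercept
    } else skipped <- c(skipped, "egger_slope", "egger_intercept")
    out$weighted_median <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
    out$weighted_mode <- mr_weighted_mode(h, phi = phi, n_boot = n_boot,
                                          seed = seed + 1L)
    out$simple_mode <- mr_simple_mode(h, phi = phi, n_boot = n_boot,
                                      seed = seed + 2L)
  } else {
    skipped <- c(skipped, "egger_slope", "egger_intercept",
                 "weighted_median", "weighted_mode", "simple_mode")
  }
  slope_methods <- intersect(
    names(out), c("ivw", "egger_slope", "weighted_median", "weighted_mode",
                  "simple_mode"))
  signs <- vapply(out[slope_methods], function(e) sign(e$beta), 0)
  list(estimates = out,
       direction_consistent = all(signs == sign(out$ivw$beta)),
       not_computable = skipped)
}
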
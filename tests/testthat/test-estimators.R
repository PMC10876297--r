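test_that("Wald ratio matches hand arithmetic and is frame invariant", {
  e <- wald_ratio(0.5, 0.02, 0.1, 0.05)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.1)
  expect_equal(wald_ratio(0.5, 0.02, 0, 0.05)$beta, 0)
  flipped <- wald_ratio(-0.5, 0.02, -0.1, 0.05)
  expect_equal(flipped$beta, e$beta)
  expect_equal(flipped$se, e$se)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.05), "beta_x")
})

test_that("estimate CIs and ORs follow the 95% normal convention", {
  e <- wald_ratio(0.5, 0.02, 0.1, 0.05)
  expect_equal(e$ci_low, e$beta - 1.959964 * e$se)
  expect_equal(e$ci_high, e$beta + 1.959964 * e$se)
  expect_equal(e$or_point, exp(e$beta))
  expect_equal(e$or_low, exp(e$ci_low))
  expect_true(e$or_low < e$or_point && e$or_point < e$or_high)
})

test_that("IVW equals the zero-intercept WLS oracle on random fixtures", {
  for (seed in 101:105) {
    h <- fixture_harmonized(k = 10, seed = seed)
    s <- h$snps
    fit <- lm(beta_y ~ beta_x - 1, data = s, weights = 1 / s$se_y^2)
    est <- mr_ivw(h, re_mode = "fixed")
    expect_equal(est$beta, unname(coef(fit)["beta_x"]), tolerance = 1e-10)
    # fixed-effect se is the meta-analysis form, not the lm sigma-scaled one
    expect_equal(est$se, sqrt(1 / sum(s$beta_x^2 / s$se_y^2)),
                 tolerance = 1e-12)
    # random-effects se is never narrower than fixed
    expect_gte(mr_ivw(h)$se, est$se)
  }
})

test_that("IVW on perfectly homogeneous ratios returns the ratio with Q = 0", {
  bx <- c(0.2, -0.3, 0.4, 0.25)
  h <- harmonized_set(bx, rep(0.02, 4), 0.3 * bx, rep(0.05, 4))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(attr(est, "Q"), 0, tolerance = 1e-20)
})

test_that("single-SNP input falls back to the Wald ratio", {
  h <- harmonized_set(0.5, 0.02, 0.1, 0.05)
  est <- mr_ivw(h)
  expect_equal(est$method, "wald")
  expect_equal(est$beta, 0.2)
})

test_that("MR-Egger recovers slope and intercept exactly on noiseless data", {
  bx <- seq(0.1, 0.5, length.out = 8)
  by <- 0.01 + 0.3 * bx          # exact line, zero noise
  h <- harmonized_set(bx, rep(0.02, 8), by, rep(0.05, 8))
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.01, tolerance = 1e-10)

  # zero-intercept data gives an exactly zero intercept
  h0 <- harmonized_set(bx, rep(0.02, 8), 0.3 * bx, rep(0.05, 8))
  expect_equal(mr_egger(h0)$intercept$beta, 0, tolerance = 1e-12)
})

test_that("MR-Egger rejects a degenerate all-equal design", {
  h <- harmonized_set(rep(0.2, 5), rep(0.02, 5), rnorm(5, 0.06, 0.001),
                      rep(0.05, 5))
  expect_error(mr_egger(h), "degenerate")
})

test_that("weighted median matches the cumulative-weight percentile oracle", {
  # hand fixture: ratios and weights chosen so the interpolation is exercised
  bx <- c(1, 1, 1, 1, 1)
  by <- c(0.1, 0.2, 0.3, 0.5, 0.9)
  sey <- c(0.2, 0.1, 0.4, 0.2, 0.3)
  h <- harmonized_set(bx, rep(0.01, 5), by, sey)
  # oracle: sort ratios, cumulative weights minus half, interpolate at 0.5
  r <- by / bx
  w <- bx^2 / sey^2
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  i <- max(which(cw < 0.5))
  expected <- r[i] + (r[i + 1] - r[i]) * (0.5 - cw[i]) / (cw[i + 1] - cw[i])
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, expected, tolerance = 1e-12)

  # all ratios equal: the median is that ratio
  h_eq <- harmonized_set(bx, rep(0.01, 5), 0.25 * bx, sey)
  expect_equal(mr_weighted_median(h_eq, n_boot = 10, seed = 1)$beta, 0.25)
})

test_that("mode estimators resist a far outlier and respond to weights", {
  bx <- rep(1, 7)
  by <- c(0.19, 0.2, 0.2, 0.21, 0.2, 0.205, 3)   # tight cluster + outlier
  sey <- c(rep(0.05, 6), 0.5)
  h <- harmonized_set(bx, rep(0.01, 7), by, sey)
  wm <- mr_weighted_mode(h, n_boot = 20, seed = 2)
  expect_lt(abs(wm$beta - 0.2), 0.05)

  # equal weights: weighted and simple mode coincide
  h_eq <- harmonized_set(rep(1, 5), rep(0.01, 5),
                         c(0.1, 0.2, 0.2, 0.25, 0.6), rep(0.1, 5))
  expect_equal(mr_weighted_mode(h_eq, n_boot = 10, seed = 3)$beta,
               mr_simple_mode(h_eq, n_boot = 10, seed = 3)$beta,
               tolerance = 1e-10)

  # heterogeneous weights: down-weighting one cluster moves the weighted
  # mode toward the heavy cluster while the simple mode ignores weights
  by2 <- c(0.10, 0.11, 0.12, 0.50, 0.51, 0.52, 0.53)
  sey2 <- c(0.02, 0.02, 0.02, 0.4, 0.4, 0.4, 0.4)  # heavy weight near 0.1
  h2 <- harmonized_set(rep(1, 7), rep(0.01, 7), by2, sey2)
  wmode <- mr_weighted_mode(h2, n_boot = 10, seed = 4)$beta
  smode <- mr_simple_mode(h2, n_boot = 10, seed = 4)$beta
  expect_lt(abs(wmode - 0.1), abs(wmode - 0.5))
  expect_lt(abs(smode - 0.5), abs(smode - 0.1))
})

test_that("mode estimate varies smoothly in the bandwidth multiplier", {
  h <- fixture_harmonized(k = 20, seed = 140)
  m1 <- mr_weighted_mode(h, phi = 1, n_boot = 10, seed = 5)$beta
  m2 <- mr_weighted_mode(h, phi = 2, n_boot = 10, seed = 5)$beta
  expect_lt(abs(m1 - m2), 0.2)  # documented sensitivity, no equality claim
})

test_that("bootstrap standard errors are bit-reproducible for a given seed", {
  h <- fixture_harmonized(k = 12, seed = 123)
  a <- mr_weighted_median(h, n_boot = 100, seed = 42)
  b <- mr_weighted_median(h, n_boot = 100, seed = 42)
  c <- mr_weighted_median(h, n_boot = 100, seed = 43)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_identical(mr_weighted_mode(h, n_boot = 50, seed = 7)$se,
                   mr_weighted_mode(h, n_boot = 50, seed = 7)$se)
})

test_that("estimators are scale equivariant and sign-flip invariant", {
  h <- fixture_harmonized(k = 15, seed = 160)
  s <- h$snps
  for (c_scale in c(0.5, 2)) {
    h_scaled <- harmonized_set(s$beta_x * c_scale, s$se_x * c_scale,
                               s$beta_y, s$se_y)
    expect_equal(mr_ivw(h_scaled)$beta, mr_ivw(h)$beta / c_scale,
                 tolerance = 1e-10)
    expect_equal(mr_weighted_median(h_scaled, n_boot = 2, seed = 1)$beta,
                 mr_weighted_median(h, n_boot = 2, seed = 1)$beta / c_scale,
                 tolerance = 1e-10)
  }
  flip <- sample(c(-1, 1), nrow(s), replace = TRUE)
  h_flip <- harmonized_set(s$beta_x * flip, s$se_x, s$beta_y * flip, s$se_y)
  expect_equal(mr_ivw(h_flip)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h_flip, n_boot = 2, seed = 1)$beta,
               mr_weighted_median(h, n_boot = 2, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("estimate_all flags direction consistency and degrades gracefully", {
  sim_h <- sim_harmonized(sim_config(k_snps = 30, theta = 0.1, seed = 200))
  all_est <- estimate_all(sim_h, n_boot = 50, seed = 1)
  expect_setequal(names(all_est$estimates),
                  c("ivw", "egger_slope", "egger_intercept",
                    "weighted_median", "weighted_mode", "simple_mode"))
  expect_true(all_est$direction_consistent)

  h2 <- fixture_harmonized(k = 2, seed = 201)
  small <- estimate_all(h2, n_boot = 10, seed = 1)
  expect_equal(names(small$estimates), "ivw")
  expect_true(all(c("egger_slope", "weighted_median") %in%
                    small$not_computable))
})

test_that("estimate_table serializes all methods with the expected columns", {
  h <- fixture_harmonized(k = 8, seed = 210)
  all_est <- estimate_all(h, n_boot = 10, seed = 1)
  tab <- estimate_table(unname(all_est$estimates), exposure = "x",
                        outcome = "y")
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("exposure", "outcome", "method", "nsnp", "beta", "se",
                      "ci_low", "ci_high", "pval", "or", "or_low", "or_high"))
  expect_equal(tab$or, exp(tab$beta))
})
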
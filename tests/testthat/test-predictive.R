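test_that("a degenerate posterior yields the closed-form lognormal
           predictive", {
  mat <- matrix(rep(c(5, 20, 0.85, 0.26, 0.18), each = 5000), ncol = 5,
                dimnames = list(NULL, c("c", "k", "mu_pop", "sigma_pop",
                                        "sigma_pat")))
  dr <- fake_draws(mat)
  pp <- posterior_predictive(dr, n = 2e4, seed = 9)
  s_tot <- sqrt(0.26^2 + 0.18^2)
  ks <- ks.test(pp$draws, "plnorm", 0.85, s_tot)
  expect_gt(ks$p.value, 0.01)

  # determinism and input validation
  pp2 <- posterior_predictive(dr, n = 2e4, seed = 9)
  expect_identical(pp$draws, pp2$draws)
  expect_error(posterior_predictive(dr, n = 0), "positive")
})

test_that("the predictive mean matches the analytic posterior-mixture
           mean", {
  fit <- fx_fit()
  pp <- posterior_predictive(fit, seed = 4)
  th <- as.matrix(fit)
  analytic <- mean(exp(th[, "mu_pop"] +
                       (th[, "sigma_pop"]^2 + th[, "sigma_pat"]^2) / 2))
  mc_se <- sd(pp$draws) / sqrt(length(pp$draws))
  expect_equal(mean(pp$draws), analytic, tolerance = 5 * mc_se / analytic)
})

test_that("the lognormal approximation is a log-scale moment match", {
  set.seed(10)
  x <- rlnorm(2e5, 0.85, 0.32)
  fit <- fit_lognormal_approx(x)
  expect_equal(unname(fit["mu"]), 0.85, tolerance = 0.01)
  expect_equal(unname(fit["sigma"]), 0.32, tolerance = 0.01)

  expect_equal(unname(fit_lognormal_approx(rep(exp(1), 100),
                                           min_draws = 10)),
               c(1, 0))
  expect_error(fit_lognormal_approx(c(-1, rep(1, 2e4))), "positive")
  expect_error(fit_lognormal_approx(rlnorm(100)), "at least")

  # a posterior-like lognormal mixture is approximated to 0.02 sup-norm
  set.seed(11)
  mix <- c(rlnorm(1e5, 0.80, 0.30), rlnorm(1e5, 0.90, 0.33))
  fm <- fit_lognormal_approx(mix)
  grid <- seq(0.5, 6, by = 0.01)
  sup <- max(abs(ecdf(mix)(grid) - plnorm(grid, fm["mu"], fm["sigma"])))
  expect_lt(sup, 0.02)
})

test_that("tail probabilities reproduce the published lognormal
           approximation table and are monotone", {
  expect_equal(round(tail_probability(0.85, 0.32, 1.0), 3), 0.395)
  expect_equal(round(tail_probability(0.85, 0.32, 0.9), 3), 0.142)
  expect_equal(round(tail_probability(0.85, 0.32, 0.8), 3), 0.040)
  expect_equal(round(tail_probability(0.85, 0.32, 0.7), 3), 0.008)

  # the median threshold gives 50%
  expect_equal(tail_probability(0.85, 0.32, exp(0.85)), 50)

  # strictly increasing in the threshold, and in sigma below the median
  p <- tail_probability(0.85, 0.32, seq(0.5, 2, by = 0.1))
  expect_true(all(diff(p) > 0))
  ps <- vapply(seq(0.2, 0.5, by = 0.05), function(s) {
    tail_probability(0.85, s, 1.0)
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("undeforming a zero-pressure study is the identity and
           contact studies are corrected upward", {
  fit <- fx_fit()
  coh <- fx_cohort()
  corr <- undeform_study(coh$samples, fit)
  rec <- corr$records
  zero <- rec$pressure_kpa == 0
  expect_equal(rec$corrected_mean[zero], rec$original_mean[zero])
  expect_equal(rec$corrected_median[zero], rec$original_median[zero])
  expect_true(all(rec$corrected_mean[!zero] > rec$original_mean[!zero]))

  # round trip: corrected means approach the generating undeformed means
  latent <- coh$truth$latent
  for (lab in rec$label[!zero]) {
    gen_mean <- mean(latent$T_mm[latent$study_id == lab])
    got <- rec$corrected_mean[rec$label == lab]
    expect_equal(got, gen_mean, tolerance = 0.05)
  }

  # draw-averaged mode agrees closely with the median mode here
  corr2 <- undeform_study(coh$samples, fit, mode = "draws",
                          n_draws = 300)
  expect_equal(corr2$records$corrected_mean, rec$corrected_mean,
               tolerance = 0.03)
})

test_that("shift metrics quantify the inter-study range reduction", {
  rec <- data.frame(
    label = c("a", "b", "c"),
    original_mean = c(2.5, 1.7, 2.2),
    original_median = c(2.4, 1.6, 2.1),
    corrected_mean = c(2.5, 2.3, 2.4),
    corrected_median = c(2.4, 2.2, 2.35))
  s <- shift_metrics(rec)
  expect_equal(unname(s$range_before), c(0.8, 0.8))
  expect_equal(unname(s$range_after), c(0.2, 0.2))
  expect_equal(unname(s$pct_reduction), c(75, 75))

  same <- rec; same$original_mean <- 2; same$original_median <- 2
  same$corrected_mean <- 2; same$corrected_median <- 2
  s0 <- shift_metrics(same)
  expect_equal(unname(s0$range_before), c(0, 0))
  expect_error(shift_metrics(rec[1, ]), "nrow")
})

test_that("theoretical-quantile boxplots reproduce analytic quartiles
           and converge in the quantile count", {
  u <- theoretical_quantile_boxplot(function(p) p, n_quantiles = 98)
  expect_lt(abs(u$stats["median"] - 0.5), 0.01)
  expect_lt(abs(u$stats["q1"] - 0.25), 0.01)
  expect_lt(abs(u$stats["q3"] - 0.75), 0.01)

  ln <- theoretical_quantile_boxplot(c(0.85, 0.32), n_quantiles = 98)
  expect_equal(unname(ln$stats["median"]), exp(0.85), tolerance = 0.01)

  # refining the quantile count barely moves the box (the residual
  # ~0.5% at the quartiles is the plotting-position offset 1/(n+1))
  fine <- theoretical_quantile_boxplot(c(0.85, 0.32),
                                       n_quantiles = 9800)
  for (q in c("q1", "median", "q3")) {
    expect_lt(abs(ln$stats[q] - fine$stats[q]) / fine$stats[q], 0.006)
  }

  # a summary-statistics study is drawn through its moment-matched fit
  st <- summary_stat_study(2.71, 0.83, 34)
  bs <- theoretical_quantile_boxplot(st)
  mom <- lognormal_mom(2.71, 0.83)
  expect_equal(unname(bs$stats["median"]), exp(mom[["mu"]]),
               tolerance = 0.01)
})
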
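test_that("with one zero-pressure sample per patient the model
           collapses to iid lognormal sampling", {
  coh <- fx_small_cohort(n_pat = 50, n_samp = 50, seed = 5)
  m <- build_model(coh$samples, list(), fx_surface())
  t <- coh$samples$thickness_mm
  for (th in list(c(c = 5, k = 20, mu_pop = 0.9, sigma_pop = 0.2,
                    sigma_pat = 0.15),
                  c(c = 1, k = 3, mu_pop = 0.7, sigma_pop = 0.31,
                    sigma_pat = 0.05))) {
    s_tot <- sqrt(th["sigma_pop"]^2 + th["sigma_pat"]^2)
    expect_equal(m$log_lik(th),
                 sum(dlnorm(t, th["mu_pop"], s_tot, log = TRUE)),
                 tolerance = 1e-10)
  }

  # the conditional MAP of mu_pop is the mean log-thickness
  f <- function(mu) m$log_lik(c(c = 5, k = 20, mu_pop = mu,
                                sigma_pop = 0.2, sigma_pat = 0.15))
  opt <- optimize(f, c(0, 2), maximum = TRUE)
  expect_equal(opt$maximum, mean(log(t)), tolerance = 1e-4)
})

test_that("vanishing intra-patient variability forbids disagreeing
           replicate samples", {
  samples <- data.frame(
    study_id = "s", patient_id = c("p1", "p1", "p2"),
    sample_id = c("a", "b", "a"),
    thickness_mm = c(2.0, 2.4, 2.2), pressure_kpa = 0)
  m <- build_model(samples, list(), fx_surface())
  base <- c(c = 5, k = 20, mu_pop = 0.8, sigma_pop = 0.25,
            sigma_pat = NA)
  lls <- vapply(c(0.1, 0.01, 0.001), function(s) {
    base["sigma_pat"] <- s
    m$log_lik(base)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))      # diverges to -Inf
  expect_lt(lls[3], -1e3)
  base["sigma_pat"] <- 0
  expect_identical(m$log_lik(base), -Inf)
})

test_that("the joint log-density matches a pencil-and-paper assembly
           and its analytic patient-effect marginalization matches
           numerical integration", {
  samples <- data.frame(
    study_id = c("s0", "s0", "s16"),
    patient_id = c("p1", "p1", "p2"),
    sample_id = c("a", "b", "a"),
    thickness_mm = c(2.1, 2.5, 1.8),
    pressure_kpa = c(0, 0, 16))
  surf <- fx_surface()
  m <- build_model(samples, list(), surf)
  th <- c(c = 4, k = 15, mu_pop = 0.9, sigma_pop = 0.3,
          sigma_pat = 0.2)
  mu_i <- c(0.95, 0.82)    # ordered as factor levels p1, p2

  lam16 <- surface_lambda(surf, 4, 15, 16)
  by_hand <- dnorm(0.95, 0.9, 0.3, log = TRUE) +
    dnorm(0.82, 0.9, 0.3, log = TRUE) +
    dlnorm(2.1, 0.95, 0.2, log = TRUE) +
    dlnorm(2.5, 0.95, 0.2, log = TRUE) +
    dlnorm(1.8, 0.82 + log(lam16), 0.2, log = TRUE) +
    m$log_prior(th)
  expect_equal(m$log_joint(th, mu_i), by_hand, tolerance = 1e-10)

  # marginal likelihood equals the integral of the joint over mu_i
  joint_no_prior <- function(m1, m2) {
    exp(m$log_joint(th, c(m1, m2)) - m$log_prior(th))
  }
  int1 <- integrate(function(v) {
    vapply(v, function(m1) {
      integrate(function(w) vapply(w, function(m2) joint_no_prior(m1, m2),
                                   numeric(1)),
                0.82 - 1.5, 0.82 + 1.5, rel.tol = 1e-9)$value
    }, numeric(1))
  }, 0.95 - 1.5, 0.95 + 1.5, rel.tol = 1e-8)$value
  expect_equal(m$log_lik(th), log(int1), tolerance = 1e-5)
})

test_that("pressures missing from the surface are rejected at build
           time", {
  samples <- data.frame(study_id = "s", patient_id = "p",
                        sample_id = "a", thickness_mm = 2,
                        pressure_kpa = 7)
  expect_error(build_model(samples, list(), fx_surface()),
               "not covered")
})

test_that("prior-only sampling recovers the uniform priors", {
  m <- build_model(NULL, list(), fx_surface())
  dr <- sample_posterior(m, chains = 2, iter = 4000, warmup = 800,
                         seed = 31)
  sup <- list(c = c(0, 10), k = c(0, 40), mu_pop = c(0, 2),
              sigma_pop = c(0, 1), sigma_pat = c(0, 1))
  for (p in names(sup)) {
    x <- as.vector(dr$draws[, , p])
    thin <- x[seq(1, length(x), by = 25)]
    ks <- suppressWarnings(ks.test(thin, "punif", sup[[p]][1],
                                   sup[[p]][2]))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("sampling is reproducible and its metadata is coherent", {
  coh <- fx_small_cohort(n_pat = 30, n_samp = 60, seed = 6)
  m <- build_model(coh$samples, list(), fx_surface())
  d1 <- sample_posterior(m, chains = 2, iter = 300, warmup = 300,
                         seed = 77)
  d2 <- sample_posterior(m, chains = 2, iter = 300, warmup = 300,
                         seed = 77)
  expect_identical(d1$draws, d2$draws)
  d3 <- sample_posterior(m, chains = 2, iter = 300, warmup = 300,
                         seed = 78)
  expect_false(identical(d1$draws, d3$draws))
  expect_equal(dim(d1$draws), c(300, 2, 5))
  expect_true(all(d1$accept_rate > 0 & d1$accept_rate < 1))
})

test_that("variance components are separately identifiable only with
           replicate samples per patient", {
  surf <- fx_surface()
  # design A: strictly one sample per patient -> only the total scale
  # sqrt(sigma_pop^2 + sigma_pat^2) is identified (ridge posterior)
  cohA <- fx_small_cohort(n_pat = 150, n_samp = 150, seed = 8)
  mA <- build_model(cohA$samples, list(), surf)
  drA <- sample_posterior(mA, chains = 2, iter = 1200, warmup = 1000,
                          seed = 41)
  # design B: two samples per patient
  cohB <- fx_small_cohort(n_pat = 75, n_samp = 150, seed = 9)
  mB <- build_model(cohB$samples, list(), surf)
  drB <- sample_posterior(mB, chains = 2, iter = 1200, warmup = 1000,
                          seed = 42)

  tot <- function(dr) {
    sqrt(as.vector(dr$draws[, , "sigma_pop"])^2 +
         as.vector(dr$draws[, , "sigma_pat"])^2)
  }
  truth_tot <- sqrt(0.26^2 + 0.18^2)
  for (dr in list(drA, drB)) {
    ci <- quantile(tot(dr), c(0.025, 0.975))
    expect_gt(truth_tot, ci[1]); expect_lt(truth_tot, ci[2])
  }
  # ridge: strongly negative dependence without replicates, and a much
  # wider marginal for each component
  corA <- diagnostics(drA)$pair_cor["sigma_pop_sigma_pat"]
  corB <- diagnostics(drB)$pair_cor["sigma_pop_sigma_pat"]
  expect_lt(corA, -0.6)
  expect_gt(corB, corA + 0.3)
  widthA <- diff(unlist(posterior_summary(drA, "sigma_pat")[c("lower",
                                                              "upper")]))
  widthB <- diff(unlist(posterior_summary(drB, "sigma_pat")[c("lower",
                                                              "upper")]))
  expect_lt(widthB, widthA)
  # with replicates both components are recovered
  sB <- posterior_summary(drB)
  for (p in c("sigma_pop", "sigma_pat")) {
    row <- sB[sB$parameter == p, ]
    expect_gt(fx_truth()[p], row$lower)
    expect_lt(fx_truth()[p], row$upper)
  }
})

test_that("summary-statistics studies sharpen the population location", {
  surf <- fx_surface()
  coh <- fx_small_cohort(n_pat = 40, n_samp = 80, seed = 10)
  summ <- list(summary_stat_study(2.46, 0.81, 90, "lit"))
  m_with <- build_model(coh$samples, summ, surf)
  m_without <- build_model(coh$samples, list(), surf)
  d_with <- sample_posterior(m_with, chains = 2, iter = 1000,
                             warmup = 800, seed = 51)
  d_without <- sample_posterior(m_without, chains = 2, iter = 1000,
                                warmup = 800, seed = 51)
  w <- function(d) {
    s <- posterior_summary(d, "mu_pop")
    s$upper - s$lower
  }
  expect_lt(w(d_with), w(d_without))
})

test_that("patient effects are exact conjugate draws: their moments
           match the closed-form full conditional", {
  coh <- fx_small_cohort(n_pat = 20, n_samp = 100, seed = 12)
  m <- build_model(coh$samples, list(), fx_surface())
  # degenerate posterior at a fixed parameter point -> the patient
  # effects must be iid draws from the exact Gaussian full conditional
  th <- c(c = 5, k = 20, mu_pop = 0.85, sigma_pop = 0.26,
          sigma_pat = 0.18)
  dr <- fake_draws(matrix(rep(th, each = 4000), ncol = 5,
                          dimnames = list(NULL, names(th))))
  pe <- patient_effects(m, dr, seed = 62)
  expect_equal(dim(pe), c(4000L, 20L))

  lt <- log(coh$samples$thickness_mm)
  pid <- coh$samples$patient_id
  for (p in colnames(pe)[c(1, 7, 20)]) {
    y <- lt[pid == p]
    prec <- 1 / 0.26^2 + length(y) / 0.18^2
    mean_i <- (0.85 / 0.26^2 + sum(y) / 0.18^2) / prec
    expect_equal(mean(pe[, p]), mean_i,
                 tolerance = 4 / sqrt(prec) / sqrt(4000) / mean_i)
    expect_equal(sd(pe[, p]), sqrt(1 / prec), tolerance = 0.05)
  }
})
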
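test_that("method-of-moments lognormal fits reproduce the published
           worked examples", {
  martufi <- lognormal_mom(2.71, 0.83)
  expect_equal(round(unname(martufi["mu"]), 2), 0.95)
  expect_equal(round(unname(martufi["sigma"]), 2), 0.30)

  tong <- lognormal_mom(2.56, 0.59)
  expect_equal(round(unname(tong["mu"]), 2), 0.91)
  expect_equal(round(unname(tong["sigma"]), 2), 0.23)

  # degenerate distribution
  expect_equal(unname(lognormal_mom(3, 0)), c(log(3), 0))
  expect_error(lognormal_mom(-1, 0.5), "positive")
})

test_that("pooling subset statistics is exact", {
  # two identical subsets: pooled mean and count are exact; the pooled
  # n-1 SD of the duplicated values is S * sqrt(2(N-1)/(2N-1))
  a <- summary_stat_study(2.5, 0.6, 40, "a")
  p0 <- pool_subset_stats(list(a, a))
  expect_equal(p0$M, 2.5)
  expect_equal(p0$N, 80L)
  expect_equal(p0$S, 0.6 * sqrt(2 * 39 / 79))

  # four implied values: 2 at 1, 2 at 3 -> mean 2, sd sqrt(4/3)
  p <- pool_subset_stats(list(summary_stat_study(1, 0, 2),
                              summary_stat_study(3, 0, 2)))
  expect_equal(p$M, 2)
  expect_equal(p$S, sqrt(4 / 3))

  # random subsets against brute-force pooling of the raw values
  set.seed(42)
  for (rep in 1:5) {
    x1 <- rlnorm(17, 0.9, 0.3); x2 <- rlnorm(31, 0.8, 0.35)
    p <- pool_subset_stats(list(
      summary_stat_study(mean(x1), sd(x1), 17),
      summary_stat_study(mean(x2), sd(x2), 31)))
    expect_equal(p$M, mean(c(x1, x2)))
    expect_equal(p$S, sd(c(x1, x2)))
  }
  expect_error(pool_subset_stats(list()), "non-empty")
})

test_that("the (mean, SD) sampling density is a normalized density with
           the right mean-of-means", {
  d <- joint_mean_sd_density(0.9, 0.3, 34)
  expect_lt(abs(d$mass - 1), 0.01)

  Mg <- seq(d$M_range[1], d$M_range[2], length.out = 161)
  Sg <- seq(0, d$S_max, length.out = 161)
  f <- outer(Mg, Sg, function(a, b) d$density(a, b))
  dA <- diff(Mg[1:2]) * diff(Sg[1:2])
  EM <- sum(outer(Mg, rep(1, 161)) * f) * dA
  expect_equal(EM, exp(0.9 + 0.3^2 / 2), tolerance = 0.01)
})

test_that("integrating out the SD recovers the sampling distribution of
           the mean (Monte-Carlo check)", {
  N <- 20
  d <- joint_mean_sd_density(0.7, 0.25, N, check = FALSE)
  Sg <- seq(0, d$S_max, length.out = 201)
  marg <- function(m) {
    vapply(m, function(mm) {
      v <- d$density(mm, Sg)
      sum((v[-1] + v[-length(v)]) / 2) * diff(Sg[1:2])
    }, numeric(1))
  }
  set.seed(11)
  means <- rowMeans(matrix(rlnorm(2e5 * N, 0.7, 0.25), 2e5, N))
  br <- quantile(means, c(0.001, 0.999))
  bins <- seq(br[1], br[2], length.out = 31)
  h <- hist(means[means >= br[1] & means <= br[2]], breaks = bins,
            plot = FALSE)
  dens <- h$counts / 2e5 / diff(bins[1:2])
  th <- marg(h$mids)
  bulk <- th > 0.25 * max(th)
  expect_lt(max(abs(dens[bulk] - th[bulk]) / th[bulk]), 0.05)
})

test_that("the variance of the sample mean under the density scales
           as 1/N", {
  v <- vapply(c(10, 40, 160), function(N) {
    d <- joint_mean_sd_density(0.9, 0.3, N, check = FALSE)
    Mg <- seq(d$M_range[1], d$M_range[2], length.out = 161)
    Sg <- seq(0, d$S_max, length.out = 161)
    f <- outer(Mg, Sg, function(a, b) d$density(a, b))
    dA <- diff(Mg[1:2]) * diff(Sg[1:2])
    mass <- sum(f) * dA
    EM <- sum(outer(Mg, rep(1, 161)) * f) * dA / mass
    sum(outer(Mg^2, rep(1, 161)) * f) * dA / mass - EM^2
  }, numeric(1))
  expect_equal(v[1] / v[2], 4, tolerance = 0.1)
  expect_equal(v[2] / v[3], 4, tolerance = 0.1)
})

test_that("an impossible quadrature demand fails with a mass report", {
  expect_error(
    joint_mean_sd_density(0.9, 0.3, 34,
                          quad = cf_quadrature(n_freq = 16,
                                               n_t_max = 1024)),
    "normalization")
})

test_that("the log-likelihood surface peaks at the method-of-moments
           estimate and concentrates with sample size", {
  martufi <- summary_stat_study(2.71, 0.83, 34, "martufi")
  tong <- summary_stat_study(2.56, 0.59, 90, "tong")
  rng_mu <- c(0.7, 1.15); rng_s <- c(0.1, 0.5)

  g1 <- loglik_surface(martufi, rng_mu, rng_s)
  g2 <- loglik_surface(tong, rng_mu, rng_s)

  cell <- c(diff(rng_mu), diff(rng_s)) / 99
  expect_lt(abs(g1$argmax["mu"] - g1$mom["mu"]), cell[1] * 1.5)
  expect_lt(abs(g1$argmax["sigma"] - g1$mom["sigma"]), cell[2] * 1.5)
  expect_lt(abs(g2$argmax["mu"] - g2$mom["mu"]), cell[1] * 1.5)
  expect_lt(abs(g2$argmax["sigma"] - g2$mom["sigma"]), cell[2] * 1.5)

  # the larger study is more concentrated: smaller area within 2 nats
  area <- function(g) mean(g$log_density > max(g$log_density) - 2)
  expect_lt(area(g2), area(g1))

  # Fisher-information scaling: curvature at the mode grows with N
  curv <- function(g) {
    mu0 <- g$argmax["mu"]; s0 <- g$argmax["sigma"]; h <- 0.01
    -(g$log_lik(mu0 + h, s0) - 2 * g$log_lik(mu0, s0) +
        g$log_lik(mu0 - h, s0)) / h^2
  }
  m68 <- summary_stat_study(2.71, 0.83, 68, "martufi_x2")
  g3 <- loglik_surface(m68, rng_mu, rng_s)
  expect_equal(curv(g3) / curv(g1), 2, tolerance = 0.25)
})

test_that("the surface interpolant agrees with direct density
           evaluation off-grid", {
  st <- summary_stat_study(2.71, 0.83, 34, "martufi")
  g <- loglik_surface(st, c(0.75, 1.15), c(0.15, 0.45))
  peak <- exp(max(g$log_density))
  set.seed(21)
  checked <- 0
  while (checked < 50) {
    mu <- runif(1, 0.8, 1.1); s <- runif(1, 0.2, 0.4)
    direct <- joint_mean_sd_density(mu, s, 34, check = FALSE)$density(
      st$M, st$S)
    # compare where the likelihood is appreciable (> 1% of the peak);
    # on the super-quadratic flank far below the peak the interpolant
    # is only qualitatively accurate
    if (direct < 0.01 * peak) next
    rel <- abs(exp(g$log_lik(mu, s)) - direct) / direct
    expect_lt(rel, 0.01)
    checked <- checked + 1
  }
})

test_that("a too-narrow surface range warns about its boundary", {
  st <- summary_stat_study(2.71, 0.83, 34, "martufi")
  expect_warning(
    loglik_surface(st, c(0.95, 1.3), c(0.2, 0.45), n_grid = c(20, 20)),
    "boundary")
})

test_that("log-likelihood surfaces serialize and round-trip", {
  st <- summary_stat_study(2.56, 0.59, 90, "tong")
  g <- loglik_surface(st, c(0.75, 1.1), c(0.12, 0.4), n_grid = c(40, 40))
  path <- tempfile(fileext = ".json")
  write_loglik_grid(g, path)
  back <- read_loglik_grid(path)
  expect_equal(back$log_density, g$log_density)
  for (pt in list(c(0.9, 0.23), c(0.95, 0.3), c(0.85, 0.2))) {
    expect_equal(back$log_lik(pt[1], pt[2]), g$log_lik(pt[1], pt[2]),
                 tolerance = 1e-10)
  }
  unlink(path)
})
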
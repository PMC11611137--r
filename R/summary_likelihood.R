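#' Method-of-moments lognormal fit from a sample mean and SD
#'
#' Matches a lognormal distribution `LN(mu, sigma)` to a reported sample
#' mean `M` and sample standard deviation `S`:
#' `sigma^2 = log(1 + S^2 / M^2)`, `mu = log(M) - sigma^2 / 2`.
#'
#' @param M Sample mean \[mm\], `> 0`.
#' @param S Sample standard deviation \[mm\], `>= 0`.
#' @return Named vector `c(mu, sigma)` (log-scale location and scale).
#' @examples
#' lognormal_mom(2.71, 0.83)  # approximately (0.95, 0.30)
#' @export
lognormal_mom <- function(M, S) {
  stopifnot(is.numeric(M), is.numeric(S), length(M) == 1L,
            length(S) == 1L, is.finite(M), is.finite(S))
  if (M <= 0) stop("'M' must be positive")
  if (S < 0) stop("'S' must be non-negative")
  sigma2 <- log(1 + S^2 / M^2)
  c(mu = log(M) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' A study available only as summary statistics
#'
#' Container for a study that reports its undeformed wall-thickness
#' measurements only as a sample mean, sample standard deviation (the
#' `n - 1` convention) and sample count.
#'
#' @param M Sample mean \[mm\], `> 0`.
#' @param S Sample SD \[mm\], `>= 0`.
#' @param N Sample count, integer `>= 2`.
#' @param label Study identifier.
#' @return An object of class `summary_stat_study`.
#' @export
summary_stat_study <- function(M, S, N, label = "summary") {
  stopifnot(is.numeric(M), is.numeric(S), is.numeric(N),
            length(M) == 1L, length(S) == 1L, length(N) == 1L)
  if (M <= 0) stop("'M' must be positive")
  if (S < 0) stop("'S' must be non-negative")
  if (N < 2 || N != round(N)) stop("'N' must be an integer >= 2")
  structure(list(M = M, S = S, N = as.integer(N),
                 label = as.character(label)),
            class = "summary_stat_study")
}

#' @export
print.summary_stat_study <- function(x, ...) {
  cat(sprintf("Summary-statistics study '%s': M = %g mm, S = %g mm, N = %d\n",
              x$label, x$M, x$S, x$N))
  invisible(x)
}

#' Pool summary statistics of split subsets
#'
#' Combines the `(M, S, N)` triples of two or more disjoint subsets of one
#' data set into the exact mean and (`n - 1`) SD of the concatenated,
#' unseen samples.
#'
#' @param subsets List of [summary_stat_study()] objects.
#' @param label Label for the pooled study.
#' @return A [summary_stat_study()] for the pooled data.
#' @export
pool_subset_stats <- function(subsets, label = "pooled") {
  if (!is.list(subsets) || length(subsets) < 1L) {
    stop("'subsets' must be a non-empty list of summary_stat_study objects")
  }
  stopifnot(all(vapply(subsets, inherits, logical(1), "summary_stat_study")))
  n <- vapply(subsets, `[[`, numeric(1), "N")
  m <- vapply(subsets, `[[`, numeric(1), "M")
  s <- vapply(subsets, `[[`, numeric(1), "S")
  N <- sum(n)
  M <- sum(n * m) / N
  ss <- sum((n - 1) * s^2 + n * m^2)   # sum of squares of raw values
  S <- sqrt((ss - N * M^2) / (N - 1))
  summary_stat_study(M, S, N, label = label)
}

# ---------------------------------------------------------------------------
# Joint sampling density of (sample mean, sample SD) of N iid lognormal
# variables, computed through the characteristic function of (T, T^2):
#   (i)   phi(u, v) = E exp(i u T + i v T^2) by quadrature on a truncated
#         t-grid;
#   (ii)  phi^N  (convolution theorem) gives the CF of
#         V = (sum T, sum T^2);
#   (iii) the density of V is recovered as a 2-D Fourier series on a
#         window covering the mean of V +/- many SDs;
#   (iv)  change of variables V1 = N M, V2 = (N-1) S^2 + N M^2 with
#         Jacobian 2 N (N-1) S yields the density of (M, S).
# ---------------------------------------------------------------------------

#' Default quadrature specification for the summary-statistics density
#'
#' @param n_freq Frequency-grid size per dimension of the 2-D Fourier
#'   series (also the resolution of the recovered density of the sums).
#' @param n_t_min,n_t_max Bounds on the adaptive quadrature-grid size for
#'   the characteristic-function integral.
#' @param t_tail Lognormal tail probability at which the integrand support
#'   is truncated (renormalized afterwards).
#' @param z_lo,z_hi Half-widths, in SDs of the sums, of the Fourier window
#'   below and above the mean of `(sum T, sum T^2)`.
#' @return A list of quadrature settings.
#' @export
cf_quadrature <- function(n_freq = 192, n_t_min = 1024, n_t_max = 8192,
                          t_tail = 1e-8, z_lo = 9, z_hi = 13) {
  list(n_freq = as.integer(n_freq), n_t_min = as.integer(n_t_min),
       n_t_max = as.integer(n_t_max), t_tail = t_tail,
       z_lo = z_lo, z_hi = z_hi)
}

# Core builder: CF of the truncated lognormal pair (T, T^2) raised to the
# N-th power, plus window geometry.  mu enters only through scaling, so
# surfaces over mu reuse builds at mu = 0 (see loglik_surface).
cf_build <- function(mu, sigma, N, quad) {
  stopifnot(sigma > 0, N >= 2)
  t_lo <- stats::qlnorm(quad$t_tail, mu, sigma)
  t_hi <- stats::qlnorm(1 - quad$t_tail, mu, sigma)

  m1 <- exp(mu + sigma^2 / 2)
  s1 <- sqrt(exp(2 * mu + sigma^2) * expm1(sigma^2))
  m2 <- exp(2 * mu + 2 * sigma^2)
  s2 <- sqrt(exp(4 * mu + 4 * sigma^2) * expm1(4 * sigma^2))

  a1 <- max(N * t_lo, N * m1 - quad$z_lo * sqrt(N) * s1)
  b1 <- N * m1 + quad$z_hi * sqrt(N) * s1
  a2 <- max(N * t_lo^2, N * m2 - quad$z_lo * sqrt(N) * s2)
  b2 <- N * m2 + quad$z_hi * sqrt(N) * s2
  L1 <- b1 - a1; L2 <- b2 - a2

  n1 <- quad$n_freq; n2 <- quad$n_freq
  j <- seq.int(-n1 / 2, n1 / 2 - 1)
  l <- seq.int(-n2 / 2, n2 / 2 - 1)
  u <- 2 * pi * j / L1
  v <- 2 * pi * l / L2

  # resolve the fastest oscillation of exp(i u t + i v t^2) on the t-grid
  max_rate <- max(abs(u)) + 2 * max(abs(v)) * t_hi
  n_t <- min(quad$n_t_max,
             max(quad$n_t_min, ceiling(4 * (t_hi - t_lo) * max_rate / pi)))
  tg <- seq(t_lo, t_hi, length.out = n_t)
  w <- rep(1, n_t); w[c(1, n_t)] <- 0.5        # trapezoid
  ct <- w * stats::dlnorm(tg, mu, sigma)
  ct <- ct / sum(ct)                            # phi(0, 0) = 1 exactly

  A <- exp(1i * outer(u, tg))                   # n1 x n_t
  B <- exp(1i * outer(tg^2, v))                 # n_t x n2
  Phi <- A %*% (ct * B)
  list(PhiN = Phi^N, u = u, v = v, a1 = a1, b1 = b1, a2 = a2, b2 = b2,
       L1 = L1, L2 = L2, N = N, mu = mu, sigma = sigma, n_t = n_t)
}

# Evaluate the (M, S) density from a cf_build object at arbitrary points.
cf_eval <- function(cf, M, S) {
  n <- max(length(M), length(S))
  M <- rep_len(M, n); S <- rep_len(S, n)
  N <- cf$N
  v1 <- N * M
  v2 <- (N - 1) * S^2 + N * M^2
  ok <- is.finite(M) & is.finite(S) & S >= 0 &
    v1 >= cf$a1 & v1 <= cf$b1 & v2 >= cf$a2 & v2 <= cf$b2
  out <- numeric(n)
  if (any(ok)) {
    E1 <- exp(-1i * outer(cf$u, v1[ok]))        # n1 x P
    E2 <- exp(-1i * outer(cf$v, v2[ok]))        # n2 x P
    fV <- Re(colSums(E2 * (t(cf$PhiN) %*% E1))) / (cf$L1 * cf$L2)
    out[ok] <- pmax(fV, 0) * 2 * N * (N - 1) * S[ok]
  }
  out
}

# Session cache for cf_build results (keyed on all build inputs); bounded.
.cf_cache <- new.env(parent = emptyenv())

cf_build_cached <- function(mu, sigma, N, quad) {
  key <- paste(format(c(mu, sigma, N, quad$n_freq, quad$n_t_min,
                        quad$n_t_max, quad$t_tail, quad$z_lo, quad$z_hi),
                      digits = 15), collapse = "|")
  if (!is.null(.cf_cache[[key]])) return(.cf_cache[[key]])
  val <- cf_build(mu, sigma, N, quad)
  keys <- ls(.cf_cache)
  if (length(keys) > 512L) rm(list = keys[1:64], envir = .cf_cache)
  assign(key, val, envir = .cf_cache)
  val
}

#' Joint sampling density of the mean and SD of N lognormal samples
#'
#' Computes the joint density of the sample mean `M` and sample SD `S`
#' (the `n - 1` convention) of `N` independent `LN(mu, sigma)` thickness
#' values, exactly up to quadrature, through the characteristic function
#' of `(T, T^2)` and the convolution theorem.  No closed form or tractable
#' analytic approximation of this density exists.
#'
#' @param mu Log-scale location of the individual thicknesses.
#' @param sigma Log-scale scale, `> 0`.
#' @param N Sample count, `>= 2`.
#' @param quad Quadrature settings from [cf_quadrature()].
#' @param check If `TRUE`, numerically integrates the returned density and
#'   stops if the captured mass deviates from 1 by more than `mass_tol`.
#' @param mass_tol Allowed normalization defect.
#' @return An object of class `aawt_ms_density`: call its `$density(M, S)`
#'   element to evaluate; `$mass` holds the captured probability mass when
#'   `check = TRUE`.
#' @export
joint_mean_sd_density <- function(mu, sigma, N, quad = cf_quadrature(),
                                  check = TRUE, mass_tol = 0.01) {
  cf <- cf_build(mu, sigma, N, quad)
  obj <- structure(
    list(mu = mu, sigma = sigma, N = N, quad = quad,
         M_range = c(cf$a1 / N, cf$b1 / N),
         S_max = sqrt(cf$b2 / (N - 1)),
         density = function(M, S) cf_eval(cf, M, S),
         mass = NA_real_),
    class = "aawt_ms_density")
  if (check) {
    mass <- ms_density_mass(obj)
    if (abs(mass - 1) > mass_tol) {
      stop(sprintf(paste0(
        "summary-statistics density failed its normalization check: ",
        "captured mass %.4f (defect %.2e); enlarge the quadrature grid"),
        mass, abs(mass - 1)))
    }
    obj$mass <- mass
  }
  obj
}

# Trapezoid integral of the (M, S) density over its support rectangle.
ms_density_mass <- function(obj, n_m = 161, n_s = 161) {
  Mg <- seq(obj$M_range[1], obj$M_range[2], length.out = n_m)
  Sg <- seq(0, obj$S_max, length.out = n_s)
  f <- outer(Mg, Sg, function(a, b) obj$density(a, b))
  wm <- rep(1, n_m); wm[c(1, n_m)] <- 0.5
  ws <- rep(1, n_s); ws[c(1, n_s)] <- 0.5
  sum((wm %o% ws) * f) * diff(Mg[1:2]) * diff(Sg[1:2])
}

#' @export
print.aawt_ms_density <- function(x, ...) {
  cat(sprintf(paste0(
    "Joint (mean, SD) sampling density: LN(%g, %g), N = %d\n",
    "  support window: M in [%.3g, %.3g], S <= %.3g%s\n"),
    x$mu, x$sigma, x$N, x$M_range[1], x$M_range[2], x$S_max,
    if (is.na(x$mass)) "" else sprintf("; captured mass %.4f", x$mass)))
  invisible(x)
}

# Smooth interpolant of a log-likelihood grid.  The log-density spans
# hundreds of nats between its peak and the underflow floor; splining it
# directly would overshoot wildly at the cliff between the two.  Instead
# the near-linear transform q = -sqrt(2 (top - log f)) is splined (for a
# locally Gaussian likelihood q is conical, with slope of order 1/scale)
# and mapped back as log f = top - q^2 / 2, which is bounded above by the
# grid maximum, so the interpolant cannot invent spurious peaks.
loglik_grid_interpolant <- function(mu_grid, sigma_grid, logf) {
  top <- max(logf)
  floor_val <- min(logf)
  q <- -sqrt(2 * pmax(top - logf, 0))
  interp_q <- make_tensor_spline(mu_grid, sigma_grid, q)
  function(mu, sigma) {
    qv <- interp_q(mu, sigma)
    ifelse(is.na(qv), -Inf, pmax(top - qv^2 / 2, floor_val))
  }
}

#' Log-likelihood surface of a summary-statistics study
#'
#' Evaluates `log f(M_k, S_k; mu_pop, sigma)` -- the log sampling density
#' of the study's reported mean and SD under a population lognormal
#' `LN(mu_pop, sigma)` -- on a grid over `(mu_pop, sigma)` and fits a
#' smooth tensor-product cubic-spline interpolant, so the term can be
#' evaluated cheaply inside the sampler.  The lognormal scale family
#' (`T = e^mu T0`) reduces the grid to one characteristic-function build
#' per `sigma` value.
#'
#' Log-density values are floored at `max - clip` nats to keep the
#' interpolant well behaved where the density underflows.
#'
#' @param study A [summary_stat_study()].
#' @param mu_range,sigma_range Grid ranges; must cover the
#'   method-of-moments point estimate.  A warning is issued if the grid
#'   argmax lies on the boundary (range too narrow).
#' @param n_grid Grid size, `c(n_mu, n_sigma)` (default 100 x 100).
#' @param quad Quadrature settings from [cf_quadrature()].
#' @param clip Floor depth in nats below the grid maximum.
#' @return An object of class `aawt_loglik_grid` with elements
#'   `mu_grid`, `sigma_grid`, `log_density`, and `$log_lik(mu, sigma)`
#'   (spline interpolant, `-Inf` outside the grid).
#' @export
loglik_surface <- function(study,
                           mu_range = NULL, sigma_range = NULL,
                           n_grid = c(100, 100),
                           quad = cf_quadrature(), clip = 700) {
  stopifnot(inherits(study, "summary_stat_study"), length(n_grid) == 2L,
            all(n_grid >= 10))
  mom <- lognormal_mom(study$M, study$S)
  if (is.null(mu_range)) mu_range <- mom["mu"] + c(-0.3, 0.3)
  if (is.null(sigma_range)) {
    sigma_range <- c(max(0.02, mom["sigma"] - 0.15), mom["sigma"] + 0.2)
  }
  stopifnot(sigma_range[1] > 0,
            mu_range[1] <= mom["mu"], mu_range[2] >= mom["mu"],
            sigma_range[1] <= mom["sigma"], sigma_range[2] >= mom["sigma"])
  mu_grid <- seq(mu_range[1], mu_range[2], length.out = n_grid[1])
  sigma_grid <- seq(sigma_range[1], sigma_range[2], length.out = n_grid[2])

  logf <- matrix(NA_real_, n_grid[1], n_grid[2])
  for (jl in seq_along(sigma_grid)) {
    cf0 <- cf_build_cached(0, sigma_grid[jl], study$N, quad)
    sc <- exp(-mu_grid)                       # scale to the mu = 0 family
    f0 <- cf_eval(cf0, study$M * sc, study$S * sc)
    logf[, jl] <- log(pmax(f0, .Machine$double.xmin)) - 2 * mu_grid
  }
  top <- max(logf)
  logf <- pmax(logf, top - clip)

  arg <- which(logf == top, arr.ind = TRUE)[1, ]
  if (arg[1] %in% c(1L, n_grid[1]) || arg[2] %in% c(1L, n_grid[2])) {
    warning("log-likelihood argmax lies on the grid boundary; ",
            "the (mu, sigma) ranges are too narrow")
  }

  structure(
    list(study = study, mu_grid = mu_grid, sigma_grid = sigma_grid,
         log_density = logf, mom = mom,
         argmax = c(mu = mu_grid[arg[1]], sigma = sigma_grid[arg[2]]),
         quad = quad,
         log_lik = loglik_grid_interpolant(mu_grid, sigma_grid, logf)),
    class = "aawt_loglik_grid")
}

#' @export
print.aawt_loglik_grid <- function(x, ...) {
  cat(sprintf(paste0(
    "Summary-study log-likelihood surface '%s' (M = %g, S = %g, N = %d)\n",
    "  grid %d x %d over mu in [%.3g, %.3g], sigma in [%.3g, %.3g]\n",
    "  argmax (%.3f, %.3f); method-of-moments (%.3f, %.3f)\n"),
    x$study$label, x$study$M, x$study$S, x$study$N,
    length(x$mu_grid), length(x$sigma_grid),
    min(x$mu_grid), max(x$mu_grid), min(x$sigma_grid), max(x$sigma_grid),
    x$argmax["mu"], x$argmax["sigma"], x$mom["mu"], x$mom["sigma"]))
  invisible(x)
}

#' Serialize a log-likelihood surface to JSON
#'
#' @param grid An `aawt_loglik_grid` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_loglik_grid <- function(grid, path) {
  stopifnot(inherits(grid, "aawt_loglik_grid"))
  obj <- list(format = "aawt_loglik_grid",
              package_version = as.character(utils::packageVersion("aawt")),
              study = unclass(grid$study),
              mu_grid = grid$mu_grid, sigma_grid = grid$sigma_grid,
              log_density = as.vector(grid$log_density),
              dim = dim(grid$log_density), quad = grid$quad)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a log-likelihood surface written by [write_loglik_grid()]
#'
#' @param path File path.
#' @return An `aawt_loglik_grid` object with the interpolant rebuilt.
#' @export
read_loglik_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "aawt_loglik_grid") {
    stop("'", path, "' is not a serialized log-likelihood surface")
  }
  logf <- matrix(obj$log_density, obj$dim[1], obj$dim[2])
  study <- summary_stat_study(obj$study$M, obj$study$S, obj$study$N,
                              obj$study$label)
  arg <- which(logf == max(logf), arr.ind = TRUE)[1, ]
  structure(
    list(study = study, mu_grid = obj$mu_grid, sigma_grid = obj$sigma_grid,
         log_density = logf, mom = lognormal_mom(study$M, study$S),
         argmax = c(mu = obj$mu_grid[arg[1]], sigma = obj$sigma_grid[arg[2]]),
         quad = obj$quad,
         log_lik = loglik_grid_interpolant(obj$mu_grid, obj$sigma_grid,
                                           logf)),
    class = "aawt_loglik_grid")
}
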
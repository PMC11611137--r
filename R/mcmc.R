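# Adaptive random-walk Metropolis sampler and rank-normalized convergence
# diagnostics.  The sampler targets the marginal posterior of the five
# free parameters (patient effects are integrated out analytically in the
# model's log-density, see hierarchical.R), so a low-dimensional
# covariance-adapted random walk mixes well.

# --- prior specification ----------------------------------------------------

#' Prior distribution specification for one parameter
#'
#' Supported families: `"uniform"` (`min`, `max`), `"normal"` (`mean`,
#' `sd`, optionally truncated to `[lower, upper]`), `"halfnormal"` (`sd`),
#' `"exponential"` (`rate`).  Truncation bounds default to the family's
#' natural support.
#'
#' @param dist Family name.
#' @param ... Family parameters (see above).
#' @param lower,upper Truncation bounds.
#' @return An object of class `aawt_prior`.
#' @export
prior_dist <- function(dist = c("uniform", "normal", "halfnormal",
                                "exponential"),
                       ..., lower = NULL, upper = NULL) {
  dist <- match.arg(dist)
  p <- list(...)
  spec <- switch(dist,
    uniform = {
      stopifnot(!is.null(p$min), !is.null(p$max), p$min < p$max)
      list(lower = p$min, upper = p$max,
           logd = function(x) stats::dunif(x, p$min, p$max, log = TRUE),
           rng = function(n) stats::runif(n, p$min, p$max))
    },
    normal = {
      stopifnot(!is.null(p$mean), !is.null(p$sd), p$sd > 0)
      lo <- if (is.null(lower)) -Inf else lower
      hi <- if (is.null(upper)) Inf else upper
      list(lower = lo, upper = hi,
           logd = function(x) stats::dnorm(x, p$mean, p$sd, log = TRUE),
           rng = function(n) {
             q <- stats::runif(n, stats::pnorm(lo, p$mean, p$sd),
                               stats::pnorm(hi, p$mean, p$sd))
             stats::qnorm(q, p$mean, p$sd)
           })
    },
    halfnormal = {
      stopifnot(!is.null(p$sd), p$sd > 0)
      list(lower = 0, upper = if (is.null(upper)) Inf else upper,
           logd = function(x) log(2) + stats::dnorm(x, 0, p$sd, log = TRUE),
           rng = function(n) abs(stats::rnorm(n, 0, p$sd)))
    },
    exponential = {
      stopifnot(!is.null(p$rate), p$rate > 0)
      list(lower = 0, upper = if (is.null(upper)) Inf else upper,
           logd = function(x) stats::dexp(x, p$rate, log = TRUE),
           rng = function(n) stats::rexp(n, p$rate))
    })
  structure(c(list(dist = dist, params = p), spec), class = "aawt_prior")
}

#' Default priors for the five model parameters
#'
#' Independent uniform priors on wide intervals: `c ~ U(0, 10)` kPa and
#' `k ~ U(0, 40)` kPa (the response-surface build ranges),
#' `mu_pop ~ U(0, 2)`, `sigma_pop ~ U(0, 1)`, `sigma_pat ~ U(0, 1)`.
#' All are configurable; alternative families are available through
#' [prior_dist()] for prior-robustness checks.
#'
#' @return Named list of [prior_dist()] objects.
#' @export
default_priors <- function() {
  list(c = prior_dist("uniform", min = 0, max = 10),
       k = prior_dist("uniform", min = 0, max = 40),
       mu_pop = prior_dist("uniform", min = 0, max = 2),
       sigma_pop = prior_dist("uniform", min = 0, max = 1),
       sigma_pat = prior_dist("uniform", min = 0, max = 1))
}

prior_log_density <- function(priors, theta) {
  s <- 0
  for (nm in names(priors)) {
    x <- theta[[nm]]
    pr <- priors[[nm]]
    if (x < pr$lower || x > pr$upper) return(-Inf)
    s <- s + pr$logd(x)
  }
  s
}

prior_sample <- function(priors) {
  vapply(priors, function(pr) pr$rng(1), numeric(1))
}

# --- adaptive random-walk Metropolis ---------------------------------------

# One chain.  Two-phase warmup: a scale-only phase with a diagonal
# proposal, then Haario-style covariance adaptation accumulated from the
# post-phase-one states only (so the covariance is not polluted by the
# approach path).  The kernel is frozen for the sampling phase.
rwm_chain <- function(log_post, theta0, iter, warmup, target_accept,
                      scale0) {
  d <- length(theta0)
  draws <- matrix(NA_real_, iter, d,
                  dimnames = list(NULL, names(theta0)))
  lp_out <- numeric(iter)
  theta <- theta0
  lp <- log_post(theta)
  if (!is.finite(lp)) stop("initial value has non-finite log-posterior")

  phase1 <- floor(warmup * 0.4)
  mean_acc <- theta
  cov_acc <- diag(scale0^2, d)
  n_acc <- 1
  log_scale <- 0
  L <- diag(scale0, d)
  cov_kernel <- FALSE
  n_accepted_sampling <- 0L
  n_invalid <- 0L
  total <- warmup + iter

  for (t in seq_len(total)) {
    z <- stats::rnorm(d)
    prop <- theta + exp(log_scale) * drop(z %*% L)
    lp_prop <- log_post(prop)
    if (identical(lp_prop, -Inf)) n_invalid <- n_invalid + 1L
    acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
    if (acc) {
      theta <- prop; lp <- lp_prop
      if (t > warmup) n_accepted_sampling <- n_accepted_sampling + 1L
    }
    if (t <= warmup) {
      a_rate <- if (acc) 1 else 0
      log_scale <- log_scale +
        min(1, 10 * max(t - phase1, 1)^-0.6) * (a_rate - target_accept)
      if (t == phase1) {
        # reset moment accumulation at the start of phase two
        mean_acc <- theta
        cov_acc <- matrix(0, d, d)
        n_acc <- 1
      } else if (t > phase1) {
        n_acc <- n_acc + 1
        delta <- theta - mean_acc
        mean_acc <- mean_acc + delta / n_acc
        cov_acc <- cov_acc * (n_acc - 2) / max(n_acc - 1, 1) +
          tcrossprod(delta) / n_acc
        if (n_acc >= 3 * d && t %% 25 == 0) {
          C <- 2.38^2 / d * (cov_acc + diag(1e-10 + 1e-6 * diag(cov_acc)))
          Lnew <- tryCatch(chol(C), error = function(e) NULL)
          if (!is.null(Lnew)) {
            if (!cov_kernel) log_scale <- 0  # switch to the adapted kernel
            cov_kernel <- TRUE
            L <- Lnew
          }
        }
      }
    } else {
      draws[t - warmup, ] <- theta
      lp_out[t - warmup] <- lp
    }
  }
  list(draws = draws, lp = lp_out,
       accept_rate = n_accepted_sampling / iter,
       n_invalid = n_invalid)
}

# Rough posterior mode: Nelder-Mead from the best of a set of prior
# draws, used to start chains near the typical set.
find_map <- function(log_post, priors, n_start = 64) {
  best <- NULL; best_lp <- -Inf
  for (i in seq_len(n_start)) {
    cand <- prior_sample(priors)
    lp <- log_post(cand)
    if (is.finite(lp) && lp > best_lp) { best <- cand; best_lp <- lp }
  }
  if (is.null(best)) {
    stop("could not find a finite-posterior starting point in ", n_start,
         " prior draws; check the data/surface/priors")
  }
  opt <- tryCatch(
    stats::optim(best, function(x) {
      v <- log_post(x)
      if (is.finite(v)) -v else 1e12
    }, method = "Nelder-Mead", control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && -opt$value > best_lp) {
    best <- opt$par
  }
  best
}

# --- convergence diagnostics ------------------------------------------------

split_chains <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[seq.int(n - h + 1, n), , drop = FALSE])
}

rank_normalize <- function(mat) {
  r <- rank(as.vector(mat), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

rhat_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 3 || m < 2) return(NA_real_)
  W <- mean(apply(mat, 2, stats::var))
  B <- n * stats::var(colMeans(mat))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Potential-scale-reduction diagnostic computed on rank-normalized split
#' chains; the reported value is the maximum of the bulk and the folded
#' (tail-sensitive) variants.  Values above about 1.01 indicate
#' non-convergence.
#'
#' @param mat Matrix of draws, iterations by chains.
#' @return R-hat value (`NA` for a single chain).
#' @export
rhat <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) return(NA_real_)
  s <- split_chains(mat)
  if (stats::var(as.vector(s)) == 0) return(1)
  bulk <- rhat_basic(rank_normalize(s))
  folded <- rhat_basic(rank_normalize(abs(s - stats::median(s))))
  max(bulk, folded)
}

#' Bulk effective sample size
#'
#' Effective sample size of rank-normalized split chains, combining
#' per-chain autocorrelations with Geyer's initial monotone positive
#' sequence.
#'
#' @param mat Matrix of draws, iterations by chains.
#' @return Effective sample size (capped at the total draw count).
#' @export
ess_bulk <- function(mat) {
  mat <- as.matrix(mat)
  s <- split_chains(mat)
  if (stats::var(as.vector(s)) == 0) return(NA_real_)
  z <- rank_normalize(s)
  n <- nrow(z); m <- ncol(z)
  acov <- vapply(seq_len(m), function(j) {
    drop(stats::acf(z[, j], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf)
  }, numeric(n))
  W <- mean(acov[1, ])
  B <- if (m > 1) n * stats::var(colMeans(z)) else 0
  vp <- (n - 1) / n * W + B / n
  rho <- 1 - (W - rowMeans(acov)) / vp   # rho[1] corresponds to lag 0
  # Geyer initial monotone positive sequence on pair sums
  max_pairs <- floor((n - 2) / 2)
  P <- numeric(0)
  for (kk in seq_len(max_pairs)) {
    p <- rho[2 * kk] + rho[2 * kk + 1]
    if (p < 0) break
    P <- c(P, p)
  }
  if (length(P) > 1) P <- cummin(P)
  tau <- -rho[1] + 2 * sum(c(rho[1], P))  # = 1 + 2 sum_{t>=1} rho_t
  max(1, min(n * m / tau, n * m))
}

#' Convergence diagnostics for posterior draws
#'
#' Computes rank-normalized split R-hat and bulk effective sample size
#' per parameter, and joint-dependence summaries (correlations) for the
#' parameter pairs the model could confound: the variance components
#' `(sigma_pop, sigma_pat)` and the stiffnesses `(c, k)`.
#'
#' @param draws An `aawt_draws` object from [sample_posterior()].
#' @param rhat_threshold Convergence flag threshold (default 1.01).
#' @return An object of class `aawt_diagnostics`: a per-parameter table,
#'   pair correlations, and a `converged` flag.
#' @export
diagnostics <- function(draws, rhat_threshold = 1.01) {
  stopifnot(inherits(draws, "aawt_draws"))
  a <- draws$draws
  params <- dimnames(a)[[3]]
  single <- dim(a)[2] < 2
  tab <- data.frame(
    parameter = params,
    rhat = vapply(params, function(p) {
      if (single) NA_real_ else rhat(a[, , p])
    }, numeric(1)),
    ess_bulk = vapply(params, function(p) ess_bulk(a[, , p]), numeric(1)),
    row.names = NULL)
  flat <- apply(a, 3, as.vector)
  pair_cor <- c(
    sigma_pop_sigma_pat = stats::cor(flat[, "sigma_pop"],
                                     flat[, "sigma_pat"]),
    c_k = stats::cor(flat[, "c"], flat[, "k"]))
  converged <- if (single) NA else all(tab$rhat <= rhat_threshold)
  structure(list(summary = tab, pair_cor = pair_cor,
                 converged = converged,
                 rhat_threshold = rhat_threshold,
                 note = if (single) "single chain: R-hat undefined" else NULL),
            class = "aawt_diagnostics")
}

#' @export
print.aawt_diagnostics <- function(x, ...) {
  cat("Posterior convergence diagnostics\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("pair correlations: cor(sigma_pop, sigma_pat) = %.3f, cor(c, k) = %.3f\n",
              x$pair_cor["sigma_pop_sigma_pat"], x$pair_cor["c_k"]))
  if (!is.null(x$note)) cat(x$note, "\n")
  else cat(sprintf("converged (all R-hat <= %.3g): %s\n",
                   x$rhat_threshold, x$converged))
  invisible(x)
}

#' Posterior median and credible interval
#'
#' Equal-tailed credible interval and median, pooled over chains.
#'
#' @param draws An `aawt_draws` object.
#' @param param Parameter name, or `NULL` for all.
#' @param prob Interval probability (default 0.95).
#' @return A data frame with columns `parameter`, `median`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(draws, param = NULL, prob = 0.95) {
  stopifnot(inherits(draws, "aawt_draws"), prob > 0, prob < 1)
  params <- dimnames(draws$draws)[[3]]
  if (!is.null(param)) {
    stopifnot(all(param %in% params))
    params <- param
  }
  al <- (1 - prob) / 2
  out <- lapply(params, function(p) {
    x <- as.vector(draws$draws[, , p])
    q <- unname(stats::quantile(x, c(al, 0.5, 1 - al), type = 7))
    data.frame(parameter = p, median = q[2], lower = q[1], upper = q[3])
  })
  do.call(rbind, out)
}
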
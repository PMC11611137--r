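#' Build the hierarchical wall-thickness model
#'
#' Assembles the joint posterior of the five free parameters
#' `(c, k, mu_pop, sigma_pop, sigma_pat)` from raw multi-pressure
#' measurement data and summary-statistics studies.
#'
#' The generative model: patient-level log-thickness locations
#' `mu_i ~ N(mu_pop, sigma_pop)`; undeformed sample thicknesses
#' `T_ij ~ LN(mu_i, sigma_pat)`; measured (deformed) thicknesses
#' `t_ij = lambda_r(c, k, p_ij) * T_ij`, with the radial stretch supplied
#' by the response-surface emulator (`lambda_r = 1` exactly for
#' non-contact, zero-pressure studies).  Studies reported only as
#' `(M, S, N)` contribute the sampling density of their mean and SD under
#' `LN(mu_pop, sqrt(sigma_pop^2 + sigma_pat^2))`, each sample treated as
#' an independent patient, via a precomputed [loglik_surface()]
#' interpolant.
#'
#' On the log scale the raw-data model is linear-Gaussian given `(c, k)`,
#' so the patient effects `mu_i` are marginalized analytically: for
#' patient `i` with `n_i` samples the adjusted log-thicknesses
#' `y_ij = log t_ij - log lambda_r(c, k, p_ij)` are jointly
#' `N(mu_pop 1, sigma_pat^2 I + sigma_pop^2 J)`.  The sampler therefore
#' targets the exact marginal posterior in five dimensions; `mu_i` can be
#' recovered exactly afterwards with [patient_effects()].
#'
#' @param samples Data frame of raw measurements with columns `study_id`,
#'   `patient_id`, `sample_id`, `thickness_mm`, `pressure_kpa` (see
#'   [read_cohort()]), or `NULL` for none.
#' @param summaries List of [summary_stat_study()] objects (may be empty).
#' @param surface An `aawt_surface` covering every distinct positive
#'   pressure in `samples`.
#' @param priors Named list of [prior_dist()] objects; see
#'   [default_priors()].
#' @param loglik_grids Optional precomputed [loglik_surface()] objects
#'   matching `summaries`; built automatically when `NULL`.
#' @param summary_grid Grid size for automatically built summary-study
#'   surfaces.
#' @param sigma_cf_max Upper limit of the total-scale grid for summary
#'   studies; combined scales above it (far beyond any plausible
#'   posterior) are treated as having zero summary likelihood.
#' @param quad Quadrature settings from [cf_quadrature()].
#' @return An object of class `aawt_model` exposing `$log_post(theta)`,
#'   `$log_lik(theta)`, `$log_prior(theta)` and `$log_joint(theta, mu_i)`.
#' @export
build_model <- function(samples, summaries = list(), surface,
                        priors = default_priors(),
                        loglik_grids = NULL,
                        summary_grid = c(100, 100),
                        sigma_cf_max = 0.9,
                        quad = cf_quadrature()) {
  stopifnot(inherits(surface, "aawt_surface"), is.list(summaries))
  param_names <- c("c", "k", "mu_pop", "sigma_pop", "sigma_pat")
  stopifnot(setequal(names(priors), param_names))

  has_raw <- !is.null(samples) && nrow(samples) > 0
  if (has_raw) {
    samples <- validate_cohort(samples)
    pvec <- sort(unique(samples$pressure_kpa))
    pos_p <- pvec[pvec > 0]
    covered <- vapply(pos_p, function(p) {
      any(abs(surface$pressures - p) < 1e-9)
    }, logical(1))
    if (!all(covered)) {
      stop("pressures not covered by the response surface: ",
           paste(pos_p[!covered], collapse = ", "))
    }
    p_idx <- match(samples$pressure_kpa, pvec)
    pid <- factor(samples$patient_id)
    pidx <- as.integer(pid)
    n_pat <- nlevels(pid)
    n_i <- as.vector(table(pidx))
    logt <- log(samples$thickness_mm)
    sum_logt <- sum(logt)
    n_samp <- nrow(samples)
  } else {
    pvec <- numeric(0)
  }

  if (length(summaries) > 0) {
    stopifnot(all(vapply(summaries, inherits, logical(1),
                         "summary_stat_study")))
    if (is.null(loglik_grids)) {
      mu_lo <- max(priors$mu_pop$lower, -2)
      mu_hi <- min(priors$mu_pop$upper, 4)
      s_hi <- min(sigma_cf_max,
                  sqrt(min(priors$sigma_pop$upper, 5)^2 +
                       min(priors$sigma_pat$upper, 5)^2))
      loglik_grids <- lapply(summaries, function(st) {
        mom <- lognormal_mom(st$M, st$S)
        loglik_surface(
          st,
          mu_range = range(mu_lo, mu_hi, mom["mu"] + c(-0.1, 0.1)),
          sigma_range = range(0.02, s_hi, mom["sigma"] + c(-0.01, 0.05)),
          n_grid = summary_grid, quad = quad)
      })
    } else {
      stopifnot(length(loglik_grids) == length(summaries),
                all(vapply(loglik_grids, inherits, logical(1),
                           "aawt_loglik_grid")))
    }
  } else {
    loglik_grids <- list()
  }

  lambda_min <- surface$lambda_range[1]

  log_lik <- function(theta) {
    th <- as.list(theta)
    if (th$sigma_pat <= 0 || th$sigma_pop < 0) return(-Inf)
    ll <- 0
    if (has_raw) {
      lam <- vapply(pvec, function(p) {
        if (p == 0) 1 else surface_lambda(surface, th$c, th$k, p)
      }, numeric(1))
      if (any(is.na(lam)) || any(lam < lambda_min) || any(lam > 1 + 1e-9)) {
        return(-Inf)
      }
      y <- logt - log(lam)[p_idx]
      ybar <- as.vector(rowsum(y, pidx)) / n_i
      ssw <- as.vector(rowsum(y^2, pidx)) - n_i * ybar^2
      sw2 <- th$sigma_pat^2
      denom <- sw2 + n_i * th$sigma_pop^2
      ll <- ll - 0.5 * ((n_samp - n_pat) * log(2 * pi * sw2) +
                        sum(log(2 * pi * denom)) +
                        sum(ssw) / sw2 +
                        sum(n_i * (ybar - th$mu_pop)^2 / denom)) -
        sum_logt
    }
    if (length(loglik_grids) > 0) {
      s_tot <- sqrt(th$sigma_pop^2 + th$sigma_pat^2)
      for (g in loglik_grids) {
        ll <- ll + g$log_lik(th$mu_pop, s_tot)
      }
      if (!is.finite(ll)) return(-Inf)
    }
    ll
  }

  log_prior <- function(theta) prior_log_density(priors, as.list(theta))

  log_post <- function(theta) {
    lp <- log_prior(theta)
    if (!is.finite(lp)) return(-Inf)
    lp + log_lik(theta)
  }

  # Full joint log-density including explicit patient effects (used by
  # tests as a pencil-and-paper oracle; equals log_lik after integrating
  # the mu_i out).
  log_joint <- function(theta, mu_i) {
    th <- as.list(theta)
    if (!has_raw) stop("log_joint requires raw samples")
    stopifnot(length(mu_i) == n_pat)
    lam <- vapply(pvec, function(p) {
      if (p == 0) 1 else surface_lambda(surface, th$c, th$k, p)
    }, numeric(1))
    if (any(is.na(lam)) || any(lam < lambda_min)) return(-Inf)
    lj <- sum(stats::dnorm(mu_i, th$mu_pop, th$sigma_pop, log = TRUE)) +
      sum(stats::dlnorm(samples$thickness_mm,
                        mu_i[pidx] + log(lam)[p_idx],
                        th$sigma_pat, log = TRUE))
    if (length(loglik_grids) > 0) {
      s_tot <- sqrt(th$sigma_pop^2 + th$sigma_pat^2)
      for (g in loglik_grids) lj <- lj + g$log_lik(th$mu_pop, s_tot)
    }
    lj + log_prior(theta)
  }

  structure(
    list(samples = if (has_raw) samples else NULL,
         summaries = summaries,
         loglik_grids = loglik_grids,
         surface = surface, priors = priors,
         param_names = param_names,
         pressures = pvec,
         n_patients = if (has_raw) n_pat else 0L,
         patient_levels = if (has_raw) levels(pid) else character(0),
         log_lik = log_lik, log_prior = log_prior,
         log_post = log_post, log_joint = log_joint,
         internal = if (has_raw) {
           list(pidx = pidx, p_idx = p_idx, n_i = n_i, logt = logt)
         } else NULL),
    class = "aawt_model")
}

#' @export
print.aawt_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Hierarchical wall-thickness model: %d raw samples / %d patients, ",
    "%d summary studies\n  pressures: %s kPa\n"),
    if (is.null(x$samples)) 0L else nrow(x$samples), x$n_patients,
    length(x$summaries),
    if (length(x$pressures)) paste(x$pressures, collapse = ", ") else "-"))
  invisible(x)
}

#' Sample the posterior distribution
#'
#' Runs independent adaptive random-walk Metropolis chains on the
#' marginal posterior of `(c, k, mu_pop, sigma_pop, sigma_pat)`.
#' The proposal covariance is adapted to the posterior during warmup
#' and frozen afterwards.  Desk-scale defaults are 4 chains of 2,000
#' retained draws each; `paper_scale = TRUE` switches to 20 chains of
#' 10,000 draws.
#'
#' Runs are reproducible: all randomness derives from `seed`.  If any
#' parameter's rank-normalized split R-hat exceeds 1.01 the result is
#' flagged (not discarded) via its `converged` field.
#'
#' @param model An `aawt_model` from [build_model()].
#' @param chains Number of chains.
#' @param iter Retained draws per chain.
#' @param warmup Adaptation iterations per chain (discarded).
#' @param seed Integer seed.
#' @param paper_scale If `TRUE`, use 20 chains x 10,000 draws.
#' @param target_accept Target acceptance rate of the random walk.
#' @param init Optional named starting values (recycled across chains);
#'   by default chains start at independent prior draws.
#' @param include_patient_effects If `TRUE`, attach exact conjugate draws
#'   of the patient effects `mu_i` (see [patient_effects()]).
#' @return An object of class `aawt_draws`: `draws` is an array
#'   (iterations x chains x parameters); metadata includes acceptance
#'   rates, counts of out-of-support proposals, seed and the diagnostics
#'   summary.
#' @export
sample_posterior <- function(model, chains = 4, iter = 2000,
                             warmup = 1500, seed = 1,
                             paper_scale = FALSE,
                             target_accept = 0.234, init = NULL,
                             include_patient_effects = FALSE) {
  stopifnot(inherits(model, "aawt_model"), chains >= 1, iter >= 10,
            warmup >= 0)
  if (paper_scale) {
    chains <- 20; iter <- 10000
    warmup <- max(warmup, 2000)
  }
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  pn <- model$param_names
  widths <- vapply(model$priors, function(pr) {
    if (is.finite(pr$lower) && is.finite(pr$upper)) {
      pr$upper - pr$lower
    } else {
      2 * (pr$params$sd %||% (1 / (pr$params$rate %||% 1)))
    }
  }, numeric(1))

  if (is.null(init)) {
    map <- find_map(model$log_post, model$priors)
  } else {
    map <- unlist(init)[pn]
    if (!is.finite(model$log_post(map))) {
      stop("supplied init has non-finite log-posterior")
    }
  }

  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    theta0 <- map
    for (try in 1:200) {
      cand <- map + stats::rnorm(length(pn), 0, widths / 100)
      if (is.finite(model$log_post(cand))) { theta0 <- cand; break }
    }
    res[[ch]] <- rwm_chain(model$log_post, theta0, iter, warmup,
                           target_accept, scale0 = min(widths) / 100)
  }

  a <- array(NA_real_, c(iter, chains, length(pn)),
             dimnames = list(NULL, NULL, pn))
  lp <- matrix(NA_real_, iter, chains)
  for (ch in seq_len(chains)) {
    a[, ch, ] <- res[[ch]]$draws
    lp[, ch] <- res[[ch]]$lp
  }
  out <- structure(
    list(draws = a, lp = lp,
         accept_rate = vapply(res, `[[`, numeric(1), "accept_rate"),
         n_invalid = vapply(res, `[[`, integer(1), "n_invalid"),
         chains = chains, iter = iter, warmup = warmup, seed = seed,
         model = model),
    class = "aawt_draws")
  diag <- diagnostics(out)
  out$rhat_max <- if (chains > 1) max(diag$summary$rhat) else NA_real_
  out$converged <- diag$converged
  if (include_patient_effects && !is.null(model$samples)) {
    out$patient_effects <- patient_effects(model, out, seed = seed + 1L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.aawt_draws <- function(x, ...) {
  cat(sprintf(paste0(
    "Posterior draws: %d chains x %d iterations (warmup %d, seed %d)\n",
    "  mean acceptance %.2f, max R-hat %.4f, converged: %s\n"),
    x$chains, x$iter, x$warmup, x$seed, mean(x$accept_rate),
    x$rhat_max, x$converged))
  print(posterior_summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.matrix.aawt_draws <- function(x, ...) {
  apply(x$draws, 3, as.vector)
}

#' Exact conditional draws of the patient effects
#'
#' Given posterior draws of the five free parameters, draws each patient's
#' log-thickness location `mu_i` from its exact Gaussian full conditional
#' (the model is conjugate in `mu_i` given everything else), one draw per
#' retained posterior sample.
#'
#' @param model The `aawt_model` the draws came from.
#' @param draws An `aawt_draws` object.
#' @param seed Integer seed.
#' @return Matrix, total draws by patients (column names are patient ids).
#' @export
patient_effects <- function(model, draws, seed = 1) {
  stopifnot(inherits(model, "aawt_model"), inherits(draws, "aawt_draws"),
            !is.null(model$samples))
  set.seed(seed)
  th <- as.matrix(draws)
  nd <- nrow(th)
  ii <- model$internal
  n_pat <- model$n_patients
  pvec <- model$pressures
  out <- matrix(NA_real_, nd, n_pat,
                dimnames = list(NULL, model$patient_levels))
  for (d in seq_len(nd)) {
    lam <- vapply(pvec, function(p) {
      if (p == 0) 1 else surface_lambda(model$surface, th[d, "c"],
                                        th[d, "k"], p)
    }, numeric(1))
    y <- ii$logt - log(lam)[ii$p_idx]
    ybar <- as.vector(rowsum(y, ii$pidx)) / ii$n_i
    prec <- 1 / th[d, "sigma_pop"]^2 + ii$n_i / th[d, "sigma_pat"]^2
    mean_i <- (th[d, "mu_pop"] / th[d, "sigma_pop"]^2 +
               ii$n_i * ybar / th[d, "sigma_pat"]^2) / prec
    out[d, ] <- stats::rnorm(n_pat, mean_i, sqrt(1 / prec))
  }
  out
}
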
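#' Posterior predictive distribution of undeformed wall thickness
#'
#' For each retained posterior draw of `(mu_pop, sigma_pop, sigma_pat)`,
#' draws a new patient's location `mu_new ~ N(mu_pop, sigma_pop)` and a
#' new sample `T ~ LN(mu_new, sigma_pat)` -- equivalently
#' `T ~ LN(mu_pop, sqrt(sigma_pop^2 + sigma_pat^2))` -- giving the
#' distribution of the undeformed thickness of an unseen sample with all
#' parameter uncertainty propagated.
#'
#' @param draws An `aawt_draws` object from [sample_posterior()].
#' @param n Number of predictive draws; defaults to one per posterior
#'   draw.  Other values resample posterior draws with replacement.
#' @param seed Integer seed.
#' @return An object of class `aawt_predictive` with elements `draws`
#'   \[mm\], `n`, `seed` and provenance.
#' @export
posterior_predictive <- function(draws, n = NULL, seed = 1) {
  stopifnot(inherits(draws, "aawt_draws"))
  th <- as.matrix(draws)
  total <- nrow(th)
  if (is.null(n)) n <- total
  if (n <= 0) stop("'n' must be positive")
  set.seed(seed)
  idx <- if (n == total) seq_len(total) else {
    sample.int(total, n, replace = TRUE)
  }
  s_tot <- sqrt(th[idx, "sigma_pop"]^2 + th[idx, "sigma_pat"]^2)
  t_new <- stats::rlnorm(n, th[idx, "mu_pop"], s_tot)
  structure(list(draws = t_new, n = n, seed = seed,
                 posterior_seed = draws$seed),
            class = "aawt_predictive")
}

#' @export
print.aawt_predictive <- function(x, ...) {
  q <- stats::quantile(x$draws, c(0.025, 0.5, 0.975))
  cat(sprintf(paste0(
    "Posterior predictive undeformed thickness: %d draws\n",
    "  mean %.2f mm, median %.2f mm, 95%% PI [%.2f, %.2f] mm\n"),
    x$n, mean(x$draws), q[2], q[1], q[3]))
  invisible(x)
}

#' Lognormal approximation of a predictive distribution
#'
#' Moment-matches a lognormal on the log scale: `mu` is the mean and
#' `sigma` the SD of the log draws.  The approximation is what downstream
#' stochastic rupture-risk analyses consume.
#'
#' @param dist An `aawt_predictive` object or a numeric vector of
#'   positive draws.
#' @param min_draws Minimum number of draws required for a stable fit.
#' @return Named vector `c(mu, sigma)`.
#' @export
fit_lognormal_approx <- function(dist, min_draws = 1e4) {
  x <- if (inherits(dist, "aawt_predictive")) dist$draws else dist
  stopifnot(is.numeric(x))
  if (length(x) < min_draws) {
    stop("need at least ", min_draws, " draws for a stable fit")
  }
  if (any(x <= 0)) stop("draws must be positive")
  lx <- log(x)
  c(mu = mean(lx), sigma = stats::sd(lx))
}

#' Probability of a wall thickness below a threshold
#'
#' Lower-tail probability `P(T < t1)` of a lognormal thickness
#' distribution, reported in percent:
#' `100 * Phi((log t1 - mu) / sigma)`.
#'
#' @param mu,sigma Lognormal parameters (log scale), `sigma > 0`.
#' @param t1 Threshold thickness(es) \[mm\], `> 0`; vectorized.
#' @return Probability(ies) in percent.
#' @examples
#' tail_probability(0.85, 0.32, 1.0)  # about 0.395 (percent)
#' @export
tail_probability <- function(mu, sigma, t1) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(mu) == 1L,
            length(sigma) == 1L, sigma > 0, all(t1 > 0))
  100 * stats::pnorm((log(t1) - mu) / sigma)
}

#' Correct measured studies to undeformed thickness
#'
#' Divides each measured (deformed) thickness by the radial stretch
#' `lambda_r(c, k, p)` implied by the fitted compression model, giving
#' the study's undeformed thicknesses.  Zero-pressure studies pass
#' through unchanged.  Two modes: `"median"` evaluates the stretch at the
#' posterior medians of `(c, k)`; `"draws"` averages the per-sample
#' correction `t / lambda_r` over (a subsample of) posterior draws.
#'
#' @param samples Data frame of raw measurements (may span several
#'   studies; see [read_cohort()]).
#' @param draws An `aawt_draws` object whose model surface covers the
#'   pressures in `samples`.
#' @param mode `"median"` or `"draws"`.
#' @param n_draws Posterior subsample size for `mode = "draws"`.
#' @param seed Seed for the posterior subsample.
#' @return An object of class `aawt_correction`: a per-study record table
#'   (`label`, `pressure_kpa`, `n`, original and corrected means and
#'   medians) with the per-sample corrected values in
#'   `$corrected_values`.
#' @export
undeform_study <- function(samples, draws, mode = c("median", "draws"),
                           n_draws = 500, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(draws, "aawt_draws"))
  samples <- validate_cohort(samples)
  surface <- draws$model$surface
  pvec <- sort(unique(samples$pressure_kpa))
  pos_p <- pvec[pvec > 0]
  if (length(pos_p)) {
    covered <- vapply(pos_p, function(p) {
      any(abs(surface$pressures - p) < 1e-9)
    }, logical(1))
    if (!all(covered)) {
      stop("pressures not covered by the model's response surface: ",
           paste(pos_p[!covered], collapse = ", "))
    }
  }
  th <- as.matrix(draws)
  if (mode == "median") {
    c_med <- stats::median(th[, "c"])
    k_med <- stats::median(th[, "k"])
    lam <- vapply(pvec, function(p) {
      if (p == 0) 1 else surface_lambda(surface, c_med, k_med, p)
    }, numeric(1))
    if (any(is.na(lam))) stop("posterior-median stretch is infeasible")
    corrected <- samples$thickness_mm /
      lam[match(samples$pressure_kpa, pvec)]
  } else {
    set.seed(seed)
    idx <- sample.int(nrow(th), min(n_draws, nrow(th)))
    # mean over draws of 1 / lambda_r(c_d, k_d, p), per pressure
    inv_lam <- vapply(pvec, function(p) {
      if (p == 0) return(1)
      l <- surface_lambda(surface, th[idx, "c"], th[idx, "k"], p)
      if (any(is.na(l))) l <- l[!is.na(l)]
      mean(1 / l)
    }, numeric(1))
    corrected <- samples$thickness_mm *
      inv_lam[match(samples$pressure_kpa, pvec)]
  }
  split_idx <- split(seq_len(nrow(samples)), samples$study_id)
  rec <- do.call(rbind, lapply(names(split_idx), function(lab) {
    i <- split_idx[[lab]]
    data.frame(
      label = lab,
      pressure_kpa = samples$pressure_kpa[i][1],
      n = length(i),
      original_mean = mean(samples$thickness_mm[i]),
      original_median = stats::median(samples$thickness_mm[i]),
      corrected_mean = mean(corrected[i]),
      corrected_median = stats::median(corrected[i]))
  }))
  rownames(rec) <- NULL
  structure(list(records = rec, corrected_values = corrected,
                 samples = samples, mode = mode),
            class = "aawt_correction")
}

#' @export
print.aawt_correction <- function(x, ...) {
  cat(sprintf("Undeforming correction (%s mode)\n", x$mode))
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' Inter-study range metrics before and after undeforming
#'
#' The spread between the most and least extreme study means (and
#' medians) quantifies the systematic inter-study shift caused by
#' different contact pressures; the percent reduction after correction
#' measures how much of that spread the compression model explains.
#'
#' @param records Data frame of correction records (the `records` element
#'   of [undeform_study()] output, or any data frame with columns
#'   `original_mean`, `original_median`, `corrected_mean`,
#'   `corrected_median`), one row per study; at least two rows.
#' @return A list with the mean and median ranges \[mm\] before and after
#'   correction and the percent reductions.
#' @export
shift_metrics <- function(records) {
  if (inherits(records, "aawt_correction")) records <- records$records
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  rng <- function(x) diff(range(x))
  before <- c(mean = rng(records$original_mean),
              median = rng(records$original_median))
  after <- c(mean = rng(records$corrected_mean),
             median = rng(records$corrected_median))
  list(range_before = before, range_after = after,
       pct_reduction = ifelse(before > 0, 100 * (1 - after / before),
                              0))
}

#' Boxplot statistics from theoretical quantiles
#'
#' Builds boxplot statistics from `n_quantiles` theoretical quantiles of
#' a distribution (plotting positions `i / (n + 1)`), the device used to
#' draw comparable boxplots for studies known only through a fitted or
#' predictive distribution rather than raw data.
#'
#' @param dist One of: a quantile function `function(p)`, an
#'   `aawt_predictive` object (empirical quantiles of its draws), a
#'   [summary_stat_study()] (quantiles of its method-of-moments lognormal
#'   fit), or a length-2 numeric `c(mu, sigma)` of a lognormal.
#' @param n_quantiles Number of quantiles (default 98, matching typical
#'   study sizes).
#' @return List with `quantiles` (the theoretical quantiles), and `stats`
#'   (min, lower quartile, median, upper quartile, max of those
#'   quantiles; whiskers span the extremes).
#' @export
theoretical_quantile_boxplot <- function(dist, n_quantiles = 98) {
  stopifnot(n_quantiles >= 5)
  qfun <-
    if (is.function(dist)) {
      dist
    } else if (inherits(dist, "aawt_predictive")) {
      function(p) stats::quantile(dist$draws, p, names = FALSE, type = 7)
    } else if (inherits(dist, "summary_stat_study")) {
      mom <- lognormal_mom(dist$M, dist$S)
      function(p) stats::qlnorm(p, mom["mu"], mom["sigma"])
    } else if (is.numeric(dist) && length(dist) == 2L) {
      function(p) stats::qlnorm(p, dist[1], dist[2])
    } else {
      stop("unsupported distribution specification")
    }
  qs <- qfun(seq_len(n_quantiles) / (n_quantiles + 1))
  st <- stats::quantile(qs, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                        type = 7)
  names(st) <- c("min", "q1", "median", "q3", "max")
  list(quantiles = qs, stats = st)
}
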
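# Shared fixtures, built lazily and memoized for the whole test run.
# Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Default response surface (pressures 0, 1, 16, 25 kPa).
fx_surface <- function() {
  fixture("surface", function() build_response_surface())
}

# Six-study synthetic cohort at the benchmark truth.
fx_cohort <- function() {
  fixture("cohort", function() generate_cohort(six_study_design(),
                                               seed = 20260901))
}

fx_truth <- function() {
  c(c = 5, k = 20, mu_pop = 0.85, sigma_pop = 0.26, sigma_pat = 0.18)
}

# Full model on the six-study cohort.
fx_model <- function() {
  fixture("model", function() {
    coh <- fx_cohort()
    build_model(coh$samples, coh$summaries, fx_surface())
  })
}

# Desk-scale posterior fit on the six-study cohort.
fx_fit <- function() {
  fixture("fit", function() {
    sample_posterior(fx_model(), chains = 4, iter = 2000, warmup = 1500,
                     seed = 20260902)
  })
}

# Small single-study zero-pressure cohort for cheap model checks.
fx_small_cohort <- function(n_pat = 60, n_samp = 120, pressure = 0,
                            seed = 3) {
  studies <- data.frame(label = "s1", pressure_kpa = pressure,
                        n_patients = n_pat, n_samples = n_samp,
                        summary_only = FALSE)
  design <- suppressWarnings(cohort_design(
    studies, truth = list(mu_pop = 0.85, sigma_pop = 0.26,
                          sigma_pat = 0.18, c = 5, k = 20)))
  generate_cohort(design, seed = seed)
}

# An aawt_draws object assembled from a plain matrix of draws (one
# chain), for testing summary utilities without a sampler run.
fake_draws <- function(mat, chains = 1) {
  stopifnot(is.matrix(mat))
  n <- nrow(mat) %/% chains
  a <- array(NA_real_, c(n, chains, ncol(mat)),
             dimnames = list(NULL, NULL, colnames(mat)))
  for (ch in seq_len(chains)) {
    a[, ch, ] <- mat[seq.int((ch - 1) * n + 1, ch * n), ]
  }
  structure(list(draws = a, chains = chains, iter = n, warmup = 0,
                 seed = NA_integer_, model = NULL),
            class = "aawt_draws")
}
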
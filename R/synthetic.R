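#' Define a multi-study synthetic cohort design
#'
#' Describes a set of studies (contact pressure, patient and sample
#' counts, whether the study reports raw values or only summary
#' statistics) plus the generating truth, so that synthetic cohorts with
#' the exact statistical structure the hierarchical model assumes can be
#' simulated and every stage of the pipeline tested without external
#' data.
#'
#' @param studies Data frame with columns `label`, `pressure_kpa`,
#'   `n_patients`, `n_samples`, `summary_only` (logical).  Summary-only
#'   studies must have zero pressure (the real ones used non-contact
#'   laser measurement).
#' @param truth Named list of generating parameters: `mu_pop`,
#'   `sigma_pop`, `sigma_pat` (log-scale population parameters), `c`, `k`
#'   \[kPa\], and optionally `k2`, `phi` (defaults 15 and 0.546).
#' @param shared Optional list of patient-sharing specs, each
#'   `list(studies = c(label_a, label_b), n = <count>)`: the two raw
#'   studies draw `n` of their patients from a common pool, as happens
#'   when one lab measures two specimen types from the same surgical
#'   harvests.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(studies, truth, shared = NULL) {
  req <- c("label", "pressure_kpa", "n_patients", "n_samples",
           "summary_only")
  stopifnot(is.data.frame(studies), all(req %in% names(studies)))
  if (anyDuplicated(studies$label)) stop("study labels must be unique")
  if (any(studies$pressure_kpa < 0)) stop("pressures must be >= 0")
  if (any(studies$n_patients < 1)) stop("each study needs >= 1 patient")
  if (any(studies$n_samples < studies$n_patients)) {
    stop("'n_samples' must be >= 'n_patients' (every patient sampled)")
  }
  if (any(studies$summary_only & studies$pressure_kpa > 0)) {
    stop("summary-only studies must have zero contact pressure")
  }
  for (nm in c("mu_pop", "sigma_pop", "sigma_pat", "c", "k")) {
    if (is.null(truth[[nm]])) stop("truth is missing '", nm, "'")
  }
  if (truth$sigma_pop < 0 || truth$sigma_pat < 0) {
    stop("truth variance components must be >= 0")
  }
  truth$k2 <- truth$k2 %||% 15
  truth$phi <- truth$phi %||% 0.546
  if (!is.null(shared)) {
    for (sh in shared) {
      stopifnot(length(sh$studies) == 2L, sh$n >= 1)
      if (!all(sh$studies %in% studies$label)) {
        stop("shared-patient spec names unknown studies")
      }
      idx <- match(sh$studies, studies$label)
      if (any(studies$summary_only[idx])) {
        stop("patients can only be shared between raw studies")
      }
      if (sh$n > min(studies$n_patients[idx])) {
        stop("shared patient count exceeds a study's patient count")
      }
    }
  }
  multi <- any(studies$n_samples > studies$n_patients & !studies$summary_only)
  if (!multi) {
    warning("no raw study has repeat samples per patient: ",
            "inter- and intra-patient variability will not be separately ",
            "identifiable from this design")
  }
  structure(list(studies = studies, truth = truth, shared = shared),
            class = "cohort_design")
}

#' The six-study benchmark design
#'
#' A synthetic design mirroring the structure of the six published AAA
#' wall-thickness data sets the model is meant for: contact pressures
#' (0, 0, 25, 0, 16, 1) kPa; raw-sample counts 39, 251, 90 and 92
#' (472 raw measurements in total); two studies reduced to summary
#' statistics only (N = 34, each sample treated as its own patient, and
#' N = 90); and a shared pool of 34 patients between the 16 kPa and
#' 1 kPa studies, which is what identifies the radial stiffness.
#'
#' @param mu_pop,sigma_pop,sigma_pat Generating population parameters
#'   (log scale); defaults 0.85, 0.26, 0.18.
#' @param c,k Generating stiffness \[kPa\]; defaults mid-range 5 and 20.
#' @return A [cohort_design()].
#' @export
six_study_design <- function(mu_pop = 0.85, sigma_pop = 0.26,
                             sigma_pat = 0.18, c = 5, k = 20) {
  studies <- data.frame(
    label = c("laser_raw", "summary_34", "micrometer_25kpa",
              "summary_90", "gauge_16kpa", "gauge_1kpa"),
    pressure_kpa = c(0, 0, 25, 0, 16, 1),
    n_patients = c(25L, 34L, 113L, 90L, 45L, 75L),
    n_samples = c(39L, 34L, 251L, 90L, 90L, 92L),
    summary_only = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  cohort_design(
    studies,
    truth = list(mu_pop = mu_pop, sigma_pop = sigma_pop,
                 sigma_pat = sigma_pat, c = c, k = k),
    shared = list(list(studies = c("gauge_16kpa", "gauge_1kpa"), n = 34)))
}

#' Generate a synthetic cohort from a design
#'
#' Simulates the generative model exactly: patient locations
#' `mu_i ~ N(mu_pop, sigma_pop)` (drawn once per patient, shared across
#' studies for shared patients), undeformed thicknesses
#' `T_ij ~ LN(mu_i, sigma_pat)`, and deformed measurements
#' `t_ij = lambda_r(c, k, p) * T_ij` with the stretch from exact
#' inversion of the compression model.  Summary-only studies emit the
#' `(M, S, N)` of their undeformed thicknesses and discard the raw
#' values.  Each raw patient receives at least one sample; remaining
#' samples are assigned to patients uniformly at random.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; the output is reproducible.
#' @return List with elements `samples` (data frame of raw measurements),
#'   `summaries` (list of [summary_stat_study()]), and `truth` (the
#'   generating parameters, per-study stretches, patient effects and
#'   latent undeformed thicknesses).
#' @export
generate_cohort <- function(design, seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  st <- design$studies
  tr <- design$truth
  par <- hgo_params(tr$c, tr$k, k2 = tr$k2, phi = tr$phi)
  lam <- vapply(st$pressure_kpa, function(p) {
    if (p == 0) 1 else invert_pressure(par, p)
  }, numeric(1))

  # patient registry: shared pools first, then study-private patients
  pat_of_study <- vector("list", nrow(st))
  names(pat_of_study) <- st$label
  counter <- 0L
  new_ids <- function(n) {
    ids <- sprintf("P%04d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  if (!is.null(design$shared)) {
    for (sh in design$shared) {
      pool <- new_ids(sh$n)
      for (lab in sh$studies) {
        pat_of_study[[lab]] <- pool
      }
    }
  }
  for (i in seq_len(nrow(st))) {
    lab <- st$label[i]
    have <- length(pat_of_study[[lab]])
    need <- st$n_patients[i] - have
    if (need < 0) stop("shared pool larger than study patient count")
    pat_of_study[[lab]] <- c(pat_of_study[[lab]], new_ids(need))
  }
  all_pat <- unique(unlist(pat_of_study))
  mu_i <- stats::rnorm(length(all_pat), tr$mu_pop, tr$sigma_pop)
  names(mu_i) <- all_pat

  samples <- NULL
  latent <- NULL
  summaries <- list()
  for (i in seq_len(nrow(st))) {
    lab <- st$label[i]
    pats <- pat_of_study[[lab]]
    extra <- st$n_samples[i] - st$n_patients[i]
    assign_pat <- c(pats,
                    if (extra > 0) sample(pats, extra, replace = TRUE))
    assign_pat <- sort(assign_pat)
    sample_id <- stats::ave(seq_along(assign_pat), assign_pat,
                            FUN = seq_along)
    T_ij <- stats::rlnorm(length(assign_pat), mu_i[assign_pat],
                          tr$sigma_pat)
    if (st$summary_only[i]) {
      summaries[[length(summaries) + 1L]] <-
        summary_stat_study(mean(T_ij), stats::sd(T_ij), length(T_ij),
                           label = lab)
    } else {
      samples <- rbind(samples, data.frame(
        study_id = lab, patient_id = assign_pat,
        sample_id = sprintf("%s_s%02d", assign_pat, sample_id),
        thickness_mm = lam[i] * T_ij,
        pressure_kpa = st$pressure_kpa[i]))
    }
    latent <- rbind(latent, data.frame(
      study_id = lab, patient_id = assign_pat,
      T_mm = T_ij, lambda_r = lam[i]))
  }
  rownames(samples) <- NULL
  list(samples = samples, summaries = summaries,
       truth = list(params = tr, lambda_r = stats::setNames(lam, st$label),
                    mu_i = mu_i, latent = latent, seed = seed))
}
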
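#' Validate a cohort table of raw thickness measurements
#'
#' Checks the schema used throughout the package: columns `study_id`,
#' `patient_id`, `sample_id`, `thickness_mm`, `pressure_kpa`; positive
#' thicknesses; non-negative pressures; unique
#' `(study_id, patient_id, sample_id)` keys.  Violations are reported
#' with their row numbers.
#'
#' @param samples Data frame.
#' @return The validated data frame with id columns coerced to character.
#' @export
validate_cohort <- function(samples) {
  req <- c("study_id", "patient_id", "sample_id", "thickness_mm",
           "pressure_kpa")
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("cohort table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  samples$study_id <- as.character(samples$study_id)
  samples$patient_id <- as.character(samples$patient_id)
  samples$sample_id <- as.character(samples$sample_id)
  if (nrow(samples) == 0) return(samples[req])
  bad_rows <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(which(cond), 20), collapse = ", ")))
    }
  }
  bad_rows(!is.finite(samples$thickness_mm) | samples$thickness_mm <= 0,
           "non-positive or missing thickness_mm")
  bad_rows(!is.finite(samples$pressure_kpa) | samples$pressure_kpa < 0,
           "negative or missing pressure_kpa")
  key <- paste(samples$study_id, samples$patient_id, samples$sample_id,
               sep = "\r")
  bad_rows(duplicated(key), "duplicate (study_id, patient_id, sample_id)")
  samples[req]
}

#' Read a cohort CSV
#'
#' @param path CSV file with the columns described in
#'   [validate_cohort()].
#' @return Validated data frame of measurements.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort CSV
#'
#' @param samples Validated cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(samples, path) {
  samples <- validate_cohort(samples)
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Read summary-statistics studies from JSON
#'
#' Expects a JSON array of objects with fields `label`, `mean_mm`,
#' `sd_mm`, `n`.
#'
#' @param path JSON file path.
#' @return List of [summary_stat_study()] objects.
#' @export
read_summaries <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(s) {
    for (f in c("label", "mean_mm", "sd_mm", "n")) {
      if (is.null(s[[f]])) stop("summary entry is missing field '", f, "'")
    }
    summary_stat_study(s$mean_mm, s$sd_mm, s$n, label = s$label)
  })
}

#' Write summary-statistics studies to JSON
#'
#' @param summaries List of [summary_stat_study()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  stopifnot(all(vapply(summaries, inherits, logical(1),
                       "summary_stat_study")))
  obj <- lapply(summaries, function(s) {
    list(label = s$label, mean_mm = s$M, sd_mm = s$S, n = s$N)
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write posterior draws to CSV (long format)
#'
#' One row per (chain, draw, parameter) triple.
#'
#' @param draws An `aawt_draws` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "aawt_draws"))
  a <- draws$draws
  params <- dimnames(a)[[3]]
  long <- do.call(rbind, lapply(params, function(p) {
    data.frame(chain = rep(seq_len(dim(a)[2]), each = dim(a)[1]),
               draw = rep(seq_len(dim(a)[1]), times = dim(a)[2]),
               parameter = p,
               value = as.vector(a[, , p]))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' Reconstructs the draw array (without model or sampler metadata).
#'
#' @param path CSV path.
#' @return An `aawt_draws`-like object usable by [posterior_summary()],
#'   [diagnostics()] and [posterior_predictive()] (its `model` field is
#'   `NULL`).
#' @export
read_draws <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("chain", "draw", "parameter", "value")
  stopifnot(all(req %in% names(long)))
  params <- unique(long$parameter)
  chains <- max(long$chain)
  iter <- max(long$draw)
  a <- array(NA_real_, c(iter, chains, length(params)),
             dimnames = list(NULL, NULL, params))
  for (p in params) {
    sub <- long[long$parameter == p, ]
    a[cbind(sub$draw, sub$chain, match(p, params))] <- sub$value
  }
  structure(list(draws = a, chains = chains, iter = iter,
                 warmup = NA_integer_, seed = NA_integer_, model = NULL),
            class = "aawt_draws")
}
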
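#' Assemble a pipeline run configuration
#'
#' Collects paths, surface-build settings, priors, sampler settings and
#' mode flags for [run_pipeline()].  `config` may also be read from a
#' YAML or JSON file; values given there override the defaults shown
#' here.
#'
#' @param data Cohort CSV path or a validated data frame (`NULL` for
#'   none).
#' @param summaries Summaries JSON path or a list of
#'   [summary_stat_study()] (`NULL` for none).
#' @param surface Serialized surface path (reused if it exists), or
#'   `NULL` to build one from `surface_spec`.
#' @param out_dir Output directory (`NULL` disables file output).
#' @param surface_spec Arguments for [build_response_surface()] (the
#'   pressures are completed from the data automatically).
#' @param priors Named list of [prior_dist()] objects.
#' @param chains,iter,warmup Sampler settings (desk scale by default).
#' @param paper_scale If `TRUE`, sample 20 chains x 10,000 draws.
#' @param n_predictive Predictive draw count (defaults to all posterior
#'   draws).
#' @param seed Integer seed governing every random stage.
#' @return A `run_config` list.
#' @export
run_config <- function(data = NULL, summaries = NULL, surface = NULL,
                       out_dir = NULL, surface_spec = list(),
                       priors = default_priors(),
                       chains = 4, iter = 2000, warmup = 1500,
                       paper_scale = FALSE, n_predictive = NULL,
                       seed = 1) {
  structure(list(data = data, summaries = summaries, surface = surface,
                 out_dir = out_dir, surface_spec = surface_spec,
                 priors = priors, chains = chains, iter = iter,
                 warmup = warmup, paper_scale = paper_scale,
                 n_predictive = n_predictive, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Scalar fields of [run_config()] may be set in the file; priors may be
#' given as `priors: {c: {dist: uniform, min: 0, max: 10}, ...}`.
#'
#' @param path YAML (requires the yaml package) or JSON file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  priors <- default_priors()
  if (!is.null(obj$priors)) {
    for (nm in names(obj$priors)) {
      p <- obj$priors[[nm]]
      priors[[nm]] <- do.call(prior_dist, p)
    }
  }
  args <- obj[intersect(names(obj),
                        setdiff(names(formals(run_config)), "priors"))]
  args$priors <- priors
  do.call(run_config, args)
}

config_hash <- function(config) {
  plain <- rapply(unclass(config), function(x) {
    if (is.function(x)) "<function>" else x
  }, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, digits = 12, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full estimation pipeline
#'
#' Sequences the stages: load or build the response surface; load the
#' data; build the hierarchical model (including summary-study
#' likelihood surfaces); sample the posterior; compute diagnostics, the
#' posterior predictive distribution with its lognormal approximation
#' and tail table; and the per-study undeforming corrections with range
#' metrics.  Every artifact is stamped with the configuration hash and
#' seed.  If a stage fails, previously completed outputs are kept and
#' the error names the failing stage.
#'
#' @param config A [run_config()] (or a path accepted by
#'   [read_config()]).
#' @param quiet Suppress stage messages.
#' @return A list with elements `surface`, `model`, `draws`,
#'   `diagnostics`, `predictive`, `lognormal_fit`, `tail_table`,
#'   `correction`, `shift`, `summary`, plus `config_hash` and `seed`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- list(config_hash = config_hash(config), seed = config$seed)
  stage <- function(name, expr) {
    say("[aawt] stage: %s", name)
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("[aawt]   done in %.1fs", as.numeric(Sys.time() - t0, "secs"))
    val
  }

  samples <- stage("load-data", {
    if (is.character(config$data)) read_cohort(config$data)
    else if (!is.null(config$data)) validate_cohort(config$data)
    else NULL
  })
  summaries <- stage("load-summaries", {
    if (is.character(config$summaries)) read_summaries(config$summaries)
    else config$summaries %||% list()
  })

  out$surface <- stage("surface", {
    if (is.character(config$surface) && file.exists(config$surface)) {
      read_surface(config$surface)
    } else {
      spec <- config$surface_spec
      data_p <- if (!is.null(samples)) unique(samples$pressure_kpa) else 0
      spec$pressures <- sort(unique(c(0, spec$pressures, data_p)))
      do.call(build_response_surface, spec)
    }
  })
  say("[aawt]   emulator error %.2e", out$surface$achieved_error)

  out$model <- stage("model", {
    build_model(samples, summaries, out$surface, priors = config$priors)
  })
  out$draws <- stage("sample", {
    sample_posterior(out$model, chains = config$chains,
                     iter = config$iter, warmup = config$warmup,
                     seed = config$seed,
                     paper_scale = config$paper_scale)
  })
  out$diagnostics <- stage("diagnostics", diagnostics(out$draws))
  say("[aawt]   max R-hat %.4f", max(out$diagnostics$summary$rhat))

  out$predictive <- stage("predictive", {
    n_pred <- config$n_predictive %||%
      max(20000L, config$chains * config$iter)
    posterior_predictive(out$draws, n = n_pred, seed = config$seed)
  })
  out$lognormal_fit <- stage("lognormal-fit", {
    fit_lognormal_approx(out$predictive)
  })
  out$tail_table <- stage("tail-table", {
    t1 <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
    data.frame(
      threshold_mm = t1,
      predictive_pct = 100 * vapply(t1, function(z) {
        mean(out$predictive$draws < z)
      }, numeric(1)),
      lognormal_pct = tail_probability(out$lognormal_fit["mu"],
                                       out$lognormal_fit["sigma"], t1))
  })
  if (!is.null(samples)) {
    out$correction <- stage("correction", {
      undeform_study(samples, out$draws)
    })
    if (nrow(out$correction$records) >= 2) {
      out$shift <- stage("shift-metrics", shift_metrics(out$correction))
    }
  }

  q <- stats::quantile(out$predictive$draws, c(0.025, 0.5, 0.975))
  out$summary <- list(
    config_hash = out$config_hash, seed = config$seed,
    parameters = posterior_summary(out$draws),
    rhat = out$diagnostics$summary,
    predictive = list(mean_mm = mean(out$predictive$draws),
                      median_mm = unname(q[2]),
                      pi95_mm = unname(q[c(1, 3)]),
                      lognormal_mu = unname(out$lognormal_fit["mu"]),
                      lognormal_sigma = unname(out$lognormal_fit["sigma"])),
    shift = out$shift)

  if (!is.null(config$out_dir)) {
    stage("write-outputs", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_surface(out$surface,
                    file.path(config$out_dir, "surface.json"))
      write_draws(out$draws, file.path(config$out_dir, "draws.csv"))
      utils::write.csv(out$tail_table,
                       file.path(config$out_dir, "tail_table.csv"),
                       row.names = FALSE)
      if (!is.null(out$correction)) {
        utils::write.csv(out$correction$records,
                         file.path(config$out_dir, "corrections.csv"),
                         row.names = FALSE)
      }
      jsonlite::write_json(out$summary,
                           file.path(config$out_dir, "summary.json"),
                           digits = 10, auto_unbox = TRUE, force = TRUE,
                           pretty = TRUE)
    })
  }
  out
}
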